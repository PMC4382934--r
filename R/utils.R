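# internal helpers shared across modules

#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr across all_of
NULL

# day tolerance for floating comparisons on day quantities
.day_tol <- 1e-9

as_date_strict <- function(x, format = NULL) {
  if (inherits(x, "Date")) return(x)
  if (is.null(format)) as.Date(x) else as.Date(x, format = format)
}

# Number of calendar days of [from, to) covered by the union of half-open
# stay intervals [admission, discharge). `stays` must be merged (non
# overlapping); open discharges are +Inf. Vectorised over nothing: one
# interval at a time, stays as a data frame with numeric adm/dis columns.
days_in_stays <- function(from, to, adm, dis) {
  if (length(adm) == 0L || to <= from) return(0)
  sum(pmax(0, pmin(to, dis) - pmax(from, adm)))
}

# positive scalar check for parameter validation
chk_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number, got %s",
                  what, deparse(x)))
  }
  invisible(x)
}

chk_unit <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  what, deparse(x)))
  }
  invisible(x)
}

# ATC code grammar: L, LDD, LDDL, LDDLL, LDDLLDD (levels 1/3/4/5/7)
atc_pattern <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

is_valid_atc <- function(x) {
  !is.na(x) & grepl(atc_pattern, x)
}
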