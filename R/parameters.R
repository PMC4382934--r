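#' Global modelling constants
#'
#' The global level of the three-level parameter hierarchy
#' (global -> ATC class -> drug package). Global limits restrict period
#' construction everywhere and cannot be overridden by finer levels; they
#' stop purchases being joined over implausibly long intervals (long
#' hospital stays, doses too low to be realistic).
#'
#' @param max_refill_gap_days Maximum refill time (days) used in the sliding
#'   temporal average: a larger purchase gap restarts the average. Default 300.
#' @param max_hospital_days_in_period Longest continuous hospital stay (days)
#'   over which a period may be extended after its last purchase. Default 30.
#' @param max_ddd_per_day Upper cap on any applied daily dose (DDD/day),
#'   guarding against purchases only days apart. Default 10.
#' @param max_single_purchase_days Hard cap on the length of a
#'   single-purchase period, regardless of the purchased amount. Default 150.
#' @param dvar Weight on the coefficient of variation in the
#'   purchase-regularity multiplier `1 + dvar * cv`. Default 0.5.
#' @param adherence_slack Non-perfect-adherence allowance used when a
#'   single-purchase length is derived from a typical dose. Default 0.2.
#' @param mode_min_purchases A learned package refill mode is only used when
#'   its joined count strictly exceeds this. Default 10.
#' @param refill_source_min_purchases Minimum number of purchases a period
#'   must contain to contribute refill-length observations. Default 6.
#' @param ddd_avg_min_purchases Minimum purchases in a segment for the
#'   sliding dose average to be computed. Default 3.
#'
#' @return A list of class `rx_global_params`.
#' @examples
#' global_params()
#' global_params(max_single_purchase_days = 120)
#' @export
global_params <- function(max_refill_gap_days = 300,
                          max_hospital_days_in_period = 30,
                          max_ddd_per_day = 10,
                          max_single_purchase_days = 150,
                          dvar = 0.5,
                          adherence_slack = 0.2,
                          mode_min_purchases = 10,
                          refill_source_min_purchases = 6,
                          ddd_avg_min_purchases = 3) {
  chk_pos(max_refill_gap_days, "max_refill_gap_days")
  chk_pos(max_hospital_days_in_period, "max_hospital_days_in_period")
  chk_pos(max_ddd_per_day, "max_ddd_per_day")
  chk_pos(max_single_purchase_days, "max_single_purchase_days")
  chk_unit(dvar, "dvar")
  chk_unit(adherence_slack, "adherence_slack")
  chk_pos(mode_min_purchases, "mode_min_purchases")
  chk_pos(refill_source_min_purchases, "refill_source_min_purchases")
  chk_pos(ddd_avg_min_purchases, "ddd_avg_min_purchases")
  structure(
    list(max_refill_gap_days = max_refill_gap_days,
         max_hospital_days_in_period = max_hospital_days_in_period,
         max_ddd_per_day = max_ddd_per_day,
         max_single_purchase_days = max_single_purchase_days,
         dvar = dvar,
         adherence_slack = adherence_slack,
         mode_min_purchases = mode_min_purchases,
         refill_source_min_purchases = refill_source_min_purchases,
         ddd_avg_min_purchases = ddd_avg_min_purchases),
    class = "rx_global_params")
}

#' Assemble a parameter space
#'
#' Bundles the three parameter levels. ATC-class parameters are keyed by an
#' ATC prefix at any level of the classification (e.g. `"N"`, `"N05A"`,
#' `"N05AH02"`); package parameters are keyed by the package (vnr) number
#' and represent the finest expert level, overriding ATC-class values.
#'
#' @param global A [global_params()] object.
#' @param atc A data frame with columns `atc_prefix`, `min_ddd_per_day`,
#'   `common_ddd_per_day`, `min_period_days`, `max_refill_days`; or `NULL`.
#' @param vnr A data frame with columns `vnr`, `min_refill_days`,
#'   `max_refill_days`, `typical_refill_days`, `ddd_per_day_at_min`,
#'   `ddd_per_day_at_max`, `ddd_per_day_typical`; or `NULL`.
#'
#' @return A list of class `rx_parameter_space` with elements `global`,
#'   `atc`, `vnr`.
#' @examples
#' sp <- parameter_space(
#'   atc = data.frame(atc_prefix = "N05A", min_ddd_per_day = 0.1,
#'                    common_ddd_per_day = 1, min_period_days = 10,
#'                    max_refill_days = 120))
#' resolve_atc("N05AH02", sp)
#' @export
parameter_space <- function(global = global_params(), atc = NULL, vnr = NULL) {
  if (!inherits(global, "rx_global_params")) {
    global <- do.call(global_params, as.list(global))
  }
  atc <- validate_atc_params(atc)
  vnr <- validate_vnr_params(vnr)
  structure(list(global = global, atc = atc, vnr = vnr),
            class = "rx_parameter_space")
}

atc_param_cols <- c("atc_prefix", "min_ddd_per_day", "common_ddd_per_day",
                    "min_period_days", "max_refill_days")
vnr_param_cols <- c("vnr", "min_refill_days", "max_refill_days",
                    "typical_refill_days", "ddd_per_day_at_min",
                    "ddd_per_day_at_max", "ddd_per_day_typical")

validate_atc_params <- function(atc) {
  if (is.null(atc)) {
    return(tibble::tibble(atc_prefix = character(), min_ddd_per_day = double(),
                          common_ddd_per_day = double(),
                          min_period_days = double(), max_refill_days = double()))
  }
  atc <- tibble::as_tibble(atc)
  missing <- setdiff(atc_param_cols, names(atc))
  if (length(missing)) {
    abort(paste0("ATC parameter table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  atc <- atc[atc_param_cols]
  dup <- atc$atc_prefix[duplicated(atc$atc_prefix)]
  if (length(dup)) {
    abort(paste0("duplicate ATC prefix key(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad <- !is_valid_atc(atc$atc_prefix)
  if (any(bad)) {
    abort(paste0("invalid ATC prefix(es): ",
                 paste(atc$atc_prefix[bad], collapse = ", ")))
  }
  num <- setdiff(atc_param_cols, "atc_prefix")
  for (col in num) {
    v <- atc[[col]]
    if (any(!is.na(v) & v <= 0)) {
      abort(sprintf("ATC parameter `%s` must be positive (prefix %s)",
                    col, paste(atc$atc_prefix[!is.na(v) & v <= 0], collapse = ", ")))
    }
  }
  viol <- !is.na(atc$min_ddd_per_day) & !is.na(atc$common_ddd_per_day) &
    atc$min_ddd_per_day > atc$common_ddd_per_day
  if (any(viol)) {
    abort(paste0("min_ddd_per_day > common_ddd_per_day for prefix ",
                 paste(atc$atc_prefix[viol], collapse = ", ")))
  }
  atc
}

validate_vnr_params <- function(vnr) {
  if (is.null(vnr)) {
    return(tibble::tibble(vnr = character(), min_refill_days = double(),
                          max_refill_days = double(), typical_refill_days = double(),
                          ddd_per_day_at_min = double(), ddd_per_day_at_max = double(),
                          ddd_per_day_typical = double()))
  }
  vnr <- tibble::as_tibble(vnr)
  missing <- setdiff(vnr_param_cols, names(vnr))
  if (length(missing)) {
    abort(paste0("package (vnr) parameter table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  vnr <- vnr[vnr_param_cols]
  vnr$vnr <- as.character(vnr$vnr)
  dup <- vnr$vnr[duplicated(vnr$vnr)]
  if (length(dup)) {
    abort(paste0("duplicate vnr key(s): ", paste(unique(dup), collapse = ", ")))
  }
  ord_ok <- function(a, b) is.na(a) | is.na(b) | a <= b
  viol <- !(ord_ok(vnr$min_refill_days, vnr$typical_refill_days) &
              ord_ok(vnr$typical_refill_days, vnr$max_refill_days) &
              ord_ok(vnr$min_refill_days, vnr$max_refill_days))
  if (any(viol)) {
    abort(paste0("refill lengths must satisfy min <= typical <= max for vnr ",
                 paste(vnr$vnr[viol], collapse = ", ")))
  }
  num <- setdiff(vnr_param_cols, "vnr")
  for (col in num) {
    v <- vnr[[col]]
    if (any(!is.na(v) & v <= 0)) {
      abort(sprintf("package parameter `%s` must be positive (vnr %s)",
                    col, paste(vnr$vnr[!is.na(v) & v <= 0], collapse = ", ")))
    }
  }
  vnr
}

#' Load a parameter space from configuration files
#'
#' The global file is YAML (keys as in [global_params()]); the ATC and
#' package tables are delimited text with the column names documented in
#' [parameter_space()]. Any file may be `NULL`, in which case the defaults
#' (global) or an empty table (atc/vnr) apply. Commented templates ship in
#' `inst/extdata/`.
#'
#' @param global_file,atc_file,vnr_file Paths or `NULL`.
#' @param delim Field delimiter of the ATC/vnr tables, default `","`.
#' @return An `rx_parameter_space`.
#' @export
read_parameter_space <- function(global_file = NULL, atc_file = NULL,
                                 vnr_file = NULL, delim = ",") {
  global <- global_params()
  if (!is.null(global_file)) {
    vals <- yaml::read_yaml(global_file)
    unknown <- setdiff(names(vals), names(formals(global_params)))
    if (length(unknown)) {
      abort(paste0("unknown global parameter(s): ", paste(unknown, collapse = ", ")))
    }
    global <- do.call(global_params, vals)
  }
  read_tbl <- function(path) {
    if (is.null(path)) return(NULL)
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE, comment = "#")
  }
  parameter_space(global = global, atc = read_tbl(atc_file),
                  vnr = read_tbl(vnr_file))
}

#' Resolve ATC-class parameters for a code
#'
#' Returns the parameter row whose prefix is the longest defined prefix of
#' `atc` — the finest level of the classification hierarchy with an entry —
#' or `NULL` when no prefix matches.
#'
#' @param atc A single ATC code (1--7 characters).
#' @param space An `rx_parameter_space`.
#' @return A one-row tibble of ATC parameters, or `NULL`.
#' @export
resolve_atc <- function(atc, space) {
  stopifnot(inherits(space, "rx_parameter_space"))
  if (is.null(atc) || length(atc) != 1L || is.na(atc) || !nzchar(atc)) {
    return(NULL)
  }
  tbl <- space$atc
  if (nrow(tbl) == 0L) return(NULL)
  hit <- startsWith(atc, tbl$atc_prefix)
  if (!any(hit)) return(NULL)
  cand <- tbl[hit, ]
  cand[which.max(nchar(cand$atc_prefix)), ]
}

#' Resolve package (vnr) parameters
#'
#' Exact-key lookup of the package-level parameters; `NULL` for a missing
#' vnr or an unknown key. Package parameters are the finest expert level
#' and take precedence over ATC-class values where both define a limit.
#'
#' @param vnr A single package identifier, or `NA`.
#' @param space An `rx_parameter_space`.
#' @return A one-row tibble of package parameters, or `NULL`.
#' @export
resolve_package <- function(vnr, space) {
  stopifnot(inherits(space, "rx_parameter_space"))
  if (is.null(vnr) || length(vnr) != 1L || is.na(vnr)) return(NULL)
  tbl <- space$vnr
  i <- match(as.character(vnr), tbl$vnr)
  if (is.na(i)) return(NULL)
  tbl[i, ]
}

#' @export
print.rx_parameter_space <- function(x, ...) {
  cat("<rx_parameter_space>\n")
  cat(sprintf("  ATC-class entries: %d; package (vnr) entries: %d\n",
              nrow(x$atc), nrow(x$vnr)))
  g <- x$global
  cat(sprintf(paste0("  global: max refill gap %g d; max hospital stay %g d; ",
                     "max dose %g DDD/d; single purchase cap %g d\n"),
              g$max_refill_gap_days, g$max_hospital_days_in_period,
              g$max_ddd_per_day, g$max_single_purchase_days))
  invisible(x)
}
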