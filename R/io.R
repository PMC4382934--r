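#' Read purchase records
#'
#' Reads one dispensing event per row from delimited text. The expected
#' columns are `person_id`, `date`, `atc`, `vnr`, `n_packages`,
#' `ddd_amount`, `dose_dispensing`; register exports with other headers are
#' adapted through `col_map` without touching the file. Rows whose date
#' cannot be parsed are rejected (returned in the `"rejected"` attribute
#' with their row numbers), never silently coerced. Missing vnr or DDD stay
#' missing — they are meaningful states downstream, not zeros.
#'
#' @param file Path or connection to a delimited text file with a header row.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(person_id = "HENKILO", date = "OSTOPV")`.
#' @param delim Field delimiter (default `","`).
#' @param date_format Optional date format string; by default dates must be
#'   ISO-8601 (`YYYY-MM-DD`).
#' @return A tibble of purchases (possibly zero rows), dates as `Date`,
#'   with attribute `rejected` holding a tibble (`row`, `reason`) of
#'   unparseable rows.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("person_id,date,atc,vnr,n_packages,ddd_amount,dose_dispensing",
#'              "P1,2005-03-01,N05AH02,012345,1,30,FALSE"), f)
#' read_purchases(f)
#' @export
read_purchases <- function(file, col_map = NULL, delim = ",",
                           date_format = NULL) {
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  raw <- rename_mapped(raw, col_map)
  need <- c("person_id", "date")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("purchase file lacks required column(s): ",
                 paste(missing, collapse = ", "),
                 " (map register headers with `col_map`)"))
  }
  for (opt in c("atc", "vnr", "n_packages", "ddd_amount", "dose_dispensing")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }
  n <- nrow(raw)
  dates <- if (is.null(date_format)) {
    as.Date(raw$date, optional = TRUE)
  } else {
    as.Date(raw$date, format = date_format, optional = TRUE)
  }
  bad <- which(is.na(dates) | is.na(raw$person_id))
  rejected <- tibble::tibble(
    row = bad,
    reason = ifelse(is.na(raw$person_id[bad]), "missing person_id",
                    "unparseable date"))
  if (nrow(rejected)) {
    warn(sprintf("%d row(s) rejected while reading purchases (see attr(., \"rejected\"))",
                 nrow(rejected)))
  }
  keep <- setdiff(seq_len(n), bad)
  out <- tibble::tibble(
    person_id = raw$person_id[keep],
    date = dates[keep],
    atc = raw$atc[keep],
    vnr = raw$vnr[keep],
    n_packages = parse_count(raw$n_packages[keep], default = 1L),
    ddd_amount = suppressWarnings(as.numeric(raw$ddd_amount[keep])),
    dose_dispensing = parse_flag(raw$dose_dispensing[keep]))
  if (any(!is.na(out$n_packages) & out$n_packages < 1L)) {
    abort("n_packages must be >= 1 where present")
  }
  if (any(!is.na(out$ddd_amount) & out$ddd_amount < 0)) {
    abort("ddd_amount must be >= 0 where present")
  }
  attr(out, "rejected") <- rejected
  out
}

rename_mapped <- function(tbl, col_map) {
  if (is.null(col_map)) return(tbl)
  for (canon in names(col_map)) {
    src <- col_map[[canon]]
    if (!src %in% names(tbl)) {
      abort(sprintf("column `%s` (mapped to `%s`) not found in file", src, canon))
    }
    names(tbl)[names(tbl) == src] <- canon
  }
  tbl
}

parse_count <- function(x, default = NA_integer_) {
  v <- suppressWarnings(as.integer(x))
  v[is.na(v) & (is.na(x) | !nzchar(x))] <- default
  v
}

parse_flag <- function(x) {
  v <- toupper(trimws(ifelse(is.na(x), "", x)))
  out <- v %in% c("TRUE", "T", "1", "YES", "Y")
  out
}

#' Read institutional-stay records
#'
#' Hospital or long-term-care intervals during which purchasing pauses.
#' Expected columns `person_id`, `admission`, `discharge`; an empty
#' discharge means the person is still in care at data end (open stay).
#' Per person, overlapping or abutting stays are merged so stored stays
#' never overlap.
#'
#' @inheritParams read_purchases
#' @return A tibble (`person_id`, `admission`, `discharge`) of merged
#'   stays; `discharge` is `NA` for open stays.
#' @export
read_stays <- function(file, col_map = NULL, delim = ",", date_format = NULL) {
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  raw <- rename_mapped(raw, col_map)
  missing <- setdiff(c("person_id", "admission", "discharge"), names(raw))
  if (length(missing)) {
    abort(paste0("stay file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  parse_d <- function(x) {
    if (is.null(date_format)) as.Date(x, optional = TRUE)
    else as.Date(x, format = date_format, optional = TRUE)
  }
  out <- tibble::tibble(
    person_id = raw$person_id,
    admission = parse_d(raw$admission),
    discharge = parse_d(raw$discharge))
  if (any(is.na(out$admission))) {
    abort("every stay needs a parseable admission date")
  }
  merge_stays(out)
}

#' Merge overlapping institutional stays
#'
#' @param stays A tibble with `person_id`, `admission`, `discharge` (`NA`
#'   discharge = open).
#' @return The same tibble with, per person, overlapping or abutting stays
#'   collapsed into one; closed stays satisfy `discharge >= admission`.
#' @export
merge_stays <- function(stays) {
  stays <- tibble::as_tibble(stays)
  if (nrow(stays) == 0L) return(stays)
  bad <- !is.na(stays$discharge) & stays$discharge < stays$admission
  if (any(bad)) abort("stay discharge precedes admission")
  stays |>
    dplyr::mutate(.dis = dplyr::if_else(is.na(.data$discharge),
                                        as.Date("9999-12-31"), .data$discharge)) |>
    dplyr::arrange(.data$person_id, .data$admission) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(.grp = cumsum(
      dplyr::lag(cummax(as.numeric(.data$.dis)), default = -Inf) <
        as.numeric(.data$admission))) |>
    dplyr::group_by(.data$person_id, .data$.grp) |>
    dplyr::summarise(admission = min(.data$admission),
                     discharge = max(.data$.dis), .groups = "drop") |>
    dplyr::mutate(discharge = dplyr::if_else(
      .data$discharge == as.Date("9999-12-31"), as.Date(NA), .data$discharge)) |>
    dplyr::select("person_id", "admission", "discharge")
}

#' Harmonize ATC codes and DDD amounts
#'
#' Applies a code map: outdated ATC codes are replaced by their current
#' code, and missing DDD amounts are filled from a per-package DDD value
#' times the number of packages, where a mapping exists. Purchases that
#' still lack a valid ATC code afterwards are routed to the exceptions sink
#' (column `exception`) rather than dropped, keeping the pipeline total and
#' auditable: every input row ends up either in a history or in the sink.
#'
#' @param purchases A purchases tibble ([read_purchases()]).
#' @param map A [code_map()].
#' @return The purchases tibble with an added `exception` column (`NA` for
#'   usable rows, a reason string otherwise). Idempotent: applying twice
#'   changes nothing.
#' @export
harmonize_purchases <- function(purchases, map = code_map()) {
  stopifnot(inherits(map, "rx_code_map"))
  p <- tibble::as_tibble(purchases)
  if (!nrow(p)) {
    p$exception <- character(0)
    return(p)
  }
  i <- match(p$atc, map$atc_renames$old)
  p$atc <- ifelse(!is.na(i), map$atc_renames$new[i], p$atc)
  j <- match(p$vnr, map$ddd_fills$vnr)
  fill <- is.na(p$ddd_amount) & !is.na(j)
  p$ddd_amount[fill] <- map$ddd_fills$ddd_per_package[j[fill]] *
    dplyr::coalesce(p$n_packages[fill], 1L)
  p$exception <- dplyr::case_when(
    is.na(p$atc) | !nzchar(p$atc) ~ "missing ATC code",
    !is_valid_atc(p$atc) ~ "invalid ATC code",
    TRUE ~ NA_character_)
  p
}

#' Build a code map
#'
#' @param atc_renames Data frame (`old`, `new`): outdated ATC code to its
#'   current code. Must be acyclic in one step: no `new` value may itself
#'   appear as an `old` key, so applying the map twice equals applying once.
#' @param ddd_fills Data frame (`vnr`, `ddd_per_package`): DDD content per
#'   package, used to fill missing dispensed amounts.
#' @return An object of class `rx_code_map`.
#' @export
code_map <- function(atc_renames = NULL, ddd_fills = NULL) {
  atc_renames <- if (is.null(atc_renames)) {
    tibble::tibble(old = character(), new = character())
  } else tibble::as_tibble(atc_renames)[c("old", "new")]
  ddd_fills <- if (is.null(ddd_fills)) {
    tibble::tibble(vnr = character(), ddd_per_package = double())
  } else tibble::as_tibble(ddd_fills)[c("vnr", "ddd_per_package")]
  if (any(atc_renames$new %in% atc_renames$old)) {
    abort("atc_renames must be acyclic: a current code cannot also be an old key")
  }
  ddd_fills$vnr <- as.character(ddd_fills$vnr)
  structure(list(atc_renames = atc_renames, ddd_fills = ddd_fills),
            class = "rx_code_map")
}

#' Arrange purchases into chronological per-person, per-ATC histories
#'
#' Orders each person's purchases of one ATC code by date and merges
#' same-day purchases of the same code into one row (summing the DDD amount
#' and package count). Gap arithmetic downstream divides by inter-purchase
#' intervals, so zero-day duplicates must not survive. When merged rows
#' carried different package numbers the merged row's `vnr` is set missing
#' and flagged `vnr_mixed`, which excludes it from refill-length learning.
#' Rows in the exceptions sink are excluded (use [exception_rows()] to
#' retrieve them).
#'
#' @param purchases A harmonized purchases tibble.
#' @return A tibble sorted by `person_id`, `atc`, `date`, one row per
#'   (person, ATC, day), with columns `vnr_mixed` and `n_merged` added.
#' @export
sort_histories <- function(purchases) {
  p <- tibble::as_tibble(purchases)
  if (!"exception" %in% names(p)) p$exception <- NA_character_
  if (!"dose_dispensing" %in% names(p)) p$dose_dispensing <- FALSE
  if (!"n_packages" %in% names(p)) p$n_packages <- 1L
  if (!"vnr" %in% names(p)) p$vnr <- NA_character_
  p |>
    dplyr::filter(is.na(.data$exception)) |>
    dplyr::group_by(.data$person_id, .data$atc, .data$date) |>
    dplyr::summarise(
      ddd_amount = if (all(is.na(.data$ddd_amount))) NA_real_
                   else sum(.data$ddd_amount, na.rm = TRUE),
      n_packages = if (all(is.na(.data$n_packages))) NA_integer_
                   else sum(.data$n_packages, na.rm = TRUE),
      vnr_mixed = dplyr::n_distinct(.data$vnr, na.rm = TRUE) > 1L,
      vnr = if (dplyr::n_distinct(.data$vnr, na.rm = TRUE) == 1L)
              .data$vnr[!is.na(.data$vnr)][1] else NA_character_,
      dose_dispensing = any(.data$dose_dispensing, na.rm = TRUE),
      n_merged = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$person_id, .data$atc, .data$date) |>
    dplyr::relocate("person_id", "date", "atc", "vnr", "n_packages",
                    "ddd_amount", "dose_dispensing")
}

#' Rows routed to the exceptions sink
#'
#' @param purchases A harmonized purchases tibble.
#' @return The rows with a non-missing `exception` reason.
#' @export
exception_rows <- function(purchases) {
  dplyr::filter(tibble::as_tibble(purchases), !is.na(.data$exception))
}

period_file_cols <- c("person_id", "atc", "start", "end", "total_ddd",
                      "hospital_days", "n_purchases", "mean_ddd_per_day")

#' Write drug use periods
#'
#' Writes the eight canonical fields — person id, ATC code, start date, end
#' date, total purchased DDD, hospital days inside the period, number of
#' purchases, and average DDD per day — as delimited text with ISO-8601
#' dates. [read_periods()] reproduces the periods exactly.
#'
#' @param periods A periods tibble ([build_periods()] or [tidy()] of a fit).
#' @param file Path or writable connection.
#' @param delim Field delimiter, default `","`.
#' @return `periods`, invisibly.
#' @export
write_periods <- function(periods, file, delim = ",") {
  p <- tibble::as_tibble(periods)
  missing <- setdiff(period_file_cols, names(p))
  if (length(missing)) {
    abort(paste0("periods table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_delim(p[period_file_cols], file, delim = delim)
  invisible(periods)
}

#' Read drug use periods written by [write_periods()]
#'
#' @param file Path to a period file.
#' @param delim Field delimiter, default `","`.
#' @return A tibble with the eight period fields, dates as `Date`.
#' @export
read_periods <- function(file, delim = ",") {
  readr::read_delim(
    file, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      person_id = readr::col_character(),
      atc = readr::col_character(),
      start = readr::col_date(),
      end = readr::col_date(),
      total_ddd = readr::col_double(),
      hospital_days = readr::col_double(),
      n_purchases = readr::col_integer(),
      mean_ddd_per_day = readr::col_double()))
}
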