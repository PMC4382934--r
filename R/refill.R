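#' Collect package refill-length observations
#'
#' Builds the raw material for learning each package's typical refill
#' length from a previous iteration's periods. For every non-final purchase
#' inside a qualifying period (at least `refill_source_min_purchases`
#' members) the raw calendar gap to the next member purchase is recorded
#' under the purchase's package number. Gaps are used as-is, without
#' subtracting hospital stays. Multi-package purchases of a single vnr
#' contribute `gap / n_packages` (rounded to whole days); rows mixing
#' different packages, dose-dispensing purchases (the whole package is not
#' dispensed to one person) and final purchases of periods contribute
#' nothing.
#'
#' @param audit A purchase-level audit tibble carrying `period_id`,
#'   `person_id`, `atc`, `date`, `vnr`, `vnr_mixed`, `n_packages`,
#'   `dose_dispensing`, `raw_gap_days` ([build_periods()] attribute or
#'   `purchase_audit()` of a fit).
#' @param global A [global_params()] object.
#' @return A tibble (`vnr`, `refill_days`, `n`): the raw per-package
#'   histogram in long form.
#' @export
collect_refill_observations <- function(audit, global = global_params()) {
  a <- tibble::as_tibble(audit)
  if (!nrow(a)) return(tibble::tibble(vnr = character(),
                                      refill_days = integer(), n = integer()))
  if (!"vnr_mixed" %in% names(a)) a$vnr_mixed <- FALSE
  a |>
    dplyr::group_by(.data$period_id) |>
    dplyr::filter(dplyr::n() >= global$refill_source_min_purchases) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::mutate(gap_in_period = dplyr::if_else(
      dplyr::row_number() < dplyr::n(), .data$raw_gap_days, NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gap_in_period),
                  !is.na(.data$vnr), !.data$vnr_mixed,
                  !.data$dose_dispensing) |>
    dplyr::mutate(
      refill_days = as.integer(round(
        .data$gap_in_period / pmax(1L, dplyr::coalesce(.data$n_packages, 1L))))) |>
    dplyr::filter(.data$refill_days >= 1L) |>
    dplyr::count(.data$vnr, .data$refill_days, name = "n")
}

#' Join histogram counts to the nearest local maximum
#'
#' Consolidates a refill-length histogram by moving every bin's count,
#' through iterated hill-climbing, to a nearby local maximum: from each day
#' the count moves to the largest bin within a +/-3-day window of the raw
#' histogram, repeating until it sits on a bin that is itself the largest
#' in its own window. Ties break toward the shorter refill length. Total
#' count is conserved exactly, and the operation is idempotent on its own
#' output's peaks.
#'
#' @param hist A tibble (`refill_days`, `n`) for one package.
#' @param window Half-width in days of the climbing neighborhood.
#' @return A tibble (`refill_days`, `n`) with counts accumulated on local
#'   maxima, sorted by day.
#' @export
join_to_local_maxima <- function(hist, window = 3L) {
  h <- tibble::as_tibble(hist)
  if (!nrow(h)) return(tibble::tibble(refill_days = integer(), n = integer()))
  h <- h |>
    dplyr::group_by(.data$refill_days) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$refill_days)
  days <- h$refill_days
  counts <- stats::setNames(h$n, days)
  climb <- function(d) {
    repeat {
      win <- days[abs(days - d) <= window]
      wc <- counts[as.character(win)]
      best <- min(win[wc == max(wc)])   # tie -> shorter refill length
      if (best == d) return(d)
      d <- best
    }
  }
  dest <- vapply(days, climb, numeric(1))
  tibble::tibble(refill_days = as.integer(dest), n = h$n) |>
    dplyr::group_by(.data$refill_days) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$refill_days)
}

#' Select the typical refill length (mode) of a joined histogram
#'
#' The refill length with the highest joined count, provided that count
#' strictly exceeds `mode_min_purchases`; otherwise none. Ties break toward
#' the shorter length.
#'
#' @param joined A joined histogram tibble (`refill_days`, `n`).
#' @param global A [global_params()] object.
#' @return A one-row tibble (`mode_days`, `mode_count`), or a zero-row
#'   tibble when no qualifying mode exists.
#' @export
select_mode <- function(joined, global = global_params()) {
  j <- tibble::as_tibble(joined)
  empty <- tibble::tibble(mode_days = integer(), mode_count = integer())
  if (!nrow(j)) return(empty)
  top <- max(j$n)
  if (top <= global$mode_min_purchases) return(empty)
  tibble::tibble(mode_days = min(j$refill_days[j$n == top]),
                 mode_count = as.integer(top))
}

#' Learn the per-package refill mode table
#'
#' Runs [join_to_local_maxima()] and [select_mode()] per package over the
#' observations of [collect_refill_observations()]. The result feeds the
#' next pipeline iteration, where a learned mode overrides the
#' expert-defined typical refill length for single purchases.
#'
#' @param observations Long-form histogram tibble (`vnr`, `refill_days`, `n`).
#' @param global A [global_params()] object.
#' @return A tibble (`vnr`, `mode_days`, `mode_count`), one row per package
#'   with a qualifying mode.
#' @export
refill_modes <- function(observations, global = global_params()) {
  obs <- tibble::as_tibble(observations)
  if (!nrow(obs)) {
    return(tibble::tibble(vnr = character(), mode_days = integer(),
                          mode_count = integer()))
  }
  obs |>
    dplyr::group_by(.data$vnr) |>
    dplyr::group_modify(function(h, key) {
      select_mode(join_to_local_maxima(h), global)
    }) |>
    dplyr::ungroup()
}

#' Write / read a refill mode table
#'
#' Plain delimited text (`vnr`, `mode_days`, `mode_count`) so one
#' population's learned refill lengths can seed later runs.
#'
#' @param modes A mode table ([refill_modes()]).
#' @param file Path.
#' @param delim Field delimiter, default `","`.
#' @return `modes` invisibly (write); the mode tibble (read).
#' @export
write_modes <- function(modes, file, delim = ",") {
  readr::write_delim(tibble::as_tibble(modes), file, delim = delim)
  invisible(modes)
}

#' @rdname write_modes
#' @export
read_modes <- function(file, delim = ",") {
  readr::read_delim(file, delim = delim, show_col_types = FALSE,
                    progress = FALSE,
                    col_types = readr::cols(
                      vnr = readr::col_character(),
                      mode_days = readr::col_integer(),
                      mode_count = readr::col_integer()))
}
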