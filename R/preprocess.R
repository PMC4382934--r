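#' Hospital-adjusted refill gaps
#'
#' For every consecutive purchase pair within a (person, ATC) history this
#' computes the raw calendar gap, the number of hospital days falling in
#' that gap, and the net gap (raw minus hospital, floored at one day so
#' later ratios stay finite when a stay spans the whole interval). A net
#' gap above the global maximum refill time starts a new segment: such
#' purchases cannot share a treatment period, and the sliding dose average
#' restarts after the break.
#'
#' Hospital days are counted over the half-open interval
#' `[date_i, date_{i+1})` against half-open stays `[admission, discharge)`
#' (the discharge day is spent at home and can carry a purchase); open
#' discharges extend to data end.
#'
#' @param purchases A sorted histories tibble ([sort_histories()]).
#' @param stays A merged stays tibble ([read_stays()]/[merge_stays()]), or
#'   `NULL` for none.
#' @param global A [global_params()] object.
#' @return `purchases` with columns `raw_gap_days`, `hospital_days_in_gap`,
#'   `net_gap_days` (all `NA` on the last purchase of a history) and
#'   `segment_id` (1-based within each history).
#' @export
compute_gaps <- function(purchases, stays = NULL, global = global_params()) {
  p <- tibble::as_tibble(purchases)
  stays <- prepare_stays(stays)
  p |>
    dplyr::group_by(.data$person_id, .data$atc) |>
    dplyr::group_modify(function(h, key) {
      s <- stays[stays$person_id == key$person_id, ]
      gap_series(h, s, global)
    }) |>
    dplyr::ungroup()
}

prepare_stays <- function(stays) {
  if (is.null(stays) || !nrow(tibble::as_tibble(stays))) {
    return(tibble::tibble(person_id = character(), adm = numeric(),
                          dis = numeric()))
  }
  stays <- merge_stays(stays)
  tibble::tibble(person_id = stays$person_id,
                 adm = as.numeric(stays$admission),
                 dis = ifelse(is.na(stays$discharge), Inf,
                              as.numeric(stays$discharge)))
}

# one history, stays already restricted to the person
gap_series <- function(h, person_stays, global) {
  n <- nrow(h)
  if (n == 0L) {
    h$raw_gap_days <- h$hospital_days_in_gap <- h$net_gap_days <- numeric(0)
    h$segment_id <- integer(0)
    return(h)
  }
  d <- as.numeric(h$date)
  raw <- c(diff(d), NA_real_)
  hosp <- rep(NA_real_, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      hosp[i] <- days_in_stays(d[i], d[i + 1L],
                               person_stays$adm, person_stays$dis)
    }
  }
  net <- pmax(raw - hosp, 1)
  brk <- !is.na(net) & net > global$max_refill_gap_days
  h$raw_gap_days <- raw
  h$hospital_days_in_gap <- hosp
  h$net_gap_days <- net
  h$segment_id <- cumsum(c(1L, as.integer(brk[-n])))
  h
}

#' Sliding weighted temporal dose average (DDDAVG)
#'
#' For each purchase the average daily dose around it is estimated as a
#' weighted ratio of dispensed DDD amounts to net inter-purchase times:
#' weights (1, 4, 1) over the previous, current and next purchase for both
#' numerator and denominator. The first purchase of a segment uses weights
#' (5, 1) over (current, next); the last uses (1, 5) over (previous,
#' current), with the last purchase's own time imputed under the assumption
#' that the dose of the previous interval continues:
#' `T_last = DDD_last / (DDD_prev / T_prev)`. All times are net
#' (hospital-subtracted) gaps. The average is only computed for segments
#' with at least `ddd_avg_min_purchases` purchases; shorter segments pass
#' to the core decision walk without a dose profile. Purchases whose
#' three-purchase window touches a zero or missing DDD amount get a missing
#' average.
#'
#' @param gaps Output of [compute_gaps()].
#' @param global A [global_params()] object.
#' @return `gaps` with a `ddd_avg` column (DDD/day, `NA` where undefined).
#' @export
compute_ddd_avg <- function(gaps, global = global_params()) {
  gaps |>
    dplyr::group_by(.data$person_id, .data$atc, .data$segment_id) |>
    dplyr::group_modify(function(seg, key) {
      seg$ddd_avg <- ddd_avg_segment(seg$ddd_amount, seg$net_gap_days,
                                     global$ddd_avg_min_purchases)
      seg
    }) |>
    dplyr::ungroup()
}

# Eq-style weighted average over one segment; tnet[i] is the net gap from
# purchase i to i+1 (NA/irrelevant for the last purchase of the segment).
ddd_avg_segment <- function(ddd, tnet, min_purchases) {
  n <- length(ddd)
  out <- rep(NA_real_, n)
  if (n < min_purchases) return(out)
  usable <- !is.na(ddd) & ddd > 0
  t_own <- tnet
  # impute the last purchase's time from the previous interval's dose
  t_own[n] <- if (n >= 2L && usable[n] && usable[n - 1L] &&
                  !is.na(tnet[n - 1L]) && tnet[n - 1L] > 0) {
    ddd[n] * tnet[n - 1L] / ddd[n - 1L]
  } else NA_real_
  for (i in seq_len(n)) {
    if (i == 1L) {
      idx <- c(1L, 2L); w <- c(5, 1)
    } else if (i == n) {
      idx <- c(n - 1L, n); w <- c(1, 5)
    } else {
      idx <- c(i - 1L, i, i + 1L); w <- c(1, 4, 1)
    }
    if (all(usable[idx]) && !anyNA(t_own[idx])) {
      out[i] <- sum(w * ddd[idx]) / sum(w * t_own[idx])
    }
  }
  out
}

#' Coefficient of variation of the sliding dose average
#'
#' One regularity statistic per (person, ATC): the sample standard
#' deviation of the purchase-level dose averages divided by their mean.
#' Large values mean irregular refill times and/or amounts. Missing when
#' fewer than two averages exist.
#'
#' @param profile Output of [compute_ddd_avg()].
#' @return `profile` with a constant-within-history `ddd_avg_cv` column.
#' @export
compute_cv <- function(profile) {
  profile |>
    dplyr::group_by(.data$person_id, .data$atc) |>
    dplyr::mutate(ddd_avg_cv = {
      v <- .data$ddd_avg[!is.na(.data$ddd_avg)]
      if (length(v) >= 2L && mean(v) > 0) stats::sd(v) / mean(v) else NA_real_
    }) |>
    dplyr::ungroup()
}

#' Full preprocessing of sorted histories
#'
#' Convenience chain: [compute_gaps()], [compute_ddd_avg()], [compute_cv()].
#'
#' @inheritParams compute_gaps
#' @return The purchases tibble with gap, segment, `ddd_avg` and
#'   `ddd_avg_cv` columns.
#' @export
preprocess_histories <- function(purchases, stays = NULL,
                                 global = global_params()) {
  purchases |>
    compute_gaps(stays, global) |>
    compute_ddd_avg(global) |>
    compute_cv()
}
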