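#' Construct drug use periods from purchase histories
#'
#' The core decision walk. Each (person, ATC) history is preprocessed
#' (hospital-adjusted gaps, sliding dose averages, regularity statistic)
#' and scanned left to right:
#'
#' * a purchase connects to the next when its expected refill length
#'   ([expected_refill_length()]) covers the net gap (ties connect);
#' * otherwise the stockpiling test may rescue the connection through the
#'   combined reach of the current and previous purchase;
#' * a dose average below the resolved lower limit closes the period after
#'   the current purchase (lower-dose split);
#' * a net gap above the global maximum refill time always closes;
#' * histories (or segments) without a dose profile — fewer than three
#'   purchases, or missing DDD amounts — join consecutive purchases when
#'   the raw gap is within the package maximum refill length times the
#'   package count (else the ATC maximum, else the global single-purchase
#'   cap).
#'
#' Closed periods get their end date from [period_end()] (multi-purchase,
#' dose known), from the package-based refill length (lower-dose split), or
#' from [single_purchase_duration()] (one purchase, or last purchase
#' without dose data), with the nearest multi-purchase period of the same
#' history supplying a borrowed daily dose where available. Ends never
#' cross the next period's start.
#'
#' @param purchases A sorted histories tibble ([sort_histories()]).
#' @param stays Merged institutional stays, or `NULL`.
#' @param space An `rx_parameter_space`.
#' @param modes A learned refill mode table ([refill_modes()]), or `NULL`
#'   for the first iteration (expert parameters only).
#' @return A tibble of periods — `person_id`, `atc`, `start`, `end`,
#'   `total_ddd`, `hospital_days`, `n_purchases`, `mean_ddd_per_day`,
#'   `period_id`, `end_rule` — with a purchase-level audit tibble in
#'   attribute `"audit"` (see [purchase_audit()]).
#' @export
build_periods <- function(purchases, stays = NULL, space = parameter_space(),
                          modes = NULL) {
  stopifnot(inherits(space, "rx_parameter_space"))
  global <- space$global
  if (!nrow(tibble::as_tibble(purchases))) {
    empty <- tibble::tibble(
      person_id = character(), atc = character(),
      start = as.Date(character()), end = as.Date(character()),
      total_ddd = double(), hospital_days = double(),
      n_purchases = integer(), mean_ddd_per_day = double(),
      period_id = character(), end_rule = character())
    attr(empty, "audit") <- tibble::as_tibble(purchases)
    return(empty)
  }
  pre <- preprocess_histories(purchases, stays, global)
  stays_m <- if (is.null(stays) || !nrow(tibble::as_tibble(stays))) {
    tibble::tibble(person_id = character(), admission = as.Date(character()),
                   discharge = as.Date(character()))
  } else merge_stays(stays)
  if (is.null(modes)) {
    modes <- tibble::tibble(vnr = character(), mode_days = integer(),
                            mode_count = integer())
  }
  res <- pre |>
    dplyr::group_by(.data$person_id, .data$atc) |>
    dplyr::group_modify(function(h, key) {
      ps <- stays_m[stays_m$person_id == key$person_id, ]
      walk_history(h, key, ps, space, modes)
    }) |>
    dplyr::ungroup()
  audit <- res |>
    dplyr::mutate(period_id = paste(.data$person_id, .data$atc,
                                    .data$period_idx, sep = "/")) |>
    dplyr::select(-"period_start", -"period_end", -"period_end_rule")
  periods <- res |>
    dplyr::group_by(.data$person_id, .data$atc, .data$period_idx) |>
    dplyr::summarise(
      start = min(.data$date),
      end = .data$period_end[1],
      total_ddd = if (all(is.na(.data$ddd_amount))) NA_real_
                  else sum(.data$ddd_amount, na.rm = TRUE),
      n_purchases = dplyr::n(),
      end_rule = .data$period_end_rule[1],
      .groups = "drop")
  periods <- periods |>
    dplyr::group_by(.data$person_id) |>
    dplyr::group_modify(function(pp, key) {
      ps <- stays_m[stays_m$person_id == key$person_id, ]
      pp$hospital_days <- vapply(seq_len(nrow(pp)), function(i) {
        days_in_stays(as.numeric(pp$start[i]), as.numeric(pp$end[i]),
                      as.numeric(ps$admission),
                      ifelse(is.na(ps$discharge), Inf, as.numeric(ps$discharge)))
      }, numeric(1))
      pp
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      exposure_days = pmax(1, as.numeric(.data$end - .data$start) -
                             .data$hospital_days),
      mean_ddd_per_day = .data$total_ddd / .data$exposure_days,
      period_id = paste(.data$person_id, .data$atc, .data$period_idx,
                        sep = "/")) |>
    dplyr::select("person_id", "atc", "start", "end", "total_ddd",
                  "hospital_days", "n_purchases", "mean_ddd_per_day",
                  "period_id", "end_rule") |>
    dplyr::arrange(.data$person_id, .data$atc, .data$start)
  attr(periods, "audit") <- audit
  periods
}

#' Purchase-level audit of a period construction
#'
#' One row per purchase with its `period_id` and the decision branch taken
#' (`decision`): how the walk treated the step from this purchase to the
#' next.
#'
#' @param x The result of [build_periods()] or an `rx_dup_fit`.
#' @return A tibble.
#' @export
purchase_audit <- function(x) {
  if (inherits(x, "rx_dup_fit")) return(x$audit)
  attr(x, "audit")
}

# The left-to-right scan of one preprocessed history. Returns the history
# rows with period_idx, decision, period_end, period_end_rule columns.
walk_history <- function(h, key, person_stays, space, modes) {
  global <- space$global
  n <- nrow(h)
  if (n == 0L) {
    h$period_idx <- integer(0)
    h$decision <- character(0)
    h$period_start <- h$period_end <- as.Date(character(0))
    h$period_end_rule <- character(0)
    return(h)
  }
  atcp <- resolve_atc(key$atc, space)
  pkg_rows <- lapply(h$vnr, resolve_package, space = space)
  mode_days <- modes$mode_days[match(h$vnr, modes$vnr)]
  cv <- if (n) h$ddd_avg_cv[1] else NA_real_

  period_idx <- integer(n)
  decision <- character(n)
  close_info <- vector("list", 0L)
  s <- 1L
  pidx <- 0L

  close_at <- function(i, reason, er = NULL) {
    pidx <<- pidx + 1L
    period_idx[s:i] <<- pidx
    close_info[[pidx]] <<- list(s = s, i = i, reason = reason, er = er)
    s <<- i + 1L
  }

  for (i in seq_len(n)) {
    if (i == n) {
      decision[i] <- "last_purchase"
      close_at(i, "history_end")
      break
    }
    if (h$segment_id[i + 1L] != h$segment_id[i]) {
      decision[i] <- "segment_break"
      close_at(i, "segment_break")
      next
    }
    if (!is.na(h$ddd_avg[i]) && !is.na(h$ddd_amount[i])) {
      er <- expected_refill_length(h$ddd_amount[i], h$n_packages[i],
                                   h$ddd_avg[i], cv, pkg_rows[[i]], atcp,
                                   global)
      if (er$limit_applied == "lower_dose_split") {
        decision[i] <- "lower_dose_split"
        close_at(i, "lower_dose_split", er)
        next
      }
      if (er$erfl_days >= h$net_gap_days[i] - .day_tol) {
        decision[i] <- "connect_erfl"
        next
      }
      if (i > s && !is.na(h$ddd_avg[i - 1L]) && !is.na(h$ddd_avg[i + 1L]) &&
          stockpiling_test(h$ddd_avg[i - 1L], h$ddd_avg[i], h$ddd_avg[i + 1L])) {
        reach <- combined_two_purchase_reach(
          h$ddd_amount[i - 1L], h$ddd_amount[i],
          sum(h$n_packages[c(i - 1L, i)], na.rm = TRUE),
          h$ddd_avg[i], cv, pkg_rows[[i]], atcp, global)
        if (!is.na(reach) &&
            reach >= h$net_gap_days[i - 1L] + h$net_gap_days[i] - .day_tol) {
          decision[i] <- "connect_stockpiling"
          next
        }
      }
      decision[i] <- "close_erfl_short"
      close_at(i, "erfl_short")
    } else {
      lim <- param_join_limit(pkg_rows[[i]], h$n_packages[i], atcp, global)
      if (h$raw_gap_days[i] <= lim + .day_tol) {
        decision[i] <- "connect_params"
      } else {
        decision[i] <- "close_gap_over_params"
        close_at(i, "gap_over_params")
      }
    }
  }

  # end dates: multi-purchase, dose-informed periods first; then periods
  # ending through single-purchase rules, which may borrow a neighbor dose
  ends <- rep(as.Date(NA), pidx)
  end_rule <- character(pidx)
  needs_single <- logical(pidx)
  for (p in seq_len(pidx)) {
    ci <- close_info[[p]]
    i <- ci$i
    k <- i - ci$s + 1L
    if (k == 1L) {
      if (ci$reason == "lower_dose_split") {
        dur <- min(ci$er$erfl_days, global$max_single_purchase_days)
        ends[p] <- h$date[i] + floor(dur + .day_tol)
        end_rule[p] <- "lower_dose_split"
      } else {
        needs_single[p] <- TRUE
      }
    } else if (ci$reason == "lower_dose_split") {
      ends[p] <- extend_over_stays(h$date[i], ci$er$erfl_days, person_stays,
                                   global)
      end_rule[p] <- "lower_dose_split"
    } else if (!is.na(h$ddd_avg[i]) && !is.na(h$ddd_amount[i])) {
      ends[p] <- period_end(h$date[i], h$ddd_amount[i], h$ddd_avg[i], cv, k,
                            person_stays, global)
      end_rule[p] <- "supply_model"
    } else {
      needs_single[p] <- TRUE
    }
  }
  # borrowed dose: nearest period with >= 2 purchases and a computed dose
  donor <- which(!needs_single &
                 vapply(close_info, function(ci) ci$i - ci$s + 1L, 0L) >= 2L)
  donor_dose <- vapply(donor, function(p) {
    ci <- close_info[[p]]
    span <- as.numeric(ends[p] - h$date[ci$s])
    tot <- sum(h$ddd_amount[ci$s:ci$i], na.rm = TRUE)
    if (span >= 1 && tot > 0) tot / span else NA_real_
  }, numeric(1))
  for (p in which(needs_single)) {
    ci <- close_info[[p]]
    i <- ci$i
    nb <- NA_real_
    ok <- donor[!is.na(donor_dose)]
    if (length(ok)) {
      dist <- abs(as.numeric(h$date[i]) -
                  vapply(ok, function(q) as.numeric(h$date[close_info[[q]]$s]), 0))
      nb <- donor_dose[match(ok[which.min(dist)], donor)]
    }
    sp <- single_purchase_duration(h$ddd_amount[i], h$n_packages[i],
                                   mode_days[i], nb, pkg_rows[[i]], atcp,
                                   global)
    ends[p] <- h$date[i] + floor(sp$days + .day_tol)
    end_rule[p] <- paste0("single_", sp$source)
  }
  # non-overlap: an end never crosses the next period's start
  for (p in seq_len(pidx - 1L)) {
    nxt <- h$date[close_info[[p + 1L]]$s]
    if (!is.na(ends[p]) && ends[p] >= nxt) ends[p] <- nxt - 1L
  }
  h$period_idx <- period_idx
  h$decision <- decision
  h$period_start <- h$date[vapply(close_info, `[[`, 0L, "s")][period_idx]
  h$period_end <- ends[period_idx]
  h$period_end_rule <- end_rule[period_idx]
  h
}

param_join_limit <- function(pkg, n_packages, atcp, global) {
  n_packages <- if (is.na(n_packages)) 1L else n_packages
  mx <- fld(pkg, "max_refill_days")
  if (!is.na(mx)) return(mx * n_packages)
  mx <- fld(atcp, "max_refill_days")
  if (!is.na(mx)) return(mx)
  global$max_single_purchase_days
}

#' Run the full iterative pipeline
#'
#' Iteration 1 builds periods with expert parameters only (or a supplied
#' starting mode table). Each further iteration learns the per-package
#' refill mode table from the previous iteration's periods
#' ([collect_refill_observations()], [refill_modes()]) and rebuilds, so
#' population-learned refill lengths override expert typical lengths where
#' enough purchases exist. Iteration stops when the period set is identical
#' to the previous one, or at `max_iter` (with a warning).
#'
#' @param purchases Purchases (harmonized or raw); they are passed through
#'   [sort_histories()].
#' @param stays Institutional stays, or `NULL`.
#' @param space An `rx_parameter_space`.
#' @param modes Optional starting mode table.
#' @param max_iter Maximum number of outer iterations.
#' @return An object of class `rx_dup_fit`: list with `periods`, `modes`,
#'   `audit`, `iterations`, `converged`, `space`. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @examples
#' coh <- generate_cohort(cohort_profiles(n_regular = 3), seed = 1)
#' fit <- run_pipeline(coh$purchases, coh$stays, example_parameter_space())
#' tidy(fit)
#' @export
run_pipeline <- function(purchases, stays = NULL, space = parameter_space(),
                         modes = NULL, max_iter = 10L) {
  hist <- sort_histories(purchases)
  periods <- build_periods(hist, stays, space, modes)
  iterations <- 1L
  converged <- nrow(hist) == 0L
  cur_modes <- modes
  while (!converged && iterations < max_iter) {
    obs <- collect_refill_observations(purchase_audit(periods), space$global)
    cur_modes <- refill_modes(obs, space$global)
    nxt <- build_periods(hist, stays, space, cur_modes)
    iterations <- iterations + 1L
    converged <- identical(period_key(nxt), period_key(periods))
    periods <- nxt
  }
  if (!converged && nrow(hist)) {
    warn(sprintf("pipeline did not stabilise within %d iterations", max_iter))
  }
  audit <- purchase_audit(periods)
  attr(periods, "audit") <- NULL
  structure(
    list(periods = periods,
         modes = cur_modes %||%
           tibble::tibble(vnr = character(), mode_days = integer(),
                          mode_count = integer()),
         audit = audit,
         iterations = iterations, converged = converged, space = space),
    class = "rx_dup_fit")
}

period_key <- function(p) {
  k <- p[c("person_id", "atc", "start", "end", "n_purchases")]
  attr(k, "audit") <- NULL
  dplyr::arrange(tibble::as_tibble(k), .data$person_id, .data$atc, .data$start)
}

#' @export
print.rx_dup_fit <- function(x, ...) {
  cat("<rx_dup_fit>\n")
  cat(sprintf("  %d drug use period(s) over %d purchase(s), %d person-ATC histories\n",
              nrow(x$periods), nrow(x$audit),
              nrow(dplyr::distinct(x$audit, .data$person_id, .data$atc))))
  cat(sprintf("  %d iteration(s); converged: %s; learned refill modes: %d\n",
              x$iterations, x$converged, nrow(x$modes)))
  invisible(x)
}
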