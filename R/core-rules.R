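# Scalar decision rules of the core process. Each takes already-resolved
# parameter rows (`pkg`, `atcp`: one-row tibbles or NULL) plus the global
# constants, so the hierarchy (package > finest ATC prefix > global) is
# decided once per purchase by the callers.

fld <- function(row, col) {
  if (is.null(row)) return(NA_real_)
  v <- row[[col]]
  if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
}

#' Expected refill length of a purchase (ERFL)
#'
#' Predicts how many days a purchase will last:
#' `ERFL = DDD * (1 + dvar * cv) / dose`, where `dose` is the purchase's
#' sliding temporal average clamped from above by the applicable dose cap
#' (the global maximum DDD/day, and the package's dose at its minimum
#' refill length when defined). The regularity multiplier grants irregular
#' purchasers longer expected supplies. Guard rails:
#'
#' * If the dose average falls below the resolved lower dose limit (the
#'   package's dose at maximum refill length, else the ATC-class lower
#'   limit) the purchase pattern is too sparse for continuous use: the
#'   function returns the package-based refill length (typical length times
#'   packages; else the common-ATC-dose length; else the ATC minimum period)
#'   and flags `lower_dose_split`, signalling that the period ends after
#'   this purchase.
#' * The result is truncated to the package maximum refill length times the
#'   number of packages (else the ATC maximum refill length), limiting
#'   stockpiling, as-needed use and restarts after long breaks.
#' * A missing DDD amount with no package information falls back to the ATC
#'   minimum period length.
#'
#' @param ddd_amount Dispensed amount in DDDs (may be `NA`).
#' @param n_packages Number of packages on the row.
#' @param ddd_avg The purchase's sliding temporal dose average (DDD/day).
#' @param cv The person-ATC coefficient of variation (`NA` treated as 0).
#' @param pkg,atcp Resolved package / ATC parameter rows, or `NULL`.
#' @param global A [global_params()] object.
#' @return A list with `erfl_days`, `dose_used` and `limit_applied` (one of
#'   `"none"`, `"package_max"`, `"atc_max"`, `"global_dose_cap"`,
#'   `"lower_dose_split"`, `"atc_min_fallback"`).
#' @examples
#' expected_refill_length(10, 1, ddd_avg = 0.8, cv = 0)$erfl_days  # 12.5
#' @export
expected_refill_length <- function(ddd_amount, n_packages = 1L, ddd_avg,
                                   cv = 0, pkg = NULL, atcp = NULL,
                                   global = global_params()) {
  cv <- if (is.na(cv)) 0 else cv
  n_packages <- if (is.na(n_packages)) 1L else n_packages
  if (is.na(ddd_avg)) {
    abort("expected_refill_length needs a dose average; histories without one use the parameter-based join test")
  }
  if (is.na(ddd_amount)) {
    days <- fld(atcp, "min_period_days")
    return(list(erfl_days = if (is.na(days)) 1 else days,
                dose_used = NA_real_, limit_applied = "atc_min_fallback"))
  }
  lower <- fld(pkg, "ddd_per_day_at_max")
  if (is.na(lower)) lower <- fld(atcp, "min_ddd_per_day")
  if (!is.na(lower) && ddd_avg < lower) {
    typical <- fld(pkg, "typical_refill_days")
    days <- if (!is.na(typical)) {
      typical * n_packages
    } else if (!is.na(fld(atcp, "common_ddd_per_day"))) {
      ddd_amount / fld(atcp, "common_ddd_per_day")
    } else if (!is.na(fld(atcp, "min_period_days"))) {
      fld(atcp, "min_period_days")
    } else 1
    return(list(erfl_days = days, dose_used = ddd_avg,
                limit_applied = "lower_dose_split"))
  }
  cap <- global$max_ddd_per_day
  pk_upper <- fld(pkg, "ddd_per_day_at_min")
  if (!is.na(pk_upper)) cap <- min(cap, pk_upper)
  dose <- min(ddd_avg, cap)
  limit <- if (dose < ddd_avg) "global_dose_cap" else "none"
  erfl <- ddd_amount * (1 + global$dvar * cv) / dose
  max_pkg <- fld(pkg, "max_refill_days")
  max_atc <- fld(atcp, "max_refill_days")
  if (!is.na(max_pkg) && erfl > max_pkg * n_packages) {
    erfl <- max_pkg * n_packages
    limit <- "package_max"
  } else if (is.na(max_pkg) && !is.na(max_atc) && erfl > max_atc) {
    erfl <- max_atc
    limit <- "atc_max"
  }
  list(erfl_days = erfl, dose_used = dose, limit_applied = limit)
}

#' Stockpiling test
#'
#' A locally depressed dose average — the current purchase's average
#' strictly below both its neighbours' — is the signature of buying ahead
#' (a short gap followed by a long gap while the stock is used up) and must
#' not be mistaken for discontinuation. `FALSE` whenever any of the three
#' averages is missing.
#'
#' @param ddd_avg_prev,ddd_avg_cur,ddd_avg_next Sliding dose averages of
#'   the previous, current and next purchase.
#' @return `TRUE` iff the middle value is strictly the smallest.
#' @export
stockpiling_test <- function(ddd_avg_prev, ddd_avg_cur, ddd_avg_next) {
  if (is.na(ddd_avg_prev) || is.na(ddd_avg_cur) || is.na(ddd_avg_next)) {
    return(FALSE)
  }
  ddd_avg_cur < ddd_avg_prev && ddd_avg_cur < ddd_avg_next
}

#' Combined reach of the current and previous purchase
#'
#' When the stockpiling test fires, the two purchases are treated as one
#' dispensing that happened at the earlier date: the expected refill length
#' is recomputed with their summed DDD amounts (and packages). The
#' connection to the next purchase holds if this reach, anchored at the
#' previous purchase, covers both intervening gaps.
#'
#' @param ddd_prev,ddd_cur DDD amounts of the previous and current purchase.
#' @param n_packages_total Combined package count (caps the truncation).
#' @inheritParams expected_refill_length
#' @return Reach in days from the previous purchase's date.
#' @export
combined_two_purchase_reach <- function(ddd_prev, ddd_cur,
                                        n_packages_total = 2L, ddd_avg,
                                        cv = 0, pkg = NULL, atcp = NULL,
                                        global = global_params()) {
  if (is.na(ddd_prev) || is.na(ddd_cur)) return(NA_real_)
  expected_refill_length(ddd_prev + ddd_cur, n_packages_total, ddd_avg, cv,
                         pkg, atcp, global)$erfl_days
}

#' Duration of a single (unjoinable) purchase
#'
#' Priority of evidence, best first: (1) a daily dose adopted from the
#' person's nearest period of the same ATC code with at least two
#' purchases; (2) the population-learned typical refill length of the
#' package, times the number of packages; (3) the dispensed amount with a
#' non-adherence allowance over the expert typical dose
#' (`DDD * (1 + adherence_slack) / typical dose`, package first, then the
#' common ATC dose); (4) the ATC-class minimum period length. With none of
#' these available the duration is one flagged day. The result is always
#' capped at the global single-purchase maximum, regardless of the amount.
#'
#' @param ddd_amount Dispensed DDDs (may be `NA`).
#' @param n_packages Number of packages.
#' @param mode_days Learned refill mode of the package, or `NA`.
#' @param neighbor_dose Daily dose of the person's nearest multi-purchase
#'   period of this ATC code, or `NA`.
#' @inheritParams expected_refill_length
#' @return A list with `days` and `source` (one of `"neighbor_dose"`,
#'   `"refill_mode"`, `"typical_dose"`, `"atc_min_period"`, `"unresolved"`).
#' @export
single_purchase_duration <- function(ddd_amount, n_packages = 1L,
                                     mode_days = NA, neighbor_dose = NA,
                                     pkg = NULL, atcp = NULL,
                                     global = global_params()) {
  n_packages <- if (is.na(n_packages)) 1L else n_packages
  typical_dose <- fld(pkg, "ddd_per_day_typical")
  if (is.na(typical_dose)) typical_dose <- fld(atcp, "common_ddd_per_day")
  res <- if (!is.na(neighbor_dose) && neighbor_dose > 0 && !is.na(ddd_amount)) {
    list(days = ddd_amount / neighbor_dose, source = "neighbor_dose")
  } else if (!is.na(mode_days)) {
    list(days = mode_days * n_packages, source = "refill_mode")
  } else if (!is.na(ddd_amount) && !is.na(typical_dose)) {
    list(days = ddd_amount * (1 + global$adherence_slack) / typical_dose,
         source = "typical_dose")
  } else if (!is.na(fld(atcp, "min_period_days"))) {
    list(days = fld(atcp, "min_period_days"), source = "atc_min_period")
  } else {
    list(days = 1, source = "unresolved")
  }
  res$days <- min(res$days, global$max_single_purchase_days)
  res
}

#' End date of a multi-purchase drug use period
#'
#' From the last purchase the remaining supply is
#' `DDD * (1 + dvar * cv) / (dose * (1 + exp(-k)))`, where `k` is the
#' number of purchases in the period — the damping term shortens periods
#' built on very few purchases, limiting terminal stockpiling — and `dose`
#' is the last purchase's sliding average clamped at the global maximum.
#' Hospital days falling inside the extension do not consume supply: they
#' are added iteratively (extend, re-count stay days inside, repeat) until
#' stable. A continuous stay longer than the global limit is not bridged:
#' the period is truncated at that stay's admission.
#'
#' @param date Date of the last purchase.
#' @param ddd_amount Its dispensed DDDs.
#' @param ddd_avg Its sliding dose average.
#' @param cv The history's coefficient of variation (`NA` treated as 0).
#' @param k Number of purchases in the closing period.
#' @param stays The person's merged stays (tibble with `admission`,
#'   `discharge`), or `NULL`.
#' @param global A [global_params()] object.
#' @return The period end date (rounded down to a whole day).
#' @examples
#' period_end(as.Date("2005-01-01"), 10, ddd_avg = 1, cv = 0, k = 5)
#' @export
period_end <- function(date, ddd_amount, ddd_avg, cv = 0, k,
                       stays = NULL, global = global_params()) {
  cv <- if (is.na(cv)) 0 else cv
  dose <- min(ddd_avg, global$max_ddd_per_day)
  base <- ddd_amount * (1 + global$dvar * cv) / (dose * (1 + exp(-k)))
  extend_over_stays(date, base, stays, global)
}

# Add hospital days inside the supply window to the end date; truncate at
# the admission of any continuous stay above the global limit.
extend_over_stays <- function(date, base_days, stays, global) {
  d0 <- as.numeric(date)
  adm <- dis <- numeric(0)
  if (!is.null(stays) && nrow(stays <- tibble::as_tibble(stays))) {
    adm <- as.numeric(stays$admission)
    dis <- ifelse(is.na(stays$discharge), Inf, as.numeric(stays$discharge))
  }
  offset <- base_days
  for (iter in seq_len(100L)) {
    touch <- adm <= d0 + offset + .day_tol & dis > d0
    if (any(touch)) {
      long <- touch & (dis - adm) > global$max_hospital_days_in_period
      if (any(long)) {
        return(as.Date(max(d0, min(adm[long])), origin = "1970-01-01"))
      }
    }
    h <- days_in_stays(d0, d0 + offset, adm, dis)
    new_offset <- base_days + h
    if (abs(new_offset - offset) < .day_tol) break
    offset <- new_offset
  }
  as.Date(d0 + floor(offset + .day_tol), origin = "1970-01-01")
}
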