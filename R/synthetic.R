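#' Describe a synthetic cohort, one row per simulated person
#'
#' Builds the profile table consumed by [generate_cohort()]. Each profile
#' kind emulates a purchasing behavior seen in dispensing registers:
#'
#' * `regular` — refills at the package supply interval
#'   (`package_ddd * n_packages / true_dose` days) with multiplicative
#'   jitter;
#' * `stockpiler` — periodically buys ahead (an interval halved) and then
#'   uses up the stock (the following interval stretched);
#' * `irregular` — a regular user with large jitter;
#' * `dose_change` — the daily dose changes mid-history (intervals shrink
#'   or stretch accordingly);
#' * `hospitalized` — an institutional stay delays the next refill by the
#'   stay length (drugs are supplied by the ward, not purchased);
#' * `single_buyer` — one purchase only;
#' * `restart_after_gap` — a break longer than the maximum refill time
#'   splits the history into two true treatment episodes.
#'
#' @param n_regular,n_stockpiler,n_irregular,n_dose_change,n_hospitalized,n_single,n_restart
#'   Number of persons of each kind.
#' @param true_dose True daily dose in DDD/day.
#' @param package_ddd DDD content of one package.
#' @param n_packages Packages per purchase.
#' @param refill_jitter Maximum fractional deviation of a refill interval;
#'   log-scale deviations are truncated at this bound (three standard
#'   deviations).
#' @param n_purchases Purchases per person.
#' @param atc,vnr Drug and package identifiers.
#' @param stay_days Stay length (days) for `hospitalized` profiles.
#' @param restart_gap_days Length of the `restart_after_gap` break.
#' @param dose_change_factor Multiplier on `true_dose` at mid-history for
#'   `dose_change` profiles.
#' @param on_time_prob Fraction of refills occurring exactly at pack
#'   exhaustion; the remainder are jittered. Register refill histograms
#'   show a dominant spike at the package length, which a purely smooth
#'   noise model cannot reproduce.
#' @return A tibble of person profiles.
#' @export
cohort_profiles <- function(n_regular = 0, n_stockpiler = 0, n_irregular = 0,
                            n_dose_change = 0, n_hospitalized = 0,
                            n_single = 0, n_restart = 0,
                            true_dose = 1, package_ddd = 30, n_packages = 1L,
                            refill_jitter = 0.05, n_purchases = 8L,
                            atc = "N05AH02", vnr = "012345",
                            stay_days = 10L, restart_gap_days = 400L,
                            dose_change_factor = 2, on_time_prob = 0.4) {
  kinds <- c(rep("regular", n_regular), rep("stockpiler", n_stockpiler),
             rep("irregular", n_irregular), rep("dose_change", n_dose_change),
             rep("hospitalized", n_hospitalized), rep("single_buyer", n_single),
             rep("restart_after_gap", n_restart))
  if (!length(kinds)) {
    abort("at least one person is required")
  }
  chk_pos(true_dose, "true_dose")
  if (refill_jitter < 0 || refill_jitter >= 0.5) {
    abort("refill_jitter must be in [0, 0.5)")
  }
  tibble::tibble(
    profile_kind = kinds,
    true_dose = true_dose, package_ddd = package_ddd,
    n_packages = as.integer(n_packages),
    refill_jitter = refill_jitter,
    n_purchases = ifelse(kinds == "single_buyer", 1L, as.integer(n_purchases)),
    atc = atc, vnr = as.character(vnr),
    stay_days = as.integer(stay_days),
    restart_gap_days = as.integer(restart_gap_days),
    dose_change_factor = dose_change_factor,
    on_time_prob = on_time_prob)
}

# Multiplicative refill-interval noise. A fraction `on_time_prob` of
# refills happens exactly at pack exhaustion — observed refill-length
# histograms have a dominant spike at the pack length, not a smooth bump —
# and the rest get log-normal deviations truncated at +/- `jitter`
# (three standard deviations) on the log scale.
jitter_factors <- function(n, jitter, on_time_prob = 0.4) {
  if (jitter <= 0 || n == 0L) return(rep(1, n))
  sdlog <- jitter / 3
  z <- pmin(pmax(stats::rnorm(n, 0, sdlog), -jitter), jitter)
  z[stats::runif(n) < on_time_prob] <- 0
  exp(z)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given `seed` (byte-identical outputs for identical seeds).
#' True treatment episodes are defined by the construction — a person
#' discontinues only where the profile says so (the `restart_after_gap`
#' break) — never by a gap heuristic, so the generator cannot encode the
#' method under test. Per-episode true average doses are derived from the
#' generated amounts and exposure days. Purchased amounts stay within a
#' roughly three-month supply per purchase, as dispensing rules allow.
#'
#' @param profiles A [cohort_profiles()] tibble.
#' @param start First possible purchase date; person start dates are
#'   staggered deterministically after it.
#' @param seed Integer seed for all randomness.
#' @return A list of class `rx_cohort`: `purchases`, `stays`, `truth`
#'   (person, ATC, episode, start, end, hospital_days, true_dose),
#'   `profiles`.
#' @export
generate_cohort <- function(profiles, start = as.Date("2005-01-01"),
                            seed = 1L) {
  start <- as_date_strict(start)
  profiles <- tibble::as_tibble(profiles)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  pur <- vector("list", nrow(profiles))
  sty <- vector("list", nrow(profiles))
  tru <- vector("list", nrow(profiles))
  for (j in seq_len(nrow(profiles))) {
    pr <- as.list(profiles[j, ])
    pid <- sprintf("P%04d", j)
    base <- pr$package_ddd * pr$n_packages / pr$true_dose
    if (base < 1) abort(sprintf("infeasible profile %s: supply interval < 1 day", pid))
    if (base > 120) {
      abort(sprintf("infeasible profile %s: one purchase would supply %.0f days (over the ~3-month dispensing limit)",
                    pid, base))
    }
    np <- pr$n_purchases
    g <- max(np - 1L, 0L)
    f <- jitter_factors(g, pr$refill_jitter, pr$on_time_prob)
    gaps <- base * f
    doses <- rep(pr$true_dose, np)
    episode_of <- rep(1L, np)
    stays_j <- NULL
    if (pr$profile_kind == "stockpiler" && g >= 2L) {
      early <- seq(2L, g, by = 3L)
      gaps[early] <- gaps[early] * 0.5
      after <- early[early + 1L <= g] + 1L
      gaps[after] <- gaps[after] * 1.5
    } else if (pr$profile_kind == "dose_change" && g >= 2L) {
      half <- ceiling(np / 2)
      new_dose <- pr$true_dose * pr$dose_change_factor
      idx <- seq(half, g)
      gaps[idx] <- pr$package_ddd * pr$n_packages / new_dose * f[idx]
      doses[(half + 1L):np] <- new_dose
    } else if (pr$profile_kind == "restart_after_gap" && g >= 1L) {
      mid <- max(1L, ceiling(g / 2))
      gaps[mid] <- pr$restart_gap_days
      episode_of[(mid + 1L):np] <- 2L
    }
    gaps <- round(pmax(gaps, 1))
    start_j <- start + ((j - 1L) * 17L) %% 120L
    dates <- start_j + cumsum(c(0, gaps))
    if (pr$profile_kind == "hospitalized" && g >= 1L) {
      mid <- max(1L, ceiling(g / 2))
      if (gaps[mid] < pr$stay_days + 5L) {
        abort(sprintf("infeasible profile %s: stay does not fit in a refill interval", pid))
      }
      adm <- dates[mid] + 3L
      stays_j <- tibble::tibble(person_id = pid, admission = adm,
                                discharge = adm + pr$stay_days)
      gaps[mid] <- gaps[mid] + pr$stay_days
      dates <- start_j + cumsum(c(0, gaps))
    }
    pur[[j]] <- tibble::tibble(
      person_id = pid, date = dates, atc = pr$atc, vnr = pr$vnr,
      n_packages = pr$n_packages,
      ddd_amount = pr$package_ddd * pr$n_packages,
      dose_dispensing = FALSE)
    if (!is.null(stays_j)) sty[[j]] <- stays_j
    tru[[j]] <- tibble::tibble(
      person_id = pid, atc = pr$atc,
      episode = sort(unique(episode_of))) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        start = min(dates[episode_of == .data$episode]),
        end = {
          last <- max(which(episode_of == .data$episode))
          tail_days <- round(pr$package_ddd * pr$n_packages / doses[last])
          dates[last] + tail_days
        },
        hospital_days = if (is.null(stays_j)) 0 else {
          days_in_stays(as.numeric(.data$start), as.numeric(.data$end),
                        as.numeric(stays_j$admission),
                        as.numeric(stays_j$discharge))
        },
        true_dose = {
          idx <- which(episode_of == .data$episode)
          sum(pur[[j]]$ddd_amount[idx]) /
            max(1, as.numeric(.data$end - .data$start) - .data$hospital_days)
        }) |>
      dplyr::ungroup()
  }
  structure(
    list(purchases = dplyr::bind_rows(pur),
         stays = if (length(purrr::compact(sty))) {
           dplyr::bind_rows(purrr::compact(sty))
         } else {
           tibble::tibble(person_id = character(),
                          admission = as.Date(character()),
                          discharge = as.Date(character()))
         },
         truth = dplyr::bind_rows(tru),
         profiles = profiles),
    class = "rx_cohort")
}

#' @export
print.rx_cohort <- function(x, ...) {
  cat("<rx_cohort>\n")
  cat(sprintf("  %d purchase(s) by %d person(s); %d stay(s); %d true episode(s)\n",
              nrow(x$purchases), dplyr::n_distinct(x$purchases$person_id),
              nrow(x$stays), nrow(x$truth)))
  invisible(x)
}

#' Score constructed periods against the generator's ground truth
#'
#' Matches each (person, ATC)'s constructed periods to the true episodes in
#' chronological order and reports episode-count error, absolute start and
#' end errors in days, and the relative dose error; cohort summaries give
#' medians and 90th percentiles.
#'
#' @param periods A periods tibble or an `rx_dup_fit`.
#' @param truth The `truth` element of an [generate_cohort()] result.
#' @return A list of class `rx_dup_score` with `histories` (one row per
#'   matched episode) and `summary` (one row of cohort-level summaries).
#' @export
score_against_truth <- function(periods, truth) {
  if (inherits(periods, "rx_dup_fit")) periods <- periods$periods
  p <- tibble::as_tibble(periods)
  t <- tibble::as_tibble(truth)
  counts <- dplyr::full_join(
    dplyr::count(p, .data$person_id, .data$atc, name = "n_built"),
    dplyr::count(t, .data$person_id, .data$atc, name = "n_true"),
    by = c("person_id", "atc")) |>
    tidyr::replace_na(list(n_built = 0L, n_true = 0L)) |>
    dplyr::mutate(episode_count_error = .data$n_built - .data$n_true)
  matched <- dplyr::inner_join(
    p |> dplyr::group_by(.data$person_id, .data$atc) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::mutate(episode = dplyr::row_number()) |> dplyr::ungroup() |>
      dplyr::select("person_id", "atc", "episode", built_start = "start",
                    built_end = "end", built_dose = "mean_ddd_per_day"),
    t |> dplyr::select("person_id", "atc", "episode", true_start = "start",
                       true_end = "end", "true_dose"),
    by = c("person_id", "atc", "episode")) |>
    dplyr::mutate(
      start_error_days = abs(as.numeric(.data$built_start - .data$true_start)),
      end_error_days = abs(as.numeric(.data$built_end - .data$true_end)),
      dose_rel_error = abs(.data$built_dose - .data$true_dose) / .data$true_dose)
  histories <- dplyr::left_join(counts, matched, by = c("person_id", "atc"))
  q <- function(v, p) if (all(is.na(v))) NA_real_ else
    unname(stats::quantile(v, p, na.rm = TRUE))
  summary <- tibble::tibble(
    n_histories = nrow(counts),
    n_matched_episodes = nrow(matched),
    mean_abs_count_error = mean(abs(counts$episode_count_error)),
    median_start_error_days = q(matched$start_error_days, 0.5),
    p90_start_error_days = q(matched$start_error_days, 0.9),
    median_end_error_days = q(matched$end_error_days, 0.5),
    p90_end_error_days = q(matched$end_error_days, 0.9),
    median_dose_rel_error = q(matched$dose_rel_error, 0.5),
    p90_dose_rel_error = q(matched$dose_rel_error, 0.9))
  structure(list(histories = histories, summary = summary),
            class = "rx_dup_score")
}

#' @export
print.rx_dup_score <- function(x, ...) {
  cat("<rx_dup_score>\n")
  print(x$summary)
  invisible(x)
}
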