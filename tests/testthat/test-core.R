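sp_ex <- example_parameter_space()

test_that("expected refill length follows the dose-ratio formula with guards", {
  # amount/dose with no regularity penalty
  expect_equal(expected_refill_length(10, 1, ddd_avg = 0.8, cv = 0)$erfl_days,
               12.5)
  # regularity multiplier: cv 0.4 at dvar 0.5 lengthens the reach by 20%
  er <- expected_refill_length(30, 1, ddd_avg = 1, cv = 0.4)
  expect_equal(er$erfl_days, 30 * 1.2)
  expect_equal(er$limit_applied, "none")
  # dose average under the class lower limit signals a period split
  atcp <- resolve_atc("N05AH02", sp_ex)
  er2 <- expected_refill_length(10, 1, ddd_avg = 0.01, cv = 0, atcp = atcp)
  expect_equal(er2$limit_applied, "lower_dose_split")
  expect_equal(er2$erfl_days, 10 / atcp$common_ddd_per_day)
  # with package parameters the split length is the typical refill length
  pkg <- resolve_package("012345", sp_ex)
  er3 <- expected_refill_length(10, 2, ddd_avg = 0.01, cv = 0, pkg = pkg,
                                atcp = atcp)
  expect_equal(er3$erfl_days, pkg$typical_refill_days * 2)
  # truncation by package and class maxima
  er4 <- expected_refill_length(300, 1, ddd_avg = 0.3, cv = 0, pkg = pkg,
                                atcp = atcp)
  expect_equal(er4$erfl_days, pkg$max_refill_days)
  expect_equal(er4$limit_applied, "package_max")
  er5 <- expected_refill_length(300, 1, ddd_avg = 0.3, cv = 0, atcp = atcp)
  expect_equal(er5$erfl_days, atcp$max_refill_days)
  expect_equal(er5$limit_applied, "atc_max")
  # missing amount falls back to the class minimum period
  er6 <- expected_refill_length(NA, 1, ddd_avg = 1, atcp = atcp)
  expect_equal(er6$limit_applied, "atc_min_fallback")
  expect_equal(er6$erfl_days, atcp$min_period_days)
})

test_that("stockpiling test requires a strict local minimum", {
  expect_true(stockpiling_test(1.33, 0.80, 0.92))
  expect_false(stockpiling_test(0.9, 0.8, 0.7))   # not below the following
  expect_false(stockpiling_test(0.8, 0.9, 1.0))   # middle not minimal
  expect_false(stockpiling_test(1, 1, 1))         # equality is not enough
  expect_false(stockpiling_test(NA, 0.5, 1))      # missing -> no rescue
})

test_that("combined two-purchase reach covers both gaps on the worked history", {
  # two 10-DDD purchases 5 days apart at dose 1/day, next purchase 15 days on
  reach <- combined_two_purchase_reach(10, 10, 2, ddd_avg = 1, cv = 0)
  expect_equal(reach, 20)
  expect_true(reach >= 5 + 15)       # boundary: reach == span connects
})

test_that("single-purchase durations follow the evidence priority and cap", {
  atcp <- resolve_atc("N05AH02", sp_ex)
  pkg <- resolve_package("012345", sp_ex)
  # learned mode wins over typical dose; multiplies by packages
  expect_equal(single_purchase_duration(30, 1, mode_days = 98)$days, 98)
  expect_equal(single_purchase_duration(30, 2, mode_days = 98)$days, 150)
  # a neighbouring period's dose outranks the mode
  nb <- single_purchase_duration(30, 1, mode_days = 98, neighbor_dose = 2)
  expect_equal(nb$days, 15)
  expect_equal(nb$source, "neighbor_dose")
  # typical dose with the non-adherence allowance, capped at 150 days
  td <- single_purchase_duration(100, 1, pkg = dplyr::mutate(
    pkg, ddd_per_day_typical = 0.5), atcp = atcp)
  expect_equal(td$days, 150)         # 100 * 1.2 / 0.5 = 240, capped
  expect_equal(td$source, "typical_dose")
  td2 <- single_purchase_duration(50, 1, pkg = pkg, atcp = atcp)
  expect_equal(td2$days, 50 * 1.2 / pkg$ddd_per_day_typical)
  # no amount, no mode: class minimum period; nothing at all: one day
  expect_equal(single_purchase_duration(NA, 1, atcp = atcp)$source,
               "atc_min_period")
  expect_equal(single_purchase_duration(NA, 1)$days, 1)
})

test_that("period end matches the damped supply formula over (k, cv) grid", {
  d0 <- as.Date("2005-06-01")
  for (k in c(1, 2, 5, 20)) {
    for (cv in c(0, 0.3)) {
      want <- floor(10 * (1 + 0.5 * cv) / (1 * (1 + exp(-k))))
      expect_equal(as.numeric(period_end(d0, 10, 1, cv, k) - d0), want)
    }
  }
  # the damping vanishes for long periods: extension -> amount/dose
  expect_equal(as.numeric(period_end(d0, 10, 1, 0, 500) - d0), 10)
  # applied dose is capped at the global maximum
  expect_equal(as.numeric(period_end(d0, 40, 20, 0, 500) - d0), 4)
})

test_that("hospital stays extend the period end but long stays truncate it", {
  d0 <- as.Date("2005-06-01")
  # 10-day supply, 5-day stay inside it: end pushed out by 5 days
  s <- stays_tbl("P1", "2005-06-03", "2005-06-08")
  expect_equal(as.numeric(period_end(d0, 10, 1, 0, 50, stays = s) - d0), 15)
  # the extension can reach a second stay; both are added
  s2 <- stays_tbl(c("P1", "P1"), c("2005-06-03", "2005-06-12"),
                  c("2005-06-08", "2005-06-16"))
  expect_equal(as.numeric(period_end(d0, 10, 1, 0, 50, stays = s2) - d0), 19)
  # a 40-day stay beginning 3 days after the last purchase truncates
  s3 <- stays_tbl("P1", "2005-06-04", "2005-07-14")
  expect_equal(period_end(d0, 10, 1, 0, 50, stays = s3), as.Date("2005-06-04"))
})

test_that("the worked stockpiling history stays one period end to end", {
  per <- build_periods(sort_histories(harmonize_purchases(stockpiling_history())),
                       space = sp_ex)
  expect_equal(nrow(per), 1L)
  expect_equal(per$n_purchases, 5L)
  expect_equal(per$start, as.Date("2005-01-01"))
  expect_equal(per$total_ddd, 50)
  expect_equal(purchase_audit(per)$decision[3], "connect_stockpiling")
})

test_that("purchases far apart become separate single-purchase periods", {
  p <- purchases_tbl("P1", c("2005-01-01", "2006-02-05"), 30)  # 400 days
  per <- build_periods(sort_histories(harmonize_purchases(p)), space = sp_ex)
  expect_equal(nrow(per), 2L)
  expect_equal(per$n_purchases, c(1L, 1L))
})

test_that("two close purchases join through package/class parameters", {
  p <- purchases_tbl("P1", c("2005-01-01", "2005-02-01"), 30)
  per <- build_periods(sort_histories(harmonize_purchases(p)), space = sp_ex)
  expect_equal(per$n_purchases, 2L)
  # beyond the package maximum refill length they fall apart
  p2 <- purchases_tbl("P1", c("2005-01-01", "2005-06-01"), 30)
  per2 <- build_periods(sort_histories(harmonize_purchases(p2)), space = sp_ex)
  expect_equal(per2$n_purchases, c(1L, 1L))
})

test_that("random histories yield a valid partition respecting every cap", {
  g <- global_params()
  p <- harmonize_purchases(random_purchases(n_persons = 40, seed = 51))
  h <- sort_histories(p)
  per <- build_periods(h, space = sp_ex)
  a <- purchase_audit(per)
  # partition: every non-exception purchase sits in exactly one period
  expect_equal(nrow(a), nrow(h))
  expect_equal(sort(unique(a$period_id)), sort(per$period_id))
  counts <- dplyr::count(a, period_id)
  expect_equal(counts$n[match(per$period_id, counts$period_id)],
               per$n_purchases)
  # conservation of dispensed amounts
  expect_equal(sum(per$total_ddd, na.rm = TRUE),
               sum(h$ddd_amount, na.rm = TRUE))
  # periods of one history are date-ordered and never overlap
  chk <- per |>
    dplyr::group_by(person_id, atc) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(as.numeric(start)) > 0) &&
                       all(head(end, -1) < tail(start, -1)),
                     .groups = "drop")
  expect_true(all(chk$ok))
  # caps
  expect_true(all(as.numeric(per$end - per$start)[per$n_purchases == 1] <=
                    g$max_single_purchase_days))
  within_gap <- a |>
    dplyr::group_by(period_id) |>
    dplyr::arrange(date, .by_group = TRUE) |>
    dplyr::summarise(mx = if (dplyr::n() > 1) max(head(net_gap_days, -1)) else 0,
                     .groups = "drop")
  expect_true(all(within_gap$mx <= g$max_refill_gap_days))
  expect_true(all(per$end >= per$start))
})

test_that("adding a purchase inside a period never shortens its span", {
  p <- purchases_tbl("P1", as.Date("2005-01-01") + c(0, 30, 60, 90), 30)
  per <- build_periods(sort_histories(harmonize_purchases(p)), space = sp_ex)
  p2 <- dplyr::bind_rows(p, purchases_tbl("P1", "2005-02-20", 30))
  per2 <- build_periods(sort_histories(harmonize_purchases(p2)), space = sp_ex)
  expect_equal(nrow(per2), 1L)
  expect_gte(as.numeric(per2$end - per2$start),
             as.numeric(per$end - per$start))
})

test_that("the pipeline reaches a fixed point and reports iterations", {
  # below the mode threshold nothing is learned: two identical iterations
  coh <- generate_cohort(cohort_profiles(n_regular = 2, n_purchases = 5),
                         seed = 5)
  fit <- run_pipeline(coh$purchases, coh$stays, sp_ex)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 2L)
  expect_equal(nrow(fit$modes), 0L)

  # a dominant package's learned mode drives single-purchase durations
  prof <- dplyr::bind_rows(
    cohort_profiles(n_regular = 20, true_dose = 0.33, package_ddd = 32.34,
                    n_purchases = 9, atc = "C10AA01", vnr = "010940"),
    cohort_profiles(n_single = 1, true_dose = 0.33, package_ddd = 32.34,
                    atc = "C10AA01", vnr = "010940"))
  coh2 <- generate_cohort(prof, seed = 6)
  fit2 <- run_pipeline(coh2$purchases, coh2$stays, sp_ex)
  expect_true(fit2$converged)
  expect_equal(fit2$modes$mode_days[fit2$modes$vnr == "010940"], 98L)
  single <- fit2$periods[fit2$periods$person_id == "P0021", ]
  expect_equal(single$n_purchases, 1L)
  expect_equal(as.numeric(single$end - single$start), 98)

  # empty input: empty output, one iteration
  fit0 <- run_pipeline(coh$purchases[0, ], NULL, sp_ex)
  expect_equal(nrow(fit0$periods), 0L)
  expect_equal(fit0$iterations, 1L)
})

test_that("tidiers and plots expose the fit", {
  coh <- generate_cohort(cohort_profiles(n_regular = 2, n_single = 1), seed = 9)
  fit <- run_pipeline(coh$purchases, coh$stays, sp_ex)
  expect_identical(tidy(fit), fit$periods)
  gl <- glance(fit)
  expect_equal(gl$n_periods, nrow(fit$periods))
  expect_s3_class(autoplot(fit), "ggplot")
  obs <- collect_refill_observations(fit$audit)
  if (nrow(obs)) {
    expect_s3_class(plot_refill_distribution(obs, obs$vnr[1]), "ggplot")
  }
})
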