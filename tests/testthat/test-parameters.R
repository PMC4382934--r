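test_that("defaults match the documented global constants", {
  g <- global_params()
  expect_equal(g$max_refill_gap_days, 300)
  expect_equal(g$max_hospital_days_in_period, 30)
  expect_equal(g$max_ddd_per_day, 10)
  expect_equal(g$max_single_purchase_days, 150)
  expect_equal(g$dvar, 0.5)
  expect_equal(g$adherence_slack, 0.2)
  expect_equal(g$mode_min_purchases, 10)
  expect_equal(g$refill_source_min_purchases, 6)
  expect_equal(g$ddd_avg_min_purchases, 3)
  expect_error(global_params(dvar = 1.5), "\\[0, 1\\]")
  expect_error(global_params(max_ddd_per_day = -1), "positive")
})

test_that("invariant violations in parameter tables are rejected", {
  expect_error(parameter_space(atc = data.frame(
    atc_prefix = "N05A", min_ddd_per_day = 2, common_ddd_per_day = 1,
    min_period_days = 10, max_refill_days = 100)),
    "min_ddd_per_day > common_ddd_per_day")
  expect_error(parameter_space(vnr = data.frame(
    vnr = "1", min_refill_days = 40, max_refill_days = 30,
    typical_refill_days = 35, ddd_per_day_at_min = 1,
    ddd_per_day_at_max = 1, ddd_per_day_typical = 1)),
    "min <= typical <= max")
  expect_error(parameter_space(atc = data.frame(
    atc_prefix = c("N", "N"), min_ddd_per_day = 0.1, common_ddd_per_day = 1,
    min_period_days = 10, max_refill_days = 100)),
    "duplicate")
  expect_error(parameter_space(atc = data.frame(
    atc_prefix = "n05", min_ddd_per_day = 0.1, common_ddd_per_day = 1,
    min_period_days = 10, max_refill_days = 100)),
    "invalid ATC")
})

test_that("ATC resolution picks the finest defined prefix", {
  sp <- parameter_space(atc = tibble::tibble(
    atc_prefix = c("N", "N05A"),
    min_ddd_per_day = c(0.01, 0.1), common_ddd_per_day = c(1, 2),
    min_period_days = c(5, 10), max_refill_days = c(100, 120)))
  expect_equal(resolve_atc("N05AH02", sp)$atc_prefix, "N05A")
  expect_equal(resolve_atc("N06AB04", sp)$atc_prefix, "N")
  expect_null(resolve_atc("C10AA01", sp))
  expect_null(resolve_atc(NA, sp))
})

test_that("prefix resolution agrees with a brute-force scan on random codes", {
  set.seed(11)
  rand_code <- function(n) {
    vapply(seq_len(n), function(i) {
      full <- paste0(sample(LETTERS[1:14], 1), sprintf("%02d", sample(0:99, 1)),
                     paste(sample(LETTERS[1:8], 2, replace = TRUE), collapse = ""),
                     sprintf("%02d", sample(0:99, 1)))
      substr(full, 1, sample(c(1, 3, 4, 5, 7), 1))
    }, character(1))
  }
  prefixes <- unique(rand_code(80))
  sp <- parameter_space(atc = tibble::tibble(
    atc_prefix = prefixes, min_ddd_per_day = 0.1, common_ddd_per_day = 1,
    min_period_days = 10, max_refill_days = 100))
  codes <- rand_code(1000)
  for (code in codes) {
    hits <- prefixes[startsWith(code, prefixes)]
    want <- if (length(hits)) hits[which.max(nchar(hits))] else NULL
    got <- resolve_atc(code, sp)
    if (is.null(want)) expect_null(got) else expect_equal(got$atc_prefix, want)
  }
})

test_that("package lookup is exact and missing-safe", {
  sp <- example_parameter_space()
  row <- resolve_package("012345", sp)
  expect_equal(row$typical_refill_days, 30)
  expect_null(resolve_package("000000", sp))
  expect_null(resolve_package(NA, sp))
  # a 30-capsule once-daily pack configured with slack comes back unchanged
  sp2 <- parameter_space(vnr = tibble::tibble(
    vnr = "7", min_refill_days = 15, max_refill_days = 36,
    typical_refill_days = 30, ddd_per_day_at_min = 2,
    ddd_per_day_at_max = 30 / 36, ddd_per_day_typical = 1))
  expect_equal(resolve_package("7", sp2)$max_refill_days, 36)
})

test_that("parameter files load with defaults when absent", {
  sp0 <- read_parameter_space()
  expect_equal(sp0$global$max_refill_gap_days, 300)
  expect_equal(nrow(sp0$atc), 0L)

  gf <- withr::local_tempfile(fileext = ".yml")
  writeLines("max_single_purchase_days: 120\ndvar: 0.4", gf)
  af <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("atc_prefix,min_ddd_per_day,common_ddd_per_day,min_period_days,max_refill_days",
               "N05A,0.1,1,10,120", "N,0.02,1,5,100"), af)
  sp <- read_parameter_space(gf, af)
  expect_equal(sp$global$max_single_purchase_days, 120)
  expect_equal(sp$global$dvar, 0.4)
  expect_equal(sp$global$max_refill_gap_days, 300)  # untouched default
  expect_equal(nrow(sp$atc), 2L)                     # both levels retained
  expect_error(read_parameter_space(withr::local_tempfile(lines = "nope: 1",
                                                          fileext = ".yml")),
               "unknown global parameter")
})

test_that("global caps bound every resolved dose and refill decision", {
  # a package cannot push the applied dose over the global ceiling
  sp <- parameter_space(vnr = tibble::tibble(
    vnr = "X", min_refill_days = 1, max_refill_days = 400,
    typical_refill_days = 30, ddd_per_day_at_min = 50,
    ddd_per_day_at_max = 0.01, ddd_per_day_typical = 1))
  er <- expected_refill_length(30, 1, ddd_avg = 40, cv = 0,
                               pkg = resolve_package("X", sp),
                               global = sp$global)
  expect_lte(er$dose_used, sp$global$max_ddd_per_day)
  expect_equal(er$limit_applied, "global_dose_cap")
})
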