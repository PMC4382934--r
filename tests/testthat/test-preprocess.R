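test_that("gap arithmetic subtracts hospital days and floors at one", {
  p <- purchases_tbl("P1", c("2005-01-01", "2005-01-31"), 30)
  s <- stays_tbl("P1", "2005-01-10", "2005-01-20")
  g <- compute_gaps(sort_histories(harmonize_purchases(p)), s)
  expect_equal(g$raw_gap_days[1], 30)
  expect_equal(g$hospital_days_in_gap[1], 10)
  expect_equal(g$net_gap_days[1], 20)

  # a stay spanning the whole gap floors the net gap at 1 day
  s2 <- stays_tbl("P1", "2004-12-01", "2005-03-01")
  g2 <- compute_gaps(sort_histories(harmonize_purchases(p)), s2)
  expect_equal(g2$net_gap_days[1], 1)
})

test_that("gaps over the maximum refill time start a new segment", {
  p <- purchases_tbl("P1", as.Date("2005-01-01") + c(0, 400, 430), 30)
  g <- compute_gaps(sort_histories(harmonize_purchases(p)))
  expect_equal(g$segment_id, c(1L, 2L, 2L))
  # a 400-day raw gap mostly spent in hospital does not break the segment
  s <- stays_tbl("P1", "2005-01-15", "2006-01-15")
  g2 <- compute_gaps(sort_histories(harmonize_purchases(p)), s)
  expect_equal(g2$segment_id, c(1L, 1L, 1L))
})

test_that("hospital day counts match day-by-day enumeration on random stays", {
  set.seed(21)
  for (rep in 1:30) {
    d1 <- as.Date("2005-01-01") + sample(0:50, 1)
    d2 <- d1 + sample(1:120, 1)
    adm <- as.Date("2005-01-01") + sort(sample(0:200, 3))
    len <- sample(1:40, 3, replace = TRUE)
    s <- stays_tbl("P1", as.character(adm), as.character(adm + len))
    p <- purchases_tbl("P1", c(d1, d2), 30)
    g <- compute_gaps(sort_histories(harmonize_purchases(p)), s)
    sm <- merge_stays(s)
    days <- seq(d1, d2 - 1, by = "day")
    truth <- sum(vapply(days, function(day) {
      any(day >= sm$admission & day < sm$discharge)
    }, logical(1)))
    expect_equal(g$hospital_days_in_gap[1], truth)
  }
})

test_that("the worked five-purchase example reproduces exactly", {
  pre <- prepped(stockpiling_history())
  expect_equal(pre$ddd_avg, stockpiling_ddd_avg, tolerance = 1e-12)
  expect_equal(round(pre$ddd_avg, 2), c(1.09, 1.33, 0.80, 0.92, 1.00))
  # diagnostic refill times DDD_i / DDDAVG_i
  expect_equal(round(pre$ddd_amount / pre$ddd_avg, 2),
               c(9.17, 7.50, 12.50, 10.83, 10.00))
})

test_that("constant dosing gives a flat average of exactly the true dose", {
  p <- purchases_tbl("P1", as.Date("2005-01-01") + seq(0, 120, by = 30), 30)
  pre <- prepped(p)
  expect_equal(pre$ddd_avg, rep(1, 5))
  expect_equal(pre$ddd_avg_cv[1], 0)
})

test_that("histories below the minimum purchase count get no profile", {
  pre <- prepped(purchases_tbl("P1", c("2005-01-01", "2005-02-01"), 30))
  expect_true(all(is.na(pre$ddd_avg)))
  expect_true(all(is.na(pre$ddd_avg_cv)))
  # a short trailing segment of a long history is likewise untouched
  p <- purchases_tbl("P1", as.Date("2005-01-01") + c(0, 30, 60, 500, 530), 30)
  pre2 <- prepped(p)
  expect_equal(is.na(pre2$ddd_avg), c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("sliding average matches an independent transcription on random input", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    ddd <- sample(c(10, 20, 33, 50, 100), n, replace = TRUE)
    gaps <- sample(1:120, n - 1, replace = TRUE)
    p <- purchases_tbl("P1", as.Date("2005-01-01") + cumsum(c(0, gaps)), ddd)
    pre <- prepped(p)
    expect_equal(pre$ddd_avg, oracle_ddd_avg(ddd, gaps), tolerance = 1e-9)
  }
})

test_that("scale equivariance: c x amounts => c x averages, cv unchanged", {
  p <- purchases_tbl("P1", as.Date("2005-01-01") + c(0, 10, 15, 30, 40),
                     c(10, 10, 10, 10, 10))
  p2 <- dplyr::mutate(p, ddd_amount = ddd_amount * 3.7)
  a <- prepped(p); b <- prepped(p2)
  expect_equal(b$ddd_avg, 3.7 * a$ddd_avg, tolerance = 1e-12)
  expect_equal(b$ddd_avg_cv, a$ddd_avg_cv, tolerance = 1e-12)
})

test_that("hospital neutrality: a stay stretching a gap leaves doses unchanged", {
  p <- purchases_tbl("P1", as.Date("2005-01-01") + c(0, 10, 15, 30, 40), 10)
  a <- prepped(p)
  # insert a 12-day stay into the third gap and lengthen it by 12 days
  p2 <- p
  p2$date[4:5] <- p2$date[4:5] + 12
  s <- stays_tbl("P1", "2005-01-18", "2005-01-30")
  b <- prepped(p2, s)
  expect_equal(b$ddd_avg, a$ddd_avg, tolerance = 1e-12)
  expect_equal(b$ddd_avg_cv, a$ddd_avg_cv, tolerance = 1e-12)
})

test_that("cv equals sd/mean of the dose averages, computed independently", {
  pre <- prepped(stockpiling_history())
  v <- c(60 / 55, 60 / 45, 60 / 75, 60 / 65, 1)
  expect_equal(pre$ddd_avg_cv[1], stats::sd(v) / mean(v), tolerance = 1e-12)
})

test_that("missing amounts poison only the purchases whose window sees them", {
  p <- purchases_tbl("P1", as.Date("2005-01-01") + c(0, 30, 60, 90, 120),
                     c(30, 30, NA, 30, 30))
  pre <- prepped(p)
  expect_equal(is.na(pre$ddd_avg), c(FALSE, TRUE, TRUE, TRUE, FALSE))
})
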