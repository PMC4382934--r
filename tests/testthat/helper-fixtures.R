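# Shared fixtures, all built in code.

# A five-purchase history of 10 DDD each with inter-purchase gaps
# 10, 5, 15, 10 days: the canonical stockpiling example (purchase 2 buys
# ahead, purchase 3 uses the stock).
stockpiling_history <- function(person = "P1", atc = "N05AH02",
                                vnr = "012345",
                                start = as.Date("2005-01-01")) {
  tibble::tibble(
    person_id = person,
    date = start + c(0, 10, 15, 30, 40),
    atc = atc, vnr = vnr, n_packages = 1L, ddd_amount = 10,
    dose_dispensing = FALSE)
}

# frozen expectations for that history, recomputed by hand from the
# weighted-ratio definition: (5*10+10)/(5*10+5), (10+40+10)/(10+20+15),
# (10+40+10)/(5+60+10), (10+40+10)/(15+40+10), (10+50)/(10+50)
stockpiling_ddd_avg <- c(60 / 55, 60 / 45, 60 / 75, 60 / 65, 1)

purchases_tbl <- function(person, dates, ddd, atc = "N05AH02",
                          vnr = "012345", n_packages = 1L,
                          dose_dispensing = FALSE) {
  tibble::tibble(person_id = person, date = as.Date(dates), atc = atc,
                 vnr = vnr, n_packages = as.integer(n_packages),
                 ddd_amount = ddd, dose_dispensing = dose_dispensing)
}

stays_tbl <- function(person, admission, discharge) {
  tibble::tibble(person_id = person, admission = as.Date(admission),
                 discharge = as.Date(discharge))
}

prepped <- function(purchases, stays = NULL, global = global_params()) {
  preprocess_histories(sort_histories(harmonize_purchases(purchases)),
                       stays, global)
}

# independent transcription of the sliding average for one segment: loops
# and explicit boundary weights, no shared code with the implementation
oracle_ddd_avg <- function(ddd, tnet) {
  n <- length(ddd)
  t_imp <- ddd[n] / (ddd[n - 1] / tnet[n - 1])
  tt <- c(tnet[seq_len(n - 1)], t_imp)
  sapply(seq_len(n), function(i) {
    if (i == 1) {
      (5 * ddd[1] + ddd[2]) / (5 * tt[1] + tt[2])
    } else if (i == n) {
      (ddd[n - 1] + 5 * ddd[n]) / (tt[n - 1] + 5 * tt[n])
    } else {
      (ddd[i - 1] + 4 * ddd[i] + ddd[i + 1]) /
        (tt[i - 1] + 4 * tt[i] + tt[i + 1])
    }
  })
}

# random small purchase table across several persons/ATCs, for property
# tests; gaps and amounts chosen to exercise joins, splits and segments
random_purchases <- function(n_persons = 20, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_persons), function(j) {
    np <- sample(1:9, 1)
    gaps <- sample(c(5:40, 90, 200, 350, 400), np, replace = TRUE)
    tibble::tibble(
      person_id = sprintf("R%03d", j),
      date = as.Date("2004-01-01") + cumsum(c(sample(0:200, 1), gaps[-1])),
      atc = sample(c("N05AH02", "N06AB04"), np, replace = TRUE),
      vnr = sample(c("012345", "010940", NA), np, replace = TRUE),
      n_packages = sample(1:2, np, replace = TRUE),
      ddd_amount = sample(c(10, 30, 50, NA), np, replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1)),
      dose_dispensing = FALSE)
  })
}
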