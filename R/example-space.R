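#' A small illustrative parameter space
#'
#' Expert parameter tables are register- and cohort-specific and are
#' supplied by the user in practice; this space ships a handful of
#' plausible entries for documentation, tests and the packaged examples:
#' an antipsychotic-like and an antidepressant-like nervous-system class, a
#' statin-like lipid modifier, and two packages — a 30-DDD monthly pack
#' (vnr `012345`) and a 98-tablet, 0.33-DDD-per-tablet pack (vnr `010940`).
#'
#' @return An `rx_parameter_space`.
#' @examples
#' example_parameter_space()
#' @export
example_parameter_space <- function() {
  parameter_space(
    global = global_params(),
    atc = tibble::tibble(
      atc_prefix = c("N05A", "N06A", "C10AA", "N"),
      min_ddd_per_day = c(0.02, 0.05, 0.05, 0.02),
      common_ddd_per_day = c(1, 1, 1, 1),
      min_period_days = c(10, 14, 30, 10),
      max_refill_days = c(200, 200, 250, 200)),
    vnr = tibble::tibble(
      vnr = c("012345", "010940"),
      min_refill_days = c(15, 49),
      max_refill_days = c(120, 118),
      typical_refill_days = c(30, 98),
      ddd_per_day_at_min = c(2, 0.66),
      ddd_per_day_at_max = c(0.25, 0.27),
      ddd_per_day_typical = c(1, 0.33)))
}
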