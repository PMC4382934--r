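#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline fit into its period table
#'
#' @param x An `rx_dup_fit`.
#' @param ... Unused.
#' @return The periods tibble (one row per drug use period).
#' @method tidy rx_dup_fit
#' @export
tidy.rx_dup_fit <- function(x, ...) x$periods

#' One-row summary of a pipeline fit
#'
#' @param x An `rx_dup_fit`.
#' @param ... Unused.
#' @return A tibble with cohort-level counts, the iteration count,
#'   convergence flag, and period-length / dose summaries.
#' @method glance rx_dup_fit
#' @export
glance.rx_dup_fit <- function(x, ...) {
  p <- x$periods
  tibble::tibble(
    n_periods = nrow(p),
    n_purchases = nrow(x$audit),
    n_persons = dplyr::n_distinct(p$person_id),
    n_single_purchase = sum(p$n_purchases == 1L),
    mean_period_days = mean(as.numeric(p$end - p$start)),
    median_dose_ddd_day = stats::median(p$mean_ddd_per_day, na.rm = TRUE),
    n_refill_modes = nrow(x$modes),
    iterations = x$iterations,
    converged = x$converged)
}

#' @rdname tidy.rx_dup_fit
#' @method tidy rx_dup_score
#' @export
tidy.rx_dup_score <- function(x, ...) x$histories

#' @rdname glance.rx_dup_fit
#' @method glance rx_dup_score
#' @export
glance.rx_dup_score <- function(x, ...) x$summary

#' Timeline plot of drug use periods
#'
#' One horizontal segment per period, persons on the y axis, faceted by
#' ATC code, with member purchases overplotted as points. Useful for
#' eyeballing whether the decision walk joined and split histories
#' sensibly.
#'
#' @param object An `rx_dup_fit`.
#' @param persons Optional character vector restricting the persons shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rx_dup_fit
#' @export
autoplot.rx_dup_fit <- function(object, persons = NULL, ...) {
  p <- object$periods
  a <- object$audit
  if (!is.null(persons)) {
    p <- dplyr::filter(p, .data$person_id %in% persons)
    a <- dplyr::filter(a, .data$person_id %in% persons)
  }
  ggplot2::ggplot(p) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$person_id,
                                       yend = .data$person_id,
                                       colour = .data$mean_ddd_per_day),
                          linewidth = 2) +
    ggplot2::geom_point(data = a,
                        ggplot2::aes(x = .data$date, y = .data$person_id),
                        shape = 3, size = 1) +
    ggplot2::facet_wrap(~atc, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "DDD/day",
                  title = "Drug use periods",
                  subtitle = "segments: periods; crosses: purchases") +
    ggplot2::theme_minimal()
}

#' Plot a package refill-length histogram and its joined form
#'
#' @param observations Long-form observations ([collect_refill_observations()]).
#' @param vnr The package to plot.
#' @param global A [global_params()] object (for the mode threshold line).
#' @return A ggplot object: raw counts as bars, joined counts overlaid.
#' @export
plot_refill_distribution <- function(observations, vnr,
                                     global = global_params()) {
  h <- dplyr::filter(tibble::as_tibble(observations), .data$vnr == !!vnr)
  if (!nrow(h)) abort(sprintf("no observations for vnr %s", vnr))
  joined <- join_to_local_maxima(h)
  both <- dplyr::bind_rows(
    dplyr::mutate(h[c("refill_days", "n")], what = "raw"),
    dplyr::mutate(joined, what = "joined"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$refill_days, y = .data$n,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = global$mode_min_purchases,
                        linetype = "dashed") +
    ggplot2::labs(x = "refill length (days)", y = "purchases", fill = NULL,
                  title = sprintf("Refill length distribution, package %s", vnr)) +
    ggplot2::theme_minimal()
}
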