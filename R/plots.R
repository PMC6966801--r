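# ggplot2 views of survey summaries and simulation output.

#' Plot a binned conditional-power distribution
#'
#' Bar chart of the four conventional CP bins, faceted by hypothesis, and
#' optionally filled by sponsor (current-trend values only, reported-only
#' values included — the convention surveys use when authors do not state
#' their assumption).
#'
#' @param summary A `survey_summary` from [summarize_survey()].
#' @param by_sponsor Fill bars by sponsor (requires the summary to have been
#'   built with a registry).
#' @return A ggplot object.
#' @export
plot_cp_bins <- function(summary, by_sponsor = FALSE) {
  stopifnot(inherits(summary, "survey_summary"))
  if (by_sponsor) {
    if (is.null(summary$bins_by_sponsor)) {
      abort("sponsor strata unavailable: build the summary with its registry",
            class = "cpaudit_error")
    }
    p <- ggplot2::ggplot(summary$bins_by_sponsor,
                         ggplot2::aes(x = .data$bin, y = .data$n,
                                      fill = .data$sponsor)) +
      ggplot2::geom_col(position = "stack") +
      ggplot2::labs(title = "Conditional power by sponsor (current-trend hypothesis)")
  } else {
    p <- ggplot2::ggplot(summary$bins,
                         ggplot2::aes(x = .data$bin, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~hypothesis) +
      ggplot2::labs(title = "Conditional power at the final interim analysis")
  }
  p + ggplot2::labs(x = "conditional power", y = "trials") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cp_bins
#' @param object A `survey_summary`.
#' @param ... Passed to [plot_cp_bins()].
#' @method autoplot survey_summary
#' @export
autoplot.survey_summary <- function(object, ...) plot_cp_bins(object, ...)

#' Plot estimate distributions by stopping stratum
#'
#' Histograms of the final effect estimate for stopped versus completed
#' simulated trials, with the true effect marked — the visual form of the
#' under/over-estimation pattern that futility rules induce.
#'
#' @param sims Output of [simulate_trials()].
#' @param theta_true True effect used in the simulation.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_bias <- function(sims, theta_true, bins = 40) {
  stopifnot(is.data.frame(sims))
  d <- sims |>
    mutate(stratum = ifelse(.data$stopped_at_look > 0L, "stopped", "completed"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$final_estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey55") +
    ggplot2::geom_vline(xintercept = theta_true, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~stratum, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "final effect estimate", y = "trials",
                  title = "Effect estimates under a futility stopping rule",
                  subtitle = "dashed line: true effect") +
    ggplot2::theme_minimal()
}
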