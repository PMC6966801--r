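# Converters from published trial summaries to interim states on the common
# information scale.  Each converter tags its output with the variance method
# used so downstream audits are traceable.

#' Interim state from per-arm binary outcomes
#'
#' Builds an [interim_state()] from event counts in each arm, on either the
#' risk-difference scale (unpooled Wald variance) or the log-odds-ratio scale
#' (Woolf variance \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}). Benefit-positive
#' orientation: the treatment arm comes first, so a positive risk difference
#' or log odds ratio favours treatment — negate the inputs' arm order if more
#' events mean harm.
#'
#' @param events_treat,n_treat Events and sample size in the treatment arm.
#' @param events_ctrl,n_ctrl Events and sample size in the control arm.
#' @param measure `"risk_difference"` or `"log_odds_ratio"`.
#' @param correction Apply the +0.5 continuity correction to all four cells
#'   of the 2x2 table (log odds ratio only). Default off; with it off a zero
#'   cell is an error naming the cell.
#' @return An [interim_state()] with `estimate`, `se`, `z`, `information`
#'   filled, `method` tagged.
#' @examples
#' interim_from_binary(30, 100, 20, 100, measure = "risk_difference")
#' @export
interim_from_binary <- function(events_treat, n_treat, events_ctrl, n_ctrl,
                                measure = c("risk_difference", "log_odds_ratio"),
                                correction = FALSE) {
  measure <- match.arg(measure)
  check_number(n_treat, "n_treat", 1, Inf)
  check_number(n_ctrl, "n_ctrl", 1, Inf)
  check_number(events_treat, "events_treat", 0, n_treat)
  check_number(events_ctrl, "events_ctrl", 0, n_ctrl)

  flags <- character()
  if (measure == "risk_difference") {
    p1 <- events_treat / n_treat
    p0 <- events_ctrl / n_ctrl
    est <- p1 - p0
    v1 <- p1 * (1 - p1) / n_treat
    v0 <- p0 * (1 - p0) / n_ctrl
    if (v1 == 0 || v0 == 0) flags <- c(flags, "degenerate_arm_proportion")
    se <- sqrt(v1 + v0)
    if (se == 0) {
      abort_domain("both arm variances are zero; risk-difference SE undefined")
    }
    method <- "wald_risk_difference"
  } else {
    a <- events_treat; b <- n_treat - events_treat
    cc <- events_ctrl; d <- n_ctrl - events_ctrl
    cells <- c(a = a, b = b, c = cc, d = d)
    if (any(cells == 0)) {
      if (!correction) {
        abort_domain(sprintf(
          "zero cell(s) %s in the 2x2 table; enable `correction` for a +0.5 continuity correction",
          paste(names(cells)[cells == 0], collapse = ", ")
        ))
      }
      cells <- cells + 0.5
      flags <- c(flags, "continuity_corrected")
    }
    est <- log(cells[["a"]] * cells[["d"]] / (cells[["b"]] * cells[["c"]]))
    se <- sqrt(sum(1 / cells))
    method <- "woolf_log_odds_ratio"
  }
  interim_state(estimate = est, se = se, method = method, flags = flags)
}

#' Interim state from per-arm continuous outcomes
#'
#' Two-sample Wald statistic on the mean difference:
#' \eqn{\hat\theta = \bar x_t - \bar x_c},
#' \eqn{SE = \sqrt{s_t^2/n_t + s_c^2/n_c}}.
#'
#' @param mean_treat,sd_treat,n_treat Treatment-arm mean, SD, size.
#' @param mean_ctrl,sd_ctrl,n_ctrl Control-arm mean, SD, size.
#' @return An [interim_state()], `method = "wald_mean_difference"`.
#' @examples
#' interim_from_continuous(1, 2, 50, 0, 2, 50)
#' @export
interim_from_continuous <- function(mean_treat, sd_treat, n_treat,
                                    mean_ctrl, sd_ctrl, n_ctrl) {
  check_number(mean_treat, "mean_treat")
  check_number(mean_ctrl, "mean_ctrl")
  check_number(sd_treat, "sd_treat", 0, Inf, open_lower = TRUE)
  check_number(sd_ctrl, "sd_ctrl", 0, Inf, open_lower = TRUE)
  check_number(n_treat, "n_treat", 2, Inf)
  check_number(n_ctrl, "n_ctrl", 2, Inf)
  est <- mean_treat - mean_ctrl
  se <- sqrt(sd_treat^2 / n_treat + sd_ctrl^2 / n_ctrl)
  interim_state(estimate = est, se = se, method = "wald_mean_difference")
}

#' Interim state from a survival summary
#'
#' Uses the reported SE of the log hazard ratio when available
#' (\eqn{I = SE^{-2}}); otherwise the 1:1-allocation approximation
#' \eqn{I \approx d/4} with d the total number of events, flagged as
#' approximate. The log hazard ratio must be oriented benefit-positive by the
#' caller (negate a hazard ratio where events are bad and treatment reduces
#' them, if necessary).
#'
#' @param log_hazard_ratio Benefit-positive log hazard ratio.
#' @param total_events Total observed events, optional.
#' @param se_log_hr SE of the log hazard ratio, optional. At least one of
#'   `total_events` / `se_log_hr` is required.
#' @return An [interim_state()].
#' @examples
#' interim_from_survival(0.2, se_log_hr = 0.2)
#' interim_from_survival(0.2, total_events = 100) # events/4 approximation
#' @export
interim_from_survival <- function(log_hazard_ratio, total_events = NULL,
                                  se_log_hr = NULL) {
  check_number(log_hazard_ratio, "log_hazard_ratio")
  check_number(total_events, "total_events", 1, Inf, allow_null = TRUE)
  check_number(se_log_hr, "se_log_hr", 0, Inf, open_lower = TRUE,
               allow_null = TRUE)
  if (is.null(total_events) && is.null(se_log_hr)) {
    abort_insufficient(
      "survival summary needs `se_log_hr` or `total_events` to recover information",
      missing = c("se_log_hr", "total_events")
    )
  }
  if (!is.null(se_log_hr)) {
    interim_state(estimate = log_hazard_ratio, se = se_log_hr,
                  method = "cox_se")
  } else {
    info <- total_events / 4
    interim_state(estimate = log_hazard_ratio, se = 1 / sqrt(info),
                  method = "events_over_four",
                  flags = "approximate_information")
  }
}

#' Z statistic from an exact p-value
#'
#' Reconstructs the standardised test statistic from a reported exact
#' p-value: one-sided \eqn{Z = \Phi^{-1}(1-p)}, two-sided
#' \eqn{|Z| = \Phi^{-1}(1-p/2)}, signed by the reported direction of effect.
#' A p-value reported only as a bound (e.g. "<0.001", "NS") carries too
#' little information and is refused, never imputed.
#'
#' @param p Exact p-value strictly inside (0, 1).
#' @param sidedness `"one"` or `"two"` (the convention of the reported test).
#' @param direction `"benefit"` (positive Z) or `"harm"` (negative Z).
#' @param is_bound Set `TRUE` when the report gives only an inequality; this
#'   raises an insufficient-information error.
#' @return Signed Z.
#' @examples
#' z_from_pvalue(0.05, "two", "benefit") # 1.9600
#' @export
z_from_pvalue <- function(p, sidedness = c("two", "one"),
                          direction = c("benefit", "harm"),
                          is_bound = FALSE) {
  sidedness <- match.arg(sidedness)
  direction <- match.arg(direction)
  if (isTRUE(is_bound)) {
    abort_insufficient(
      "p-value reported only as a bound; Z cannot be reconstructed without guessing",
      missing = "p"
    )
  }
  check_number(p, "p", 0, 1, open_lower = TRUE, open_upper = TRUE)
  z <- if (sidedness == "one") qnorm(1 - p) else qnorm(1 - p / 2)
  if (direction == "harm") -z else z
}
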