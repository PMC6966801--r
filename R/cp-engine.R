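# Closed-form conditional power on the information-time scale.
#
# A two-arm sequential trial is modelled through its score process S(t) on
# information time t = I_k / I_K: increments are independent normal with mean
# theta * I_K * dt and variance I_K * dt, so Z_k = S(t_k) / sqrt(I_K t_k) and
# the conditional distribution of the final Z given the interim one is normal.
# Conditional power is the probability that the final test rejects at level
# alpha, given the interim statistic and a hypothesised effect theta for the
# remaining (1 - t_k) of the information.

#' Trial design parameters
#'
#' Bundles the planning parameters of a trial: significance level, sidedness,
#' planned power, and the design effect size \eqn{\theta_d} on the natural
#' analysis scale (the same scale as its standard error; log scale for ratio
#' measures). Total planned information \eqn{I_K} may be given explicitly;
#' otherwise it is derived from \eqn{(\alpha, \mathrm{power}, \theta_d)} by
#' [total_information()].
#'
#' The sign convention is benefit-positive throughout: a positive effect
#' favours the experimental arm, and the one-sided test rejects for large
#' positive Z.
#'
#' @param alpha Type-I error rate, in (0, 0.5].
#' @param sidedness `"one"` or `"two"`.
#' @param power Planned power, in (0, 1).
#' @param effect Design effect size \eqn{\theta_d}, nonzero, benefit-positive.
#' @param total_information Optional explicit total information \eqn{I_K}
#'   (inverse squared standard error of the final estimate). Takes precedence
#'   over the derived value.
#' @param planned_n Optional planned total sample size (descriptive only;
#'   never used to derive information).
#' @param outcome One of `"binary"`, `"continuous"`, `"time_to_event"`,
#'   `"other"`.
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(alpha = 0.025, sidedness = "one", power = 0.9, effect = 0.3)
#' @export
design_spec <- function(alpha = 0.05,
                        sidedness = c("two", "one"),
                        power = 0.8,
                        effect = NULL,
                        total_information = NULL,
                        planned_n = NULL,
                        outcome = c("other", "binary", "continuous", "time_to_event")) {
  sidedness <- match.arg(sidedness)
  outcome <- match.arg(outcome)
  check_number(alpha, "alpha", 0, 0.5, open_lower = TRUE)
  check_number(power, "power", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(effect, "effect", allow_null = TRUE)
  if (!is.null(effect) && effect == 0) {
    abort_domain("`effect` must be nonzero (benefit-positive orientation)")
  }
  check_number(total_information, "total_information", 0, Inf,
               open_lower = TRUE, allow_null = TRUE)
  check_number(planned_n, "planned_n", 1, Inf, allow_null = TRUE)
  structure(
    list(alpha = alpha, sidedness = sidedness, power = power, effect = effect,
         total_information = total_information, planned_n = planned_n,
         outcome = outcome),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> alpha = %g (%s-sided), power = %g\n",
              x$alpha, x$sidedness, x$power))
  if (!is.null(x$effect)) cat(sprintf("  design effect: %g\n", x$effect))
  if (!is.null(x$total_information)) {
    cat(sprintf("  total information (explicit): %g\n", x$total_information))
  }
  invisible(x)
}

#' Interim-analysis state
#'
#' The observable state of a trial at its k-th interim look: the standardised
#' test statistic \eqn{Z_k}, and whatever combination of effect estimate,
#' standard error, information \eqn{I_k} and information fraction
#' \eqn{t_k = I_k/I_K} the trial report provides.
#'
#' Internal consistency is enforced where fields overlap: when `se` and
#' `information` are both supplied, `information` must equal `se^-2`
#' (relative tolerance 1e-8); when `estimate` and `se` are both supplied, `z`
#' must equal `estimate / se` (same tolerance). Missing derivable fields are
#' filled from the identities.
#'
#' @param z Test statistic \eqn{Z_k}, benefit-positive.
#' @param estimate Interim effect estimate \eqn{\hat\theta_k}, optional.
#' @param se Standard error of the estimate, positive, optional.
#' @param information Interim information \eqn{I_k = SE^{-2}}, optional.
#' @param info_fraction Information fraction \eqn{t_k}, in (0, 1), optional.
#'   At least one of `information` / `info_fraction` must be resolvable by the
#'   time conditional power is computed.
#' @param look Look index k (positive integer).
#' @param method Optional tag naming the conversion that produced this state
#'   (set by the `interim_from_*()` converters).
#' @param flags Character vector of quality flags (e.g. approximate
#'   information).
#' @return An object of class `interim_state`.
#' @examples
#' interim_state(z = 1.2, info_fraction = 0.5)
#' interim_state(estimate = 0.1, se = 0.05)
#' @export
interim_state <- function(z = NULL, estimate = NULL, se = NULL,
                          information = NULL, info_fraction = NULL,
                          look = 1L, method = NULL, flags = character()) {
  check_number(se, "se", 0, Inf, open_lower = TRUE, allow_null = TRUE)
  check_number(information, "information", 0, Inf, open_lower = TRUE,
               allow_null = TRUE)
  check_number(info_fraction, "info_fraction", 0, 1,
               open_lower = TRUE, open_upper = TRUE, allow_null = TRUE)
  check_number(estimate, "estimate", allow_null = TRUE)
  check_number(z, "z", allow_null = TRUE)
  check_number(look, "look", 1, Inf)

  if (!is.null(se)) {
    if (!is.null(information)) {
      if (abs(information - se^-2) > 1e-8 * information) {
        abort_domain("`information` and `se` are inconsistent: information must equal se^-2")
      }
    } else {
      information <- se^-2
    }
  }
  if (!is.null(estimate) && !is.null(se)) {
    z_implied <- estimate / se
    if (is.null(z)) {
      z <- z_implied
    } else if (abs(z - z_implied) > 1e-8 * max(1, abs(z))) {
      abort_domain("`z` and `estimate`/`se` are inconsistent: z must equal estimate/se")
    }
  }
  structure(
    list(z = z, estimate = estimate, se = se, information = information,
         info_fraction = info_fraction, look = as.integer(look),
         method = method, flags = flags),
    class = "interim_state"
  )
}

#' @export
print.interim_state <- function(x, ...) {
  cat(sprintf("<interim_state> look %d\n", x$look))
  fld <- c(z = x$z, estimate = x$estimate, se = x$se,
           information = x$information, info_fraction = x$info_fraction)
  for (nm in names(fld)) cat(sprintf("  %s: %g\n", nm, fld[[nm]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Hypotheses about future data
#'
#' Conditional power depends on what true effect \eqn{\theta} is assumed for
#' the data not yet observed. Four conventional choices are supported:
#' the current trend in the interim data continues (`"current_trend"`,
#' \eqn{\theta = \hat\theta_k}); the original design effect is retained
#' (`"design"`, \eqn{\theta = \theta_d}); the optimistic upper limit of an
#' interim confidence interval (`"upper_cl"`,
#' \eqn{\theta = \hat\theta_k + \Phi^{-1}((1+\gamma)/2)\,SE}, two-sided CI
#' convention); or the null of no effect (`"null"`, \eqn{\theta = 0}).
#'
#' @param kind One of `"current_trend"`, `"design"`, `"upper_cl"`, `"null"`.
#' @param conf_level Confidence level \eqn{\gamma} in (0, 1); required exactly
#'   when `kind = "upper_cl"`.
#' @return An object of class `future_hypothesis`.
#' @examples
#' future_hypothesis("current_trend")
#' future_hypothesis("upper_cl", conf_level = 0.95)
#' @export
future_hypothesis <- function(kind = c("current_trend", "design", "upper_cl", "null"),
                              conf_level = NULL) {
  kind <- match.arg(kind)
  if (kind == "upper_cl") {
    check_number(conf_level, "conf_level", 0, 1,
                 open_lower = TRUE, open_upper = TRUE)
  } else if (!is.null(conf_level)) {
    abort_domain("`conf_level` is only meaningful for kind = \"upper_cl\"")
  }
  structure(list(kind = kind, conf_level = conf_level),
            class = "future_hypothesis")
}

as_hypothesis <- function(x) {
  if (inherits(x, "future_hypothesis")) return(x)
  if (is.character(x) && length(x) == 1L) return(future_hypothesis(x))
  abort_domain("`hypothesis` must be a future_hypothesis or a kind string")
}

#' Critical value of the final test
#'
#' \eqn{\Phi^{-1}(1-\alpha)} for a one-sided test, \eqn{\Phi^{-1}(1-\alpha/2)}
#' for a two-sided test, so that the rejection probability under the null is
#' exactly \eqn{\alpha} in both cases.
#'
#' @param alpha Type-I error rate, in (0, 0.5].
#' @param sidedness `"one"` or `"two"`.
#' @return The positive critical value c.
#' @examples
#' critical_value(0.05, "one") # 1.6449
#' critical_value(0.05, "two") # 1.9600
#' @export
critical_value <- function(alpha, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  check_number(alpha, "alpha", 0, 0.5, open_lower = TRUE)
  if (sidedness == "one") qnorm(1 - alpha) else qnorm(1 - alpha / 2)
}

#' Total planned information of a design
#'
#' Returns the explicit `total_information` of the design when set; otherwise
#' derives it from the standard sample-size identity on the information scale,
#' \deqn{I_K = \left(\frac{c + \Phi^{-1}(\mathrm{power})}{|\theta_d|}\right)^2,}
#' with c the critical value at the design's alpha and sidedness. The planned
#' sample size alone is never used (no variance model is available for it).
#'
#' @param design A [design_spec()].
#' @return Positive total information \eqn{I_K}.
#' @examples
#' total_information(design_spec(0.025, "one", 0.9, effect = 0.3)) # 116.75
#' @export
total_information <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(design$total_information)) return(design$total_information)
  if (is.null(design$effect)) {
    abort_insufficient(
      "cannot derive total information: design effect missing and no explicit value",
      missing = "effect"
    )
  }
  cv <- critical_value(design$alpha, design$sidedness)
  ((cv + qnorm(design$power)) / abs(design$effect))^2
}

#' Information from a standard error
#'
#' Statistical information is the inverse squared standard error of the
#' effect estimate, \eqn{I = SE^{-2}}.
#'
#' @param se Positive standard error.
#' @return Positive information.
#' @examples
#' information_from_se(0.1) # 100
#' @export
information_from_se <- function(se) {
  check_number(se, "se", 0, Inf, open_lower = TRUE)
  se^-2
}

#' Information fraction (information time)
#'
#' \eqn{t_k = I_k / I_K}, the proportion of the total planned information
#' accrued at look k. An interim at or beyond full information
#' (\eqn{I_k \ge I_K}) is a hard error of class `cpaudit_beyond_full_error`:
#' conditional power is undefined there and the value is never clamped —
#' the audit layer surfaces it as a flag and reports current significance
#' instead.
#'
#' @param i_k Interim information, positive.
#' @param i_total Total planned information, positive.
#' @return \eqn{t_k} in (0, 1).
#' @examples
#' information_fraction(50, 100) # 0.5
#' @export
information_fraction <- function(i_k, i_total) {
  check_number(i_k, "i_k", 0, Inf, open_lower = TRUE)
  check_number(i_total, "i_total", 0, Inf, open_lower = TRUE)
  if (i_k >= i_total) {
    abort_beyond_full(sprintf(
      "interim information (%g) is at or beyond full information (%g): conditional power is undefined; report current significance instead",
      i_k, i_total
    ))
  }
  i_k / i_total
}

#' Resolve the hypothesised future effect
#'
#' Maps a [future_hypothesis()] to the numeric \eqn{\theta} used in the
#' conditional-power formula: the interim estimate for `current_trend`, the
#' design effect for `design`, zero for `null`, and
#' \eqn{\hat\theta_k + \Phi^{-1}((1+\gamma)/2)\,SE} for `upper_cl`.
#' Missing required interim fields raise an insufficient-information error
#' (caught, not fatal, in the audit layer).
#'
#' @param interim An [interim_state()].
#' @param design A [design_spec()].
#' @param hypothesis A [future_hypothesis()] or its kind as a string.
#' @return The numeric effect \eqn{\theta} to assume for future data.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' resolve_theta(interim_state(z = 1), d, "design") # 0.3
#' @export
resolve_theta <- function(interim, design, hypothesis) {
  stopifnot(inherits(interim, "interim_state"), inherits(design, "design_spec"))
  hypothesis <- as_hypothesis(hypothesis)
  switch(
    hypothesis$kind,
    null = 0,
    design = {
      if (is.null(design$effect)) {
        abort_insufficient("design hypothesis requires the design effect size",
                           missing = "effect")
      }
      design$effect
    },
    current_trend = {
      if (is.null(interim$estimate)) {
        abort_insufficient("current-trend hypothesis requires the interim effect estimate",
                           missing = "estimate")
      }
      interim$estimate
    },
    upper_cl = {
      if (is.null(interim$estimate) || is.null(interim$se)) {
        abort_insufficient(
          "upper-confidence-limit hypothesis requires the interim estimate and its SE",
          missing = c("estimate", "se")[c(is.null(interim$estimate), is.null(interim$se))]
        )
      }
      interim$estimate + qnorm((1 + hypothesis$conf_level) / 2) * interim$se
    }
  )
}

# Vectorised closed form; all arguments recycled.  Clamps only floating-point
# overshoot (guard 1e-12); the formula itself stays in [0,1].
cp_closed_form <- function(z, t, theta, i_total, crit, sidedness) {
  drift <- theta * sqrt(i_total) * (1 - t)
  s <- sqrt(1 - t)
  cp <- 1 - pnorm((crit - z * sqrt(t) - drift) / s)
  if (sidedness == "two") {
    cp <- cp + pnorm((-crit - z * sqrt(t) - drift) / s)
  }
  pmin(pmax(cp, 0), 1)
}

resolve_t_k <- function(interim, design) {
  if (!is.null(interim$info_fraction)) return(interim$info_fraction)
  if (!is.null(interim$information)) {
    return(information_fraction(interim$information, total_information(design)))
  }
  abort_insufficient(
    "cannot resolve the information fraction: need info_fraction or interim information",
    missing = "info_fraction"
  )
}

#' Conditional power at an interim analysis
#'
#' The probability of rejecting the null at the completion of the trial,
#' given the interim data and a hypothesised true effect \eqn{\theta} for the
#' unobserved future data. One-sided:
#' \deqn{CP_k(\theta) = 1 - \Phi\!\left(\frac{c - Z_k\sqrt{t_k} -
#'   \theta\sqrt{I_K}(1-t_k)}{\sqrt{1-t_k}}\right),}
#' and the two-sided version adds the symmetric lower-tail term
#' \eqn{\Phi((-c - Z_k\sqrt{t_k} - \theta\sqrt{I_K}(1-t_k))/\sqrt{1-t_k})},
#' with c from [critical_value()] (\eqn{\alpha/2} convention for two-sided
#' tests, recorded in the result).
#'
#' @param interim An [interim_state()]; `z` and a resolvable \eqn{t_k} are
#'   required.
#' @param design A [design_spec()]; \eqn{I_K} must be resolvable via
#'   [total_information()].
#' @param hypothesis A [future_hypothesis()] or kind string
#'   (default `"current_trend"`).
#' @param threshold Futility threshold on CP (default 0.15, the conventional
#'   value for stochastic-curtailment stopping).
#' @return An object of class `cp_result` with elements `cp`, `theta`,
#'   `hypothesis`, `t_k`, `critical_value`, `sidedness`, `threshold`,
#'   `futile`. Use [tidy()] for a one-row tibble.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' i <- interim_state(z = 1.0, info_fraction = 0.5, estimate = 0.13)
#' conditional_power(i, d, "design")
#' @export
conditional_power <- function(interim, design,
                              hypothesis = "current_trend",
                              threshold = 0.15) {
  stopifnot(inherits(interim, "interim_state"), inherits(design, "design_spec"))
  hypothesis <- as_hypothesis(hypothesis)
  check_number(threshold, "threshold", 0, 1)
  if (is.null(interim$z)) {
    abort_insufficient("conditional power requires the interim test statistic z",
                       missing = "z")
  }
  t_k <- resolve_t_k(interim, design)
  i_total <- total_information(design)
  theta <- resolve_theta(interim, design, hypothesis)
  crit <- critical_value(design$alpha, design$sidedness)
  cp <- cp_closed_form(interim$z, t_k, theta, i_total, crit, design$sidedness)
  structure(
    list(cp = cp, theta = theta, hypothesis = hypothesis$kind, t_k = t_k,
         critical_value = crit, sidedness = design$sidedness,
         threshold = threshold, futile = classify_futility(cp, threshold),
         z = interim$z, total_information = i_total),
    class = "cp_result"
  )
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf(
    "<cp_result> CP = %.4f under %s hypothesis (theta = %.4g)\n  t_k = %.3f, %s-sided c = %.4f, futile at %.2f: %s\n",
    x$cp, x$hypothesis, x$theta, x$t_k, x$sidedness, x$critical_value,
    x$threshold, x$futile
  ))
  invisible(x)
}

#' @rdname conditional_power
#' @param x A `cp_result`.
#' @param ... Unused.
#' @method tidy cp_result
#' @export
tidy.cp_result <- function(x, ...) {
  tibble(
    cp = x$cp, theta = x$theta, hypothesis = x$hypothesis, t_k = x$t_k,
    z = x$z, critical_value = x$critical_value, sidedness = x$sidedness,
    total_information = x$total_information, threshold = x$threshold,
    futile = x$futile
  )
}

#' Classify futility from conditional power
#'
#' A trial is classified futile when its conditional power falls strictly
#' below the threshold (so CP exactly at the threshold is not futile).
#' Conventional thresholds are 0.10-0.15.
#'
#' @param cp Conditional power in \[0, 1\].
#' @param threshold Futility threshold in \[0, 1\].
#' @return Logical.
#' @examples
#' classify_futility(0.10, 0.15) # TRUE
#' classify_futility(0.15, 0.15) # FALSE
#' @export
classify_futility <- function(cp, threshold) {
  check_number(cp, "cp", 0, 1)
  check_number(threshold, "threshold", 0, 1)
  cp < threshold
}
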