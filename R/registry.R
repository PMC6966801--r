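# Synthetic registry of trials stopped for futility.
#
# Emulates the marginal structure of a survey of 52 such trials: outcome-type
# mix 33/10/8 over the supported kinds, industry/non-industry sponsorship
# 21/31, sidedness 14/33/5, roughly 16/52 records too incomplete to compute
# conditional power and 11/52 reporting a CP value without computable inputs,
# planned sample sizes lognormal around a median of 209, and interim timing
# concentrated near half information.  Joint dependencies between columns are
# modelled as independent.  Interim results are generated from the Brownian
# score model at the drawn information fraction, with the true effect a
# configurable fraction of the design effect (default half).

#' Registry generator configuration
#'
#' All category mixes are probability vectors (validated to sum to 1 within
#' 1e-9). Defaults reproduce the surveyed marginals; every one is
#' overridable.
#'
#' @param n_trials Number of registry rows (default 52).
#' @param outcome_mix Probabilities over `binary`, `continuous`,
#'   `time_to_event`.
#' @param sponsor_mix Probabilities over `industry`, `non_industry`.
#' @param sidedness_mix Probabilities over `one`, `two`, `unclear`.
#' @param power_mix Probabilities over planned powers 0.75, 0.80, 0.90.
#' @param info_fraction_mix Probabilities over interim-timing bins
#'   `[0.11,0.40)`, `[0.40,0.60)`, `[0.60,0.80)`, `[0.80,0.98)`; the fraction
#'   is drawn uniformly within the sampled bin.
#' @param planned_n_meanlog,planned_n_sdlog Lognormal parameters of the
#'   planned total sample size (median 209, log-scale spread matching an
#'   inter-quartile range of roughly 133-586).
#' @param insufficient_fraction Probability a row lacks every CP-computable
#'   interim field (p-value reported only as a bound).
#' @param reported_fraction Probability a row reports a conditional-power
#'   value while lacking computable inputs (audited as reported-only).
#' @param effect_ratio True effect as a multiple of the design effect
#'   (default 0.5: observed effects in trials stopped for futility run well
#'   below their targets).
#' @param effect_range Range the design effect is drawn from (uniform).
#' @param seed Master seed.
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(n_trials = 52L,
                            outcome_mix = c(binary = 33, continuous = 10,
                                            time_to_event = 8) / 51,
                            sponsor_mix = c(industry = 21, non_industry = 31) / 52,
                            sidedness_mix = c(one = 14, two = 33, unclear = 5) / 52,
                            power_mix = c(`0.75` = 1, `0.8` = 32, `0.9` = 15) / 48,
                            info_fraction_mix = c(early = 11, half = 20,
                                                  late = 12, very_late = 6) / 49,
                            planned_n_meanlog = log(209),
                            planned_n_sdlog = 1.1,
                            insufficient_fraction = 16 / 52,
                            reported_fraction = 11 / 52,
                            effect_ratio = 0.5,
                            effect_range = c(0.2, 0.5),
                            seed = 1L) {
  check_number(n_trials, "n_trials", 1, Inf)
  check_number(insufficient_fraction, "insufficient_fraction", 0, 1)
  check_number(reported_fraction, "reported_fraction", 0, 1)
  if (insufficient_fraction + reported_fraction > 1) {
    abort_domain("insufficient_fraction + reported_fraction must not exceed 1")
  }
  check_number(effect_ratio, "effect_ratio")
  check_number(seed, "seed")
  for (nm in c("outcome_mix", "sponsor_mix", "sidedness_mix", "power_mix",
               "info_fraction_mix")) {
    v <- get(nm)
    if (!is.numeric(v) || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      abort_domain(sprintf("`%s` must be nonnegative probabilities summing to 1", nm))
    }
  }
  structure(
    list(n_trials = as.integer(n_trials), outcome_mix = outcome_mix,
         sponsor_mix = sponsor_mix, sidedness_mix = sidedness_mix,
         power_mix = power_mix, info_fraction_mix = info_fraction_mix,
         planned_n_meanlog = planned_n_meanlog,
         planned_n_sdlog = planned_n_sdlog,
         insufficient_fraction = insufficient_fraction,
         reported_fraction = reported_fraction,
         effect_ratio = effect_ratio, effect_range = effect_range,
         seed = as.integer(seed)),
    class = "registry_config"
  )
}

info_fraction_bins <- rbind(early = c(0.11, 0.40), half = c(0.40, 0.60),
                            late = c(0.60, 0.80), very_late = c(0.80, 0.98))

#' Generate a synthetic trial registry
#'
#' Emits one row per trial in the documented registry schema (see
#' `system.file("extdata", "registry_schema.csv", package = "cpaudit")`).
#' Rows come in three completeness classes: fully computable interim results;
#' rows whose p-value is only a bound and that lack estimate, SE and Z
#' (audited as insufficient); and rows that carry a `reported_cp` — the
#' current-trend conditional power of the hidden simulated interim, rounded
#' to two decimals — but no computable inputs (audited as reported-only).
#' Fully seeded: the same configuration yields byte-identical tables.
#'
#' @param ... Arguments passed to [registry_config()] when `config` is not
#'   supplied.
#' @param config A [registry_config()]; overrides `...`.
#' @return A tibble, one row per trial.
#' @examples
#' generate_registry(n_trials = 10, seed = 42)
#' @export
generate_registry <- function(..., config = NULL) {
  if (is.null(config)) config <- registry_config(...)
  stopifnot(inherits(config, "registry_config"))
  n <- config$n_trials
  withr::with_seed(config$seed, {
    status <- sample(c("computed", "insufficient", "reported_only"), n,
                     replace = TRUE,
                     prob = c(1 - config$insufficient_fraction - config$reported_fraction,
                              config$insufficient_fraction,
                              config$reported_fraction))
    outcome_kind <- sample(names(config$outcome_mix), n, replace = TRUE,
                           prob = config$outcome_mix)
    sponsor <- sample(names(config$sponsor_mix), n, replace = TRUE,
                      prob = config$sponsor_mix)
    sidedness <- sample(names(config$sidedness_mix), n, replace = TRUE,
                        prob = config$sidedness_mix)
    planned_power <- as.numeric(sample(names(config$power_mix), n,
                                       replace = TRUE, prob = config$power_mix))
    alpha <- ifelse(sidedness == "one", 0.025, 0.05)
    planned_total_n <- pmax(
      20L, 2L * round(exp(rnorm(n, config$planned_n_meanlog,
                                config$planned_n_sdlog)) / 2)
    )
    bin <- sample(rownames(info_fraction_bins), n, replace = TRUE,
                  prob = config$info_fraction_mix)
    info_fraction <- runif(n, info_fraction_bins[bin, 1],
                           info_fraction_bins[bin, 2])
    design_effect <- runif(n, config$effect_range[1], config$effect_range[2])
    theta_true <- config$effect_ratio * design_effect
    dsmb <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(36, 16) / 52)
    decision_maker <- sample(
      c("investigators_on_dsmb_advice", "dsmb", "sponsor",
        "executive_committee", "not_stated"),
      n, replace = TRUE, prob = c(30, 3, 3, 1, 15) / 52
    )
    data_collection_continued <- sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                                        prob = c(21, 23, 8) / 52)
    n_looks_planned <- sample(c(1L, 2L, 3L), n, replace = TRUE,
                              prob = c(19, 5, 2) / 26)
    n_looks_actual <- 1L

    # interim results from the Brownian score model (two-sided alpha used to
    # size unclear-sidedness designs)
    gen_sided <- ifelse(sidedness == "one", "one", "two")
    crit <- qnorm(ifelse(gen_sided == "one", 1 - alpha, 1 - alpha / 2))
    i_total <- ((crit + qnorm(planned_power)) / design_effect)^2
    se <- 1 / sqrt(info_fraction * i_total)
    estimate <- rnorm(n, theta_true, se)
    z_value <- estimate / se
    p_value <- ifelse(gen_sided == "one", 1 - pnorm(z_value),
                      2 * (1 - pnorm(abs(z_value))))
    p_is_bound <- rep(FALSE, n)

    # hidden-data current-trend CP, used for rows that only report a value
    cp_hidden <- cp_vec(z_value, info_fraction, estimate, i_total, crit,
                        gen_sided)
    reported_cp <- rep(NA_real_, n)
    reported_cp_hypothesis <- rep(NA_character_, n)

    insufficient <- status == "insufficient"
    reported <- status == "reported_only"
    blank <- insufficient | reported
    estimate[blank] <- NA_real_
    se[blank] <- NA_real_
    z_value[blank] <- NA_real_
    p_value[blank] <- NA_real_
    p_value[insufficient] <- 0.001
    p_is_bound[insufficient] <- TRUE
    reported_cp[reported] <- pmin(pmax(round(cp_hidden[reported], 2), 0.01), 0.99)
    reported_cp_hypothesis[reported] <- sample(
      c("current_trend", NA_character_), sum(reported), replace = TRUE,
      prob = c(2, 9) / 11
    )

    tibble(
      trial_id = sprintf("T%03d", seq_len(n)),
      outcome_kind = outcome_kind,
      measure = c(binary = "risk_difference", continuous = "mean_difference",
                  time_to_event = "log_hazard_ratio")[outcome_kind],
      sponsor = sponsor,
      dsmb = dsmb,
      decision_maker = decision_maker,
      alpha = alpha,
      sidedness = sidedness,
      planned_power = planned_power,
      design_effect = design_effect,
      design_effect_scale = ifelse(outcome_kind == "time_to_event",
                                   "log_ratio", "natural"),
      planned_total_n = as.integer(planned_total_n),
      n_looks_planned = n_looks_planned,
      n_looks_actual = n_looks_actual,
      info_fraction = info_fraction,
      interim_n = as.integer(round(info_fraction * planned_total_n)),
      estimate = estimate,
      se = se,
      z_value = z_value,
      p_value = p_value,
      p_is_bound = p_is_bound,
      reported_cp = reported_cp,
      reported_cp_hypothesis = reported_cp_hypothesis,
      data_collection_continued = data_collection_continued
    )
  })
}

# vectorised one/two-sided CP where `sidedness` is a vector
cp_vec <- function(z, t, theta, i_total, crit, sidedness) {
  drift <- theta * sqrt(i_total) * (1 - t)
  s <- sqrt(1 - t)
  upper <- 1 - pnorm((crit - z * sqrt(t) - drift) / s)
  lower <- pnorm((-crit - z * sqrt(t) - drift) / s)
  pmin(pmax(upper + ifelse(sidedness == "two", lower, 0), 0), 1)
}

#' Write a registry to delimited text
#'
#' Plain CSV, UTF-8, empty cell for missing values — the same format
#' [read_registry()] reads.
#'
#' @param registry A registry tibble.
#' @param path Output file path.
#' @return `registry`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(is.data.frame(registry))
  readr::write_csv(registry, path, na = "")
  invisible(registry)
}
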