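# Group-sequential trial simulator on the information scale.
#
# The score process S(t) is Brownian motion with drift: between information
# times t and t' the increment is N(theta * I_K * (t'-t), I_K * (t'-t)).
# This is the canonical large-sample model behind the closed-form conditional
# power, which makes the simulator both a Monte-Carlo oracle for the closed
# form and a test bed for the estimation-bias properties of futility rules.

#' Simulation configuration
#'
#' @param design A [design_spec()] (supplies alpha, sidedness, and — directly
#'   or derived — the total information \eqn{I_K}).
#' @param theta_true True effect generating the data, benefit-positive.
#' @param look_fractions Strictly increasing information fractions of the
#'   interim looks, all in (0, 1). Default a single look at 0.5, the most
#'   common surveyed timing.
#' @param hypothesis [future_hypothesis()] (or kind string) used in the
#'   futility rule at each look. The current-trend hypothesis uses the
#'   running estimate \eqn{S_k/I_k}, recomputed at every look.
#' @param threshold Futility threshold on conditional power (default 0.15).
#' @param n_sim Number of simulated trials.
#' @param seed Master seed; per-trial seeds are derived from it so results
#'   do not depend on execution order.
#' @return An object of class `sim_config`.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' sim_config(d, theta_true = 0.15, n_sim = 100, seed = 1)
#' @export
sim_config <- function(design, theta_true, look_fractions = 0.5,
                       hypothesis = "current_trend", threshold = 0.15,
                       n_sim = 1000L, seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  check_number(theta_true, "theta_true")
  check_number(threshold, "threshold", 0, 1)
  check_number(n_sim, "n_sim", 1, Inf)
  check_number(seed, "seed")
  if (!is.numeric(look_fractions) || length(look_fractions) < 1L ||
      any(look_fractions <= 0) || any(look_fractions >= 1) ||
      any(diff(look_fractions) <= 0)) {
    abort_domain("`look_fractions` must be strictly increasing, all in (0, 1)")
  }
  hypothesis <- as_hypothesis(hypothesis)
  structure(
    list(design = design, theta_true = theta_true,
         look_fractions = as.numeric(look_fractions),
         hypothesis = hypothesis, threshold = threshold,
         n_sim = as.integer(n_sim), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Monte-Carlo conditional power
#'
#' Brute-force evaluation of conditional power by simulating the future
#' score increment: the final statistic is drawn as
#' \eqn{Z_K = Z_k\sqrt{t_k} + \theta\sqrt{I_K}(1-t_k) + \epsilon\sqrt{1-t_k}}
#' with \eqn{\epsilon \sim N(0,1)}, and the rejection fraction at the
#' design's alpha and sidedness is returned with its binomial standard
#' error. This is the independent oracle for [conditional_power()].
#'
#' @param interim An [interim_state()].
#' @param design A [design_spec()].
#' @param theta Hypothesised future effect (numeric; use [resolve_theta()]
#'   to obtain it from a named hypothesis).
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Seed for reproducibility.
#' @return A one-row tibble with `cp`, `mc_se`, `n_draws`.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' monte_carlo_cp(interim_state(z = 1, info_fraction = 0.5), d,
#'                theta = 0, n_draws = 1e4, seed = 1)
#' @export
monte_carlo_cp <- function(interim, design, theta, n_draws = 1e5, seed = 1L) {
  stopifnot(inherits(interim, "interim_state"), inherits(design, "design_spec"))
  check_number(theta, "theta")
  check_number(n_draws, "n_draws", 1, Inf)
  if (is.null(interim$z)) {
    abort_insufficient("Monte-Carlo CP requires the interim test statistic z",
                       missing = "z")
  }
  t_k <- resolve_t_k(interim, design)
  i_total <- total_information(design)
  crit <- critical_value(design$alpha, design$sidedness)
  z_final <- withr::with_seed(seed, {
    interim$z * sqrt(t_k) + theta * sqrt(i_total) * (1 - t_k) +
      rnorm(n_draws) * sqrt(1 - t_k)
  })
  reject <- if (design$sidedness == "one") z_final > crit else abs(z_final) > crit
  p_hat <- mean(reject)
  tibble(cp = p_hat, mc_se = sqrt(p_hat * (1 - p_hat) / n_draws),
         n_draws = as.integer(n_draws))
}

# One trial from its own seed.  Returns c(stopped_at_look, final_estimate,
# significant (NA if stopped), cp at looks evaluated padded with NA).
sim_trial_core <- function(trial_seed, theta_true, i_total, looks, crit,
                           sidedness, threshold, hyp_kind, hyp_theta_fixed,
                           hyp_q) {
  set.seed(trial_seed)
  k_max <- length(looks)
  dt <- diff(c(0, looks, 1))
  incr <- rnorm(k_max + 1L, mean = theta_true * i_total * dt,
                sd = sqrt(i_total * dt))
  s <- cumsum(incr)
  cps <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    i_k <- looks[k] * i_total
    z_k <- s[k] / sqrt(i_k)
    theta_k <- switch(
      hyp_kind,
      current_trend = s[k] / i_k,
      design = hyp_theta_fixed,
      null = 0,
      upper_cl = s[k] / i_k + hyp_q / sqrt(i_k)
    )
    cps[k] <- cp_closed_form(z_k, looks[k], theta_k, i_total, crit, sidedness)
    if (cps[k] < threshold) {
      return(c(k, s[k] / i_k, NA, cps))
    }
  }
  z_final <- s[k_max + 1L] / sqrt(i_total)
  sig <- if (sidedness == "one") z_final > crit else abs(z_final) > crit
  c(0, s[k_max + 1L] / i_total, sig, cps)
}

sim_params <- function(config) {
  design <- config$design
  hyp <- config$hypothesis
  if (hyp$kind == "design" && is.null(design$effect)) {
    abort_insufficient("design hypothesis requires a design effect",
                       missing = "effect")
  }
  list(
    i_total = total_information(design),
    crit = critical_value(design$alpha, design$sidedness),
    sidedness = design$sidedness,
    hyp_kind = hyp$kind,
    hyp_theta_fixed = design$effect %||% NA_real_,
    hyp_q = if (hyp$kind == "upper_cl") qnorm((1 + hyp$conf_level) / 2) else NA_real_
  )
}

trial_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n,
                                           replace = TRUE))
}

#' Simulate one group-sequential trial
#'
#' Generates independent score increments between consecutive looks and to
#' full information, computes \eqn{Z_k = S(t_k)/\sqrt{I_K t_k}} at each look,
#' evaluates conditional power under the configured hypothesis, and stops the
#' first time [classify_futility()] fires. The final estimate is the interim
#' estimate \eqn{S_k/I_k} when stopped (no bias adjustment, mirroring how
#' truncated trials report effects) and the full-data estimate
#' \eqn{S(1)/I_K} otherwise. The significance flag refers to the final test
#' at the design's alpha and is `NA` for stopped trials.
#'
#' @param config A [sim_config()].
#' @param trial_seed Seed for this single trial.
#' @return A one-row tibble: `stopped_at_look` (0 = completed),
#'   `final_estimate`, `significant`, and list-column `cp_at_looks`.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' simulate_sequential_trial(sim_config(d, 0.15, seed = 1), trial_seed = 42)
#' @export
simulate_sequential_trial <- function(config, trial_seed) {
  stopifnot(inherits(config, "sim_config"))
  check_number(trial_seed, "trial_seed")
  p <- sim_params(config)
  out <- sim_trial_core(trial_seed, config$theta_true, p$i_total,
                        config$look_fractions, p$crit, p$sidedness,
                        config$threshold, p$hyp_kind, p$hyp_theta_fixed,
                        p$hyp_q)
  k_max <- length(config$look_fractions)
  cps <- out[seq(4L, 3L + k_max)]
  tibble(
    stopped_at_look = as.integer(out[1]),
    final_estimate = out[2],
    significant = as.logical(out[3]),
    cp_at_looks = list(cps[!is.na(cps)])
  )
}

#' Simulate many sequential trials
#'
#' Runs `config$n_sim` independent trials, each from its own RNG stream
#' derived from the master seed (so results are independent of execution
#' order). Single trials simulated via [simulate_sequential_trial()] with the
#' same derived seed reproduce the corresponding rows exactly.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per trial: `trial`, `trial_seed`,
#'   `stopped_at_look` (0 = completed to full information), `final_estimate`,
#'   `significant` (`NA` when stopped early), and `cp_look<k>` columns with
#'   the conditional power at each evaluated look.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' simulate_trials(sim_config(d, 0.15, n_sim = 50, seed = 7))
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- sim_params(config)
  n <- config$n_sim
  seeds <- trial_seeds(config$seed, n)
  k_max <- length(config$look_fractions)
  m <- vapply(
    seeds, sim_trial_core, numeric(3L + k_max),
    theta_true = config$theta_true, i_total = p$i_total,
    looks = config$look_fractions, crit = p$crit, sidedness = p$sidedness,
    threshold = config$threshold, hyp_kind = p$hyp_kind,
    hyp_theta_fixed = p$hyp_theta_fixed, hyp_q = p$hyp_q
  )
  out <- tibble(
    trial = seq_len(n),
    trial_seed = seeds,
    stopped_at_look = as.integer(m[1, ]),
    final_estimate = m[2, ],
    significant = as.logical(m[3, ])
  )
  cp_cols <- as_tibble(t(m[seq(4L, 3L + k_max), , drop = FALSE]),
                       .name_repair = ~ paste0("cp_look", seq_len(k_max)))
  bind_cols(out, cp_cols)
}

#' Probability of stopping for futility
#'
#' The fraction of simulated trials that stop at any interim look, with its
#' binomial Monte-Carlo standard error.
#'
#' @param config A [sim_config()] with `n_sim >= 100`.
#' @return A one-row tibble: `stop_prob`, `mc_se`, `n_sim`.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' estimate_stopping_probability(sim_config(d, 0, n_sim = 200, seed = 3))
#' @export
estimate_stopping_probability <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_sim < 100L) {
    abort_domain("`n_sim` must be at least 100 for a stopping-probability estimate")
  }
  sims <- simulate_trials(config)
  p_hat <- mean(sims$stopped_at_look > 0L)
  tibble(stop_prob = p_hat,
         mc_se = sqrt(p_hat * (1 - p_hat) / config$n_sim),
         n_sim = config$n_sim)
}

#' Estimation bias by stopping stratum
#'
#' Mean final estimate among trials that stopped for futility, among trials
#' that completed, and overall, each with its Monte-Carlo standard error and
#' signed bias against the true effect. This makes the directional claims
#' about futility rules assertable: stopped trials under-estimate the effect,
#' completed trials under a rule over-estimate it, and the overall mean is
#' biased downward. An empty stratum is reported with `n = 0` and a note
#' rather than a number.
#'
#' @param sims A tibble of simulated trials from [simulate_trials()] (needs
#'   columns `stopped_at_look`, `final_estimate`).
#' @param theta_true The true effect used in the simulation.
#' @return A tibble with rows `stopped`, `completed`, `overall` and columns
#'   `n`, `mean_estimate`, `mc_se`, `bias`, `note`.
#' @examples
#' d <- design_spec(0.025, "one", 0.9, effect = 0.3)
#' sims <- simulate_trials(sim_config(d, 0.15, n_sim = 200, seed = 11))
#' bias_summary(sims, theta_true = 0.15)
#' @export
bias_summary <- function(sims, theta_true) {
  stopifnot(is.data.frame(sims), nrow(sims) > 0L)
  check_number(theta_true, "theta_true")
  stratum_of <- function(stopped) if (stopped) "stopped" else "completed"
  one <- function(est, label) {
    n <- length(est)
    if (n == 0L) {
      return(tibble(stratum = label, n = 0L, mean_estimate = NA_real_,
                    mc_se = NA_real_, bias = NA_real_, note = "empty"))
    }
    m <- mean(est)
    se <- if (n > 1L) sd(est) / sqrt(n) else NA_real_
    tibble(stratum = label, n = n, mean_estimate = m, mc_se = se,
           bias = m - theta_true, note = NA_character_)
  }
  bind_rows(
    one(sims$final_estimate[sims$stopped_at_look > 0L], "stopped"),
    one(sims$final_estimate[sims$stopped_at_look == 0L], "completed"),
    one(sims$final_estimate, "overall")
  )
}
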