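test_that("a well-formed registry file loads cleanly", {
  path <- system.file("extdata", "example_registry.csv", package = "cpaudit")
  reg <- read_registry(path)
  expect_equal(nrow(reg), 3)
  expect_equal(nrow(registry_issues(reg)), 0)
})

test_that("registry validation flags domains and rejects broken keys", {
  reg <- generate_registry(n_trials = 4, seed = 3)
  reg$reported_cp <- NA_real_
  reg$alpha[2] <- 1.5
  path <- write_temp_registry(reg)
  loaded <- read_registry(path)
  iss <- registry_issues(loaded)
  expect_equal(iss$trial_id, reg$trial_id[2])
  expect_match(iss$problem, "alpha out of domain")
  # the offending field is excluded from CP computation
  audit <- audit_trial(loaded[2, ])
  expect_identical(audit$status, "insufficient")
  expect_match(audit$failure_reason, "alpha out of domain")

  dup <- reg
  dup$trial_id[2] <- dup$trial_id[1]
  expect_error(read_registry(write_temp_registry(dup)),
               regexp = "duplicate trial_id")
  expect_error(audit_registry(dup), regexp = "duplicate trial_id")
})

test_that("audit delegates to the conditional-power engine", {
  reg <- generate_registry(n_trials = 10, seed = 5,
                           insufficient_fraction = 0, reported_fraction = 0)
  audits <- audit_registry(reg)
  for (i in seq_len(nrow(reg))) {
    d <- design_spec(alpha = reg$alpha[i], sidedness = reg$sidedness[i],
                     power = reg$planned_power[i], effect = reg$design_effect[i])
    st <- interim_state(z = reg$z_value[i], estimate = reg$estimate[i],
                        se = reg$se[i], info_fraction = reg$info_fraction[i])
    expect_equal(audits$cp_current_trend[i],
                 conditional_power(st, d, "current_trend")$cp)
    expect_equal(audits$cp_design[i],
                 conditional_power(st, d, "design")$cp)
  }
})

test_that("audit verdicts mirror the survey's three classes", {
  # reported value retained verbatim when nothing is computable
  rep_only <- list(trial_id = "A", p_value = 0.001, p_is_bound = TRUE,
                   reported_cp = 0.54)
  a <- audit_trial(rep_only)
  expect_identical(a$status, "reported_only")
  expect_equal(a$reported_cp, 0.54)
  expect_true(is.na(a$cp_current_trend))
  # a bound-only p-value with no estimate/SE is insufficient, with the
  # missing quantities named
  bare <- list(trial_id = "B", alpha = 0.05, sidedness = "two",
               planned_power = 0.8, design_effect = 0.3,
               p_value = 0.001, p_is_bound = TRUE, info_fraction = 0.5)
  b <- audit_trial(bare)
  expect_identical(b$status, "insufficient")
  expect_match(b$failure_reason, "bound")
  expect_match(b$failure_reason, "no interim test statistic")
})

test_that("an interim at or beyond full information is flagged, not clamped", {
  rec <- list(trial_id = "C", alpha = 0.05, sidedness = "two",
              planned_power = 0.8, design_effect = 0.3,
              z_value = 1.1, info_fraction = 1)
  a <- audit_trial(rec)
  expect_identical(a$status, "insufficient")
  expect_match(a$failure_reason, "beyond full information")
  # same flag via the sample-size route: interim n past the planned total
  rec2 <- list(trial_id = "C2", alpha = 0.05, sidedness = "two",
               planned_power = 0.8, design_effect = 0.3,
               z_value = 1.1, interim_n = 110L, planned_total_n = 100L)
  a2 <- audit_trial(rec2)
  expect_identical(a2$status, "insufficient")
  expect_match(a2$failure_reason, "beyond full information")
})

test_that("percent information fractions are auto-detected and logged", {
  rec <- list(trial_id = "D", alpha = 0.05, sidedness = "two",
              planned_power = 0.8, design_effect = 0.3,
              z_value = 1.0, info_fraction = 50)
  a <- audit_trial(rec)
  expect_identical(a$status, "computed")
  expect_match(a$assumptions, "percentage")
  direct <- audit_trial(within(rec, info_fraction <- 0.5))
  expect_equal(a$cp_design, direct$cp_design)
})

test_that("records stripped of every statistic route always audit insufficient", {
  reg <- generate_registry(n_trials = 25, seed = 19)
  stripped <- reg |>
    dplyr::mutate(estimate = NA_real_, se = NA_real_, z_value = NA_real_,
                  p_value = NA_real_, reported_cp = NA_real_)
  audits <- audit_registry(stripped)
  expect_true(all(audits$status == "insufficient"))
  expect_true(all(!is.na(audits$failure_reason)))
})

test_that("design-hypothesis CP dominates current-trend CP when the design effect is larger", {
  reg <- generate_registry(n_trials = 60, seed = 29,
                           insufficient_fraction = 0, reported_fraction = 0)
  audits <- audit_registry(reg)
  # restricted to benefit-direction interims: for a two-sided test the
  # harm-direction tail makes CP non-monotone over negative estimates
  both <- dplyr::inner_join(audits, reg, by = "trial_id") |>
    dplyr::filter(!is.na(cp_current_trend), !is.na(cp_design),
                  design_effect > estimate, estimate >= 0)
  expect_gt(nrow(both), 10)
  expect_true(all(both$cp_design > both$cp_current_trend))
})

test_that("conditional-power bins follow the survey convention", {
  b <- bin_cp(c(0.05, 0.20, 0.40, 0.60))
  expect_equal(b$n, c(1L, 1L, 1L, 1L))
  # boundaries are left-closed, so 0.15 falls in the second bin and 1 in the last
  expect_equal(bin_cp(0.15)$n, c(0L, 1L, 0L, 0L))
  expect_equal(bin_cp(1)$n, c(0L, 0L, 0L, 1L))
  expect_equal(bin_cp(numeric(0))$n, rep(0L, 4))
  expect_error(bin_cp(c(0.5, 1.2)), class = "cpaudit_domain_error")
})

test_that("survey summaries conserve counts and bin reported-only values as current trend", {
  reg <- generate_registry(n_trials = 52, seed = 1)
  audits <- audit_registry(reg)
  s <- summarize_survey(audits, reg)
  g <- glance(s)
  expect_equal(sum(s$status_counts$n), 52)
  expect_equal(g$n_binned_current_trend, g$n_computed + g$n_reported_only)
  expect_equal(g$n_binned_design, g$n_computed)
  ct <- s$bins |> dplyr::filter(hypothesis == "current_trend")
  expect_equal(sum(ct$n), g$n_binned_current_trend)
  # a reported-only CP of 0.10 lands in the first current-trend bin
  rep_audit <- audit_trial(list(trial_id = "R", reported_cp = 0.10))
  s2 <- summarize_survey(rep_audit)
  ct2 <- s2$bins |> dplyr::filter(hypothesis == "current_trend")
  expect_equal(ct2$n, c(1L, 0L, 0L, 0L))
  # sponsor strata and tallies are present when the registry is supplied
  expect_false(is.null(s$bins_by_sponsor))
  expect_true("sponsor" %in% names(s$tallies))
  expect_error(summarize_survey(audits, reg[-1, ]), regexp = "mismatch")
})

test_that("audit of a seeded registry is reproducible end to end", {
  run <- function() {
    reg <- generate_registry(n_trials = 52, seed = 33)
    audit_registry(reg)
  }
  expect_identical(run(), run())
})

test_that("summary plots build without evaluation errors", {
  reg <- generate_registry(n_trials = 30, seed = 41)
  audits <- audit_registry(reg)
  s <- summarize_survey(audits, reg)
  p1 <- autoplot(s)
  p2 <- plot_cp_bins(s, by_sponsor = TRUE)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  sims <- simulate_trials(sim_config(ref_design(), 0.15, n_sim = 50, seed = 2))
  expect_s3_class(plot_bias(sims, 0.15), "ggplot")
})
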