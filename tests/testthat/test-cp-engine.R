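test_that("critical values match high-precision normal quantiles", {
  # frozen from an independent high-precision quantile evaluation
  expect_equal(critical_value(0.05, "one"), 1.644854, tolerance = 1e-4)
  expect_equal(critical_value(0.05, "two"), 1.959964, tolerance = 1e-4)
  expect_equal(critical_value(0.5, "one"), 0)
  expect_error(critical_value(0, "one"), class = "cpaudit_domain_error")
  expect_error(critical_value(0.6, "two"), class = "cpaudit_domain_error")
})

test_that("total information follows the sample-size identity and explicit precedence", {
  # (1.959964 + 1.281552)^2 / 0.3^2, frozen from high-precision quantiles
  expect_equal(total_information(ref_design()), 116.7491, tolerance = 1e-2)
  # power 0.5 collapses the power term: (1.959964 / 0.3)^2
  d50 <- design_spec(0.025, "one", 0.5, effect = 0.3)
  expect_equal(total_information(d50), 42.6828, tolerance = 1e-2)
  # an explicit value always wins over the derived one
  dexp <- design_spec(0.025, "one", 0.9, effect = 0.3, total_information = 200)
  expect_equal(total_information(dexp), 200)
  expect_error(design_spec(0.025, "one", 0.9, effect = 0),
               class = "cpaudit_domain_error")
})

test_that("information identities and the beyond-full-information guard", {
  expect_equal(information_from_se(0.1), 100)
  expect_equal(information_from_se(2), 0.25)
  expect_error(information_from_se(0), class = "cpaudit_domain_error")
  expect_equal(information_fraction(50, 100), 0.5)
  expect_equal(information_fraction(25, 100), 0.25)
  # an interim past its target is flagged, never clamped
  expect_error(information_fraction(110, 100),
               class = "cpaudit_beyond_full_error")
  expect_error(information_fraction(100, 100),
               class = "cpaudit_beyond_full_error")
  expect_error(information_fraction(-1, 100), class = "cpaudit_domain_error")
})

test_that("future-data hypotheses resolve to the intended theta", {
  d <- ref_design()
  i <- interim_state(estimate = 0.10, se = 0.05)
  expect_equal(resolve_theta(i, d, "null"), 0)
  expect_equal(resolve_theta(i, d, "design"), 0.3)
  expect_equal(resolve_theta(i, d, "current_trend"), 0.10)
  # 0.10 + 1.959964 * 0.05, frozen from a high-precision quantile
  expect_equal(resolve_theta(i, d, future_hypothesis("upper_cl", 0.95)),
               0.19800, tolerance = 1e-4)
  bare <- interim_state(z = 1, info_fraction = 0.5)
  expect_error(resolve_theta(bare, d, "current_trend"),
               class = "cpaudit_insufficient_error")
  expect_error(resolve_theta(bare, d, future_hypothesis("upper_cl", 0.95)),
               class = "cpaudit_insufficient_error")
  expect_error(future_hypothesis("upper_cl"), class = "cpaudit_domain_error")
  expect_error(future_hypothesis("null", conf_level = 0.9),
               class = "cpaudit_domain_error")
})

test_that("conditional power recovers its analytic limits", {
  d <- ref_design()
  # no information yet + design effect for the future = planned power
  res0 <- conditional_power(interim_state(z = 0, info_fraction = 1e-12),
                            d, "design")
  expect_equal(res0$cp, 0.9, tolerance = 1e-6)
  # all information in hand: CP degenerates to the rejection indicator
  hi <- conditional_power(interim_state(z = 2.5, info_fraction = 1 - 1e-12),
                          d, "design")
  expect_equal(hi$cp, 1, tolerance = 1e-6)
  lo <- conditional_power(interim_state(z = 1.2, info_fraction = 1 - 1e-12),
                          d, "design")
  expect_equal(lo$cp, 0, tolerance = 1e-6)
  # two-sided CP under the null with no data = the type-I error rate
  d2 <- design_spec(alpha = 0.05, sidedness = "two", power = 0.9, effect = 0.3)
  null0 <- conditional_power(
    interim_state(z = 0, info_fraction = 1e-12, estimate = 0), d2, "null"
  )
  expect_equal(null0$cp, 0.05, tolerance = 1e-6)
})

test_that("closed form matches the frozen mid-trial value", {
  # Z_k = 1, t = 0.5, theta = 0, alpha = 0.025 one-sided; frozen from a
  # 10^6-draw Monte-Carlo run of the future score increment (0.0384 +- 0.0002)
  res <- conditional_power(ref_interim(z = 1, t = 0.5, estimate = 0),
                           ref_design(), "null")
  expect_lt(abs(res$cp - 0.0383), 5e-4)
  expect_true(res$futile)
})

test_that("conditional power is strictly monotone in theta and in z (one-sided)", {
  d <- ref_design()
  cp_theta <- vapply(
    seq(-0.4, 0.4, by = 0.05),
    function(th) conditional_power(ref_interim(z = 0.8, estimate = th), d,
                                   "current_trend")$cp,
    numeric(1)
  )
  expect_true(all(diff(cp_theta) > 0))
  cp_z <- vapply(
    seq(-2, 3, by = 0.25),
    function(z) conditional_power(ref_interim(z = z), d, "design")$cp,
    numeric(1)
  )
  expect_true(all(diff(cp_z) > 0))
})

test_that("conditional power stays in [0, 1] across fuzzed inputs", {
  withr::with_seed(421, {
    for (rep in 1:200) {
      sided <- sample(c("one", "two"), 1)
      d <- design_spec(alpha = runif(1, 0.001, 0.5), sidedness = sided,
                       power = runif(1, 0.05, 0.99),
                       effect = runif(1, 0.05, 1) * sample(c(-1, 1), 1))
      res <- conditional_power(
        interim_state(z = runif(1, -6, 6), info_fraction = runif(1, 1e-6, 1 - 1e-6),
                      estimate = runif(1, -2, 2)),
        d, sample(c("current_trend", "design", "null"), 1)
      )
      expect_gte(res$cp, 0)
      expect_lte(res$cp, 1)
    }
  })
})

test_that("futility classification uses a strict threshold", {
  expect_true(classify_futility(0.10, 0.15))
  expect_false(classify_futility(0.15, 0.15))
  expect_false(classify_futility(1.0, 0.15))
  expect_error(classify_futility(1.2, 0.15), class = "cpaudit_domain_error")
})

test_that("interim states enforce internal consistency", {
  expect_error(interim_state(z = 3, estimate = 0.1, se = 0.1),
               class = "cpaudit_domain_error")
  expect_error(interim_state(se = 0.1, information = 50),
               class = "cpaudit_domain_error")
  # derivable fields are filled from the identities
  i <- interim_state(estimate = 0.1, se = 0.05)
  expect_equal(i$z, 2)
  expect_equal(i$information, 400)
  expect_error(interim_state(info_fraction = 1), class = "cpaudit_domain_error")
  # CP without any information-time route is an insufficiency, not a crash
  expect_error(conditional_power(interim_state(z = 1), ref_design(), "design"),
               class = "cpaudit_insufficient_error")
})
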