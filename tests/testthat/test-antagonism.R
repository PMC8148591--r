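# Opposing-direction preset mirroring the ternary antagonism experiment:
# two hyperactive components with a small fraction of the hypoactive
# abamectin (hypo:hyper 0.33:0.66 in EC50 terms -> molar 0.34:0.64:0.02).
mix_d_scenario <- function(concs = c(0, 0.5, 1, 2, 4, 8, 16)) {
  stc_scenario("Mixture D",
               t1_curves[c("chlorpyrifos", "hexaconazole", "abamectin")],
               fractions = c(0.34, 0.64, 0.02),
               concentrations = concs)
}

test_that("a noise-free Gaussian response is recovered exactly", {
  x <- 10^seq(-1, 1.3, length.out = 9)
  truth <- c(amplitude = 60, center = log10(2), width = 0.3, baseline = 0)
  y <- truth["baseline"] + truth["amplitude"] *
    exp(-(log10(x) - truth["center"])^2 / (2 * truth["width"]^2))
  fit <- fit_biphasic(data.frame(concentration_um = x, percent_change = y))
  expect_equal(fit$amplitude, 60, tolerance = 1e-6)
  expect_equal(fit$center_log10c, log10(2), tolerance = 1e-6)
  expect_equal(fit$width_log10c, 0.3, tolerance = 1e-6)
  expect_equal(fit$baseline, 0, tolerance = 1e-5)
  expect_identical(fit$preferred, "gaussian")
  expect_equal(predict(fit, newdata = 2), 60, tolerance = 1e-6)
})

test_that("a negative baseline captures the hypoactive undershoot", {
  x <- 10^seq(-1, 1.5, length.out = 10)
  y <- -25 + 80 * exp(-(log10(x) - 0.2)^2 / (2 * 0.35^2))
  fit <- fit_biphasic(data.frame(concentration_um = x, percent_change = y))
  expect_equal(fit$baseline, -25, tolerance = 1e-5)
  expect_lt(min(predict(fit, newdata = c(0.01, 1000))), 0)
})

test_that("monotone data prefer the monotone model", {
  x <- c(0.25, 0.5, 1, 2, 4, 8)
  y <- ll4_effect(x, ll4_curve(b = 1.5, e = 2))
  fit <- fit_biphasic(data.frame(concentration_um = x, percent_change = y))
  expect_identical(fit$preferred, "monotone")
  expect_lt(fit$rss_monotone, fit$rss_gaussian)
})

test_that("fit_biphasic validates its input", {
  expect_error(fit_biphasic(data.frame(concentration_um = c(1, 2, 4, 8),
                                       percent_change = c(1, 5, 3, 1))),
               "5 distinct")
  expect_error(fit_biphasic(data.frame(x = 1)), "columns")
})

test_that("an observation identical to the reference is not antagonistic", {
  reference <- predict_mixture(mix_b_hyper, "CA")
  obs <- data.frame(concentration_um = reference$grid$concentration_um,
                    percent_change = reference$grid$effect_percent,
                    se_percent_change = 5)
  rep <- assess_antagonism(obs, reference)
  expect_identical(rep$verdict, "not_antagonistic")
  expect_equal(rep$suppression, 0, tolerance = 1e-9)
  expect_true(is.na(rep$direction_reversal_concentration))
})

test_that("responses above the reference are never antagonistic", {
  reference <- predict_mixture(mix_b_hyper, "CA")
  obs <- data.frame(concentration_um = reference$grid$concentration_um,
                    percent_change = reference$grid$effect_percent + 30,
                    se_percent_change = 5)
  expect_identical(assess_antagonism(obs, reference)$verdict,
                   "not_antagonistic")
})

test_that("the synthetic opposing-direction mixture is antagonistic with a
          mid-high sign flip", {
  sc <- mix_d_scenario()
  rec <- simulate_stc(sc, seed = 7)
  pc <- percent_change(rec)
  reference <- predict_mixture(mix_b_hyper, "CA")
  rep <- assess_antagonism(pc, reference)
  expect_identical(rep$verdict, "antagonistic")
  expect_gt(rep$suppression, 0)
  # hypoactivity relative to control appears at mid-high concentration
  expect_true(is.finite(rep$direction_reversal_concentration))
  expect_gte(rep$direction_reversal_concentration, 4)
  # the generated mean response rises then falls, matching the analytic
  # mean curve's interior maximum
  truth <- true_percent_change(sc, sc$concentrations)
  expect_gt(max(truth), truth[1])
  expect_lt(truth[length(truth)], 0)
  biph <- fit_biphasic(pc)
  expect_identical(biph$preferred, "gaussian")
})

test_that("verdict is invariant to observation row order", {
  sc <- mix_d_scenario()
  pc <- percent_change(simulate_stc(sc, seed = 7))
  reference <- predict_mixture(mix_b_hyper, "CA")
  shuffled <- pc[rev(seq_len(nrow(pc))), ]
  expect_identical(assess_antagonism(pc, reference)$verdict,
                   assess_antagonism(shuffled, reference)$verdict)
  expect_equal(assess_antagonism(pc, reference)$suppression,
               assess_antagonism(shuffled, reference)$suppression)
})

test_that("non-overlapping concentration ranges raise a comparability error", {
  reference <- predict_mixture(mix_b_hyper, "CA")
  far <- data.frame(concentration_um = c(1e5, 2e5, 4e5),
                    percent_change = c(10, 20, 30),
                    se_percent_change = 2)
  expect_error(assess_antagonism(far, reference), "overlap")
})
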