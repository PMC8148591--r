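embryo_rows <- function(substance, conc, counts, experiment = 1,
                        replicate = 1) {
  data.frame(substance = substance, concentration_um = conc,
             embryo_id = paste0(substance, "_", conc, "_", experiment, "_",
                                seq_along(counts)),
             stc_per_min = counts, replicate = replicate,
             experiment = experiment)
}

test_that("percent change is computed against the matched experiment control", {
  rec <- rbind(
    embryo_rows("s", 0, c(6, 6, 6), experiment = 1),
    embryo_rows("s", 1, c(9, 9, 9), experiment = 1),
    embryo_rows("s", 2, c(6, 6, 6), experiment = 1),
    embryo_rows("s", 0, c(4, 4, 4), experiment = 2),
    embryo_rows("s", 1, c(6, 6, 6), experiment = 2))
  pc <- percent_change(rec)
  get <- function(exp, conc) {
    pc$percent_change[pc$experiment == exp & pc$concentration_um == conc]
  }
  expect_equal(get(1, 1), 50)   # 9 vs 6
  expect_equal(get(1, 2), 0)    # treated mean equals control mean
  expect_equal(get(2, 1), 50)   # 6 vs 4: controls matched within experiment
  expect_equal(get(1, 0), 0)
})

test_that("missing or degenerate controls are rejected", {
  no_ctrl <- embryo_rows("s", 1, c(5, 6))
  expect_error(percent_change(no_ctrl), "control")
  zero_ctrl <- rbind(embryo_rows("s", 0, c(0, 0)),
                     embryo_rows("s", 1, c(5, 6)))
  expect_error(percent_change(zero_ctrl), "zero")
  expect_error(percent_change(data.frame()), "columns")
})

test_that("generator percent changes track the programmed curve within
          Monte-Carlo bounds", {
  crc <- ll4_curve(b = 1.5, e = 2)
  sc <- stc_scenario("mc", list(crc), concentrations = c(0, 1, 2, 4, 8, 16))
  rec <- simulate_stc(sc, seed = 101)
  pc <- percent_change(rec)
  truth <- true_percent_change(sc, pc$concentration_um)
  # Monte-Carlo oracle for the sampling sd of a per-experiment percent
  # change: 10,000 draws of (mean of 40 NB counts) for treated and control.
  mc_sd <- function(mult, n = 40, base = 6, disp = 0.05, draws = 10000) {
    set.seed(99)
    m0 <- colMeans(matrix(rnbinom(n * draws, mu = base, size = 1 / disp),
                          n, draws))
    mt <- colMeans(matrix(rnbinom(n * draws, mu = base * mult,
                                  size = 1 / disp), n, draws))
    stats::sd(100 * (mt - m0) / m0)
  }
  for (cc in c(2, 8)) {
    rows <- pc$concentration_um == cc
    bound <- 4 * mc_sd(true_mean_multiplier(sc, cc))
    expect_true(all(abs(pc$percent_change[rows] - truth[rows]) < bound))
  }
})

test_that("hyperactivity standardization rescales to a 100 percent ceiling", {
  # substances peaking at 82 and 48 percent: their half-maximum raw effects
  # map to the standardized 50
  expect_equal(standardize_hyperactivity(41, 82), 50)
  expect_equal(standardize_hyperactivity(24, 48), 50)
  expect_equal(standardize_hyperactivity(c(-10, 20, 100), 100),
               c(-10, 20, 100))
  expect_error(standardize_hyperactivity(10, 0), "positive")
  expect_error(standardize_hyperactivity(10, -5), "positive")
})

test_that("standardization is linear and preserves concentration ranking", {
  pc <- c(3, 12, 28, 55, 70, 76)
  std <- standardize_hyperactivity(pc, 76)
  expect_identical(order(std), order(pc))
  expect_equal(max(std), 100)
  # standardized EC50 equals the raw EC at half the maximum, by construction
  raw <- ll4_curve(b = 1.3, e = 2, d = 82)
  x50 <- ll4_inverse(41, raw)
  std_curve <- ll4_curve(b = 1.3, e = x50)
  expect_equal(ll4_effect(x50, raw) / 82 * 100, 50)
  expect_equal(estimate_ec(50, std_curve)$estimate, x50)
})

test_that("max_effect_from_fit only accepts free-ceiling hyperactivity fits", {
  x <- c(0.5, 1, 2, 4, 8, 16)
  raw <- ll4_curve(b = 1.3, e = 2, d = 82)
  dat <- data.frame(concentration_um = x, effect_percent = ll4_effect(x, raw))
  expect_error(max_effect_from_fit(fit_ll4(dat)), "free ceiling")
  hypo <- fit_ll4(dat, fix_ceiling = FALSE, direction = "hypoactivity")
  expect_error(max_effect_from_fit(hypo), "hyperactivity")
  expect_error(max_effect_from_fit("not a fit"), "ll4_fit")
})

test_that("normalized_response maps both directions onto the 0-100 scale", {
  pc_tab <- data.frame(concentration_um = c(1, 2, 4),
                       percent_change = c(-20, -60, -120))
  expect_warning(out <- normalized_response(pc_tab, "hypoactivity"),
                 "clamped")
  expect_equal(out$effect_percent, c(20, 60, 100))
  hyper <- data.frame(concentration_um = c(1, 2), percent_change = c(20, 41))
  expect_equal(normalized_response(hyper, "hyperactivity",
                                   max_effect_m = 82)$effect_percent,
               c(100 * 20 / 82, 50))
  expect_error(normalized_response(hyper, "hyperactivity"), "max_effect_m")
})

test_that("biphasic single-substance series are truncated at the peak", {
  tab <- data.frame(concentration_um = c(0.5, 1, 2, 4, 8),
                    percent_change = c(10, 40, 70, 50, -20))
  kept <- truncate_at_peak(tab)
  expect_equal(kept$concentration_um, c(0.5, 1, 2))
  # monotone data are untouched
  mono <- data.frame(concentration_um = c(1, 2, 4),
                     percent_change = c(10, 20, 30))
  expect_identical(truncate_at_peak(mono), mono)
})
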