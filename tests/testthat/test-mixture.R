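single_design <- function(crc, name = "solo") {
  mixture_design(list(mixture_component(name, crc, 1)), label = name)
}

test_that("equitoxic fractions are EC50-proportional and sum to one", {
  expect_equal(unname(equitoxic_fractions(c(1.95, 0.44))), c(0.816, 0.184),
               tolerance = 5e-4)
  expect_equal(unname(equitoxic_fractions(c(0.09, 46))), c(0.002, 0.998),
               tolerance = 5e-4)
  expect_equal(unname(equitoxic_fractions(c(3, 3, 3))), rep(1 / 3, 3))
  expect_equal(sum(equitoxic_fractions(c(0.2, 7, 31))), 1)
  expect_error(equitoxic_fractions(c(1, -2)), "positive")
  expect_error(equitoxic_fractions(c(1, 0)), "positive")
})

test_that("design invariants are enforced", {
  cmp <- function(nm, p) mixture_component(nm, ll4_curve(b = 1, e = 1), p)
  expect_error(mixture_design(list(cmp("a", 0.6), cmp("a", 0.4))), "unique")
  expect_error(mixture_design(list(cmp("a", 0.6), cmp("b", 0.5))), "sum to 1")
  expect_error(mixture_component("a", ll4_curve(b = 1, e = 1), 1.2),
               "fraction")
})

test_that("CA ECx matches Loewe additivity and its closed forms", {
  # equitoxic closed form: CA EC50 = sum(EC50) / n
  expect_equal(ca_ecx(50, mix_a_hyper), (1.95 + 0.44) / 2, tolerance = 1e-12)
  expect_equal(ca_ecx(50, mix_c), (1.95 + 3.63 + 0.44) / 3,
               tolerance = 1e-12)
  # single component: the CA sum collapses to the substance's own ECx
  solo <- single_design(t1_curves$chlorpyrifos)
  expect_equal(ca_ecx(50, solo), 1.95)
  expect_equal(ca_ecx(30, solo), ll4_inverse(30, t1_curves$chlorpyrifos))
})

test_that("CA ECx agrees with a brute-force tabulated-inverse oracle", {
  # hexaconazole + chlorpyrifos at fractions (0.65, 0.35), level 30:
  # solve the CA toxic-unit equation from high-resolution tabulated inverses
  hex <- t1_curves$hexaconazole
  chl <- t1_curves$chlorpyrifos
  design <- mixture_design(list(mixture_component("hexaconazole", hex, 0.65),
                                mixture_component("chlorpyrifos", chl, 0.35)))
  grid <- 10^seq(-6, 6, length.out = 1e6)
  tab_inverse <- function(crc, level) {
    eff <- ll4_effect(grid, crc)
    grid[which.min(abs(eff - level))]
  }
  oracle <- 1 / (0.65 / tab_inverse(hex, 30) + 0.35 / tab_inverse(chl, 30))
  expect_equal(ca_ecx(30, design), oracle, tolerance = 1e-4)
})

test_that("CA prediction curves are monotone and self-consistent", {
  curve <- ca_curve(mix_b_hyper, levels = seq(5, 95, by = 5))
  expect_true(all(diff(curve$grid$concentration_um) > 0))
  expect_true(all(diff(curve$grid$effect_percent) > 0))
  # an equitoxic design of identical components is a dilution of itself
  crc <- ll4_curve(b = 1.4, e = 2.5)
  self_mix <- equitoxic_design(list(a = crc, b = crc))
  lv <- seq(10, 90, by = 10)
  expect_equal(ca_curve(self_mix, lv)$grid$concentration_um,
               ll4_inverse(lv, crc), tolerance = 1e-12)
})

test_that("IA combines fractional effects multiplicatively", {
  # two components each at 30 percent effect: 1 - 0.7^2 = 51 percent
  crc <- ll4_curve(b = 1, e = 7 / 3)
  design <- equitoxic_design(list(a = crc, b = crc))
  expect_equal(ia_effect(2, design), 51, tolerance = 1e-12)
  expect_equal(ia_effect(0, design), 0)
  # single component: the product collapses to the substance's own curve
  solo <- single_design(t1_curves$propafenone)
  cc <- c(0, 5, 20, 46, 100)
  expect_equal(ia_effect(cc, solo), ll4_effect(cc, t1_curves$propafenone))
  # monotone, bounded by 100
  cs <- 10^seq(-3, 4, length.out = 300)
  eff <- ia_effect(cs, mix_c)
  expect_true(all(diff(eff) >= 0))
  expect_true(all(eff <= 100))
})

test_that("ia_ecx root-finding matches a brute-force grid scan", {
  scan_ecx <- function(design, level) {
    cc <- 10^seq(-4, 4, length.out = 1e6)
    eff <- ia_effect(cc, design)
    cc[which.min(abs(eff - level))]
  }
  for (level in c(20, 50, 80)) {
    root <- ia_ecx(level, mix_c)
    expect_equal(root, scan_ecx(mix_c, level), tolerance = 1e-4)
    expect_equal(ia_effect(root, mix_c), level, tolerance = 1e-6)
  }
  solo <- single_design(t1_curves$abamectin)
  expect_equal(ia_ecx(50, solo), 0.09, tolerance = 1e-8)
})

test_that("IA effect levels above the asymptotic maximum are rejected", {
  low_max <- suppressWarnings(equitoxic_design(list(
    a = ll4_curve(b = 1, e = 1, d = 60), b = ll4_curve(b = 1, e = 2, d = 60))))
  # asymptote: 100 * (1 - 0.4 * 0.4) = 84
  expect_error(suppressWarnings(ia_ecx(90, low_max)), "asymptotic maximum")
  expect_silent(r <- suppressWarnings(ia_ecx(80, low_max)))
  expect_true(is.finite(r))
})

test_that("predictions are invariant to component order", {
  reversed <- mixture_design(rev(unname(mix_c$components)), label = "rev")
  expect_equal(ca_ecx(37, mix_c), ca_ecx(37, reversed), tolerance = 1e-12)
  expect_equal(ia_ecx(37, mix_c), ia_ecx(37, reversed), tolerance = 1e-8)
  expect_equal(ia_effect(2.5, mix_c), ia_effect(2.5, reversed))
})

test_that("opposing-direction designs are rejected with guidance", {
  mixed <- mixture_design(list(
    mixture_component("chlorpyrifos", t1_curves$chlorpyrifos, 0.5),
    mixture_component("abamectin", t1_curves$abamectin, 0.5)))
  expect_error(ca_ecx(50, mixed), "assess_antagonism")
  expect_error(ia_ecx(50, mixed), "assess_antagonism")
  expect_error(ia_effect(1, mixed), "opposing")
})

test_that("raw (unstandardized) curves trigger a standardization warning", {
  raw <- list(a = ll4_curve(b = 1.3, e = 2, d = 82),
              b = ll4_curve(b = 1, e = 1, d = 48))
  design <- suppressWarnings(equitoxic_design(raw))
  expect_warning(ca_ecx(40, design), "standardize")
  expect_warning(ia_effect(1, design), "standardize")
})

test_that("substitution reproduces the study's dilution-experiment ratios", {
  # part of chlorpyrifos replaced by an EC50-equitoxic portion of
  # hexaconazole: 0.184:0.816 -> 0.184:(0.286:0.53)
  sub_a <- substitution_design(
    mix_a_hyper, "chlorpyrifos",
    mixture_component("hexaconazole", t1_curves$hexaconazole))
  fr <- design_fractions(sub_a)
  expect_equal(fr[["chlorpyrifos-oxon"]], 0.184, tolerance = 1e-3)
  expect_equal(fr[["chlorpyrifos"]], 0.286, tolerance = 5e-3)
  expect_equal(fr[["hexaconazole"]], 0.53, tolerance = 5e-3)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # part of chlorpyrifos replaced by chlorpyrifos-oxon:
  # 0.65:0.35 -> 0.65:(0.286:0.064)
  sub_b <- substitution_design(
    mix_b_hyper, "chlorpyrifos",
    mixture_component("chlorpyrifos-oxon", t1_curves$`chlorpyrifos-oxon`))
  fr_b <- design_fractions(sub_b)
  expect_equal(fr_b[["hexaconazole"]], 0.65, tolerance = 2e-3)
  expect_equal(fr_b[["chlorpyrifos"]], 0.286, tolerance = 5e-3)
  expect_equal(fr_b[["chlorpyrifos-oxon"]], 0.064, tolerance = 6e-3)
})

test_that("substituting an identical-potency component leaves CA unchanged", {
  twin <- ll4_curve(b = 1.1, e = 1.95)  # same EC50 as chlorpyrifos
  sub <- substitution_design(mix_a_hyper, "chlorpyrifos",
                             mixture_component("twin", twin), portion = 1)
  expect_equal(ca_ecx(50, sub), ca_ecx(50, mix_a_hyper), tolerance = 1e-9)
})

test_that("CA is associative: a substituted slice behaves as a
          pseudo-component carrying its own CA ECx", {
  sub_a <- substitution_design(
    mix_a_hyper, "chlorpyrifos",
    mixture_component("hexaconazole", t1_curves$hexaconazole))
  for (level in c(20, 50, 75)) {
    fr <- design_fractions(sub_a)
    slice <- fr[["chlorpyrifos"]] + fr[["hexaconazole"]]
    sub_mix <- mixture_design(list(
      mixture_component("chlorpyrifos", t1_curves$chlorpyrifos,
                        fr[["chlorpyrifos"]] / slice),
      mixture_component("hexaconazole", t1_curves$hexaconazole,
                        fr[["hexaconazole"]] / slice)))
    # CA applied hierarchically: ( p_oxon/ECx_oxon + slice/ECx_slice )^-1
    ecx_slice <- ca_ecx(level, sub_mix)
    ecx_oxon <- ll4_inverse(level, t1_curves$`chlorpyrifos-oxon`)
    hierarchical <- 1 / (fr[["chlorpyrifos-oxon"]] / ecx_oxon +
                           slice / ecx_slice)
    expect_equal(ca_ecx(level, sub_a), hierarchical, tolerance = 1e-9)
  }
})

test_that("substitution rejects unknown components and bad portions", {
  hx <- mixture_component("hexaconazole", t1_curves$hexaconazole)
  expect_error(substitution_design(mix_a_hyper, "nope", hx), "not part")
  expect_error(substitution_design(mix_a_hyper, "chlorpyrifos", hx,
                                   portion = 0), "portion")
  expect_error(substitution_design(mix_a_hyper, "chlorpyrifos", hx,
                                   portion = 1.5), "portion")
})
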