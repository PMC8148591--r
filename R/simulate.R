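#' Exposure scenario for the STC data generator
#'
#' Describes the "truth" the generator draws from: one substance or mixture
#' with raw-scale concentration-response curves (hyperactivity ceilings may
#' differ from 100 to exercise the standardization step) and the tested
#' concentration series including the control at 0.
#'
#' Components sharing an effect direction combine by concentration addition
#' (they act as dilutions of each other), giving a combined hyperactivity
#' effect `h` and hypoactivity effect `k` at each total concentration; the
#' two directions then act multiplicatively on the mean coiling frequency:
#' `baseline * (1 + h/100) * (1 - k/100)`. For a single substance this
#' reduces to the substance's own curve; for same-direction mixtures the
#' truth is exactly concentration-additive (so the CA prediction is the
#' recoverable target); for opposing-direction mixtures the rule produces
#' the rise-then-fall biphasic pattern.
#'
#' @param label Substance or mixture label (becomes the `substance` column).
#' @param curves Named list of raw-scale [ll4_curve] objects (each carries
#'   its own `direction`).
#' @param fractions Molar fractions summing to 1; default a single component
#'   at fraction 1.
#' @param concentrations Total-concentration series in umol/L, must include 0
#'   (the controls).
#' @return An object of class `stc_scenario`.
#' @export
stc_scenario <- function(label, curves, fractions = NULL, concentrations) {
  if (!is.list(curves) || length(curves) < 1L) {
    stop("'curves' must be a non-empty list of ll4_curve objects",
         call. = FALSE)
  }
  curves <- lapply(curves, as_ll4_curve)
  if (is.null(fractions)) {
    if (length(curves) != 1L) {
      stop("'fractions' must be given for multi-component scenarios",
           call. = FALSE)
    }
    fractions <- 1
  }
  if (length(fractions) != length(curves) ||
      abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0)) {
    stop("'fractions' must be positive and sum to 1", call. = FALSE)
  }
  if (!is.numeric(concentrations) || !any(concentrations == 0) ||
      any(concentrations < 0)) {
    stop("'concentrations' must be non-negative and include 0 (controls)",
         call. = FALSE)
  }
  structure(list(label = label, curves = curves, fractions = fractions,
                 concentrations = sort(unique(concentrations))),
            class = "stc_scenario")
}

# CA-combined effect of a same-direction component subset at a total
# concentration: the level y solving sum(p_i / ECy_i) = 1/c, found by
# bisection (the CA ECy is increasing in y). Levels are capped at the
# smallest component ceiling, beyond which the combined response saturates.
ca_combined_effect <- function(curves, fractions, total_c) {
  if (length(curves) == 1L) {
    return(ll4_effect(fractions * total_c, curves[[1]]))
  }
  ymax <- min(vapply(curves, function(cr) cr$d, numeric(1)))
  ecy <- function(y) {
    1 / sum(vapply(seq_along(curves), function(i) {
      fractions[i] / ll4_inverse(y, curves[[i]])
    }, numeric(1)))
  }
  vapply(total_c, function(cc) {
    if (cc <= 0) return(0)
    lo <- 1e-9
    hi <- ymax - 1e-9
    if (ecy(hi) <= cc) return(ymax)
    if (ecy(lo) >= cc) return(0)
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (ecy(mid) < cc) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' True mean multiplier and percent change of a scenario
#'
#' Analytic mean response of the generator at given total concentrations:
#' components sharing a direction are combined by concentration addition
#' into a hyperactivity effect `h` and a hypoactivity effect `k`, and the
#' mean multiplier is `(1 + h/100) * (1 - k/100)`.
#' `true_percent_change()` is `100 * (multiplier - 1)` - the curve the
#' normalization and fitting pipeline should recover.
#'
#' @param scenario An [stc_scenario()].
#' @param total_c Total concentrations in umol/L.
#' @return Numeric vector.
#' @export
true_mean_multiplier <- function(scenario, total_c) {
  stopifnot(inherits(scenario, "stc_scenario"))
  dirs <- vapply(scenario$curves, `[[`, character(1), "direction")
  mult <- rep(1, length(total_c))
  for (dir in unique(dirs)) {
    idx <- which(dirs == dir)
    eff <- ca_combined_effect(scenario$curves[idx],
                              scenario$fractions[idx], total_c)
    mult <- mult * if (dir == "hyperactivity") 1 + eff / 100 else 1 - eff / 100
  }
  mult
}

#' @rdname true_mean_multiplier
#' @export
true_percent_change <- function(scenario, total_c) {
  100 * (true_mean_multiplier(scenario, total_c) - 1)
}

#' Simulate embryo-level STC count records
#'
#' Generates a seeded dataset with the structure of the STC assay: per
#' concentration, `n_replicates` dishes of `n_embryos` embryos each, repeated
#' in `n_experiments` independent experiments whose baseline coiling
#' frequency varies between experiments (lognormal with relative standard
#' deviation `experiment_effect_sd`, mean-corrected so the expected baseline
#' stays at `baseline_stc`). Each embryo's coils-per-minute count is drawn
#' from a negative binomial with mean
#' `baseline * true_mean_multiplier(scenario, concentration)` and variance
#' `mu + dispersion * mu^2` (Poisson when `dispersion = 0`). Means driven
#' below zero are clamped at zero with a warning. The same seed and
#' configuration always reproduce the identical dataset; the caller's RNG
#' state is left untouched.
#'
#' @param scenario An [stc_scenario()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @param baseline_stc Control coiling frequency in coils/min (default 6).
#' @param dispersion Negative-binomial overdispersion (default 0.05; 0 gives
#'   Poisson counts).
#' @param n_embryos Embryos per dish (default 20).
#' @param n_replicates Replicate dishes per concentration (default 2).
#' @param n_experiments Independent experiments (default 2).
#' @param experiment_effect_sd Relative between-experiment baseline standard
#'   deviation (default 0.15).
#' @return A data.frame of embryo records with columns `substance`,
#'   `concentration_um`, `embryo_id`, `stc_per_min`, `replicate`,
#'   `experiment`.
#' @examples
#' sc <- stc_scenario("demo", list(ll4_curve(b = 1.5, e = 2)),
#'                    concentrations = c(0, 0.5, 1, 2, 4, 8))
#' head(simulate_stc(sc, seed = 1))
#' @export
simulate_stc <- function(scenario, seed, baseline_stc = 6, dispersion = 0.05,
                         n_embryos = 20, n_replicates = 2, n_experiments = 2,
                         experiment_effect_sd = 0.15) {
  stopifnot(inherits(scenario, "stc_scenario"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("an integer 'seed' is mandatory for reproducible simulation",
         call. = FALSE)
  }
  for (nm in c("baseline_stc", "n_embryos", "n_replicates",
               "n_experiments")) {
    if (get(nm) <= 0) stop("'", nm, "' must be positive", call. = FALSE)
  }
  if (dispersion < 0) stop("'dispersion' must be >= 0", call. = FALSE)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  mult <- true_mean_multiplier(scenario, scenario$concentrations)
  clamped <- FALSE
  rows <- vector("list", 0L)
  for (ex in seq_len(n_experiments)) {
    s <- experiment_effect_sd
    base_ex <- if (s > 0) {
      sl <- sqrt(log(1 + s^2))
      baseline_stc * stats::rlnorm(1, meanlog = -sl^2 / 2, sdlog = sl)
    } else {
      baseline_stc
    }
    for (ci in seq_along(scenario$concentrations)) {
      cc <- scenario$concentrations[ci]
      mu <- base_ex * mult[ci]
      if (mu < 0) {
        mu <- 0
        clamped <- TRUE
      }
      for (rep_i in seq_len(n_replicates)) {
        counts <- if (dispersion == 0) {
          stats::rpois(n_embryos, mu)
        } else {
          stats::rnbinom(n_embryos, mu = mu, size = 1 / dispersion)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          substance = scenario$label,
          concentration_um = cc,
          embryo_id = sprintf("ex%d_c%g_r%d_e%02d", ex, cc, rep_i,
                              seq_len(n_embryos)),
          stc_per_min = counts,
          replicate = rep_i,
          experiment = ex)
      }
    }
  }
  if (clamped) {
    warning("some dish means were driven below zero and clamped at 0",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Single-substance parameters of the six tested neuroactive chemicals:
# printed EC50, the independent-experiment ("modeling") EC50 used for
# mixture prediction, slope, and effect direction. Carbamazepine has no
# separate modeling value.
table1_data <- function() {
  data.frame(
    substance = c("chlorpyrifos", "chlorpyrifos-oxon", "hexaconazole",
                  "abamectin", "carbamazepine", "propafenone"),
    ec50_um = c(1.85, 0.32, 4.03, 0.06, 271, 32),
    ec50_modeling_um = c(1.95, 0.44, 3.63, 0.09, 271, 46),
    slope = c(1.30, 1, 1.80, 1.70, 2.28, 1.94),
    direction = c("hyperactivity", "hyperactivity", "hyperactivity",
                  "hypoactivity", "hypoactivity", "hypoactivity"),
    stringsAsFactors = FALSE)
}

#' Single-substance STC parameters of the six reference chemicals
#'
#' Returns the single-substance concentration-response parameters used for
#' mixture prediction: the EC50 reported for the main experiments, the
#' independent-experiment ("modeling") EC50 actually used in the mixture
#' models, the curve slope, and the effect direction, for chlorpyrifos,
#' chlorpyrifos-oxon, hexaconazole, abamectin, carbamazepine and
#' propafenone.
#'
#' @param substance Optional substance name(s); unknown names raise an
#'   error.
#' @return A data.frame keyed by `substance`.
#' @examples
#' table1_fixture("abamectin")
#' @export
table1_fixture <- function(substance = NULL) {
  tab <- table1_data()
  if (is.null(substance)) return(tab)
  miss <- setdiff(substance, tab$substance)
  if (length(miss)) {
    stop("unknown substance(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab[match(substance, tab$substance), , drop = FALSE]
}

#' Standardized curves for the six reference chemicals
#'
#' Builds [ll4_curve] objects (floor 0, ceiling 100) from
#' [table1_fixture()].
#'
#' @param which `"modeling"` (the independent-experiment EC50s used for
#'   mixture prediction; default) or `"printed"`.
#' @return A named list of [ll4_curve] objects.
#' @export
table1_curves <- function(which = c("modeling", "printed")) {
  which <- match.arg(which)
  tab <- table1_data()
  e <- if (which == "modeling") tab$ec50_modeling_um else tab$ec50_um
  out <- Map(function(b, e, dir, nm) {
    ll4_curve(b = b, e = e, direction = dir, label = nm)
  }, tab$slope, e, tab$direction, tab$substance)
  names(out) <- tab$substance
  out
}
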