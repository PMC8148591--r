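#' Mixture component
#'
#' A named substance entering a mixture: its molar fraction of the total
#' mixture concentration and its single-substance concentration-response
#' curve on the standardized scale (floor 0, ceiling 100).
#'
#' @param name Substance name (unique within a design).
#' @param crc An [ll4_curve] (or [ll4_fit]) for the substance on the
#'   standardized effect scale.
#' @param fraction Molar fraction of the total mixture concentration in
#'   (0, 1]; may be `NA` when the design assigns fractions (e.g.
#'   [equitoxic_design()] or [substitution_design()]).
#' @return An object of class `mixture_component`.
#' @export
mixture_component <- function(name, crc, fraction = NA_real_) {
  crc <- as_ll4_curve(crc)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("component 'name' must be a non-empty string", call. = FALSE)
  }
  if (!is.na(fraction) &&
      (!is.numeric(fraction) || fraction <= 0 || fraction > 1)) {
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(name = name, fraction = as.numeric(fraction), crc = crc,
                 direction = crc$direction),
            class = "mixture_component")
}

#' Mixture design
#'
#' A set of named components whose molar fractions sum to one. A
#' single-component "design" (fraction 1) is allowed: both CA and IA then
#' collapse to the single-substance curve, which is useful as a consistency
#' check.
#'
#' @param components List of [mixture_component()] objects, all with
#'   fractions set.
#' @param label Optional mixture label.
#' @return An object of class `mixture_design`.
#' @seealso [equitoxic_design()], [substitution_design()]
#' @export
mixture_design <- function(components, label = NULL) {
  if (!is.list(components) || length(components) < 1L ||
      !all(vapply(components, inherits, logical(1), "mixture_component"))) {
    stop("'components' must be a list of mixture_component objects",
         call. = FALSE)
  }
  nms <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("component names must be unique", call. = FALSE)
  }
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (any(is.na(fr))) {
    stop("all components must carry a molar fraction ",
         "(or use equitoxic_design())", call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("molar fractions must sum to 1 (got %.12g)", sum(fr)),
         call. = FALSE)
  }
  names(components) <- nms
  structure(list(components = components, label = label),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, digits = 4, ...) {
  cat("Mixture design", if (!is.null(x$label)) paste0("(", x$label, ")"),
      "\n")
  for (cmp in x$components) {
    cat(sprintf("  %-18s p = %-8.4g EC50 = %-8.4g b = %-6.4g %s\n",
                cmp$name, cmp$fraction, cmp$crc$e, cmp$crc$b, cmp$direction))
  }
  invisible(x)
}

#' Equitoxic molar fractions from single-substance EC50s
#'
#' In an equitoxic mixture each component contributes equal toxic units, so
#' the molar fractions are proportional to the EC50s:
#' `p_i = EC50_i / sum(EC50)`.
#'
#' @param ec50s Positive EC50 concentrations (umol/L), optionally named.
#' @return Molar fractions summing to 1, same names as `ec50s`.
#' @examples
#' equitoxic_fractions(c(chlorpyrifos = 1.95, `chlorpyrifos-oxon` = 0.44))
#' @export
equitoxic_fractions <- function(ec50s) {
  if (!is.numeric(ec50s) || any(!is.finite(ec50s)) || any(ec50s <= 0)) {
    stop("all EC50s must be positive finite concentrations", call. = FALSE)
  }
  ec50s / sum(ec50s)
}

#' Equitoxic mixture design from single-substance curves
#'
#' @param curves Named list of [ll4_curve] objects (standardized scale); the
#'   EC50 of each is its inflection on the (floor, ceiling) midpoint.
#' @param label Optional mixture label.
#' @return A [mixture_design()] with EC50-proportional fractions.
#' @examples
#' tc <- table1_curves()
#' equitoxic_design(tc[c("chlorpyrifos", "chlorpyrifos-oxon")], "Mixture A")
#' @export
equitoxic_design <- function(curves, label = NULL) {
  if (!is.list(curves) || is.null(names(curves)) ||
      any(!nzchar(names(curves)))) {
    stop("'curves' must be a named list of ll4_curve objects", call. = FALSE)
  }
  curves <- lapply(curves, as_ll4_curve)
  ec50 <- vapply(curves, function(cr) estimate_ec(50, cr)$estimate,
                 numeric(1))
  fr <- equitoxic_fractions(ec50)
  comps <- Map(function(nm, cr, p) mixture_component(nm, cr, p),
               names(curves), curves, fr)
  mixture_design(unname(comps), label = label)
}

#' @keywords internal
design_directions <- function(design) {
  vapply(design$components, `[[`, character(1), "direction")
}

#' @keywords internal
check_same_direction <- function(design, what) {
  dirs <- unique(design_directions(design))
  if (length(dirs) > 1L) {
    stop(what, " is undefined for components with opposing effect ",
         "directions; evaluate the opposing-direction mixture with ",
         "assess_antagonism() / fit_biphasic() instead", call. = FALSE)
  }
  invisible(dirs)
}

#' @keywords internal
check_standardized <- function(design) {
  raw <- vapply(design$components,
                function(cmp) cmp$crc$c != 0 || cmp$crc$d != 100, logical(1))
  if (any(raw)) {
    warning("component curves are not on the standardized 0-100 scale (",
            paste(names(design$components)[raw], collapse = ", "),
            "); mixture predictions across unequal maxima are unreliable - ",
            "standardize with standardize_hyperactivity() / ",
            "normalized_response() first", call. = FALSE)
  }
  invisible(design)
}

#' Concentration-addition (Loewe) mixture ECx
#'
#' Under concentration addition the components behave as dilutions of each
#' other, and the total mixture concentration provoking `level` percent
#' effect is the harmonic combination of the single-substance ECx values
#' weighted by molar fractions:
#' \deqn{ECx_{Mix} = \left( \sum_i \frac{p_i}{ECx_i} \right)^{-1}}
#' For an equitoxic design this reduces to `sum(EC50_i) / n` at the 50
#' percent level.
#'
#' @param level Effect level in percent, strictly in (0, 100).
#' @param design A same-direction [mixture_design()] on the standardized
#'   scale.
#' @return Total mixture concentration in umol/L.
#' @examples
#' tc <- table1_curves()
#' mixA <- equitoxic_design(tc[c("chlorpyrifos", "chlorpyrifos-oxon")])
#' ca_ecx(50, mixA)  # 1.19 umol/L
#' @export
ca_ecx <- function(level, design) {
  stopifnot(inherits(design, "mixture_design"))
  check_same_direction(design, "concentration addition")
  check_standardized(design)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 100) {
    stop("'level' must lie strictly between 0 and 100 percent", call. = FALSE)
  }
  ecx <- vapply(design$components, function(cmp) {
    ll4_inverse(level, cmp$crc)
  }, numeric(1))
  p <- vapply(design$components, `[[`, numeric(1), "fraction")
  1 / sum(p / ecx)
}

#' Concentration-addition prediction curve
#'
#' @param design A same-direction [mixture_design()].
#' @param levels Effect levels in percent, strictly inside (0, 100); default
#'   1 to 99.
#' @return A `mixture_prediction` object: model `"CA"`, a grid of (total
#'   concentration, predicted effect) pairs increasing in concentration, and
#'   the predicted EC50.
#' @export
ca_curve <- function(design, levels = 1:99) {
  conc <- vapply(sort(levels), ca_ecx, numeric(1), design = design)
  new_mixture_prediction("CA", design, sort(levels), conc)
}

#' Independent-action (Bliss) mixture effect
#'
#' Under independent action the components act on statistically independent
#' "targets": fractional effects combine as
#' \deqn{E_{Mix} = 1 - \prod_i (1 - E_i)}
#' where `E_i` is the fractional effect of component `i` at its partial
#' concentration `p_i * total_c`.
#'
#' @param total_c Total mixture concentration(s) in umol/L, non-negative.
#' @param design A same-direction [mixture_design()] on the standardized
#'   scale.
#' @return Predicted percent effect, same length as `total_c`; non-decreasing
#'   in `total_c` and bounded by 100.
#' @export
ia_effect <- function(total_c, design) {
  stopifnot(inherits(design, "mixture_design"))
  check_same_direction(design, "independent action")
  check_standardized(design)
  if (!is.numeric(total_c) || any(!is.finite(total_c)) || any(total_c < 0)) {
    stop("'total_c' must be finite and non-negative", call. = FALSE)
  }
  surv <- rep(1, length(total_c))
  for (cmp in design$components) {
    e_frac <- ll4_effect(cmp$fraction * total_c, cmp$crc) / 100
    surv <- surv * (1 - e_frac)
  }
  100 * (1 - surv)
}

#' Independent-action mixture ECx by root finding
#'
#' Solves `ia_effect(c, design) = level` for the total concentration by
#' bracketing and bisection on the log-concentration scale; [ia_effect()] is
#' monotone so the root is unique. The initial bracket spans
#' `[min(EC50_i * p_i) / 1e3, max(EC50_i / p_i) * 1e3]` and is expanded
#' geometrically if needed; the bisection stops at a relative width of 1e-8.
#'
#' @param level Effect level in percent, strictly in (0, 100) and below the
#'   asymptotic maximum `100 * (1 - prod(1 - d_i/100))`.
#' @param design A same-direction [mixture_design()].
#' @return Total mixture concentration in umol/L.
#' @examples
#' tc <- table1_curves()
#' mixC <- equitoxic_design(tc[c("chlorpyrifos", "hexaconazole",
#'                               "chlorpyrifos-oxon")])
#' ia_ecx(50, mixC)  # about 2.2 umol/L
#' @export
ia_ecx <- function(level, design) {
  stopifnot(inherits(design, "mixture_design"))
  check_same_direction(design, "independent action")
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 100) {
    stop("'level' must lie strictly between 0 and 100 percent", call. = FALSE)
  }
  dmax <- vapply(design$components, function(cmp) cmp$crc$d, numeric(1))
  asym <- 100 * (1 - prod(1 - dmax / 100))
  if (level >= asym) {
    stop(sprintf(
      "effect level %g%% is at or above the asymptotic maximum %g%% of the IA curve",
      level, asym), call. = FALSE)
  }
  e50 <- vapply(design$components, function(cmp) cmp$crc$e, numeric(1))
  p <- vapply(design$components, `[[`, numeric(1), "fraction")
  lo <- min(e50 * p) / 1e3
  hi <- max(e50 / p) * 1e3
  f <- function(cc) ia_effect(cc, design) - level
  for (i in 1:60) {
    if (f(lo) < 0) break
    lo <- lo / 10
  }
  for (i in 1:60) {
    if (f(hi) > 0) break
    hi <- hi * 10
  }
  if (f(lo) >= 0 || f(hi) <= 0) {
    stop("could not bracket the IA effect level", call. = FALSE)
  }
  while (hi / lo - 1 > 1e-8) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Independent-action prediction curve
#'
#' @inheritParams ca_curve
#' @return A `mixture_prediction` with model `"IA"`.
#' @export
ia_curve <- function(design, levels = 1:99) {
  dmax <- vapply(design$components, function(cmp) cmp$crc$d, numeric(1))
  asym <- 100 * (1 - prod(1 - dmax / 100))
  levels <- sort(levels)
  levels <- levels[levels < asym]
  conc <- vapply(levels, ia_ecx, numeric(1), design = design)
  new_mixture_prediction("IA", design, levels, conc)
}

#' Predict a mixture concentration-response curve
#'
#' @param design A same-direction [mixture_design()].
#' @param model `"CA"` (concentration addition) or `"IA"` (independent
#'   action).
#' @param levels Effect levels in percent for the prediction grid.
#' @return A `mixture_prediction` object with elements `model`, `label`,
#'   `grid` (data.frame `concentration_um`, `effect_percent`) and `ec50`.
#' @export
predict_mixture <- function(design, model = c("CA", "IA"), levels = 1:99) {
  model <- match.arg(model)
  if (model == "CA") ca_curve(design, levels) else ia_curve(design, levels)
}

#' @keywords internal
new_mixture_prediction <- function(model, design, levels, conc) {
  if (any(diff(conc) <= 0)) {
    stop("internal error: prediction grid is not strictly increasing")
  }
  ec50 <- if (model == "CA") ca_ecx(50, design) else ia_ecx(50, design)
  structure(
    list(model = model, label = design$label,
         grid = data.frame(concentration_um = conc,
                           effect_percent = levels),
         ec50 = ec50),
    class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, digits = 4, ...) {
  cat(sprintf("%s mixture prediction%s: EC50 = %.*g umol/L (%d grid points)\n",
              x$model, if (!is.null(x$label)) paste0(" (", x$label, ")")
              else "", digits, x$ec50, nrow(x$grid)))
  invisible(x)
}

#' @export
as.data.frame.mixture_prediction <- function(x, ...) {
  cbind(model = x$model, x$grid)
}

#' @export
plot.mixture_prediction <- function(x, ...) {
  plot(x$grid$concentration_um, x$grid$effect_percent, type = "l", log = "x",
       xlab = "total concentration [umol/L]", ylab = "predicted effect [%]",
       main = paste(x$model, "prediction", x$label), ...)
  invisible(x)
}

#' Substitute a mixture component by an equitoxic portion of another substance
#'
#' Implements the dilution experiment: a portion of one component's molar
#' fraction is opened for substitution and repartitioned between the original
#' substance and the substitute in the ratio of their EC50s, so that the
#' remaining and the added substance are equitoxic within the substituted
#' slice. With `portion = 1`, replacing part of chlorpyrifos (EC50 1.95) by
#' hexaconazole (EC50 3.63) in the chlorpyrifos-oxon/chlorpyrifos mixture
#' turns fractions 0.184:0.816 into 0.184:0.286:0.530. The total molar
#' fraction is preserved, so no renormalization is needed.
#'
#' Because concentration addition is associative, the CA-predicted ECx of the
#' substituted design equals the CA prediction of the original design with
#' the substituted slice treated as a single pseudo-component carrying the
#' slice's own CA ECx (an exact identity, testable to numerical precision).
#' The predicted EC50 in umol/L does change when the substitute has a
#' different potency: substituting a less potent substance shifts the curve
#' to higher total concentrations.
#'
#' @param design A [mixture_design()].
#' @param replace Name of the component to substitute.
#' @param with A [mixture_component()] for the substitute (its `fraction` is
#'   ignored and computed here). If a component with the same name already
#'   exists in the design, the fractions are merged.
#' @param portion Share in (0, 1] of the replaced component's molar fraction
#'   opened to substitution (default 1: the whole fraction is repartitioned).
#' @return A new [mixture_design()].
#' @examples
#' tc <- table1_curves()
#' mixA <- equitoxic_design(tc[c("chlorpyrifos", "chlorpyrifos-oxon")])
#' substitution_design(mixA, "chlorpyrifos",
#'                     mixture_component("hexaconazole", tc$hexaconazole))
#' @export
substitution_design <- function(design, replace, with, portion = 1) {
  stopifnot(inherits(design, "mixture_design"))
  if (!inherits(with, "mixture_component")) {
    stop("'with' must be a mixture_component", call. = FALSE)
  }
  if (!replace %in% names(design$components)) {
    stop("component '", replace, "' is not part of the design", call. = FALSE)
  }
  if (!is.numeric(portion) || length(portion) != 1L || portion <= 0 ||
      portion > 1) {
    stop("'portion' must lie in (0, 1]", call. = FALSE)
  }
  old <- design$components[[replace]]
  e_old <- estimate_ec(50, old$crc)$estimate
  e_new <- estimate_ec(50, with$crc)$estimate
  slice <- portion * old$fraction
  p_new <- slice * e_new / (e_old + e_new)
  p_old <- old$fraction - p_new

  comps <- design$components
  comps[[replace]]$fraction <- p_old
  if (with$name %in% names(comps)) {
    comps[[with$name]]$fraction <- comps[[with$name]]$fraction + p_new
  } else {
    comps[[with$name]] <- mixture_component(with$name, with$crc, p_new)
  }
  mixture_design(unname(comps),
                 label = paste0(design$label %||% "mixture",
                                " [", replace, " -> ", with$name, "]"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
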