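#' Fit a biphasic (Gaussian-on-log-concentration) response
#'
#' Mixtures containing components with opposing effect directions can show a
#' rise-then-fall response: hyperactivity at low concentrations suppressed,
#' and even reversed into hypoactivity, as the counteracting component takes
#' effect. Such a biphasic response is modelled as a Gaussian in log10
#' concentration,
#' \deqn{y = baseline + amplitude \cdot \exp\left(-\frac{(\log_{10} x - center)^2}{2\,width^2}\right)}
#' with a free baseline that may go negative so the hypoactivity undershoot
#' at high concentrations is representable.
#'
#' The Gaussian is accepted only if its residual sum of squares beats the
#' best monotone LL.4 fit (free ceiling, tried in both effect directions) on
#' the same points; otherwise the monotone model is reported as preferred, so
#' genuinely monotone data are never forced into a biphasic description.
#'
#' @param data A data.frame with columns `concentration_um` and
#'   `percent_change` (signed percent change versus control). Zero
#'   concentrations are dropped (the model lives on the log scale). At least
#'   5 distinct non-zero concentrations are required.
#' @param control Optimizer settings as in [fit_ll4()].
#' @return An object of class `biphasic_fit` with elements `amplitude`,
#'   `center_log10c`, `width_log10c`, `baseline`, `preferred` (`"gaussian"`
#'   or `"monotone"`), `rss_gaussian`, `rss_monotone`, `monotone_fit` (the
#'   competing [ll4_fit] or `NULL`), `data`, `fitted.values`, `residuals`.
#' @examples
#' x <- 10^seq(-1, 1.2, length.out = 8)
#' y <- 60 * exp(-(log10(x) - log10(2))^2 / (2 * 0.3^2))
#' fit_biphasic(data.frame(concentration_um = x, percent_change = y))
#' @export
fit_biphasic <- function(data, control = list()) {
  ctl <- utils::modifyList(list(ftol = 1e-10, ptol = 1e-10, maxiter = 500),
                           control)
  if (!is.data.frame(data) ||
      !all(c("concentration_um", "percent_change") %in% names(data))) {
    stop("'data' needs columns 'concentration_um' and 'percent_change'",
         call. = FALSE)
  }
  keep <- data$concentration_um > 0
  x <- data$concentration_um[keep]
  y <- data$percent_change[keep]
  if (length(unique(x)) < 5L) {
    stop("at least 5 distinct non-zero concentrations are required",
         call. = FALSE)
  }
  ord <- order(x, y)
  x <- x[ord]
  y <- y[ord]
  t <- log10(x)

  # Gaussian fit, width parameterized on the log scale to stay positive.
  gauss <- function(p, t) {
    p[["base"]] + p[["amp"]] *
      exp(-(t - p[["center"]])^2 / (2 * exp(2 * p[["logw"]])))
  }
  resid_fn <- function(p) y - gauss(p, t)
  means <- tapply(y, t, mean)
  t_peak <- as.numeric(names(means))[which.max(means)]
  w0 <- diff(range(t)) / 4
  starts <- lapply(c(0.5, 1, 2), function(k) {
    c(amp = max(means) - min(0, min(means)), center = t_peak,
      logw = log(max(w0 * k, 1e-3)), base = min(0, min(means)))
  })
  fits <- lapply(starts, function(s) {
    tryCatch(minpack.lm::nls.lm(
      par = s, fn = resid_fn,
      control = minpack.lm::nls.lm.control(ftol = ctl$ftol, ptol = ctl$ptol,
                                           maxiter = ctl$maxiter)),
      error = function(e) NULL)
  })
  dev <- vapply(fits, function(f) {
    if (is.null(f) || !f$info %in% 1:4) Inf else f$deviance
  }, numeric(1))
  if (all(!is.finite(dev))) {
    stop("Gaussian fit did not converge from any starting point",
         call. = FALSE)
  }
  g <- fits[[which.min(dev)]]
  rss_g <- g$deviance

  # Competing monotone LL.4 fits (increasing on y and on -y).
  mono_candidates <- list()
  for (sgn in c(1, -1)) {
    mf <- tryCatch(
      fit_ll4(data.frame(concentration_um = x, effect_percent = sgn * y),
              fix_floor = TRUE, fix_ceiling = FALSE),
      error = function(e) NULL)
    if (!is.null(mf)) mono_candidates[[length(mono_candidates) + 1L]] <-
        list(fit = mf, sign = sgn)
  }
  rss_m <- vapply(mono_candidates, function(m) m$fit$deviance, numeric(1))
  best_m <- if (length(rss_m)) mono_candidates[[which.min(rss_m)]] else NULL
  rss_m_best <- if (length(rss_m)) min(rss_m) else Inf

  pars <- g$par
  fitted_vals <- gauss(pars, t)
  structure(
    list(amplitude = unname(pars[["amp"]]),
         center_log10c = unname(pars[["center"]]),
         width_log10c = unname(exp(pars[["logw"]])),
         baseline = unname(pars[["base"]]),
         preferred = if (rss_g < rss_m_best) "gaussian" else "monotone",
         rss_gaussian = rss_g, rss_monotone = rss_m_best,
         monotone_fit = best_m$fit, monotone_sign = best_m$sign,
         data = data.frame(concentration_um = x, percent_change = y),
         fitted.values = fitted_vals, residuals = y - fitted_vals),
    class = "biphasic_fit")
}

#' @export
coef.biphasic_fit <- function(object, ...) {
  c(amplitude = object$amplitude, center_log10c = object$center_log10c,
    width_log10c = object$width_log10c, baseline = object$baseline)
}

#' @export
print.biphasic_fit <- function(x, digits = 4, ...) {
  cat("Biphasic (Gaussian on log10 concentration) fit\n")
  print(signif(coef(x), digits))
  cat(sprintf("  RSS: gaussian %.4g vs monotone %.4g -> %s model preferred\n",
              x$rss_gaussian, x$rss_monotone, x$preferred))
  invisible(x)
}

#' @export
predict.biphasic_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$concentration_um
  } else if (is.data.frame(newdata)) {
    newdata$concentration_um
  } else {
    newdata
  }
  t <- log10(x)
  object$baseline + object$amplitude *
    exp(-(t - object$center_log10c)^2 / (2 * object$width_log10c^2))
}

#' @export
fitted.biphasic_fit <- function(object, ...) object$fitted.values

#' @export
residuals.biphasic_fit <- function(object, ...) object$residuals

#' Assess antagonism of an opposing-direction mixture
#'
#' Compares the observed response of a mixture containing a counteracting
#' (opposite-direction) component against the additive expectation built
#' from its same-direction components (for example, the CA prediction of the
#' hyperactive sub-mixture). The mixture is called antagonistic when the
#' observed mean response falls short of the prediction by more than
#' `se_mult` standard errors at `n_consecutive` or more consecutive tested
#' concentrations. The verdict is one-sided: observed responses at or above
#' the prediction are never antagonistic. Both inputs must be on the same
#' effect scale.
#'
#' @param observed A data.frame with columns `concentration_um` and
#'   `percent_change`; replicate rows per concentration (e.g. one per
#'   independent experiment) supply the observed standard error, or an
#'   explicit `se_percent_change` column can be given.
#' @param reference A `mixture_prediction` (see [predict_mixture()]) for the
#'   same-direction sub-mixture; predicted effects at observed concentrations
#'   are interpolated on the log-concentration scale. Observed concentrations
#'   outside the prediction grid are ignored; if no tested concentration
#'   falls inside the grid an error is raised.
#' @param se_mult Shortfall threshold in observed standard errors (default 2,
#'   mirroring the assay's 2-standard-error interval rule).
#' @param n_consecutive Minimum run of consecutive flagged concentrations
#'   (default 2).
#' @return An object of class `antagonism_report`: `reference_model`,
#'   `verdict` (`"antagonistic"` / `"not_antagonistic"`),
#'   `max_observed_effect`, `max_predicted_effect`, `suppression`
#'   (predicted minus observed maxima, percent points),
#'   `direction_reversal_concentration` (lowest concentration where the
#'   observed mean response flips sign relative to control; `NA` if none)
#'   and `comparison` (the per-concentration table).
#' @export
assess_antagonism <- function(observed, reference, se_mult = 2,
                              n_consecutive = 2) {
  if (!inherits(reference, "mixture_prediction")) {
    stop("'reference' must be a mixture_prediction", call. = FALSE)
  }
  if (!is.data.frame(observed) ||
      !all(c("concentration_um", "percent_change") %in% names(observed))) {
    stop("'observed' needs columns 'concentration_um' and 'percent_change'",
         call. = FALSE)
  }
  obs <- observed[observed$concentration_um > 0, , drop = FALSE]
  concs <- sort(unique(obs$concentration_um))
  mean_obs <- vapply(concs, function(cc) {
    mean(obs$percent_change[obs$concentration_um == cc])
  }, numeric(1))
  se_obs <- vapply(concs, function(cc) {
    rows <- obs$concentration_um == cc
    if ("se_percent_change" %in% names(obs) &&
        any(is.finite(obs$se_percent_change[rows]))) {
      v <- obs$se_percent_change[rows]
      sqrt(mean(v[is.finite(v)]^2) / sum(is.finite(v)))
    } else if (sum(rows) > 1) {
      stats::sd(obs$percent_change[rows]) / sqrt(sum(rows))
    } else {
      NA_real_
    }
  }, numeric(1))
  if (any(is.na(se_obs))) {
    stop("observed standard errors are unavailable; supply replicate rows ",
         "per concentration or an 'se_percent_change' column", call. = FALSE)
  }

  grid <- reference$grid
  inside <- concs >= min(grid$concentration_um) &
    concs <= max(grid$concentration_um)
  if (!any(inside)) {
    stop("observed concentrations do not overlap the reference prediction ",
         "range; the curves are not comparable", call. = FALSE)
  }
  pred <- rep(NA_real_, length(concs))
  pred[inside] <- stats::approx(log10(grid$concentration_um),
                                grid$effect_percent,
                                xout = log10(concs[inside]))$y

  shortfall <- pred - mean_obs
  flagged <- !is.na(pred) & shortfall > se_mult * se_obs
  runs <- rle(flagged)
  antagonistic <- any(runs$values & runs$lengths >= n_consecutive)

  # A direction reversal is a sign flip after the rise: the lowest tested
  # concentration beyond the observed maximum where the mean response has
  # the opposite sign to the reference prediction. Restricting to the
  # falling limb keeps low-concentration noise around zero from counting.
  peak_conc <- concs[which.max(mean_obs)]
  flip <- concs[concs > peak_conc & !is.na(pred) &
                  sign(mean_obs) == -sign(pred) & mean_obs != 0]
  comparison <- data.frame(
    concentration_um = concs, observed = mean_obs, se_observed = se_obs,
    predicted = pred, shortfall = shortfall, flagged = flagged)

  structure(
    list(reference_model = reference$model,
         verdict = if (antagonistic) "antagonistic" else "not_antagonistic",
         max_observed_effect = max(mean_obs[!is.na(pred)]),
         max_predicted_effect = max(pred, na.rm = TRUE),
         suppression = max(pred, na.rm = TRUE) - max(mean_obs[!is.na(pred)]),
         direction_reversal_concentration =
           if (length(flip)) min(flip) else NA_real_,
         se_mult = se_mult, n_consecutive = n_consecutive,
         comparison = comparison),
    class = "antagonism_report")
}

#' @export
print.antagonism_report <- function(x, digits = 4, ...) {
  cat("Antagonism assessment vs", x$reference_model, "reference\n")
  cat("  verdict:", x$verdict, "\n")
  cat(sprintf("  max observed %.4g%% vs max predicted %.4g%% (suppression %.4g points)\n",
              x$max_observed_effect, x$max_predicted_effect, x$suppression))
  if (!is.na(x$direction_reversal_concentration)) {
    cat(sprintf("  sign reversal relative to control from %.4g umol/L\n",
                x$direction_reversal_concentration))
  }
  cat(sprintf("  rule: shortfall > %g x SE at >= %d consecutive concentrations\n",
              x$se_mult, x$n_consecutive))
  invisible(x)
}
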