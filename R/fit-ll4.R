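# Internal: model on the log10-concentration scale for conditioning.
# (e/x)^b == 10^(b * (theta - t)) with theta = log10(e), t = log10(x).
ll4_model_log <- function(t, b, theta, cc, dd) {
  cc + (dd - cc) / (1 + 10^(b * (theta - t)))
}

#' Fit the four-parameter log-logistic concentration-response model
#'
#' Least-squares fit of the LL.4 model to per-concentration percent-effect
#' data. By default the floor and ceiling are fixed at 0 and 100 (the
#' standardized effect scale); raw hyperactivity curves are fitted with a
#' free ceiling (`fix_ceiling = FALSE`) whose estimate becomes the
#' standardization divisor (see [max_effect_from_fit()]).
#'
#' Fitting is performed on the log10-concentration scale with the inflection
#' parameterized as `log10(e)` for conditioning, by Levenberg-Marquardt least
#' squares ([minpack.lm::nls.lm]) from three starting points (inflection at
#' the geometric mean of the tested concentrations, one decade below and one
#' above; slope 1) to avoid local minima; the best converged fit is kept.
#' Standard errors come from the Gauss-Newton approximation of the Hessian at
#' the optimum. Control (zero-concentration) observations are not used by the
#' fitter: they are consumed upstream by the normalization step, so rows with
#' zero concentration are dropped here.
#'
#' @param data A data.frame with numeric columns `concentration_um` and
#'   `effect_percent` (one row per concentration and experiment, after
#'   normalization). At least 4 distinct non-zero concentrations are
#'   required.
#' @param fix_floor,fix_ceiling Fix `c = 0` / `d = 100` (defaults `TRUE`).
#' @param direction Effect direction flag carried into the fitted curve.
#' @param label Optional substance or mixture label.
#' @param control List of optimizer settings: `ftol`, `ptol` (convergence
#'   tolerances on the objective and parameters, default `1e-8`) and
#'   `maxiter` (default 200).
#' @return An object of class `ll4_fit`: a list with elements `curve` (the
#'   fitted [ll4_curve] including `se_e`), `coefficients`, `se` (standard
#'   errors of the free parameters), `data`, `fitted.values`, `residuals`,
#'   `deviance` (residual sum of squares), `df.residual`, `sigma`, `vcov`
#'   (free parameters, internal `log10(e)` scale), `fix`, and `convergence`.
#' @examples
#' x <- c(0.25, 0.5, 1, 2, 4, 8)
#' dat <- data.frame(concentration_um = x,
#'                   effect_percent = ll4_effect(x, ll4_curve(b = 1.94, e = 46) ))
#' fit <- fit_ll4(dat)
#' coef(fit)
#' @export
fit_ll4 <- function(data, fix_floor = TRUE, fix_ceiling = TRUE,
                    direction = c("hyperactivity", "hypoactivity"),
                    label = NULL, control = list()) {
  direction <- match.arg(direction)
  ctl <- utils::modifyList(list(ftol = 1e-8, ptol = 1e-8, maxiter = 200),
                           control)
  if (!is.data.frame(data) ||
      !all(c("concentration_um", "effect_percent") %in% names(data))) {
    stop("'data' must contain columns 'concentration_um' and 'effect_percent'",
         call. = FALSE)
  }
  x <- data$concentration_um
  y <- data$effect_percent
  if (!is.numeric(x) || !is.numeric(y) || any(!is.finite(x)) ||
      any(!is.finite(y)) || any(x < 0)) {
    stop("concentrations must be finite and non-negative, effects finite",
         call. = FALSE)
  }
  keep <- x > 0
  x <- x[keep]
  y <- y[keep]
  if (length(unique(x)) < 4L) {
    stop("at least 4 distinct non-zero concentrations are required",
         call. = FALSE)
  }
  if (all(y == 0)) {
    stop("all responses are zero; no concentration-response signal to fit",
         call. = FALSE)
  }
  # Sort for determinism: the fit is invariant to input row order.
  ord <- order(x, y)
  x <- x[ord]
  y <- y[ord]
  t <- log10(x)

  free <- c(b = TRUE, theta = TRUE, c = !fix_floor, d = !fix_ceiling)
  fixed_c <- 0
  fixed_d <- 100

  build_par <- function(theta0) {
    p <- c(b = 1, theta = theta0)
    if (!fix_floor) p <- c(p, c = min(y, 0))
    if (!fix_ceiling) p <- c(p, d = max(y))
    p
  }
  resid_fn <- function(p) {
    cc <- if (fix_floor) fixed_c else p[["c"]]
    dd <- if (fix_ceiling) fixed_d else p[["d"]]
    y - ll4_model_log(t, p[["b"]], p[["theta"]], cc, dd)
  }

  theta_gm <- mean(t)  # log10 geometric mean of tested concentrations
  starts <- lapply(theta_gm + c(0, -1, 1), build_par)
  fits <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    fits[[i]] <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[i]], fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = ctl$ftol, ptol = ctl$ptol, maxiter = ctl$maxiter)),
      error = function(e) NULL)
  }
  ok <- vapply(fits, function(f) {
    !is.null(f) && f$info %in% 1:4 && f$par[["b"]] > 0 &&
      all(is.finite(unlist(f$par)))
  }, logical(1))
  if (!any(ok)) {
    last <- Filter(Negate(is.null), fits)
    diag <- if (length(last)) {
      f <- last[[length(last)]]
      list(par = f$par, info = f$info, message = f$message,
           deviance = f$deviance)
    } else NULL
    cond <- structure(
      class = c("stcmix_fit_error", "error", "condition"),
      list(message = paste0(
             "log-logistic fit did not converge",
             if (!is.null(label)) paste0(" for '", label, "'"),
             if (!is.null(diag)) paste0(" (last iterate: ",
               paste(sprintf("%s=%.4g", names(diag$par), unlist(diag$par)),
                     collapse = ", "), "; ", diag$message, ")")),
           call = sys.call(-1), diagnostics = diag))
    stop(cond)
  }
  best <- which.min(vapply(fits, function(f) {
    if (is.null(f)) Inf else f$deviance
  }, numeric(1)) + ifelse(ok, 0, Inf))
  fit <- fits[[best]]

  p <- fit$par
  cc <- if (fix_floor) fixed_c else p[["c"]]
  dd <- if (fix_ceiling) fixed_d else p[["d"]]
  b_hat <- p[["b"]]
  e_hat <- 10^p[["theta"]]

  # Gauss-Newton covariance: sigma^2 * (J'J)^-1 on the internal parameters.
  n <- length(y)
  npar <- length(p)
  dfres <- max(n - npar, 1L)
  sigma2 <- fit$deviance / dfres
  vc <- tryCatch(sigma2 * chol2inv(chol(fit$hessian / 2)),
                 error = function(e) matrix(NA_real_, npar, npar))
  dimnames(vc) <- list(names(p), names(p))
  se <- sqrt(pmax(diag(vc), 0))
  # delta method: e = 10^theta => se(e) = se(theta) * e * ln(10)
  se_e <- unname(se["theta"] * e_hat * log(10))

  curve <- ll4_curve(b = b_hat, c = cc, d = dd, e = e_hat, se_e = se_e,
                     direction = direction, label = label)
  fitted_vals <- ll4_effect(x, curve)
  coefs <- c(b = b_hat, c = cc, d = dd, e = e_hat)
  se_out <- c(b = unname(se["b"]),
              c = if (fix_floor) NA_real_ else unname(se["c"]),
              d = if (fix_ceiling) NA_real_ else unname(se["d"]),
              e = se_e)
  structure(
    list(curve = curve, coefficients = coefs, se = se_out,
         data = data.frame(concentration_um = x, effect_percent = y),
         fitted.values = fitted_vals, residuals = y - fitted_vals,
         deviance = fit$deviance, df.residual = n - npar,
         sigma = sqrt(sigma2), vcov = vc,
         fix = c(floor = fix_floor, ceiling = fix_ceiling),
         convergence = list(start = best, info = fit$info,
                            message = fit$message, niter = fit$niter),
         call = match.call()),
    class = "ll4_fit")
}

#' @export
coef.ll4_fit <- function(object, ...) object$coefficients

#' @export
vcov.ll4_fit <- function(object, ...) object$vcov

#' @export
fitted.ll4_fit <- function(object, ...) object$fitted.values

#' @export
residuals.ll4_fit <- function(object, ...) object$residuals

#' @export
deviance.ll4_fit <- function(object, ...) object$deviance

#' @export
print.ll4_fit <- function(x, digits = 4, ...) {
  cat("Log-logistic (LL.4) concentration-response fit",
      if (!is.null(x$curve$label)) paste0("(", x$curve$label, ")"), "\n")
  cat("  direction:", x$curve$direction,
      "| floor", if (x$fix["floor"]) "fixed" else "free",
      "| ceiling", if (x$fix["ceiling"]) "fixed" else "free", "\n")
  print(signif(x$coefficients, digits))
  ec <- estimate_ec(50, x)
  cat(sprintf("  EC50 = %.*g umol/L (CI %.*g - %.*g)\n",
              digits, ec$estimate, digits, ec$ci_low, digits, ec$ci_high))
  invisible(x)
}

#' @export
summary.ll4_fit <- function(object, ci_mult = 2, ...) {
  free <- c("b", if (!object$fix["floor"]) "c",
            if (!object$fix["ceiling"]) "d", "e")
  tab <- data.frame(
    estimate = object$coefficients[free],
    se = object$se[free],
    row.names = free)
  tab$ci_low <- tab$estimate - ci_mult * tab$se
  tab$ci_high <- tab$estimate + ci_mult * tab$se
  out <- list(label = object$curve$label, direction = object$curve$direction,
              parameters = tab, ec50 = estimate_ec(50, object, ci_mult),
              deviance = object$deviance, sigma = object$sigma,
              df.residual = object$df.residual, fix = object$fix)
  class(out) <- "summary.ll4_fit"
  out
}

#' @export
print.summary.ll4_fit <- function(x, digits = 4, ...) {
  cat("Log-logistic (LL.4) fit",
      if (!is.null(x$label)) paste0("(", x$label, ")"),
      "-", x$direction, "\n\nParameters:\n")
  print(signif(as.matrix(x$parameters), digits))
  cat(sprintf("\nEC50: %.*g umol/L (CI %.*g - %.*g)\n", digits,
              x$ec50$estimate, digits, x$ec50$ci_low, digits, x$ec50$ci_high))
  cat(sprintf("Residual sum of squares: %.*g on %d df\n", digits,
              x$deviance, x$df.residual))
  invisible(x)
}

#' Predict percent effect from a fitted LL.4 model
#'
#' @param object An `ll4_fit`.
#' @param newdata Numeric vector of concentrations (umol/L) or a data.frame
#'   with a `concentration_um` column. Defaults to the fitted concentrations.
#' @param ... Unused.
#' @return Numeric vector of percent effects.
#' @export
predict.ll4_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$concentration_um
  } else if (is.data.frame(newdata)) {
    newdata$concentration_um
  } else {
    newdata
  }
  ll4_effect(x, object$curve)
}

#' Simulate responses from a fitted LL.4 model
#'
#' Draws Gaussian residuals with the fit's residual standard deviation around
#' the fitted curve, at the fitted concentrations.
#'
#' @param object An `ll4_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed applied locally (the caller's RNG state is
#'   restored on exit).
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of simulated `effect_percent`.
#' @export
simulate.ll4_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  mu <- object$fitted.values
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted LL.4 concentration-response curve
#'
#' Base-graphics plot of the data points and fitted curve on a
#' log-concentration axis.
#'
#' @param x An `ll4_fit`.
#' @param n Number of curve evaluation points.
#' @param ... Passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ll4_fit <- function(x, n = 200, ...) {
  xs <- x$data$concentration_um
  grid <- 10^seq(log10(min(xs)) - 0.5, log10(max(xs)) + 0.5, length.out = n)
  plot(xs, x$data$effect_percent, log = "x",
       xlab = "concentration [umol/L]",
       ylab = paste0("effect [% ", x$curve$direction, "]"),
       main = x$curve$label, ...)
  graphics::lines(grid, ll4_effect(grid, x$curve))
  invisible(x)
}
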