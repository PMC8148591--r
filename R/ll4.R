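#' Four-parameter log-logistic concentration-response curve
#'
#' Constructs the parameter object for the log-logistic model
#' \deqn{y(x) = c + \frac{d - c}{1 + (e/x)^b}}
#' used throughout the package to describe spontaneous tail coiling (STC)
#' effects as a function of exposure concentration. With the floor `c` fixed
#' at 0 and the ceiling `d` at 100 (the standardized effect scale), the
#' inflection `e` is the EC50. The curve is always written so that the effect
#' increases with concentration (`b > 0`); hypoactivity is represented as
#' percent *decrease* in STC frequency on the same 0--100 scale, with the
#' `direction` flag retained for reporting.
#'
#' @param b Slope parameter, dimensionless, strictly positive.
#' @param c Floor (minimum effect), percent. Default 0.
#' @param d Ceiling (maximum effect), percent. Default 100; raw hyperactivity
#'   curves may have `d < 100` before standardization.
#' @param e Inflection concentration in umol/L, strictly positive. Equals the
#'   EC50 when `c = 0`, `d = 100`.
#' @param se_e Standard error of `e` in umol/L (`NA` if unknown).
#' @param direction `"hyperactivity"` (STC increase) or `"hypoactivity"`
#'   (STC decrease, modelled as percent decrease).
#' @param label Optional substance or mixture label.
#' @return An object of class `ll4_curve`.
#' @examples
#' crc <- ll4_curve(b = 1.3, e = 1.95, label = "chlorpyrifos")
#' ll4_effect(c(0, 1.95, 3.9), crc)
#' @seealso [ll4_effect()], [ll4_inverse()], [estimate_ec()], [fit_ll4()]
#' @export
ll4_curve <- function(b, c = 0, d = 100, e, se_e = NA_real_,
                      direction = c("hyperactivity", "hypoactivity"),
                      label = NULL) {
  direction <- match.arg(direction)
  for (nm in c("b", "c", "d", "e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (b <= 0) stop("slope 'b' must be positive", call. = FALSE)
  if (e <= 0) stop("inflection 'e' must be a positive concentration",
                   call. = FALSE)
  if (c >= d) stop("floor 'c' must lie below ceiling 'd'", call. = FALSE)
  if (!is.na(se_e) && se_e < 0) stop("'se_e' must be non-negative",
                                     call. = FALSE)
  structure(
    list(b = b, c = c, d = d, e = e, se_e = as.numeric(se_e),
         direction = direction, label = label),
    class = "ll4_curve"
  )
}

#' Coerce to an ll4_curve
#'
#' @param x An `ll4_curve` or a fitted [ll4_fit] object.
#' @param ... Unused.
#' @return An `ll4_curve`.
#' @export
as_ll4_curve <- function(x, ...) UseMethod("as_ll4_curve")

#' @export
as_ll4_curve.ll4_curve <- function(x, ...) x

#' @export
as_ll4_curve.ll4_fit <- function(x, ...) x$curve

#' @export
as_ll4_curve.default <- function(x, ...) {
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a log-logistic curve", call. = FALSE)
}

#' @export
print.ll4_curve <- function(x, digits = 4, ...) {
  cat("Log-logistic concentration-response curve",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  direction:", x$direction, "\n")
  cat(sprintf("  b = %.*g, c = %.*g, d = %.*g, e = %.*g umol/L",
              digits, x$b, digits, x$c, digits, x$d, digits, x$e))
  if (!is.na(x$se_e)) cat(sprintf(" (se %.*g)", digits, x$se_e))
  cat("\n")
  invisible(x)
}

#' Evaluate the log-logistic effect at given concentrations
#'
#' @param x Concentrations in umol/L, non-negative. At `x = 0` the curve
#'   returns its floor `c`.
#' @param crc An [ll4_curve] (or fitted [ll4_fit]).
#' @return Percent effect, same length as `x`; strictly increasing in `x`.
#' @examples
#' ll4_effect(3.9, ll4_curve(b = 1.3, e = 1.95))  # 100 / (1 + 2^-1.3)
#' @export
ll4_effect <- function(x, crc) {
  crc <- as_ll4_curve(crc)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  y <- rep(crc$c, length(x))
  pos <- x > 0
  y[pos] <- crc$c + (crc$d - crc$c) / (1 + (crc$e / x[pos])^crc$b)
  y
}

#' Invert the log-logistic curve
#'
#' Returns the unique concentration producing a given percent effect. The
#' inverse exists only strictly between the floor and the ceiling; outside
#' that open interval concentration addition (and the ECx) is undefined.
#'
#' @param y Percent effect, strictly inside `(c, d)`.
#' @param crc An [ll4_curve] (or fitted [ll4_fit]).
#' @return Concentration in umol/L.
#' @examples
#' ll4_inverse(50, ll4_curve(b = 1.8, e = 3.63))
#' @export
ll4_inverse <- function(y, crc) {
  crc <- as_ll4_curve(crc)
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("effect levels must be finite numbers", call. = FALSE)
  }
  if (any(y <= crc$c) || any(y >= crc$d)) {
    stop(sprintf(
      "effect level outside the open interval (%g, %g); the curve never attains it",
      crc$c, crc$d), call. = FALSE)
  }
  crc$e * ((y - crc$c) / (crc$d - y))^(1 / crc$b)
}

#' Effect concentration (ECx) with confidence interval
#'
#' Computes the concentration provoking `level` percent of the curve's own
#' maximal effect, i.e. the inverse of the curve at
#' `c + level/100 * (d - c)`. The confidence interval follows the assay's
#' reporting rule: estimate +/- `ci_mult` standard errors, with the standard
#' error of the ECx propagated from the standard error of the inflection by
#' the delta method (the inversion is proportional to `e`, so
#' `se(ECx) = se(e) * ECx / e`).
#'
#' @param level Effect level(s) in percent, strictly between 0 and 100.
#'   `level = 50` on a standardized curve returns the inflection `e`.
#' @param crc An [ll4_curve] or fitted [ll4_fit].
#' @param ci_mult Width of the confidence interval in standard errors
#'   (default 2).
#' @return A data.frame with columns `level`, `estimate`, `se`, `ci_low`,
#'   `ci_high` (concentrations in umol/L).
#' @examples
#' estimate_ec(c(25, 50), ll4_curve(b = 1, e = 0.44, se_e = 0.03))
#' @export
estimate_ec <- function(level, crc, ci_mult = 2) {
  crc <- as_ll4_curve(crc)
  if (!is.numeric(level) || any(!is.finite(level)) ||
      any(level <= 0) || any(level >= 100)) {
    stop("'level' must lie strictly between 0 and 100 percent", call. = FALSE)
  }
  y <- crc$c + level / 100 * (crc$d - crc$c)
  x <- ll4_inverse(y, crc)
  se <- if (is.na(crc$se_e)) rep(NA_real_, length(x)) else crc$se_e * x / crc$e
  data.frame(
    level = level,
    estimate = x,
    se = se,
    ci_low = x - ci_mult * se,
    ci_high = x + ci_mult * se
  )
}
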