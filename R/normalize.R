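#' @keywords internal
check_stc_records <- function(records) {
  need <- c("substance", "concentration_um", "embryo_id", "stc_per_min",
            "replicate", "experiment")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("embryo records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("embryo record table is empty", call. = FALSE)
  }
  if (any(!is.finite(records$concentration_um)) ||
      any(records$concentration_um < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(records$stc_per_min)) || any(records$stc_per_min < 0)) {
    stop("STC counts per minute must be finite and non-negative",
         call. = FALSE)
  }
  invisible(records)
}

#' Percent change in STC frequency versus unexposed controls
#'
#' Converts embryo-level STC counts to the mean percent change in coiling
#' frequency relative to the unexposed (zero-concentration) embryos of the
#' same independent experiment. Because the absolute STC frequency varies
#' between experiments, controls are matched within experiment; the resulting
#' per-experiment percent changes are kept as separate rows and pooled later
#' by fitting them jointly.
#'
#' @param records Embryo-level data.frame with columns `substance`,
#'   `concentration_um`, `embryo_id`, `stc_per_min`, `replicate`,
#'   `experiment`. Every experiment must contain zero-concentration controls
#'   for each substance.
#' @return A data.frame with one row per (substance, experiment,
#'   concentration): `substance`, `experiment`, `concentration_um`,
#'   `n_embryos`, `mean_stc`, `percent_change` (signed; positive =
#'   hyperactivity) and `se_percent_change` (standard error of the mean
#'   percent change, from the spread of treated embryos).
#' @examples
#' rec <- data.frame(substance = "x", concentration_um = rep(c(0, 1), each = 3),
#'                   embryo_id = 1:6, stc_per_min = c(6, 6, 6, 9, 9, 9),
#'                   replicate = 1, experiment = 1)
#' percent_change(rec)  # +50 at 1 umol/L
#' @export
percent_change <- function(records) {
  check_stc_records(records)
  out <- do.call(rbind, lapply(
    split(records, records[c("substance", "experiment")], drop = TRUE),
    function(grp) {
      ctrl <- grp$stc_per_min[grp$concentration_um == 0]
      if (length(ctrl) == 0L) {
        stop("no control (concentration 0) embryos for substance '",
             grp$substance[1], "' in experiment '", grp$experiment[1], "'",
             call. = FALSE)
      }
      m0 <- mean(ctrl)
      if (m0 == 0) {
        stop("control mean STC frequency is zero for substance '",
             grp$substance[1], "' in experiment '", grp$experiment[1],
             "'; percent change is undefined", call. = FALSE)
      }
      concs <- sort(unique(grp$concentration_um))
      rows <- lapply(concs, function(cc) {
        v <- grp$stc_per_min[grp$concentration_um == cc]
        data.frame(
          substance = grp$substance[1],
          experiment = grp$experiment[1],
          concentration_um = cc,
          n_embryos = length(v),
          mean_stc = mean(v),
          percent_change = 100 * (mean(v) - m0) / m0,
          se_percent_change = if (length(v) > 1)
            100 * stats::sd(v) / sqrt(length(v)) / m0 else NA_real_)
      })
      do.call(rbind, rows)
    }))
  rownames(out) <- NULL
  out[order(out$substance, out$experiment, out$concentration_um), ,
      drop = FALSE]
}

#' Standardize hyperactivity percent changes to a 100 percent maximum
#'
#' The three hyperactive substances reach different maximal percent increases
#' in coiling frequency, so their raw curves are not comparable for equitoxic
#' mixture design. Dividing each percent change by the substance's maximal
#' percent effect and multiplying by 100 rescales every hyperactivity curve
#' to a common ceiling of 100, so the standardized EC50 equals the raw
#' effect concentration at half the substance's own maximum (e.g. the raw
#' EC41 for a substance with maximum 82).
#'
#' @param percent_changes Numeric vector of signed percent changes.
#' @param max_effect_m The substance's maximal percent effect (> 0), usually
#'   the fitted ceiling of the raw curve ([max_effect_from_fit()]).
#' @return Standardized effect percents (100 * percent_changes / max_effect_m).
#' @examples
#' standardize_hyperactivity(41, 82)  # 50
#' @export
standardize_hyperactivity <- function(percent_changes, max_effect_m) {
  if (!is.numeric(max_effect_m) || length(max_effect_m) != 1L ||
      !is.finite(max_effect_m) || max_effect_m <= 0) {
    stop("'max_effect_m' must be a single positive percent effect",
         call. = FALSE)
  }
  if (!is.numeric(percent_changes) || any(!is.finite(percent_changes))) {
    stop("'percent_changes' must be finite numbers", call. = FALSE)
  }
  100 * percent_changes / max_effect_m
}

#' Standardization divisor from a fitted raw hyperactivity curve
#'
#' Returns the fitted ceiling of a raw hyperactivity curve (fitted with a
#' free maximum) for use as the standardization divisor. The fitted ceiling
#' is used rather than the largest observed mean because observed maxima are
#' single noisy points while the fit borrows strength from the whole curve.
#'
#' @param raw_fit An [ll4_fit] of raw percent-change hyperactivity data with
#'   `fix_ceiling = FALSE`.
#' @return The fitted maximal percent effect.
#' @export
max_effect_from_fit <- function(raw_fit) {
  if (!inherits(raw_fit, "ll4_fit")) {
    stop("'raw_fit' must be a fitted ll4_fit object", call. = FALSE)
  }
  if (raw_fit$fix["ceiling"]) {
    stop("the raw curve must be fitted with a free ceiling ",
         "(fix_ceiling = FALSE) to provide a standardization divisor",
         call. = FALSE)
  }
  if (raw_fit$curve$direction != "hyperactivity") {
    stop("standardization applies to hyperactivity curves only",
         call. = FALSE)
  }
  unname(raw_fit$coefficients["d"])
}

#' Truncate a biphasic hyperactivity series at its peak
#'
#' Hyperactivity is typically followed by a decline at high concentrations
#' (possibly paralysis). For fitting the monotone hyperactivity curve, rows
#' above the concentration of maximal mean response are dropped; the decline
#' is a separate phenomenon handled by the antagonism/biphasic tools.
#'
#' @param pc_table Output of [percent_change()] (or any data.frame with
#'   `concentration_um` and `percent_change`).
#' @return The table restricted to concentrations up to the peak.
#' @export
truncate_at_peak <- function(pc_table) {
  if (!all(c("concentration_um", "percent_change") %in% names(pc_table))) {
    stop("'pc_table' needs columns 'concentration_um' and 'percent_change'",
         call. = FALSE)
  }
  means <- tapply(pc_table$percent_change, pc_table$concentration_um, mean)
  concs <- as.numeric(names(means))
  peak <- concs[which.max(means)]
  pc_table[pc_table$concentration_um <= peak, , drop = FALSE]
}

#' Normalized response table on the direction-specific effect scale
#'
#' Maps signed percent changes onto the increasing 0--100 effect scale used
#' by the fitter: hyperactivity percent changes are divided by the maximal
#' percent effect (standardization); hypoactivity percent changes are negated
#' so a 40 percent decrease maps to effect 40. Hypoactivity changes below
#' -100 percent (impossible: an embryo cannot coil negatively) are clamped to
#' -100 with a warning.
#'
#' @param pc_table Output of [percent_change()].
#' @param direction `"hyperactivity"` or `"hypoactivity"`.
#' @param max_effect_m Standardization divisor, required for hyperactivity
#'   (see [max_effect_from_fit()]); ignored for hypoactivity.
#' @return `pc_table` with an added `effect_percent` column, ready for
#'   [fit_ll4()].
#' @export
normalized_response <- function(pc_table,
                                direction = c("hyperactivity",
                                              "hypoactivity"),
                                max_effect_m = NULL) {
  direction <- match.arg(direction)
  if (!all(c("concentration_um", "percent_change") %in% names(pc_table))) {
    stop("'pc_table' needs columns 'concentration_um' and 'percent_change'",
         call. = FALSE)
  }
  pc <- pc_table$percent_change
  if (direction == "hyperactivity") {
    if (is.null(max_effect_m)) {
      stop("hyperactivity standardization requires 'max_effect_m' ",
           "(the fitted ceiling of the raw curve)", call. = FALSE)
    }
    pc_table$effect_percent <- standardize_hyperactivity(pc, max_effect_m)
  } else {
    if (any(pc < -100)) {
      warning("percent changes below -100 clamped to -100 ",
              "(an embryo cannot coil negatively)", call. = FALSE)
      pc <- pmax(pc, -100)
    }
    pc_table$effect_percent <- -pc
  }
  pc_table
}
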