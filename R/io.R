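#' Read and write embryo-level STC records
#'
#' Tab-separated text with header columns `substance`, `concentration_um`,
#' `embryo_id`, `stc_per_min`, `replicate`, `experiment`. Concentrations are
#' nominal and in umol/L throughout; the column names carry the unit to
#' prevent silent mismatches.
#'
#' @param path File path.
#' @return `read_stc()` returns the validated records data.frame.
#' @export
read_stc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_stc_records(rec)
  rec
}

#' @rdname read_stc
#' @param records Embryo records data.frame.
#' @export
write_stc <- function(records, path) {
  check_stc_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mixture design file
#'
#' Plain-text YAML design specification, e.g.
#' ```
#' label: Hyperactive Mixture A
#' fractions: equitoxic
#' components:
#'   - {name: chlorpyrifos,      ec50_um: 1.95, slope: 1.30, direction: hyperactivity}
#'   - {name: chlorpyrifos-oxon, ec50_um: 0.44, slope: 1,    direction: hyperactivity}
#' ```
#' `fractions: equitoxic` assigns EC50-proportional fractions; otherwise
#' every component must carry a `fraction` field (summing to 1).
#'
#' @param path File path (or a list already parsed from YAML).
#' @return A [mixture_design()].
#' @export
read_design <- function(path) {
  spec <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(spec$components) || length(spec$components) < 2L) {
    stop("design must list at least two components", call. = FALSE)
  }
  curves <- lapply(spec$components, function(cmp) {
    ll4_curve(b = cmp$slope, e = cmp$ec50_um,
              direction = match.arg(cmp$direction,
                                    c("hyperactivity", "hypoactivity")),
              label = cmp$name)
  })
  names(curves) <- vapply(spec$components, `[[`, character(1), "name")
  if (identical(spec$fractions, "equitoxic")) {
    # Equitoxic assignment is per effect direction: opposing-direction
    # designs state the hypo:hyper split explicitly via 'fraction'.
    return(equitoxic_design(curves, label = spec$label))
  }
  fr <- vapply(spec$components, function(cmp) {
    if (is.null(cmp$fraction)) {
      stop("component '", cmp$name, "' has no fraction and 'fractions' is ",
           "not \"equitoxic\"", call. = FALSE)
    }
    as.numeric(cmp$fraction)
  }, numeric(1))
  comps <- Map(mixture_component, names(curves), curves, fr)
  mixture_design(unname(comps), label = spec$label)
}

#' Write a fitted-parameter table
#'
#' One row per fitted curve with columns `substance`, `b`, `c`, `d`, `e`,
#' `se_e`, `ec50`, `ci_low`, `ci_high` (tab-separated).
#'
#' @param fits A list of [ll4_fit] objects.
#' @param path File path.
#' @param ci_mult Confidence-interval width in standard errors (default 2).
#' @export
write_crc_table <- function(fits, path, ci_mult = 2) {
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "ll4_fit"))
    ec <- estimate_ec(50, f, ci_mult)
    data.frame(substance = f$curve$label %||% NA_character_,
               b = f$coefficients[["b"]], c = f$coefficients[["c"]],
               d = f$coefficients[["d"]], e = f$coefficients[["e"]],
               se_e = f$curve$se_e, ec50 = ec$estimate,
               ci_low = ec$ci_low, ci_high = ec$ci_high)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a mixture prediction curve
#'
#' Tab-separated `model`, `concentration_um`, `effect_percent` grid followed
#' by no summary row; the predicted EC50 is reported in the pipeline's
#' comparison table.
#'
#' @param prediction A `mixture_prediction`.
#' @param path File path.
#' @export
write_prediction <- function(prediction, path) {
  stopifnot(inherits(prediction, "mixture_prediction"))
  utils::write.table(as.data.frame(prediction), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
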