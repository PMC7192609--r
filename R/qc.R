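#' Plate-level context for the QC checkpoints
#'
#' Two checkpoints need plate-wide information: the mean and SD of the slow
#' (background hydrolysis) rate constant over all converged double-model
#' wells, and the fitted total amplitude of the lowest calibration point.
#'
#' @param fits list of `exp_fit` objects.
#' @param layout a [plate_layout()].
#' @return A `plate_context` list with `mean_k2obs`, `sd_k2obs` (NA unless
#'   at least two double-model wells converged) and
#'   `lowest_calibration_total_amplitude` (NA without a usable lowest
#'   calibration well).
#' @export
plate_context <- function(fits, layout) {
  k2 <- vapply(fits, function(f)
    if (f$converged && f$model == "double") f$k2obs else NA_real_, 0)
  k2 <- k2[!is.na(k2)]
  mean_k2 <- if (length(k2) >= 2) mean(k2) else NA_real_
  sd_k2 <- if (length(k2) >= 2) stats::sd(k2) else NA_real_

  low_amp <- NA_real_
  cal <- layout[layout$role == "calibration", , drop = FALSE]
  if (nrow(cal) > 0) {
    by_well <- stats::setNames(fits, vapply(fits, `[[`, "", "well_id"))
    for (a in sort(unique(cal$amount_pmol))) {
      ws <- cal$well[cal$amount_pmol == a]
      amps <- vapply(ws, function(w) {
        f <- by_well[[w]]
        if (is.null(f) || !f$converged) return(NA_real_)
        total_amplitude(f)
      }, 0)
      amps <- amps[!is.na(amps)]
      if (length(amps) > 0) { low_amp <- mean(amps); break }
    }
  }
  structure(list(mean_k2obs = mean_k2, sd_k2obs = sd_k2,
                 lowest_calibration_total_amplitude = low_amp),
            class = "plate_context")
}

# fitted total fluorescence change of a curve
total_amplitude <- function(fit) {
  if (fit$model == "double") fit$A1 + fit$A2 else fit$A1
}

qc_explanations <- c(
  INSEPARABLE_PHASES = paste("single-exponential model selected by AICc:",
    "the incorporation and background phases could not be separated"),
  A1_ERROR_EXCEEDS_VALUE =
    "standard error of the fast-phase amplitude A1 exceeds its value",
  K1_WITHIN_K2_RANGE = paste("fast rate k1obs lies within the error range of",
    "the plate average of the slow rates k2obs"),
  K2_TOO_SLOW = "slow rate k2obs below 1e-5 /s",
  A1_NEGATIVE = "fast-phase amplitude non-positive (inverse run)",
  SIGNAL_TOO_SMALL = paste("total fluorescence change under 50% of the",
    "lowest calibration point's"),
  NOT_CONVERGED = "neither exponential model converged; well unanalyzable")

#' Apply the six per-well analysis checkpoints
#'
#' Wells failing any checkpoint are unreliable and are excluded from
#' calibration and quantification:
#' \enumerate{
#'   \item `INSEPARABLE_PHASES` — AICc selected the single model for a well
#'     expected to contain the specific dNTP (blanks are exempt: they are
#'     expected single-exponential).
#'   \item `A1_ERROR_EXCEEDS_VALUE` — se(A1) > A1.
#'   \item `K1_WITHIN_K2_RANGE` — |k1obs − mean(k2obs)| ≤ `sd_multiplier` ×
#'     SD of the plate's k2obs values.
#'   \item `K2_TOO_SLOW` — k2obs strictly below 1e-5 /s.
#'   \item `A1_NEGATIVE` — raw fast amplitude (before phase reordering)
#'     non-positive; with the 0 lower bound on amplitudes an inverse run
#'     pins A1 at 0.
#'   \item `SIGNAL_TOO_SMALL` — fitted total amplitude under half the
#'     lowest calibration point's.
#' }
#' Non-converged wells carry only `NOT_CONVERGED`. Checkpoints whose plate
#' context is missing are skipped and recorded in the `not_evaluated`
#' attribute.
#'
#' @param fit an `exp_fit`.
#' @param ctx a [plate_context()].
#' @param role the well's layout role (`"blank"` exempts checkpoint 1).
#' @param sd_multiplier width of the "error range of the average" in plate
#'   k2obs SDs (default 1).
#' @return A `qc_flags` character vector of failure codes; attributes
#'   `explanations` (named one-liners) and `not_evaluated`. Empty means the
#'   well is usable.
#' @export
apply_checkpoints <- function(fit, ctx, role = "sample", sd_multiplier = 1) {
  flags <- character()
  skipped <- character()
  if (!fit$converged) {
    flags <- "NOT_CONVERGED"
  } else {
    expects_dntp <- !identical(role, "blank")
    if (expects_dntp && fit$model != "double")
      flags <- c(flags, "INSEPARABLE_PHASES")
    if (fit$model == "double") {
      se_a1 <- unname(fit$se["A1"])
      if (is.na(se_a1) || se_a1 > fit$A1)
        flags <- c(flags, "A1_ERROR_EXCEEDS_VALUE")
      if (is.na(ctx$mean_k2obs) || is.na(ctx$sd_k2obs)) {
        skipped <- c(skipped, "K1_WITHIN_K2_RANGE")
      } else if (abs(fit$k1obs - ctx$mean_k2obs) <=
                 sd_multiplier * ctx$sd_k2obs) {
        flags <- c(flags, "K1_WITHIN_K2_RANGE")
      }
      if (fit$k2obs < 1e-5) flags <- c(flags, "K2_TOO_SLOW")
      if (!is.na(fit$A1_raw) && fit$A1_raw <= 0)
        flags <- c(flags, "A1_NEGATIVE")
    }
    if (is.na(ctx$lowest_calibration_total_amplitude)) {
      skipped <- c(skipped, "SIGNAL_TOO_SMALL")
    } else if (total_amplitude(fit) <
               0.5 * ctx$lowest_calibration_total_amplitude) {
      flags <- c(flags, "SIGNAL_TOO_SMALL")
    }
  }
  structure(flags,
            explanations = qc_explanations[flags],
            not_evaluated = skipped,
            class = "qc_flags")
}

#' @export
print.qc_flags <- function(x, ...) {
  if (length(x) == 0) {
    cat("QC: pass\n")
  } else {
    cat("QC failures:\n")
    for (f in unclass(x)) cat(sprintf("  %s: %s\n", f, qc_explanations[[f]]))
  }
  ne <- attr(x, "not_evaluated")
  if (length(ne)) cat("not evaluated:", paste(ne, collapse = ", "), "\n")
  invisible(x)
}
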