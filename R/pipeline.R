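#' Analyze a full plate
#'
#' Runs the complete kinetic quantification pipeline: per-well lag trimming
#' and single/double model fitting with AICc selection, plate-context QC
#' checkpoints, fast-phase amplitude calibration with LOD/LOQ, inverse
#' prediction for the sample wells and normalization to cells/CFU where the
#' sample metadata is complete.
#'
#' @param curves named list of [progress_curve()] (e.g. from
#'   [read_plate_export()] or [synth_plate()]).
#' @param layout a [plate_layout()].
#' @param config a [fit_config()]; set `max_lag_s = 0` to disable lag
#'   trimming.
#' @param calibration_range optional `c(lo, hi)` pmol range for the
#'   calibration fit.
#' @param exclude_wells calibration wells to exclude (refinement loop).
#' @param sd_multiplier passed to [apply_checkpoints()].
#' @return A `plate_analysis` list: `fits`, `qc`, `context`, `calibration`,
#'   `quant`, `layout` and a per-well `wells` data frame (the report
#'   table).
#' @export
analyze_plate <- function(curves, layout, config = fit_config(),
                          calibration_range = NULL, exclude_wells = NULL,
                          sd_multiplier = 1) {
  stopifnot(inherits(layout, "plate_layout"))
  known <- intersect(names(curves), layout$well)
  curves <- curves[known]
  roles <- stats::setNames(layout$role, layout$well)

  fits <- lapply(curves, function(cur) {
    if (roles[[cur$well_id]] == "excluded") return(NULL)
    if (config$max_lag_s > 0) trim_lag(cur, config)$fit
    else select_model(cur, config)
  })
  fits <- Filter(Negate(is.null), fits)

  ctx <- plate_context(fits, layout)
  qc <- lapply(fits, function(f)
    apply_checkpoints(f, ctx, role = roles[[f$well_id]],
                      sd_multiplier = sd_multiplier))

  calib <- tryCatch({
    cb <- build_calibration(fits, layout, qc = qc,
                            range = calibration_range,
                            exclude_wells = exclude_wells)
    estimate_lod_loq(cb)
  }, error = function(e) {
    warning("calibration not built: ", conditionMessage(e))
    NULL
  })

  quant <- list()
  if (!is.null(calib)) {
    for (w in names(fits)) {
      if (roles[[w]] %in% c("sample", "calibration"))
        quant[[w]] <- quantify_well(fits[[w]], calib, qc = qc[[w]])
    }
  }

  wells <- plate_report_table(fits, qc, quant, calib, layout)
  structure(list(fits = fits, qc = qc, context = ctx, calibration = calib,
                 quant = quant, layout = layout, wells = wells),
            class = "plate_analysis")
}

# assemble the per-well report table
plate_report_table <- function(fits, qc, quant, calib, layout) {
  meta <- stats::setNames(split(layout, seq_len(nrow(layout))), layout$well)
  rows <- lapply(layout$well, function(w) {
    f <- fits[[w]]
    m <- meta[[w]]
    row <- data.frame(
      well = w, role = m$role, sample_id = m$sample_id,
      model = NA_character_, converged = NA,
      A1 = NA_real_, se_A1 = NA_real_, k1obs = NA_real_, se_k1obs = NA_real_,
      A2 = NA_real_, se_A2 = NA_real_, k2obs = NA_real_, se_k2obs = NA_real_,
      F0 = NA_real_, se_F0 = NA_real_,
      RSS = NA_real_, aicc_single = NA_real_, aicc_double = NA_real_,
      trim_offset_s = NA_real_, qc_flags = "", qc_explanation = "",
      pmol_in_reaction = NA_real_, range_flag = NA_character_,
      normalized_amount = NA_real_, stringsAsFactors = FALSE)
    if (is.null(f)) return(row)
    row$model <- f$model
    row$converged <- f$converged
    if (f$converged) {
      row$A1 <- f$A1; row$se_A1 <- unname(f$se["A1"])
      row$k1obs <- f$k1obs; row$se_k1obs <- unname(f$se["k1"])
      if (f$model == "double") {
        row$A2 <- f$A2; row$se_A2 <- unname(f$se["A2"])
        row$k2obs <- f$k2obs; row$se_k2obs <- unname(f$se["k2"])
      }
      row$F0 <- f$F0; row$se_F0 <- unname(f$se["F0"])
      row$RSS <- f$RSS
    }
    row$aicc_single <- f$aicc_single
    row$aicc_double <- f$aicc_double
    row$trim_offset_s <- f$trim_offset_s
    fl <- qc[[w]]
    if (!is.null(fl) && length(fl) > 0) {
      row$qc_flags <- paste(unclass(fl), collapse = "+")
      row$qc_explanation <- paste(attr(fl, "explanations"), collapse = "; ")
    }
    q <- quant[[w]]
    if (!is.null(q)) {
      row$pmol_in_reaction <- q$pmol_in_reaction
      row$range_flag <- q$flag
      complete <- !anyNA(c(m$extract_volume_ul, m$assayed_volume_ul,
                           m$cells_extracted)) && !is.na(m$basis) &&
        !is.na(q$pmol_in_reaction)
      if (complete)
        row$normalized_amount <- normalize_amount(
          q$pmol_in_reaction, m$dilution_factor, m$extract_volume_ul,
          m$assayed_volume_ul, m$cells_extracted, m$basis)
    }
    row
  })
  do.call(rbind, rows)
}

#' @export
print.plate_analysis <- function(x, ...) {
  n_fit <- sum(vapply(x$fits, `[[`, TRUE, "converged"))
  n_fail <- sum(vapply(x$qc, length, 0L) > 0)
  cat(sprintf("Plate analysis: %d wells, %d converged fits, %d QC failures\n",
              nrow(x$layout), n_fit, n_fail))
  if (!is.null(x$calibration)) print(x$calibration)
  q <- x$wells[!is.na(x$wells$pmol_in_reaction) & x$wells$role == "sample", ]
  if (nrow(q) > 0) {
    cat("Sample quantities (pmol in reaction):\n")
    print(q[, c("well", "sample_id", "pmol_in_reaction", "range_flag",
                "normalized_amount")], row.names = FALSE)
  }
  invisible(x)
}
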