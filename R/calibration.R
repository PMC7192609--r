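#' Build the fast-phase amplitude calibration
#'
#' The fast-phase amplitude A1 of the double-exponential fit is directly
#' proportional to the amount of specific dNTP in the reaction; an ordinary
#' least-squares line through (amount, A1) of the QC-passing calibration
#' wells gives the quantification model. Blanks, QC-flagged wells and
#' low-concentration wells where the double fit failed are excluded; the
#' latter are recorded as points under the detection limit. Outlier points
#' may be excluded by well id and the fit repeated (refinement loop).
#'
#' @param fits list of `exp_fit` objects.
#' @param layout a [plate_layout()].
#' @param qc named list of `qc_flags` per well (from [apply_checkpoints()]);
#'   if `NULL` all converged double fits are taken as passing.
#' @param range optional `c(lo, hi)` in pmol restricting the fitted range;
#'   default is all usable points.
#' @param exclude_wells wells to drop from the fit (user refinement).
#' @return A `calibration_model`: `slope` (fluorescence units / pmol),
#'   `intercept`, `r_squared`, `fitted_range`, a `points` data frame
#'   (`well`, `amount_pmol`, `A1`, `included`, `reason`), and `lod_pmol` /
#'   `loq_pmol` (NA until [estimate_lod_loq()] is applied).
#' @export
build_calibration <- function(fits, layout, qc = NULL, range = NULL,
                              exclude_wells = NULL) {
  cal <- layout[layout$role == "calibration", , drop = FALSE]
  if (nrow(cal) == 0) stop("layout contains no calibration wells")
  by_well <- stats::setNames(fits, vapply(fits, `[[`, "", "well_id"))
  pts <- do.call(rbind, lapply(seq_len(nrow(cal)), function(i) {
    w <- cal$well[i]
    f <- by_well[[w]]
    a1 <- NA_real_
    included <- FALSE
    reason <- ""
    if (is.null(f)) {
      reason <- "no curve for well"
    } else if (!f$converged || f$model != "double") {
      reason <- "under detection limit (double fit failed)"
    } else {
      a1 <- f$A1
      fl <- if (!is.null(qc)) qc[[w]] else character()
      if (length(fl) > 0) {
        reason <- paste("QC:", paste(unclass(fl), collapse = "+"))
      } else if (w %in% exclude_wells) {
        reason <- "excluded by user"
      } else if (!is.null(range) &&
                 (cal$amount_pmol[i] < range[1] ||
                  cal$amount_pmol[i] > range[2])) {
        reason <- "outside requested range"
      } else {
        included <- TRUE
      }
    }
    data.frame(well = w, amount_pmol = cal$amount_pmol[i], A1 = a1,
               included = included, reason = reason, stringsAsFactors = FALSE)
  }))
  use <- pts[pts$included, , drop = FALSE]
  if (nrow(use) < 2 || length(unique(use$amount_pmol)) < 2)
    stop("need at least 2 usable calibration points at 2 distinct amounts")
  ols <- stats::lm(A1 ~ amount_pmol, data = use)
  co <- stats::coef(ols)
  # exact synthetic data triggers the harmless perfect-fit warning
  r2 <- suppressWarnings(summary(ols)$r.squared)
  structure(list(
    dntp_species = attr(layout, "dntp_species"),
    slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2,
    fitted_range = range(use$amount_pmol), points = pts,
    lod_pmol = NA_real_, loq_pmol = NA_real_),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Calibration (%s): A1 = %.4g * pmol + %.4g, R^2 = %.4f\n",
    if (is.na(x$dntp_species)) "dNTP" else x$dntp_species,
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  range [%g, %g] pmol, %d/%d points included\n",
              x$fitted_range[1], x$fitted_range[2],
              sum(x$points$included), nrow(x$points)))
  if (!is.na(x$lod_pmol))
    cat(sprintf("  LOD = %.4g pmol, LOQ = %.4g pmol\n",
                x$lod_pmol, x$loq_pmol))
  invisible(x)
}

#' Estimate limits of detection and quantification
#'
#' Two methods are combined. Method A: the lowest calibration amount whose
#' replicates all fitted and passed QC (the lowest resolvable point).
#' Method B: 3×SD of the fast-phase amplitude replicates at that lowest
#' amount, expressed on the amount axis by dividing by the calibration
#' slope (5×SD for the LOQ). The reported LOD is the larger of the two —
#' when the mathematical value falls below the lowest resolvable
#' calibration point, the lowest point is the LOD; likewise for the LOQ.
#'
#' @param calib a `calibration_model`.
#' @param low_point_A1_replicates optional numeric vector of A1 replicates
#'   at the lowest included amount; defaults to the replicates in
#'   `calib$points`.
#' @return `calib` with `lod_pmol` and `loq_pmol` filled in (always
#'   `lod_pmol <= loq_pmol`).
#' @export
estimate_lod_loq <- function(calib, low_point_A1_replicates = NULL) {
  use <- calib$points[calib$points$included, , drop = FALSE]
  lowest <- min(use$amount_pmol)
  reps <- low_point_A1_replicates %||%
    use$A1[use$amount_pmol == lowest]
  if (length(reps) < 2) {
    warning("fewer than 2 replicates at the lowest calibration amount; ",
            "SD-based method skipped, reporting the lowest fittable point")
    lod_b <- loq_b <- 0
  } else {
    sdl <- stats::sd(reps)
    lod_b <- 3 * sdl / calib$slope
    loq_b <- 5 * sdl / calib$slope
  }
  calib$lod_pmol <- max(lod_b, lowest)
  calib$loq_pmol <- max(loq_b, lowest)
  calib
}

#' Quantify one well against a calibration
#'
#' Inverts the calibration line: `pmol = (A1 − intercept) / slope`. QC-failed
#' wells yield no quantity and carry the failure explanation instead.
#'
#' @param fit an `exp_fit` for the well.
#' @param calib a `calibration_model` (ideally with LOD/LOQ populated).
#' @param qc optional `qc_flags` for the well.
#' @return A `quant_result` list: `well_id`, `pmol_in_reaction`, `flag`
#'   (`"BELOW_LOD"`, `"BELOW_LOQ"`, `"ABOVE_RANGE"` or `"OK"`),
#'   `failure` (QC explanation, if any).
#' @export
quantify_well <- function(fit, calib, qc = NULL) {
  if (!is.null(qc) && length(qc) > 0) {
    return(structure(list(well_id = fit$well_id,
                          pmol_in_reaction = NA_real_, flag = "QC_FAILED",
                          failure = paste(unclass(qc), collapse = "+")),
                     class = "quant_result"))
  }
  if (!fit$converged || fit$model != "double")
    return(structure(list(well_id = fit$well_id,
                          pmol_in_reaction = NA_real_, flag = "QC_FAILED",
                          failure = "no usable double-exponential fit"),
                     class = "quant_result"))
  if (calib$slope <= 0) stop("calibration slope must be positive")
  pmol <- (fit$A1 - calib$intercept) / calib$slope
  flag <- "OK"
  if (!is.na(calib$lod_pmol) && pmol < calib$lod_pmol) {
    flag <- "BELOW_LOD"
  } else if (!is.na(calib$loq_pmol) && pmol < calib$loq_pmol) {
    flag <- "BELOW_LOQ"
  } else if (pmol > calib$fitted_range[2]) {
    flag <- "ABOVE_RANGE"
  }
  structure(list(well_id = fit$well_id, pmol_in_reaction = pmol,
                 flag = flag, failure = NA_character_),
            class = "quant_result")
}

#' Normalize a reaction amount to cells or CFU
#'
#' Scales the in-reaction amount back through the dilution and the
#' extract/assayed volume ratio to the whole extract, then to the
#' normalization basis: pmol per 1e6 cells (human samples) or per 1e8 CFU
#' (bacterial samples).
#'
#' @param pmol_in_reaction quantified amount in the assayed reaction.
#' @param dilution_factor fold dilution applied to the extract (>= 1).
#' @param extract_volume_ul total extract volume.
#' @param assayed_volume_ul volume of (diluted) extract assayed per well.
#' @param cells_extracted number of cells (or CFU) the extract came from.
#' @param basis `"per_1e6_cells"` or `"per_1e8_cfu"`.
#' @return Normalized amount (pmol per basis count).
#' @export
normalize_amount <- function(pmol_in_reaction, dilution_factor = 1,
                             extract_volume_ul, assayed_volume_ul,
                             cells_extracted,
                             basis = c("per_1e6_cells", "per_1e8_cfu")) {
  basis <- match.arg(basis)
  if (any(c(extract_volume_ul, assayed_volume_ul, cells_extracted) <= 0))
    stop("volumes and cell counts must be positive")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  basis_count <- if (basis == "per_1e6_cells") 1e6 else 1e8
  total <- pmol_in_reaction * dilution_factor *
    (extract_volume_ul / assayed_volume_ul)
  total * basis_count / cells_extracted
}

#' Assay-performance statistics
#'
#' Coefficients of variation use the sample SD: intra-assay CV is
#' 100·SD/mean over technical replicates within a plate (averaged over
#' plates/levels when several are given), inter-assay CV the same over
#' plate means. Accuracy is 100·mean(measured/nominal) at the lowest and
#' highest calibration amounts. Recovery uses standard addition:
#' 100·(measured_spiked − measured_unspiked)/amount_added.
#'
#' @param measured numeric vector of measured amounts (pmol).
#' @param nominal nominal amounts, parallel to `measured`.
#' @param plate plate identifier, parallel to `measured` (defaults to one
#'   plate).
#' @param spiked,unspiked,added optional vectors for standard-addition
#'   recovery.
#' @return List with `intra_cv`, `inter_cv`, `accuracy_low`,
#'   `accuracy_high` (all percent) and `recovery` (percent, `NA` without
#'   spike data).
#' @export
assay_statistics <- function(measured, nominal, plate = NULL,
                             spiked = NULL, unspiked = NULL, added = NULL) {
  stopifnot(length(measured) == length(nominal))
  plate <- plate %||% rep(1L, length(measured))
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  key <- interaction(plate, nominal, drop = TRUE)
  sizes <- table(key)
  if (any(sizes < 2))
    stop("intra-assay CV needs >= 2 replicates per plate and amount")
  intra <- mean(tapply(measured, key, cv))
  inter <- NA_real_
  if (length(unique(plate)) >= 2) {
    plate_means <- tapply(measured, interaction(plate, nominal, drop = TRUE),
                          mean)
    lev <- sub("^[^.]*\\.", "", names(plate_means))
    inter <- mean(tapply(plate_means, lev, cv))
  }
  lo <- min(nominal)
  hi <- max(nominal)
  acc <- function(a) 100 * mean(measured[nominal == a] / a)
  recovery <- NA_real_
  if (!is.null(spiked)) {
    stopifnot(length(spiked) == length(unspiked),
              length(spiked) == length(added))
    recovery <- mean(100 * (spiked - unspiked) / added)
  }
  list(intra_cv = intra, inter_cv = inter,
       accuracy_low = acc(lo), accuracy_high = acc(hi),
       recovery = recovery)
}

#' Serialize / restore a calibration model
#'
#' Models round-trip through a plain YAML mapping (scalars plus the points
#' table) so a plate's calibration can be saved and reused.
#'
#' @param calib a `calibration_model`.
#' @param path file path (.yml/.yaml or .json).
#' @export
write_calibration <- function(calib, path) {
  obj <- list(dntp_species = calib$dntp_species, slope = calib$slope,
              intercept = calib$intercept, r_squared = calib$r_squared,
              fitted_range = calib$fitted_range,
              lod_pmol = calib$lod_pmol, loq_pmol = calib$loq_pmol,
              points = lapply(seq_len(nrow(calib$points)), function(i)
                as.list(calib$points[i, ])))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  pts <- do.call(rbind, lapply(obj$points, function(p)
    data.frame(well = p$well, amount_pmol = p$amount_pmol,
               A1 = p$A1 %||% NA_real_, included = isTRUE(p$included),
               reason = p$reason %||% "", stringsAsFactors = FALSE)))
  structure(list(dntp_species = obj$dntp_species %||% NA_character_,
                 slope = obj$slope, intercept = obj$intercept,
                 r_squared = obj$r_squared,
                 fitted_range = unlist(obj$fitted_range),
                 points = pts,
                 lod_pmol = obj$lod_pmol %||% NA_real_,
                 loq_pmol = obj$loq_pmol %||% NA_real_),
            class = "calibration_model")
}
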