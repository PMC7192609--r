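#' A single well's fluorescence progress curve
#'
#' Holds one time-ordered fluorescence record from a single-cycle (no
#' amplification) polymerase reaction. Fluorescence units are arbitrary and
#' never rescaled on input; the calibration absorbs the scale.
#'
#' @param well_id plate coordinate, "A1".."H12".
#' @param times_s numeric, strictly increasing times in seconds.
#' @param fluorescence numeric, same length as `times_s`, no missing values.
#' @param meta optional named list of free-form metadata.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(well_id, times_s, fluorescence, meta = list()) {
  well_id <- as.character(well_id)
  if (!grepl("^[A-H](1[0-2]|[1-9])$", well_id))
    stop("well_id must be a plate coordinate A1..H12, got '", well_id, "'")
  times_s <- as.numeric(times_s)
  fluorescence <- as.numeric(fluorescence)
  if (length(times_s) != length(fluorescence))
    stop("times_s and fluorescence must have equal length")
  if (length(times_s) < 8L)
    stop("a progress curve needs at least 8 points (well ", well_id, ")")
  if (anyNA(times_s) || anyNA(fluorescence))
    stop("missing values in progress curve for well ", well_id)
  if (any(diff(times_s) <= 0))
    stop("times must be strictly increasing (well ", well_id, ")")
  structure(list(well_id = well_id, times_s = times_s,
                 fluorescence = fluorescence, meta = meta),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("Progress curve %s: %d points, t = [%g, %g] s, F = [%g, %g]\n",
              x$well_id, length(x$times_s), min(x$times_s), max(x$times_s),
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' @export
as.data.frame.progress_curve <- function(x, ...) {
  data.frame(well = x$well_id, time_s = x$times_s,
             fluorescence = x$fluorescence, stringsAsFactors = FALSE)
}

# all 96 coordinates in row-major order (A1, A2, ..., H12)
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}
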