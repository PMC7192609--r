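#' Acquisition schedule for a single-cycle fluorescence run
#'
#' Real-time PCR instruments record one fluorescence read per cycle. A
#' schedule is a list of segments, each repeating a fixed cycle length; a
#' "split time" schedule uses short early cycles to resolve the fast
#' incorporation phase and long late cycles for the slow background phase.
#'
#' @param cycles integer vector, number of cycles per segment (all > 0).
#' @param cycle_length_s numeric vector, seconds per cycle in each segment
#'   (all > 0); recycled against `cycles` must match in length.
#' @return An object of class `acquisition_schedule`.
#' @examples
#' acquisition_schedule(4, 17)                 # 4 reads, 17 s apart
#' acquisition_schedule(c(100, 200), c(13, 80)) # split-time schedule
#' @export
acquisition_schedule <- function(cycles, cycle_length_s) {
  if (length(cycles) != length(cycle_length_s))
    stop("'cycles' and 'cycle_length_s' must have equal length")
  if (length(cycles) < 1L)
    stop("schedule needs at least one segment")
  cycles <- as.integer(cycles)
  if (any(is.na(cycles)) || any(cycles <= 0L))
    stop("cycle counts must be positive integers")
  if (any(!is.finite(cycle_length_s)) || any(cycle_length_s <= 0))
    stop("cycle lengths must be positive seconds")
  structure(list(cycles = cycles, cycle_length_s = as.numeric(cycle_length_s)),
            class = "acquisition_schedule")
}

#' Expand a schedule to absolute acquisition times
#'
#' The first recorded point is assigned t = 0; the n-th point sits at the
#' cumulative acquisition time of the preceding cycles. Any constant offset
#' in the instrument's true timestamp origin is absorbed by the fitted
#' amplitudes and plateau and does not affect the fast-phase amplitude.
#'
#' @param schedule an [acquisition_schedule()].
#' @return Numeric vector of strictly increasing times in seconds, one per
#'   recorded cycle.
#' @examples
#' expand_schedule(acquisition_schedule(4, 17))  # 0 17 34 51
#' @export
expand_schedule <- function(schedule) {
  if (!inherits(schedule, "acquisition_schedule"))
    schedule <- do.call(acquisition_schedule, as.list(schedule))
  steps <- rep(schedule$cycle_length_s, schedule$cycles)
  cumsum(c(0, steps[-length(steps)]))
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat("Acquisition schedule:",
      paste(sprintf("%d x %gs", x$cycles, x$cycle_length_s), collapse = ", "),
      sprintf("(%d cycles, %gs total)\n", sum(x$cycles),
              sum(x$cycles * x$cycle_length_s)))
  invisible(x)
}

# Parse "100x13,200x80" (CLI/config shorthand) into a schedule.
#' @rdname acquisition_schedule
#' @param text schedule given as `"<cycles>x<seconds>[,...]"`.
#' @export
parse_schedule <- function(text) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  mat <- vapply(parts, function(p) {
    kv <- as.numeric(strsplit(p, "x", fixed = TRUE)[[1]])
    if (length(kv) != 2 || anyNA(kv)) stop("cannot parse schedule segment: ", p)
    kv
  }, numeric(2))
  acquisition_schedule(mat[1, ], mat[2, ])
}
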