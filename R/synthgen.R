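#' Generate one synthetic progress curve
#'
#' Forward-evaluates the single- or double-exponential model on an
#' acquisition schedule, optionally prepends a lag (fluorescence held at
#' F(0) for `lag_s` seconds, i.e. the curve is time-shifted) and adds
#' independent Gaussian read noise.
#'
#' @param params named list with `F0`, `A1`, `k1` and optionally `A2`,
#'   `k2` (their presence selects the double model).
#' @param schedule an [acquisition_schedule()].
#' @param noise_sd additive Gaussian noise SD in fluorescence units (>= 0).
#' @param lag_s lag duration in seconds.
#' @param seed optional integer seed (omit to draw from the current RNG
#'   stream).
#' @param well_id plate coordinate for the curve.
#' @return A [progress_curve()]; its `meta` records the generating
#'   parameters.
#' @export
synth_curve <- function(params, schedule, noise_sd = 0, lag_s = 0,
                        seed = NULL, well_id = "A1") {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (lag_s < 0) stop("lag_s must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  t <- expand_schedule(schedule)
  model <- if (!is.null(params$A2)) "double" else "single"
  f <- eval_model(params, pmax(0, t - lag_s), model)
  if (noise_sd > 0) f <- f + stats::rnorm(length(t), 0, noise_sd)
  progress_curve(well_id, t, f,
                 meta = c(params, list(model = model, noise_sd = noise_sd,
                                       lag_s = lag_s)))
}

#' Specification of a synthetic 96-well plate
#'
#' Defaults emulate a dGTP-style run: blank kinetics and plateau magnitudes
#' as seen for background probe hydrolysis (amplitude ~29 000 fluorescence
#' units, rate ~2e-4 /s), a calibration slope of ~1000 units/pmol, the
#' split-time acquisition schedule (100 cycles of 13 s then 200 of 80 s)
#' and 2% read noise. An optional competition law replaces the linear
#' calibration law with the quadratic binding model for the fast-phase
#' share, reproducing amplitude competition between incorporation and
#' background hydrolysis.
#'
#' @param calibration_amounts pmol levels of the calibration series.
#' @param replicates technical replicates per calibration level.
#' @param calibration_law list(slope, intercept): amount -> A1.
#' @param competition optional list(`A_quad`, `F0`, `E_T`, `K_app`):
#'   amount -> relA1 via [eval_quadratic_binding()]; overrides
#'   `calibration_law`.
#' @param samples data frame of sample wells: `sample_id`, `true_pmol`,
#'   optional `matrix_factor` (in (0, 1]; scales both rate constants,
#'   emulating kinetic inhibition by the sample matrix), optional
#'   normalization metadata columns (`dilution_factor`,
#'   `extract_volume_ul`, `assayed_volume_ul`, `cells_extracted`, `basis`).
#' @param n_blanks number of blank wells (single-exponential).
#' @param A_total total fluorescence change of dNTP-containing wells.
#' @param F0 plateau fluorescence.
#' @param k1,k2 fast/slow rate constants (s^-1) of dNTP-containing wells.
#' @param blank list(`A`, `k`, `F0`) kinetics of blank wells.
#' @param noise_frac Gaussian noise SD as a fraction of the total
#'   amplitude (`noise_sd` overrides with absolute units).
#' @param noise_sd absolute noise SD in fluorescence units, or NULL.
#' @param lag_s lag duration applied to every well (seconds).
#' @param schedule acquisition schedule.
#' @param seed integer seed; all plate randomness derives from it.
#' @param dntp_species annotated species.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(calibration_amounts = c(0.5, 1, 2, 4, 6, 8),
                       replicates = 2L,
                       calibration_law = list(slope = 1056, intercept = 0),
                       competition = NULL,
                       samples = NULL,
                       n_blanks = 2L,
                       A_total = 29878, F0 = 35540,
                       k1 = 2.5e-3, k2 = 1.1e-4,
                       blank = list(A = 28869, k = 2e-4, F0 = 35978),
                       noise_frac = 0.02, noise_sd = NULL,
                       lag_s = 0,
                       schedule = acquisition_schedule(c(100, 200), c(13, 80)),
                       seed = 1L,
                       dntp_species = "dGTP") {
  if (any(calibration_amounts < 0)) stop("amounts must be nonnegative")
  if (noise_frac < 0 || (!is.null(noise_sd) && noise_sd < 0))
    stop("noise SD must be nonnegative")
  if (!is.null(samples) && "matrix_factor" %in% names(samples) &&
      any(samples$matrix_factor <= 0 | samples$matrix_factor > 1))
    stop("matrix_factor must be in (0, 1]")
  structure(list(calibration_amounts = calibration_amounts,
                 replicates = as.integer(replicates),
                 calibration_law = calibration_law,
                 competition = competition, samples = samples,
                 n_blanks = as.integer(n_blanks),
                 A_total = A_total, F0 = F0, k1 = k1, k2 = k2,
                 blank = blank, noise_frac = noise_frac, noise_sd = noise_sd,
                 lag_s = lag_s, schedule = schedule, seed = as.integer(seed),
                 dntp_species = dntp_species),
            class = "plate_spec")
}

# fast-phase amplitude implied by the spec's law at a given amount
spec_A1 <- function(spec, amount) {
  if (!is.null(spec$competition)) {
    rel <- eval_quadratic_binding(spec$competition, amount)
    rel * spec$A_total
  } else {
    spec$calibration_law$slope * amount + spec$calibration_law$intercept
  }
}

#' Generate a synthetic plate with known ground truth
#'
#' Lays out blanks, the calibration series and sample wells on a 96-well
#' plate, draws every curve from the spec's kinetic laws plus noise, and
#' records every generating parameter in a truth table. The matrix factor
#' of a sample well scales both rate constants but leaves the amplitudes
#' untouched: amplitude-based quantification is insensitive to matrix
#' inhibition of the kinetics.
#'
#' @param spec a [plate_spec()].
#' @return List with `curves` (named list of [progress_curve()]),
#'   `layout` (a [plate_layout()]) and `truth` (data frame of generating
#'   parameters per well).
#' @export
synth_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  set.seed(spec$seed)
  wells <- plate_wells()
  n_cal <- length(spec$calibration_amounts) * spec$replicates
  n_smp <- if (is.null(spec$samples)) 0L else nrow(spec$samples)
  n_tot <- spec$n_blanks + n_cal + n_smp
  if (n_tot > length(wells))
    stop("spec asks for ", n_tot, " wells; a plate has 96")

  noise_abs <- spec$noise_sd %||% (spec$noise_frac * spec$A_total)
  truth <- list()
  layout_rows <- list()
  curves <- list()
  wi <- 0L
  add_well <- function(role, params, model, amount = NA_real_,
                       sample_id = NA_character_, matrix_factor = NA_real_,
                       meta = NULL) {
    wi <<- wi + 1L
    w <- wells[wi]
    cur <- synth_curve(params, spec$schedule, noise_sd = noise_abs,
                       lag_s = spec$lag_s, well_id = w)
    curves[[w]] <<- cur
    truth[[w]] <<- data.frame(
      well = w, role = role, amount_pmol = amount, sample_id = sample_id,
      model = model, A1 = params$A1, k1 = params$k1,
      A2 = params$A2 %||% NA_real_, k2 = params$k2 %||% NA_real_,
      F0 = params$F0, lag_s = spec$lag_s, matrix_factor = matrix_factor,
      noise_sd = noise_abs, stringsAsFactors = FALSE)
    layout_rows[[w]] <<- data.frame(
      well = w, role = role, amount_pmol = amount, sample_id = sample_id,
      dilution_factor = meta$dilution_factor %||% 1,
      extract_volume_ul = meta$extract_volume_ul %||% NA_real_,
      assayed_volume_ul = meta$assayed_volume_ul %||% NA_real_,
      cells_extracted = meta$cells_extracted %||% NA_real_,
      basis = meta$basis %||% NA_character_, stringsAsFactors = FALSE)
  }

  for (i in seq_len(spec$n_blanks))
    add_well("blank",
             list(A1 = spec$blank$A, k1 = spec$blank$k, F0 = spec$blank$F0),
             "single", amount = 0)

  for (a in spec$calibration_amounts) {
    for (r in seq_len(spec$replicates)) {
      A1 <- spec_A1(spec, a)
      if (A1 <= 0 || A1 >= spec$A_total)
        stop("calibration law puts A1 outside (0, A_total) at ", a, " pmol")
      add_well("calibration",
               list(A1 = A1, k1 = spec$k1, A2 = spec$A_total - A1,
                    k2 = spec$k2, F0 = spec$F0),
               "double", amount = a)
    }
  }

  if (n_smp > 0) {
    for (i in seq_len(n_smp)) {
      s <- spec$samples[i, , drop = FALSE]
      mf <- if ("matrix_factor" %in% names(s)) s$matrix_factor else 1
      A1 <- spec_A1(spec, s$true_pmol)
      if (A1 <= 0 || A1 >= spec$A_total)
        stop("sample amount ", s$true_pmol, " pmol maps outside (0, A_total)")
      add_well("sample",
               list(A1 = A1, k1 = spec$k1 * mf, A2 = spec$A_total - A1,
                    k2 = spec$k2 * mf, F0 = spec$F0),
               "double", amount = s$true_pmol, sample_id = s$sample_id,
               matrix_factor = mf, meta = as.list(s))
    }
  }

  layout <- plate_layout(do.call(rbind, layout_rows),
                         dntp_species = spec$dntp_species)
  # quantification inputs must not leak the truth
  layout$amount_pmol[layout$role == "sample"] <- NA_real_
  list(curves = curves, layout = layout,
       truth = do.call(rbind, truth))
}
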