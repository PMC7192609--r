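fake_cal_fit <- function(well, A1) {
  se <- c(A1 = 0.01 * A1, k1 = 1e-4, A2 = 100, k2 = 1e-5, F0 = 50)
  dntpquant:::new_exp_fit(well, "double", TRUE, A1 = A1, k1obs = 2.5e-3,
                          A2 = 25000 - A1, k2obs = 1.1e-4, F0 = 35000,
                          A1_raw = A1, se = se, RSS = 1, N = 100,
                          k_params = 5, aicc = 0)
}
linear_plate <- function(amounts = 1:8, slope = 1000, intercept = 50) {
  wells <- plate_wells()[seq_along(amounts)]
  fits <- Map(fake_cal_fit, wells, slope * amounts + intercept)
  layout <- plate_layout(data.frame(well = wells, role = "calibration",
                                    amount_pmol = amounts))
  list(fits = fits, layout = layout, wells = wells)
}

test_that("exact linear amplitudes give back slope, intercept and R^2 = 1", {
  lp <- linear_plate()
  cal <- build_calibration(lp$fits, lp$layout)
  expect_equal(cal$slope, 1000)
  expect_equal(cal$intercept, 50)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$fitted_range, c(1, 8))
})

test_that("QC-flagged wells drop out of the fit with their reason recorded", {
  lp <- linear_plate()
  qc <- stats::setNames(rep(list(structure(character(), class = "qc_flags")),
                            8), lp$wells)
  qc[[lp$wells[4]]] <- structure("K2_TOO_SLOW", class = "qc_flags")
  cal <- build_calibration(lp$fits, lp$layout, qc = qc)
  pt <- cal$points
  expect_false(pt$included[pt$well == lp$wells[4]])
  expect_match(pt$reason[pt$well == lp$wells[4]], "QC")
  expect_equal(sum(pt$included), 7)
  expect_equal(cal$slope, 1000)  # exact data: dropping a point changes nothing
})

test_that("noisy duplicate calibration recovers the slope within 5%", {
  set.seed(23)
  amounts <- rep(1:8, each = 2)
  wells <- plate_wells()[seq_along(amounts)]
  a1 <- 1000 * amounts + 50
  a1 <- a1 * (1 + rnorm(length(a1), 0, 0.02))
  fits <- Map(fake_cal_fit, wells, a1)
  layout <- plate_layout(data.frame(well = wells, role = "calibration",
                                    amount_pmol = amounts))
  cal <- build_calibration(fits, layout)
  expect_lt(abs(cal$slope - 1000) / 1000, 0.05)
})

test_that("calibration needs two distinct usable amounts", {
  lp <- linear_plate(amounts = c(2, 2, 2))
  expect_error(build_calibration(lp$fits, lp$layout), "distinct")
})

test_that("LOD/LOQ combine the SD criterion with the lowest fittable point", {
  # zero replicate scatter: the footnote rule leaves the lowest point
  lp <- linear_plate(amounts = rep(c(1, 2, 4, 8), each = 2))
  cal <- build_calibration(lp$fits, lp$layout)
  cal <- estimate_lod_loq(cal)
  expect_equal(cal$lod_pmol, 1)
  expect_equal(cal$loq_pmol, 1)
  # slope 1000, low-point SD 100 -> 0.3 / 0.5 pmol on the amount axis
  lp2 <- linear_plate(amounts = rep(c(0.2, 2, 4, 8), each = 2))
  cal2 <- build_calibration(lp2$fits, lp2$layout)
  cal2 <- estimate_lod_loq(cal2, low_point_A1_replicates =
                             c(250 - 100 / sqrt(2), 250 + 100 / sqrt(2)))
  expect_equal(cal2$lod_pmol, 0.3)
  expect_equal(cal2$loq_pmol, 0.5)
  expect_lte(cal2$lod_pmol, cal2$loq_pmol)
})

test_that("LOD is monotone in the low-point scatter and never above LOQ", {
  lp <- linear_plate(amounts = rep(c(0.1, 2, 4, 8), each = 2))
  cal <- build_calibration(lp$fits, lp$layout)
  prev <- 0
  for (sdv in c(0, 50, 100, 400, 1000)) {
    reps <- c(100 - sdv / sqrt(2), 100 + sdv / sqrt(2))
    c2 <- estimate_lod_loq(cal, low_point_A1_replicates = reps)
    expect_gte(c2$lod_pmol, prev)
    expect_lte(c2$lod_pmol, c2$loq_pmol)
    prev <- c2$lod_pmol
  }
})

test_that("quantification inverts the calibration and flags range issues", {
  lp <- linear_plate()
  cal <- estimate_lod_loq(build_calibration(lp$fits, lp$layout))
  # A1 = intercept -> 0 pmol, below detection
  q0 <- quantify_well(fake_cal_fit("H1", 50), cal)
  expect_equal(q0$pmol_in_reaction, 0)
  expect_identical(q0$flag, "BELOW_LOD")
  # calibration well re-quantified against its own calibration
  q3 <- quantify_well(lp$fits[[3]], cal)
  expect_equal(q3$pmol_in_reaction, 3, tolerance = 1e-6)
  expect_identical(q3$flag, "OK")
  # above the top of the fitted range
  qh <- quantify_well(fake_cal_fit("H2", 1000 * 12 + 50), cal)
  expect_identical(qh$flag, "ABOVE_RANGE")
  # QC-failed wells yield no quantity, only the explanation
  qf <- quantify_well(lp$fits[[1]], cal,
                      qc = structure("K2_TOO_SLOW", class = "qc_flags"))
  expect_true(is.na(qf$pmol_in_reaction))
  expect_match(qf$failure, "K2_TOO_SLOW")
})

test_that("normalization follows dilution, volumes and the counting basis", {
  expect_equal(normalize_amount(2, 1, 50, 10, 5e5, "per_1e6_cells"), 20)
  # assayed volume equals extract volume and cells equal the basis: identity
  expect_equal(normalize_amount(3, 1, 10, 10, 1e6, "per_1e6_cells"), 3)
  expect_equal(normalize_amount(1, 2, 50, 5, 1e8, "per_1e8_cfu"), 20)
  expect_error(normalize_amount(1, 1, 0, 10, 1e6, "per_1e6_cells"),
               "positive")
  expect_error(normalize_amount(1, 0.5, 50, 10, 1e6, "per_1e6_cells"),
               "dilution")
})

test_that("assay statistics reproduce their defining formulas", {
  # identical replicates: CV = 0; measured == nominal: accuracy/recovery 100
  r <- assay_statistics(measured = rep(c(1, 8), each = 2),
                        nominal = rep(c(1, 8), each = 2),
                        spiked = 5, unspiked = 3, added = 2)
  expect_equal(r$intra_cv, 0)
  expect_equal(r$accuracy_low, 100)
  expect_equal(r$accuracy_high, 100)
  expect_equal(r$recovery, 100)
  # replicates {9, 11}: sample SD / mean = sqrt(2)/10
  r2 <- assay_statistics(measured = c(9, 11, 9, 11), nominal = rep(c(1, 2),
                                                                   each = 2))
  expect_equal(r2$intra_cv, 100 * sqrt(2) / 10)
  # two plates: inter-assay CV over plate means
  r3 <- assay_statistics(measured = c(9, 11, 19, 21), nominal = rep(1, 4),
                         plate = c("p1", "p1", "p2", "p2"))
  expect_equal(r3$inter_cv, 100 * stats::sd(c(10, 20)) / 15)
  expect_error(assay_statistics(measured = 1, nominal = 1), "replicates")
})

test_that("calibration models round-trip through YAML and JSON", {
  lp <- linear_plate()
  cal <- estimate_lod_loq(build_calibration(lp$fits, lp$layout))
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_calibration(cal, p)
    back <- read_calibration(p)
    expect_equal(back$slope, cal$slope)
    expect_equal(back$intercept, cal$intercept)
    expect_equal(back$lod_pmol, cal$lod_pmol)
    expect_equal(back$points$included, cal$points$included)
  }
})
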