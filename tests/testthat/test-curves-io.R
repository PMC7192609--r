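make_long_csv <- function(df) {
  p <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  utils::write.csv(df, p, row.names = FALSE)
  p
}

test_that("progress curves enforce their invariants", {
  t <- seq(0, 170, 17)
  expect_s3_class(progress_curve("A1", t, seq_along(t)), "progress_curve")
  expect_error(progress_curve("Z9", t, seq_along(t)), "coordinate")
  expect_error(progress_curve("A1", t[1:5], 1:5), "at least 8")
  expect_error(progress_curve("A1", rev(t), seq_along(t)), "increasing")
  expect_error(progress_curve("A1", t, c(NA, seq_along(t)[-1])), "missing")
})

test_that("long-format exports read into one curve per well", {
  t <- seq(0, 170, 17)
  df <- rbind(data.frame(well = "A1", time_s = t, fluorescence = 100 + t),
              data.frame(well = "B2", time_s = t, fluorescence = 200 + t))
  curves <- read_plate_export(make_long_csv(df))
  expect_named(curves, c("A1", "B2"))
  expect_equal(curves$A1$times_s, t)
  expect_equal(curves$B2$fluorescence, 200 + t)
  expect_equal(nrow(attr(curves, "errors")), 0)
})

test_that("wide-cycle exports take times from the schedule", {
  wide <- data.frame(well = c("A1", "A2"),
                     matrix(1:16, nrow = 2, byrow = TRUE))
  p <- make_long_csv(wide)
  curves <- read_plate_export(p, dialect = "wide_cycles",
                              schedule = acquisition_schedule(8, 17))
  expect_equal(curves$A1$times_s, seq(0, 119, 17))
  expect_equal(curves$A1$fluorescence, 1:8)
  expect_equal(curves$A2$fluorescence, 9:16)
  expect_error(read_plate_export(p, dialect = "wide_cycles"), "schedule")
})

test_that("per-well defects are reported without failing the whole file", {
  t <- seq(0, 170, 17)
  bad_t <- t; bad_t[3] <- 10  # time goes backwards
  df <- rbind(data.frame(well = "A1", time_s = t, fluorescence = 1:11),
              data.frame(well = "B1", time_s = bad_t, fluorescence = 1:11),
              data.frame(well = "C1", time_s = c(t, 170),
                         fluorescence = 1:12))
  curves <- read_plate_export(make_long_csv(df))
  expect_named(curves, "A1")
  errs <- attr(curves, "errors")
  expect_setequal(errs$well, c("B1", "C1"))
  expect_match(errs$message[errs$well == "B1"], "increasing")
  expect_match(errs$message[errs$well == "C1"], "duplicate")
})

test_that("malformed headers fail the whole file", {
  p <- make_long_csv(data.frame(foo = 1:3, bar = 4:6))
  expect_error(read_plate_export(p), "malformed header")
})

test_that("write/read of a synthetic plate reproduces times and values", {
  pl <- synth_plate(plate_spec(n_blanks = 1, replicates = 1, seed = 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_plate_export(pl$curves, p)
  back <- read_plate_export(p)
  expect_setequal(names(back), names(pl$curves))
  for (w in names(back)) {
    expect_equal(back[[w]]$times_s, pl$curves[[w]]$times_s)
    expect_equal(back[[w]]$fluorescence, pl$curves[[w]]$fluorescence)
  }
})

test_that("layouts read from CSV and YAML, reclassifying zero-amount wells", {
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    well = c("A1", "A2", "B1"), role = c("calibration", "calibration", "blank"),
    amount_pmol = c(0, 2, NA)), csv, row.names = FALSE)
  lay <- read_plate_layout(csv, dntp_species = "dGTP")
  expect_equal(lay$role, c("blank", "calibration", "blank"))
  expect_equal(attr(lay, "dntp_species"), "dGTP")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "dntp_species: dTTP",
    "wells:",
    "  A1: {role: calibration, amount_pmol: 1}",
    "  B1: {role: sample, sample_id: s1, dilution_factor: 2,",
    "       extract_volume_ul: 50, assayed_volume_ul: 10,",
    "       cells_extracted: 5.0e5, basis: per_1e6_cells}"), yml)
  lay2 <- read_plate_layout(yml)
  expect_equal(attr(lay2, "dntp_species"), "dTTP")
  expect_equal(lay2$dilution_factor[lay2$well == "B1"], 2)
  expect_equal(lay2$cells_extracted[lay2$well == "B1"], 5e5)
})

test_that("layout validation rejects bad roles and duplicates", {
  expect_error(plate_layout(data.frame(well = "A1", role = "mystery")),
               "unknown roles")
  expect_error(plate_layout(data.frame(well = c("A1", "A1"),
                                       role = c("blank", "blank"))),
               "duplicate")
  expect_error(plate_layout(data.frame(well = "A1", role = "calibration",
                                       amount_pmol = -1)),
               "amount_pmol")
})

test_that("reports carry failure explanations and survive a round trip", {
  samples <- data.frame(sample_id = "s1", true_pmol = 3,
                        extract_volume_ul = 50, assayed_volume_ul = 10,
                        cells_extracted = 5e5, basis = "per_1e6_cells")
  pl <- synth_plate(plate_spec(samples = samples, noise_frac = 0.01,
                               seed = 11))
  # sabotage one sample well into a blank-like (single-exponential) curve
  w_bad <- pl$layout$well[pl$layout$role == "sample"][1]
  pl$curves[[w_bad]] <- synth_curve(blank_params, split_schedule(),
                                    noise_sd = 300, well_id = w_bad)
  an <- analyze_plate(pl$curves, pl$layout, fast_config())
  p <- withr::local_tempfile(fileext = ".csv")
  write_report(an, p)
  expect_error(write_report(an, p, format = "xlsx"), "not supported")

  rep <- utils::read.csv(p, comment.char = "#", stringsAsFactors = FALSE)
  expect_equal(nrow(rep), nrow(pl$layout))
  bad_row <- rep[rep$well == w_bad, ]
  expect_match(bad_row$qc_flags, "INSEPARABLE_PHASES")
  expect_match(bad_row$qc_explanation, "could not be separated")
  # numeric fields identical to 6 significant digits after the round trip
  for (col in c("A1", "k1obs", "A2", "k2obs", "F0", "RSS"))
    expect_equal(signif(rep[[col]], 6), signif(an$wells[[col]], 6))
  # calibration summary footer present
  foot <- grep("^#", readLines(p), value = TRUE)
  expect_true(any(grepl("slope", foot)))
  expect_true(any(grepl("lod_pmol", foot)))
})

test_that("an empty result set writes a header-only report", {
  p <- withr::local_tempfile(fileext = ".csv")
  empty <- data.frame(well = character(), model = character())
  write_report(empty, p)
  expect_equal(nrow(utils::read.csv(p)), 0)
})
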