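#' Read a plate export of fluorescence time series
#'
#' Instrument exports are mapped onto a canonical long format
#' (`well, time_s, fluorescence`) by thin dialect adapters:
#' \describe{
#'   \item{`generic_long`}{CSV with columns `well`, `time_s`,
#'     `fluorescence` (extra columns ignored).}
#'   \item{`wide_cycles`}{CSV with a `well` column followed by one column
#'     per recorded cycle; times come from `schedule`.}
#' }
#' Per-well problems (non-monotone time, duplicate well/time pairs,
#' unparseable fluorescence) do not abort the whole file: the offending
#' wells are dropped and reported in the `errors` attribute of the result.
#' A malformed header is a whole-file failure.
#'
#' @param path CSV file path.
#' @param dialect `"generic_long"` or `"wide_cycles"`.
#' @param schedule an [acquisition_schedule()]; required for `wide_cycles`.
#' @return Named list of [progress_curve()] objects (one per well present
#'   in the file), with attribute `errors`: a data frame of per-well error
#'   records (`well`, `message`).
#' @export
read_plate_export <- function(path, dialect = c("generic_long", "wide_cycles"),
                              schedule = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "generic_long") {
    need <- c("well", "time_s", "fluorescence")
    if (!all(need %in% names(df)))
      stop("malformed header: expected columns ", paste(need, collapse = ", "))
    long <- df[need]
  } else {
    if (is.null(schedule))
      stop("dialect 'wide_cycles' requires an acquisition schedule")
    if (!"well" %in% names(df) || ncol(df) < 2)
      stop("malformed header: expected a 'well' column plus cycle columns")
    times <- expand_schedule(schedule)
    cyc <- setdiff(names(df), "well")
    if (length(cyc) != length(times))
      stop("schedule expands to ", length(times), " cycles but file has ",
           length(cyc), " cycle columns")
    long <- data.frame(
      well = rep(df$well, each = length(times)),
      time_s = rep(times, times = nrow(df)),
      fluorescence = as.vector(t(as.matrix(
        as.data.frame(lapply(df[cyc], function(x) as.numeric(as.character(x))))
      ))),
      stringsAsFactors = FALSE)
  }
  curves_from_long(long)
}

# assemble per-well curves from canonical long data, collecting errors
curves_from_long <- function(long) {
  errors <- data.frame(well = character(), message = character(),
                       stringsAsFactors = FALSE)
  out <- list()
  for (w in unique(long$well)) {
    rows <- long[long$well == w, , drop = FALSE]
    msg <- NULL
    tt <- suppressWarnings(as.numeric(rows$time_s))
    ff <- suppressWarnings(as.numeric(rows$fluorescence))
    if (anyNA(tt) || anyNA(ff)) {
      msg <- "unparseable time or fluorescence values"
    } else if (anyDuplicated(tt)) {
      msg <- "duplicate well/time pairs"
    } else if (is.unsorted(tt, strictly = TRUE)) {
      msg <- "time not strictly increasing"
    }
    if (is.null(msg)) {
      cur <- tryCatch(progress_curve(w, tt, ff), error = function(e) e$message)
      if (inherits(cur, "progress_curve")) out[[w]] <- cur else msg <- cur
    }
    if (!is.null(msg))
      errors <- rbind(errors, data.frame(well = w, message = msg,
                                         stringsAsFactors = FALSE))
  }
  attr(out, "errors") <- errors
  out
}

#' Write progress curves to the canonical long CSV
#'
#' @param curves list of [progress_curve()] objects.
#' @param path output CSV path.
#' @export
write_plate_export <- function(curves, path) {
  long <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate layout
#'
#' The layout assigns each well a role: `blank` (no specific dNTP),
#' `calibration` (known `amount_pmol`), `sample` (with quantification
#' metadata) or `excluded`. A calibration well with amount 0 is reclassified
#' as blank. Accepted as CSV (columns `well`, `role`, and the optional
#' fields below) or YAML (top-level `dntp_species` and `wells:` mapping of
#' well id to a field map).
#'
#' @param path layout file (.csv, .yml/.yaml).
#' @param dntp_species which dNTP the plate assays; overrides any value in
#'   the file when given.
#' @return A `plate_layout`: data frame with columns `well`, `role`,
#'   `amount_pmol`, `sample_id`, `dilution_factor`, `extract_volume_ul`,
#'   `assayed_volume_ul`, `cells_extracted`, `basis`, plus attribute
#'   `dntp_species`.
#' @export
read_plate_layout <- function(path, dntp_species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    sp <- dntp_species %||% y$dntp_species
    rows <- lapply(names(y$wells), function(w) {
      f <- y$wells[[w]]
      num <- function(x) as.numeric(x %||% NA_real_)  # YAML 1.1 "5.0e5" quirk
      data.frame(well = w, role = f$role %||% "excluded",
                 amount_pmol = num(f$amount_pmol),
                 sample_id = f$sample_id %||% NA_character_,
                 dilution_factor = num(f$dilution_factor %||% 1),
                 extract_volume_ul = num(f$extract_volume_ul),
                 assayed_volume_ul = num(f$assayed_volume_ul),
                 cells_extracted = num(f$cells_extracted),
                 basis = f$basis %||% NA_character_,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    sp <- dntp_species %||% (if ("dntp_species" %in% names(df))
      df$dntp_species[1] else NULL)
  }
  plate_layout(df, dntp_species = sp %||% NA_character_)
}

#' Construct/validate a plate layout
#'
#' @param df data frame with at least `well` and `role` columns; see
#'   [read_plate_layout()] for the full column set.
#' @param dntp_species one of dATP, dCTP, dGTP, dTTP, dUTP (or NA).
#' @export
plate_layout <- function(df, dntp_species = NA_character_) {
  if (!all(c("well", "role") %in% names(df)))
    stop("layout needs 'well' and 'role' columns")
  defaults <- list(amount_pmol = NA_real_, sample_id = NA_character_,
                   dilution_factor = 1, extract_volume_ul = NA_real_,
                   assayed_volume_ul = NA_real_, cells_extracted = NA_real_,
                   basis = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df <- df[c("well", "role", names(defaults))]
  ok_roles <- c("blank", "calibration", "sample", "excluded")
  if (!all(df$role %in% ok_roles))
    stop("unknown roles: ", paste(setdiff(df$role, ok_roles), collapse = ", "))
  if (anyDuplicated(df$well)) stop("duplicate wells in layout")
  # zero-amount calibration wells are blanks
  recls <- df$role == "calibration" & !is.na(df$amount_pmol) &
    df$amount_pmol == 0
  df$role[recls] <- "blank"
  bad <- df$role == "calibration" &
    (is.na(df$amount_pmol) | df$amount_pmol < 0)
  if (any(bad))
    stop("calibration wells need amount_pmol >= 0: ",
         paste(df$well[bad], collapse = ", "))
  if (any(!is.na(df$dilution_factor) & df$dilution_factor < 1))
    stop("dilution_factor must be >= 1")
  if (!is.na(dntp_species) &&
      !dntp_species %in% c("dATP", "dCTP", "dGTP", "dTTP", "dUTP"))
    stop("unknown dntp_species: ", dntp_species)
  structure(df, dntp_species = dntp_species,
            class = c("plate_layout", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the per-well analysis report
#'
#' One row per well: selected model, all fitted parameters with standard
#' errors, RSS, both AICc values, lag trim, QC flags with their
#' human-readable failure explanations, the quantified pmol, the normalized
#' amount and the calibration-range flag. The calibration summary (slope,
#' intercept, R-squared, LOD, LOQ) is appended as a commented footer
#' section so a single CSV carries the full analysis.
#'
#' @param results a `plate_analysis` from [analyze_plate()] (or a data frame
#'   shaped like its `wells` table).
#' @param path output path.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx")
    stop("xlsx output is not supported by this build; use format = 'csv' ",
         "(the CSV report carries the identical content)")
  wells <- if (inherits(results, "plate_analysis")) results$wells else
    as.data.frame(results)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(wells, con, row.names = FALSE, na = "")
  if (inherits(results, "plate_analysis") && !is.null(results$calibration)) {
    cal <- results$calibration
    writeLines(c(
      "# calibration summary",
      sprintf("# dntp_species,%s", attr(results$layout, "dntp_species")),
      sprintf("# slope,%.10g", cal$slope),
      sprintf("# intercept,%.10g", cal$intercept),
      sprintf("# r_squared,%.10g", cal$r_squared),
      sprintf("# fitted_range_pmol,%.10g,%.10g",
              cal$fitted_range[1], cal$fitted_range[2]),
      sprintf("# lod_pmol,%.10g", cal$lod_pmol),
      sprintf("# loq_pmol,%.10g", cal$loq_pmol)), con)
  }
  invisible(path)
}
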