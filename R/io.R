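# Cohort serialization.
#
# Two dialects:
#  * packed_csv  - canonical interchange: one row per
#                  (subject, arm, channel, frequency index), magnitude/phase
#                  columns as recorded by the analyzer (phase in degrees).
#  * touchstone_dir - one Touchstone v1 .s2p file per subject-arm
#                  (`# HZ S MA R 50` dialect) plus a JSON demographics
#                  sidecar per subject; convenience for instrument exports.

CSV_COLUMNS <- c("subject_id", "group", "age", "bmi", "circumference_left",
                 "circumference_right", "arm", "channel", "freq_hz",
                 "mag_linear", "phase_deg")

#' Read a cohort from disk
#'
#' @param path File (packed CSV) or directory (Touchstone) to read.
#' @param dialect `"packed_csv"` or `"touchstone_dir"`.
#' @param grid Optional [rf_grid()] override. When `NULL`, spectra must have
#'   201 points on the stored frequencies; with an override, any length
#'   matching the override is accepted.
#' @return An [rf_cohort()].
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, dialect = c("packed_csv", "touchstone_dir"),
                        grid = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_wristrf("cohort path does not exist: %s", path)
  }
  switch(dialect,
         packed_csv = read_cohort_csv(path, grid),
         touchstone_dir = read_cohort_touchstone(path, grid))
}

#' Write a cohort to disk
#'
#' Writing then reading reproduces the cohort to numeric tolerance
#' (phase/magnitude are stored in full double precision).
#'
#' @param cohort An [rf_cohort()].
#' @param path Output file (packed CSV) or directory (Touchstone).
#' @param dialect `"packed_csv"` or `"touchstone_dir"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         dialect = c("packed_csv", "touchstone_dir")) {
  dialect <- match.arg(dialect)
  if (!inherits(cohort, "rf_cohort")) {
    stop_wristrf("`cohort` must be an rf_cohort")
  }
  switch(dialect,
         packed_csv = write_cohort_csv(cohort, path),
         touchstone_dir = write_cohort_touchstone(cohort, path))
  invisible(path)
}

# ---- packed CSV ------------------------------------------------------------

subject_rows <- function(s) {
  parts <- lapply(names(s$spectra), function(key) {
    sp <- s$spectra[[key]]
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               bmi = s$bmi,
               circumference_left = s$circumference_left,
               circumference_right = s$circumference_right,
               arm = sp$arm, channel = sp$channel,
               freq_hz = sp$grid$points,
               mag_linear = Mod(sp$values),
               phase_deg = Arg(sp$values) * 180 / pi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

write_cohort_csv <- function(cohort, path) {
  if (length(cohort$subjects) == 0L) {
    # degenerate but valid: header-only file
    empty <- as.data.frame(setNames(rep(list(character(0)), length(CSV_COLUMNS)),
                                    CSV_COLUMNS))
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  tab <- do.call(rbind, lapply(cohort$subjects, subject_rows))
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_cohort_csv <- function(path, grid = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CSV_COLUMNS, names(tab))
  if (length(missing_cols) > 0L) {
    stop_wristrf("packed CSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(rf_cohort(list(), provenance = path))
  subjects <- lapply(split(tab, tab$subject_id), csv_subject, grid = grid)
  ids <- unique(tab$subject_id)  # preserve file order
  rf_cohort(unname(subjects[ids]), provenance = path)
}

csv_subject <- function(rows, grid = NULL) {
  id <- rows$subject_id[1L]
  spectra <- list()
  for (channel in CHANNELS) {
    for (arm in ARMS) {
      sel <- rows[rows$channel == channel & rows$arm == arm, , drop = FALSE]
      if (nrow(sel) == 0L) {
        stop_wristrf("subject '%s' is missing its (%s, %s) spectrum",
                     id, channel, arm)
      }
      sel <- sel[order(sel$freq_hz), , drop = FALSE]
      use_grid <- if (is.null(grid)) {
        if (nrow(sel) != 201L) {
          stop_wristrf(
            "subject '%s' (%s, %s): %d points where 201 expected; pass a grid override to accept",
            id, channel, arm, nrow(sel))
        }
        rf_grid(sel$freq_hz)
      } else {
        if (nrow(sel) != grid$n_points) {
          stop_wristrf("subject '%s' (%s, %s): %d points but override grid has %d",
                       id, channel, arm, nrow(sel), grid$n_points)
        }
        grid
      }
      spectra[[spectrum_key(channel, arm)]] <-
        rf_spectrum(mag_phase_to_complex(sel$mag_linear, sel$phase_deg),
                    grid = use_grid, channel = channel, arm = arm)
    }
  }
  rf_subject(id, rows$group[1L], rows$age[1L], rows$bmi[1L],
             rows$circumference_left[1L], rows$circumference_right[1L],
             spectra)
}

# ---- Touchstone ------------------------------------------------------------

# v1 2-port data line order: f  S11  S21  S12  S22, magnitude/angle pairs.
# Only S11 and S21 are part of the data model; files are written reciprocal
# (S12 = S21) and symmetric (S22 = S11) so they remain valid 2-port files.

write_cohort_touchstone <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    meta <- list(subject_id = s$subject_id, group = s$group, age = s$age,
                 bmi = s$bmi,
                 circumference_left = s$circumference_left,
                 circumference_right = s$circumference_right)
    jsonlite::write_json(meta, file.path(path, paste0(s$subject_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    for (arm in ARMS) {
      s11 <- s$spectra[[spectrum_key("S11", arm)]]
      s21 <- s$spectra[[spectrum_key("S21", arm)]]
      lines <- c(
        sprintf("! wristrf export, subject %s, %s arm", s$subject_id, arm),
        "# HZ S MA R 50",
        sprintf("%.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                s11$grid$points,
                Mod(s11$values), Arg(s11$values) * 180 / pi,
                Mod(s21$values), Arg(s21$values) * 180 / pi,
                Mod(s21$values), Arg(s21$values) * 180 / pi,
                Mod(s11$values), Arg(s11$values) * 180 / pi))
      writeLines(lines, file.path(path, sprintf("%s_%s.s2p", s$subject_id, arm)))
    }
  }
  invisible(path)
}

read_touchstone_s2p <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  opt <- lines[startsWith(lines, "#")]
  if (length(opt) == 0L) stop_wristrf("%s: no Touchstone option line", file)
  tokens <- toupper(strsplit(opt[1L], "\\s+")[[1L]])
  freq_unit <- if (length(tokens) >= 2L) tokens[2L] else "GHZ"
  fmt <- if ("RI" %in% tokens) "RI" else if ("DB" %in% tokens) "DB" else "MA"
  scale <- switch(freq_unit, HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9,
                  stop_wristrf("%s: unsupported frequency unit %s", file, freq_unit))
  data_lines <- lines[!startsWith(lines, "!") & !startsWith(lines, "#") &
                        nzchar(lines)]
  fields <- lapply(strsplit(data_lines, "\\s+"), as.numeric)
  n_col <- unique(vapply(fields, length, integer(1)))
  if (length(n_col) != 1L || n_col != 9L) {
    stop_wristrf("%s: expected 9 numeric columns per 2-port data line", file)
  }
  mat <- do.call(rbind, fields)
  pair_to_complex <- function(a, b) {
    switch(fmt,
           MA = mag_phase_to_complex(a, b),
           RI = complex(real = a, imaginary = b),
           DB = mag_phase_to_complex(10^(a / 20), b))
  }
  list(freq_hz = mat[, 1L] * scale,
       s11 = pair_to_complex(mat[, 2L], mat[, 3L]),
       s21 = pair_to_complex(mat[, 4L], mat[, 5L]))
}

read_cohort_touchstone <- function(path, grid = NULL) {
  if (!dir.exists(path)) stop_wristrf("not a directory: %s", path)
  metas <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(metas) == 0L) {
    stop_wristrf("no subject sidecar JSON files found in %s", path)
  }
  subjects <- lapply(metas, function(meta_file) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    id <- meta$subject_id
    spectra <- list()
    for (arm in ARMS) {
      s2p <- file.path(path, sprintf("%s_%s.s2p", id, arm))
      if (!file.exists(s2p)) {
        stop_wristrf("subject '%s' is missing its %s-arm .s2p file", id, arm)
      }
      dat <- read_touchstone_s2p(s2p)
      use_grid <- grid %||% (if (length(dat$freq_hz) == 201L) rf_grid(dat$freq_hz)
                             else stop_wristrf(
                               "subject '%s' (%s): %d points where 201 expected; pass a grid override",
                               id, arm, length(dat$freq_hz)))
      spectra[[spectrum_key("S21", arm)]] <-
        rf_spectrum(dat$s21, use_grid, "S21", arm)
      spectra[[spectrum_key("S11", arm)]] <-
        rf_spectrum(dat$s11, use_grid, "S11", arm)
    }
    rf_subject(id, meta$group, meta$age, meta$bmi,
               meta$circumference_left, meta$circumference_right, spectra)
  })
  rf_cohort(subjects, provenance = path)
}
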