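# Domain types for cohorts of bilateral wrist S-parameter measurements.
#
# A subject record carries demographics plus four 201-point complex spectra:
# the transmission coefficient S21 and the reflection coefficient S11, for
# the left and the right wrist. Group labels follow the screening convention
# that group 1 (osteopenic/osteoporotic, the "positive" class) is the
# low-bone-density group and group 2 is healthy.

GROUP_LEVELS <- c("group1_osteo", "group2_healthy", "unknown")
CHANNELS <- c("S21", "S11")
ARMS <- c("left", "right")

#' Default measurement frequency grid
#'
#' Linearly spaced grid matching the network-analyzer sweep used for wrist
#' transmission measurements: 201 points from 300 kHz to 2 GHz inclusive.
#'
#' @param n_points Number of frequency samples (default 201).
#' @param f_start Sweep start in Hz (default 3e5).
#' @param f_end Sweep end in Hz (default 2e9).
#' @return An `rf_grid` object: a list with `points` (Hz, strictly
#'   increasing) and `n_points`.
#' @examples
#' g <- default_grid()
#' g$n_points
#' @export
default_grid <- function(n_points = 201L, f_start = 3e5, f_end = 2e9) {
  rf_grid(seq(f_start, f_end, length.out = n_points))
}

#' Construct a frequency grid
#'
#' @param points Strictly increasing numeric vector of frequencies in Hz.
#' @return An `rf_grid` object.
#' @export
rf_grid <- function(points) {
  points <- as.numeric(points)
  if (length(points) < 2L || any(!is.finite(points))) {
    stop_wristrf("grid must contain at least 2 finite frequencies")
  }
  if (any(diff(points) <= 0)) {
    stop_wristrf("grid frequencies must be strictly increasing")
  }
  structure(list(points = points, n_points = length(points)),
            class = "rf_grid")
}

#' Convert magnitude/phase readings to complex S-parameters
#'
#' Network analyzers record each S-parameter sample as a linear magnitude and
#' a phase in degrees; the classifier consumes the complex (real/imaginary)
#' representation. Vectorized over both arguments.
#'
#' @param magnitude Non-negative linear magnitude(s).
#' @param phase_deg Phase(s) in degrees; any real value is accepted and
#'   wrapped implicitly by the trigonometry.
#' @return Complex vector `magnitude * exp(1i * phase_in_radians)`.
#' @examples
#' mag_phase_to_complex(0.5, 90) # 0 + 0.5i
#' @export
mag_phase_to_complex <- function(magnitude, phase_deg) {
  if (!is.numeric(magnitude) || !is.numeric(phase_deg)) {
    stop_wristrf("magnitude and phase must be numeric")
  }
  if (any(magnitude < 0, na.rm = TRUE)) {
    stop_wristrf("magnitude must be non-negative")
  }
  theta <- phase_deg * pi / 180
  complex(real = magnitude * cos(theta), imaginary = magnitude * sin(theta))
}

#' Construct a single S-parameter spectrum
#'
#' @param values Complex vector, one value per grid point.
#' @param grid An [rf_grid()]; defaults to [default_grid()].
#' @param channel `"S21"` (transmission) or `"S11"` (reflection).
#' @param arm `"left"` or `"right"`.
#' @return An `rf_spectrum` object.
#' @details Magnitudes above 1 are physically implausible for passive
#'   transmission; the validator warns but does not reject, since calibration
#'   artefacts can produce slight violations in real exports.
#' @export
rf_spectrum <- function(values, grid = default_grid(), channel = "S21",
                        arm = "left") {
  channel <- match.arg(channel, CHANNELS)
  arm <- match.arg(arm, ARMS)
  values <- as.complex(values)
  if (!inherits(grid, "rf_grid")) grid <- rf_grid(grid)
  if (length(values) != grid$n_points) {
    stop_wristrf("spectrum has %d values but grid has %d points",
                 length(values), grid$n_points)
  }
  if (any(!is.finite(Re(values)) | !is.finite(Im(values)))) {
    stop_wristrf("spectrum values must be finite")
  }
  if (any(Mod(values) > 1 + 1e-12)) {
    warning(sprintf("%s/%s spectrum has |S| > 1 at %d point(s); passive %s",
                    channel, arm, sum(Mod(values) > 1 + 1e-12),
                    "transmission normally satisfies |S| <= 1"),
            call. = FALSE)
  }
  structure(list(values = values, grid = grid, channel = channel, arm = arm),
            class = "rf_spectrum")
}

spectrum_key <- function(channel, arm) paste(channel, arm, sep = "_")

#' Construct a subject record
#'
#' @param subject_id Opaque identifier string.
#' @param group One of `"group1_osteo"`, `"group2_healthy"`, `"unknown"`.
#' @param age Age in years (> 0).
#' @param bmi Body mass index in kg/m^2 (> 0).
#' @param circumference_left,circumference_right Wrist circumferences in cm.
#' @param spectra Named list of four [rf_spectrum()] objects with names
#'   `S21_left`, `S21_right`, `S11_left`, `S11_right`.
#' @return An `rf_subject` object.
#' @export
rf_subject <- function(subject_id, group, age, bmi,
                       circumference_left, circumference_right, spectra) {
  subject_id <- as.character(subject_id)
  if (length(subject_id) != 1L || !nzchar(subject_id)) {
    stop_wristrf("subject_id must be a non-empty string")
  }
  group <- match.arg(group, GROUP_LEVELS)
  check_scalar_number(age, "age", positive = TRUE)
  check_scalar_number(bmi, "bmi", positive = TRUE)
  check_scalar_number(circumference_left, "circumference_left", positive = TRUE)
  check_scalar_number(circumference_right, "circumference_right", positive = TRUE)
  wanted <- as.vector(outer(CHANNELS, ARMS, spectrum_key))
  missing <- setdiff(wanted, names(spectra))
  if (length(missing) > 0L) {
    stop_wristrf("subject '%s' is missing spectra: %s",
                 subject_id, paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(spectra), wanted)
  if (length(extra) > 0L) {
    stop_wristrf("subject '%s' has unexpected spectra: %s",
                 subject_id, paste(extra, collapse = ", "))
  }
  for (key in wanted) {
    sp <- spectra[[key]]
    if (!inherits(sp, "rf_spectrum")) {
      stop_wristrf("subject '%s': spectra[['%s']] is not an rf_spectrum",
                   subject_id, key)
    }
    if (spectrum_key(sp$channel, sp$arm) != key) {
      stop_wristrf("subject '%s': spectrum stored under '%s' is tagged %s/%s",
                   subject_id, key, sp$channel, sp$arm)
    }
  }
  structure(list(subject_id = subject_id, group = group, age = age, bmi = bmi,
                 circumference_left = circumference_left,
                 circumference_right = circumference_right,
                 spectra = spectra[wanted]),
            class = "rf_subject")
}

#' Construct a cohort
#'
#' @param subjects List of [rf_subject()] records with unique ids.
#' @param provenance Free-text provenance note (e.g. `"synthetic seed=7"`).
#' @return An `rf_cohort` object.
#' @export
rf_cohort <- function(subjects, provenance = "") {
  if (!is.list(subjects) ||
      !all(vapply(subjects, inherits, logical(1), "rf_subject"))) {
    stop_wristrf("subjects must be a list of rf_subject records")
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop_wristrf("duplicate subject_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(subjects = subjects, provenance = as.character(provenance)),
            class = "rf_cohort")
}

#' @export
print.rf_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("<rf_cohort> %d subjects (%d group1_osteo, %d group2_healthy)\n",
              length(x$subjects), sum(groups == "group1_osteo"),
              sum(groups == "group2_healthy")))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.rf_spectrum <- function(x, ...) {
  cat(sprintf("<rf_spectrum> %s/%s, %d points, %.3g-%.3g Hz\n", x$channel,
              x$arm, x$grid$n_points, min(x$grid$points), max(x$grid$points)))
  invisible(x)
}

cohort_groups <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}

cohort_ids <- function(cohort) {
  vapply(cohort$subjects, function(s) s$subject_id, character(1))
}
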