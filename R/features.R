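# Feature assembly: turn subject records into the numeric vectors the
# classifier trains on. A recipe fixes four choices:
#   encoding  - magnitude | phase | mag_phase | complex_reim
#   arm_mode  - average | concatenate | separate
#   include_circumference - append wrist circumference(s) in cm
#   normalize_age_bmi     - scale the complex spectrum by age/BMI first
#
# Resulting lengths per 201-point grid: a single encoded spectrum is 201
# (magnitude, phase) or 402 (mag_phase, complex_reim); concatenate doubles
# the spectral part; the circumference feature adds 1 (average/separate)
# or 2 (concatenate). The longest realizable vector is 806 =
# 2 x 402 + 2 (complex both-arm concatenation with both circumferences).

ENCODINGS <- c("magnitude", "phase", "mag_phase", "complex_reim")
ARM_MODES <- c("average", "concatenate", "separate")

#' Define a feature-assembly recipe
#'
#' @param encoding How complex S21 samples become real features:
#'   `"magnitude"` (|S21|), `"phase"` (arg S21 in radians, wrapped),
#'   `"mag_phase"` (magnitudes then phases), or `"complex_reim"` (real parts
#'   then imaginary parts).
#' @param arm_mode `"average"` (complex pointwise mean across arms, one
#'   vector per subject), `"concatenate"` (left then right, one vector), or
#'   `"separate"` (one vector per arm).
#' @param include_circumference Append raw wrist circumference(s) in cm.
#' @param normalize_age_bmi Multiply the complex spectrum by the scalar
#'   age/BMI before encoding (risk-factor normalization). Applied to the
#'   spectrum only, never to the circumference feature.
#' @return A `feature_recipe` object.
#' @export
feature_recipe <- function(encoding = c("complex_reim", "magnitude", "phase",
                                        "mag_phase"),
                           arm_mode = c("separate", "average", "concatenate"),
                           include_circumference = TRUE,
                           normalize_age_bmi = FALSE) {
  encoding <- match.arg(encoding[1L], ENCODINGS)
  arm_mode <- match.arg(arm_mode[1L], ARM_MODES)
  stopifnot(is.logical(include_circumference), length(include_circumference) == 1L,
            is.logical(normalize_age_bmi), length(normalize_age_bmi) == 1L)
  structure(list(encoding = encoding, arm_mode = arm_mode,
                 include_circumference = include_circumference,
                 normalize_age_bmi = normalize_age_bmi),
            class = "feature_recipe")
}

#' Encode a complex spectrum as a real feature vector
#'
#' @param spectrum An [rf_spectrum()] or a complex vector.
#' @param encoding One of `"magnitude"`, `"phase"`, `"mag_phase"`,
#'   `"complex_reim"`.
#' @return Numeric vector of length n (magnitude/phase) or 2n
#'   (mag_phase/complex_reim). Phases are in radians, wrapped to (-pi, pi].
#' @export
encode_spectrum <- function(spectrum, encoding = ENCODINGS) {
  encoding <- match.arg(encoding[1L], ENCODINGS)
  v <- if (inherits(spectrum, "rf_spectrum")) spectrum$values
       else as.complex(spectrum)
  switch(encoding,
         magnitude = Mod(v),
         phase = Arg(v),
         mag_phase = c(Mod(v), Arg(v)),
         complex_reim = c(Re(v), Im(v)))
}

#' Age/BMI normalization of a complex spectrum
#'
#' Scales every complex S21 sample by the scalar age/BMI, so real and
#' imaginary parts (hence magnitudes) scale while phases are unchanged.
#'
#' @param values Complex vector.
#' @param age Age in years.
#' @param bmi Body mass index in kg/m^2 (> 0).
#' @return The scaled complex vector.
#' @examples
#' normalize_age_bmi(0.5 + 0.2i, age = 60, bmi = 30) # factor 2
#' @export
normalize_age_bmi <- function(values, age, bmi) {
  check_scalar_number(age, "age", positive = TRUE)
  check_scalar_number(bmi, "bmi", positive = TRUE)
  as.complex(values) * (age / bmi)
}

#' Expected feature-vector length for a recipe
#'
#' @param recipe A [feature_recipe()].
#' @param n_points Spectrum length (default 201).
#' @return Length of each assembled vector (each of the two, in
#'   `"separate"` mode).
#' @export
feature_length <- function(recipe, n_points = 201L) {
  per_spectrum <- switch(recipe$encoding,
                         magnitude = n_points, phase = n_points,
                         mag_phase = 2L * n_points,
                         complex_reim = 2L * n_points)
  spectral <- if (recipe$arm_mode == "concatenate") 2L * per_spectrum
              else per_spectrum
  circ <- if (!recipe$include_circumference) 0L
          else if (recipe$arm_mode == "concatenate") 2L else 1L
  as.integer(spectral + circ)
}

new_feature_vector <- function(values, subject_id, arm_tag, recipe) {
  structure(list(values = as.numeric(values), subject_id = subject_id,
                 arm_tag = arm_tag, recipe = recipe),
            class = "rf_features")
}

#' Assemble feature vector(s) for one subject
#'
#' Normalization (when enabled) is applied to the complex spectra before
#' encoding; in `"average"` mode the two complex spectra are averaged
#' pointwise before encoding. Circumference features are appended raw
#' (cm) and are never normalized.
#'
#' @param subject An [rf_subject()].
#' @param recipe A [feature_recipe()].
#' @return A list of `rf_features`: one element (`arm_tag` `"both"`) for
#'   `"average"`/`"concatenate"`, two (`"left"`, `"right"`) for
#'   `"separate"`.
#' @export
assemble_features <- function(subject, recipe) {
  if (!inherits(subject, "rf_subject")) stop_wristrf("not an rf_subject")
  if (!inherits(recipe, "feature_recipe")) stop_wristrf("not a feature_recipe")
  s21 <- lapply(ARMS, function(arm) {
    sp <- subject$spectra[[spectrum_key("S21", arm)]]
    if (is.null(sp)) stop_wristrf("subject '%s' lacks its %s S21 spectrum",
                                  subject$subject_id, arm)
    v <- sp$values
    if (recipe$normalize_age_bmi) {
      v <- normalize_age_bmi(v, subject$age, subject$bmi)
    }
    v
  })
  names(s21) <- ARMS
  circ <- c(left = subject$circumference_left,
            right = subject$circumference_right)
  out <- switch(
    recipe$arm_mode,
    average = {
      avg <- (s21$left + s21$right) / 2
      vals <- encode_spectrum(avg, recipe$encoding)
      if (recipe$include_circumference) vals <- c(vals, mean(circ))
      list(new_feature_vector(vals, subject$subject_id, "both", recipe))
    },
    concatenate = {
      vals <- c(encode_spectrum(s21$left, recipe$encoding),
                encode_spectrum(s21$right, recipe$encoding))
      if (recipe$include_circumference) vals <- c(vals, circ[["left"]],
                                                  circ[["right"]])
      list(new_feature_vector(vals, subject$subject_id, "both", recipe))
    },
    separate = {
      lapply(ARMS, function(arm) {
        vals <- encode_spectrum(s21[[arm]], recipe$encoding)
        if (recipe$include_circumference) vals <- c(vals, circ[[arm]])
        new_feature_vector(vals, subject$subject_id, arm, recipe)
      })
    })
  expected <- feature_length(recipe, subject$spectra$S21_left$grid$n_points)
  for (fv in out) {
    if (length(fv$values) != expected) {
      stop_wristrf("assembled length %d != expected %d (internal error)",
                   length(fv$values), expected)
    }
  }
  out
}

#' Assemble a design matrix for a whole cohort
#'
#' @param cohort An [rf_cohort()].
#' @param recipe A [feature_recipe()].
#' @return A list with `x` (numeric matrix, one row per instance), `y`
#'   (group label per row; each arm inherits its subject's label),
#'   `subject_id`, and `arm_tag`.
#' @export
assemble_cohort <- function(cohort, recipe) {
  if (!inherits(cohort, "rf_cohort")) stop_wristrf("not an rf_cohort")
  fvs <- unlist(lapply(cohort$subjects, assemble_features, recipe = recipe),
                recursive = FALSE)
  groups <- stats::setNames(cohort_groups(cohort), cohort_ids(cohort))
  x <- do.call(rbind, lapply(fvs, `[[`, "values"))
  ids <- vapply(fvs, `[[`, character(1), "subject_id")
  list(x = x, y = unname(groups[ids]), subject_id = ids,
       arm_tag = vapply(fvs, `[[`, character(1), "arm_tag"))
}
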