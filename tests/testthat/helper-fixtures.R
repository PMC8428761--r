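# Shared fixture builders. Everything is generated in code; no stored data.

# Deterministic hand-built subject with distinguishable spectra per channel/arm.
tiny_subject <- function(id = "t001", group = "group1_osteo", n_points = 201L,
                         age = 70, bmi = 25, circ_l = 16, circ_r = 17) {
  grid <- default_grid(n_points)
  f <- grid$points / max(grid$points)
  mk <- function(channel, arm, scale) {
    vals <- scale * complex(real = 0.02 + 0.01 * cos(2 * pi * f),
                            imaginary = 0.01 * sin(2 * pi * f))
    rf_spectrum(vals, grid, channel, arm)
  }
  rf_subject(id, group, age, bmi, circ_l, circ_r,
             list(S21_left = mk("S21", "left", 1.0),
                  S21_right = mk("S21", "right", 1.1),
                  S11_left = mk("S11", "left", 0.5),
                  S11_right = mk("S11", "right", 0.6)))
}

tiny_cohort <- function(n1 = 1L, n2 = 1L) {
  subs <- c(
    lapply(seq_len(n1), function(i) {
      tiny_subject(sprintf("g1_%02d", i), "group1_osteo")
    }),
    lapply(seq_len(n2), function(i) {
      tiny_subject(sprintf("g2_%02d", i), "group2_healthy")
    }))
  rf_cohort(subs, provenance = "hand-built fixture")
}

# Fast simulation defaults for unit tests (full-size defaults are exercised
# in the acceptance suite).
fast_sim <- function(...) {
  sim_params(n_group1 = 6L, n_group2 = 8L, ...)
}

fast_classifier <- list(epochs = 30L)

expect_complex_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(Mod(a - b)), tol * max(1, max(Mod(b))))
}
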