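# Synthetic cohort generator.

test_that("simulation is deterministic given the seed", {
  p <- fast_sim(seed = 7)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  c2 <- simulate_cohort(fast_sim(seed = 8))
  expect_false(identical(a$subjects[[1]]$spectra$S21_left$values,
                         c2$subjects[[1]]$spectra$S21_left$values))
})

test_that("group sizes and labels follow the parameters", {
  co <- simulate_cohort(sim_params(seed = 1))
  expect_length(co$subjects, 67)
  groups <- vapply(co$subjects, `[[`, "", "group")
  expect_equal(sum(groups == "group1_osteo"), 27)
  expect_equal(sum(groups == "group2_healthy"), 40)
})

test_that("with all variability switched off the groups are spectrally identical", {
  p <- fast_sim(effect_amplitude = 0, effect_shift = 0, subject_sd = 0,
                noise_sd = 0, circumference_sd = 0, seed = 3)
  co <- simulate_cohort(p)
  groups <- vapply(co$subjects, `[[`, "", "group")
  ref <- co$subjects[[which(groups == "group1_osteo")[1]]]$spectra$S21_left$values
  other <- co$subjects[[which(groups == "group2_healthy")[1]]]$spectra$S21_right$values
  expect_complex_equal(other, ref, tol = 1e-12)
})

test_that("perfectly correlated arms without noise are identical", {
  p <- fast_sim(arm_correlation = 1, noise_sd = 0, seed = 5)
  co <- simulate_cohort(p)
  for (s in co$subjects) {
    expect_complex_equal(s$spectra$S21_right$values, s$spectra$S21_left$values,
                         tol = 1e-12)
  }
})

test_that("every simulated transmission spectrum is passive (|S21| <= 1)", {
  p <- fast_sim(subject_sd = 1.5, noise_sd = 0.02, effect_amplitude = 2,
                seed = 9)  # deliberately extreme variability
  co <- simulate_cohort(p)
  for (s in co$subjects) {
    expect_lte(max(Mod(s$spectra$S21_left$values)), 1)
    expect_lte(max(Mod(s$spectra$S21_right$values)), 1)
  }
})

test_that("mean group separation of |S21| grows with effect_amplitude", {
  sep <- vapply(c(0, 0.25, 0.5), function(eff) {
    co <- simulate_cohort(sim_params(n_group1 = 200, n_group2 = 200,
                                     effect_amplitude = eff, seed = 11))
    groups <- vapply(co$subjects, `[[`, "", "group")
    auc <- vapply(co$subjects, function(s) {
      mean(Mod(s$spectra$S21_left$values)) +
        mean(Mod(s$spectra$S21_right$values))
    }, numeric(1))
    mean(auc[groups == "group1_osteo"]) - mean(auc[groups == "group2_healthy"])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("zero-effect cohorts show no spurious group difference", {
  p_base <- sim_params(effect_amplitude = 0, effect_shift = 0)
  pvals <- vapply(1:100, function(seed) {
    p <- p_base
    p$seed <- seed
    co <- simulate_cohort(p)
    groups <- vapply(co$subjects, `[[`, "", "group")
    auc <- vapply(co$subjects, function(s) {
      mean(Mod(s$spectra$S21_left$values)) +
        mean(Mod(s$spectra$S21_right$values))
    }, numeric(1))
    stats::t.test(auc[groups == "group1_osteo"],
                  auc[groups == "group2_healthy"])$p.value
  }, numeric(1))
  expect_gte(mean(pvals >= 0.01), 0.95)
})

test_that("realized demographics match the fitted distributions at n = 10000", {
  co <- simulate_cohort(sim_params(n_group1 = 10000, n_group2 = 10000,
                                   seed = 123))
  groups <- vapply(co$subjects, `[[`, "", "group")
  ages <- vapply(co$subjects, `[[`, 1, "age")
  fits <- wristrf:::demographic_fits(sim_params())
  imp1 <- wristrf:::truncnorm_moments(fits$age_g1$mu, fits$age_g1$sigma, 55, 90)
  imp2 <- wristrf:::truncnorm_moments(fits$age_g2$mu, fits$age_g2$sigma, 23, 94)
  m1 <- mean(ages[groups == "group1_osteo"])
  m2 <- mean(ages[groups == "group2_healthy"])
  s1 <- sd(ages[groups == "group1_osteo"])
  s2 <- sd(ages[groups == "group2_healthy"])
  # means recover the published group targets
  expect_lt(abs(m1 - 77.5), 2 * imp1[["sd"]] / 100 + 0.02)
  expect_lt(abs(m2 - 60.2), 2 * imp2[["sd"]] / 100 + 0.02)
  # sds recover the fitted distributions' own implied moments
  expect_lt(abs(s1 - imp1[["sd"]]), 3 * imp1[["sd"]] / sqrt(2 * 10000))
  expect_lt(abs(s2 - imp2[["sd"]]), 3 * imp2[["sd"]] / sqrt(2 * 10000))
  # ages honour the published ranges
  expect_gte(min(ages[groups == "group1_osteo"]), 55)
  expect_lte(max(ages[groups == "group1_osteo"]), 90)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(arm_correlation = 1.5), "arm_correlation")
  expect_error(sim_params(effect_amplitude = -1), "effect_amplitude")
  expect_error(sim_params(noise_sd = -1), "noise_sd")
  expect_error(sim_params(n_group1 = -1), "group sizes")
})
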