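test_that("zero-noise measurement equals the simulated curve, reproducibly", {
  sch <- default_schedule()
  tis <- phantom_presets()$SiliconeOil
  flips <- c(10, 30, 60)
  ms <- generate_measurement(tis, psi = 117, sch, flips = flips,
                             noise_sigma = 0, roi_voxel_count = 1, seed = 5)
  truth <- signal_curve(sch, tis, spoiling_scheme(117), flips)
  expect_equal(ms$signal_mean, truth$s_plus, tolerance = 1e-14)

  msa <- generate_measurement(tis, psi = 117, sch, flips = flips,
                              noise_sigma = 0.01, roi_voxel_count = 20, seed = 9)
  msb <- generate_measurement(tis, psi = 117, sch, flips = flips,
                              noise_sigma = 0.01, roi_voxel_count = 20, seed = 9)
  expect_identical(msa$signal_mean, msb$signal_mean)
})

test_that("ROI mean of pure noise matches the Rician (Rayleigh) closed form", {
  # zero true signal: magnitude is Rayleigh with mean sigma sqrt(pi/2)
  sigma <- 0.01; nvox <- 1e4
  set.seed(11)
  roi <- mean(sqrt(stats::rnorm(nvox, 0, sigma)^2 + stats::rnorm(nvox, 0, sigma)^2))
  expected <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt((4 - pi) / 2) / sqrt(nvox)
  expect_lt(abs(roi - expected), 3 * se)
})

test_that("Ernst-angle normalization picks the nearest measured flip", {
  sch <- default_schedule()
  pre <- phantom_presets()
  ms_h2o <- generate_measurement(pre$H2O_CuSO4, psi = 117, sch,
                                 noise_sigma = 0, seed = 1)
  n_h2o <- normalize_at_ernst(ms_h2o, 20 / 540)     # alpha_E = 15.5 deg
  expect_equal(attr(n_h2o, "norm_flip"), 15)
  expect_equal(n_h2o$signal_mean[n_h2o$flip_deg == 15], 1)

  ms_oil <- generate_measurement(pre$SiliconeOil, psi = 117, sch,
                                 noise_sigma = 0, seed = 1)
  n_oil <- normalize_at_ernst(ms_oil, 20 / 1290)    # alpha_E = 10.1 deg
  expect_equal(attr(n_oil, "norm_flip"), 10)

  # idempotence
  again <- normalize_at_ernst(n_oil, 20 / 1290)
  expect_equal(again$signal_mean, n_oil$signal_mean)

  # a grid missing the Ernst-angle region cannot be normalized
  ms_far <- generate_measurement(pre$SiliconeOil, psi = 117, sch,
                                 flips = seq(30, 90, 10), noise_sigma = 0, seed = 1)
  expect_error(normalize_at_ernst(ms_far, 20 / 1290), "Ernst angle")
})

test_that("measured-vs-simulated residuals vanish without noise and shrink with ROI size", {
  sch <- default_schedule()
  tis <- phantom_presets()$H2O_CuSO4
  flips <- seq(5, 90, 5)
  sim <- signal_curve(sch, tis, spoiling_scheme(169), flips)

  ms0 <- generate_measurement(tis, psi = 169, sch, flips = flips,
                              noise_sigma = 0, seed = 2)
  r0 <- compare_measured_simulated(ms0, sim, tr_over_t1 = 20 / 540)
  expect_lt(r0$mean_abs_rel, 1e-12)
  expect_lt(r0$max_abs_rel, 1e-12)

  # Monte Carlo scaling: residual ~ 1/sqrt(roi). Checked on the high-signal
  # part of the curve where the (roi-independent) Rician bias is negligible.
  flips_hi <- seq(10, 45, 5)
  sim_hi <- signal_curve(sch, tis, spoiling_scheme(169), flips_hi)
  ms_small <- generate_measurement(tis, psi = 169, sch, flips = flips_hi,
                                   noise_sigma = 0.002, roi_voxel_count = 50, seed = 3)
  ms_big <- generate_measurement(tis, psi = 169, sch, flips = flips_hi,
                                 noise_sigma = 0.002, roi_voxel_count = 5000, seed = 3)
  r_small <- compare_measured_simulated(ms_small, sim_hi, tr_over_t1 = 20 / 540)
  r_big <- compare_measured_simulated(ms_big, sim_hi, tr_over_t1 = 20 / 540)
  expect_gt(r_small$mean_abs_rel / r_big$mean_abs_rel, 3)
})

test_that("pipeline consistency: measurement-derived epsilon equals direct epsilon", {
  sch <- default_schedule()
  tis <- phantom_presets()$H2O_CuSO4
  ms <- generate_measurement(tis, psi = 115.4, sch, noise_sigma = 0, seed = 4)
  msn <- normalize_at_ernst(ms, 20 / 540)
  eps_pipe <- epsilon_from_measurement(msn, 115.4, 20 / 540)
  eps_direct <- epsilon_for(sch, tis, spoiling_scheme(115.4))
  expect_equal(eps_pipe, eps_direct, tolerance = 1e-9)
})

test_that("epsilon from realistically noisy measurements stays within one point", {
  sch <- default_schedule()
  pre <- phantom_presets()
  for (nm in c("H2O_CuSO4", "SiliconeOil")) {
    tis <- pre[[nm]]
    ms <- generate_measurement(tis, psi = vendor_psis, sch,
                               noise_sigma = 0.005, roi_voxel_count = 500,
                               seed = 20)
    msn <- normalize_at_ernst(ms, 20 / tis$t1)
    for (p in vendor_psis) {
      noisy <- epsilon_from_measurement(msn, p, 20 / tis$t1)
      clean <- epsilon_for(sch, tis, spoiling_scheme(p))
      expect_lt(abs(noisy - clean), 1)
    }
  }
})
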