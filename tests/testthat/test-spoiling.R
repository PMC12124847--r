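test_that("Ernst amplitude matches the saturation-recovery recursion", {
  expect_equal(ernst_amplitude(0.05, 0), 0)
  expect_equal(ernst_amplitude(50, 90), 1, tolerance = 1e-12)
  expect_equal(ernst_amplitude(0.05, 30), ernst_recursion(0.05, 30),
               tolerance = 1e-10)
  expect_equal(ernst_amplitude(0.2, 75, m0 = 2), ernst_recursion(0.2, 75, m0 = 2),
               tolerance = 1e-10)
})

test_that("Ernst angle maximizes the Ernst amplitude", {
  expect_lt(ernst_angle(1e-6), 0.1)
  for (r in c(0.01, 0.05, 0.5)) {
    amax <- stats::optimize(function(a) ernst_amplitude(r, a),
                            c(0.01, 90), maximum = TRUE)$maximum
    expect_equal(ernst_angle(r), amax, tolerance = 1e-3)
  }
})

test_that("epsilon: zero at the Ernst curve, constant relative offset, guards", {
  flips <- seq(5, 90, 5)
  se <- ernst_amplitude(0.05, flips)
  expect_equal(epsilon(data.frame(flip_deg = flips, s_plus = se), 0.05), 0)
  expect_equal(epsilon(data.frame(flip_deg = flips, s_plus = 1.1 * se), 0.05),
               10, tolerance = 1e-10)
  set.seed(1)
  expect_gt(epsilon(data.frame(flip_deg = flips, s_plus = se * runif(18, 0.9, 1.1)),
                    0.05), 0)
  expect_error(epsilon(data.frame(flip_deg = c(0, flips), s_plus = c(0, se)), 0.05),
               "undefined")
})

test_that("grid sweep: single-cell consistency and TR-invariance at D=0", {
  cfg <- sweep_config(psi = 117, log10_t1_tr = 1.0, log10_t2_tr = 0.8,
                      tr = c(20, 50))
  g <- grid_sweep(cfg)
  expect_equal(nrow(g), 2L)
  direct <- epsilon_for(gre_protocol(tr = 20, te = 4),
                        tissue_params(10 * 20, 10^0.8 * 20, d = 0),
                        spoiling_scheme(117))
  expect_equal(g$epsilon[g$tr == 20], direct, tolerance = 1e-12)
  # with D = 0 the signal depends on the ratios only, not on TR
  expect_equal(g$epsilon[g$tr == 20], g$epsilon[g$tr == 50], tolerance = 1e-9)
})

test_that("grid sweep masks T2 > T1 cells and has the documented axes", {
  cfg <- sweep_config()
  expect_length(cfg$log10_t1_tr, 34L)
  expect_length(cfg$log10_t2_tr, 34L)
  small <- sweep_config(psi = 117, log10_t1_tr = c(0, 0.5),
                        log10_t2_tr = c(0, 0.5))
  g <- grid_sweep(small)
  expect_equal(nrow(g), 3L)  # the T2 > T1 cell is absent
  expect_true(all(round(10 * g$log10_t2_tr) <= round(10 * g$log10_t1_tr)))
  expect_true(all(g$epsilon >= 0))
})

test_that("grid sweep caching resumes from disk without recomputation", {
  cache <- tempfile(fileext = ".csv")
  cfg <- sweep_config(psi = c(117, 169), log10_t1_tr = 0.5, log10_t2_tr = 0.3)
  g1 <- grid_sweep(cfg, cache_path = cache)
  expect_true(file.exists(cache))
  n_rows <- nrow(utils::read.csv(cache))
  expect_equal(n_rows, nrow(g1))
  g2 <- grid_sweep(cfg, cache_path = cache)   # all cells served from cache
  expect_equal(g2$epsilon, g1$epsilon)
  expect_equal(nrow(utils::read.csv(cache)), n_rows)
})

test_that("voxel-size sweep reproduces the unscaled cell and is flat at D=0", {
  sch <- default_schedule()
  tis0 <- tissue_params(540, 340, d = 0)
  cfg <- sweep_config(psi = 115.4, voxel_sizes = c(0.15, 0.30, 0.60))
  vs <- voxel_size_sweep(cfg, tis0, sch)
  expect_equal(vs$voxel_mm, c(0.15, 0.30, 0.60))
  direct <- epsilon_for(sch, tis0, spoiling_scheme(115.4))
  expect_equal(vs$epsilon[vs$voxel_mm == 0.30], direct, tolerance = 1e-12)
  expect_lt(diff(range(vs$epsilon)), 1e-9)  # no diffusion => no gradient effect
})

test_that("best-psi map picks the cellwise argmin with ties toward smaller psi", {
  g <- data.frame(log10_t1_tr = rep(c(1, 2), each = 3),
                  log10_t2_tr = rep(c(1, 2), each = 3),
                  psi = rep(c(169, 50, 117), 2), d = 0, tr = 20,
                  epsilon = c(2, 1, 3, 4, 4, 5))
  bp <- best_psi_map(g)
  expect_equal(bp$best_psi[bp$log10_t1_tr == 1], 50)
  expect_equal(bp$best_psi[bp$log10_t1_tr == 2], 50)   # tie 50 vs 169 -> 50
  expect_equal(bp$epsilon, c(1, 4))
})

test_that("substance table computes both diffusion columns consistently", {
  subs <- list(ref20 = ratio_params(20), gm = phantom_presets()$GreyMatter3T)
  tab <- substance_table(subs, psi = c(115.4, 169), trs = 20)
  # ratio substance has D = 0: no with-diffusion rows for it
  expect_equal(sum(tab$substance == "ref20"), 2L)
  expect_equal(sum(tab$substance == "gm"), 4L)
  expect_true(all(tab$epsilon >= 0))
  gm_nd <- tab[tab$substance == "gm" & !tab$diffusion & tab$psi_deg == 169, ]
  direct <- epsilon_for(default_schedule(), tissue_params(1500, 100, d = 0),
                        spoiling_scheme(169))
  expect_equal(gm_nd$epsilon, direct, tolerance = 1e-12)
})
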