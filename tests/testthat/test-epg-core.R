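test_that("rf_rotation handles identity, inversion and 90-degree excitation", {
  st <- epg_states()
  expect_identical(rf_rotation(st, 0, 123)$z[1], complex(real = 1))
  expect_equal(Mod(rf_rotation(st, 0, 123)$fp[1]), 0)

  inv <- rf_rotation(st, 180, 0)
  expect_equal(Re(inv$z[1]), -1, tolerance = 1e-12)
  expect_lt(Mod(inv$fp[1]), 1e-12)

  phase <- 37
  ex <- rf_rotation(st, 90, phase)
  expect_equal(Mod(ex$fp[1]), 1, tolerance = 1e-12)
  expect_lt(Mod(ex$z[1]), 1e-12)

  # brute-force oracle: rotate a uniform isochromat ensemble at equilibrium
  # with the 3x3 real rotation Rz(phi) Rx(alpha) Rz(-phi) and Fourier-average
  m <- 64L
  theta <- -pi + (1:m) * 2 * pi / m
  a <- 90 * pi / 180; p <- phase * pi / 180
  rz <- function(g) matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  rx <- function(g) matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3, 3)
  rot <- rz(p) %*% rx(a) %*% rz(-p)
  vecs <- matrix(rot %*% c(0, 0, 1), 3, m)  # all isochromats start at M0 z
  mxy <- complex(real = vecs[1, ], imaginary = vecs[2, ])
  f0_oracle <- mean(mxy)                       # zero-order Fourier coefficient
  expect_equal(Mod(f0_oracle), Mod(ex$fp[1]), tolerance = 1e-12)
  f1_oracle <- mean(mxy * exp(-1i * theta))    # order 1 must be empty
  expect_lt(Mod(f1_oracle), 1e-12)
})

test_that("rf_rotation rejects out-of-range flip angles", {
  st <- epg_states()
  expect_error(rf_rotation(st, -1), "flip")
  expect_error(rf_rotation(st, 181), "flip")
})

test_that("conjugate-symmetry convention survives random operator sequences", {
  set.seed(42)
  iv <- schedule_to_intervals(default_schedule())
  tis <- tissue_params(300, 120, d = 1e-3)
  st <- epg_states(dephasing_per_tr = attr(iv, "quantum"))
  for (i in 1:25) {
    st <- rf_rotation(st, runif(1, 5, 170), runif(1, 0, 360))
    for (k in seq_along(iv)) st <- evolve_interval(st, iv[[k]], tis)
    expect_equal(st$fm[1], Conj(st$fp[1]), tolerance = 1e-12)
    expect_lt(abs(Im(st$z[1])), 1e-12)
    expect_true(all(Mod(st$fp) <= 1 + 1e-9))   # physicality from equilibrium
    expect_true(all(Mod(st$z) <= 1 + 1e-9))
  }
})

test_that("shift re-indexes orders, conserves energy and composes", {
  # populate a few orders through pulses and shifts
  st <- epg_states()
  st <- rf_rotation(st, 60, 10)
  st <- shift_states(st, 1L)
  st <- rf_rotation(st, 45, 200)
  e0 <- epgspoil:::transverse_energy(st)

  expect_identical(shift_states(st, 0L), st)

  two_units <- shift_states(shift_states(st, 1L), 1L)
  one_double <- shift_states(st, 2L)
  expect_equal(two_units$fp, one_double$fp, tolerance = 1e-14)
  expect_equal(two_units$fm, one_double$fm, tolerance = 1e-14)

  expect_equal(epgspoil:::transverse_energy(one_double), e0, tolerance = 1e-14)

  # shifting down again restores the original spectrum
  back <- shift_states(one_double, -2L)
  n <- st$max_order + 1
  expect_equal(back$fp[1:n], st$fp[1:n], tolerance = 1e-14)
  expect_equal(back$fm[1:n], st$fm[1:n], tolerance = 1e-14)
})

test_that("truncate drops sub-floor orders and leaves the signal unchanged", {
  st <- epg_states()
  st <- rf_rotation(st, 60, 0)
  st <- shift_states(st, 2L)
  expect_identical(truncate_states(st, 0), st)

  tiny <- epg_states(max_order = 3)
  tiny$fp[3] <- 1e-15
  expect_equal(truncate_states(tiny, 1e-12)$max_order, 0L)

  sch <- default_schedule()
  zur <- ratio_params(20)
  a <- steady_state_signal(sch, zur, spoiling_scheme(117), 30, floor_amp = 1e-12)
  b <- steady_state_signal(sch, zur, spoiling_scheme(117), 30, floor_amp = 0)
  expect_equal(a$s_plus, b$s_plus, tolerance = 1e-9)
})

test_that("evolve_interval without diffusion is pure relaxation and regrowth", {
  tis <- tissue_params(1000, 100, d = 0)
  st <- epg_states(max_order = 2, dephasing_per_tr = c(10, 5))
  st$fp[2] <- 0.3 + 0.1i; st$fm[2] <- 0.2i; st$z[2] <- 0.1; st$z[1] <- 0.5
  out <- evolve_interval(st, evolution_interval(duration = 50), tis)
  expect_equal(out$fp[2], (0.3 + 0.1i) * exp(-50 / 100), tolerance = 1e-14)
  expect_equal(out$fm[2], 0.2i * exp(-50 / 100), tolerance = 1e-14)
  expect_equal(Re(out$z[2]), 0.1 * exp(-50 / 1000), tolerance = 1e-14)
  expect_equal(Re(out$z[1]), 0.5 * exp(-50 / 1000) + (1 - exp(-50 / 1000)),
               tolerance = 1e-14)
})

test_that("diffusion attenuation matches the b-value quadrature oracle", {
  q <- c(10, 4)  # rad/mm per order, readout / slice
  d <- 1.5e-3
  t1 <- 5000; t2 <- 2000
  tis <- tissue_params(t1, t2, d = d)

  # gap: longitudinal order k at constant spatial frequency
  st <- epg_states(max_order = 2, dephasing_per_tr = q)
  st$z[3] <- 0.4
  out <- evolve_interval(st, evolution_interval(duration = 8), tis)
  b_gap <- (8 / 1000) * ((2 * q[1])^2 + (2 * q[2])^2)
  expect_equal(Re(out$z[3]), 0.4 * exp(-8 / t1) * exp(-b_gap * d),
               tolerance = 1e-12)

  # lobe: transverse order runs linearly from k1 to k2; oracle integrates k(t)^2
  tau <- 2.5
  mom <- c(-14, 6)
  kst <- c(3, -1)
  st <- single_order_state(1, amp = 0.7 + 0.2i, quantum = q)
  out <- evolve_interval(st, evolution_interval(tau, moment = mom, k_start = kst),
                         tis)
  b_or <- bval_quadrature(q[1] + kst[1], q[1] + kst[1] + mom[1], tau) +
          bval_quadrature(q[2] + kst[2], q[2] + kst[2] + mom[2], tau)
  expect_equal(Mod(out$fp[2]), Mod(0.7 + 0.2i) * exp(-tau / t2) * exp(-b_or * d),
               tolerance = 1e-9)

  # negative order sees the mirrored trajectory (crosses k = 0 here)
  stn <- single_order_state(-1, amp = 0.5, quantum = q)
  outn <- evolve_interval(stn, evolution_interval(tau, moment = c(14, 2),
                                                  k_start = c(0, 0)), tis)
  b_or_n <- bval_quadrature(-q[1], -q[1] + 14, tau) +
            bval_quadrature(-q[2], -q[2] + 2, tau)
  expect_equal(Mod(outn$fm[2]), 0.5 * exp(-tau / t2) * exp(-b_or_n * d),
               tolerance = 1e-9)
})

test_that("fractional interval moment without declared re-indexing errors", {
  st <- epg_states(dephasing_per_tr = c(10, 5))
  tis <- tissue_params(1000, 500)
  iv <- evolution_interval(1, moment = c(3, 1.5), shift = NA_integer_)
  expect_error(evolve_interval(st, iv, tis), "integer multiple")
  iv_ok <- evolution_interval(1, moment = c(10, 5), shift = NA_integer_)
  expect_silent(evolve_interval(st, iv_ok, tis))
})
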