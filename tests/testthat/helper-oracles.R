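# Shared fixtures and independent oracles for the test suite.

default_schedule <- function(tr = 20, te = 4, ...) gre_protocol(tr = tr, te = te, ...)

vendor_psis <- c(50, 115.4, 117, 150, 169)

# numerical-quadrature oracle for the diffusion b-value of a piecewise-linear
# spatial-frequency trajectory k(t) from k1 to k2 over tau_ms (rad/mm, ms):
# fine trapezoidal integration of k(t)^2
bval_quadrature <- function(k1, k2, tau_ms, n = 200001L) {
  t <- seq(0, 1, length.out = n)
  k2t <- (k1 + (k2 - k1) * t)^2
  w <- rep(1, n); w[c(1, n)] <- 0.5
  (tau_ms / 1000) * sum(w * k2t) / (n - 1)
}

# drive a pulse train through the pure-R operator layer; returns the
# demodulated complex F0 after each pulse
drive_tr_r <- function(schedule, tissue, scheme, flip, npulse) {
  iv <- schedule_to_intervals(schedule)
  st <- epg_states(dephasing_per_tr = attr(iv, "quantum"), m0 = tissue$m0)
  f0 <- complex(length.out = npulse)
  for (n in 0:(npulse - 1L)) {
    phi <- quadratic_phase(scheme, n)
    st <- rf_rotation(st, flip, phi)
    f0[n + 1L] <- st$fp[1] * exp(-1i * phi * pi / 180)
    for (k in seq_along(iv)) st <- evolve_interval(st, iv[[k]], tissue)
  }
  f0
}

# scalar saturation-recovery recursion: independent route to the ideally
# spoiled steady-state amplitude (no transverse history at all)
ernst_recursion <- function(tr_over_t1, flip_deg, m0 = 1, iters = 10000L) {
  e1 <- exp(-tr_over_t1)
  a <- flip_deg * pi / 180
  mz <- m0
  for (i in seq_len(iters)) mz <- mz * cos(a) * e1 + m0 * (1 - e1)
  mz * sin(a)
}

# build an epg_states object holding a single transverse order
single_order_state <- function(k, amp = 1, quantum = c(10, 5)) {
  st <- epg_states(max_order = abs(k), dephasing_per_tr = quantum)
  st$z[1] <- 0
  if (k >= 0) st$fp[k + 1] <- amp else st$fm[abs(k) + 1] <- Conj(amp)
  st
}

eps_tolerance <- function(printed) pmax(0.15, 0.03 * printed)
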