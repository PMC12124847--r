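#' Configuration-state set for extended-phase-graph simulation
#'
#' Creates the EPG state container: complex transverse configuration
#' amplitudes \eqn{F_k} for orders \eqn{k \in [-K, K]} and longitudinal
#' amplitudes \eqn{Z_k} for \eqn{k \in [0, K]}, all expressed as fractions of
#' the equilibrium magnetization \eqn{M_0}. Negative transverse orders are
#' stored explicitly via the conjugate convention: slot \code{fm[k+1]} holds
#' \eqn{\tilde F_k = F_{-k}^*}, so \code{fm[1] == Conj(fp[1])} at all times.
#'
#' @param max_order initial maximum configuration order K (storage grows as
#'   needed).
#' @param dephasing_per_tr named numeric of length 2, \code{c(readout=, slice=)}:
#'   spatial-frequency increment of one configuration order per axis (rad/mm).
#'   Both axes repeat identically every TR, so a single integer order indexes
#'   a two-component spatial frequency.
#' @param m0 equilibrium magnetization (dimensionless scale).
#' @return object of class \code{epg_states} with elements \code{fp},
#'   \code{fm}, \code{z} (complex vectors of length K+1), \code{max_order},
#'   \code{dephasing_per_tr}, \code{m0}. At construction the set is at thermal
#'   equilibrium: \eqn{Z_0 = M_0}, everything else zero.
#' @export
epg_states <- function(max_order = 0L,
                       dephasing_per_tr = c(readout = 0, slice = 0),
                       m0 = 1) {
  stopifnot(max_order >= 0, m0 > 0, length(dephasing_per_tr) == 2)
  k <- as.integer(max_order)
  st <- list(
    fp = complex(length.out = k + 1L),
    fm = complex(length.out = k + 1L),
    z  = complex(length.out = k + 1L),
    max_order = k,
    dephasing_per_tr = dephasing_per_tr,
    m0 = m0
  )
  st$z[1] <- complex(real = m0)
  structure(st, class = "epg_states")
}

#' @export
print.epg_states <- function(x, ...) {
  cat(sprintf("<epg_states> K = %d, m0 = %g\n", x$max_order, x$m0))
  cat(sprintf("  |F0| = %.6g, Z0 = %.6g, sum|F|^2 = %.6g\n",
              Mod(x$fp[1]), Re(x$z[1]), transverse_energy(x)))
  invisible(x)
}

# total transverse energy sum_k |F_k|^2 over the full spectrum
# (orders -K..K; order 0 counted once)
transverse_energy <- function(states) {
  sum(Mod(states$fp)^2) + sum(Mod(states$fm[-1])^2)
}

#' Apply an RF pulse to a configuration-state set
#'
#' Mixes every order triple \eqn{(F_k, F_{-k}^*, Z_k)} by the standard 3x3
#' EPG pulse operator parameterized by flip angle and pulse phase. The order
#' index is unchanged.
#'
#' @param states an \code{epg_states} object.
#' @param flip flip angle in degrees, in \code{[0, 180]}.
#' @param phase pulse phase in degrees.
#' @return the rotated \code{epg_states}.
#' @export
rf_rotation <- function(states, flip, phase = 0) {
  if (!is.finite(flip) || flip < 0 || flip > 180)
    stop("flip angle must be in [0, 180] degrees", call. = FALSE)
  a  <- flip * pi / 180
  ei <- exp(1i * phase * pi / 180)
  cc <- cos(a / 2)^2; ss <- sin(a / 2)^2
  sa <- sin(a); ca <- cos(a)
  fp <- states$fp; fm <- states$fm; z <- states$z
  states$fp <- cc * fp + ss * ei^2 * fm - 1i * ei * sa * z
  states$fm <- ss * Conj(ei)^2 * fp + cc * fm + 1i * Conj(ei) * sa * z
  states$z  <- -0.5i * Conj(ei) * sa * fp + 0.5i * ei * sa * fm + ca * z
  states
}

#' One evolution interval: relaxation, regrowth, diffusion, gradient action
#'
#' Describes a piecewise-constant segment of the repetition interval. The
#' \code{moment} is the dephasing the interval adds per axis (rad/mm);
#' \code{k_start} is the intra-TR spatial-frequency offset per axis already
#' accumulated at the start of the interval by the zero-order transverse
#' pathway (fractional bookkeeping between re-indexing boundaries).
#'
#' @param duration interval duration in ms (>= 0).
#' @param moment numeric length-2, dephasing added per axis in rad/mm;
#'   a gap has zero moment.
#' @param k_start numeric length-2, intra-TR offset at interval start (rad/mm).
#' @param shift integer number of whole configuration-order quanta by which
#'   states are re-indexed at the end of the interval, or \code{NA} to derive
#'   it from \code{moment} (which must then be an integer multiple of the
#'   per-TR quantum).
#' @return object of class \code{evolution_interval}.
#' @export
evolution_interval <- function(duration, moment = c(0, 0), k_start = c(0, 0),
                               shift = 0L) {
  stopifnot(duration >= 0, length(moment) == 2, length(k_start) == 2)
  structure(list(duration = duration, moment = as.numeric(moment),
                 k_start = as.numeric(k_start), shift = shift),
            class = "evolution_interval")
}

# b-value (s/mm^2) of a spatial-frequency trajectory running linearly from k1
# to k2 (rad/mm) over tau milliseconds: tau * (k1^2 + k1 k2 + k2^2) / 3.
bvalue_linear <- function(k1, k2, tau_ms) {
  (tau_ms / 1000) * (k1^2 + k1 * k2 + k2^2) / 3
}

#' Evolve a configuration-state set through one interval
#'
#' Applies T2 decay to the transverse orders, T1 decay with regrowth of
#' \eqn{Z_0} toward equilibrium, diffusion attenuation \eqn{e^{-bD}} per
#' order with the b-value of each order's piecewise-linear spatial-frequency
#' trajectory (summed over the readout and slice axes), and finally the
#' integer re-indexing carried by the interval.
#'
#' Transverse order \eqn{m} travels from \eqn{k_1 = m q + c} to
#' \eqn{k_2 = k_1 + \delta} per axis (q = order quantum, c = intra-TR offset,
#' \eqn{\delta} = interval moment), giving
#' \eqn{b = \tau (k_1^2 + k_1 k_2 + k_2^2)/3}; a longitudinal order sits at
#' constant \eqn{k = m q}, giving \eqn{b = \tau k^2}.
#'
#' @param states an \code{epg_states} object.
#' @param interval an \code{evolution_interval}.
#' @param tissue a \code{tissue_params} object (T1 >= T2 > 0, D >= 0).
#' @return the evolved \code{epg_states}.
#' @export
evolve_interval <- function(states, interval, tissue) {
  stopifnot(inherits(interval, "evolution_interval"),
            inherits(tissue, "tissue_params"))
  tau <- interval$duration
  e2 <- exp(-tau / tissue$t2); e1 <- exp(-tau / tissue$t1)
  states$fp <- states$fp * e2
  states$fm <- states$fm * e2
  states$z  <- states$z * e1
  states$z[1] <- states$z[1] + states$m0 * (1 - e1)

  if (tissue$d > 0 && tau > 0) {
    m <- 0:states$max_order
    q <- states$dephasing_per_tr
    b_fp <- b_fm <- b_z <- numeric(length(m))
    for (ax in 1:2) {
      k1p <- m * q[ax] + interval$k_start[ax]
      k1m <- -m * q[ax] + interval$k_start[ax]
      d   <- interval$moment[ax]
      b_fp <- b_fp + bvalue_linear(k1p, k1p + d, tau)
      b_fm <- b_fm + bvalue_linear(k1m, k1m + d, tau)
      b_z  <- b_z + (tau / 1000) * (m * q[ax])^2
    }
    states$fp <- states$fp * exp(-b_fp * tissue$d)
    states$fm <- states$fm * exp(-b_fm * tissue$d)
    states$z  <- states$z * exp(-b_z * tissue$d)
  }

  n_shift <- interval$shift
  if (is.na(n_shift)) {
    q <- states$dephasing_per_tr
    ax <- which(abs(q) > 0)
    if (length(ax) == 0) {
      n_shift <- 0L
    } else {
      units <- interval$moment[ax] / q[ax]
      if (any(abs(units - round(units[1])) > 1e-9))
        stop("interval moment is not an integer multiple of the per-TR quantum",
             call. = FALSE)
      n_shift <- as.integer(round(units[1]))
    }
  }
  if (n_shift != 0L) states <- shift_states(states, n_shift)
  states
}

#' Re-index transverse configuration orders
#'
#' Moves every transverse order by \code{n_units} quanta
#' (\eqn{F_k \to F_{k+n}}), handling the crossing through order zero by the
#' conjugate convention. Longitudinal orders are unaffected. Storage grows as
#' needed; the total transverse energy is conserved.
#'
#' @param states an \code{epg_states} object.
#' @param n_units signed integer shift.
#' @return the shifted \code{epg_states}.
#' @export
shift_states <- function(states, n_units) {
  n_units <- as.integer(n_units)
  if (n_units == 0L) return(states)
  k <- states$max_order
  # work on the full spectrum F_{-K-|n|} .. F_{K+|n|}
  pad <- abs(n_units)
  kk <- k + pad
  full <- complex(length.out = 2L * kk + 1L)        # index i -> order i - kk - 1
  full[(kk + 1L):(2L * kk + 1L)] <- c(states$fp, complex(length.out = pad))
  if (k >= 1L)  # orders -1 .. -k from the conjugate store
    full[kk + 1L - seq_len(k)] <- Conj(states$fm[2:(k + 1L)])
  shifted <- complex(length.out = 2L * kk + 1L)
  src <- seq_along(full) - n_units
  ok <- src >= 1L & src <= length(full)
  shifted[ok] <- full[src[ok]]
  states$fp <- shifted[(kk + 1L):(2L * kk + 1L)]
  states$fm <- c(Conj(shifted[kk + 1L]),
                 if (kk >= 1L) Conj(shifted[kk:1L]) else complex(0))
  states$z <- c(states$z, complex(length.out = pad))
  states$max_order <- kk
  states
}

#' Drop configuration orders below an amplitude floor
#'
#' Reduces K by removing trailing orders whose transverse and longitudinal
#' amplitudes are all below \code{amplitude_floor}.
#'
#' @param states an \code{epg_states} object.
#' @param amplitude_floor non-negative threshold (fraction of \eqn{M_0}).
#' @return the truncated \code{epg_states}.
#' @export
truncate_states <- function(states, amplitude_floor = 1e-12) {
  stopifnot(amplitude_floor >= 0)
  k <- states$max_order
  while (k > 0L &&
         Mod(states$fp[k + 1L]) < amplitude_floor &&
         Mod(states$fm[k + 1L]) < amplitude_floor &&
         Mod(states$z[k + 1L]) < amplitude_floor) {
    k <- k - 1L
  }
  states$fp <- states$fp[1:(k + 1L)]
  states$fm <- states$fm[1:(k + 1L)]
  states$z  <- states$z[1:(k + 1L)]
  states$max_order <- k
  states
}
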