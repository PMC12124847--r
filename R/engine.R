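# Precompute per-interval diffusion attenuation factors exp(-b D) for
# transverse orders +m / -m and longitudinal orders m, m = 0..kmax.
# Returns list(fp, fm, z): matrices n_intervals x (kmax + 1).
attenuation_tables <- function(intervals, tissue, kmax) {
  q <- attr(intervals, "quantum")
  nint <- length(intervals)
  m <- 0:kmax
  att_fp <- att_fm <- att_z <- matrix(1, nint, kmax + 1L)
  if (tissue$d > 0) {
    for (i in seq_len(nint)) {
      iv <- intervals[[i]]
      b_fp <- b_fm <- b_z <- numeric(kmax + 1L)
      for (ax in 1:2) {
        k1p <- m * q[ax] + iv$k_start[ax]
        k1m <- -m * q[ax] + iv$k_start[ax]
        b_fp <- b_fp + bvalue_linear(k1p, k1p + iv$moment[ax], iv$duration)
        b_fm <- b_fm + bvalue_linear(k1m, k1m + iv$moment[ax], iv$duration)
        b_z  <- b_z + (iv$duration / 1000) * (m * q[ax])^2
      }
      att_fp[i, ] <- exp(-b_fp * tissue$d)
      att_fm[i, ] <- exp(-b_fm * tissue$d)
      att_z[i, ]  <- exp(-b_z * tissue$d)
    }
  }
  list(fp = att_fp, fm = att_fm, z = att_z)
}

# Run the compiled EPG propagation for one flip angle and return the raw
# demodulated F0 traces (complex, one entry per pulse).
epg_traces <- function(schedule, tissue, scheme, flip, npulse,
                       floor_amp = 1e-12) {
  intervals <- schedule_to_intervals(schedule)
  e2 <- vapply(intervals, function(iv) exp(-iv$duration / tissue$t2), 0)
  e1 <- vapply(intervals, function(iv) exp(-iv$duration / tissue$t1), 0)
  use_att <- tissue$d > 0
  if (use_att) {
    att <- attenuation_tables(intervals, tissue, kmax = npulse + 1L)
  } else {
    att <- list(fp = matrix(1, 1, 1), fm = matrix(1, 1, 1), z = matrix(1, 1, 1))
  }
  res <- epg_propagate_cpp(npulse, flip * pi / 180, scheme$psi,
                           e2, e1, att$fp, att$fm, att$z, use_att,
                           attr(intervals, "te_boundary"), tissue$m0, floor_amp)
  res
}

# Default convergence policy: pulse count max(2000, 10 T1/TR), magnitude
# averaged over the final `navg` pulses.
default_npulse <- function(tissue, tr) max(2000L, as.integer(ceiling(10 * tissue$t1 / tr)))

#' Pseudo-steady-state signal of the RF-spoiled GRE sequence
#'
#' Drives the EPG configuration states over many repetitions with the
#' quadratic phase cycle and reports the converged signal magnitudes:
#' \describe{
#'   \item{s_plus}{magnitude of the demodulated zero-order transverse
#'     configuration immediately after the pulse — the flip-angle response
#'     that the spoiling-quality metric compares against the Ernst curve.}
#'   \item{s_echo}{the same pathway sampled at TE, i.e. including T2 decay
#'     between excitation and echo and the diffusion attenuation of the
#'     readout excursion (what a scanner records up to a global T2* factor).}
#'   \item{s_minus}{magnitude at the end of the repetition interval, just
#'     before the next pulse.}
#' }
#' Because the quadratically cycled magnitude can micro-oscillate, each value
#' is the mean over the final \code{navg} pulses; the peak-to-peak residual
#' over that window is reported and a warning is issued when it exceeds
#' \code{1e-4 * m0}.
#'
#' @param schedule a \code{tr_schedule}.
#' @param tissue a \code{tissue_params}.
#' @param scheme a \code{spoiling_scheme}.
#' @param flip flip angle in degrees, in (0, 180].
#' @param npulse number of pulses; default \code{max(2000, 10 T1/TR)}.
#' @param navg averaging window (pulses).
#' @param floor_amp truncation floor for configuration orders (fraction of m0).
#' @return list with \code{s_plus}, \code{s_minus}, \code{s_echo},
#'   \code{npulse}, \code{residual}, \code{converged}.
#' @export
steady_state_signal <- function(schedule, tissue, scheme, flip,
                                npulse = NULL, navg = 100L, floor_amp = 1e-12) {
  stopifnot(inherits(schedule, "tr_schedule"), inherits(tissue, "tissue_params"),
            inherits(scheme, "spoiling_scheme"))
  if (!is.finite(flip) || flip <= 0 || flip > 180)
    stop("flip must be in (0, 180] degrees", call. = FALSE)
  if (is.null(npulse)) npulse <- default_npulse(tissue, schedule$tr)
  npulse <- max(npulse, navg)
  tr <- epg_traces(schedule, tissue, scheme, flip, npulse, floor_amp)
  w <- (npulse - navg + 1L):npulse
  mp <- Mod(tr$f0_pulse[w])
  res <- diff(range(mp))
  conv <- res <= 1e-4 * tissue$m0
  if (!conv)
    warning(sprintf("steady-state residual %.3g exceeds 1e-4 m0 (flip %g, psi %g)",
                    res, flip, scheme$psi), call. = FALSE)
  list(s_plus = mean(mp),
       s_minus = mean(Mod(tr$f0_end[w])),
       s_echo = mean(Mod(tr$f0_te[w])),
       npulse = npulse, residual = res, converged = conv)
}

#' Steady-state signal across a flip-angle grid
#'
#' Element-wise \code{\link{steady_state_signal}} over \code{flips}.
#'
#' @inheritParams steady_state_signal
#' @param flips flip angles in degrees (default 5..90 in 5-degree steps).
#' @return a \code{signal_curve} data frame with columns \code{flip_deg},
#'   \code{s_plus}, \code{s_minus}, \code{s_echo}, \code{psi_deg},
#'   \code{npulse}, \code{residual}, \code{converged}.
#' @export
signal_curve <- function(schedule, tissue, scheme, flips = seq(5, 90, by = 5),
                         npulse = NULL, navg = 100L, floor_amp = 1e-12) {
  stopifnot(length(flips) > 0)
  rows <- lapply(flips, function(a) {
    s <- steady_state_signal(schedule, tissue, scheme, a, npulse, navg, floor_amp)
    data.frame(flip_deg = a, s_plus = s$s_plus, s_minus = s$s_minus,
               s_echo = s$s_echo, psi_deg = scheme$psi,
               npulse = s$npulse, residual = s$residual, converged = s$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("signal_curve", "data.frame")
  out
}

#' Write a signal curve as CSV with a metadata sidecar
#'
#' @param curve a \code{signal_curve}.
#' @param path CSV output path; a YAML sidecar is written next to it as
#'   \code{<path>.meta.yaml} when \code{meta} is given.
#' @param meta optional named list (protocol, tissue, convergence notes).
#' @return \code{path}, invisibly.
#' @export
write_signal_curve <- function(curve, path, meta = NULL) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  if (!is.null(meta))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Isochromat-ensemble reference signal (no diffusion)
#'
#' Independent cross-check of the EPG engine: evolves \code{m_isochromats}
#' discrete spin packets with uniformly spaced per-TR precession angles
#' \eqn{\theta \in (-\pi, \pi]} under the same pulse phases and relaxation,
#' and averages their transverse magnetization. With a uniform
#' \eqn{\theta}-grid the ensemble mean equals the zero-order configuration
#' amplitude exactly once \code{m_isochromats} exceeds the number of occupied
#' dephasing orders, which makes this a machine-precision oracle for pulse
#' trains up to about \code{m_isochromats / 2} pulses.
#'
#' @inheritParams steady_state_signal
#' @param m_isochromats ensemble size (>= 2; use at least twice the pulse count).
#' @param n_pulses number of pulses to simulate.
#' @param trace if \code{TRUE}, also return the complex demodulated ensemble
#'   means after every pulse and at every TR end.
#' @return list with \code{s_plus}, \code{s_minus} (magnitudes at pulse
#'   \code{n_pulses}) and, if requested, \code{f0_pulse}, \code{f0_end}.
#' @export
isochromat_signal <- function(schedule, tissue, scheme, flip,
                              m_isochromats, n_pulses, trace = FALSE) {
  if (tissue$d > 0)
    stop("the isochromat reference is defined without diffusion (D = 0)",
         call. = FALSE)
  stopifnot(m_isochromats >= 2, n_pulses >= 1)
  if (!is.finite(flip) || flip <= 0 || flip > 180)
    stop("flip must be in (0, 180] degrees", call. = FALSE)
  m <- m_isochromats
  theta <- -pi + (1:m) * (2 * pi / m)
  prec <- exp(1i * theta)
  e2 <- exp(-schedule$tr / tissue$t2)
  e1 <- exp(-schedule$tr / tissue$t1)
  a <- flip * pi / 180
  cc <- cos(a / 2)^2; ss <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  mxy <- complex(length.out = m)
  mz <- rep(tissue$m0, m)
  f0p <- f0e <- complex(length.out = n_pulses)
  for (n in 0:(n_pulses - 1L)) {
    phi <- quadratic_phase(scheme, n) * pi / 180
    ei <- exp(1i * phi)
    new_xy <- cc * mxy + ss * ei^2 * Conj(mxy) - 1i * ei * sa * mz
    mz <- Re(-0.5i * Conj(ei) * sa * mxy + 0.5i * ei * sa * Conj(mxy) + ca * mz)
    mxy <- new_xy
    f0p[n + 1L] <- mean(mxy) * Conj(ei)
    mxy <- mxy * e2 * prec
    mz <- mz * e1 + tissue$m0 * (1 - e1)
    f0e[n + 1L] <- mean(mxy) * Conj(ei)
  }
  out <- list(s_plus = Mod(f0p[n_pulses]), s_minus = Mod(f0e[n_pulses]))
  if (trace) {
    out$f0_pulse <- f0p
    out$f0_end <- f0e
  }
  out
}
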