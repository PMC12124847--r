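# gyromagnetic ratio of 1H: rad/mm dephasing per (mT/m x ms)
GAMMA_RAD_PER_MT_MS <- 2.6752218744e-1

#' RF spoiling scheme
#'
#' @param psi phase difference increment in degrees, in \code{[0, 360)}.
#' @return object of class \code{spoiling_scheme}.
#' @export
spoiling_scheme <- function(psi) {
  if (!is.finite(psi) || psi < 0 || psi >= 360)
    stop("psi must be in [0, 360) degrees", call. = FALSE)
  structure(list(psi = psi), class = "spoiling_scheme")
}

#' Quadratic RF phase of the n-th pulse
#'
#' The RF-spoiling phase schedule \eqn{\phi_n = n(n+1)\psi/2}, reduced modulo
#' 360 degrees. The reduction is performed on integers in millidegrees
#' (exactly representable in double precision for any realistic pulse count),
#' so no floating-point drift accumulates at large n.
#'
#' @param scheme a \code{spoiling_scheme}.
#' @param n pulse index (vectorized), n >= 0.
#' @return phase(s) in degrees in \code{[0, 360)}.
#' @export
quadratic_phase <- function(scheme, n) {
  stopifnot(inherits(scheme, "spoiling_scheme"), all(n >= 0))
  tri <- n * (n + 1) / 2
  psimd <- round(scheme$psi * 1000)
  ((tri * psimd) %% 360000) / 1000
}

#' A trapezoid-free rectangular gradient lobe
#'
#' @param axis \code{"readout"} or \code{"slice"}.
#' @param amplitude gradient amplitude in mT/m (signed).
#' @param duration lobe duration in ms (> 0).
#' @param start start time within the TR in ms.
#' @return object of class \code{gradient_lobe}. Its zeroth moment in rad/mm
#'   is \code{gamma * amplitude * duration}.
#' @export
gradient_lobe <- function(axis = c("readout", "slice"), amplitude, duration, start) {
  axis <- match.arg(axis)
  stopifnot(duration > 0, start >= 0)
  structure(list(axis = axis, amplitude = amplitude, duration = duration,
                 start = start), class = "gradient_lobe")
}

lobe_moment <- function(lobe) GAMMA_RAD_PER_MT_MS * lobe$amplitude * lobe$duration

#' Build the default one-TR gradient schedule of the spoiled GRE protocol
#'
#' Constructs the repetition-interval gradient layout used by all
#' simulations: a readout prephaser (duration \code{prephaser_dur}, ending at
#' TE minus half the readout plateau), a readout plateau centered on TE whose
#' duration is \code{matrix_size / bandwidth_khz} and whose full moment is one
#' dephasing cycle across the readout voxel, and end-of-TR spoiler lobes on
#' the readout and slice axes sized so that the net per-TR dephasing equals
#' \code{readout_cycles} (resp. \code{slice_cycles}) cycles per voxel. This
#' layout is a documented approximation of the acquisition waveform; every
#' lobe can be replaced via \code{lobes} for an exact timing diagram.
#'
#' @param tr repetition time in ms.
#' @param te echo time in ms (0 < te < tr).
#' @param voxel_readout,voxel_slice voxel size per axis in mm.
#' @param readout_cycles,slice_cycles net spoiling moment per axis in
#'   dephasing cycles per voxel (net moment = 2 pi cycles / voxel rad/mm).
#' @param matrix_size readout matrix size (sets the plateau duration together
#'   with \code{bandwidth_khz}).
#' @param bandwidth_khz readout bandwidth in kHz.
#' @param prephaser_dur,spoiler_dur lobe durations in ms.
#' @param lobes optional list of \code{gradient_lobe} overriding the default
#'   layout entirely (net moments are then taken from the lobes).
#' @return object of class \code{tr_schedule}: fields \code{tr}, \code{te},
#'   \code{lobes}, \code{voxel_size} (named length-2), \code{spoil_cycles}
#'   (named length-2).
#' @export
gre_protocol <- function(tr = 20, te = 4,
                         voxel_readout = 0.30, voxel_slice = 0.78,
                         readout_cycles = 3, slice_cycles = 3.76,
                         matrix_size = 100, bandwidth_khz = 50,
                         prephaser_dur = 1, spoiler_dur = 2,
                         lobes = NULL) {
  if (te <= 0 || te >= tr) stop("need 0 < te < tr", call. = FALSE)
  stopifnot(voxel_readout > 0, voxel_slice > 0,
            readout_cycles >= 0, slice_cycles >= 0)
  if (is.null(lobes)) {
    plateau_dur <- matrix_size / bandwidth_khz
    plateau_moment <- 2 * pi / voxel_readout           # one cycle per voxel
    plateau_amp <- plateau_moment / (GAMMA_RAD_PER_MT_MS * plateau_dur)
    pre_moment <- -plateau_moment / 2                  # echo centered on TE
    pre_amp <- pre_moment / (GAMMA_RAD_PER_MT_MS * prephaser_dur)
    pre_start <- te - plateau_dur / 2 - prephaser_dur
    if (pre_start < 0)
      stop("prephaser does not fit before the readout plateau", call. = FALSE)
    net_ro <- 2 * pi * readout_cycles / voxel_readout
    spoil_ro_moment <- net_ro - (pre_moment + plateau_moment)
    spoil_ro_amp <- spoil_ro_moment / (GAMMA_RAD_PER_MT_MS * spoiler_dur)
    net_sl <- 2 * pi * slice_cycles / voxel_slice
    spoil_sl_amp <- net_sl / (GAMMA_RAD_PER_MT_MS * spoiler_dur)
    if (te + plateau_dur / 2 > tr - spoiler_dur)
      stop("readout plateau overlaps the end-of-TR spoilers", call. = FALSE)
    lobes <- list(
      gradient_lobe("readout", pre_amp, prephaser_dur, pre_start),
      gradient_lobe("readout", plateau_amp, plateau_dur, te - plateau_dur / 2),
      gradient_lobe("readout", spoil_ro_amp, spoiler_dur, tr - spoiler_dur),
      gradient_lobe("slice", spoil_sl_amp, spoiler_dur, tr - spoiler_dur)
    )
  }
  structure(list(tr = tr, te = te, lobes = lobes,
                 voxel_size = c(readout = voxel_readout, slice = voxel_slice),
                 spoil_cycles = c(readout = readout_cycles, slice = slice_cycles)),
            class = "tr_schedule")
}

#' @export
print.tr_schedule <- function(x, ...) {
  nm <- schedule_net_moment(x)
  cat(sprintf("<tr_schedule> TR = %g ms, TE = %g ms, voxel %g x %g mm\n",
              x$tr, x$te, x$voxel_size[["readout"]], x$voxel_size[["slice"]]))
  cat(sprintf("  net dephasing: readout %.4g rad/mm (%g cyc/voxel), slice %.4g rad/mm (%g cyc/voxel)\n",
              nm[["readout"]], x$spoil_cycles[["readout"]],
              nm[["slice"]], x$spoil_cycles[["slice"]]))
  cat(sprintf("  %d gradient lobes\n", length(x$lobes)))
  invisible(x)
}

#' Net per-TR dephasing of a schedule, per axis
#'
#' @param schedule a \code{tr_schedule}.
#' @return named numeric \code{c(readout=, slice=)} in rad/mm.
#' @export
schedule_net_moment <- function(schedule) {
  out <- c(readout = 0, slice = 0)
  for (lb in schedule$lobes) out[lb$axis] <- out[lb$axis] + lobe_moment(lb)
  out
}

#' Scale a schedule to a different voxel size
#'
#' Emulates a resolution change: all readout-axis gradient amplitudes and the
#' slice-axis spoiler amplitude are scaled by \code{1/factor}
#' (\code{factor = new_voxel / old_voxel}); timings are unchanged, voxel
#' sizes are multiplied by \code{factor}. Cycles per voxel are invariant, so
#' halving the voxel doubles the dephasing moments and with them the
#' sequence's inherent diffusion weighting.
#'
#' @param schedule a \code{tr_schedule}.
#' @param factor positive voxel-size ratio (0.5 = doubled resolution).
#' @return the scaled \code{tr_schedule}.
#' @export
scale_resolution <- function(schedule, factor) {
  stopifnot(factor > 0)
  schedule$lobes <- lapply(schedule$lobes, function(lb) {
    lb$amplitude <- lb$amplitude / factor
    lb
  })
  schedule$voxel_size <- schedule$voxel_size * factor
  schedule
}

#' Partition one TR into evolution intervals
#'
#' Cuts the repetition interval at every lobe edge and at TE, producing a
#' list of \code{evolution_interval} objects whose durations sum to TR and
#' whose per-axis moments sum to the schedule's net dephasing. Each interval
#' carries the accumulated intra-TR spatial-frequency offset for b-value
#' bookkeeping; the single re-indexing by one configuration order is attached
#' to the last interval. The attribute \code{te_boundary} gives the number of
#' intervals up to the TE sample point.
#'
#' @param schedule a \code{tr_schedule}.
#' @return list of \code{evolution_interval} with attributes
#'   \code{te_boundary} (integer) and \code{quantum} (named per-axis order
#'   quantum in rad/mm).
#' @export
schedule_to_intervals <- function(schedule) {
  lobes <- schedule$lobes
  for (ax in c("readout", "slice")) {
    lb <- Filter(function(l) l$axis == ax, lobes)
    if (length(lb) > 1) {
      iv <- t(vapply(lb, function(l) c(l$start, l$start + l$duration), numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-9))
        stop("overlapping gradient lobes on axis ", ax, call. = FALSE)
    }
    if (any(vapply(lb, function(l) l$start + l$duration, 0) > schedule$tr + 1e-9))
      stop("gradient lobe extends beyond TR", call. = FALSE)
  }
  edges <- sort(unique(c(0, schedule$tr, schedule$te,
                         unlist(lapply(lobes, function(l) c(l$start, l$start + l$duration))))))
  edges <- edges[edges >= 0 & edges <= schedule$tr]
  quantum <- schedule_net_moment(schedule)
  out <- vector("list", length(edges) - 1L)
  k_acc <- c(0, 0)
  for (i in seq_along(out)) {
    t0 <- edges[i]; t1 <- edges[i + 1L]
    mom <- c(readout = 0, slice = 0)
    for (lb in lobes) {
      ov <- min(t1, lb$start + lb$duration) - max(t0, lb$start)
      if (ov > 1e-12)
        mom[lb$axis] <- mom[lb$axis] + GAMMA_RAD_PER_MT_MS * lb$amplitude * ov
    }
    out[[i]] <- evolution_interval(duration = t1 - t0, moment = unname(mom),
                                   k_start = k_acc,
                                   shift = if (i == length(out)) NA_integer_ else 0L)
    k_acc <- k_acc + unname(mom)
  }
  # the accumulated moment is one order quantum by construction; the final
  # interval re-indexes by exactly one
  out[[length(out)]]$shift <- if (all(abs(quantum) < 1e-12)) 0L else 1L
  structure(out,
            te_boundary = which(abs(edges[-1] - schedule$te) < 1e-9)[1],
            quantum = quantum, tr = schedule$tr)
}
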