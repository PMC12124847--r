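#' Generate a synthetic phantom measurement set
#'
#' Emulates the ROI evaluation of a phantom acquisition: for each phase
#' increment the true steady-state curve is simulated, then each flip angle's
#' ROI mean is drawn as the average of \code{roi_voxel_count} Rician samples
#' (true signal plus independent complex Gaussian noise of standard deviation
#' \code{noise_sigma} per channel, magnitude taken). Reproducible for a fixed
#' seed. This is a synthetic stand-in for scanner data; externally exported
#' ROI curves can be loaded with \code{\link{read_measurement}} instead.
#'
#' @param tissue a \code{tissue_params} (e.g. one of
#'   \code{\link{phantom_presets}}).
#' @param psi phase difference increments in degrees.
#' @param schedule a \code{tr_schedule}.
#' @param flips flip-angle grid in degrees.
#' @param noise_sigma per-channel noise standard deviation (fraction of m0).
#' @param roi_voxel_count voxels averaged per ROI.
#' @param seed integer RNG seed.
#' @param signal which simulated magnitude the "scanner" records:
#'   \code{"s_plus"} (post-pulse, default) or \code{"s_echo"} (TE-sampled).
#' @return object of class \code{measurement_set}: a data frame with columns
#'   \code{flip_deg}, \code{psi_deg}, \code{signal_mean}, \code{n_voxels},
#'   \code{normalized}; attributes \code{noise_sigma}, \code{seed},
#'   \code{norm_flip}, \code{norm_values}.
#' @export
generate_measurement <- function(tissue, psi, schedule,
                                 flips = seq(5, 90, by = 5),
                                 noise_sigma = 0.005, roi_voxel_count = 500,
                                 seed = 1L, signal = c("s_plus", "s_echo")) {
  stopifnot(noise_sigma >= 0, roi_voxel_count >= 1)
  signal <- match.arg(signal)
  set.seed(seed)
  rows <- lapply(psi, function(p) {
    curve <- signal_curve(schedule, tissue, spoiling_scheme(p), flips)
    truth <- curve[[signal]]
    meas <- vapply(truth, function(s) {
      if (noise_sigma == 0) return(s)
      re <- stats::rnorm(roi_voxel_count, mean = s, sd = noise_sigma)
      im <- stats::rnorm(roi_voxel_count, mean = 0, sd = noise_sigma)
      mean(sqrt(re^2 + im^2))
    }, 0)
    data.frame(flip_deg = flips, psi_deg = p, signal_mean = meas,
               n_voxels = roi_voxel_count, normalized = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, noise_sigma = noise_sigma, seed = seed,
            norm_flip = NA_real_, norm_values = NULL,
            class = c("measurement_set", "data.frame"))
}

#' Normalize measured curves at the Ernst angle
#'
#' Divides each per-\eqn{\psi} curve by its own value at the measured flip
#' angle nearest the Ernst angle \eqn{\alpha_E = \arccos(e^{-TR/T_1})}. At
#' that flip angle the steady-state curves for different \eqn{\psi} coincide,
#' so this normalization puts all curves (and any global receive/T2* factor)
#' on a common scale. Idempotent; the normalization flip and the divisors are
#' recorded so the scaling can be undone.
#'
#' @param ms a \code{measurement_set}.
#' @param tr_over_t1 ratio TR/T1 of the substance.
#' @param max_gap largest tolerated distance (degrees) between the Ernst
#'   angle and the nearest measured flip.
#' @return the normalized \code{measurement_set}.
#' @export
normalize_at_ernst <- function(ms, tr_over_t1, max_gap = 2.5) {
  stopifnot(inherits(ms, "measurement_set"))
  if (all(ms$normalized)) return(ms)
  ae <- ernst_angle(tr_over_t1)
  flips <- sort(unique(ms$flip_deg))
  nf <- flips[which.min(abs(flips - ae))]
  if (abs(nf - ae) > max_gap)
    stop(sprintf("no measured flip within %g deg of the Ernst angle (%.1f deg)",
                 max_gap, ae), call. = FALSE)
  norm_values <- c()
  for (p in unique(ms$psi_deg)) {
    sel <- ms$psi_deg == p
    v <- ms$signal_mean[sel & ms$flip_deg == nf]
    if (length(v) != 1 || v <= 0)
      stop("cannot normalize: missing or non-positive value at the Ernst flip",
           call. = FALSE)
    ms$signal_mean[sel] <- ms$signal_mean[sel] / v
    norm_values[as.character(p)] <- v
  }
  ms$normalized <- TRUE
  attr(ms, "norm_flip") <- nf
  attr(ms, "norm_values") <- norm_values
  ms
}

#' Compare measured and simulated curves
#'
#' Normalizes the measurement (if not already normalized) and the simulated
#' curves identically — each divided by its value at the measurement's
#' normalization flip — then reports per-\eqn{\psi} residuals.
#'
#' @param ms a \code{measurement_set}.
#' @param curves list of \code{signal_curve} (one per \eqn{\psi} present in
#'   \code{ms}), or one combined data frame with a \code{psi_deg} column.
#' @param tr_over_t1 TR/T1, needed if \code{ms} is not yet normalized.
#' @param signal simulated column to compare against (default \code{s_plus}).
#' @return data frame: \code{psi_deg}, \code{mean_abs_rel}, \code{max_abs_rel}.
#' @export
compare_measured_simulated <- function(ms, curves, tr_over_t1 = NULL,
                                       signal = "s_plus") {
  stopifnot(inherits(ms, "measurement_set"))
  if (!all(ms$normalized)) {
    if (is.null(tr_over_t1))
      stop("tr_over_t1 required to normalize the measurement", call. = FALSE)
    ms <- normalize_at_ernst(ms, tr_over_t1)
  }
  sim <- if (is.data.frame(curves)) curves else do.call(rbind, curves)
  nf <- attr(ms, "norm_flip")
  rows <- lapply(unique(ms$psi_deg), function(p) {
    m <- ms[ms$psi_deg == p, ]
    s <- sim[sim$psi_deg == p, ]
    if (nrow(s) == 0) stop("no simulated curve for psi = ", p, call. = FALSE)
    if (!isTRUE(all.equal(sort(m$flip_deg), sort(s$flip_deg))))
      stop("flip grids of measurement and simulation differ", call. = FALSE)
    s <- s[match(m$flip_deg, s$flip_deg), ]
    ref <- s[[signal]] / s[[signal]][m$flip_deg == nf]
    rel <- abs(m$signal_mean - ref) / ref
    data.frame(psi_deg = p, mean_abs_rel = mean(rel), max_abs_rel = max(rel))
  })
  do.call(rbind, rows)
}

#' Epsilon estimated from a (synthetic) measurement
#'
#' Undoes the Ernst-angle normalization using the recorded divisor and
#' evaluates the spoiling metric on the recovered absolute curve. For a
#' noise-free synthetic measurement this reproduces the directly simulated
#' \eqn{\epsilon} exactly. With noise, magnitude images carry the Rician
#' bias \eqn{E[|s+n|] > s}, which inflates the relative deviation where the
#' signal is low (high flip angles); when the noise level is known, the
#' moment-based correction \eqn{\hat s = \sqrt{\max(\bar m^2 - \sigma^2, 0)}}
#' removes most of it.
#'
#' @param ms a normalized \code{measurement_set}.
#' @param psi which phase increment's curve to evaluate.
#' @param tr_over_t1 ratio TR/T1.
#' @param m0 equilibrium magnetization of the generating simulation.
#' @param sigma per-channel noise level for Rician bias correction; defaults
#'   to the value recorded by \code{\link{generate_measurement}}. Use
#'   \code{sigma = 0} to disable the correction.
#' @return \eqn{\epsilon} in percent.
#' @export
epsilon_from_measurement <- function(ms, psi, tr_over_t1, m0 = 1, sigma = NULL) {
  stopifnot(inherits(ms, "measurement_set"))
  sel <- ms$psi_deg == psi
  if (!any(sel)) stop("psi not present in measurement set", call. = FALSE)
  sig <- ms$signal_mean[sel]
  if (all(ms$normalized)) {
    nv <- attr(ms, "norm_values")[as.character(psi)]
    if (is.na(nv)) stop("no stored normalization value for this psi", call. = FALSE)
    sig <- sig * nv
  }
  if (is.null(sigma)) sigma <- attr(ms, "noise_sigma")
  if (!is.null(sigma) && is.finite(sigma) && sigma > 0)
    sig <- sqrt(pmax(sig^2 - sigma^2, 0))
  epsilon(data.frame(flip_deg = ms$flip_deg[sel], s_plus = sig), tr_over_t1, m0)
}

#' Write / read measurement CSV
#'
#' The writer emits the five-column layout (\code{flip_deg}, \code{psi_deg},
#' \code{signal_mean}, \code{n_voxels}, \code{normalized}). The reader also
#' accepts a bare two-column (flip, signal) export — e.g. an external ROI
#' table — in which case \code{psi} must be supplied.
#'
#' @param ms a \code{measurement_set}.
#' @param path CSV path.
#' @return \code{path} invisibly (writer); a \code{measurement_set} (reader).
#' @export
write_measurement <- function(ms, path) {
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement
#' @param psi phase increment to attach when reading a two-column export.
#' @export
read_measurement <- function(path, psi = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) == 2) {
    if (is.null(psi))
      stop("two-column layout: supply psi", call. = FALSE)
    names(df) <- c("flip_deg", "signal")
    df <- data.frame(flip_deg = df$flip_deg, psi_deg = psi,
                     signal_mean = df$signal, n_voxels = NA_integer_,
                     normalized = FALSE)
  }
  stopifnot(all(c("flip_deg", "psi_deg", "signal_mean") %in% names(df)))
  if (is.null(df$n_voxels)) df$n_voxels <- NA_integer_
  if (is.null(df$normalized)) df$normalized <- FALSE
  structure(df, noise_sigma = NA_real_, seed = NA_integer_,
            norm_flip = NA_real_, norm_values = NULL,
            class = c("measurement_set", "data.frame"))
}
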