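#' Ernst amplitude of the ideally spoiled GRE signal
#'
#' Closed-form saturation-recovery signal
#' \eqn{M_0 (1 - E_1)\sin\alpha / (1 - E_1\cos\alpha)} with
#' \eqn{E_1 = e^{-TR/T_1}}: the flip-angle response when the transverse
#' history contributes nothing (ideal spoiling, no T2 dependence).
#'
#' @param tr_over_t1 ratio TR/T1 (> 0). Vectorized, as is \code{flip}.
#' @param flip flip angle in degrees.
#' @param m0 equilibrium magnetization.
#' @return signal amplitude in units of \code{m0}.
#' @export
ernst_amplitude <- function(tr_over_t1, flip, m0 = 1) {
  stopifnot(all(tr_over_t1 > 0))
  e1 <- exp(-tr_over_t1)
  a <- flip * pi / 180
  m0 * (1 - e1) * sin(a) / (1 - e1 * cos(a))
}

#' Ernst angle
#'
#' The flip angle maximizing the ideally spoiled signal,
#' \eqn{\alpha_E = \arccos(e^{-TR/T_1})}.
#'
#' @param tr_over_t1 ratio TR/T1 (> 0), vectorized.
#' @return angle in degrees.
#' @export
ernst_angle <- function(tr_over_t1) {
  stopifnot(all(tr_over_t1 > 0))
  acos(exp(-tr_over_t1)) * 180 / pi
}

#' Spoiling-quality metric: mean relative deviation from the Ernst curve
#'
#' The flip-angle-averaged absolute relative deviation, in percent, of a
#' simulated steady-state curve from the ideally spoiled (Ernst) curve:
#' \deqn{\epsilon = \frac{100}{N}\sum_k \frac{|S^+(\alpha_k) -
#'   S_{Ernst}(\alpha_k)|}{S_{Ernst}(\alpha_k)}.}
#' Smaller \eqn{\epsilon} means the phase increment spoils better. The
#' comparison uses the post-pulse signal \code{s_plus}.
#'
#' @param curve a \code{signal_curve} (or data frame with \code{flip_deg} and
#'   \code{s_plus}).
#' @param tr_over_t1 ratio TR/T1 of the simulated tissue.
#' @param m0 equilibrium magnetization used in the simulation.
#' @return \eqn{\epsilon} in percent.
#' @export
epsilon <- function(curve, tr_over_t1, m0 = 1) {
  stopifnot(all(c("flip_deg", "s_plus") %in% names(curve)))
  se <- ernst_amplitude(tr_over_t1, curve$flip_deg, m0)
  if (any(se == 0))
    stop("Ernst amplitude vanishes on the flip grid; epsilon undefined",
         call. = FALSE)
  100 * mean(abs(curve$s_plus - se) / se)
}

#' Simulate one curve and compute its epsilon in one call
#'
#' @inheritParams signal_curve
#' @return \eqn{\epsilon} in percent.
#' @export
epsilon_for <- function(schedule, tissue, scheme, flips = seq(5, 90, by = 5),
                        npulse = NULL, navg = 100L, floor_amp = 1e-12) {
  curve <- signal_curve(schedule, tissue, scheme, flips, npulse, navg, floor_amp)
  epsilon(curve, schedule$tr / tissue$t1, tissue$m0)
}

#' Sweep configuration for the parameter-space pipelines
#'
#' @param flips flip-angle grid in degrees.
#' @param psi phase difference increments in degrees.
#' @param d diffusion coefficients in mm^2/s.
#' @param tr repetition times in ms.
#' @param log10_t1_tr,log10_t2_tr grid axes as integer tenths are implied:
#'   values are rounded to one decimal and keyed exactly.
#' @param voxel_sizes readout voxel sizes in mm for resolution sweeps.
#' @param npulse,navg,floor_amp optional convergence overrides.
#' @return object of class \code{sweep_config}.
#' @export
sweep_config <- function(flips = seq(5, 90, by = 5),
                         psi = c(50, 115.4, 117, 150, 169),
                         d = 0, tr = 20,
                         log10_t1_tr = seq(-1, 2.3, by = 0.1),
                         log10_t2_tr = seq(-1, 2.3, by = 0.1),
                         voxel_sizes = exp(seq(log(0.075), log(1.2), length.out = 12)),
                         npulse = NULL, navg = 100L, floor_amp = 1e-12) {
  stopifnot(length(flips) > 0, length(psi) > 0, length(d) > 0, length(tr) > 0)
  structure(list(flips = flips, psi = psi, d = d, tr = tr,
                 log10_t1_tr = round(log10_t1_tr, 1),
                 log10_t2_tr = round(log10_t2_tr, 1),
                 voxel_sizes = voxel_sizes,
                 npulse = npulse, navg = navg, floor_amp = floor_amp),
            class = "sweep_config")
}

#' Epsilon over the (T1/TR, T2/TR) parameter grid
#'
#' Computes \eqn{\epsilon} for every grid cell with \eqn{T_2 \le T_1}, for
#' each combination of \eqn{\psi}, D and TR in the configuration. Axis values
#' are keyed by integer tenths of their log10 to avoid floating-point drift.
#' Cells are optionally cached: with \code{cache_path}, completed rows are
#' appended to a CSV after each cell and previously cached cells are not
#' recomputed, so an interrupted sweep resumes where it stopped.
#'
#' @param config a \code{sweep_config}.
#' @param schedule_fn function(tr, voxel_readout) -> \code{tr_schedule}; the
#'   default builds \code{\link{gre_protocol}} at the reference resolution (0.30 mm readout voxel).
#' @param cache_path optional CSV path for resumable caching.
#' @param progress print one line per cell block.
#' @return data frame (class \code{epsilon_grid}) with columns
#'   \code{log10_t1_tr}, \code{log10_t2_tr}, \code{t1_tr}, \code{t2_tr},
#'   \code{psi_deg}, \code{d}, \code{tr}, \code{epsilon}.
#' @export
grid_sweep <- function(config,
                       schedule_fn = function(tr, voxel_readout = 0.30)
                         gre_protocol(tr = tr, te = 4, voxel_readout = voxel_readout),
                       cache_path = NULL, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  cells <- expand.grid(log10_t2_tr = config$log10_t2_tr,
                       log10_t1_tr = config$log10_t1_tr,
                       psi = config$psi, d = config$d, tr = config$tr,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[round(10 * cells$log10_t2_tr) <= round(10 * cells$log10_t1_tr), ]
  key <- function(df) sprintf("%d_%d_%s_%g_%g", round(10 * df$log10_t1_tr),
                              round(10 * df$log10_t2_tr), format(df$psi), df$d, df$tr)
  done <- NULL
  if (!is.null(cache_path) && file.exists(cache_path)) {
    done <- utils::read.csv(cache_path)
  }
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    if (!is.null(done)) {
      hit <- done[key(done) == key(cl), , drop = FALSE]
      if (nrow(hit) == 1) { rows[[i]] <- hit; next }
    }
    t1 <- 10^cl$log10_t1_tr * cl$tr
    t2 <- 10^cl$log10_t2_tr * cl$tr
    tissue <- tissue_params(t1 = t1, t2 = t2, d = cl$d)
    sch <- schedule_fn(cl$tr)
    eps <- tryCatch(
      epsilon_for(sch, tissue, spoiling_scheme(cl$psi), config$flips,
                  npulse = config$npulse, navg = config$navg,
                  floor_amp = config$floor_amp),
      error = function(e) NA_real_)
    rows[[i]] <- data.frame(log10_t1_tr = cl$log10_t1_tr,
                            log10_t2_tr = cl$log10_t2_tr,
                            t1_tr = 10^cl$log10_t1_tr, t2_tr = 10^cl$log10_t2_tr,
                            psi = cl$psi, d = cl$d, tr = cl$tr, epsilon = eps)
    if (!is.null(cache_path)) {
      utils::write.table(rows[[i]], cache_path, sep = ",", row.names = FALSE,
                         col.names = !file.exists(cache_path), append = file.exists(cache_path))
    }
    if (progress && i %% 50 == 0)
      message(sprintf("grid_sweep: %d / %d cells", i, nrow(cells)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("epsilon_grid", "data.frame")
  out
}

#' Best phase increment per grid cell
#'
#' Reduces an epsilon grid to the \eqn{\psi} with the smallest \eqn{\epsilon}
#' in every (T1/TR, T2/TR, D, TR) cell. Ties are broken toward the smaller
#' \eqn{\psi}.
#'
#' @param grid an \code{epsilon_grid} from \code{\link{grid_sweep}}.
#' @return data frame with one row per cell: the grid keys, \code{best_psi}
#'   and \code{epsilon}.
#' @export
best_psi_map <- function(grid) {
  stopifnot(all(c("log10_t1_tr", "log10_t2_tr", "psi", "epsilon") %in% names(grid)))
  key <- interaction(grid$log10_t1_tr, grid$log10_t2_tr, grid$d, grid$tr,
                     drop = TRUE)
  rows <- lapply(split(grid, key), function(cell) {
    cell <- cell[order(cell$psi), ]            # ties -> smaller psi
    i <- which.min(cell$epsilon)
    data.frame(log10_t1_tr = cell$log10_t1_tr[1],
               log10_t2_tr = cell$log10_t2_tr[1],
               d = cell$d[1], tr = cell$tr[1],
               best_psi = cell$psi[i], epsilon = cell$epsilon[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$d, out$tr, out$log10_t1_tr, out$log10_t2_tr), ]
}

#' Epsilon versus voxel size for one substance
#'
#' For each voxel size the base schedule is rescaled with
#' \code{\link{scale_resolution}} (gradient amplitudes scale inversely with
#' the voxel) and \eqn{\epsilon} recomputed, tracing how the sequence's
#' inherent diffusion weighting changes spoiling quality with resolution.
#'
#' @param config a \code{sweep_config} (supplies \code{voxel_sizes},
#'   \code{psi}, \code{flips} and convergence overrides).
#' @param substance a \code{tissue_params}.
#' @param base_schedule the unscaled \code{tr_schedule}.
#' @return data frame ordered by voxel size: \code{voxel_mm}, \code{psi_deg},
#'   \code{tr}, \code{epsilon}.
#' @export
voxel_size_sweep <- function(config, substance, base_schedule) {
  stopifnot(inherits(config, "sweep_config"), all(config$voxel_sizes > 0))
  base_voxel <- base_schedule$voxel_size[["readout"]]
  grid <- expand.grid(voxel = sort(config$voxel_sizes), psi = config$psi,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$voxel[i]
    sch <- scale_resolution(base_schedule, v / base_voxel)
    eps <- epsilon_for(sch, substance, spoiling_scheme(grid$psi[i]),
                       config$flips, npulse = config$npulse,
                       navg = config$navg, floor_amp = config$floor_amp)
    data.frame(voxel_mm = v, psi_deg = grid$psi[i], tr = base_schedule$tr,
               epsilon = eps)
  })
  out <- do.call(rbind, rows)
  out[order(out$voxel_mm, out$psi_deg), ]
}

#' Epsilon table for named substances
#'
#' Computes \eqn{\epsilon} for every combination of substance, \eqn{\psi} and
#' TR, both with each substance's diffusion coefficient as given and with
#' diffusion forced off, mirroring the "with / without diffusion" columns of
#' the reference-substance comparison.
#'
#' @param substances named list of \code{tissue_params}.
#' @param psi phase difference increments in degrees.
#' @param trs repetition times in ms.
#' @param schedule_fn function(tr) -> \code{tr_schedule}.
#' @param flips flip-angle grid.
#' @param ... convergence overrides passed to \code{\link{epsilon_for}}.
#' @return long data frame: \code{substance}, \code{psi_deg}, \code{tr},
#'   \code{diffusion} (logical), \code{d}, \code{epsilon}.
#' @export
substance_table <- function(substances, psi = c(50, 115.4, 117, 150, 169),
                            trs = c(20, 50),
                            schedule_fn = function(tr) gre_protocol(tr = tr, te = 4),
                            flips = seq(5, 90, by = 5), ...) {
  stopifnot(length(substances) > 0, !is.null(names(substances)))
  rows <- list()
  for (nm in names(substances)) {
    for (tr in trs) {
      sch <- schedule_fn(tr)
      for (withd in c(FALSE, TRUE)) {
        tis <- substances[[nm]]
        if (!withd) tis$d <- 0
        if (withd && tis$d == 0) next
        for (p in psi) {
          eps <- epsilon_for(sch, tis, spoiling_scheme(p), flips, ...)
          rows[[length(rows) + 1L]] <-
            data.frame(substance = nm, psi_deg = p, tr = tr,
                       diffusion = withd, d = tis$d, epsilon = eps)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
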