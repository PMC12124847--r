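#' Tissue / substance relaxation and diffusion parameters
#'
#' @param t1 longitudinal relaxation time in ms.
#' @param t2 transverse relaxation time in ms; must satisfy T1 >= T2 > 0.
#' @param d isotropic diffusion coefficient in mm^2/s (0 disables diffusion).
#' @param m0 equilibrium magnetization (dimensionless scale, default 1).
#' @return object of class \code{tissue_params}.
#' @export
tissue_params <- function(t1, t2, d = 0, m0 = 1) {
  if (!is.finite(t1) || !is.finite(t2) || t2 <= 0 || t1 < t2)
    stop("tissue parameters must satisfy T1 >= T2 > 0", call. = FALSE)
  if (!is.finite(d) || d < 0) stop("D must be >= 0", call. = FALSE)
  if (m0 <= 0) stop("m0 must be positive", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, d = d, m0 = m0), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> T1 = %g ms, T2 = %g ms, D = %g mm^2/s, m0 = %g\n",
              x$t1, x$t2, x$d, x$m0))
  invisible(x)
}

#' Named substance presets
#'
#' Relaxation and diffusion parameters of the reference substances used
#' throughout the analyses:
#' \describe{
#'   \item{H2O_CuSO4}{copper-sulfate-doped water, T1 = 540 ms, T2 = 340 ms,
#'     D = 1.93e-3 mm^2/s.}
#'   \item{SiliconeOil}{silicone oil, T1 = 1290 ms, T2 = 399 ms,
#'     D = 0.0055e-3 mm^2/s (near-negligible diffusion).}
#'   \item{H2O_Gd}{gadolinium-doped water, T1 = 1603 ms, T2 = 613 ms; its
#'     diffusion coefficient was not characterized, stored as D = 0 — set D
#'     explicitly for diffusion simulations.}
#'   \item{GreyMatter3T}{human brain grey matter at 3 T, T1 = 1500 ms,
#'     T2 = 100 ms, D = 0.8e-3 mm^2/s.}
#' }
#'
#' @return named list of \code{tissue_params}.
#' @export
phantom_presets <- function() {
  list(
    H2O_CuSO4    = tissue_params(t1 = 540,  t2 = 340, d = 1.93e-3),
    SiliconeOil  = tissue_params(t1 = 1290, t2 = 399, d = 0.0055e-3),
    H2O_Gd       = tissue_params(t1 = 1603, t2 = 613, d = 0),
    GreyMatter3T = tissue_params(t1 = 1500, t2 = 100, d = 0.8e-3)
  )
}

#' Reference ratio parameter set T1 = T2 = 20 TR
#'
#' The classic benchmark condition T1/TR = T2/TR = 20 with no diffusion,
#' expressed for a concrete TR.
#'
#' @param tr repetition time in ms.
#' @return a \code{tissue_params} object with T1 = T2 = 20 TR, D = 0.
#' @export
ratio_params <- function(tr = 20) tissue_params(t1 = 20 * tr, t2 = 20 * tr, d = 0)
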