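#' Library parameter bounds
#'
#' Hard bounds of the decay-library parameter space: cellular water efflux
#' rate constant \code{k_io} (s^-1), mean cell volume \code{V} (pL/cell),
#' cell density \code{rho} (cells/uL tissue) and the intracellular volume
#' fraction \code{vi = V * rho * 1e-6} (dimensionless; the 1e-6 converts
#' pL * cells/uL to a volume fraction).
#'
#' @return Named list with elements \code{kio}, \code{V}, \code{rho},
#'   \code{vi}, each a length-2 numeric \code{c(min, max)}.
#' @export
madi_bounds <- function() {
  list(
    kio = c(0, 1.3e2),
    V   = c(1.13e-2, 2.1e2),
    rho = c(0.044e5, 580e5),
    vi  = c(0.5, 0.994)
  )
}

#' Intracellular volume fraction from cell volume and density
#'
#' @param V mean cell volume, pL/cell.
#' @param rho cell density, cells/uL tissue.
#' @return vi, dimensionless (1 pL * 1 cell/uL = 1e-6).
#' @export
vi_from <- function(V, rho) V * rho * 1e-6

#' Tissue parameter triple
#'
#' Bundles the three quantities the inversion estimates per voxel, plus the
#' compartmental free diffusivities used by the forward models. The derived
#' intracellular volume fraction \code{vi} and mean intracellular water
#' lifetime \code{tau_i = 1/k_io} are attached.
#'
#' @param kio water efflux rate constant, s^-1.
#' @param V mean cell volume, pL/cell.
#' @param rho cell density, cells/uL tissue.
#' @param D_i intracellular free diffusivity, um^2/ms.
#' @param D_e extracellular free diffusivity, um^2/ms.
#' @param check if TRUE (default) enforce the library bounds on
#'   \code{kio}, \code{V}, \code{rho}; \code{vi} must be < 1 always but is
#'   only required to sit inside [0.5, 0.994] for library entries.
#' @return Object of class \code{tissue_params}.
#' @export
tissue_params <- function(kio, V, rho, D_i = 1.0, D_e = 2.0, check = TRUE) {
  stopifnot(is.finite(kio), is.finite(V), is.finite(rho), D_i > 0, D_e > 0)
  vi <- vi_from(V, rho)
  if (vi >= 1)
    stop("infeasible geometry: vi = V*rho = ", signif(vi, 4), " >= 1")
  if (check) {
    b <- madi_bounds()
    if (kio < b$kio[1] || kio > b$kio[2]) stop("kio outside library bounds")
    if (V < b$V[1] || V > b$V[2]) stop("V outside library bounds")
    if (rho < b$rho[1] || rho > b$rho[2]) stop("rho outside library bounds")
  }
  structure(
    list(kio = kio, V = V, rho = rho, D_i = D_i, D_e = D_e,
         vi = vi, tau_i = if (kio > 0) 1 / kio else Inf),
    class = "tissue_params"
  )
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "tissue_params: k_io = %.3g /s, V = %.3g pL, rho = %.3g /uL (vi = %.3f)\n",
    x$kio, x$V, x$rho, x$vi))
  invisible(x)
}
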