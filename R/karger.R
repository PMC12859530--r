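#' Apparent compartment diffusivities for the analytic engine
#'
#' Maps a cell geometry onto effective Gaussian diffusivities for the
#' two-site exchange model. The intracellular diffusivity interpolates
#' between free diffusion (large cells) and the fully restricted long-time
#' limit where the mean-squared displacement saturates at the cell scale
#' (sphere-equivalent radius r, one-axis position variance r^2/5, hence
#' apparent D -> r^2 / (5 t_D)):
#'   Da_i = D_i / (1 + 5 D_i t_D / r^2).
#' The extracellular space is slowed by tortuosity with an Archie-type law
#'   Da_e = D_e * sqrt(1 - vi).
#'
#' @param V mean cell volume, pL.
#' @param vi intracellular volume fraction.
#' @param D_i,D_e free compartment diffusivities, um^2/ms.
#' @param t_D effective diffusion time, ms.
#' @return list with \code{Da_i}, \code{Da_e} (um^2/ms).
#' @export
apparent_diffusivities <- function(V, vi, D_i = 1.0, D_e = 2.0, t_D = 25 - 7 / 3) {
  r2 <- (3 * V * 1000 / (4 * pi))^(2 / 3)   # um^2
  list(Da_i = D_i / (1 + 5 * D_i * t_D / r2),
       Da_e = D_e * sqrt(pmax(0, 1 - vi)))
}

#' Analytic two-site exchange (Karger) decay
#'
#' Closed-form signal of two exchanging Gaussian compartments with apparent
#' diffusivities \code{Da_i}, \code{Da_e}, intracellular fraction \code{vi}
#' and efflux rate \code{k_io} (influx rate \code{k_oi = k_io vi/(1-vi)} by
#' mass balance). The coupled decay equations over the effective diffusion
#' time t_D = Delta - delta/3,
#'   dM/dt = A M,  A = [[-q^2 Da_i - k_io, k_oi], [k_io, -q^2 Da_e - k_oi]],
#' with q^2 t_D = b, are solved by the 2x2 eigenvalue decomposition; the
#' signal is the sum of the compartment magnetizations, normalized at the
#' smallest b.
#'
#' @param params \code{tissue_params} (uses \code{kio}, \code{vi}).
#' @param protocol \code{acquisition_protocol}.
#' @param Da_i,Da_e apparent compartment diffusivities, um^2/ms. Defaults
#'   map from the cell geometry via \code{\link{apparent_diffusivities}}.
#' @return \code{decay_curve}.
#' @export
karger_decay <- function(params, protocol, Da_i = NULL, Da_e = NULL) {
  stopifnot(inherits(params, "tissue_params"),
            inherits(protocol, "acquisition_protocol"))
  vi <- params$vi
  if (vi >= 1) stop("vi = 1 is infeasible (division by zero in mass balance)")
  if (is.null(Da_i) || is.null(Da_e)) {
    da <- apparent_diffusivities(params$V, vi, params$D_i, params$D_e,
                                 diffusion_time(protocol))
    if (is.null(Da_i)) Da_i <- da$Da_i
    if (is.null(Da_e)) Da_e <- da$Da_e
  }
  S <- karger_signal(protocol$b_values, vi, params$kio, Da_i, Da_e,
                     diffusion_time(protocol))
  decay_curve(protocol$b_values, S)
}

# unnormalized Karger signal; b s/mm^2, kio s^-1, D um^2/ms, t_D ms
karger_signal <- function(b, vi, kio, Da_i, Da_e, t_D) {
  t_s <- t_D * 1e-3                 # s
  D_i <- Da_i * 1e-3                # mm^2/s
  D_e <- Da_e * 1e-3
  koi <- if (vi < 1) kio * vi / (1 - vi) else Inf
  q2 <- b / t_s                     # 1/mm^2
  a11 <- -q2 * D_i - kio            # all 1/s
  a22 <- -q2 * D_e - koi
  a12 <- rep(koi, length(b))
  a21 <- rep(kio, length(b))
  tr <- a11 + a22
  disc <- sqrt(pmax(0, (a11 - a22)^2 + 4 * a12 * a21))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  M0i <- vi; M0e <- 1 - vi
  S <- numeric(length(b))
  for (j in seq_along(b)) {
    if (disc[j] < 1e-12 * max(1, abs(tr[j]))) {
      # degenerate eigenvalues: expm(A t) = e^{l t}(I + (A - l I) t)
      l <- l1[j]
      E <- exp(l * t_s)
      m_i <- E * ((1 + (a11[j] - l) * t_s) * M0i + a12[j] * t_s * M0e)
      m_e <- E * (a21[j] * t_s * M0i + (1 + (a22[j] - l) * t_s) * M0e)
    } else {
      # expm(A t) = (e^{l1 t}(A - l2 I) - e^{l2 t}(A - l1 I)) / (l1 - l2)
      E1 <- exp(l1[j] * t_s); E2 <- exp(l2[j] * t_s)
      d <- l1[j] - l2[j]
      m_i <- (E1 * ((a11[j] - l2[j]) * M0i + a12[j] * M0e) -
              E2 * ((a11[j] - l1[j]) * M0i + a12[j] * M0e)) / d
      m_e <- (E1 * (a21[j] * M0i + (a22[j] - l2[j]) * M0e) -
              E2 * (a21[j] * M0i + (a22[j] - l1[j]) * M0e)) / d
    }
    S[j] <- m_i + m_e
  }
  S
}
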