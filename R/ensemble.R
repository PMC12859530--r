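#' Build a periodic shrunk-Voronoi cell ensemble
#'
#' Seeds a periodic cubic box with Poisson-positioned points at density
#' \code{rho}, takes the (implicit) Voronoi tessellation of the seeds, and
#' shrinks every cell toward its centroid by the linear factor
#' \code{vi^(1/3)} so that the intracellular volume fraction equals
#' \code{vi = V * rho * 1e-6}. Because the tessellation is space-filling,
#' uniform linear shrinkage by \code{s} leaves exactly \code{s^3} of the box
#' intracellular, and the mean shrunk-cell volume equals \code{V}.
#'
#' Cells are never materialized as polytopes: a point \code{p} belongs to the
#' shrunk cell of seed \code{i} iff \code{c_i + (p - c_i)/s} falls in the
#' Voronoi cell of \code{i} (nearest-seed test). Cell centroids are estimated
#' by seeded Monte-Carlo integration.
#'
#' @param rho cell density, cells/uL tissue.
#' @param V mean cell volume, pL/cell.
#' @param box_edge edge of the periodic cube, um. Must hold >= 50 cells.
#' @param seed integer RNG seed (deterministic ensembles).
#' @param centroid_samples Monte-Carlo samples for centroid estimation.
#' @return Object of class \code{voronoi_ensemble} with fields
#'   \code{box_edge}, \code{seeds} (n x 3 matrix, um), \code{centroids},
#'   \code{shrink_factor}, \code{vi}, \code{V}, \code{rho},
#'   \code{membrane_crossing_prob} (NULL until calibrated).
#' @export
build_ensemble <- function(rho, V, box_edge, seed = 1L,
                           centroid_samples = NULL) {
  b <- madi_bounds()
  stopifnot(rho >= b$rho[1], rho <= b$rho[2], V >= b$V[1], V <= b$V[2])
  vi <- vi_from(V, rho)
  if (vi >= 1)
    stop("infeasible geometry: vi = ", signif(vi, 4), " >= 1")
  rho_um3 <- rho * 1e-9                 # cells per um^3
  n <- as.integer(round(rho_um3 * box_edge^3))
  if (n < 50)
    stop("degenerate ensemble: box holds only ", n, " cells (need >= 50)")
  set.seed(seed)
  seeds <- matrix(stats::runif(3L * n, 0, box_edge), ncol = 3)
  if (is.null(centroid_samples))
    centroid_samples <- max(20000L, 400L * n)
  centroids <- cpp_estimate_centroids(seeds, box_edge, as.integer(centroid_samples))
  structure(
    list(box_edge = box_edge, seeds = seeds, centroids = centroids,
         shrink_factor = vi^(1 / 3), vi = vi, V = V, rho = rho,
         n_cells = n, seed = seed,
         membrane_crossing_prob = NULL, calibrated_kio = NULL),
    class = "voronoi_ensemble"
  )
}

#' @export
print.voronoi_ensemble <- function(x, ...) {
  cat(sprintf(
    "voronoi_ensemble: %d cells in %.1f um box, vi = %.3f (shrink %.3f)%s\n",
    x$n_cells, x$box_edge, x$vi, x$shrink_factor,
    if (is.null(x$membrane_crossing_prob)) " [uncalibrated]"
    else sprintf(" [p_cross = %.4g for k_io = %.3g /s]",
                 x$membrane_crossing_prob, x$calibrated_kio)))
  invisible(x)
}

#' Monte-Carlo intracellular volume fraction of an ensemble
#'
#' Rejection estimate of the fraction of the box covered by shrunk cells,
#' used to check the geometric contract \code{fraction == vi}.
#'
#' @param ensemble \code{voronoi_ensemble}.
#' @param n number of uniform test points.
#' @param seed RNG seed.
#' @return Estimated intracellular fraction.
#' @export
intracellular_fraction <- function(ensemble, n = 1e5, seed = 1L) {
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n, 0, ensemble$box_edge), ncol = 3)
  idx <- cpp_in_shrunk_cell(pts, ensemble$seeds, ensemble$centroids,
                            ensemble$shrink_factor, ensemble$box_edge)
  mean(idx > 0L)
}

# sphere-equivalent cell diameter, um
cell_diameter <- function(V_pl) 2 * (3 * V_pl * 1000 / (4 * pi))^(1 / 3)

# default time step: walker step length <= min(0.1 um, cell diameter / 10)
default_dt <- function(V_pl, D_max) {
  step <- min(0.1, cell_diameter(V_pl) / 10)
  step^2 / (6 * D_max)
}

# censoring-aware exponential rate from residence times (MLE: events / time)
residence_rate <- function(res) {
  n_exit <- sum(!res$censored)
  if (n_exit == 0) return(0)
  n_exit / sum(res$time)
}

#' Calibrate the membrane crossing probability to a target efflux rate
#'
#' Finds the per-encounter crossing probability such that walkers started
#' inside cells leave with first-order rate constant \code{k_io}. Because
#' the encounter frequency seen by a walker depends weakly on the crossing
#' probability itself (near-membrane depletion), the probability is found
#' iteratively: measure the empirical rate by censored-exponential maximum
#' likelihood over walker residence times, apply the secant update
#' p <- p * k_io / k_measured, and stop once the measured rate is within
#' \code{tol} of the target. \code{k_io = 0} returns exactly 0.
#'
#' The calibrated probability is specific to the time step it was obtained
#' at; \code{\link{simulate_decay}} therefore reuses the calibration
#' \code{dt} by default.
#'
#' @param ensemble \code{voronoi_ensemble}.
#' @param kio target efflux rate constant, s^-1.
#' @param D_i intracellular diffusivity, um^2/ms.
#' @param dt time step, ms; default sets the walker step length to a
#'   twentieth of the cell diameter. The step must stay under a third of
#'   the cell diameter.
#' @param seed RNG seed.
#' @param n_walkers walkers per calibration run.
#' @param tol relative tolerance on the measured rate (default 0.025, half
#'   the 5 percent calibration contract, leaving room for verification
#'   noise).
#' @param max_iter maximum secant iterations.
#' @return Crossing probability in (0, 1]; attributes \code{measured_kio}
#'   (final-run estimate, s^-1), \code{dt} and \code{iterations}.
#' @export
calibrate_permeability <- function(ensemble, kio, D_i = 1.0, dt = NULL,
                                   seed = 1L, n_walkers = 4000L,
                                   tol = 0.025, max_iter = 8L) {
  stopifnot(inherits(ensemble, "voronoi_ensemble"), kio >= 0)
  if (is.null(dt)) dt <- calibration_dt(ensemble$V, D_i)
  if (kio == 0) return(structure(0, measured_kio = 0, dt = dt, iterations = 0L))
  step <- sqrt(6 * D_i * dt)
  if (step >= cell_diameter(ensemble$V) / 3)
    stop("dt too coarse: step length ", signif(step, 3),
         " um exceeds a third of the cell diameter")
  kio_ms <- kio * 1e-3                      # per ms
  t_max <- min(6 / kio_ms, 400)
  set.seed(seed)
  p <- 0.02
  k <- NA_real_
  for (it in seq_len(max_iter)) {
    run <- cpp_residence(ensemble$seeds, ensemble$centroids,
                         ensemble$shrink_factor, ensemble$box_edge,
                         D_i, dt, p, as.integer(n_walkers), t_max)
    k <- residence_rate(run)                # per ms
    if (k <= 0) stop("calibration failed: no exits observed")
    if (abs(k - kio_ms) / kio_ms < tol) break
    p_new <- p * kio_ms / k
    if (p_new > 1)
      stop("unattainable k_io at this dt (required probability ",
           signif(p_new, 3), " > 1); use a smaller dt")
    p <- p_new
  }
  structure(p, measured_kio = k * 1e3, dt = dt, iterations = it)
}

# calibration/simulation default time step: walker step = cell diameter / 20
calibration_dt <- function(V_pl, D_max) {
  (cell_diameter(V_pl) / 20)^2 / (6 * D_max)
}

#' Attach a calibrated crossing probability to an ensemble
#'
#' @param ensemble \code{voronoi_ensemble}.
#' @param prob crossing probability (from \code{\link{calibrate_permeability}};
#'   its \code{dt} attribute is carried over unless \code{dt} is given).
#' @param kio the efflux rate the probability was calibrated for, s^-1.
#' @param dt the time step the probability was calibrated at, ms.
#' @return Updated ensemble.
#' @export
set_permeability <- function(ensemble, prob, kio, dt = attr(prob, "dt")) {
  stopifnot(prob >= 0, prob <= 1)
  ensemble$membrane_crossing_prob <- as.numeric(prob)
  ensemble$calibrated_kio <- kio
  ensemble$calibrated_dt <- dt
  ensemble
}

#' Monte-Carlo PGSE decay of a calibrated ensemble
#'
#' Random walk with diffusivity \code{D_i} inside cells and \code{D_e}
#' outside, membrane transit by the calibrated per-encounter probability
#' (inward transit scaled by \code{sqrt(D_i/D_e)} to preserve the
#' equilibrium intracellular fraction), periodic boundaries, and phase
#' accrual during two rectangular gradient lobes of duration \code{delta}
#' separated by \code{Delta}. The gradient amplitude for each b follows
#' the PGSE relation b = (gamma*G*delta)^2 (Delta - delta/3). Signal is the
#' modulus of the ensemble-mean phasor, normalized at the smallest b.
#'
#' @param ensemble calibrated \code{voronoi_ensemble} (or an uncalibrated
#'   one when \code{params$kio == 0}).
#' @param params \code{tissue_params} (supplies \code{kio, D_i, D_e}).
#' @param protocol \code{acquisition_protocol}.
#' @param n_walkers number of walkers (>= 1e4 for reported curves).
#' @param dt time step, ms (default sized from the cell diameter).
#' @param seed RNG seed.
#' @return \code{decay_curve} with Monte-Carlo standard errors and
#'   attributes \code{S_intra} (curve over walkers that started inside and
#'   never crossed) and \code{frac_start_inside}.
#' @export
simulate_decay <- function(ensemble, params, protocol,
                           n_walkers = 10000L, dt = NULL, seed = 1L) {
  stopifnot(inherits(params, "tissue_params"),
            inherits(protocol, "acquisition_protocol"))
  free <- is.null(ensemble)
  if (!free) {
    stopifnot(inherits(ensemble, "voronoi_ensemble"))
    if (params$kio > 0 && is.null(ensemble$membrane_crossing_prob))
      stop("uncalibrated ensemble: call calibrate_permeability()/set_permeability() first")
    if (!is.null(ensemble$calibrated_kio) &&
        abs(ensemble$calibrated_kio - params$kio) > 1e-9 * max(1, params$kio))
      stop("ensemble calibrated for k_io = ", ensemble$calibrated_kio,
           ", not ", params$kio)
    p_io <- if (is.null(ensemble$membrane_crossing_prob)) 0
            else ensemble$membrane_crossing_prob
  }
  if (is.null(dt)) {
    dt <- if (free) 0.01
          else ensemble$calibrated_dt %||%
            calibration_dt(params$V, max(params$D_i, params$D_e))
  }
  if (!free && sqrt(6 * max(params$D_i, params$D_e) * dt) >=
        cell_diameter(params$V) / 3)
    stop("dt too coarse for this cell size")
  set.seed(seed)
  if (free) {
    w <- cpp_walk(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3),
                  0, 100, params$D_i, params$D_e, 0, dt,
                  protocol$delta, protocol$Delta, as.integer(n_walkers))
  } else {
    w <- cpp_walk(ensemble$seeds, ensemble$centroids, ensemble$shrink_factor,
                  ensemble$box_edge, params$D_i, params$D_e, p_io, dt,
                  protocol$delta, protocol$Delta, as.integer(n_walkers))
  }
  sig <- phasor_signal(w$F, protocol)
  curve <- decay_curve(protocol$b_values, sig$S, se = sig$se)
  keep <- w$start_inside & !w$crossed
  if (any(keep)) {
    si <- phasor_signal(w$F[keep], protocol)
    attr(curve, "S_intra") <- si$S   # unnormalized modulus, intracellular-only
  }
  keep_e <- !w$start_inside & !w$crossed
  if (any(keep_e)) {
    se_ <- phasor_signal(w$F[keep_e], protocol)
    attr(curve, "S_extra") <- se_$S  # extracellular never-crossed population
  }
  attr(curve, "frac_start_inside") <- mean(w$start_inside)
  curve
}

# signal and phasor standard error at each protocol b from the per-walker
# displacement integrals F (um*ms)
phasor_signal <- function(F, protocol) {
  td <- diffusion_time(protocol)                    # ms
  b_ms <- protocol$b_values * 1e-3                  # ms/um^2
  gammaG <- sqrt(b_ms / td) / protocol$delta        # 1/(um*ms)
  n <- length(F)
  S <- numeric(length(b_ms))
  se <- numeric(length(b_ms))
  for (j in seq_along(b_ms)) {
    phi <- gammaG[j] * F
    m <- complex(real = mean(cos(phi)), imaginary = mean(sin(phi)))
    S[j] <- Mod(m)
    rot <- cos(phi - Arg(m))
    se[j] <- stats::sd(rot) / sqrt(n)
  }
  list(S = S, se = se)
}
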