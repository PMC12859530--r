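#' Parameter grid over the library bounds
#'
#' Axes span the full library bounds inclusive: \code{k_io} linearly, \code{V}
#' and \code{rho} logarithmically. Candidate triples whose intracellular
#' volume fraction \code{vi = V*rho*1e-6} falls outside [0.5, 0.994] are
#' excluded. Retained triples are ordered by (k_io, V, rho) so that exact
#' residual ties in matching resolve to the smallest k_io, then smallest V.
#'
#' @param n_kio,n_V,n_rho points per axis (each >= 2). Defaults give a
#'   half-step quantization of ~8 percent in V and rho and ~2.8 s^-1 in
#'   k_io, sized to the 10-percent recovery contract of the inversion.
#' @return Object of class \code{parameter_grid}: axes, retained triples
#'   (data.frame kio, V, rho, vi), candidate and retained counts.
#' @export
make_grid <- function(n_kio = 24L, n_V = 64L, n_rho = 64L) {
  stopifnot(n_kio >= 2, n_V >= 2, n_rho >= 2)
  b <- madi_bounds()
  kio_axis <- seq(b$kio[1], b$kio[2], length.out = n_kio)
  V_axis <- 10^seq(log10(b$V[1]), log10(b$V[2]), length.out = n_V)
  rho_axis <- 10^seq(log10(b$rho[1]), log10(b$rho[2]), length.out = n_rho)
  cand <- expand.grid(kio = kio_axis, V = V_axis, rho = rho_axis,
                      KEEP.OUT.ATTRS = FALSE)
  cand$vi <- vi_from(cand$V, cand$rho)
  keep <- cand$vi >= b$vi[1] & cand$vi <= b$vi[2]
  triples <- cand[keep, , drop = FALSE]
  triples <- triples[order(triples$kio, triples$V, triples$rho), ]
  rownames(triples) <- NULL
  structure(
    list(kio_axis = kio_axis, V_axis = V_axis, rho_axis = rho_axis,
         triples = triples, n_candidates = nrow(cand),
         n_retained = nrow(triples)),
    class = "parameter_grid"
  )
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf(
    "parameter_grid: %d x %d x %d axes, %d / %d triples retained (vi in [0.5, 0.994])\n",
    length(x$kio_axis), length(x$V_axis), length(x$rho_axis),
    x$n_retained, x$n_candidates))
  invisible(x)
}

#' Generate the decay library over a parameter grid
#'
#' One normalized decay curve per retained triple, from the analytic
#' two-site-exchange engine (default) or the Monte-Carlo random-walk
#' simulator. Deterministic given \code{seed}. Triples on which the engine
#' fails are dropped with a warning, never silently.
#'
#' @param grid \code{parameter_grid}.
#' @param protocol \code{acquisition_protocol}.
#' @param engine \code{"analytic"} or \code{"monte-carlo"}.
#' @param seed RNG seed (Monte-Carlo engine).
#' @param D_i,D_e free compartment diffusivities, um^2/ms.
#' @param mc list of Monte-Carlo settings (\code{n_walkers}, \code{box_cells}
#'   target cell count) used when \code{engine = "monte-carlo"}.
#' @return Object of class \code{decay_library}: \code{params} (data.frame),
#'   \code{curves} (n_triples x n_b matrix, each row normalized at the first
#'   b), \code{b}, \code{engine}, \code{protocol}, \code{fingerprint}.
#' @export
generate_library <- function(grid, protocol, engine = c("analytic", "monte-carlo"),
                             seed = 1L, D_i = 1.0, D_e = 2.0,
                             mc = list(n_walkers = 5000L, box_cells = 60)) {
  engine <- match.arg(engine)
  stopifnot(inherits(grid, "parameter_grid"),
            inherits(protocol, "acquisition_protocol"))
  tr <- grid$triples
  nb <- length(protocol$b_values)
  curves <- matrix(NA_real_, nrow(tr), nb)
  t_D <- diffusion_time(protocol)
  if (engine == "analytic") {
    da <- apparent_diffusivities(tr$V, tr$vi, D_i, D_e, t_D)
    for (i in seq_len(nrow(tr))) {
      S <- karger_signal(protocol$b_values, tr$vi[i], tr$kio[i],
                         da$Da_i[i], da$Da_e[i], t_D)
      curves[i, ] <- S / S[1]
    }
  } else {
    for (i in seq_len(nrow(tr))) {
      ok <- tryCatch({
        box <- (mc$box_cells / (tr$rho[i] * 1e-9))^(1 / 3)
        ens <- build_ensemble(tr$rho[i], tr$V[i], box, seed = seed + i)
        if (tr$kio[i] > 0) {
          p <- calibrate_permeability(ens, tr$kio[i], D_i, seed = seed + i)
          ens <- set_permeability(ens, p, tr$kio[i])
        }
        pars <- tissue_params(tr$kio[i], tr$V[i], tr$rho[i], D_i, D_e)
        cur <- simulate_decay(ens, pars, protocol,
                              n_walkers = mc$n_walkers, seed = seed + i)
        curves[i, ] <- cur$S
        TRUE
      }, error = function(e) {
        warning("dropping triple ", i, " (", conditionMessage(e), ")")
        FALSE
      })
    }
  }
  drop <- !stats::complete.cases(curves)
  if (any(drop)) {
    tr <- tr[!drop, , drop = FALSE]
    curves <- curves[!drop, , drop = FALSE]
  }
  structure(
    list(params = tr, curves = curves, b = protocol$b_values,
         engine = engine, protocol = protocol, grid = grid, seed = seed,
         fingerprint = paste(c(protocol$b_values, protocol$delta,
                               protocol$Delta), collapse = ",")),
    class = "decay_library"
  )
}

#' @export
print.decay_library <- function(x, ...) {
  cat(sprintf("decay_library: %d curves over %d b-values (%s engine)\n",
              nrow(x$curves), length(x$b), x$engine))
  invisible(x)
}

#' Write / read a decay library as a flat CSV table
#'
#' Long format with columns (kio, V, rho, vi, b, S); one row per curve point.
#'
#' @param library \code{decay_library}.
#' @param path file path.
#' @return \code{read_library} returns a \code{decay_library} (protocol
#'   reconstructed with default gradient timing).
#' @export
write_library <- function(library, path) {
  tr <- library$params
  nb <- length(library$b)
  df <- data.frame(
    kio = rep(tr$kio, each = nb), V = rep(tr$V, each = nb),
    rho = rep(tr$rho, each = nb), vi = rep(tr$vi, each = nb),
    b = rep(library$b, nrow(tr)), S = as.vector(t(library$curves))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path)
  b <- sort(unique(df$b))
  key <- paste(df$kio, df$V, df$rho)
  ids <- unique(key)
  tr <- df[!duplicated(key), c("kio", "V", "rho", "vi")]
  rownames(tr) <- NULL
  curves <- matrix(NA_real_, length(ids), length(b))
  idx <- match(key, ids)
  bidx <- match(df$b, b)
  curves[cbind(idx, bidx)] <- df$S
  structure(
    list(params = tr, curves = curves, b = b, engine = "file",
         protocol = acquisition_protocol(b),
         fingerprint = paste(b, collapse = ",")),
    class = "decay_library"
  )
}

#' Average repeated DWI volumes
#'
#' Collapses a raw 4-D stack whose 4th dimension runs over the expanded
#' acquisition (repeats of each b consecutive, in protocol b-order) to one
#' arithmetic-mean volume per b-value.
#'
#' @param raw 4-D array \code{[x, y, z, sum(repeats)]}.
#' @param protocol \code{acquisition_protocol}.
#' @return 4-D array \code{[x, y, z, n_b]} in protocol b-order.
#' @export
average_repeats <- function(raw, protocol) {
  stopifnot(length(dim(raw)) == 4)
  n_total <- sum(protocol$repeats)
  if (dim(raw)[4] != n_total)
    stop("protocol error: expected ", n_total, " volumes, found ", dim(raw)[4])
  nb <- length(protocol$b_values)
  out <- array(0, c(dim(raw)[1:3], nb))
  off <- 0L
  for (j in seq_len(nb)) {
    r <- protocol$repeats[j]
    vols <- raw[, , , off + seq_len(r), drop = FALSE]
    out[, , , j] <- apply(vols, 1:3, mean)
    off <- off + r
  }
  out
}
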