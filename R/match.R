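#' Match one voxel decay against the library
#'
#' Exhaustive weighted-least-squares match: returns the library triple
#' minimizing the weighted sum of squared differences between the voxel's
#' normalized decay and each library curve. The default weights are the
#' protocol repeat counts (inverse noise variance of the averaged volumes);
#' pass \code{weights = 1} for plain least squares. Exact residual ties
#' resolve to the smallest k_io, then the smallest V (the library rows are
#' kept in that order). Non-finite signal values mark the voxel invalid
#' rather than raising an error.
#'
#' @param signal \code{decay_curve} or numeric signal vector over the
#'   library's b-values (normalized at the first b; re-normalized here).
#' @param library \code{decay_library}.
#' @param weights per-b weights; defaults to the library protocol's repeat
#'   counts, recycled to the b-list length.
#' @return list: \code{kio}, \code{V}, \code{rho}, \code{vi},
#'   \code{residual}, \code{index} (library row), \code{valid} (FALSE for
#'   non-finite input or a bound-sitting match).
#' @export
match_voxel <- function(signal, library, weights = NULL) {
  S <- if (inherits(signal, "decay_curve")) signal$S else as.numeric(signal)
  if (length(S) != length(library$b))
    stop("signal b-list does not match library b-list")
  w <- match_weights(library, weights)
  if (!all(is.finite(S)) || S[1] <= 0)
    return(list(kio = NA_real_, V = NA_real_, rho = NA_real_, vi = NA_real_,
                residual = NA_real_, index = NA_integer_, valid = FALSE))
  S <- S / S[1]
  d <- sweep(library$curves, 2, S)
  ssd <- as.vector((d * d) %*% w)
  i <- which.min(ssd)   # rows pre-ordered by (kio, V, rho): ties -> smallest
  p <- library$params[i, ]
  list(kio = p$kio, V = p$V, rho = p$rho, vi = p$vi,
       residual = ssd[i], index = i,
       valid = !on_grid_bound(p, library))
}

# default matching weights: protocol repeat counts (inverse noise variance
# of repeat-averaged volumes), else equal
match_weights <- function(library, weights) {
  nb <- length(library$b)
  if (!is.null(weights)) return(rep_len(as.numeric(weights), nb))
  if (!is.null(library$protocol) && !is.null(library$protocol$repeats) &&
      length(library$protocol$repeats) == nb)
    return(as.numeric(library$protocol$repeats))
  rep(1, nb)
}

# does a matched triple sit on any axis bound of the generating grid?
on_grid_bound <- function(p, library) {
  ax <- if (!is.null(library$grid)) {
    library$grid
  } else {
    list(kio_axis = range(library$params$kio),
         V_axis = range(library$params$V),
         rho_axis = range(library$params$rho))
  }
  near <- function(a, b) abs(a - b) <= 1e-9 * max(1, abs(b))
  near(p$kio, min(ax$kio_axis)) || near(p$kio, max(ax$kio_axis)) ||
    near(p$V, min(ax$V_axis)) || near(p$V, max(ax$V_axis)) ||
    near(p$rho, min(ax$rho_axis)) || near(p$rho, max(ax$rho_axis))
}

#' Fit parametric maps by library matching
#'
#' Runs \code{\link{match_voxel}} (vectorized) over every voxel inside the
#' mask of an averaged DWI stack. Voxels outside the mask carry \code{NA}.
#' The returned object reports the fraction of invalid or bound-sitting
#' voxels rather than hiding them.
#'
#' @param stack averaged 4-D array \code{[x, y, z, n_b]} in library b-order.
#' @param mask logical/0-1 array \code{[x, y, z]}; may be all-FALSE.
#' @param library \code{decay_library}.
#' @param resid_thresh residual above which a voxel is flagged invalid
#'   (default \code{Inf}: only bound-sitting invalidates).
#' @param weights per-b matching weights (see \code{\link{match_voxel}}).
#' @return Object of class \code{parametric_maps}: arrays \code{kio},
#'   \code{V}, \code{rho}, \code{vi}, \code{residual}, logical \code{valid},
#'   plus \code{n_fitted}, \code{n_invalid}, \code{frac_invalid}.
#' @export
fit_image <- function(stack, mask, library, resid_thresh = Inf,
                      weights = NULL) {
  stopifnot(length(dim(stack)) == 4)
  dims <- dim(stack)[1:3]
  if (!all(dim(mask) == dims))
    stop("input error: stack and mask geometries differ")
  if (dim(stack)[4] != length(library$b))
    stop("input error: stack volume count differs from library b-list")
  mk <- array(as.logical(mask), dims)
  empty <- array(NA_real_, dims)
  maps <- list(kio = empty, V = empty, rho = empty, vi = empty,
               residual = empty,
               valid = array(FALSE, dims))
  vox <- which(mk)
  if (length(vox) > 0) {
    X <- matrix(stack, prod(dims), dim(stack)[4])[vox, , drop = FALSE]
    fin <- rowSums(!is.finite(X)) == 0 & X[, 1] > 0
    Xn <- X / X[, 1]
    w <- match_weights(library, weights)
    L <- sweep(library$curves, 2, sqrt(w), "*")
    # weighted ssd(i,j) = |x_i|^2 - 2 x_i . l_j + |l_j|^2, argmin over j
    best <- rep(NA_integer_, nrow(Xn))
    resid <- rep(NA_real_, nrow(Xn))
    if (any(fin)) {
      Xw <- sweep(Xn[fin, , drop = FALSE], 2, sqrt(w), "*")
      G <- Xw %*% t(L)
      l2 <- rowSums(L * L)
      x2 <- rowSums(Xw^2)
      ssd <- sweep(-2 * G, 2, l2, "+") + x2
      bi <- max.col(-ssd, ties.method = "first")
      best[fin] <- bi
      resid[fin] <- ssd[cbind(seq_len(nrow(ssd)), bi)]
    }
    ok <- !is.na(best)
    p <- library$params
    bound <- vapply(which(ok), function(r) on_grid_bound(p[best[r], ], library),
                    logical(1))
    maps$kio[vox[ok]] <- p$kio[best[ok]]
    maps$V[vox[ok]] <- p$V[best[ok]]
    maps$rho[vox[ok]] <- p$rho[best[ok]]
    maps$vi[vox[ok]] <- p$vi[best[ok]]
    maps$residual[vox[ok]] <- resid[ok]
    maps$valid[vox[ok]] <- !bound & resid[ok] <= resid_thresh
  }
  n_fit <- length(vox)
  n_inv <- if (n_fit) sum(!maps$valid[vox]) else 0L
  structure(
    c(maps, list(n_fitted = n_fit, n_invalid = n_inv,
                 frac_invalid = if (n_fit) n_inv / n_fit else NA_real_)),
    class = "parametric_maps"
  )
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf(
    "parametric_maps: %d fitted voxels, %d invalid/bound-sitting (%.1f%%)\n",
    x$n_fitted, x$n_invalid, 100 * (x$frac_invalid %||% NA_real_)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
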