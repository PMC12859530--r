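#' Two-point apparent diffusion coefficient map
#'
#' ADC = -ln(S_b / S_ref) / b, in mm^2/s. (The ratio is divided by b: the
#' log-ratio is dimensionless and ADC must carry 1/b units.) Voxels with a
#' non-positive diffusion-weighted signal are marked missing.
#'
#' @param S_b diffusion-weighted volume (array).
#' @param S_ref reference volume of identical geometry (the lowest-b image
#'   stands in for the T2-weighted reference).
#' @param b b-value of \code{S_b} relative to the reference, s/mm^2
#'   (default 1013).
#' @return ADC array, mm^2/s.
#' @export
compute_adc <- function(S_b, S_ref, b = 1013) {
  if (!all(dim(S_b) == dim(S_ref)))
    stop("input error: volume geometries differ")
  adc <- -log(S_b / S_ref) / b
  adc[!is.finite(adc) | S_b <= 0 | S_ref <= 0] <- NA_real_
  adc
}

#' Combination biomarker maps
#'
#' Voxel-wise products of the fitted maps: \code{kioV = k_io * V}
#' (pL/s/cell, water efflux rate per cell), \code{kioVrho = k_io * V * rho}
#' (pL/s/uL tissue, efflux rate per tissue volume; the paper-style table
#' unit is this value / 1e6), and \code{vi = V * rho * 1e-6}. Invalid
#' voxels propagate as missing.
#'
#' @param maps \code{parametric_maps}.
#' @param valid_only if TRUE (default) blank voxels whose validity flag is
#'   FALSE.
#' @return list of arrays \code{kioV}, \code{kioVrho}, \code{vi}.
#' @export
combine_maps <- function(maps, valid_only = TRUE) {
  stopifnot(inherits(maps, "parametric_maps"))
  kioV <- maps$kio * maps$V
  kioVrho <- maps$kio * maps$V * maps$rho
  vi <- vi_from(maps$V, maps$rho)
  if (valid_only) {
    bad <- !maps$valid
    kioV[bad] <- NA_real_; kioVrho[bad] <- NA_real_; vi[bad] <- NA_real_
  }
  list(kioV = kioV, kioVrho = kioVrho, vi = vi)
}

#' Per-animal ROI summary
#'
#' Median and mean of a parameter map over the valid voxels of one ROI.
#'
#' @param map parameter array.
#' @param roi_mask logical/0-1 array, same geometry.
#' @param animal animal identifier carried into the output.
#' @param roi ROI label carried into the output.
#' @return data.frame (animal, roi, median, mean, n_voxels).
#' @export
summarize_roi <- function(map, roi_mask, animal = NA, roi = "roi") {
  if (!all(dim(map) == dim(roi_mask)))
    stop("input error: map and ROI geometries differ")
  v <- map[as.logical(roi_mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0)
    stop("empty ROI '", roi, "': no valid voxels")
  data.frame(animal = animal, roi = roi,
             median = stats::median(v), mean = mean(v), n_voxels = length(v))
}

#' Paired group contrast of per-animal ROI medians
#'
#' Mean-of-medians with standard error for each group, the percent
#' difference 100 * (mean_A - mean_B) / mean_B, and a classical two-sided
#' paired t-test. With fewer than 2 pairs only the means are reported; with
#' identical pairs the difference is 0 and the p-value is flagged degenerate
#' (NA).
#'
#' @param medians_a,medians_b equal-length per-animal medians, paired order.
#' @return list: \code{mean_a}, \code{se_a}, \code{mean_b}, \code{se_b},
#'   \code{pct_diff}, \code{p_value}, \code{n}, \code{degenerate}.
#' @export
group_contrast <- function(medians_a, medians_b) {
  if (length(medians_a) != length(medians_b))
    stop("paired contrast requires equal-length animal lists")
  n <- length(medians_a)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- list(mean_a = mean(medians_a), se_a = se(medians_a),
              mean_b = mean(medians_b), se_b = se(medians_b),
              pct_diff = 100 * (mean(medians_a) - mean(medians_b)) / mean(medians_b),
              p_value = NA_real_, n = n, degenerate = FALSE)
  d <- medians_a - medians_b
  if (n < 2) return(out)
  if (all(d == 0) || stats::sd(d) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  out$p_value <- stats::t.test(medians_a, medians_b, paired = TRUE)$p.value
  out
}
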