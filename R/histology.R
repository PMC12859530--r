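#' 3-D nuclear counting rules for segmented confocal objects
#'
#' Applies the Z-stack counting rules to a table of segmented nuclear
#' objects: objects below the region-specific XY-area threshold are excluded
#' (10 um^2 in tumor fields, 3 um^2 in peritumor/contralateral fields, where
#' different segmentation settings are used); objects under 2 um in Z are
#' excluded as partial nuclei at the stack edge; objects with Z extent in
#' [2, 7.2) count as one nucleus, in [7.2, 15] as two (unsplit doubles).
#' Objects beyond 15 um in Z are counted as two with a warning tally (the
#' rules are silent there; such objects span most of the 20-um stack).
#' A logical \code{manually_added} column, if present, adds its TRUEs to the
#' count unconditionally (hand-added nuclei bypass the filters).
#'
#' @param table data.frame with columns \code{region} (one of
#'   \code{"tumor"}, \code{"peritumor"}, \code{"contralateral"}),
#'   \code{xy_area_um2}, \code{z_extent_um}; optional \code{manually_added}.
#' @return list: \code{count} (corrected nucleus count), \code{tally}
#'   (named exclusion/assignment tally), \code{region}.
#' @export
filter_and_count <- function(table) {
  need <- c("region", "xy_area_um2", "z_extent_um")
  if (!all(need %in% names(table)))
    stop("object table must have columns ", paste(need, collapse = ", "))
  region <- unique(as.character(table$region))
  if (length(region) > 1) stop("one region per table")
  if (length(region) == 0) region <- NA_character_
  if (!is.na(region) && !region %in% c("tumor", "peritumor", "contralateral"))
    stop("unknown region label: ", region)
  area_min <- if (identical(region, "tumor")) 10 else 3
  manual <- if ("manually_added" %in% names(table))
    as.logical(table$manually_added) else rep(FALSE, nrow(table))
  auto <- table[!manual, , drop = FALSE]
  small_area <- auto$xy_area_um2 < area_min
  small_z <- auto$z_extent_um < 2
  kept <- auto[!small_area & !small_z, , drop = FALSE]
  singles <- kept$z_extent_um >= 2 & kept$z_extent_um < 7.2
  doubles <- kept$z_extent_um >= 7.2 & kept$z_extent_um <= 15
  over <- kept$z_extent_um > 15
  count <- sum(singles) + 2L * sum(doubles) + 2L * sum(over) + sum(manual)
  if (any(over))
    warning(sum(over), " object(s) exceed 15 um in Z; counted as doubles")
  list(count = count,
       tally = c(excluded_area = sum(small_area),
                 excluded_z = sum(small_z & !small_area),
                 singles = sum(singles), doubles = sum(doubles),
                 over_15um = sum(over), manually_added = sum(manual)),
       region = region)
}

#' Nuclear density of a confocal field
#'
#' count / field volume, converted um^-3 -> cells/uL (x 1e9).
#'
#' @param count nucleus count (>= 0).
#' @param field_dims field dimensions c(x, y, z), um (default the
#'   160 x 160 x 20 um Z-stack).
#' @return density, cells/uL.
#' @export
nucleus_density <- function(count, field_dims = c(160, 160, 20)) {
  stopifnot(count >= 0, all(field_dims > 0))
  count / prod(field_dims) * 1e9
}

#' Correct a histological density for fixation shrinkage
#'
#' Fixed tissue is linearly smaller by the shrinkage fraction, so a measured
#' density overstates the in vivo density; the in vivo value is
#' rho_hist * (1 - linear_shrinkage)^3. The default 3 percent linear
#' shrinkage corresponds to ~9 percent volume shrinkage.
#'
#' @param rho_hist measured density, cells/uL.
#' @param linear_shrinkage linear shrinkage fraction in [0, 1).
#' @return in vivo density, cells/uL.
#' @export
shrinkage_correct <- function(rho_hist, linear_shrinkage = 0.03) {
  stopifnot(linear_shrinkage >= 0, linear_shrinkage < 1)
  rho_hist * (1 - linear_shrinkage)^3
}

#' Compare imaging and histological cell densities
#'
#' Ordinary least squares of the imaging density on the histological
#' density, with an identity-line comparison.
#'
#' @param rho_madi imaging (fitted) densities.
#' @param rho_hist histological densities, same length and pairing (>= 3
#'   pairs).
#' @return list: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n_above_identity}, \code{mean_residual_vs_identity},
#'   \code{table} (per-pair data.frame), \code{fit} (the \code{lm} object).
#' @export
compare_to_madi <- function(rho_madi, rho_hist) {
  if (length(rho_madi) != length(rho_hist))
    stop("paired densities required")
  if (length(rho_madi) < 3) stop("need at least 3 pairs")
  fit <- stats::lm(rho_madi ~ rho_hist)
  resid_id <- rho_madi - rho_hist
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_above_identity = sum(resid_id > 0),
       mean_residual_vs_identity = mean(resid_id),
       table = data.frame(rho_hist = rho_hist, rho_madi = rho_madi,
                          above_identity = resid_id > 0),
       fit = fit)
}
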