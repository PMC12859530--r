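#' Radioactive decay adjustment of injected activity
#'
#' A * 2^(-t / T_half): the activity remaining after the latent period
#' between injection and acquisition (18F half-life 110 min).
#'
#' @param injected_activity injected activity, Bq.
#' @param latent_time latent period, min.
#' @param half_life isotope half-life, min (default 110, 18F).
#' @return Decay-adjusted activity, Bq.
#' @export
decay_adjust <- function(injected_activity, latent_time, half_life = 110) {
  if (half_life <= 0) stop("half_life must be positive")
  if (any(latent_time < 0)) stop("input error: negative latent time")
  injected_activity * 2^(-latent_time / half_life)
}

#' PET study record
#'
#' @param activity activity volume (array), Bq/mL.
#' @param injected_activity injected activity, Bq.
#' @param body_mass animal body mass, g.
#' @param latent_time injection-to-acquisition latent period, min.
#' @param half_life isotope half-life, min.
#' @return Object of class \code{pet_study}.
#' @export
pet_study <- function(activity, injected_activity, body_mass,
                      latent_time = 60, half_life = 110) {
  stopifnot(injected_activity > 0, body_mass > 0, latent_time >= 0,
            half_life > 0)
  structure(list(activity = activity, injected_activity = injected_activity,
                 body_mass = body_mass, latent_time = latent_time,
                 half_life = half_life),
            class = "pet_study")
}

#' Standardized uptake value map
#'
#' SUV = voxel activity (Bq/mL) * body mass (g) / decay-adjusted injected
#' activity (Bq), dimensionless.
#'
#' @param study \code{pet_study}.
#' @return SUV array.
#' @export
compute_suv <- function(study) {
  stopifnot(inherits(study, "pet_study"))
  adj <- decay_adjust(study$injected_activity, study$latent_time,
                      study$half_life)
  if (adj <= 0) stop("input error: zero decay-adjusted activity")
  study$activity * study$body_mass / adj
}

#' Maximum SUV inside an ROI
#'
#' @param suv SUV array.
#' @param roi_mask logical/0-1 array, same geometry.
#' @return SUV_max scalar.
#' @export
suv_max <- function(suv, roi_mask) {
  if (!all(dim(suv) == dim(roi_mask)))
    stop("input error: SUV and ROI geometries differ")
  v <- suv[as.logical(roi_mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("empty ROI")
  max(v)
}

#' Tissue glucose uptake rate from SUV_max
#'
#' tMR_glc = 3.2 * SUV_max, pmole(glc)/s/uL tissue (18F-FDG calibration
#' factor).
#'
#' @param suvmax SUV_max (>= 0).
#' @return tMR_glc, pmole/s/uL.
#' @export
tmr_glc <- function(suvmax) {
  stopifnot(all(suvmax >= 0))
  3.2 * suvmax
}

#' Per-cell glucose uptake rate
#'
#' cMR_glc = tMR_glc / rho, converted pmole -> amole (x 1e6).
#'
#' @param tmr tissue glucose uptake rate, pmole/s/uL.
#' @param rho cell density, cells/uL.
#' @return cMR_glc, amole(glc)/s/cell.
#' @export
cmr_glc <- function(tmr, rho) {
  if (any(rho <= 0)) stop("rho must be positive")
  tmr / rho * 1e6
}

#' Water-glucose index
#'
#' Ratio of the per-cell water efflux rate (cMR_AWC = k_io*V, pL/s/cell) to
#' the per-cell glucose uptake rate (amole/s/cell). Numerically
#' cMR_AWC / cMR_glc is already uL H2O per pmole glucose (pL/amole =
#' uL/pmole); the molar ratio multiplies by 1e6 pL/uL and the molar density
#' of water (default 55.5 pmol H2O per pL).
#'
#' @param cmr_awc per-cell water efflux rate, pL/s/cell.
#' @param cmrglc per-cell glucose uptake rate, amole/s/cell (> 0).
#' @param water_pmol_per_pl molar density of water, pmol/pL.
#' @return list: \code{wgi} (uL H2O / pmole glc), \code{molar_ratio}
#'   (molecules H2O per molecule glucose).
#' @export
wgi <- function(cmr_awc, cmrglc, water_pmol_per_pl = 55.5) {
  if (any(cmrglc <= 0)) stop("zero glucose rate")
  w <- cmr_awc / cmrglc
  list(wgi = w, molar_ratio = w * 1e6 * water_pmol_per_pl)
}
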