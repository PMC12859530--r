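#' Phantom specification
#'
#' Desk-scale stand-in for the rat-glioma study geometry: a 64 x 64 x 3
#' grid at 0.312 x 0.312 x 1.5 mm with an ellipsoidal tumor in the right
#' hemisphere, a peritumoral shell around it, a mirror-image contralateral
#' region, and background. Each region carries a (rho, vi, k_io) triple at
#' the magnitudes of the untreated-cohort medians, with the cell volume
#' derived as V = vi / rho (the reported per-region averages are not
#' mutually consistent as a product, so rho and vi are taken as primary),
#' plus a target SUV.
#'
#' @param dims grid dimensions.
#' @param vox_mm voxel size, mm.
#' @param regions named list (tumor, peritumor, contralateral, background)
#'   of lists with elements \code{rho} (cells/uL), \code{vi}, \code{kio}
#'   (s^-1), \code{suv}.
#' @param snr signal-to-noise ratio at the lowest b-value.
#' @param seed RNG seed.
#' @param grid optional \code{parameter_grid}: when supplied, each region's
#'   (k_io, V, rho) is snapped to the nearest retained grid triple (log
#'   metric in V and rho), so the phantom truths are representable by the
#'   inversion dictionary and recovery measures noise response rather than
#'   grid quantization.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(dims = c(64, 64, 3),
                         vox_mm = c(0.312, 0.312, 1.5),
                         regions = list(
                           tumor         = list(rho = 27.5e5, vi = 0.885, kio = 40.7, suv = 7.67),
                           peritumor     = list(rho = 7.61e5, vi = 0.835, kio = 44.3, suv = 6.9),
                           contralateral = list(rho = 10.4e5, vi = 0.889, kio = 34.9, suv = 4.16),
                           background    = list(rho = 10.0e5, vi = 0.88,  kio = 35.0, suv = 2.5)
                         ),
                         snr = 50, seed = 1L, grid = NULL) {
  b <- madi_bounds()
  for (nm in names(regions)) {
    r <- regions[[nm]]
    V <- r$vi / (r$rho * 1e-6)
    if (r$rho < b$rho[1] || r$rho > b$rho[2] ||
        V < b$V[1] || V > b$V[2] ||
        r$kio < b$kio[1] || r$kio > b$kio[2] || r$vi >= 1)
      stop("inconsistent region spec '", nm, "': outside library bounds")
    regions[[nm]]$V <- V
    if (!is.null(grid)) {
      tr <- grid$triples
      d <- ((tr$kio - r$kio) / diff(b$kio))^2 +
        log(tr$V / V)^2 + log(tr$rho / r$rho)^2
      s <- tr[which.min(d), ]
      regions[[nm]][c("kio", "V", "rho", "vi")] <-
        as.list(s[c("kio", "V", "rho", "vi")])
    }
  }
  structure(list(dims = dims, vox_mm = vox_mm, regions = regions,
                 snr = snr, seed = seed, snapped = !is.null(grid)),
            class = "phantom_spec")
}

# region label array: 0 background, 1 tumor, 2 peritumor, 3 contralateral
phantom_labels <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- round(nx * 0.70); cy <- round(ny / 2)
  rx <- round(nx * 0.11); ry <- round(ny * 0.14)
  lab <- array(0L, dims)
  xi <- matrix(rep(seq_len(nx), ny), nx, ny)
  yi <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  e_t <- ((xi - cx) / rx)^2 + ((yi - cy) / ry)^2 <= 1
  e_p <- ((xi - cx) / (rx + 3))^2 + ((yi - cy) / (ry + 3))^2 <= 1 & !e_t
  cxm <- nx + 1 - cx
  e_c <- ((xi - cxm) / rx)^2 + ((yi - cy) / ry)^2 <= 1
  sl <- matrix(0L, nx, ny)
  sl[e_c] <- 3L; sl[e_p] <- 2L; sl[e_t] <- 1L
  for (z in seq_len(nz)) lab[, , z] <- sl
  lab
}

#' Build ground-truth parameter maps and ROI masks from a spec
#'
#' @param spec \code{phantom_spec}.
#' @return Object of class \code{phantom}: truth arrays \code{kio},
#'   \code{V}, \code{rho}, \code{vi}, \code{suv}; \code{labels};
#'   \code{masks} (named list of logical arrays); the \code{spec}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_labels(spec$dims)
  codes <- c(background = 0L, tumor = 1L, peritumor = 2L, contralateral = 3L)
  mk <- function(field) {
    a <- array(NA_real_, spec$dims)
    for (nm in names(codes)) a[lab == codes[[nm]]] <- spec$regions[[nm]][[field]]
    a
  }
  masks <- lapply(codes[-1], function(cd) lab == cd)
  structure(list(kio = mk("kio"), V = mk("V"), rho = mk("rho"),
                 vi = mk("vi"), suv = mk("suv"),
                 labels = lab, masks = masks, spec = spec),
            class = "phantom")
}

#' Synthesize a raw repeated DWI stack from a phantom
#'
#' Noise-free per-region decays from the forward model (analytic engine by
#' default), scaled so the lowest-b signal is 1, then independent Rician
#' magnitude noise per repeat volume at the spec SNR and expansion to the
#' protocol repeat scheme.
#'
#' @param phantom \code{phantom}.
#' @param protocol \code{acquisition_protocol}.
#' @param engine \code{"analytic"} or \code{"monte-carlo"}.
#' @param snr SNR at the lowest b (default from the spec); \code{Inf} for
#'   noise-free.
#' @param seed RNG seed (default from the spec).
#' @param D_i,D_e free compartment diffusivities, um^2/ms.
#' @return 4-D array \code{[x, y, z, sum(repeats)]}.
#' @export
synthesize_dwi <- function(phantom, protocol = default_protocol(),
                           engine = c("analytic", "monte-carlo"),
                           snr = NULL, seed = NULL, D_i = 1.0, D_e = 2.0) {
  engine <- match.arg(engine)
  stopifnot(inherits(phantom, "phantom"))
  snr <- snr %||% phantom$spec$snr
  seed <- seed %||% phantom$spec$seed
  if (snr <= 0) stop("SNR must be positive")
  spec <- phantom$spec
  codes <- c(background = 0L, tumor = 1L, peritumor = 2L, contralateral = 3L)
  curves <- list()
  for (nm in names(codes)) {
    r <- spec$regions[[nm]]
    pars <- tissue_params(r$kio, r$V, r$rho, D_i, D_e)
    curves[[nm]] <- if (engine == "analytic") {
      karger_decay(pars, protocol)$S
    } else {
      box <- (60 / (r$rho * 1e-9))^(1 / 3)
      ens <- build_ensemble(r$rho, r$V, box, seed = seed)
      if (r$kio > 0) {
        p <- calibrate_permeability(ens, r$kio, D_i, seed = seed)
        ens <- set_permeability(ens, p, r$kio)
      }
      simulate_decay(ens, pars, protocol, seed = seed)$S
    }
  }
  nb <- length(protocol$b_values)
  noisefree <- array(0, c(spec$dims, nb))
  for (nm in names(codes)) {
    m <- phantom$labels == codes[[nm]]
    for (j in seq_len(nb)) {
      v <- noisefree[, , , j]
      v[m] <- curves[[nm]][j]
      noisefree[, , , j] <- v
    }
  }
  n_total <- sum(protocol$repeats)
  raw <- array(0, c(spec$dims, n_total))
  set.seed(seed)
  sigma <- if (is.finite(snr)) 1 / snr else 0
  off <- 0L
  nvox <- prod(spec$dims)
  for (j in seq_len(nb)) {
    for (r in seq_len(protocol$repeats[j])) {
      S <- array(noisefree[, , , j], spec$dims)
      if (sigma > 0) {
        e1 <- array(stats::rnorm(nvox, 0, sigma), spec$dims)
        e2 <- array(stats::rnorm(nvox, 0, sigma), spec$dims)
        S <- sqrt((S + e1)^2 + e2^2)
      }
      raw[, , , off + r] <- S
    }
    off <- off + protocol$repeats[j]
  }
  raw
}

# separable in-plane Gaussian blur (sd in voxels), periodic-free (renormalized
# truncated kernel at edges)
gauss_blur2d <- function(vol, sd_vox) {
  if (sd_vox <= 0) return(vol)
  half <- max(1L, ceiling(3 * sd_vox))
  k <- stats::dnorm(seq(-half, half), sd = sd_vox)
  k <- k / sum(k)
  conv1 <- function(x) { # along first dim of a matrix, edge-renormalized
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
      kk <- kk / sum(kk)
      out[i, ] <- kk %*% x[lo:hi, , drop = FALSE]
    }
    out
  }
  for (z in seq_len(dim(vol)[3])) {
    sl <- vol[, , z]
    vol[, , z] <- t(conv1(t(conv1(sl))))
  }
  vol
}

# block-average in-plane downsampling by an integer factor
block_mean2d <- function(vol, f) {
  if (f <= 1) return(vol)
  d <- dim(vol)
  nx <- d[1] %/% f; ny <- d[2] %/% f
  out <- array(0, c(nx, ny, d[3]))
  for (z in seq_len(d[3]))
    for (i in seq_len(nx))
      for (j in seq_len(ny))
        out[i, j, z] <- mean(vol[(i - 1) * f + 1:f, (j - 1) * f + 1:f, z])
  out
}

#' Synthesize a PET activity volume and dose record from a phantom
#'
#' The piecewise-constant target SUV field is block-averaged onto a coarser
#' PET grid, blurred with an in-plane Gaussian point-spread function, given
#' Poisson-like noise (standard deviation proportional to the square root of
#' local activity), and converted to an activity volume such that
#' \code{\link{compute_suv}} inverts exactly to the (blurred, noisy) SUV
#' field.
#'
#' @param phantom \code{phantom}.
#' @param psf_fwhm PET point-spread FWHM, mm (0 disables blurring).
#' @param noise_cv coefficient of variation of the noise at the maximum
#'   activity (0 disables noise).
#' @param downsample integer in-plane block factor from the MR to the PET
#'   grid (default 2: 0.312 -> 0.624 mm, near the 0.78 mm PET resolution).
#' @param seed RNG seed.
#' @param injected_bq,mass_g,latent_min,half_life_min dose record.
#' @return list: \code{study} (\code{pet_study}), \code{suv_truth}
#'   (MR grid), \code{masks} (ROI masks on the PET grid), \code{dose}
#'   (named list), \code{pet_vox_mm}.
#' @export
synthesize_pet <- function(phantom, psf_fwhm = 0.78, noise_cv = 0.005,
                           downsample = 2L, seed = NULL,
                           injected_bq = 3.7e7, mass_g = 300,
                           latent_min = 60, half_life_min = 110) {
  stopifnot(inherits(phantom, "phantom"), all(unlist(
    lapply(phantom$spec$regions, `[[`, "suv")) >= 0))
  seed <- seed %||% phantom$spec$seed
  suv <- phantom$suv
  pet_vox <- phantom$spec$vox_mm[1] * downsample
  pet <- block_mean2d(suv, downsample)
  if (psf_fwhm > 0)
    pet <- gauss_blur2d(pet, (psf_fwhm / 2.3548) / pet_vox)
  set.seed(seed)
  if (noise_cv > 0) {
    mx <- max(pet)
    pet <- pet + array(stats::rnorm(length(pet), 0,
                                    noise_cv * sqrt(pet * mx)), dim(pet))
    pet[pet < 0] <- 0
  }
  adj <- decay_adjust(injected_bq, latent_min, half_life_min)
  activity <- pet * adj / mass_g
  masks <- lapply(phantom$masks, function(m) {
    mm <- block_mean2d(m + 0, downsample)
    mm >= 0.5
  })
  list(study = pet_study(activity, injected_bq, mass_g, latent_min,
                         half_life_min),
       suv_truth = suv, masks = masks,
       dose = list(injected_Bq = injected_bq, mass_g = mass_g,
                   latent_min = latent_min, half_life_min = half_life_min),
       pet_vox_mm = c(pet_vox, pet_vox, phantom$spec$vox_mm[3]))
}

#' Synthesize histology object tables with known truth
#'
#' Per region, draws Poisson nucleus counts at the target density in each
#' confocal field, emits a configurable fraction of nuclei as unsplit
#' doubles (one object with Z extent in [7.2, 15] standing for two nuclei)
#' and adds sub-threshold debris objects (small XY area and Z extent) so
#' every counting rule is exercised. True nucleus areas are drawn above the
#' region's exclusion threshold, so with zero error rates the counting rules
#' recover the Poisson draw exactly.
#'
#' @param rho_targets named numeric (names from tumor/peritumor/
#'   contralateral), cells/uL (> 0).
#' @param n_fields fields per region.
#' @param field_dims field dimensions, um.
#' @param frac_double probability that a disjoint nucleus pair is emitted
#'   unsplit.
#' @param debris_rate expected debris objects per true nucleus.
#' @param seed RNG seed.
#' @return Object of class \code{histology_set}: \code{tables} (list of
#'   per-field data.frames), \code{truth} (data.frame region, field,
#'   n_true, rho_target, rho_true).
#' @export
synthesize_histology <- function(rho_targets = c(tumor = 27.5e5,
                                                 peritumor = 7.61e5,
                                                 contralateral = 10.4e5),
                                 n_fields = 3, field_dims = c(160, 160, 20),
                                 frac_double = 0.1, debris_rate = 0.1,
                                 seed = 1L) {
  stopifnot(all(rho_targets > 0))
  set.seed(seed)
  vol <- prod(field_dims)
  tables <- list()
  truth <- NULL
  for (nm in names(rho_targets)) {
    for (f in seq_len(n_fields)) {
      N <- stats::rpois(1, rho_targets[[nm]] * 1e-9 * vol)
      n_pairs <- stats::rbinom(1, N %/% 2, frac_double)
      n_singles <- N - 2L * n_pairs
      n_debris <- stats::rpois(1, debris_rate * N)
      area <- function(n, amin) amin + 2 + stats::rlnorm(n, log(25), 0.3)
      amin <- if (nm == "tumor") 10 else 3
      df <- rbind(
        if (n_singles > 0) data.frame(
          xy_area_um2 = area(n_singles, amin),
          z_extent_um = stats::runif(n_singles, 2.5, 7.0)),
        if (n_pairs > 0) data.frame(
          xy_area_um2 = area(n_pairs, amin),
          z_extent_um = stats::runif(n_pairs, 7.5, 14.5)),
        if (n_debris > 0) data.frame(
          xy_area_um2 = stats::runif(n_debris, 0.5, 2.5),
          z_extent_um = stats::runif(n_debris, 0.3, 1.7))
      )
      if (is.null(df)) df <- data.frame(xy_area_um2 = numeric(0),
                                        z_extent_um = numeric(0))
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      df <- cbind(object_id = seq_len(nrow(df)), region = nm, df)
      rownames(df) <- NULL
      tables[[paste0(nm, "_", f)]] <- df
      truth <- rbind(truth, data.frame(
        region = nm, field = f, n_true = N,
        rho_target = rho_targets[[nm]],
        rho_true = nucleus_density(N, field_dims)))
    }
  }
  structure(list(tables = tables, truth = truth, field_dims = field_dims,
                 frac_double = frac_double, debris_rate = debris_rate),
            class = "histology_set")
}
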