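#' Read a 4-D DWI stack with its b-table sidecar
#'
#' @param path NIfTI-1 file.
#' @param btable_path tab-separated sidecar (columns b, repeats).
#' @return list: \code{stack} (4-D array), \code{protocol}
#'   (\code{acquisition_protocol}), \code{image} (the RNifti header carrier).
#' @export
read_dwi <- function(path, btable_path) {
  img <- RNifti::readNifti(path)
  protocol <- read_btable(btable_path)
  stack <- as.array(img)
  if (length(dim(stack)) == 3) dim(stack) <- c(dim(stack), 1L)
  n_exp <- sum(protocol$repeats)
  if (dim(stack)[4] != n_exp)
    stop("format error: b-table expects ", n_exp, " volumes, file has ",
         dim(stack)[4])
  list(stack = stack, protocol = protocol, image = img)
}

#' Write a 4-D DWI stack with its b-table sidecar
#'
#' @param stack 4-D array.
#' @param protocol \code{acquisition_protocol}.
#' @param path output NIfTI path.
#' @param vox_mm voxel size, mm.
#' @return \code{path}, invisibly.
#' @export
write_dwi <- function(stack, protocol, path, vox_mm = c(0.312, 0.312, 1.5)) {
  img <- RNifti::asNifti(stack, pixdim = c(vox_mm, 1))
  RNifti::writeNifti(img, path)
  write_btable(protocol, paste0(sub("\\.nii(\\.gz)?$", "", path), "_btable.tsv"))
  invisible(path)
}

#' Write fitted parametric maps as NIfTI volumes plus a JSON fit report
#'
#' @param maps \code{parametric_maps}.
#' @param dir output directory.
#' @param vox_mm voxel size, mm.
#' @return Named vector of written file paths, invisibly.
#' @export
write_maps <- function(maps, dir, vox_mm = c(0.312, 0.312, 1.5)) {
  stopifnot(inherits(maps, "parametric_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("kio", "V", "rho", "vi", "residual")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]], pixdim = c(vox_mm, 1)), p)
    paths[nm] <- p
  }
  rp <- file.path(dir, "fit_report.json")
  jsonlite::write_json(list(n_fitted = maps$n_fitted,
                            n_invalid = maps$n_invalid,
                            frac_invalid = maps$frac_invalid),
                       rp, auto_unbox = TRUE, digits = NA)
  paths["report"] <- rp
  invisible(paths)
}

# stable fingerprint of a config (no external digest dependency)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 997)) %% 4294967291)
}

#' Run the full phantom pipeline
#'
#' Generates the seeded phantom, synthesizes and averages the repeated DWI
#' stack, builds the decay library, fits parametric maps, derives the
#' combination biomarkers and ADC, summarizes the ROIs, and (optionally)
#' runs the PET and histology stages, returning one report list.
#'
#' @param config list with optional elements \code{seed}, \code{snr},
#'   \code{grid} (list n_kio, n_V, n_rho), \code{engine}, \code{pet}
#'   (logical), \code{histology} (logical), \code{out_dir} (write NIfTI/CSV/
#'   JSON outputs there when non-NULL).
#' @return Report list: per-region truth and recovered medians, ADC medians,
#'   optional PET/histology blocks, seeds and the config fingerprint.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(seed = 1L, snr = 50, grid = list(n_kio = 24L, n_V = 64L, n_rho = 64L),
         engine = "analytic", pet = TRUE, histology = TRUE, out_dir = NULL),
    config)
  grid <- make_grid(cfg$grid$n_kio, cfg$grid$n_V, cfg$grid$n_rho)
  spec <- phantom_spec(snr = cfg$snr, seed = cfg$seed, grid = grid)
  phan <- make_phantom(spec)
  protocol <- default_protocol()
  raw <- synthesize_dwi(phan, protocol, engine = cfg$engine)
  avg <- average_repeats(raw, protocol)
  lib <- generate_library(grid, protocol, engine = "analytic", seed = cfg$seed)
  mask <- phan$labels > 0
  maps <- fit_image(avg, mask, lib)
  comb <- combine_maps(maps)
  adc <- compute_adc(avg[, , , which(protocol$b_values == 1013)],
                     avg[, , , 1], b = 1013 - 18)
  regions <- c("tumor", "peritumor", "contralateral")
  summary_rows <- NULL
  for (rg in regions) {
    m <- phan$masks[[rg]] & maps$valid
    for (par in c("kio", "V", "rho", "vi")) {
      s <- summarize_roi(maps[[par]], m, animal = 1, roi = rg)
      truth <- phan$spec$regions[[rg]][[if (par == "V") "V" else par]]
      summary_rows <- rbind(summary_rows, cbind(parameter = par, s,
                                                truth = truth))
    }
    for (par in c("kioV", "kioVrho")) {
      s <- summarize_roi(comb[[par]], m, animal = 1, roi = rg)
      summary_rows <- rbind(summary_rows, cbind(parameter = par, s,
                                                truth = NA_real_))
    }
    s <- summarize_roi(adc, m, animal = 1, roi = rg)
    summary_rows <- rbind(summary_rows, cbind(parameter = "adc", s,
                                              truth = NA_real_))
  }
  report <- list(seed = cfg$seed, snr = cfg$snr,
                 engine = cfg$engine,
                 library = list(n_curves = nrow(lib$curves),
                                engine = lib$engine),
                 fit = list(n_fitted = maps$n_fitted,
                            frac_invalid = maps$frac_invalid),
                 roi_summaries = summary_rows,
                 config_hash = config_hash(cfg))
  if (isTRUE(cfg$pet)) {
    pet <- synthesize_pet(phan, seed = cfg$seed)
    suv <- compute_suv(pet$study)
    sm <- vapply(regions, function(rg) suv_max(suv, pet$masks[[rg]]),
                 numeric(1))
    rho_med <- vapply(regions, function(rg)
      summarize_roi(maps$rho, phan$masks[[rg]])$median, numeric(1))
    report$pet <- list(suv_max = sm, tmr_glc = tmr_glc(sm),
                       cmr_glc = cmr_glc(tmr_glc(sm), rho_med),
                       dose = pet$dose)
  }
  if (isTRUE(cfg$histology)) {
    hs <- synthesize_histology(seed = cfg$seed)
    dens <- vapply(names(hs$tables), function(nm) {
      fc <- suppressWarnings(filter_and_count(hs$tables[[nm]]))
      nucleus_density(fc$count, hs$field_dims)
    }, numeric(1))
    report$histology <- list(
      field_density = dens,
      region_density = tapply(dens, sub("_[0-9]+$", "", names(dens)), mean),
      shrinkage_corrected = shrinkage_correct(
        tapply(dens, sub("_[0-9]+$", "", names(dens)), mean)))
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dwi(raw, protocol, file.path(cfg$out_dir, "dwi_raw.nii.gz"),
              spec$vox_mm)
    write_maps(maps, file.path(cfg$out_dir, "maps"), spec$vox_mm)
    utils::write.csv(summary_rows,
                     file.path(cfg$out_dir, "roi_summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "roi_summaries")],
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
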