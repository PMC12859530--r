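# synthetic phantoms: DWI, PET, histology generators

test_that("phantom regions carry Table-style magnitudes with V derived", {
  spec <- phantom_spec()
  expect_equal(spec$regions$tumor$rho, 27.5e5)
  expect_equal(spec$regions$tumor$vi, 0.885)
  expect_equal(spec$regions$tumor$V, 0.885 / 2.75, tolerance = 1e-12) # 0.32 pL
  expect_equal(spec$regions$contralateral$kio, 34.9)
  phan <- make_phantom(spec)
  # regions are disjoint and inside the grid
  expect_true(all(table(phan$labels) > 0))
  expect_false(any(phan$masks$tumor & phan$masks$peritumor))
  expect_false(any(phan$masks$tumor & phan$masks$contralateral))
  # truth maps are consistent: vi = V * rho everywhere
  inb <- phan$labels >= 0
  expect_equal(phan$vi[inb], vi_from(phan$V, phan$rho)[inb], tolerance = 1e-12)
})

test_that("grid snapping keeps region truths within a half grid step", {
  g <- make_grid()
  spec <- phantom_spec(grid = g)
  expect_true(spec$snapped)
  for (nm in c("tumor", "peritumor", "contralateral")) {
    r0 <- phantom_spec()$regions[[nm]]
    r1 <- spec$regions[[nm]]
    expect_lt(abs(log(r1$rho / r0$rho)), log(10) * 4.2 / 63)
    expect_lt(abs(r1$kio - r0$kio), 130 / 23)
    # snapped triple is representable by the grid
    expect_true(any(abs(g$triples$kio - r1$kio) < 1e-9 &
                    abs(g$triples$V - r1$V) < 1e-9 &
                    abs(g$triples$rho - r1$rho) < 1e-9))
  }
})

test_that("inconsistent region specs fail before generation", {
  expect_error(phantom_spec(regions = list(
    tumor = list(rho = 27.5e5, vi = 0.885, kio = 40.7, suv = 7.67),
    peritumor = list(rho = 7.61e5, vi = 0.835, kio = 44.3, suv = 6.9),
    contralateral = list(rho = 10.4e5, vi = 0.889, kio = 300, suv = 4.16),
    background = list(rho = 10e5, vi = 0.88, kio = 35, suv = 2.5))),
    "contralateral")
})

test_that("DWI synthesis is seeded-deterministic with the right geometry", {
  prot <- default_protocol()
  spec <- phantom_spec(dims = c(16, 16, 1), seed = 12)
  phan <- make_phantom(spec)
  a <- synthesize_dwi(phan, prot)
  b <- synthesize_dwi(phan, prot)
  expect_identical(a, b)
  expect_equal(dim(a), c(16, 16, 1, 30))
  expect_error(synthesize_dwi(phan, prot, snr = 0), "SNR")
})

test_that("noise-free synthesis reproduces the forward-model curves", {
  prot <- default_protocol()
  spec <- phantom_spec(dims = c(16, 16, 1))
  phan <- make_phantom(spec)
  raw <- synthesize_dwi(phan, prot, snr = Inf)
  avg <- average_repeats(raw, prot)
  r <- spec$regions$tumor
  cur <- karger_decay(tissue_params(r$kio, r$V, r$rho), prot)$S
  vox <- which(phan$labels == 1)
  for (j in c(1, 4, 8))
    expect_equal(unique(avg[, , , j][vox]), cur[j], tolerance = 1e-12)
})

test_that("the Rician floor lifts the mean magnitude at high b", {
  # high-decay region at b = 6013: mean of many noisy draws exceeds truth
  prot <- default_protocol()
  spec <- phantom_spec(dims = c(24, 24, 1), snr = 10, seed = 2)
  phan <- make_phantom(spec)
  raw <- synthesize_dwi(phan, prot)
  r <- spec$regions$contralateral
  cur <- karger_decay(tissue_params(r$kio, r$V, r$rho), prot)$S
  vox <- which(phan$labels == 3)
  draws <- as.vector(vapply(19:30, function(v) raw[, , , v][vox],
                            numeric(length(vox))))
  expect_gt(mean(draws), cur[8])
})

test_that("histology synthesis recovers truth when error-free", {
  hs <- synthesize_histology(c(tumor = 27.5e5), n_fields = 2,
                             frac_double = 0, debris_rate = 0, seed = 5)
  for (f in 1:2) {
    tab <- hs$tables[[paste0("tumor_", f)]]
    expect_equal(filter_and_count(tab)$count,
                 hs$truth$n_true[hs$truth$field == f])
  }
})

test_that("unsplit doubles are corrected; naive counting is biased low", {
  corrected <- 0; naive <- 0; truth <- 0
  for (s in 1:50) {
    hs <- synthesize_histology(c(contralateral = 10.4e5), n_fields = 1,
                               frac_double = 0.1, debris_rate = 0.1,
                               seed = 100 + s)
    tab <- hs$tables[[1]]
    fc <- filter_and_count(tab)
    corrected <- corrected + fc$count
    naive <- naive + fc$tally[["singles"]] + fc$tally[["doubles"]]
    truth <- truth + hs$truth$n_true
  }
  # corrected total within binomial error of truth (se ~ sqrt(N))
  expect_lt(abs(corrected - truth), 4 * sqrt(truth))
  # single-counting the unsplit doubles loses ~5 percent of nuclei
  expect_lt(naive, truth - 4 * sqrt(truth))
})

test_that("region densities hit the generating targets within 5 percent", {
  hs <- synthesize_histology(seed = 7)
  for (nm in c("tumor", "peritumor", "contralateral")) {
    d <- vapply(1:3, function(f)
      nucleus_density(filter_and_count(hs$tables[[paste0(nm, "_", f)]])$count,
                      hs$field_dims), numeric(1))
    target <- c(tumor = 27.5e5, peritumor = 7.61e5,
                contralateral = 10.4e5)[[nm]]
    expect_lt(abs(mean(d) - target) / target, 0.05)
  }
})
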