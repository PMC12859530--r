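# parameter grid, library generation, repeat averaging

test_that("grid axes span the bounds and the vi band filters triples", {
  g <- make_grid(2, 2, 2)
  b <- madi_bounds()
  expect_equal(range(g$kio_axis), b$kio)
  expect_equal(range(g$V_axis), b$V)
  expect_equal(range(g$rho_axis), b$rho)
  expect_equal(g$n_candidates, 8L)
  # corner enumeration: only (V_max, rho_min) and (V_min, rho_max) fall in
  # the vi band (0.924 and 0.655), each at both k_io values
  vis <- sort(unique(round(g$triples$vi, 3)))
  expect_equal(vis, c(0.655, 0.924))
  expect_equal(g$n_retained, 4L)
  expect_true(all(g$triples$vi >= 0.5 & g$triples$vi <= 0.994))
  expect_error(make_grid(1, 2, 2))
})

test_that("retained triples are ordered for deterministic tie-breaking", {
  g <- small_grid()
  tr <- g$triples
  o <- order(tr$kio, tr$V, tr$rho)
  expect_identical(o, seq_len(nrow(tr)))
})

test_that("analytic library curves satisfy the decay invariants", {
  lib <- small_library()
  expect_equal(nrow(lib$curves), lib$grid$n_retained)
  expect_true(all(abs(lib$curves[, 1] - 1) < 1e-12))
  expect_true(all(apply(lib$curves, 1, function(s) all(diff(s) <= 1e-12))))
  expect_true(all(lib$curves > 0 & lib$curves <= 1))
})

test_that("raising k_io at fixed (V, rho) strictly lowers the high-b signal", {
  lib <- small_library()
  tr <- lib$params
  key <- paste(tr$V, tr$rho)
  for (k in unique(key)[c(1, 25, 50)]) {
    idx <- which(key == k)
    ord <- idx[order(tr$kio[idx])]
    expect_true(all(diff(lib$curves[ord, ncol(lib$curves)]) < 0))
  }
})

test_that("single-triple library is a passthrough of the forward model", {
  prot <- default_protocol()
  g <- small_grid()
  g$triples <- g$triples[10, , drop = FALSE]
  rownames(g$triples) <- NULL
  lib <- generate_library(g, prot, engine = "analytic")
  p <- tissue_params(g$triples$kio, g$triples$V, g$triples$rho)
  expect_equal(as.vector(lib$curves[1, ]), karger_decay(p, prot)$S,
               tolerance = 1e-12)
})

test_that("library CSV persistence is deterministic and lossless", {
  lib <- small_library(small_grid(3, 8, 8))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_library(lib, f1)
  write_library(lib, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_library(f1)
  expect_equal(back$b, lib$b)
  expect_equal(dim(back$curves), dim(lib$curves))
  i <- match(paste(lib$params$kio, lib$params$V, lib$params$rho),
             paste(back$params$kio, back$params$V, back$params$rho))
  expect_true(!anyNA(i))
  expect_equal(back$curves[i, ], lib$curves, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("repeat averaging collapses 30 volumes to 8 in b-order", {
  prot <- default_protocol()
  dims <- c(4, 4, 2)
  raw <- array(0, c(dims, 30))
  # mark each volume with its b-index so means are predictable
  off <- 0
  for (j in seq_along(prot$b_values)) {
    for (r in seq_len(prot$repeats[j])) raw[, , , off + r] <- j
    off <- off + prot$repeats[j]
  }
  avg <- average_repeats(raw, prot)
  expect_equal(dim(avg), c(dims, 8))
  for (j in 1:8) expect_true(all(avg[, , , j] == j))
  expect_error(average_repeats(raw[, , , 1:29, drop = FALSE], prot),
               "expected 30")
})

test_that("averaging the 12 noisy b=6013 repeats shrinks noise by ~sqrt(12)", {
  prot <- default_protocol()
  spec <- phantom_spec(dims = c(24, 24, 1), snr = 25, seed = 9)
  phan <- make_phantom(spec)
  raw <- synthesize_dwi(phan, prot)
  avg <- average_repeats(raw, prot)
  vox <- which(phan$labels == 3)            # uniform contralateral region
  # single-repeat spread across region voxels vs spread after averaging
  single <- raw[, , , 19][vox]              # first of the 12 b=6013 repeats
  averaged <- avg[, , , 8][vox]
  ratio <- sd(single) / sd(averaged)
  expect_gt(ratio, sqrt(12) * 0.75)
  expect_lt(ratio, sqrt(12) * 1.25)
})
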