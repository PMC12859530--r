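# 3-D nuclear counting rules, densities, shrinkage, MADI comparison

test_that("counting rules apply region thresholds and Z classes", {
  # tumor object under the 10 um^2 area threshold is excluded
  t1 <- data.frame(region = "tumor", xy_area_um2 = 9, z_extent_um = 5)
  expect_equal(filter_and_count(t1)$count, 0)
  # same object in contralateral passes the 3 um^2 threshold
  t2 <- data.frame(region = "contralateral", xy_area_um2 = 9, z_extent_um = 5)
  expect_equal(filter_and_count(t2)$count, 1)
  # double-nucleus rule
  t3 <- data.frame(region = "contralateral", xy_area_um2 = 20, z_extent_um = 8)
  expect_equal(filter_and_count(t3)$count, 2)
  # boundary: 7.2 um goes to the double class; < 2 um excluded
  t4 <- data.frame(region = "tumor", xy_area_um2 = c(20, 20, 20),
                   z_extent_um = c(7.2, 1.9, 2.0))
  expect_equal(filter_and_count(t4)$count, 3)
  # > 15 um counted as double with a warning
  t5 <- data.frame(region = "tumor", xy_area_um2 = 20, z_extent_um = 16)
  expect_warning(fc <- filter_and_count(t5), "15")
  expect_equal(fc$count, 2)
  expect_error(filter_and_count(
    data.frame(region = "cortex", xy_area_um2 = 20, z_extent_um = 5)),
    "unknown region")
})

test_that("counting matches a rule-by-rule brute-force oracle", {
  for (seed in 1:5) {
    for (region in c("tumor", "peritumor", "contralateral")) {
      tab <- random_object_table(500, region, seed)
      got <- suppressWarnings(filter_and_count(tab)$count)
      expect_identical(got, brute_force_count(tab))
      # order independence: shuffled rows count identically
      tab2 <- tab[sample.int(nrow(tab)), ]
      expect_identical(suppressWarnings(filter_and_count(tab2)$count), got)
    }
  }
})

test_that("manually added nuclei bypass the filters", {
  t <- data.frame(region = "tumor", xy_area_um2 = c(1, 20),
                  z_extent_um = c(1, 5), manually_added = c(TRUE, FALSE))
  expect_equal(filter_and_count(t)$count, 2)
})

test_that("density converts counts per field volume to cells/uL", {
  expect_equal(nucleus_density(512, c(160, 160, 20)), 10e5)
  expect_equal(nucleus_density(0), 0)
  expect_equal(nucleus_density(100, c(160, 160, 40)),
               nucleus_density(100, c(160, 160, 20)) / 2)
})

test_that("shrinkage correction follows the cube of the linear factor", {
  expect_equal(shrinkage_correct(100, 0), 100)
  expect_equal(shrinkage_correct(1, 0.03), 0.912673)
  # 3 percent linear shrinkage is ~9 percent volume shrinkage
  expect_equal(round(100 * (1 - 0.97^3)), 9)
  expect_equal(shrinkage_correct(8, 0.5), 1)
})

test_that("imaging-vs-histology regression recovers known structure", {
  # identity line
  x <- c(5, 10, 20, 28)
  r <- suppressWarnings(compare_to_madi(x, x))  # lm warns on a perfect fit
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  # all points above identity, as with imaging densities running high
  r2 <- suppressWarnings(compare_to_madi(x * 1.5 + 2, x))
  expect_equal(r2$n_above_identity, 4)
  expect_gt(r2$mean_residual_vs_identity, 0)
  # OLS recovery of a generative slope within its confidence interval
  set.seed(31)
  xh <- runif(30, 4, 30)
  ym <- 1.7 * xh + rnorm(30, 0, 2)
  r3 <- compare_to_madi(ym, xh)
  ci <- confint(r3$fit)["rho_hist", ]
  expect_gt(1.7, ci[1]); expect_lt(1.7, ci[2])
  expect_error(compare_to_madi(c(1, 2), c(1, 2)), "3 pairs")
})
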