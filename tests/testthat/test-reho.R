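test_that("neighborhoods follow the connectivity scheme and the mask", {
  mask <- array(TRUE, c(5, 5, 5))
  expect_equal(nrow(neighborhood(c(3, 3, 3), mask, 26)), 26)
  expect_equal(nrow(neighborhood(c(3, 3, 3), mask, 18)), 18)
  expect_equal(nrow(neighborhood(c(3, 3, 3), mask, 6)), 6)
  # corner voxel of a cubic mask: 3x3x3 cube clipped to 2x2x2 minus center
  expect_equal(nrow(neighborhood(c(1, 1, 1), mask, 26)), 7)
  # masked-out neighbors are excluded
  mask2 <- mask; mask2[2, 3, 3] <- FALSE
  expect_equal(nrow(neighborhood(c(3, 3, 3), mask2, 26)), 25)
  mask3 <- mask; mask3[3, 3, 3] <- FALSE
  expect_error(neighborhood(c(3, 3, 3), mask3), "outside the mask")
})

test_that("Kendall's W matches hand-worked values at its extremes", {
  expect_equal(kendalls_w(cbind(1:5, 1:5, 1:5)), 1)
  expect_equal(kendalls_w(cbind(1:5, 5:1)), 0)
  # rank patterns (1,2,3,4), (1,2,3,4), (4,3,2,1): S = 5 -> W = 1/9
  expect_equal(kendalls_w(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1))),
               1 / 9)
  expect_warning(w0 <- kendalls_w(cbind(rep(1, 4), rep(2, 4))), "degenerate")
  expect_equal(w0, 0)
  expect_error(kendalls_w(matrix(1:4, 4, 1)), "at least 2")
})

test_that("Kendall's W agrees with a brute-force oracle, with and without ties", {
  set.seed(123)
  for (i in 1:100) {
    k <- sample(2:5, 1); n <- sample(3:8, 1)
    X <- matrix(rnorm(k * n), n, k)
    if (i %% 3 == 0) X <- round(X)  # force ties in a third of cases
    if (any(apply(X, 2, function(c) length(unique(c))) == 1)) next
    expect_equal(kendalls_w(X), brute_w(X), tolerance = 1e-12)
  }
})

test_that("ReHo maps recover shared-signal structure and the null level", {
  # w = 1 cluster: interior voxels concordant with all neighbors
  vox <- as.matrix(expand.grid(3:7, 3:7, 2:5))
  pe <- planted_effect(vox, coupling_by_cell = list(
    NC = c(rest = 1, task = 1), MCI = c(rest = 1, task = 1)))
  bs <- generate_bold(c(9, 9, 6), 60, 2, planted = list(pe),
                      cell = c("NC", "rest"), seed = 3)
  r <- reho_map(bs, 26)
  expect_gt(r$values[5, 5, 3], 0.95)
  expect_equal(r$k[5, 5, 3], 27)
  # bounds hold everywhere
  expect_true(all(r$values >= 0 & r$values <= 1))
  # independence: mean W over complete neighborhoods near 1/27
  null <- generate_bold(c(12, 12, 8), 154, 2, planted = list(), seed = 4)
  rn <- reho_map(null, 26)
  expect_equal(mean(rn$values[rn$k == 27]), 1 / 27, tolerance = 0.05)
  expect_error(reho_map(bold_series(array(rnorm(8), c(1, 1, 2, 4)), 2,
                                    mask = array(FALSE, c(1, 1, 2)))),
               "empty mask")
})

test_that("null W follows the Friedman chi-square relation", {
  # under independence (n-1) k W ~ chi^2(n-1): check mean and variance
  set.seed(11)
  n <- 20; k <- 27
  W <- replicate(400, kendalls_w(matrix(rnorm(n * k), n, k)))
  q <- (n - 1) * k * W
  expect_lt(abs(mean(q) - (n - 1)), 1)            # ~3 standard errors
  expect_lt(abs(var(q) - 2 * (n - 1)), 0.25 * 2 * (n - 1))
})

test_that("standardization centers and scales within the mask", {
  mask <- array(FALSE, c(3, 1, 1)); mask[] <- TRUE
  m <- structure(list(values = array(c(0.2, 0.4, 0.6), c(3, 1, 1)),
                      k = array(3L, c(3, 1, 1)), mask = mask,
                      voxel_size_mm = c(3, 3, 3), standardized = FALSE,
                      band = NULL), class = "reho_map")
  z <- standardize_map(m)
  expect_equal(as.numeric(z$values), c(-1, 0, 1))
  # any valid map -> mean 0, sd 1 within mask
  bs <- tiny_series(nt = 40, seed = 5)
  z2 <- standardize_map(reho_map(bs))
  expect_equal(mean(z2$values[z2$mask]), 0, tolerance = 1e-8)
  expect_equal(sd(z2$values[z2$mask]), 1, tolerance = 1e-8)
  m$values[] <- 0.3
  expect_error(standardize_map(m), "constant")
})

test_that("Gaussian smoothing uses the FWHM convention and conserves mass", {
  # sigma = fwhm / (voxel * 2 sqrt(2 ln 2)): 4 mm at 3 mm voxels
  expect_equal(4 / (3 * 2 * sqrt(2 * log(2))), 0.56619, tolerance = 1e-4)
  mask <- array(TRUE, c(15, 15, 15))
  vals <- array(0, c(15, 15, 15)); vals[8, 8, 8] <- 1
  m <- structure(list(values = vals, k = array(27L, dim(vals)), mask = mask,
                      voxel_size_mm = c(3, 3, 3), standardized = TRUE,
                      band = NULL), class = "reho_map")
  sm <- smooth_map(m, 4)
  expect_equal(sum(sm$values), 1, tolerance = 1e-8)
  # radial symmetry of the impulse response
  expect_equal(sm$values[7, 8, 8], sm$values[9, 8, 8])
  expect_equal(sm$values[8, 7, 8], sm$values[8, 8, 9])
  # fwhm = 0 is the identity; negative fwhm is an error
  expect_identical(smooth_map(m, 0), m)
  expect_error(smooth_map(m, -1), "non-negative")
  # mask re-applied after smoothing
  mask2 <- mask; mask2[1:3, , ] <- FALSE
  m2 <- m; m2$mask <- mask2
  expect_true(all(smooth_map(m2, 6)$values[1:3, , ] == 0))
})
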