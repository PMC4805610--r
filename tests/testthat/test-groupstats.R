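test_that("state difference is exact voxel-wise subtraction", {
  set.seed(1)
  a <- array(rnorm(60), c(5, 4, 3)); b <- array(rnorm(60), c(5, 4, 3))
  d <- state_difference(a, b)
  for (i in sample(60, 10)) expect_identical(d[i], a[i] - b[i])
  expect_true(all(state_difference(a, a) == 0))
  expect_error(state_difference(a, array(0, c(4, 4, 3))), "differ")
})

test_that("interaction F equals the squared two-sample t on difference scores", {
  set.seed(2)
  mask <- array(TRUE, c(4, 4, 2))
  g <- rep(c("NC", "MCI"), c(6, 7))
  task <- lapply(1:13, function(i) array(rnorm(32), dim(mask)))
  rest <- lapply(1:13, function(i) array(rnorm(32), dim(mask)))
  im <- interaction_map(task, rest, g, covariates = NULL, mask = mask)
  expect_equal(im$df, c(1, 11))
  # oracle: pooled-variance two-sample t per voxel
  for (v in sample(32, 8)) {
    d <- sapply(1:13, function(i) task[[i]][v] - rest[[i]][v])
    tt <- t.test(d[g == "NC"], d[g == "MCI"], var.equal = TRUE)
    expect_equal(im$F_map[v], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(im$p_map[v], tt$p.value, tolerance = 1e-10)
  }
  expect_true(all(im$F_map >= 0))
})

test_that("state main effects are absorbed by the difference scores", {
  set.seed(3)
  mask <- array(TRUE, c(3, 3, 2))
  g <- rep(c("NC", "MCI"), c(4, 4))
  covs <- data.frame(age = rnorm(8), sex = rbinom(8, 1, 0.5))
  task <- lapply(1:8, function(i) array(rnorm(18), dim(mask)))
  rest <- lapply(1:8, function(i) array(rnorm(18), dim(mask)))
  im1 <- interaction_map(task, rest, g, covs, mask)
  task_shift <- lapply(task, function(m) m + 5)   # constant state effect
  im2 <- interaction_map(task_shift, rest, g, covs, mask)
  expect_equal(im1$F_map, im2$F_map, tolerance = 1e-10)
})

test_that("degenerate voxels and collinear covariates are handled", {
  mask <- array(TRUE, c(2, 2, 1))
  g <- rep(c("NC", "MCI"), c(3, 3))
  task <- lapply(1:6, function(i) array(c(1, rnorm(3)), dim(mask)))
  rest <- lapply(1:6, function(i) array(c(1, rnorm(3)), dim(mask)))
  im <- interaction_map(task, rest, g, NULL, mask)
  expect_equal(im$p_map[1, 1, 1], 1)              # zero-variance voxel
  covs <- data.frame(a = rnorm(6))
  covs$b <- 2 * covs$a
  expect_warning(interaction_map(task, rest, g, covs, mask), "collinear")
  expect_error(interaction_map(task[1:4], rest[1:4], g[c(1, 2, 3, 4)],
                               NULL, mask), "3 subjects")
})

test_that("cluster extraction applies extent, peak and connectivity rules", {
  dims <- c(12, 12, 10)
  p <- array(1, dims); f <- array(0, dims)
  blob <- as.matrix(expand.grid(2:6, 2:7, 2:4))    # 5*6*3 = 90 voxels
  p[blob] <- 1e-4
  f[blob] <- runif(nrow(blob), 1, 10)
  f[4, 4, 3] <- 99
  cl <- extract_clusters(f, p, p_voxel = 0.01, k_min = 85, connectivity = 18)
  expect_equal(nrow(cl$table), 1)
  expect_equal(cl$table$size, 90)
  expect_equal(unlist(cl$table[, c("peak_x", "peak_y", "peak_z")]),
               c(peak_x = 4, peak_y = 4, peak_z = 3))
  expect_equal(cl$table$peak_stat, 99)
  # same blob below a 96-voxel extent threshold -> empty table
  expect_equal(nrow(extract_clusters(f, p, 0.01, k_min = 96,
                                     connectivity = 18)$table), 0)
  # two blobs touching only at a corner: separate under 18, merged under 26
  p2 <- array(1, dims)
  p2[2:3, 2:3, 2:3] <- 1e-4
  p2[4:5, 4:5, 4:5] <- 1e-4
  f2 <- array(1, dims)
  expect_equal(nrow(extract_clusters(f2, p2, 0.01, 1, 18)$table), 2)
  expect_equal(nrow(extract_clusters(f2, p2, 0.01, 1, 26)$table), 1)
})

test_that("Monte-Carlo extent threshold behaves like the Bernoulli-field oracle", {
  mask <- array(TRUE, c(20, 20, 20))
  mc <- monte_carlo_cluster_threshold(mask, fwhm_mm = 0, p_voxel = 0.01,
                                      alpha = 0.05, n_iter = 200,
                                      connectivity = 26, seed = 4)
  # expected suprathreshold voxels per iteration = mask size * p_voxel
  expect_equal(mc$mean_suprathreshold, 8000 * 0.01, tolerance = 0.05)
  expect_lte(mc$k_star, 6)
  # alpha = 1: every iteration passes at k = 1
  mc1 <- monte_carlo_cluster_threshold(mask, 0, 0.01, alpha = 1,
                                       n_iter = 100, seed = 4)
  expect_equal(mc1$k_star, 1)
  expect_error(monte_carlo_cluster_threshold(mask, 0, 0.01, alpha = 0,
                                             n_iter = 100), "alpha")
  expect_error(monte_carlo_cluster_threshold(mask, 0, 0.01, n_iter = 50),
               "at least 100")
})

test_that("post-hoc t-tests match the textbook formula and report directions", {
  g <- rep(c("NC", "MCI"), each = 4)
  set.seed(6)
  rest <- rnorm(8); task <- rnorm(8)
  ph <- posthoc_t(rest, task, g)
  expect_equal(nrow(ph), 4)
  # two-sample oracle (pooled variance), rest state
  a <- rest[g == "MCI"]; b <- rest[g == "NC"]
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(ph$t[ph$comparison == "MCI-NC (rest)"], t_oracle,
               tolerance = 1e-12)
  # paired oracle, NC group
  d <- task[g == "NC"] - rest[g == "NC"]
  expect_equal(ph$t[ph$comparison == "task-rest (NC)"],
               mean(d) / (sd(d) / 2), tolerance = 1e-12)
  # identical samples -> t = 0 in the two-sample comparisons
  ph0 <- posthoc_t(c(rest[1:4], rest[1:4]), c(task[1:4], task[1:4]), g)
  expect_equal(ph0$t[ph0$type == "two-sample"], c(0, 0))
  expect_error(posthoc_t(rest, task, rep(c("NC", "MCI"), c(7, 1))),
               "at least 2")
})
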