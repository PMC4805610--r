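test_that("seed time courses are unweighted voxel means", {
  s <- tiny_series(nx = 5, ny = 5, nz = 3, nt = 25, seed = 9)
  one <- matrix(c(2, 3, 2), 1)
  expect_equal(seed_timecourse(s, one), s$data[2, 3, 2, ])
  # cancellation: a voxel and its negation average to zero
  s$data[4, 4, 1, ] <- -s$data[4, 1, 1, ]
  expect_equal(seed_timecourse(s, rbind(c(4, 1, 1), c(4, 4, 1))),
               rep(0, 25))
  # per-timepoint mean oracle on a random 5-voxel seed
  set.seed(10)
  vox <- cbind(sample(5, 5, TRUE), sample(5, 5, TRUE), sample(3, 5, TRUE))
  oracle <- rowMeans(sapply(seq_len(5), function(i)
    s$data[vox[i, 1], vox[i, 2], vox[i, 3], ]))
  expect_equal(seed_timecourse(s, vox), oracle)
  expect_error(seed_timecourse(s, vox[0, , drop = FALSE]), "empty")
})

test_that("FC maps are correlations with a finite Fisher transform", {
  s <- tiny_series(nx = 4, ny = 4, nz = 2, nt = 40, seed = 11)
  tc <- s$data[1, 1, 1, ]
  # make one voxel orthogonal to the seed
  v <- rnorm(40)
  s$data[2, 2, 2, ] <- residuals(lm(v ~ tc))
  fm <- fc_map(s, tc)
  expect_equal(fm$r_map[1, 1, 1], 1)
  expect_true(is.finite(fm$z_map[1, 1, 1]))
  expect_equal(fm$z_map[1, 1, 1], atanh(1 - 1e-7))
  expect_lt(abs(fm$r_map[2, 2, 2]), 0.05)
  expect_true(all(abs(fm$r_map) <= 1))
  # z = atanh(r) wherever |r| < 1; Fisher z is odd and increasing
  mid <- abs(fm$r_map) < 0.999 & fm$r_map != 0
  expect_equal(fm$z_map[mid], atanh(fm$r_map[mid]))
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
  rr <- seq(-0.9, 0.9, 0.1)
  expect_equal(atanh(-rr), -atanh(rr))
  expect_true(all(diff(atanh(rr)) > 0))
  # zero-variance voxel flagged, r set to 0
  s$data[3, 3, 1, ] <- 7
  fm2 <- fc_map(s, tc)
  expect_equal(fm2$n_flagged, 1)
  expect_equal(fm2$r_map[3, 3, 1], 0)
  expect_error(fc_map(s, tc[1:10]), "length")
})

test_that("FC within the seed is positive on non-degenerate input", {
  s <- tiny_series(nx = 5, ny = 5, nz = 3, nt = 30, seed = 12)
  vox <- as.matrix(expand.grid(2:3, 2:3, 1:2))
  tc <- seed_timecourse(s, vox)
  fm <- fc_map(s, tc)
  expect_gt(mean(fm$r_map[vox]), 0)
})

test_that("group and state FC contrasts match t-test oracles", {
  mask <- array(TRUE, c(4, 4, 2))
  g <- rep(c("NC", "MCI"), each = 4)
  set.seed(13)
  zr <- lapply(1:8, function(i) array(rnorm(32), dim(mask)))
  zt <- lapply(1:8, function(i) array(rnorm(32), dim(mask)))
  gc <- group_fc_contrast(zr, zt, g, contrast = "group",
                          which_state = "task", mask = mask)
  for (v in sample(32, 5)) {
    vals <- sapply(zt, function(m) m[v])
    tt <- t.test(vals[g == "MCI"], vals[g == "NC"], var.equal = TRUE)
    expect_equal(gc$t_map[v], unname(tt$statistic), tolerance = 1e-12)
  }
  # paired-state oracle within NC
  st <- group_fc_contrast(zr, zt, g, contrast = "state",
                          which_group = "NC", mask = mask)
  for (v in sample(32, 5)) {
    d <- sapply(which(g == "NC"), function(i) zt[[i]][v] - zr[[i]][v])
    tt <- t.test(d)
    expect_equal(st$t_map[v], unname(tt$statistic), tolerance = 1e-12)
  }
  # identical groups give a null map
  zt_same <- c(zt[1:4], zt[1:4])
  gc0 <- group_fc_contrast(zr, zt_same, g, contrast = "group",
                           which_state = "task", mask = mask)
  expect_equal(max(abs(gc0$t_map)), 0)
  # swapping group labels negates the t map exactly
  g_swap <- rep(c("MCI", "NC"), each = 4)
  gc_swap <- group_fc_contrast(zr, zt, g_swap, contrast = "group",
                               which_state = "task", mask = mask)
  expect_equal(gc_swap$t_map, -gc$t_map, tolerance = 1e-12)
})
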