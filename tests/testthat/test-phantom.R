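# Cohort tests run on a small grid; the generator's scientific defaults
# (group sizes, 154 volumes, TR 2 s) are exercised in the acceptance suite.
small_args <- list(grid_shape = c(10, 10, 6), n_volumes = 20,
                   planted_clusters = list(planted_effect(
                     as.matrix(expand.grid(4:6, 4:6, 3:4)))))

test_that("cohort generation respects the configured design", {
  cfg <- do.call(phantom_config, c(small_args, list(rng_seed = 7)))
  expect_equal(cfg$n_per_group, c(16L, 17L))   # default group sizes
  coh <- generate_cohort(cfg)
  expect_equal(sum(coh$subjects$group == "NC"), 16)
  expect_equal(sum(coh$subjects$group == "MCI"), 17)
  expect_equal(length(coh$series), 33)
  expect_equal(dim(coh$series[[1]]$rest$data), c(10, 10, 6, 20))
  expect_equal(dim(coh$series[[1]]$task$data), c(10, 10, 6, 20))
  expect_equal(nrow(coh$nuisance[[1]]$task), 20)
  expect_equal(ncol(coh$nuisance[[1]]$task), 9)  # 6 motion + global/wm/csf
  expect_true(all(coh$subjects$accuracy >= 0 & coh$subjects$accuracy <= 1))
  expect_true(all(coh$subjects$rt_ms > 0))
  expect_equal(coh$subjects$performance,
               coh$subjects$accuracy / coh$subjects$rt_ms)

  cfg2 <- do.call(phantom_config,
                  c(small_args, list(n_per_group = c(3, 3), rng_seed = 7)))
  coh2 <- generate_cohort(cfg2)
  expect_equal(nrow(coh2$subjects), 6)
})

test_that("identical config and seed give identical cohorts", {
  cfg <- do.call(phantom_config, c(small_args, list(rng_seed = 21)))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$series[[5]]$task$data, b$series[[5]]$task$data)
  expect_identical(a$nuisance[[3]]$rest, b$nuisance[[3]]$rest)
  cfg2 <- do.call(phantom_config, c(small_args, list(rng_seed = 22)))
  expect_false(identical(generate_cohort(cfg2)$series[[1]]$rest$data,
                         a$series[[1]]$rest$data))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(n_volumes = 4), "at least 8")
  expect_error(phantom_config(tr_s = 0), "positive")
  expect_error(do.call(phantom_config, c(
    list(grid_shape = c(10, 10, 6), planted_clusters = list(
      planted_effect(as.matrix(expand.grid(9:11, 4:5, 3:4))))))),
    "outside the mask")
  expect_error(planted_effect(rbind(c(1, 1, 1), c(5, 5, 5))),
               "not connected")
  expect_error(planted_effect(rbind(c(1, 1, 1)), coupling_by_cell = list(
    NC = c(rest = 1.2, task = 0), MCI = c(rest = 0, task = 0))),
    "\\[0, 1\\]")
})

test_that("planted latent signals are band-limited to their band", {
  pe <- planted_effect(as.matrix(expand.grid(3:7, 3:7, 2:4)),
                       band = "slow-5",
                       coupling_by_cell = list(NC = c(rest = 0.8, task = 0.8),
                                               MCI = c(rest = 0.8, task = 0.8)))
  bs <- generate_bold(c(9, 9, 5), 154, 2, planted = list(pe),
                      cell = c("NC", "rest"), seed = 6)
  # cluster-mean series isolates the shared latent; periodogram oracle
  cm <- rowMeans(apply(pe$cluster_voxels, 1,
                       function(v) bs$data[v[1], v[2], v[3], ]))
  expect_gt(spectral_fraction(cm, 2, 0.01, 0.027), 0.9)
})

test_that("in-cluster concordance rises monotonically with the weight", {
  vox <- as.matrix(expand.grid(3:7, 3:7, 2:4))
  mean_w_at <- function(w, seed) {
    pe <- planted_effect(vox, coupling_by_cell = list(
      NC = c(rest = w, task = w), MCI = c(rest = w, task = w)))
    bs <- generate_bold(c(9, 9, 5), 154, 2,
                        planted = if (w > 0) list(pe) else list(),
                        cell = c("NC", "rest"), seed = seed)
    r <- reho_map(bs, 26)
    mean(r$values[5, 5, 3])  # fully-interior voxel
  }
  levels <- c(0, 0.3, 0.6, 0.9)
  ws <- sapply(seq_along(levels), function(i) {
    mean(sapply(1:5, function(s) mean_w_at(levels[i], seed = 50 + s)))
  })
  expect_true(all(diff(ws) > 0))
})

test_that("behavior generation couples performance to state change", {
  # deterministic line: noise 0, negative coupling -> r = -1 exactly
  x <- seq(-0.02, 0.02, length.out = 10)
  b <- generate_behavior(x, coupling = -5e-3, noise_sd = 0, seed = 1,
                         baseline = 1e-3)
  expect_equal(cor(x, b$performance), -1)
  # null coupling: correlation centered on zero across replicate cohorts
  rs <- sapply(1:500, function(i) {
    set.seed(1000 + i)
    xi <- rnorm(17, 0, 0.006)
    bi <- generate_behavior(xi, coupling = 0, noise_sd = 1.2e-4,
                            seed = 2000 + i)
    cor(xi, bi$performance)
  })
  expect_lt(abs(mean(rs)), 2 / sqrt(17 * 500) * 3)
  # performance = accuracy / RT holds exactly by construction
  expect_equal(b$performance, b$accuracy / b$rt_ms)
  expect_error(generate_behavior(x, 1, noise_sd = -1), "non-negative")
})

test_that("coupling_for_r hits its target population correlation", {
  # closed form vs a large-sample simulation oracle
  c0 <- coupling_for_r(-0.63, sd_x = 0.006, noise_sd = 1.2e-4)
  set.seed(99)
  x <- rnorm(2e5, 0, 0.006)
  y <- c0 * x + rnorm(2e5, 0, 1.2e-4)
  expect_equal(cor(x, y), -0.63, tolerance = 0.01)
  expect_error(coupling_for_r(1, 1, 1), "inside")
})
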