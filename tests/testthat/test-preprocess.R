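test_that("volume trimming drops leading volumes and preserves metadata", {
  s200 <- tiny_series(nt = 200)
  s163 <- tiny_series(nt = 163)
  expect_equal(dim(trim_volumes(s200, 46))[4], 154)
  expect_equal(dim(trim_volumes(s163, 9))[4], 154)
  expect_identical(trim_volumes(s200, 0), s200)
  t46 <- trim_volumes(s200, 46)
  expect_equal(t46$data[, , , 1], s200$data[, , , 47])
  expect_equal(t46$tr_s, s200$tr_s)
  expect_error(trim_volumes(s200, 200), "discard")
  expect_error(trim_volumes(s200, -1), "non-negative")
})

test_that("motion QC applies the strict excursion rule and reports FD", {
  zero <- matrix(0, 20, 6)
  q <- motion_qc(zero)
  expect_true(q$pass)
  expect_equal(q$max_excursion_mm, 0)
  expect_equal(q$mean_fd_mm, 0)

  big <- zero; big[10, 2] <- 3.5
  expect_false(motion_qc(big)$pass)

  edge <- zero; edge[5, 1] <- 2.99
  expect_true(motion_qc(edge, threshold_mm = 3)$pass)
  at3 <- zero; at3[5, 1] <- 3
  expect_false(motion_qc(at3, threshold_mm = 3)$pass)

  # FD oracle on a hand-built table: one step of 0.1 mm in x and 0.01 rad
  # in one rotation -> per-frame FD 0.1 + 0.01*50, averaged over frames
  mp <- matrix(0, 4, 6); mp[2:4, 1] <- 0.1; mp[2:4, 4] <- 0.01
  expect_equal(motion_qc(mp)$mean_fd_mm, (0.1 + 0.5) / 4)
  expect_error(motion_qc(zero[, 1:5]), "6")
})

test_that("nuisance regression leaves residuals orthogonal to regressors", {
  set.seed(42)
  nt <- 20
  nuis <- matrix(rnorm(nt * 3), nt, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  s <- tiny_series(nx = 3, ny = 3, nz = 2, nt = nt, seed = 2)
  # voxel equal to a regressor -> residual ~ 0
  s$data[1, 1, 1, ] <- nuis[, 2]
  # voxel orthogonal to [1 | nuisance], mean zero -> unchanged
  X <- cbind(1, nuis)
  v <- rnorm(nt)
  v <- v - X %*% solve(crossprod(X), crossprod(X, v))
  s$data[2, 1, 1, ] <- v

  r <- regress_nuisance(s, nuis)
  expect_lt(max(abs(r$data[1, 1, 1, ])), 1e-10)
  expect_equal(r$data[2, 1, 1, ], as.numeric(v), tolerance = 1e-10)

  # pseudoinverse least-squares oracle, all voxels
  Y <- mask_matrix(s)
  resid_oracle <- Y - X %*% (solve(crossprod(X)) %*% crossprod(X, Y))
  expect_equal(mask_matrix(r), resid_oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  # orthogonality invariant
  expect_lt(max(abs(crossprod(X, mask_matrix(r)))),
            1e-8 * max(abs(Y)))
  expect_warning(regress_nuisance(s, cbind(nuis, a2 = nuis[, 1])),
                 "collinear")
  expect_error(regress_nuisance(s, nuis[1:10, ]), "match")
})

test_that("ideal band-pass keeps its passband and rejects its stopband", {
  nt <- 154; tr <- 2
  tt <- seq_len(nt) * tr
  # bin-aligned in-band sinusoid (bin 16 -> 16/308 Hz ~ 0.052, inside slow-4)
  f_bin <- 16 / (nt * tr)
  s_in <- one_voxel(sin(2 * pi * f_bin * tt), tr)
  out <- bandpass(s_in, "slow-4")
  expect_gt(cor(drop(out$data), drop(s_in$data)), 0.999)
  # off-bin 0.05 Hz sinusoid: in slow-4's passband up to spectral leakage
  s05 <- one_voxel(sin(2 * pi * 0.05 * tt), tr)
  expect_gt(cor(drop(bandpass(s05, "slow-4")$data), drop(s05$data)), 0.98)
  # same sinusoid is in slow-5's stopband: the retained variance equals
  # the analytic spectral-leakage fraction (periodogram oracle) and the
  # bin-aligned sinusoid leaks well under 1%
  leak <- var(drop(bandpass(s05, "slow-5")$data)) / var(drop(s05$data))
  expect_equal(leak, spectral_fraction(drop(s05$data), tr, 0.01, 0.027),
               tolerance = 1e-8)
  expect_lt(leak, 0.02)
  expect_lt(var(drop(bandpass(s_in, "slow-5")$data)) / var(drop(s_in$data)),
            0.01)
  # constant series -> all zero for any band excluding DC
  expect_equal(max(abs(bandpass(one_voxel(rep(5, nt), tr), "slow-5")$data)), 0)
  # band beyond Nyquist rejected
  expect_error(bandpass(s05, band_spec("x", 0.2, 0.3)), "Nyquist")
})

test_that("the rectangular filter is an exact projection", {
  set.seed(7)
  s <- one_voxel(rnorm(154) + 0.05 * seq_len(154))
  y1 <- bandpass(s, "slow-4")
  y2 <- bandpass(y1, "slow-4", detrend = FALSE)
  expect_equal(y2$data, y1$data, tolerance = 1e-12)
})

test_that("band variances partition the detrended variance (Parseval)", {
  set.seed(8)
  s <- tiny_series(nx = 3, ny = 2, nz = 2, nt = 154)
  bands <- lapply(names(slow_bands), band_spec)
  v_bands <- sapply(bands, function(b) {
    apply(mask_matrix(bandpass(s, b)), 2, var)
  })
  v_detrended <- apply(rehoband:::detrend_linear(mask_matrix(s)), 2, var)
  expect_equal(rowSums(v_bands), v_detrended, tolerance = 1e-8)
  # named bands are pairwise disjoint in bin space by construction
  edges <- t(sapply(slow_bands, function(b) c(b$f_low, b$f_high)))
  expect_true(all(edges[-1, 1] == edges[-nrow(edges), 2]))
})
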