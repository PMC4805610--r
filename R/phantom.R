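# Run an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards. Keeps every generator
# reproducible and independent of ambient RNG use.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seeds below 2^31, fanned out from one master
# seed so each scan/stage has its own reproducible stream.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed)
  for (i in seq_along(ids)) s <- (s * 69069 + ids[i] * 7919 + 1) %% 2147483647
  as.integer(s)
}

#' Ellipsoidal brain-like mask
#'
#' @param grid_shape Integer length-3 voxel counts.
#' @param shape `"ellipsoid"` (default; semi-axes 0.45 of each dimension,
#'   centered) or `"full"` (every voxel in-mask).
#' @return Logical 3D array.
#' @export
phantom_mask <- function(grid_shape, shape = c("ellipsoid", "full")) {
  shape <- match.arg(shape)
  d <- as.integer(grid_shape)
  if (shape == "full") return(array(TRUE, d))
  ctr <- (d + 1) / 2
  ax <- 0.45 * d
  x <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
  y <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
  z <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
  array(outer(outer(x, y, `+`), z, `+`) <= 1, d)
}

#' Define a planted local-synchrony effect
#'
#' A connected cluster of voxels whose time series share a band-limited
#' latent signal, with the shared-variance weight w depending on the
#' (group, state) cell. A crossed weight pattern (e.g. NC task < rest, MCI
#' task > rest) plants a group-by-state interaction for the downstream
#' statistics to recover.
#'
#' @param cluster_voxels Integer matrix of grid coordinates (rows = voxels,
#'   columns x, y, z, 1-based).
#' @param band Band of the latent signal (see [band_spec()]).
#' @param coupling_by_cell Named list `list(NC = c(rest = , task = ),
#'   MCI = c(rest = , task = ))` of weights in [0, 1]. The defaults look
#'   small because w is the shared fraction of *wide-band* variance: after
#'   band-pass filtering into the effect's narrow band only a few percent
#'   of the independent white noise survives, so the within-band shared
#'   fraction (which is what ReHo sees) is an order of magnitude larger
#'   (w = 0.022 gives about 0.25 in slow-5 at TR = 2 s and 154 volumes).
#' @param connectivity Connectivity under which the cluster must be
#'   connected (default 18).
#' @return A `planted_effect` object.
#' @export
planted_effect <- function(cluster_voxels, band = "slow-5",
                           coupling_by_cell = list(
                             NC = c(rest = 0.022, task = 0.007),
                             MCI = c(rest = 0.007, task = 0.022)),
                           connectivity = 18) {
  vox <- as.matrix(cluster_voxels)
  if (ncol(vox) != 3 || nrow(vox) < 1)
    stop("'cluster_voxels' must be an n x 3 coordinate matrix")
  w <- unlist(coupling_by_cell)
  if (any(w < 0 | w > 1)) stop("all coupling weights must lie in [0, 1]")
  # connectedness check on the cluster's bounding box
  lo <- apply(vox, 2, min); hi <- apply(vox, 2, max)
  dd <- hi - lo + 1L
  bin <- array(FALSE, dd)
  bin[vox - matrix(lo - 1L, nrow(vox), 3, byrow = TRUE)] <- TRUE
  lab <- cpp_label_clusters(as.logical(bin), as.integer(dd),
                            as.integer(connectivity))
  if (max(lab) > 1) stop("planted cluster is not connected")
  structure(list(cluster_voxels = vox, band = as_band(band),
                 coupling_by_cell = coupling_by_cell),
            class = "planted_effect")
}

# Default planted cluster: a 7 x 7 x 5 box (245 voxels) at the grid
# center. ReHo dilutes a planted region at its border by one neighborhood
# radius (border voxels mix cluster and background neighbors), so the box
# must exceed the intended detectable extent after a one-voxel erosion:
# 7 x 7 x 5 erodes to 5 x 5 x 3 = 75 fully-interior voxels.
default_cluster <- function(grid_shape) {
  ctr <- round(grid_shape / 2)
  as.matrix(expand.grid(x = ctr[1] + (-3:3), y = ctr[2] + (-3:3),
                        z = ctr[3] + (-2:2)))
}

#' Phantom cohort configuration
#'
#' Defines the synthetic study: two groups (NC and MCI) of elderly
#' subjects, each scanned in a resting and a working-memory task state with
#' equal volume counts, with band-limited locally synchronized signal
#' planted in known clusters and a behavioral performance variable coupled
#' to each subject's planted state change. Defaults mirror the emulated
#' study design: 16 NC and 17 MCI subjects, 154 volumes per state at
#' TR = 2 s, 3 mm voxels on a 24 x 24 x 16 grid.
#'
#' @param n_per_group Length-2 counts, `c(NC, MCI)` (default `c(16, 17)`).
#' @param grid_shape Voxel grid (default `c(24, 24, 16)`).
#' @param voxel_size_mm Isotropic voxel edge in mm (default 3).
#' @param n_volumes Time points per state (default 154; minimum 8).
#' @param tr_s Repetition time in seconds (default 2).
#' @param planted_clusters List of [planted_effect()]s; default one slow-5
#'   cluster of 100 voxels with the crossed NC/MCI weight pattern.
#' @param noise_sd Voxel noise amplitude (default 1).
#' @param subject_w_sd Between-subject SD of the planted state-change
#'   magnitude (default 0.006): a subject-specific jitter j is added
#'   antisymmetrically (+j/2 to the task weight, -j/2 to the rest weight),
#'   so each subject has an individual state change while the cell means
#'   stay at the configured weights.
#' @param global_amp Amplitude of a shared global signal added to every
#'   in-mask voxel and emitted as the "global" nuisance regressor
#'   (default 0.3).
#' @param behavior_baseline,behavior_coupling,behavior_noise_sd Performance
#'   model: `performance = baseline + coupling * state_change + noise`
#'   (defaults chosen so group means land near 1.5e-3 and 1.2e-3 /ms).
#' @param rt_mean_ms,rt_sd_ms Subject response-time distribution (defaults
#'   650 and 70 ms).
#' @param mask_shape `"ellipsoid"` or `"full"`.
#' @param rng_seed Master seed; fixed seed implies byte-identical cohorts.
#' @return A validated `phantom_config`.
#' @export
phantom_config <- function(n_per_group = c(16, 17),
                           grid_shape = c(24, 24, 16),
                           voxel_size_mm = 3,
                           n_volumes = 154,
                           tr_s = 2,
                           planted_clusters = NULL,
                           noise_sd = 1,
                           subject_w_sd = 0.006,
                           global_amp = 0.3,
                           behavior_baseline = 1.35e-3,
                           behavior_coupling = -1.2e-2,
                           behavior_noise_sd = 1.2e-4,
                           rt_mean_ms = 650,
                           rt_sd_ms = 70,
                           mask_shape = "ellipsoid",
                           rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(n_per_group) != 2 || any(n_per_group < 1))
    stop("'n_per_group' must be two positive counts (NC, MCI)")
  if (n_volumes < 8) stop("'n_volumes' must be at least 8")
  if (tr_s <= 0) stop("'tr_s' must be positive")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  mask <- phantom_mask(grid_shape, mask_shape)
  if (is.null(planted_clusters))
    planted_clusters <- list(planted_effect(default_cluster(grid_shape)))
  for (pe in planted_clusters) {
    if (!inherits(pe, "planted_effect")) stop("planted_clusters must be planted_effect objects")
    if (any(pe$cluster_voxels < 1) ||
        any(sweep(pe$cluster_voxels, 2, grid_shape, `>`)) ||
        !all(mask[pe$cluster_voxels]))
      stop("planted cluster falls outside the mask")
    if (pe$band$f_high > 1 / (2 * tr_s))
      stop("planted band exceeds the Nyquist frequency")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), grid_shape = grid_shape,
         voxel_size_mm = voxel_size_mm, n_volumes = as.integer(n_volumes),
         tr_s = tr_s, planted_clusters = planted_clusters,
         noise_sd = noise_sd, subject_w_sd = subject_w_sd,
         global_amp = global_amp,
         behavior_baseline = behavior_baseline,
         behavior_coupling = behavior_coupling,
         behavior_noise_sd = behavior_noise_sd,
         rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
         mask = mask, rng_seed = as.integer(rng_seed)),
    class = "phantom_config"
  )
}

# Band-limited unit-variance latent signal: white noise through the same
# ideal band-pass used in preprocessing (one filter definition).
latent_signal <- function(n_volumes, tr_s, band) {
  x <- matrix(stats::rnorm(n_volumes), ncol = 1)
  y <- ideal_bandpass_matrix(detrend_linear(x), tr_s, band$f_low, band$f_high)
  drop(y) / stats::sd(y)
}

#' Generate one synthetic BOLD scan
#'
#' Each in-mask voxel's series is
#' `sqrt(w) * latent + sqrt(1 - w) * noise`, scaled by `noise_sd`, where
#' the latent is a shared band-limited signal per planted cluster and w is
#' the planted weight for the requested (group, state) cell (0 outside
#' planted clusters). An optional shared global signal of amplitude
#' `global_amp * noise_sd` is added to all in-mask voxels and returned so
#' it can be emitted as a nuisance regressor.
#'
#' @param grid_shape,n_volumes,tr_s,voxel_size_mm Grid and timing.
#' @param planted List of [planted_effect()]s.
#' @param cell Character `c(group, state)`, e.g. `c("NC", "task")`.
#' @param noise_sd Noise amplitude.
#' @param seed Integer seed.
#' @param mask Logical 3D mask (default all-true).
#' @param w_jitter Added to every planted weight (then clipped to [0, 1]);
#'   used for between-subject variation.
#' @param global_amp Shared-signal amplitude relative to `noise_sd`.
#' @return A `bold_series`; the injected global series (or NULL) is in
#'   attribute `global_signal`, the realized weight map in attribute `w`.
#' @export
generate_bold <- function(grid_shape, n_volumes, tr_s, planted = list(),
                          cell = c("NC", "rest"), noise_sd = 1, seed = 1,
                          mask = NULL, voxel_size_mm = 3, w_jitter = 0,
                          global_amp = 0) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 1) || n_volumes < 2) stop("invalid shape or length")
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  group <- cell[1]; state <- cell[2]
  with_seed(seed, {
    nvox <- prod(grid_shape)
    dat <- matrix(0, nvox, n_volumes)
    inmask <- which(as.vector(mask))
    dat[inmask, ] <- stats::rnorm(length(inmask) * n_volumes, sd = noise_sd)
    wmap <- numeric(nvox)
    for (pe in planted) {
      w <- pe$coupling_by_cell[[group]][[state]] + w_jitter
      w <- min(max(w, 0), 1)
      if (w < 0 || w > 1) stop("planted weight outside [0, 1]")
      lat <- latent_signal(n_volumes, tr_s, pe$band)
      idx <- pe$cluster_voxels[, 1] +
        grid_shape[1] * (pe$cluster_voxels[, 2] - 1L) +
        grid_shape[1] * grid_shape[2] * (pe$cluster_voxels[, 3] - 1L)
      dat[idx, ] <- sqrt(1 - w) * dat[idx, , drop = FALSE] +
        noise_sd * sqrt(w) * rep(lat, each = length(idx))
      wmap[idx] <- w
    }
    gs <- NULL
    if (global_amp > 0) {
      gs <- stats::rnorm(n_volumes)
      dat[inmask, ] <- dat[inmask, , drop = FALSE] +
        global_amp * noise_sd * rep(gs, each = length(inmask))
    }
    dim(dat) <- c(grid_shape, n_volumes)
    out <- new_bold_series(dat, tr_s = tr_s,
                           voxel_size_mm = voxel_size_mm, mask = mask)
    attr(out, "global_signal") <- gs
    attr(out, "w") <- array(wmap, grid_shape)
    out
  })
}

# Covariate distributions matched to the emulated cohort's demographics
# (age ~ 69/71 y, education ~ 12/10 y, balanced sex, small mean FD).
covariate_defaults <- list(
  NC  = list(age = c(68.56, 5.76), edu = c(11.75, 3.17), p_male = 8 / 16),
  MCI = list(age = c(70.53, 4.54), edu = c(9.82, 4.63), p_male = 9 / 17)
)

#' Generate a full synthetic cohort
#'
#' Draws covariates, simulates a resting and a task scan per subject with
#' the configured planted effects, emits per-scan nuisance regressor
#' tables, and couples a behavioral performance score to each subject's
#' planted state-change magnitude (task w minus rest w, averaged over
#' planted clusters).
#'
#' @param config A [phantom_config()].
#' @return List with `subjects` (data frame: subject_id, group, age, sex,
#'   education, mean_fd, state_change, accuracy, rt_ms, performance),
#'   `series` (per subject, list with `rest` and `task` `bold_series`),
#'   `nuisance` (per subject, list of per-state data frames), `mask`, and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  groups <- rep(c("NC", "MCI"), config$n_per_group)
  n <- length(groups)
  ids <- sprintf("sub-%02d", seq_len(n))

  covs <- with_seed(derive_seed(config$rng_seed, 1), {
    do.call(rbind, lapply(seq_len(n), function(i) {
      cd <- covariate_defaults[[groups[i]]]
      data.frame(
        age = stats::rnorm(1, cd$age[1], cd$age[2]),
        sex = stats::rbinom(1, 1, cd$p_male),
        education = stats::rnorm(1, cd$edu[1], cd$edu[2])
      )
    }))
  })
  wj <- with_seed(derive_seed(config$rng_seed, 2),
                  stats::rnorm(n, 0, config$subject_w_sd))

  series <- vector("list", n); nuis <- vector("list", n)
  state_change <- numeric(n); mean_fd <- numeric(n)
  for (i in seq_len(n)) {
    per_state <- list(); per_nuis <- list()
    for (st in c("rest", "task")) {
      sseed <- derive_seed(config$rng_seed, 10 + i, match(st, c("rest", "task")))
      bs <- generate_bold(config$grid_shape, config$n_volumes, config$tr_s,
                          planted = config$planted_clusters,
                          cell = c(groups[i], st),
                          noise_sd = config$noise_sd, seed = sseed,
                          mask = config$mask,
                          voxel_size_mm = config$voxel_size_mm,
                          w_jitter = if (st == "task") wj[i] / 2 else -wj[i] / 2,
                          global_amp = config$global_amp)
      nt <- config$n_volumes
      nu <- with_seed(derive_seed(config$rng_seed, 20 + i, match(st, c("rest", "task"))), {
        mot <- apply(matrix(stats::rnorm(nt * 6,
                                         sd = rep(c(0.02, 2e-4), each = 3 * nt)),
                            nt, 6), 2, cumsum)
        colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                           "rot_x", "rot_y", "rot_z")
        data.frame(mot,
                   global = if (is.null(attr(bs, "global_signal")))
                     stats::rnorm(nt) else attr(bs, "global_signal"),
                   wm = stats::rnorm(nt), csf = stats::rnorm(nt))
      })
      per_state[[st]] <- bs
      per_nuis[[st]] <- nu
    }
    series[[i]] <- per_state
    nuis[[i]] <- per_nuis
    mean_fd[i] <- motion_qc(per_nuis$rest[, 1:6])$mean_fd_mm
    # planted state change for this subject, averaged over clusters
    sc <- vapply(config$planted_clusters, function(pe) {
      w <- pe$coupling_by_cell[[groups[i]]]
      clip01 <- function(v) min(max(v, 0), 1)
      clip01(w[["task"]] + wj[i] / 2) - clip01(w[["rest"]] - wj[i] / 2)
    }, numeric(1))
    state_change[i] <- mean(sc)
  }

  beh <- generate_behavior(state_change,
                           coupling = config$behavior_coupling,
                           noise_sd = config$behavior_noise_sd,
                           seed = derive_seed(config$rng_seed, 3),
                           baseline = config$behavior_baseline,
                           rt_mean_ms = config$rt_mean_ms,
                           rt_sd_ms = config$rt_sd_ms)

  subjects <- cbind(
    data.frame(subject_id = ids, group = groups),
    covs,
    data.frame(mean_fd = mean_fd, state_change = state_change)
  )
  subjects <- cbind(subjects, beh)
  list(subjects = subjects, series = series, nuisance = nuis,
       mask = config$mask, config = config)
}

#' Generate behavioral scores coupled to a state-change magnitude
#'
#' The working-memory performance index (accuracy / RT, units 1/ms) is
#' `baseline + coupling * state_change + Gaussian noise`. Each subject's
#' RT is drawn from a normal distribution (truncated at 200 ms) and
#' accuracy is `performance * RT`, clipped to [0, 1], so
#' `performance = accuracy / rt_ms` holds exactly wherever clipping is
#' inactive.
#'
#' @param state_change Numeric vector, one planted state-change value per
#'   subject.
#' @param coupling Slope linking state change to performance (1/ms per unit
#'   w change).
#' @param noise_sd SD of the performance noise (1/ms).
#' @param seed Integer seed.
#' @param baseline Mean performance at zero state change (1/ms).
#' @param rt_mean_ms,rt_sd_ms Response-time distribution.
#' @return Data frame with `accuracy`, `rt_ms`, `performance`.
#' @export
generate_behavior <- function(state_change, coupling, noise_sd, seed = 1,
                              baseline = 1.35e-3, rt_mean_ms = 650,
                              rt_sd_ms = 70) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  n <- length(state_change)
  with_seed(seed, {
    perf <- baseline + coupling * state_change + stats::rnorm(n, 0, noise_sd)
    rt <- pmax(200, stats::rnorm(n, rt_mean_ms, rt_sd_ms))
    acc <- pmin(1, pmax(0, perf * rt))
    data.frame(accuracy = acc, rt_ms = rt, performance = acc / rt)
  })
}

#' Coupling slope that yields a target population correlation
#'
#' For `performance = baseline + coupling * x + e` with `e ~ N(0, sd_e)`,
#' the population Pearson correlation between x and performance is
#' `coupling * sd_x / sqrt(coupling^2 sd_x^2 + sd_e^2)`; inverting gives
#' `coupling = r * sd_e / (sd_x * sqrt(1 - r^2))`.
#'
#' @param r Target correlation in (-1, 1).
#' @param sd_x SD of the state-change values.
#' @param noise_sd SD of the performance noise.
#' @return The coupling slope.
#' @export
coupling_for_r <- function(r, sd_x, noise_sd) {
  if (abs(r) >= 1) stop("'r' must lie strictly inside (-1, 1)")
  r * noise_sd / (sd_x * sqrt(1 - r^2))
}
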