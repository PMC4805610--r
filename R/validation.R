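# Simulation experiments that validate the pipeline's statistical
# behavior on phantoms: null calibration, cluster-threshold properties,
# planted-effect recovery, and behavior-coupling recovery. These are the
# package's own power/calibration studies, kept in the package so they can
# be rerun verbatim.

#' Null calibration of ReHo and the interaction map
#'
#' Generates independence phantoms (no planted effects) and measures (i)
#' the mean Kendall's W over voxels with complete 26-neighborhoods, whose
#' expectation under independence is exactly 1/27, and (ii) the voxel-wise
#' type-I rate of the group-by-state interaction map at a nominal
#' `p_voxel`, which should match the nominal rate.
#'
#' @param n_phantoms Phantoms for the mean-W estimate (default 200).
#' @param n_cohorts Null cohorts for the type-I estimate (default 4).
#' @param grid_shape Phantom grid (default `c(12, 12, 8)`).
#' @param n_volumes Time points (default 154).
#' @param n_per_group Group sizes for the null cohorts (default
#'   `c(16, 17)`).
#' @param p_voxel Nominal voxel threshold (default 0.01).
#' @param seed Integer seed.
#' @return List: `mean_w` (over complete neighborhoods), `expected_w`
#'   (1/27), `type1_rate`, `n_type1_voxels`, `p_voxel`.
#' @export
null_calibration <- function(n_phantoms = 200, n_cohorts = 4,
                             grid_shape = c(12, 12, 8), n_volumes = 154,
                             n_per_group = c(16, 17), p_voxel = 0.01,
                             seed = 1) {
  wsum <- 0; wn <- 0
  for (r in seq_len(n_phantoms)) {
    bs <- generate_bold(grid_shape, n_volumes, tr_s = 2, planted = list(),
                        seed = derive_seed(seed, 300, r))
    rm <- reho_map(bs, 26)
    full <- rm$k == 27
    wsum <- wsum + sum(rm$values[full]); wn <- wn + sum(full)
  }
  hits <- 0; nv <- 0
  for (r in seq_len(n_cohorts)) {
    cfg <- phantom_config(n_per_group = n_per_group,
                          grid_shape = grid_shape, n_volumes = n_volumes,
                          planted_clusters = list(), mask_shape = "full",
                          rng_seed = derive_seed(seed, 400, r))
    coh <- generate_cohort(cfg)
    z <- lapply(seq_len(nrow(coh$subjects)), function(i) {
      lapply(c(rest = "rest", task = "task"), function(st) {
        scan_to_zmaps(coh$series[[i]][[st]], coh$nuisance[[i]][[st]],
                      list("slow-5"), connectivity = 26, fwhm_mm = 0)[[1]]
      })
    })
    im <- interaction_map(lapply(z, `[[`, "task"), lapply(z, `[[`, "rest"),
                          coh$subjects$group,
                          coh$subjects[, c("age", "sex", "education", "mean_fd")],
                          coh$mask)
    hits <- hits + sum(im$p_map[coh$mask] < p_voxel)
    nv <- nv + sum(coh$mask)
  }
  list(mean_w = wsum / wn, expected_w = 1 / 27,
       type1_rate = hits / nv, n_type1_voxels = nv, p_voxel = p_voxel)
}

#' Planted-effect recovery experiment
#'
#' Repeats the full analysis on freshly simulated default phantoms:
#' simulate a cohort, preprocess, compute band-limited z-ReHo maps in the
#' planted band, fit the covariate-adjusted group-by-state interaction,
#' apply the Monte-Carlo cluster-extent correction (k* is estimated once;
#' it depends only on mask, smoothness and thresholds), and check whether
#' a surviving cluster overlaps the planted one and whether the post-hoc
#' paired t-tests reproduce the planted interaction pattern (which group
#' rises and which falls from rest to task).
#'
#' @param n_replicates Number of simulated cohorts (default 50).
#' @param phantom_args Arguments for [phantom_config()] overriding the
#'   defaults.
#' @param fwhm_mm,p_voxel,alpha,connectivity,mc_iter Correction settings
#'   (defaults 4 mm, 0.01, 0.05, 18, 1000).
#' @param seed Integer seed.
#' @return List with `results` (data frame: replicate, detected,
#'   pattern_ok, n_clusters, overlap), `detection_rate`, `pattern_rate`
#'   (among detected), `k_star`.
#' @export
recovery_experiment <- function(n_replicates = 50, phantom_args = list(),
                                fwhm_mm = 4, p_voxel = 0.01, alpha = 0.05,
                                connectivity = 18, mc_iter = 1000,
                                seed = 1) {
  cfg0 <- do.call(phantom_config, c(phantom_args, list(rng_seed = 1L)))
  if (length(cfg0$planted_clusters) == 0)
    stop("recovery needs at least one planted cluster")
  pe <- cfg0$planted_clusters[[1]]
  truth_key <- paste(pe$cluster_voxels[, 1], pe$cluster_voxels[, 2],
                     pe$cluster_voxels[, 3])
  # expected paired-t directions from the planted weights
  dir_of <- function(g) {
    w <- pe$coupling_by_cell[[g]]
    if (w[["task"]] > w[["rest"]]) "task>rest" else "task<rest"
  }
  mc <- monte_carlo_cluster_threshold(cfg0$mask, fwhm_mm = fwhm_mm,
                                      p_voxel = p_voxel, alpha = alpha,
                                      n_iter = mc_iter,
                                      connectivity = connectivity,
                                      voxel_size_mm = cfg0$voxel_size_mm,
                                      seed = derive_seed(seed, 500))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- do.call(phantom_config,
                   c(phantom_args, list(rng_seed = derive_seed(seed, 600, r))))
    coh <- generate_cohort(cfg)
    zr <- list(); zt <- list()
    for (i in seq_len(nrow(coh$subjects))) {
      for (st in c("rest", "task")) {
        z <- scan_to_zmaps(coh$series[[i]][[st]], coh$nuisance[[i]][[st]],
                           list(pe$band), connectivity = 26,
                           fwhm_mm = fwhm_mm)[[1]]
        if (st == "rest") zr[[i]] <- z else zt[[i]] <- z
      }
    }
    g <- coh$subjects$group
    im <- interaction_map(zt, zr, g,
                          coh$subjects[, c("age", "sex", "education", "mean_fd")],
                          coh$mask)
    cl <- extract_clusters(im$F_map, im$p_map, p_voxel = p_voxel,
                           k_min = mc$k_star, connectivity = connectivity,
                           mask = coh$mask)
    ov <- vapply(cl$voxels, function(v)
      sum(paste(v[, 1], v[, 2], v[, 3]) %in% truth_key), integer(1))
    detected <- length(ov) > 0 && max(ov) > 0
    pattern_ok <- NA
    if (detected) {
      j <- which.max(ov)
      cm_r <- cluster_means(zr, cl$voxels[[j]])
      cm_t <- cluster_means(zt, cl$voxels[[j]])
      ph <- posthoc_t(cm_r, cm_t, g)
      paired <- ph[ph$type == "paired", ]
      grp <- sub("task-rest \\((.*)\\)", "\\1", paired$comparison)
      pattern_ok <- all(paired$direction == vapply(grp, dir_of, ""))
    }
    rows[[r]] <- data.frame(replicate = r, detected = detected,
                            pattern_ok = pattern_ok,
                            n_clusters = nrow(cl$table),
                            overlap = if (detected) max(ov) else 0L)
  }
  res <- do.call(rbind, rows)
  list(results = res, detection_rate = mean(res$detected),
       pattern_rate = mean(res$pattern_ok[res$detected]),
       k_star = mc$k_star)
}

#' Behavior-coupling recovery experiment
#'
#' Draws replicate samples of per-subject state-change values, generates
#' behavior through the performance model with the coupling slope set by
#' [coupling_for_r()] to a target population correlation, and measures the
#' mean recovered Pearson r and (optionally) the coverage of the
#' percentile bootstrap confidence interval.
#'
#' The default baseline performance matches an impaired group mean of
#' about 1.16e-3 /ms so that accuracy stays clear of its [0, 1] ceiling.
#'
#' @param n_replicates Replicates for the mean-r estimate (default 200).
#' @param n Subjects per replicate (default 17).
#' @param target_r Population correlation to plant (default -0.63).
#' @param sd_x SD of the state-change values (default 0.006).
#' @param noise_sd Performance noise SD (default 1.2e-4).
#' @param B Bootstrap resamples (default 1000).
#' @param coverage_replicates Replicates for CI coverage; 0 skips
#'   (default 0).
#' @param baseline Mean performance (default 1.16e-3).
#' @param seed Integer seed.
#' @return List: `mean_r`, `r_values`, `coupling`, and if requested
#'   `coverage` with its replicate count.
#' @export
behavior_recovery <- function(n_replicates = 200, n = 17, target_r = -0.63,
                              sd_x = 0.006, noise_sd = 1.2e-4, B = 1000,
                              coverage_replicates = 0, baseline = 1.16e-3,
                              seed = 1) {
  coupling <- coupling_for_r(target_r, sd_x, noise_sd)
  one_r <- function(s) {
    x <- with_seed(derive_seed(s, 1), stats::rnorm(n, 0, sd_x))
    beh <- generate_behavior(x, coupling, noise_sd, seed = derive_seed(s, 2),
                             baseline = baseline)
    stats::cor(x, beh$performance)
  }
  rs <- vapply(seq_len(n_replicates), function(r)
    one_r(derive_seed(seed, 700, r)), numeric(1))
  out <- list(mean_r = mean(rs), r_values = rs, coupling = coupling,
              target_r = target_r)
  if (coverage_replicates > 0) {
    covered <- logical(coverage_replicates)
    for (r in seq_len(coverage_replicates)) {
      s <- derive_seed(seed, 800, r)
      x <- with_seed(derive_seed(s, 1), stats::rnorm(n, 0, sd_x))
      beh <- generate_behavior(x, coupling, noise_sd,
                               seed = derive_seed(s, 2), baseline = baseline)
      ci <- correlate_with_bootstrap(x, beh$performance, B = B,
                                     seed = derive_seed(s, 3))
      covered[r] <- ci$ci_low <= target_r && target_r <= ci$ci_high
    }
    out$coverage <- mean(covered)
    out$coverage_replicates <- coverage_replicates
  }
  out
}
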