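#' State-related change map
#'
#' Voxel-wise task minus rest.
#'
#' @param task_map,rest_map Numeric 3D arrays (or `reho_map`s) of matching
#'   shape.
#' @return Numeric 3D difference array.
#' @export
state_difference <- function(task_map, rest_map) {
  a <- if (inherits(task_map, "reho_map")) task_map$values else task_map
  b <- if (inherits(rest_map, "reho_map")) rest_map$values else rest_map
  if (!identical(dim(a), dim(b))) stop("map shapes differ")
  a - b
}

# Stack a list of reho_maps (or 3D arrays) into a voxels x subjects matrix
# restricted to the mask.
stack_maps <- function(maps, mask) {
  vals <- vapply(maps, function(m) {
    v <- if (inherits(m, "reho_map")) m$values else m
    as.numeric(v)[as.vector(mask)]
  }, numeric(sum(mask)))
  matrix(vals, nrow = sum(mask))
}

#' Voxel-wise group-by-state interaction map
#'
#' Two-group repeated-measures interaction with subject-level covariates,
#' fitted through the difference-score formulation: per voxel, the
#' state-related change d = task - rest is regressed on
#' [intercept | group | covariates]; the interaction F is the squared t of
#' the group coefficient, with df (1, N - q). For a balanced 2 x 2 design
#' with state-invariant covariates this is algebraically the
#' repeated-measures group-by-state interaction, because differencing
#' removes subject and state main effects. F-test p-values are one-tailed
#' by construction.
#'
#' @param task_maps,rest_maps Lists of per-subject standardized
#'   `reho_map`s (or 3D arrays), same subject order as `group`.
#' @param group Per-subject group labels (2 levels).
#' @param covariates Optional data frame of subject-level covariates
#'   (e.g. age, sex, education, motion summary, GM intensity).
#' @param mask Logical 3D array.
#' @return List with `F_map`, `p_map` (3D, p = 1 outside mask and at
#'   zero-variance voxels), `df` (length 2), `n`.
#' @export
interaction_map <- function(task_maps, rest_maps, group, covariates = NULL,
                            mask) {
  n <- length(group)
  if (length(task_maps) != n || length(rest_maps) != n)
    stop("one task and one rest map per subject required")
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (min(table(g)) < 3) stop("need at least 3 subjects per group")
  D <- stack_maps(task_maps, mask) - stack_maps(rest_maps, mask)  # v x n
  X <- cbind(intercept = 1, group = as.numeric(g) - 1)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (any(!is.finite(C))) stop("covariates must be finite")
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!all(1:2 %in% keep))
      stop("group column collinear with covariates")
    warning("dropping ", ncol(X) - qrX$rank, " collinear covariate column(s)")
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  q <- ncol(X)
  df2 <- n - q
  if (df2 < 1) stop("not enough residual degrees of freedom")
  XtXinv_gg <- chol2inv(qr.R(qrX))[2, 2]
  beta_g <- qr.coef(qrX, t(D))[2, ]               # group coefficient per voxel
  res <- qr.resid(qrX, t(D))                      # n x v
  sigma2 <- colSums(res^2) / df2
  Fv <- beta_g^2 / (sigma2 * XtXinv_gg)
  Fv[!is.finite(Fv)] <- 0
  pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  zero_var <- sigma2 <= 0
  Fv[zero_var] <- 0; pv[zero_var] <- 1
  p_map <- array(1, dim(mask)); p_map[mask] <- pv
  list(F_map = unmask(Fv, mask), p_map = p_map, df = c(1, df2), n = n)
}

#' Label connected suprathreshold clusters
#'
#' @param bin Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 18: faces + edges, the 5 mm
#'   edge-distance rule at 3 mm voxels).
#' @return Integer 3D label array (0 = background).
#' @export
label_clusters <- function(bin, connectivity = 18) {
  connectivity <- as.integer(match.arg(as.character(connectivity),
                                       c("6", "18", "26")))
  cpp_label_clusters(as.logical(bin), as.integer(dim(bin)), connectivity)
}

#' Monte-Carlo cluster-extent threshold
#'
#' AlphaSim-style estimate of the minimum cluster size k* making a
#' voxel-level threshold family-wise significant at `alpha`: in each of
#' `n_iter` iterations the mask is filled with white Gaussian noise,
#' smoothed to `fwhm_mm`, re-standardized within the mask, binarized at
#' the upper `p_voxel` quantile, and labeled; k* is the smallest k for
#' which the fraction of iterations whose largest cluster reaches k is at
#' most `alpha`.
#'
#' @param mask Logical 3D array.
#' @param fwhm_mm Assumed smoothness (the applied smoothing FWHM by
#'   default convention).
#' @param p_voxel Voxel-level threshold (default 0.01).
#' @param alpha Family-wise level (default 0.05).
#' @param n_iter Iterations (default 1000, minimum 100).
#' @param connectivity Cluster connectivity (default 18).
#' @param voxel_size_mm Voxel edge in mm.
#' @param seed Integer seed.
#' @return List: `k_star`, `max_sizes` (per iteration),
#'   `mean_suprathreshold` (mean suprathreshold voxel count per iteration;
#'   approximately `sum(mask) * p_voxel`), `n_iter`, and the thresholds
#'   used.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm_mm = 4, p_voxel = 0.01,
                                          alpha = 0.05, n_iter = 1000,
                                          connectivity = 18,
                                          voxel_size_mm = 3, seed = 1) {
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  if (n_iter < 100) stop("'n_iter' must be at least 100")
  connectivity <- as.integer(match.arg(as.character(connectivity),
                                       c("6", "18", "26")))
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  nvox <- sum(mask)
  zcut <- stats::qnorm(1 - p_voxel)
  sigma <- if (fwhm_mm > 0) fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
           else c(0, 0, 0)
  stats_per_iter <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      noise <- unmask(stats::rnorm(nvox), mask)
      if (fwhm_mm > 0) noise <- smooth_array_3d(noise, sigma)
      v <- noise[mask]
      v <- (v - mean(v)) / stats::sd(v)
      supra <- v > zcut
      bin <- unmask(supra, mask) > 0
      lab <- cpp_label_clusters(as.logical(bin), as.integer(dim(mask)),
                                connectivity)
      c(if (max(lab) == 0) 0L else max(tabulate(lab[lab > 0])), sum(supra))
    }, integer(2))
  })
  max_sizes <- stats_per_iter[1, ]
  # smallest k with P(max cluster >= k) <= alpha
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  list(k_star = k, max_sizes = max_sizes,
       mean_suprathreshold = mean(stats_per_iter[2, ]), n_iter = n_iter,
       p_voxel = p_voxel, alpha = alpha, fwhm_mm = fwhm_mm,
       connectivity = connectivity)
}

#' Extract suprathreshold clusters into a table
#'
#' Binarizes `p_map < p_voxel`, labels connected components, keeps
#' clusters of at least `k_min` voxels, and reports size, peak statistic
#' and peak grid coordinate (ties in the peak broken by first voxel in
#' column-major grid order).
#'
#' @param stat_map 3D statistic (e.g. F) array.
#' @param p_map 3D p-value array.
#' @param p_voxel Voxel-level threshold.
#' @param k_min Minimum cluster extent (e.g. the Monte-Carlo k*).
#' @param connectivity 6, 18 or 26 (default 18).
#' @param mask Optional logical 3D array restricting the search.
#' @return List with `table` (data frame: label, size, peak_x, peak_y,
#'   peak_z, peak_stat), `labels` (3D array of retained cluster labels)
#'   and `voxels` (list of coordinate matrices per retained cluster).
#' @export
extract_clusters <- function(stat_map, p_map, p_voxel = 0.01, k_min = 1,
                             connectivity = 18, mask = NULL) {
  bin <- p_map < p_voxel
  if (!is.null(mask)) bin <- bin & mask
  lab <- label_clusters(bin, connectivity)
  nlab <- max(lab)
  empty <- list(table = data.frame(label = integer(), size = integer(),
                                   peak_x = integer(), peak_y = integer(),
                                   peak_z = integer(), peak_stat = numeric()),
                labels = array(0L, dim(stat_map)), voxels = list())
  if (nlab == 0) return(empty)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= k_min)
  if (length(keep) == 0) return(empty)
  out_lab <- array(0L, dim(stat_map))
  rows <- vector("list", length(keep))
  voxl <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    l <- keep[j]
    idx <- which(lab == l)                    # column-major order
    out_lab[idx] <- j
    stat <- stat_map[idx]
    peak <- idx[which.max(stat)]              # first max in grid order
    pc <- arrayInd(peak, dim(stat_map))
    rows[[j]] <- data.frame(label = j, size = sizes[l],
                            peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
                            peak_stat = max(stat))
    voxl[[j]] <- arrayInd(idx, dim(stat_map))
  }
  list(table = do.call(rbind, rows), labels = out_lab, voxels = voxl)
}

#' Per-subject cluster-mean values
#'
#' @param maps List of per-subject `reho_map`s or 3D arrays.
#' @param cluster_voxels Integer coordinate matrix (rows = voxels).
#' @return Numeric vector, one mean per subject.
#' @export
cluster_means <- function(maps, cluster_voxels) {
  vapply(maps, function(m) {
    v <- if (inherits(m, "reho_map")) m$values else m
    mean(v[as.matrix(cluster_voxels)])
  }, numeric(1))
}

#' Post-hoc t-tests for an interaction cluster
#'
#' Given per-subject cluster-mean standardized ReHo in both states:
#' between-group two-sample t-tests within each state, and within-group
#' paired t-tests between states, plus the direction of each change —
#' together these spell out the interaction pattern (which cells rise or
#' fall).
#'
#' @param rest,task Per-subject cluster means (same order as `group`).
#' @param group Per-subject group labels (2 levels, each with >= 2
#'   subjects).
#' @param var_equal Use pooled variance in the two-sample tests
#'   (default TRUE).
#' @return Data frame with one row per comparison: `comparison`, `type`,
#'   `estimate` (mean difference), `t`, `df`, `p`, `direction`.
#' @export
posthoc_t <- function(rest, task, group, var_equal = TRUE) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (min(table(g)) < 2) stop("each group needs at least 2 subjects")
  lv <- levels(g)
  rows <- list()
  for (st in c("rest", "task")) {
    v <- if (st == "rest") rest else task
    tt <- stats::t.test(v[g == lv[1]], v[g == lv[2]], var.equal = var_equal)
    est <- unname(diff(rev(tt$estimate)))     # group1 - group2
    rows[[length(rows) + 1]] <- data.frame(
      comparison = sprintf("%s-%s (%s)", lv[1], lv[2], st),
      type = "two-sample", estimate = est, t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      direction = if (est > 0) paste0(lv[1], ">", lv[2])
                  else paste0(lv[1], "<", lv[2]))
  }
  for (gr in lv) {
    sel <- g == gr
    tt <- stats::t.test(task[sel], rest[sel], paired = TRUE)
    est <- unname(tt$estimate)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = sprintf("task-rest (%s)", gr),
      type = "paired", estimate = est, t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      direction = if (est > 0) "task>rest" else "task<rest")
  }
  do.call(rbind, rows)
}
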