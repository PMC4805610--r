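#' Mean time course of a seed region
#'
#' Unweighted mean over the seed voxels at each time point.
#'
#' @param series A `bold_series`.
#' @param seed_voxels Integer coordinate matrix (rows = voxels, columns
#'   x, y, z), typically the voxels of an interaction cluster.
#' @return Numeric vector of length t.
#' @export
seed_timecourse <- function(series, seed_voxels) {
  stopifnot(inherits(series, "bold_series"))
  vox <- as.matrix(seed_voxels)
  if (nrow(vox) == 0) stop("empty seed")
  if (!all(series$mask[vox])) stop("seed voxels must lie inside the mask")
  d <- dim(series$data)
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  idx <- vox[, 1] + d[1] * (vox[, 2] - 1L) + d[1] * d[2] * (vox[, 3] - 1L)
  colMeans(flat[idx, , drop = FALSE])
}

#' Seed-based functional connectivity map
#'
#' Pearson correlation between every in-mask voxel's time series and the
#' seed time course, plus its Fisher z transform (atanh of r clipped at
#' |r| = 1 - 1e-7 so z stays finite). Zero-variance voxels get r = 0 and
#' are flagged.
#'
#' @param series A `bold_series` (same band-filtered data in which the
#'   seed was defined).
#' @param seed_tc Seed time course (length t), e.g. from
#'   [seed_timecourse()].
#' @return List with `r_map`, `z_map` (3D arrays, zero outside mask) and
#'   `n_flagged` (zero-variance voxel count).
#' @export
fc_map <- function(series, seed_tc) {
  stopifnot(inherits(series, "bold_series"))
  if (length(seed_tc) != n_volumes(series))
    stop("seed time course length must match the series")
  if (stats::sd(seed_tc) == 0) stop("constant seed time course")
  Y <- mask_matrix(series)                       # t x v
  sdv <- apply(Y, 2, stats::sd)
  r <- rep(0, ncol(Y))
  ok <- sdv > 0
  r[ok] <- drop(stats::cor(seed_tc, Y[, ok, drop = FALSE]))
  rc <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  list(r_map = unmask(r, series$mask),
       z_map = unmask(atanh(rc) * (r != 0), series$mask),
       n_flagged = sum(!ok))
}

# Voxel-wise two-sample t (pooled variance) on a voxels x subjects matrix.
two_sample_t_map <- function(M, group) {
  g <- as.factor(group)
  lv <- levels(g)
  A <- M[, g == lv[1], drop = FALSE]; B <- M[, g == lv[2], drop = FALSE]
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  s1 <- rowSums((A - m1)^2); s2 <- rowSums((B - m2)^2)
  sp2 <- (s1 + s2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat[!is.finite(tstat)] <- 0
  list(t = tstat, df = n1 + n2 - 2)
}

# Voxel-wise paired t between two matched voxels x subjects matrices.
paired_t_map <- function(A, B) {
  Dm <- A - B
  n <- ncol(Dm)
  m <- rowMeans(Dm)
  s <- sqrt(rowSums((Dm - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  tstat[!is.finite(tstat)] <- 0
  list(t = tstat, df = n - 1)
}

#' Group or state contrast of Fisher-z connectivity maps
#'
#' Voxel-wise t maps on Fisher-z FC maps: for `contrast = "group"`, a
#' two-sample t between groups within the given state; for
#' `contrast = "state"`, a paired t (task minus rest) within the given
#' group. Thresholding reuses the cluster machinery: voxel p < `p_voxel`
#' and extent >= `k_min`.
#'
#' @param z_rest,z_task Lists of per-subject 3D Fisher-z maps (subject
#'   order matching `group`).
#' @param group Per-subject group labels.
#' @param contrast `"group"` or `"state"`.
#' @param which_state State for a group contrast (`"rest"` or `"task"`).
#' @param which_group Group level for a state contrast.
#' @param mask Logical 3D array.
#' @param p_voxel,k_min,connectivity Thresholding parameters (defaults
#'   0.05, 1, 18).
#' @return List with `t_map`, `p_map`, `df`, `clusters` (from
#'   [extract_clusters()]) and `threshold_mask` (logary 3D of retained
#'   suprathreshold voxels).
#' @export
group_fc_contrast <- function(z_rest, z_task, group,
                              contrast = c("group", "state"),
                              which_state = "task", which_group = NULL,
                              mask, p_voxel = 0.05, k_min = 1,
                              connectivity = 18) {
  contrast <- match.arg(contrast)
  g <- as.factor(group)
  R <- stack_maps(z_rest, mask); T <- stack_maps(z_task, mask)
  if (contrast == "group") {
    M <- if (which_state == "task") T else R
    if (min(table(g)) < 2) stop("each group needs at least 2 subjects")
    res <- two_sample_t_map(M, g)
  } else {
    if (is.null(which_group)) which_group <- levels(g)[1]
    sel <- g == which_group
    if (sum(sel) < 2) stop("need at least 2 subjects in the group")
    res <- paired_t_map(T[, sel, drop = FALSE], R[, sel, drop = FALSE])
  }
  pv <- 2 * stats::pt(-abs(res$t), df = res$df)
  t_map <- unmask(res$t, mask)
  p_map <- array(1, dim(mask)); p_map[mask] <- pv
  cl <- extract_clusters(abs(t_map), p_map, p_voxel = p_voxel,
                         k_min = k_min, connectivity = connectivity,
                         mask = mask)
  list(t_map = t_map, p_map = p_map, df = res$df, clusters = cl,
       threshold_mask = cl$labels > 0)
}
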