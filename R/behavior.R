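#' Score a DMST response log
#'
#' Joins responses to the schedule on (block, trial, pos) and computes:
#' hit rate = proportion of targets answered "match"; false-alarm rate =
#' proportion of distractors answered "match"; accuracy = hit rate minus
#' false-alarm rate; RT = mean response time over all answered test
#' stimuli (targets and distractors); and the performance index
#' accuracy / RT (1/ms), the reciprocal of the inverse efficiency score.
#' Omitted responses count as non-hits / non-false-alarms and are excluded
#' from RT averaging.
#'
#' @param responses Data frame with `block`, `trial`, `pos`, `response`,
#'   `rt_ms`.
#' @param schedule Data frame from [generate_dmst_schedule()].
#' @return One-row data frame: `hit_rate`, `fa_rate`, `accuracy`, `rt_ms`,
#'   `performance`.
#' @export
score_dmst <- function(responses, schedule) {
  key <- function(d) paste(d$block, d$trial, d$pos)
  m <- match(key(responses), key(schedule))
  if (anyNA(m)) {
    bad <- which(is.na(m))
    stop("response rows with no scheduled stimulus: ",
         paste(utils::head(key(responses)[bad], 5), collapse = "; "))
  }
  is_target <- schedule$is_target[m]
  said_match <- !is.na(responses$response) & responses$response == "match"
  hit_rate <- mean(said_match[is_target])
  fa_rate <- mean(said_match[!is_target])
  answered <- !is.na(responses$rt_ms)
  rt <- mean(responses$rt_ms[answered])
  acc <- hit_rate - fa_rate
  data.frame(hit_rate = hit_rate, fa_rate = fa_rate, accuracy = acc,
             rt_ms = rt, performance = performance_index(acc, rt))
}

#' Working-memory performance index
#'
#' Response accuracy divided by mean RT (units 1/ms) — the reciprocal of
#' the inverse efficiency score. For realistic accuracies around 0.9 and
#' RTs around 600 ms the index is of order 1.5e-3.
#'
#' @param accuracy Accuracy in [-1, 1] (hit rate minus false-alarm rate).
#' @param rt_ms Mean response time in ms (> 0).
#' @return accuracy / rt_ms.
#' @export
performance_index <- function(accuracy, rt_ms) {
  if (any(rt_ms <= 0)) stop("'rt_ms' must be positive")
  accuracy / rt_ms
}

#' Pearson correlation with a percentile bootstrap CI
#'
#' Pearson r with a two-tailed t-approximation p-value (df = n - 2) and a
#' seeded case-resampling percentile bootstrap confidence interval.
#' Degenerate resamples (zero variance) are dropped from the percentile
#' computation.
#'
#' @param x,y Equal-length numeric vectors, n >= 4.
#' @param B Number of bootstrap resamples (default 1000, minimum 100).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `r`, `p`, `ci_low`, `ci_high`, `B`, `n`.
#' @export
correlate_with_bootstrap <- function(x, y, B = 1000, seed = 1, conf = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (B < 100) stop("'B' must be at least 100")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    xs <- matrix(x[idx], n, B); ys <- matrix(y[idx], n, B)
    sx <- colSums(xs); sy <- colSums(ys)
    vx <- n * colSums(xs^2) - sx^2; vy <- n * colSums(ys^2) - sy^2
    num <- n * colSums(xs * ys) - sx * sy
    den <- sqrt(vx * vy)
    ifelse(den > 0, num / den, NA_real_)
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  data.frame(r = r, p = p, ci_low = qs[1], ci_high = qs[2], B = B, n = n)
}

#' Per-group brain-behavior correlations for a cluster
#'
#' For each group separately (never pooled), correlates the per-subject
#' state-related ReHo change in a cluster (mean z-ReHo over cluster
#' voxels, task minus rest) with working-memory performance, with a
#' bootstrap CI.
#'
#' @param state_change Per-subject cluster-mean z-ReHo change (task minus
#'   rest).
#' @param performance Per-subject performance index.
#' @param group Per-subject group labels.
#' @param B,seed,conf Passed to [correlate_with_bootstrap()].
#' @return Data frame with one row per group.
#' @export
correlate_by_group <- function(state_change, performance, group,
                               B = 1000, seed = 1, conf = 0.95) {
  out <- lapply(unique(group), function(g) {
    sel <- group == g
    rep <- correlate_with_bootstrap(state_change[sel], performance[sel],
                                    B = B, seed = derive_seed(seed, match(g, unique(group))),
                                    conf = conf)
    cbind(data.frame(group = g), rep)
  })
  do.call(rbind, out)
}
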