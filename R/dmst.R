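#' Generate a delayed match-to-sample (DMST) trial schedule
#'
#' The hybrid DMST design: `n_blocks` blocks of `trials_per_block` trials
#' (default 4 x 8 = 32 trials). Each trial presents 2 target objects, then
#' a pseudo-randomized stream of 12--13 test objects in which every target
#' and every distractor appears 2--4 times. Test objects carry a jitter
#' drawn from {800, 900, 1000, 1100, 1200} ms.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_block Trials per block (default 8).
#' @param seed Integer seed.
#' @param n_test_range Allowed total test-object counts per trial
#'   (default `c(12, 13)`).
#' @param rep_range Allowed per-object repetition counts
#'   (default `c(2, 4)`).
#' @return Data frame (one row per test stimulus): `block`, `trial`
#'   (global index), `pos` (position in trial), `object_id`, `is_target`,
#'   `jitter_ms`.
#' @export
generate_dmst_schedule <- function(n_blocks = 4, trials_per_block = 8,
                                   seed = 1, n_test_range = c(12, 13),
                                   rep_range = c(2, 4)) {
  if (n_blocks < 1 || trials_per_block < 1) stop("counts must be positive")
  rmin <- rep_range[1]; rmax <- rep_range[2]
  n_targets <- 2L
  # feasibility: 2 targets at >= rmin reps plus >= 1 distractor at >= rmin
  if ((n_targets + 1) * rmin > max(n_test_range))
    stop("requested repetitions are incompatible with ",
         paste(n_test_range, collapse = "-"), " test objects per trial")
  jitters <- c(800, 900, 1000, 1100, 1200)
  pick <- function(x) x[sample.int(length(x), 1)]   # safe for length-1 x
  with_seed(seed, {
    rows <- list()
    trial_no <- 0L
    for (b in seq_len(n_blocks)) {
      for (tr in seq_len(trials_per_block)) {
        trial_no <- trial_no + 1L
        total <- pick(seq(n_test_range[1], n_test_range[2]))
        # repetition counts: targets first, then distractors filling the rest
        reps_t <- sample(rmin:rmax, n_targets, replace = TRUE)
        remaining <- total - sum(reps_t)
        while (remaining < rmin) {          # re-draw lighter target reps
          reps_t <- sample(rmin:rmax, n_targets, replace = TRUE)
          remaining <- total - sum(reps_t)
        }
        n_dis <- pick(seq(ceiling(remaining / rmax),
                          floor(remaining / rmin)))
        reps_d <- rep(rmin, n_dis)
        extra <- remaining - sum(reps_d)
        while (extra > 0) {
          j <- pick(which(reps_d < rmax))
          reps_d[j] <- reps_d[j] + 1
          extra <- extra - 1
        }
        ids <- c(sprintf("T%d", seq_len(n_targets)),
                 sprintf("D%d", seq_len(n_dis)))
        stim <- rep(ids, c(reps_t, reps_d))
        stim <- sample(stim)                 # pseudo-randomized order
        rows[[trial_no]] <- data.frame(
          block = b, trial = trial_no, pos = seq_along(stim),
          object_id = stim, is_target = grepl("^T", stim),
          jitter_ms = sample(jitters, length(stim), replace = TRUE)
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate responses to a DMST schedule
#'
#' One response row per scheduled test stimulus: targets elicit a "match"
#' response with probability `hit_rate`, distractors with probability
#' `fa_rate`; otherwise "nonmatch". A fraction `miss_rate` of stimuli gets
#' no response (`NA`). Response times are normal, truncated at 150 ms.
#'
#' @param schedule A schedule from [generate_dmst_schedule()].
#' @param hit_rate,fa_rate Response probabilities in [0, 1].
#' @param rt_mean_ms,rt_sd_ms Response-time distribution.
#' @param miss_rate Probability of an omitted response (default 0).
#' @param seed Integer seed.
#' @return Data frame: `block`, `trial`, `pos`, `response`
#'   ("match"/"nonmatch"/NA), `rt_ms` (NA for misses).
#' @export
generate_responses <- function(schedule, hit_rate, fa_rate,
                               rt_mean_ms = 650, rt_sd_ms = 80,
                               miss_rate = 0, seed = 1) {
  stopifnot(all(c("block", "trial", "pos", "is_target") %in% names(schedule)))
  if (any(c(hit_rate, fa_rate) < 0 | c(hit_rate, fa_rate) > 1))
    stop("rates must lie in [0, 1]")
  n <- nrow(schedule)
  with_seed(seed, {
    p <- ifelse(schedule$is_target, hit_rate, fa_rate)
    resp <- ifelse(stats::runif(n) < p, "match", "nonmatch")
    miss <- stats::runif(n) < miss_rate
    resp[miss] <- NA
    rt <- pmax(150, stats::rnorm(n, rt_mean_ms, rt_sd_ms))
    rt[miss] <- NA
    data.frame(block = schedule$block, trial = schedule$trial,
               pos = schedule$pos, response = resp, rt_ms = rt)
  })
}
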