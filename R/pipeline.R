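#' Pipeline run configuration
#'
#' One object driving the full analysis: phantom simulation (or a cohort
#' directory written by [write_cohort()]), temporal preprocessing, per-band
#' ReHo, group-by-state interaction statistics with Monte-Carlo cluster
#' correction, seed-based connectivity for the surviving clusters, and
#' behavioral coupling.
#'
#' @param input `"simulate"` (default) or a directory produced by
#'   [write_cohort()].
#' @param phantom List of arguments for [phantom_config()] when
#'   simulating.
#' @param bands Character vector of band names (default slow-5 ... slow-2;
#'   slow-6 may be added explicitly).
#' @param qc_threshold_mm Motion exclusion threshold (default 3).
#' @param fwhm_mm Smoothing FWHM applied to standardized ReHo maps and
#'   assumed by the Monte-Carlo (default 4).
#' @param p_voxel Voxel-level threshold (default 0.01).
#' @param alpha Family-wise cluster level (default 0.05).
#' @param connectivity Cluster connectivity (default 18).
#' @param mc_iter Monte-Carlo iterations (default 1000).
#' @param fc_p_voxel Voxel p for FC contrasts (default 0.05).
#' @param bootstrap_B Bootstrap resamples for behavior correlations
#'   (default 1000).
#' @param seed Global seed fanned out to every stochastic stage.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input = "simulate", phantom = list(),
                       bands = c("slow-5", "slow-4", "slow-3", "slow-2"),
                       qc_threshold_mm = 3, fwhm_mm = 4, p_voxel = 0.01,
                       alpha = 0.05, connectivity = 18, mc_iter = 1000,
                       fc_p_voxel = 0.05, bootstrap_B = 1000, seed = 1,
                       out_dir = tempfile("rehoband_run_")) {
  cfg <- list(input = input, phantom = phantom, bands = bands,
              qc_threshold_mm = qc_threshold_mm, fwhm_mm = fwhm_mm,
              p_voxel = p_voxel, alpha = alpha, connectivity = connectivity,
              mc_iter = mc_iter, fc_p_voxel = fc_p_voxel,
              bootstrap_B = bootstrap_B, seed = as.integer(seed),
              out_dir = out_dir)
  if (!p_voxel > 0 || p_voxel >= 1) stop("'p_voxel' must lie in (0, 1)")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a synthetic cohort in standard formats
#'
#' Volumes go to NIfTI (`.nii.gz`), the subject table and per-scan
#' nuisance tables to TSV, DMST schedules and response logs to TSV, and
#' the generating configuration to JSON for provenance.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Target directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a cohort-shaped list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_map(cohort$mask * 1, file.path(dir, "mask.nii.gz"),
            cohort$config$voxel_size_mm)
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[i]
    for (st in c("rest", "task")) {
      write_bold(cohort$series[[i]][[st]],
                 file.path(dir, sprintf("%s_%s_bold.nii.gz", id, st)))
      utils::write.table(cohort$nuisance[[i]][[st]],
                         file.path(dir, sprintf("%s_%s_nuisance.tsv", id, st)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  cfg <- cohort$config
  cfg$mask <- NULL
  cfg$planted_clusters <- lapply(cfg$planted_clusters, function(pe)
    list(cluster_voxels = unclass(pe$cluster_voxels), band = unclass(pe$band),
         coupling_by_cell = pe$coupling_by_cell))
  jsonlite::write_json(cfg, file.path(dir, "phantom_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"))
  mask <- read_map(file.path(dir, "mask.nii.gz")) > 0
  series <- list(); nuis <- list()
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    series[[i]] <- list(); nuis[[i]] <- list()
    for (st in c("rest", "task")) {
      series[[i]][[st]] <- read_bold(
        file.path(dir, sprintf("%s_%s_bold.nii.gz", id, st)), mask = mask)
      nuis[[i]][[st]] <- utils::read.delim(
        file.path(dir, sprintf("%s_%s_nuisance.tsv", id, st)))
    }
  }
  list(subjects = subjects, series = series, nuisance = nuis, mask = mask,
       config = NULL)
}

# Preprocess + per-band z-ReHo maps for one scan, operating on the
# in-mask matrix throughout (single grid rebuild per band).
scan_to_zmaps <- function(series, nuisance, bands, connectivity = 26,
                          fwhm_mm = 4) {
  mask <- series$mask
  d <- dim(series$data)
  Y <- mask_matrix(series)                              # t x v
  X <- cbind(1, as.matrix(nuisance))
  Y <- Y - X %*% solve(crossprod(X), crossprod(X, Y))   # normal equations:
  Y <- detrend_linear(Y)                                # small fixed design
  inmask <- as.vector(mask)
  lapply(bands, function(b) {
    b <- as_band(b)
    Yf <- ideal_bandpass_matrix(Y, series$tr_s, b$f_low, b$f_high)
    flat <- matrix(0, prod(d[1:3]), d[4])
    flat[inmask, ] <- t(Yf)
    res <- cpp_reho_map(flat, inmask, as.integer(d), as.integer(connectivity))
    m <- structure(list(values = res$W, k = res$k, mask = mask,
                        voxel_size_mm = series$voxel_size_mm,
                        standardized = FALSE, band = b),
                   class = "reho_map")
    smooth_map(standardize_map(m), fwhm_mm)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> QC -> preprocessing -> per-band ReHo ->
#' interaction statistics with Monte-Carlo cluster correction -> post-hoc
#' tests -> seed-based FC for surviving clusters -> behavioral coupling,
#' writing every artifact plus a JSON manifest (file, stage, md5) and a
#' log of all decided parameters. One global seed fans out to per-stage
#' seeds, so repeated runs are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the manifest data frame, the cluster and
#'   post-hoc tables per band, the behavior correlation table, and paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bands <- lapply(config$bands, as_band)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(path, stage)
    manifest[[length(manifest) + 1]] <<- data.frame(file = path, stage = stage)

  ## stage: cohort ----------------------------------------------------------
  if (identical(config$input, "simulate")) {
    pargs <- config$phantom
    pargs$rng_seed <- derive_seed(config$seed, 101)
    pcfg <- do.call(phantom_config, pargs)
    for (b in bands)                      # validate before any compute
      if (b$f_high > 1 / (2 * pcfg$tr_s) + 1e-12)
        stop("band '", b$name, "' exceeds the Nyquist frequency")
    cohort <- generate_cohort(pcfg)
    cdir <- file.path(out, "cohort")
    write_cohort(cohort, cdir)
    note(cdir, "simulate")
  } else {
    cohort <- read_cohort(config$input)
    for (b in bands)
      if (b$f_high > 1 / (2 * cohort$series[[1]]$rest$tr_s) + 1e-12)
        stop("band '", b$name, "' exceeds the Nyquist frequency")
  }
  subjects <- cohort$subjects
  mask <- cohort$mask
  n <- nrow(subjects)
  vox_mm <- cohort$series[[1]]$rest$voxel_size_mm[1]

  ## stage: QC + preprocessing + per-band z-ReHo ----------------------------
  qc_rows <- list(); zmaps <- list()
  for (i in seq_len(n)) {
    for (st in c("rest", "task")) {
      qc <- motion_qc(cohort$nuisance[[i]][[st]][, 1:6],
                      config$qc_threshold_mm)
      qc_rows[[length(qc_rows) + 1]] <- data.frame(
        subject_id = subjects$subject_id[i], state = st,
        pass = qc$pass, max_excursion_mm = qc$max_excursion_mm,
        mean_fd_mm = qc$mean_fd_mm)
    }
    zmaps[[i]] <- list(
      rest = scan_to_zmaps(cohort$series[[i]]$rest,
                           cohort$nuisance[[i]]$rest, bands,
                           fwhm_mm = config$fwhm_mm),
      task = scan_to_zmaps(cohort$series[[i]]$task,
                           cohort$nuisance[[i]]$task, bands,
                           fwhm_mm = config$fwhm_mm))
  }
  qc_tab <- do.call(rbind, qc_rows)
  p <- file.path(out, "qc_report.tsv")
  utils::write.table(qc_tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
  note(p, "qc")
  keep <- tapply(qc_tab$pass, qc_tab$subject_id, all)[subjects$subject_id]
  if (any(!keep)) {
    subjects <- subjects[keep, ]
    zmaps <- zmaps[keep]
    cohort$series <- cohort$series[keep]
    n <- nrow(subjects)
  }

  ## stage: group statistics -------------------------------------------------
  mc <- monte_carlo_cluster_threshold(
    mask, fwhm_mm = config$fwhm_mm, p_voxel = config$p_voxel,
    alpha = config$alpha, n_iter = config$mc_iter,
    connectivity = config$connectivity, voxel_size_mm = vox_mm,
    seed = derive_seed(config$seed, 102))
  covars <- subjects[, c("age", "sex", "education", "mean_fd")]
  cluster_tabs <- list(); posthoc_tabs <- list(); cluster_vox <- list()
  for (bi in seq_along(bands)) {
    bname <- bands[[bi]]$name
    task_maps <- lapply(zmaps, function(z) z$task[[bi]])
    rest_maps <- lapply(zmaps, function(z) z$rest[[bi]])
    im <- interaction_map(task_maps, rest_maps, subjects$group,
                          covariates = covars, mask = mask)
    write_map(im$F_map, file.path(out, sprintf("F_%s.nii.gz", bname)), vox_mm)
    write_map(im$p_map, file.path(out, sprintf("p_%s.nii.gz", bname)), vox_mm)
    note(file.path(out, sprintf("F_%s.nii.gz", bname)), "stats")
    note(file.path(out, sprintf("p_%s.nii.gz", bname)), "stats")
    cl <- extract_clusters(im$F_map, im$p_map, p_voxel = config$p_voxel,
                           k_min = mc$k_star,
                           connectivity = config$connectivity, mask = mask)
    tab <- cl$table
    if (nrow(tab) > 0) tab$band <- bname
    cluster_tabs[[bname]] <- tab
    cluster_vox[[bname]] <- cl$voxels
    ph <- list()
    for (j in seq_len(nrow(tab))) {
      cm_rest <- cluster_means(rest_maps, cl$voxels[[j]])
      cm_task <- cluster_means(task_maps, cl$voxels[[j]])
      pt <- posthoc_t(cm_rest, cm_task, subjects$group)
      pt$band <- bname; pt$cluster <- j
      ph[[j]] <- pt
    }
    posthoc_tabs[[bname]] <- if (length(ph)) do.call(rbind, ph) else NULL
  }
  all_clusters <- do.call(rbind, cluster_tabs)
  p <- file.path(out, "clusters.tsv")
  utils::write.table(all_clusters, p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  note(p, "stats")
  ph_all <- do.call(rbind, posthoc_tabs)
  if (!is.null(ph_all)) {
    p <- file.path(out, "posthoc.tsv")
    utils::write.table(ph_all, p, sep = "\t", row.names = FALSE, quote = FALSE)
    note(p, "stats")
  }

  ## stage: seed-based connectivity -----------------------------------------
  fc_summaries <- list()
  for (bname in names(cluster_vox)) {
    bi <- which(vapply(bands, `[[`, "", "name") == bname)
    for (j in seq_along(cluster_vox[[bname]])) {
      seedv <- cluster_vox[[bname]][[j]]
      zr <- list(); zt <- list()
      for (i in seq_len(n)) {
        for (st in c("rest", "task")) {
          filt <- bandpass(regress_nuisance(cohort$series[[i]][[st]],
                                            cohort$nuisance[[i]][[st]]),
                           bands[[bi]])
          fm <- fc_map(filt, seed_timecourse(filt, seedv))
          if (st == "rest") zr[[i]] <- fm$z_map else zt[[i]] <- fm$z_map
        }
      }
      for (ct in c("rest", "task")) {
        gc <- group_fc_contrast(zr, zt, subjects$group, contrast = "group",
                                which_state = ct, mask = mask,
                                p_voxel = config$fc_p_voxel,
                                connectivity = config$connectivity)
        fp <- file.path(out, sprintf("fc_t_%s_cl%d_group_%s.nii.gz",
                                     bname, j, ct))
        write_map(gc$t_map, fp, vox_mm)
        note(fp, "fc")
        fc_summaries[[length(fc_summaries) + 1]] <- data.frame(
          band = bname, cluster = j, contrast = paste0("group_", ct),
          n_suprathreshold = sum(gc$threshold_mask),
          max_abs_t = max(abs(gc$t_map)))
      }
    }
  }
  if (length(fc_summaries)) {
    p <- file.path(out, "fc_summary.tsv")
    utils::write.table(do.call(rbind, fc_summaries), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(p, "fc")
  }

  ## stage: behavior ---------------------------------------------------------
  beh_rows <- list()
  for (bname in names(cluster_vox)) {
    bi <- which(vapply(bands, `[[`, "", "name") == bname)
    for (j in seq_along(cluster_vox[[bname]])) {
      task_maps <- lapply(zmaps, function(z) z$task[[bi]])
      rest_maps <- lapply(zmaps, function(z) z$rest[[bi]])
      change <- cluster_means(task_maps, cluster_vox[[bname]][[j]]) -
        cluster_means(rest_maps, cluster_vox[[bname]][[j]])
      rep <- correlate_by_group(change, subjects$performance, subjects$group,
                                B = config$bootstrap_B,
                                seed = derive_seed(config$seed, 103, bi, j))
      rep$band <- bname; rep$cluster <- j
      beh_rows[[length(beh_rows) + 1]] <- rep
    }
  }
  beh_tab <- if (length(beh_rows)) do.call(rbind, beh_rows) else NULL
  if (!is.null(beh_tab)) {
    p <- file.path(out, "behavior_correlations.tsv")
    utils::write.table(beh_tab, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    note(p, "behavior")
  }

  ## manifest + log ----------------------------------------------------------
  man <- do.call(rbind, manifest)
  files <- unlist(lapply(man$file, function(f)
    if (dir.exists(f)) list.files(f, full.names = TRUE, recursive = TRUE)
    else f))
  stages <- rep(man$stage, vapply(man$file, function(f)
    if (dir.exists(f)) length(list.files(f, recursive = TRUE)) else 1L,
    integer(1)))
  man <- data.frame(file = files, stage = stages,
                    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(man, file.path(out, "manifest.json"), digits = NA)
  log <- c(config[setdiff(names(config), "phantom")],
           list(k_star = mc$k_star, n_subjects = n))
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(manifest = man, clusters = all_clusters,
                 posthoc = ph_all, behavior = beh_tab, k_star = mc$k_star,
                 qc = qc_tab, out_dir = out))
}
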