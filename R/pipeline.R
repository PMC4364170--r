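#' Preprocess one subject for first-level analysis
#'
#' Discards initial volumes, smooths spatially, extracts the seed / WM /
#' CSF mean time courses from the smoothed series, then band-passes the
#' cerebellar voxel matrix and all extracted time courses with the same
#' filter (the filter is linear, so filtering the mean equals the mean of
#' filtered voxels).
#'
#' @param bold a [bold_series()].
#' @param motion per-volume motion matrix (rows match the raw series).
#' @param atlas an [make_atlas()] bundle.
#' @param seed_set a [build_seed_set()] (eroded cortical seeds).
#' @param fs a [filter_spec()].
#' @param fwhm_mm spatial smoothing kernel (default 6 mm).
#' @param discard_volumes initial volumes to drop (default 4).
#' @return list: `cereb` (T x V_cb filtered matrix over the cerebellum
#'   mask), `seed_tcs` (T x networks matrix, filtered), `wm_tc`, `csf_tc`,
#'   `motion` (trimmed), `mask`, `tr_seconds`.
#' @export
preprocess_subject <- function(bold, motion, atlas, seed_set, fs,
                               fwhm_mm = 6, discard_volumes = 4) {
  dm <- drop_initial_volumes(bold, discard_volumes, motion)
  b <- smooth_spatial(dm$bold, fwhm_mm, atlas$voxel_mm)
  d <- dim(b$data)
  flat <- matrix(b$data, prod(d[1:3]), d[4])   # one flatten for all masks
  mean_tc <- function(m) colMeans(flat[as.vector(m), , drop = FALSE])
  seed_tcs <- vapply(seed_set$seeds, mean_tc, numeric(d[4]))
  wm_tc <- mean_tc(atlas$wm_mask)
  csf_tc <- mean_tc(atlas$csf_mask)
  cereb <- t(flat[as.vector(atlas$cerebellum_mask), , drop = FALSE])
  filt <- bandpass_matrix(cbind(cereb, seed_tcs, wm_tc, csf_tc), fs)
  nv <- ncol(cereb); ns <- ncol(seed_tcs)
  list(cereb = filt[, seq_len(nv), drop = FALSE],
       seed_tcs = filt[, nv + seq_len(ns), drop = FALSE],
       wm_tc = filt[, nv + ns + 1], csf_tc = filt[, nv + ns + 2],
       motion = dm$motion, mask = atlas$cerebellum_mask,
       tr_seconds = b$tr_seconds)
}

#' First-level z maps for every subject and network of a cohort
#'
#' Runs [preprocess_subject()] and the voxelwise seed GLM for each
#' subject and each retained network seed. Results are stacked as one
#' subjects x cerebellar-voxels z matrix per network (the format the
#' group stage consumes directly).
#'
#' @param cohort an in-memory [simulate_cohort()] result.
#' @param seed_set seeds (defaults to [build_seed_set()] on the cohort's
#'   own atlas with no exclusions).
#' @param networks character vector of seed ids to analyze (default all
#'   retained).
#' @param fs filter specification (default 0.009-0.08 Hz at the cohort
#'   TR).
#' @param fwhm_mm smoothing kernel.
#' @param keep_series also return each subject's preprocessed cerebellar
#'   matrix and seed time courses (needed later for cluster-symptom
#'   correlations).
#' @return list of class `first_level_set`: `z` (named list of N x V_cb
#'   matrices), `dof`, `mask`, `records`, `atlas`, `seed_set`, optional
#'   `series`.
#' @export
run_first_level <- function(cohort, seed_set = NULL, networks = NULL,
                            fs = NULL, fwhm_mm = 6, keep_series = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$subjects))
    stop("cohort must be in memory (simulate_cohort(spec, out_dir = NULL))")
  spec <- cohort$spec
  atlas <- cohort$atlas
  if (is.null(seed_set))
    seed_set <- build_seed_set(atlas$cortical_labels, atlas$cerebellar_labels,
                               threshold = 0, merge_ids = NULL)
  if (is.null(networks)) networks <- names(seed_set$seeds)
  if (is.null(fs)) fs <- filter_spec(tr_seconds = spec$tr_seconds)
  nsub <- nrow(cohort$records)
  vcb <- sum(atlas$cerebellum_mask)
  z <- lapply(networks, function(k) matrix(NA_real_, nsub, vcb))
  names(z) <- networks
  series <- if (keep_series) vector("list", nsub) else NULL
  dof <- NA_integer_
  sub_seeds <- seed_set
  sub_seeds$seeds <- seed_set$seeds[networks]
  for (i in seq_len(nsub)) {
    s <- cohort$subjects[[i]]
    pp <- preprocess_subject(s$bold, s$motion, atlas, sub_seeds, fs,
                             fwhm_mm, spec$discard_volumes)
    for (j in seq_along(networks)) {
      x <- build_first_level_design(pp$seed_tcs[, j], pp$wm_tc, pp$csf_tc,
                                    pp$motion)
      fit <- ols_column_t(x, pp$cereb, "seed")
      z[[j]][i, ] <- t_to_z(fit$t, fit$dof)
      dof <- fit$dof
    }
    if (keep_series) series[[i]] <- pp[c("cereb", "seed_tcs", "motion")]
  }
  structure(list(z = z, dof = dof, mask = atlas$cerebellum_mask,
                 records = cohort$records, atlas = atlas,
                 seed_set = sub_seeds, networks = networks,
                 series = series), class = "first_level_set")
}

#' @export
print.first_level_set <- function(x, ...) {
  cat("<first_level_set> ", nrow(x$records), " subjects x ",
      length(x$networks), " networks over ", sum(x$mask),
      " cerebellar voxels\n", sep = "")
  invisible(x)
}

#' Overlap fidelity of within-group maps against the planted atlas
#'
#' For each network and group, builds the within-group one-sample map,
#' binarizes it at the display threshold (one-sided p < `alpha`,
#' uncorrected), and scores it against the planted canonical cerebellar
#' territory with [confusion_counts()] / [overlap_metrics()].
#'
#' @param fl a [run_first_level()] result.
#' @param alpha display threshold (default 0.05, uncorrected).
#' @return data.frame: network, group, p, n, tp, fp, tn, accuracy,
#'   sensitivity, specificity, dice.
#' @export
map_fidelity <- function(fl, alpha = 0.05) {
  stopifnot(inherits(fl, "first_level_set"))
  canon <- split_labels(fl$atlas$cerebellar_labels)
  out <- list()
  for (k in fl$networks) {
    for (g in c("HC", "SZ")) {
      wg <- within_group_map(fl$z[[k]], fl$records, g, fl$mask)
      gm <- binarize_map(wg, alpha)
      cc <- confusion_counts(gm, canon[[k]], fl$mask)
      met <- overlap_metrics(cc)
      out[[length(out) + 1L]] <- data.frame(
        network = k, group = g, p = cc$p, n = cc$n, tp = cc$tp,
        fp = cc$fp, tn = cc$tn, accuracy = met$accuracy,
        sensitivity = met$sensitivity, specificity = met$specificity,
        dice = dice_coefficient(gm, canon[[k]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Group contrast with permutation cluster correction for one network
#'
#' @param fl a [run_first_level()] result.
#' @param network seed id (name in `fl$z`).
#' @param contrast `"sz_gt_hc"` or `"hc_gt_sz"`.
#' @param include_cpz medication covariate in the group design.
#' @param voxel_p,cluster_p thresholds (defaults 0.01 / 0.05).
#' @param n_perm permutations (default 1000).
#' @param rng_seed permutation seed.
#' @param connectivity cluster connectivity.
#' @return the [permutation_cluster_pvalues()] cluster table.
#' @export
contrast_clusters <- function(fl, network, contrast = "hc_gt_sz",
                              include_cpz = TRUE, voxel_p = 0.01,
                              cluster_p = 0.05, n_perm = 1000, rng_seed,
                              connectivity = 26L) {
  stopifnot(inherits(fl, "first_level_set"))
  gd <- build_group_design(fl$records, include_cpz = include_cpz)
  permutation_cluster_pvalues(fl$z[[network]], gd, contrast, fl$mask,
                              voxel_p = voxel_p, cluster_p = cluster_p,
                              n_perm = n_perm, rng_seed = rng_seed,
                              connectivity = connectivity)
}

#' Cluster-symptom correlation stage for a cohort
#'
#' For each supplied contrast's significant clusters, computes every
#' subject's cluster-seed Pearson correlation on the preprocessed series
#' and correlates the patients' values with their symptom scales under
#' Bonferroni control.
#'
#' @param fl a [run_first_level()] run with `keep_series = TRUE`.
#' @param cluster_sets named list (by contrast label) of lists with
#'   elements `network` (seed id) and `mask` (combined significant
#'   cluster mask, logical 3D).
#' @param alpha family-wise level.
#' @param rounded rounded 0.001 per-test cutoff.
#' @return list: `fc` (subjects x contrasts matrix), `correlations`
#'   ([correlate_scales()] table over SZ subjects).
#' @export
symptom_stage <- function(fl, cluster_sets, alpha = 0.05,
                          rounded = FALSE) {
  stopifnot(inherits(fl, "first_level_set"))
  if (is.null(fl$series))
    stop("run_first_level() must be called with keep_series = TRUE")
  nsub <- nrow(fl$records)
  fc <- matrix(NA_real_, nsub, length(cluster_sets),
               dimnames = list(fl$records$id, names(cluster_sets)))
  mask_idx <- which(as.vector(fl$mask))
  for (j in seq_along(cluster_sets)) {
    cs <- cluster_sets[[j]]
    kcol <- match(cs$network, fl$networks)
    cl_vox <- match(which(as.vector(cs$mask)), mask_idx)
    if (anyNA(cl_vox)) stop("cluster mask extends outside the cerebellum")
    for (i in seq_len(nsub)) {
      ser <- fl$series[[i]]
      tc <- rowMeans(ser$cereb[, cl_vox, drop = FALSE])
      fc[i, j] <- stats::cor(tc, ser$seed_tcs[, kcol])
    }
  }
  sz <- fl$records$group == "SZ"
  scales <- intersect(c("SAPS", "SANS", "YMRS", "MADRS", "PSYRATS_AH"),
                      names(fl$records))
  corr <- correlate_scales(fc[sz, , drop = FALSE],
                           fl$records[sz, scales, drop = FALSE],
                           alpha = alpha, rounded = rounded)
  list(fc = fc, correlations = corr)
}
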