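# Per-subject derived seed: deterministic function of the master seed and
# the subject index, kept below 2^31.
subject_seed <- function(master, i) as.integer((master * 1009 + i * 7919) %% 2147483647)

# Unit-variance latent time course band-limited to the analysis band
# (0.01-0.08 Hz), so planted connectivity survives the pipeline band-pass.
latent_timecourse <- function(nt, tr_seconds, n = 1L,
                              band = c(0.01, 0.08)) {
  fs <- filter_spec(band[1], min(band[2], 0.99 / (2 * tr_seconds)), tr_seconds)
  x <- bandpass_matrix(matrix(stats::rnorm(nt * n), nt, n), fs)
  scale(x)[, , drop = FALSE]   # column mean 0, sd 1
}

# AR(1) noise, exactly stationary (first sample drawn from the marginal),
# innovation sd `sd`: T x V matrix.
ar1_noise <- function(nt, v, phi, sd) {
  x <- matrix(stats::rnorm(nt * v, sd = sd), nt, v)
  if (phi != 0) {
    x[1, ] <- stats::rnorm(v, sd = sd / sqrt(1 - phi^2))
    for (t in 2:nt) x[t, ] <- phi * x[t - 1, ] + x[t, ]
  }
  x
}

#' Sample the phenotype records of a synthetic cohort
#'
#' Draws group, age, sex, chlorpromazine-equivalent dose (SZ only,
#' lognormal), scanner-upgrade flag, per-network true couplings (group
#' coupling plus between-subject jitter, truncated to \[0, 1\]), and
#' SZ symptom-scale scores (scale mean + slope x coupling deviation +
#' noise, truncated at 0) with the configured missingness rate.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per subject; coupling columns are named
#'   `coupling_<id>`, score columns after the scales.
#' @export
make_subject_records <- function(spec) {
  set.seed(subject_seed(spec$rng_seed, 0L))
  n <- spec$n_per_group
  nets <- spec$networks
  ids <- sprintf("sub-%03d", seq_len(2L * n))
  group <- rep(c("HC", "SZ"), each = n)
  rec <- data.frame(
    id = ids, group = group,
    age = round(pmin(65, pmax(18, stats::rnorm(2 * n, 38, 10)))),
    sex = ifelse(stats::runif(2 * n) < 0.4, "F", "M"),
    cpz = ifelse(group == "SZ",
                 round(stats::rlnorm(2 * n, meanlog = 5.98, sdlog = 0.87)), 0),
    scanner_flag = ifelse(stats::runif(2 * n) < 0.39, "post", "pre"),
    stringsAsFactors = FALSE)
  group_coupling <- function(g, k)
    if (g == "SZ") nets$coupling_sz[k] else nets$coupling_hc[k]
  for (k in seq_len(nrow(nets))) {
    base <- vapply(group, group_coupling, numeric(1), k = k)
    rec[[paste0("coupling_", nets$id[k])]] <-
      pmin(1, pmax(0, base + stats::rnorm(2 * n, 0, spec$coupling_jitter_sd)))
  }
  sm <- spec$symptom_model
  for (s in seq_len(nrow(sm))) {
    kcol <- paste0("coupling_", sm$network_id[s])
    kidx <- match(sm$network_id[s], nets$id)
    base <- vapply(group, group_coupling, numeric(1), k = kidx)
    dev <- rec[[kcol]] - base
    val <- pmax(0, sm$mean[s] + sm$slope[s] * dev +
                  stats::rnorm(2 * n, 0, sm$sd[s]))
    val[group == "HC"] <- NA          # scales administered to patients only
    miss <- group == "SZ" & stats::runif(2 * n) < spec$missing_rate
    val[miss] <- NA
    rec[[sm$scale[s]]] <- round(val, 1)
  }
  rec
}

#' Simulate one subject's BOLD series and motion trace
#'
#' Generative model: each network k has a band-limited unit-variance
#' latent time course L_k; every voxel in the network's cortical and
#' cerebellar territories receives true_coupling_k * L_k. WM and CSF
#' voxels receive their own slow latent nuisance series. All voxels add
#' stationary AR(1) noise, a linear + slow-cosine scanner drift with
#' voxel-specific random amplitude, and a global high-frequency sinusoid
#' (pseudo-cardiac). Head motion is a seeded
#' random walk in the 6 rigid-body parameters; the data themselves are
#' generated already aligned (motion is a nuisance trace, not an applied
#' transform).
#'
#' @param atlas an [make_atlas()] bundle.
#' @param record one row of [make_subject_records()].
#' @param spec the [cohort_spec()].
#' @param seed integer seed for this subject (defaults to a deterministic
#'   function of `spec$rng_seed` and the subject id).
#' @return list with `bold` ([bold_series()]) and `motion` (T x 6 matrix:
#'   3 rotations in radians, 3 translations in mm).
#' @export
simulate_subject <- function(atlas, record, spec, seed = NULL) {
  nets <- spec$networks
  cols <- paste0("coupling_", nets$id)
  if (!all(cols %in% names(record)))
    stop("record lacks true couplings for all atlas networks")
  if (is.null(seed))
    seed <- subject_seed(spec$rng_seed,
                         as.integer(sub("\\D*", "", record$id)))
  set.seed(seed)
  d <- spec$grid_shape; v <- prod(d); nt <- spec$n_volumes
  lat <- latent_timecourse(nt, spec$tr_seconds, n = nrow(nets))
  y <- ar1_noise(nt, v, spec$ar1_phi, spec$noise_sd)    # T x V
  cort <- as.vector(atlas$cortical_labels$data)
  cere <- as.vector(atlas$cerebellar_labels$data)
  for (k in seq_len(nrow(nets))) {
    c_k <- record[[cols[k]]]
    vox <- which(cort == nets$id[k] | cere == nets$id[k])
    if (c_k != 0 && length(vox))
      y[, vox] <- y[, vox] + c_k * lat[, k]
  }
  nuis <- latent_timecourse(nt, spec$tr_seconds, n = 2L, band = c(0.005, 0.05))
  wm_vox <- which(as.vector(atlas$wm_mask))
  csf_vox <- which(as.vector(atlas$csf_mask))
  y[, wm_vox] <- y[, wm_vox] + nuis[, 1]
  y[, csf_vox] <- y[, csf_vox] + nuis[, 2]
  tt <- seq_len(nt)
  ramp <- (tt - mean(tt)) / nt
  coswave <- cos(2 * pi * 0.005 * spec$tr_seconds * tt +
                   stats::runif(1, 0, 2 * pi))
  # scanner drift varies spatially: independent amplitude per voxel
  if (spec$drift_amp > 0)
    y <- y + spec$drift_amp * (ramp %o% stats::rnorm(v) +
                                 coswave %o% stats::rnorm(v, 0, 0.5))
  cardio <- spec$cardio_amp *
    sin(2 * pi * spec$cardio_freq_hz * spec$tr_seconds * tt +
          stats::runif(1, 0, 2 * pi))
  y <- y + cardio                      # global, recycled down columns
  y <- y + 100                         # baseline offset
  motion <- cbind(
    apply(matrix(stats::rnorm(3 * nt, 0, spec$motion_sd_deg * pi / 180),
                 nt, 3), 2, cumsum),
    apply(matrix(stats::rnorm(3 * nt, 0, spec$motion_sd_mm), nt, 3),
          2, cumsum))
  colnames(motion) <- c("rot_x", "rot_y", "rot_z",
                        "trans_x", "trans_y", "trans_z")
  list(bold = new_bold_series(array(t(y), dim = c(d, nt)), spec$tr_seconds),
       motion = motion)
}

#' Simulate a full cohort
#'
#' Generates the atlas bundle, phenotype records, and per-subject BOLD and
#' motion data. With `out_dir` set, writes per-subject 4D NIfTI files,
#' 6-column whitespace motion files, a phenotype TSV (with the configured
#' missingness), atlas NIfTIs, and a ground-truth JSON of per-subject
#' couplings; otherwise keeps everything in memory. Identical specs
#' (including the seed) regenerate identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory, or `NULL` for an in-memory cohort.
#' @return list of class `cohort`: `spec`, `atlas`, `records`, and either
#'   `subjects` (list of `simulate_subject()` outputs, in memory) or
#'   `manifest` (data.frame of file paths).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  atlas <- make_atlas(spec)
  rec <- make_subject_records(spec)
  out <- list(spec = spec, atlas = atlas, records = rec)
  subjects <- vector("list", nrow(rec))
  names(subjects) <- rec$id
  for (i in seq_len(nrow(rec)))
    subjects[[i]] <- simulate_subject(atlas, rec[i, ], spec,
                                      seed = subject_seed(spec$rng_seed, i))
  if (is.null(out_dir)) {
    out$subjects <- subjects
    class(out) <- "cohort"
    return(out)
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  bold_paths <- file.path(out_dir, paste0(rec$id, "_bold.nii.gz"))
  motion_paths <- file.path(out_dir, paste0(rec$id, "_motion.par"))
  for (i in seq_len(nrow(rec))) {
    write_nifti_volume(subjects[[i]]$bold, bold_paths[i],
                       affine = atlas$affine)
    utils::write.table(format(subjects[[i]]$motion, digits = 8),
                       motion_paths[i], row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  write_nifti_volume(atlas$cortical_labels,
                     file.path(out_dir, "atlas_cortical.nii.gz"))
  write_nifti_volume(atlas$cerebellar_labels,
                     file.path(out_dir, "atlas_cerebellar.nii.gz"))
  for (mk in c("cerebellum_mask", "wm_mask", "csf_mask"))
    write_nifti_volume(atlas[[mk]], file.path(out_dir, paste0(mk, ".nii.gz")),
                       affine = atlas$affine)
  utils::write.table(rec, file.path(out_dir, "phenotype.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  truth <- lapply(seq_len(nrow(rec)), function(i)
    as.list(rec[i, grep("^coupling_", names(rec)), drop = FALSE]))
  names(truth) <- rec$id
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- data.frame(id = rec$id, bold = bold_paths,
                             motion = motion_paths, stringsAsFactors = FALSE)
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$records), " subjects (",
      sum(x$records$group == "HC"), " HC / ", sum(x$records$group == "SZ"),
      " SZ), ", if (is.null(x$subjects)) "on disk" else "in memory",
      "\n", sep = "")
  invisible(x)
}
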