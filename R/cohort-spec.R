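#' Define a network for the synthetic cohort
#'
#' @param id integer network id (label value in the atlases).
#' @param name network name.
#' @param cortical_size,cerebellar_size territory sizes in voxels.
#' @param coupling_hc,coupling_sz dimensionless coupling of territory voxels
#'   to the network's latent time course, in \[0, 1\], per group.
#' @return A one-row data.frame.
#' @export
network_def <- function(id, name, cortical_size, cerebellar_size,
                        coupling_hc = 0.5, coupling_sz = coupling_hc) {
  stopifnot(coupling_hc >= 0, coupling_hc <= 1,
            coupling_sz >= 0, coupling_sz <= 1,
            cortical_size > 0, cerebellar_size > 0)
  data.frame(id = as.integer(id), name = name,
             cortical_size = as.integer(cortical_size),
             cerebellar_size = as.integer(cerebellar_size),
             coupling_hc = coupling_hc, coupling_sz = coupling_sz,
             stringsAsFactors = FALSE)
}

#' Default 10-network roster for analysis cohorts
#'
#' The ten networks retained by the seed-construction rules (limbic already
#' merged), with equal coupling in both groups unless modified.
#'
#' @param cortical_size,cerebellar_size voxels per territory.
#' @param coupling_hc,coupling_sz default couplings applied to all networks.
#' @return data.frame of network definitions.
#' @export
default_networks <- function(cortical_size = 80, cerebellar_size = 60,
                             coupling_hc = 0.5, coupling_sz = coupling_hc) {
  nm <- c("somatomotor A", "somatomotor B", "dorsal attention B",
          "ventral attention", "salience", "limbic", "control A",
          "control B", "default mode A", "default mode B")
  do.call(rbind, lapply(seq_along(nm), function(i)
    network_def(i, nm[i], cortical_size, cerebellar_size,
                coupling_hc, coupling_sz)))
}

#' Full 17-network roster emulating the cortical parcellation
#'
#' Seventeen networks with the standard names; the six networks with
#' minimal cerebellar representation (visual peripheral, visual central,
#' dorsal attention A, control C, auditory, default mode C) are given
#' cerebellar territories at or below the 30-voxel exclusion bound, the
#' rest well above it.
#'
#' @param minimal_cerebellar_size voxels for the six minimal networks
#'   (must be <= 30 for the roster to reproduce the 10-seed analysis set).
#' @param cerebellar_size,cortical_size voxels for the other territories.
#' @return data.frame of 17 network definitions.
#' @export
study_networks_17 <- function(minimal_cerebellar_size = 12,
                              cerebellar_size = 60, cortical_size = 60) {
  nm <- c("visual peripheral", "visual central", "somatomotor A",
          "somatomotor B", "dorsal attention A", "dorsal attention B",
          "ventral attention", "salience", "temporal pole",
          "orbitofrontal cortex", "control C", "control A", "control B",
          "auditory", "default mode C", "default mode A", "default mode B")
  minimal <- c(1L, 2L, 5L, 11L, 14L, 15L)
  do.call(rbind, lapply(1:17, function(i)
    network_def(i, nm[i], cortical_size,
                if (i %in% minimal) minimal_cerebellar_size else cerebellar_size)))
}

#' Default symptom-scale generative model
#'
#' Scale means and SDs follow typical clinical values for a chronic
#' psychosis sample (SAPS/SANS/YMRS/MADRS/PSYRATS-AH). `slope` maps a
#' subject's coupling deviation (true coupling minus the group mean for
#' `network_id`) onto the score; the default slope of 0 makes symptom
#' scores independent of connectivity (a null model). Scores are truncated
#' at zero.
#'
#' @param slope score units per unit coupling deviation (applied to every
#'   scale; pass a vector for per-scale slopes).
#' @param network_id network whose coupling drives the scores when
#'   slope != 0.
#' @return data.frame with columns scale, mean, sd, slope, network_id.
#' @export
default_symptom_model <- function(slope = 0, network_id = 1L) {
  sc <- data.frame(
    scale = c("SAPS", "SANS", "YMRS", "MADRS", "PSYRATS_AH"),
    mean  = c(35.8, 23.5, 14.7, 14.4, 12.7),
    sd    = c(19.1, 15.9, 8.0, 9.3, 14.3),
    stringsAsFactors = FALSE)
  sc$slope <- rep_len(slope, nrow(sc))
  sc$network_id <- as.integer(network_id)
  sc
}

#' Specify a synthetic two-group resting-state cohort
#'
#' The generative description of a cohort: grid, acquisition timing,
#' network territories and couplings, noise model, nuisance sources,
#' motion, symptom model, and the master seed. Defaults emulate a
#' modest-scale resting-state study: TR 2.5 s, 240 volumes, AR(1)
#' voxel noise, linear/low-frequency drift, a high-frequency
#' pseudo-cardiac sinusoid, and random-walk head motion whose mean
#' absolute displacement lands near 0.3 mm.
#'
#' @param n_per_group subjects per group (HC and SZ).
#' @param grid_shape integer 3-vector of voxel dimensions.
#' @param voxel_mm isotropic voxel size in mm.
#' @param tr_seconds repetition time (s).
#' @param n_volumes time points acquired (before any discard).
#' @param networks data.frame from [network_def()]/[default_networks()].
#' @param ar1_phi lag-1 autocorrelation of voxel noise, |phi| < 1.
#' @param noise_sd innovation SD of the AR(1) voxel noise (BOLD units).
#' @param drift_amp amplitude scale of linear + slow-cosine drift.
#' @param cardio_amp,cardio_freq_hz amplitude and frequency of the
#'   high-frequency nuisance sinusoid; frequency must be below Nyquist.
#' @param motion_sd_mm,motion_sd_deg per-volume random-walk step SDs for
#'   translations (mm) and rotations (degrees).
#' @param coupling_jitter_sd between-subject SD of true coupling around the
#'   group value (truncated to \[0, 1\]).
#' @param symptom_model data.frame from [default_symptom_model()].
#' @param missing_rate fraction of SZ symptom-scale entries set missing.
#' @param discard_volumes initial volumes the downstream pipeline discards
#'   (recorded here so `n_volumes` can be validated against it).
#' @param rng_seed master seed; everything the generator draws derives
#'   from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 12,
                        grid_shape = c(30L, 30L, 20L),
                        voxel_mm = 3,
                        tr_seconds = 2.5,
                        n_volumes = 240,
                        networks = default_networks(),
                        ar1_phi = 0.3,
                        noise_sd = 1.0,
                        drift_amp = 3,
                        cardio_amp = 1,
                        cardio_freq_hz = 0.15,
                        motion_sd_mm = 0.15,
                        motion_sd_deg = 0.1,
                        coupling_jitter_sd = 0.05,
                        symptom_model = default_symptom_model(),
                        missing_rate = 0.15,
                        discard_volumes = 4,
                        rng_seed = 1L) {
  stopifnot(n_per_group >= 1, length(grid_shape) == 3L, all(grid_shape >= 4),
            tr_seconds > 0, n_volumes >= 2, is.data.frame(networks))
  if (any(networks$coupling_hc < 0 | networks$coupling_hc > 1 |
          networks$coupling_sz < 0 | networks$coupling_sz > 1))
    stop("couplings must lie in [0, 1]")
  if (abs(ar1_phi) >= 1) stop("|ar1_phi| must be < 1")
  nyquist <- 1 / (2 * tr_seconds)
  if (cardio_freq_hz >= nyquist)
    stop(sprintf("cardio_freq_hz must be below Nyquist (%.3f Hz)", nyquist))
  # downstream design: seed + wm + csf + 6 motion + intercept = 10 columns
  if (n_volumes <= discard_volumes + 10)
    stop("n_volumes must exceed discard count plus nuisance design rank")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0, 1]")
  structure(list(
    n_per_group = as.integer(n_per_group),
    grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
    tr_seconds = tr_seconds, n_volumes = as.integer(n_volumes),
    networks = networks, ar1_phi = ar1_phi, noise_sd = noise_sd,
    drift_amp = drift_amp, cardio_amp = cardio_amp,
    cardio_freq_hz = cardio_freq_hz, motion_sd_mm = motion_sd_mm,
    motion_sd_deg = motion_sd_deg, coupling_jitter_sd = coupling_jitter_sd,
    symptom_model = symptom_model, missing_rate = missing_rate,
    discard_volumes = as.integer(discard_volumes),
    rng_seed = as.integer(rng_seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_per_group, " per group, grid ",
      paste(x$grid_shape, collapse = "x"), " @ ", x$voxel_mm, " mm, ",
      x$n_volumes, " volumes @ TR ", x$tr_seconds, " s, ",
      nrow(x$networks), " networks, seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}
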