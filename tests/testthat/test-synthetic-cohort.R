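test_that("atlas territories are disjoint, sized as requested, deterministic", {
  nets <- rbind(network_def(1, "a", 27, 27), network_def(2, "b", 27, 27))
  spec <- cohort_spec(n_per_group = 2, networks = nets, rng_seed = 7)
  at <- make_atlas(spec)
  for (lv in list(at$cortical_labels, at$cerebellar_labels)) {
    counts <- table(lv$data[lv$data != 0])
    expect_equal(as.vector(counts), c(27, 27))
  }
  at2 <- make_atlas(spec)
  expect_identical(at$cortical_labels$data, at2$cortical_labels$data)
  expect_identical(at$cerebellar_labels$data, at2$cerebellar_labels$data)
  # masks pairwise disjoint, cerebellar labels inside the cerebellum mask
  expect_false(any(at$cerebellum_mask & at$wm_mask))
  expect_false(any(at$cerebellum_mask & at$csf_mask))
  expect_false(any(at$wm_mask & at$csf_mask))
  expect_true(all(at$cerebellum_mask[at$cerebellar_labels$data != 0]))
})

test_that("a 10-network atlas gives every network >30 cerebellar voxels", {
  spec <- cohort_spec(networks = default_networks(), rng_seed = 1)
  at <- make_atlas(spec)
  counts <- table(at$cerebellar_labels$data[at$cerebellar_labels$data != 0])
  expect_length(counts, 10)
  expect_true(all(counts > 30))
})

test_that("oversized territories are rejected", {
  nets <- network_def(1, "a", 27, 1e6)
  expect_error(make_atlas(cohort_spec(networks = nets)), "capacity")
})

test_that("noiseless unit coupling copies the latent into both territories", {
  nets <- default_networks(cortical_size = 80, cerebellar_size = 60,
                           coupling_hc = 1)[1:2, ]
  spec <- cohort_spec(n_per_group = 1, networks = nets, noise_sd = 0,
                      drift_amp = 0, cardio_amp = 0,
                      coupling_jitter_sd = 0, rng_seed = 3)
  at <- make_atlas(spec)
  rec <- make_subject_records(spec)
  s <- simulate_subject(at, rec[1, ], spec, seed = 11)
  d <- dim(s$bold$data)
  m <- matrix(s$bold$data, prod(d[1:3]), d[4])
  seed_mean <- colMeans(m[at$cortical_labels$data == 1, ])
  vox <- which(at$cerebellar_labels$data == 1)
  for (v in vox[c(1, 10, 30)])
    expect_equal(cor(m[v, ], seed_mean), 1, tolerance = 1e-12)
})

test_that("zero coupling gives near-zero seed correlation", {
  nets <- default_networks(coupling_hc = 0)[1:2, ]
  spec <- cohort_spec(n_per_group = 1, networks = nets, noise_sd = 1,
                      drift_amp = 0, cardio_amp = 0,
                      coupling_jitter_sd = 0, rng_seed = 3)
  at <- make_atlas(spec)
  rec <- make_subject_records(spec)
  s <- simulate_subject(at, rec[1, ], spec, seed = 12)
  d <- dim(s$bold$data)
  m <- matrix(s$bold$data, prod(d[1:3]), d[4])
  seed_mean <- colMeans(m[at$cortical_labels$data == 1, ])
  vox <- which(at$cerebellar_labels$data == 1)
  r <- cor(t(m[vox[1:20], ]), seed_mean)
  expect_lt(mean(abs(r)), 0.15)
})

test_that("AR(1) noise matches its nominal lag-1 autocorrelation", {
  set.seed(21)
  x <- cbfc:::ar1_noise(200, 400, phi = 0.4, sd = 1)
  ac <- apply(x, 2, function(v) cor(v[-1], v[-length(v)]))
  # the sample estimator is biased low by roughly (1+3 phi)/n at n = 200
  expect_lt(abs(mean(ac) - 0.4), 0.03)
  # stationary marginal variance sd^2 / (1 - phi^2)
  expect_equal(mean(apply(x, 2, var)), 1 / (1 - 0.16), tolerance = 0.05)
})

test_that("territory voxel variance follows the variance bookkeeping", {
  # population variance = c^2 + s^2/(1-phi^2) + cardio^2/2 (drift off)
  nets <- default_networks(coupling_hc = 0.7)[1:2, ]
  spec <- cohort_spec(n_per_group = 1, networks = nets, noise_sd = 0.8,
                      ar1_phi = 0.3, drift_amp = 0, cardio_amp = 0.5,
                      coupling_jitter_sd = 0, n_volumes = 240, rng_seed = 8)
  at <- make_atlas(spec)
  rec <- make_subject_records(spec)
  s <- simulate_subject(at, rec[1, ], spec, seed = 13)
  d <- dim(s$bold$data)
  m <- matrix(s$bold$data, prod(d[1:3]), d[4])
  vox <- which(at$cerebellar_labels$data == 1)
  expected <- 0.7^2 + 0.8^2 / (1 - 0.3^2) + 0.5^2 / 2
  expect_equal(mean(apply(m[vox, ], 1, var)), expected, tolerance = 0.12)
})

test_that("cohort output files and missingness behave as specified", {
  spec <- cohort_spec(n_per_group = 3, grid_shape = c(14L, 14L, 10L),
                      n_volumes = 20, discard_volumes = 2,
                      networks = default_networks(12, 10)[1:2, ],
                      missing_rate = 0, rng_seed = 5)
  dir1 <- withr::local_tempdir()
  coh <- simulate_cohort(spec, dir1)
  expect_length(list.files(dir1, pattern = "_bold\\.nii\\.gz$"), 6)
  expect_length(list.files(dir1, pattern = "_motion\\.par$"), 6)
  expect_true(file.exists(file.path(dir1, "phenotype.tsv")))
  expect_true(file.exists(file.path(dir1, "ground_truth.json")))
  ph <- read.delim(file.path(dir1, "phenotype.tsv"))
  # missing_rate 0: every patient has every scale score
  sz <- ph$group == "SZ"
  for (sc in c("SAPS", "SANS", "YMRS", "MADRS", "PSYRATS_AH")) {
    expect_false(anyNA(ph[[sc]][sz]))
    expect_true(all(is.na(ph[[sc]][!sz])))   # scales are patient-only
  }
  expect_true(all(ph$cpz[sz] > 0))
  expect_true(all(ph$cpz[!sz] == 0))
  # regeneration is identical: voxel data, motion, phenotype all match
  dir2 <- withr::local_tempdir()
  simulate_cohort(spec, dir2)
  b1 <- RNifti::readNifti(file.path(dir1, "sub-001_bold.nii.gz"))
  b2 <- RNifti::readNifti(file.path(dir2, "sub-001_bold.nii.gz"))
  expect_identical(dim(b1), dim(b2))
  expect_identical(as.vector(as.array(b1)), as.vector(as.array(b2)))
  expect_identical(readLines(file.path(dir1, "sub-002_motion.par")),
                   readLines(file.path(dir2, "sub-002_motion.par")))
  expect_identical(readLines(file.path(dir1, "phenotype.tsv")),
                   readLines(file.path(dir2, "phenotype.tsv")))
  expect_identical(readLines(file.path(dir1, "ground_truth.json")),
                   readLines(file.path(dir2, "ground_truth.json")))
})

test_that("group coupling difference separates seed correlations by group", {
  # two networks planted in opposite directions; the within-territory
  # seed-correlation difference must carry each planted sign
  nets <- reduced_networks(2, coupling_hc = 0.6, coupling_sz = c(0.3, 0.9))
  spec <- reduced_spec(6, nets, rng_seed = 17)
  coh <- simulate_cohort(spec)
  at <- coh$atlas
  hc <- coh$records$group == "HC"
  mean_r <- function(subj, k) {
    d <- dim(subj$bold$data)
    m <- matrix(subj$bold$data, prod(d[1:3]), d[4])
    sv <- colMeans(m[at$cortical_labels$data == k, ])
    mean(cor(t(m[at$cerebellar_labels$data == k, ]), sv))
  }
  for (k in 1:2) {
    r <- vapply(coh$subjects, mean_r, numeric(1), k = k)
    diff <- mean(r[hc]) - mean(r[!hc])
    expect_identical(sign(diff),
                     sign(nets$coupling_hc[k] - nets$coupling_sz[k]))
  }
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(ar1_phi = 1), "ar1_phi")
  expect_error(cohort_spec(cardio_freq_hz = 0.25), "Nyquist")
  expect_error(cohort_spec(n_volumes = 12), "exceed")
  nets <- default_networks(); nets$coupling_hc[1] <- 1.4
  expect_error(cohort_spec(networks = nets), "couplings")
})
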