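fake_records <- function(n_per_group, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(id = sprintf("sub-%03d", 1:n),
             group = rep(c("HC", "SZ"), each = n_per_group),
             age = round(rnorm(n, 38, 10)),
             sex = rep_len(c("F", "M", "M", "F"), n),     # balanced
             cpz = c(rep(0, n_per_group), round(rlnorm(n_per_group, 6, 0.8))),
             scanner_flag = rep_len(c("pre", "post", "pre"), n),
             stringsAsFactors = FALSE)
}

# z maps as a subjects x voxels matrix over a small 3D mask
toy_mask <- function(d = c(5, 4, 3)) array(TRUE, d)

test_that("group design has the specified columns and catches problems", {
  rec <- fake_records(3)
  gd <- build_group_design(rec, include_cpz = TRUE)
  expect_equal(dim(gd$x), c(6, 6))
  expect_equal(qr(gd$x)$rank, 6)
  gd2 <- build_group_design(rec, include_cpz = FALSE)
  expect_equal(dim(gd2$x), c(6, 5))
  # covariates centered, group indicator raw
  expect_equal(unname(colMeans(gd$x[, c("age", "sex", "scanner", "cpz")])),
               rep(0, 4), tolerance = 1e-12)
  rec_na <- rec; rec_na$age[2] <- NA
  expect_error(build_group_design(rec_na), "sub-002")
  rec_const <- rec; rec_const$age <- 40  # constant covariate -> collinear
  expect_error(build_group_design(rec_const), "rank deficient|collinear")
})

test_that("group contrast equals the closed-form two-sample t", {
  rec <- fake_records(3)
  mask <- array(TRUE, c(1, 1, 1))
  vals <- c(1, 2, 3, 3, 4, 5)              # HC then SZ
  maps <- lapply(vals, function(v) array(v, c(1, 1, 1)))
  gd <- list(x = cbind(group = as.numeric(rec$group == "SZ"), intercept = 1),
             contrasts = list(sz_gt_hc = c(1, 0), hc_gt_sz = c(-1, 0)),
             records = rec)
  class(gd) <- "group_design"
  gm <- fit_group_contrast(maps, gd, "sz_gt_hc", mask)
  t_expected <- 2 / sqrt(1 * (1 / 3 + 1 / 3))  # pooled variance = 1
  expect_equal(gm$z[1, 1, 1], t_to_z(t_expected, 4), tolerance = 1e-10)
  expect_equal(t_expected, 2.449, tolerance = 1e-3)
  # flipping the contrast negates the statistic map
  gm2 <- fit_group_contrast(maps, gd, "hc_gt_sz", mask)
  expect_equal(gm2$z, -gm$z, tolerance = 1e-10)
  # identical groups give t = 0
  maps0 <- lapply(c(1, 2, 3, 1, 2, 3), function(v) array(v, c(1, 1, 1)))
  gm0 <- fit_group_contrast(maps0, gd, "sz_gt_hc", mask)
  expect_equal(gm0$z[1, 1, 1], 0, tolerance = 1e-12)
})

test_that("within-group maps match the one-sample closed form", {
  rec <- fake_records(2)
  mask <- array(TRUE, c(1, 1, 1))
  maps <- lapply(c(0.8, 1.4, 0, 0), function(v) array(v, c(1, 1, 1)))
  wg <- within_group_map(maps, rec, "HC", mask)
  t_hand <- mean(c(0.8, 1.4)) / (sd(c(0.8, 1.4)) / sqrt(2))
  expect_equal(wg$z[1, 1, 1], t_to_z(t_hand, 1), tolerance = 1e-10)
  expect_error(within_group_map(maps[1], rec[1, ], "HC", mask), "at least 2")
  # identical constant maps are flagged degenerate
  mapsc <- lapply(rep(1.5, 4), function(v) array(v, c(1, 1, 1)))
  wgc <- within_group_map(mapsc, rec, "SZ", mask)
  expect_true(wgc$degenerate[1, 1, 1])
  expect_equal(wgc$z[1, 1, 1], 0)
})

test_that("null within-group maps exceed one-sided p<0.05 at the 5% rate", {
  set.seed(30)
  mask <- toy_mask(c(12, 10, 8))
  rec <- fake_records(10)
  y <- matrix(rnorm(20 * sum(mask)), 20, sum(mask))
  wg <- within_group_map(y, rec, "HC", mask)
  frac <- mean(wg$p_one_sided[mask] < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("cluster extraction finds separated and corner-touching blobs", {
  d <- c(10, 10, 6)
  z <- array(0, d)
  z[2:2, 2:6, 2] <- 5          # 5-voxel line
  z[8:8, 2:6, 4] <- 4          # another, far away
  ct <- extract_clusters(z, voxel_p = 0.01)
  expect_equal(nrow(ct$table), 2)
  expect_equal(ct$table$n_voxels, c(5, 5))
  expect_equal(ct$table$peak_z, c(5, 4))   # equal sizes ordered by peak
  # corner contact: one cluster under 26-connectivity, two under 6
  zc <- array(0, d)
  zc[3, 3, 3] <- 5; zc[4, 4, 4] <- 5
  expect_equal(nrow(extract_clusters(zc, 0.01, 26L)$table), 1)
  expect_equal(nrow(extract_clusters(zc, 0.01, 6L)$table), 2)
  # all below threshold: empty table
  expect_equal(nrow(extract_clusters(array(0.5, d), 0.01)$table), 0)
})

test_that("component labelling agrees with a brute-force flood fill", {
  for (s in 1:6) {
    set.seed(s)
    m <- array(runif(8 * 7 * 5) < 0.4, c(8, 7, 5))
    for (conn in c(26L, 6L)) {
      got <- label_components(m, conn)
      want <- floodfill_oracle(m, conn)
      # same partition up to label renumbering
      expect_equal(max(got), max(want))
      for (k in seq_len(max(got)))
        expect_equal(length(unique(want[got == k])), 1)
    }
  }
})

test_that("permutation p equals exhaustive enumeration on 3 vs 3", {
  rec <- fake_records(3, seed = 44)
  mask <- toy_mask(c(6, 5, 4))
  nv <- prod(c(6, 5, 4))
  set.seed(45)
  y <- matrix(rnorm(6 * nv), 6, nv)
  y[rec$group == "HC", 1:20] <- y[rec$group == "HC", 1:20] + 1.5
  gd <- list(x = cbind(group = as.numeric(rec$group == "SZ"), intercept = 1),
             contrasts = list(hc_gt_sz = c(-1, 0)), records = rec)
  class(gd) <- "group_design"
  ct <- permutation_cluster_pvalues(y, gd, "hc_gt_sz", mask,
                                    voxel_p = 0.05, exhaustive = TRUE)
  # independent oracle: enumerate all 20 assignments by brute force
  groups_of_3 <- combn(6, 3)
  zcrit <- qnorm(0.95)
  max_null <- apply(groups_of_3, 2, function(hc_idx) {
    tvals <- vapply(seq_len(nv), function(v) {
      a <- y[hc_idx, v]; b <- y[-hc_idx, v]
      sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
      (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
    }, numeric(1))
    zz <- array(t_to_z(tvals, 4), dim = c(6, 5, 4))
    lab <- floodfill_oracle(zz >= zcrit)
    if (max(lab) == 0) 0 else max(tabulate(lab[lab > 0]))
  })
  for (r in seq_len(nrow(ct$table)))
    expect_equal(ct$table$p_corrected[r],
                 mean(max_null >= ct$table$n_voxels[r]))
})

test_that("permutation p-values respect bounds and monotonicity", {
  rec <- fake_records(5, seed = 46)
  mask <- toy_mask(c(8, 6, 4))
  nv <- sum(mask)
  set.seed(47)
  y <- matrix(rnorm(10 * nv, sd = 0.3), 10, nv)
  y[rec$group == "HC", 1:30] <- y[rec$group == "HC", 1:30] + 3
  gd <- build_group_design(rec, include_cpz = FALSE)
  ct <- permutation_cluster_pvalues(y, gd, "hc_gt_sz", mask,
                                    voxel_p = 0.01, n_perm = 99,
                                    rng_seed = 5)
  expect_true(all(ct$table$p_corrected > 0 & ct$table$p_corrected <= 1))
  # monotone: larger clusters never have larger corrected p
  ord <- order(-ct$table$n_voxels)
  expect_true(all(diff(ct$table$p_corrected[ord]) >= 0))
  # corrected p follows (1 + #{perm max >= size}) / (n_perm + 1), so a
  # cluster larger than every permuted max gets exactly 1/(n_perm+1)
  null_max <- attr(ct, "null_max_sizes")
  for (r in seq_len(nrow(ct$table)))
    expect_equal(ct$table$p_corrected[r],
                 (1 + sum(null_max >= ct$table$n_voxels[r])) / 100)
  if (all(null_max < max(ct$table$n_voxels)))
    expect_equal(min(ct$table$p_corrected), 1 / 100)
  expect_error(permutation_cluster_pvalues(y, gd, "hc_gt_sz", mask,
                                           n_perm = 10, rng_seed = 1),
               "coarse")
})

test_that("Freedman-Lane with no covariates matches label permutation", {
  rec <- fake_records(4, seed = 48)
  mask <- toy_mask(c(5, 5, 3))
  nv <- sum(mask)
  set.seed(49)
  y <- matrix(rnorm(8 * nv), 8, nv)
  y[rec$group == "HC", 1:10] <- y[rec$group == "HC", 1:10] + 2
  gd <- list(x = cbind(group = as.numeric(rec$group == "SZ"), intercept = 1),
             contrasts = list(hc_gt_sz = c(-1, 0)), records = rec)
  class(gd) <- "group_design"
  ct_fl <- permutation_cluster_pvalues(y, gd, "hc_gt_sz", mask,
                                       voxel_p = 0.05, exhaustive = TRUE)
  # exhaustive mode IS label permutation; FL sampling with many draws
  # must agree within Monte-Carlo error
  ct_mc <- permutation_cluster_pvalues(y, gd, "hc_gt_sz", mask,
                                       voxel_p = 0.05, n_perm = 400,
                                       rng_seed = 50)
  for (r in seq_len(nrow(ct_fl$table)))
    expect_equal(ct_mc$table$p_corrected[r], ct_fl$table$p_corrected[r],
                 tolerance = 0.08)
})
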