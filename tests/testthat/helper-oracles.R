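# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# erosion: voxel survives iff itself and every structuring-element
# neighbour (26 or 6) lies inside the mask; out-of-grid counts as outside
erode_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    ok <- TRUE
    for (r in seq_len(nrow(off))) {
      xx <- x + off[r, 1]; yy <- y + off[r, 2]; zz <- z + off[r, 3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
          zz < 1 || zz > d[3] || !mask[xx, yy, zz]) { ok <- FALSE; break }
    }
    out[x, y, z] <- ok
  }
  out
}

# connected components by breadth-first flood fill over voxel coordinates
floodfill_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  vox <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    if (lab[vox[v, 1], vox[v, 2], vox[v, 3]] != 0L) next
    cur <- cur + 1L
    queue <- list(vox[v, ])
    lab[vox[v, 1], vox[v, 2], vox[v, 3]] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(off))) {
        q <- p + off[r, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# nearest-neighbour resampling by exhaustive search over all source
# voxel centers in world space
nn_resample_oracle <- function(src_data, src_affine, tgt_dim, tgt_affine) {
  sd3 <- dim(src_data)
  src_idx <- as.matrix(expand.grid(i = 0:(sd3[1] - 1), j = 0:(sd3[2] - 1),
                                   k = 0:(sd3[3] - 1)))
  src_world <- t(src_affine %*% rbind(t(src_idx), 1))[, 1:3]
  out <- array(0L, tgt_dim)
  for (i in 0:(tgt_dim[1] - 1)) for (j in 0:(tgt_dim[2] - 1))
    for (k in 0:(tgt_dim[3] - 1)) {
      w <- (tgt_affine %*% c(i, j, k, 1))[1:3]
      d2 <- rowSums(sweep(src_world, 2, w)^2)
      b <- which.min(d2)
      out[i + 1, j + 1, k + 1] <-
        src_data[src_idx[b, 1] + 1, src_idx[b, 2] + 1, src_idx[b, 3] + 1]
    }
  out
}

# Gaussian running-mean band-pass amplitude response at frequency f (Hz):
# continuous-time transfer of the high-pass (1 - G_hp) times low-pass G_lp
bandpass_gain_oracle <- function(f_hz, sigma_hp_vols, sigma_lp_vols,
                                 tr_seconds) {
  shp <- sigma_hp_vols * tr_seconds
  slp <- sigma_lp_vols * tr_seconds
  (1 - exp(-2 * pi^2 * f_hz^2 * shp^2)) * exp(-2 * pi^2 * f_hz^2 * slp^2)
}

# empirical gain: amplitude of the filtered probe sinusoid estimated by
# regression on sine/cosine over the central portion (edges excluded)
empirical_gain <- function(filtered, f_hz, tr_seconds, trim = 0.2) {
  nt <- length(filtered)
  keep <- seq.int(ceiling(nt * trim), floor(nt * (1 - trim)))
  tt <- (keep - 1) * tr_seconds
  fit <- lm(filtered[keep] ~ sin(2 * pi * f_hz * tt) + cos(2 * pi * f_hz * tt))
  sqrt(sum(coef(fit)[2:3]^2))
}

# Jenkinson displacement by Monte-Carlo integration over a solid sphere
displacement_mc_oracle <- function(rel_transform, radius_mm, n = 20000) {
  set.seed(99)
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * radius_mm * runif(n)^(1 / 3)
  moved <- t(rel_transform %*% rbind(t(pts), 1))[, 1:3]
  sqrt(mean(rowSums((moved - pts)^2)))
}

# OLS via explicit pseudoinverse (SVD), classical t for one coefficient
glm_pinv_oracle <- function(x, y, col) {
  sv <- svd(x)
  pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
  beta <- pinv %*% y
  res <- y - x %*% beta
  dof <- nrow(x) - ncol(x)
  s2 <- sum(res^2) / dof
  covb <- sv$v %*% diag(1 / sv$d^2) %*% t(sv$v)
  list(beta = beta[col], t = beta[col] / sqrt(s2 * covb[col, col]), dof = dof)
}

# small reduced-scale network roster used by the calibration/recovery suites
reduced_networks <- function(n = 4, coupling_hc = 0.6,
                             coupling_sz = rep(coupling_hc, n)) {
  nets <- default_networks(cortical_size = 150, cerebellar_size = 80)[seq_len(n), ]
  nets$coupling_hc <- coupling_hc
  nets$coupling_sz <- coupling_sz
  nets
}

reduced_spec <- function(n_per_group, networks, rng_seed)
  cohort_spec(n_per_group = n_per_group, grid_shape = c(20L, 20L, 12L),
              n_volumes = 120, networks = networks, rng_seed = rng_seed)
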