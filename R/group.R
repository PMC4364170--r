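#' Build the group-level design matrix
#'
#' One row per subject; columns: group indicator (SZ = 1, HC = 0), age,
#' sex (M = 1), scanner-upgrade flag (post = 1), optionally chlorpromazine
#' equivalents, and an intercept. Covariates are mean-centered; the design
#' is checked for full rank. Contrast vectors for SZ > HC and HC > SZ
#' select +/- the group column.
#'
#' @param records phenotype data.frame with columns `id`, `group`
#'   (`"HC"`/`"SZ"`), `age`, `sex`, `cpz`, `scanner_flag`.
#' @param include_cpz include the medication covariate (the primary
#'   analysis does; the exploratory analysis drops it).
#' @return list of class `group_design`: `x` (matrix), `contrasts`
#'   (named list of vectors), `records`.
#' @export
build_group_design <- function(records, include_cpz = TRUE) {
  need <- c("group", "age", "sex", "scanner_flag",
            if (include_cpz) "cpz")
  for (v in need) {
    if (!v %in% names(records)) stop("records lack column ", v)
    if (anyNA(records[[v]]))
      stop("missing ", v, " for subject(s): ",
           paste(records$id[is.na(records[[v]])], collapse = ", "))
  }
  x <- cbind(group = as.numeric(records$group == "SZ"),
             age = records$age,
             sex = as.numeric(records$sex == "M"),
             scanner = as.numeric(records$scanner_flag == "post"))
  if (include_cpz) x <- cbind(x, cpz = records$cpz)
  covs <- setdiff(colnames(x), "group")
  x[, covs] <- sweep(x[, covs, drop = FALSE], 2,
                     colMeans(x[, covs, drop = FALSE]))
  x <- cbind(x, intercept = 1)
  assert_full_rank(x)
  cvec <- stats::setNames(numeric(ncol(x)), colnames(x))
  sz <- cvec; sz["group"] <- 1
  hc <- cvec; hc["group"] <- -1
  structure(list(x = x, contrasts = list(sz_gt_hc = sz, hc_gt_sz = hc),
                 records = records), class = "group_design")
}

# Generic voxelwise OLS contrast on a subjects x voxels matrix.
# Returns t, z, dof, degenerate flag per voxel.
contrast_t_map <- function(x, y, cvec) {
  xtxinv <- solve(crossprod(x))
  beta <- xtxinv %*% crossprod(x, y)
  res <- y - x %*% beta
  dof <- nrow(x) - ncol(x)
  s2 <- colSums(res^2) / dof
  cb <- drop(crossprod(cvec, beta))
  se <- sqrt(pmax(s2, 0) * drop(t(cvec) %*% xtxinv %*% cvec))
  vy <- colSums(y^2) - colSums(y)^2 / nrow(y)
  degenerate <- vy < .Machine$double.eps^0.75 * nrow(y)
  tt <- ifelse(degenerate | (se == 0 & cb == 0), 0,
               ifelse(se == 0, sign(cb) * Inf, cb / se))
  list(t = tt, z = t_to_z(tt, dof), dof = dof, degenerate = degenerate)
}

# Stack per-subject z maps (list of fc_map or 3D arrays, or an already
# stacked subjects x voxels matrix) into a matrix over the mask.
stack_maps <- function(maps, mask) {
  if (is.matrix(maps)) {
    stopifnot(ncol(maps) == sum(mask))
    return(maps)
  }
  out <- vapply(maps, function(m) {
    a <- if (inherits(m, "fc_map")) m$z else m
    a[mask]
  }, numeric(sum(mask)))
  # vapply drops to a vector when the mask has a single voxel
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  t(out)
}

#' Group-level contrast map
#'
#' Voxelwise OLS of the subjects' first-level z values on the group design;
#' returns the contrast t statistic converted to z, masked to the
#' cerebellum. Voxels with no between-subject variance get statistic 0
#' and are flagged.
#'
#' @param maps list of per-subject [fit_voxelwise_glm()] maps (or 3D z
#'   arrays), in the row order of the design.
#' @param gd a [build_group_design()].
#' @param contrast contrast name (`"sz_gt_hc"`, `"hc_gt_sz"`) or numeric
#'   vector of length ncol(design).
#' @param mask logical 3D analysis mask (cerebellum).
#' @return object of class `group_map`: `z` (3D, NA outside mask), `dof`,
#'   `mask`, `degenerate`.
#' @export
fit_group_contrast <- function(maps, gd, contrast, mask) {
  stopifnot(inherits(gd, "group_design"))
  if (length(maps) != nrow(gd$x))
    stop("number of maps != design rows")
  cvec <- if (is.character(contrast)) gd$contrasts[[contrast]] else contrast
  if (is.null(cvec)) stop("unknown contrast")
  y <- stack_maps(maps, mask)
  fit <- contrast_t_map(gd$x, y, cvec)
  as_vol <- function(v) { a <- array(NA_real_, dim = dim(mask)); a[mask] <- v; a }
  deg <- array(FALSE, dim = dim(mask)); deg[mask] <- fit$degenerate
  structure(list(z = as_vol(fit$z), dof = fit$dof, mask = mask,
                 degenerate = deg), class = "group_map")
}

#' Within-group mean connectivity map
#'
#' One-sample t test of the subjects' first-level z maps within one group,
#' converted to z, with a one-sided p map (testing positive mean
#' connectivity). Voxels with zero between-subject variance are flagged.
#'
#' @param maps list of per-subject maps (all subjects).
#' @param records phenotype data.frame aligned with `maps`.
#' @param group `"HC"` or `"SZ"`.
#' @param mask logical 3D analysis mask.
#' @return object of class `group_map` with elements `z`, `p_one_sided`,
#'   `dof`, `mask`, `degenerate`.
#' @export
within_group_map <- function(maps, records, group, mask) {
  keep <- which(records$group == group)
  if (length(keep) < 2) stop("need at least 2 subjects in group ", group)
  y <- if (is.matrix(maps)) maps[keep, , drop = FALSE] else
    stack_maps(maps[keep], mask)
  n <- nrow(y)
  mu <- colMeans(y)
  sdv <- sqrt(colSums(sweep(y, 2, mu)^2) / (n - 1))
  degenerate <- sdv < .Machine$double.eps^0.75
  tt <- ifelse(degenerate, 0, mu / (sdv / sqrt(n)))
  z <- t_to_z(tt, n - 1)
  as_vol <- function(v) { a <- array(NA_real_, dim = dim(mask)); a[mask] <- v; a }
  deg <- array(FALSE, dim = dim(mask)); deg[mask] <- degenerate
  structure(list(z = as_vol(z),
                 p_one_sided = as_vol(stats::pnorm(z, lower.tail = FALSE)),
                 dof = n - 1, mask = mask, degenerate = deg),
            class = "group_map")
}

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (default) or 6.
#' @return integer array, 0 background, components numbered 1..K.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .cc_label_3d(as.vector(mask), as.integer(dim(mask)),
               as.integer(connectivity))
}

#' Extract suprathreshold clusters from a z map
#'
#' One-sided voxel thresholding at z >= qnorm(1 - voxel_p), then grouping
#' of suprathreshold voxels into connected components, sorted by size
#' (ties by peak statistic).
#'
#' @param zmap 3D z array (NA treated as background) or `group_map`.
#' @param voxel_p one-sided voxel threshold (default 0.01).
#' @param connectivity 26 (default) or 6.
#' @return list of class `cluster_table`: `table` (data.frame: cluster id,
#'   n_voxels, peak_z, peak i/j/k), `labels` (integer array re-numbered in
#'   sorted order), `zcrit`.
#' @export
extract_clusters <- function(zmap, voxel_p = 0.01, connectivity = 26L) {
  if (inherits(zmap, "group_map")) zmap <- zmap$z
  zcrit <- stats::qnorm(1 - voxel_p)
  supra <- !is.na(zmap) & zmap >= zcrit
  lab <- label_components(supra, connectivity)
  k <- max(lab)
  if (k == 0) {
    return(structure(list(
      table = data.frame(cluster = integer(), n_voxels = integer(),
                         peak_z = numeric(), peak_i = integer(),
                         peak_j = integer(), peak_k = integer()),
      labels = lab, zcrit = zcrit), class = "cluster_table"))
  }
  sizes <- tabulate(lab[lab > 0], nbins = k)
  peaks <- vapply(seq_len(k), function(i) max(zmap[lab == i]), numeric(1))
  ord <- order(-sizes, -peaks)
  relab <- array(0L, dim = dim(lab))
  tab <- data.frame(cluster = seq_len(k), n_voxels = sizes[ord],
                    peak_z = peaks[ord], peak_i = NA_integer_,
                    peak_j = NA_integer_, peak_k = NA_integer_)
  for (r in seq_len(k)) {
    old <- ord[r]
    relab[lab == old] <- r
    w <- which(lab == old & zmap == peaks[old], arr.ind = TRUE)[1, ]
    tab[r, c("peak_i", "peak_j", "peak_k")] <- as.integer(w)
  }
  structure(list(table = tab, labels = relab, zcrit = zcrit),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("<cluster_table> ", nrow(x$table), " clusters (z crit ",
      round(x$zcrit, 3), ")\n", sep = "")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

# All distinct two-group assignments for exhaustive mode: rows index
# subjects in group "one"; includes the observed assignment first.
all_assignments <- function(g) {
  idx <- utils::combn(length(g), sum(g))
  obs <- which(g == 1)
  first <- which(apply(idx, 2, function(cc) identical(cc, obs)))
  ord <- c(first, setdiff(seq_len(ncol(idx)), first))
  idx[, ord, drop = FALSE]
}

#' Permutation cluster-extent inference for a group contrast
#'
#' Freedman-Lane scheme: the reduced model (design without the contrast's
#' columns) is fitted, its residuals are permuted across subjects and
#' added back to the reduced fit, and the full-model contrast is
#' recomputed on each permuted dataset. Each permutation's suprathreshold
#' (one-sided voxel p < `voxel_p`) maximum cluster size builds the null;
#' a cluster's corrected p is (1 + #\{perm max >= observed size\}) /
#' (n_perm + 1), and clusters with corrected p < `cluster_p` are flagged
#' significant. With no covariates the scheme reduces to simple
#' group-label permutation. `exhaustive = TRUE` (only without covariates)
#' enumerates all distinct group assignments instead.
#'
#' @param maps list of per-subject first-level maps (or 3D z arrays).
#' @param gd a [build_group_design()].
#' @param contrast contrast name or vector.
#' @param mask logical 3D analysis mask.
#' @param voxel_p one-sided voxel threshold (default 0.01).
#' @param cluster_p corrected cluster threshold (default 0.05).
#' @param n_perm number of permutations (>= 20 required, >= 100
#'   recommended; default 1000).
#' @param connectivity cluster connectivity (26 default).
#' @param rng_seed seed for the permutation stream (required).
#' @param exhaustive enumerate all group assignments (small samples, no
#'   covariates).
#' @return `cluster_table` whose table gains `p_corrected` and
#'   `significant`; attributes `null_max_sizes`, `n_perm`.
#' @export
permutation_cluster_pvalues <- function(maps, gd, contrast, mask,
                                        voxel_p = 0.01, cluster_p = 0.05,
                                        n_perm = 1000, connectivity = 26L,
                                        rng_seed, exhaustive = FALSE) {
  stopifnot(inherits(gd, "group_design"))
  cvec <- if (is.character(contrast)) gd$contrasts[[contrast]] else contrast
  if (is.null(cvec)) stop("unknown contrast")
  y <- stack_maps(maps, mask)
  x <- gd$x
  obs <- contrast_t_map(x, y, cvec)
  zobs <- array(NA_real_, dim = dim(mask)); zobs[mask] <- obs$z
  ct <- extract_clusters(zobs, voxel_p, connectivity)

  ccols <- which(cvec != 0)
  x0 <- x[, -ccols, drop = FALSE]
  b0 <- solve(crossprod(x0), crossprod(x0, y))
  fit0 <- x0 %*% b0
  r0 <- y - fit0
  n <- nrow(y)

  max_size_of <- function(ystar) {
    f <- contrast_t_map(x, ystar, cvec)
    zz <- array(NA_real_, dim = dim(mask)); zz[mask] <- f$z
    lab <- label_components(!is.na(zz) & zz >= ct$zcrit, connectivity)
    if (max(lab) == 0) 0L else max(tabulate(lab[lab > 0], nbins = max(lab)))
  }

  if (exhaustive) {
    has_cov <- ncol(x0) > 1 || any(x0[, 1] != x0[1, 1])
    if (has_cov)
      stop("exhaustive enumeration requires a covariate-free design")
    g <- x[, "group"]
    idx <- all_assignments(g)
    null_max <- numeric(ncol(idx))
    for (j in seq_len(ncol(idx))) {
      gp <- numeric(n); gp[idx[, j]] <- 1
      xp <- x; xp[, "group"] <- gp
      f <- contrast_t_map(xp, y, cvec)
      zz <- array(NA_real_, dim = dim(mask)); zz[mask] <- f$z
      lab <- label_components(!is.na(zz) & zz >= ct$zcrit, connectivity)
      null_max[j] <- if (max(lab) == 0) 0 else
        max(tabulate(lab[lab > 0], nbins = max(lab)))
    }
    denom <- length(null_max)
    pcorr <- vapply(ct$table$n_voxels,
                    function(s) sum(null_max >= s) / denom, numeric(1))
  } else {
    if (n_perm < 20) stop("n_perm < 20: permutation resolution too coarse")
    if (missing(rng_seed)) stop("rng_seed is required")
    set.seed(as.integer(rng_seed))
    null_max <- numeric(n_perm)
    for (j in seq_len(n_perm))
      null_max[j] <- max_size_of(fit0 + r0[sample.int(n), , drop = FALSE])
    pcorr <- vapply(ct$table$n_voxels,
                    function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
                    numeric(1))
  }
  ct$table$p_corrected <- pcorr
  ct$table$significant <- !is.na(pcorr) & pcorr < cluster_p
  attr(ct, "null_max_sizes") <- null_max
  attr(ct, "n_perm") <- if (exhaustive) length(null_max) else n_perm
  ct
}
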