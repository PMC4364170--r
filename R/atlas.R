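# Region boxes are laid out as fixed fractions of the grid so the same
# scheme scales from quick-test grids to the default 30x30x20: cerebellum
# in the lowest slices, WM and CSF compartments in a middle band, cortex
# in the upper slices. All four regions are pairwise disjoint.
region_box <- function(d, fx, fy, fz) {
  ix <- seq.int(max(1L, floor(fx[1] * d[1]) + 1L), floor(fx[2] * d[1]))
  iy <- seq.int(max(1L, floor(fy[1] * d[2]) + 1L), floor(fy[2] * d[2]))
  iz <- seq.int(max(1L, floor(fz[1] * d[3]) + 1L), floor(fz[2] * d[3]))
  list(x = ix, y = iy, z = iz,
       coords = as.matrix(expand.grid(x = ix, y = iy, z = iz)))
}

atlas_regions <- function(grid_shape) {
  d <- grid_shape
  list(
    cerebellum = region_box(d, c(0.08, 0.92), c(0.08, 0.92), c(0.00, 0.32)),
    wm         = region_box(d, c(0.08, 0.45), c(0.20, 0.80), c(0.38, 0.52)),
    csf        = region_box(d, c(0.55, 0.92), c(0.20, 0.80), c(0.38, 0.52)),
    cortex     = region_box(d, c(0.08, 0.92), c(0.08, 0.92), c(0.58, 0.96)))
}

# Deterministic, well-separated territory centers on an x-y lattice at the
# axial midplane of a region.
territory_centers <- function(region, k) {
  gx <- ceiling(sqrt(k)); gy <- ceiling(k / gx)
  xr <- range(region$x); yr <- range(region$y); zm <- round(mean(range(region$z)))
  cen <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    cx <- (i - 1) %% gx; cy <- (i - 1) %/% gx
    cen[i, ] <- c(round(xr[1] + (cx + 0.5) / gx * diff(xr)),
                  round(yr[1] + (cy + 0.5) / gy * diff(yr)), zm)
  }
  cen
}

# Grow one compact blob per network: the `size` unassigned region voxels
# nearest (Euclidean) to the network's center, assigned sequentially in
# network order so territories are always disjoint.
grow_territories <- function(region, sizes, grid_shape) {
  k <- length(sizes)
  if (sum(sizes) > nrow(region$coords))
    stop("territories exceed region capacity: ", sum(sizes), " voxels ",
         "requested, ", nrow(region$coords), " available")
  cen <- territory_centers(region, k)
  lab <- array(0L, dim = grid_shape)
  free <- rep(TRUE, nrow(region$coords))
  co <- region$coords
  for (i in seq_len(k)) {
    d2 <- (co[, 1] - cen[i, 1])^2 + (co[, 2] - cen[i, 2])^2 +
      (co[, 3] - cen[i, 3])^2
    d2[!free] <- Inf
    pick <- order(d2)[seq_len(sizes[i])]
    if (any(!is.finite(d2[pick]))) stop("territories overlap region capacity")
    free[pick] <- FALSE
    lab[co[pick, , drop = FALSE]] <- i
  }
  lab
}

box_mask <- function(region, grid_shape) {
  m <- array(FALSE, dim = grid_shape)
  m[region$x, region$y, region$z] <- TRUE
  m
}

#' Generate the synthetic atlas bundle for a cohort
#'
#' Builds, deterministically from the cohort specification, a cortical label volume (one
#' compact territory per network), a homotopic cerebellar label volume
#' (the planted "canonical" cerebellar parcellation), and binary
#' cerebellum / white-matter / CSF masks, all pairwise disjoint and on
#' the cohort grid. Label ids agree between the cortical and cerebellar
#' volumes. Running twice on the same spec gives voxel-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `atlas_bundle`: `cortical_labels`,
#'   `cerebellar_labels` (both [label_volume()]), `cerebellum_mask`,
#'   `wm_mask`, `csf_mask` (logical arrays), `affine`, `voxel_mm`,
#'   `networks`.
#' @export
make_atlas <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$grid_shape
  reg <- atlas_regions(d)
  nets <- spec$networks
  aff <- diag(c(rep(spec$voxel_mm, 3), 1))
  labtab <- data.frame(id = nets$id, name = nets$name, stringsAsFactors = FALSE)
  cort <- grow_territories(reg$cortex, nets$cortical_size, d)
  cort[cort != 0L] <- nets$id[cort[cort != 0L]]
  cere <- grow_territories(reg$cerebellum, nets$cerebellar_size, d)
  cere[cere != 0L] <- nets$id[cere[cere != 0L]]
  out <- list(
    cortical_labels = label_volume(cort, aff, labtab),
    cerebellar_labels = label_volume(cere, aff, labtab),
    cerebellum_mask = box_mask(reg$cerebellum, d),
    wm_mask = box_mask(reg$wm, d),
    csf_mask = box_mask(reg$csf, d),
    affine = aff, voxel_mm = spec$voxel_mm, networks = nets)
  stopifnot(!any(out$cerebellum_mask & out$wm_mask),
            !any(out$cerebellum_mask & out$csf_mask),
            !any(out$wm_mask & out$csf_mask),
            all(out$cerebellum_mask[out$cerebellar_labels$data != 0L]))
  class(out) <- "atlas_bundle"
  out
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat("<atlas_bundle> ", nrow(x$networks), " networks, cerebellum ",
      sum(x$cerebellum_mask), " voxels (", sum(x$cerebellar_labels$data != 0),
      " labelled), WM ", sum(x$wm_mask), ", CSF ", sum(x$csf_mask),
      " voxels\n", sep = "")
  invisible(x)
}
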