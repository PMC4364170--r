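#' Nearest-neighbour resampling of a label volume
#'
#' Each target voxel takes the label of the nearest source voxel center
#' (labels are categorical and must never be averaged). The target voxel
#' center is mapped through the target affine to world coordinates, then
#' through the inverse source affine to a continuous source index, which
#' is rounded; out-of-grid voxels become background.
#'
#' @param lv a [label_volume()].
#' @param target_grid integer 3-vector of target dimensions.
#' @param target_affine 4x4 voxel-to-world matrix of the target grid.
#' @return resampled `label_volume`; its label set is a subset of the
#'   source label set.
#' @export
resample_labels_nearest <- function(lv, target_grid, target_affine) {
  stopifnot(inherits(lv, "label_volume"), length(target_grid) == 3L)
  if (abs(det(target_affine)) < .Machine$double.eps)
    stop("target affine must be invertible")
  src_inv <- solve(lv$affine)
  d <- as.integer(target_grid)
  # 0-based voxel indices, homogeneous coordinates
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  world <- target_affine %*% rbind(t(idx), 1)
  src <- round(src_inv %*% world)[1:3, , drop = FALSE]
  sd3 <- dim(lv$data)
  inb <- src[1, ] >= 0 & src[1, ] < sd3[1] &
         src[2, ] >= 0 & src[2, ] < sd3[2] &
         src[3, ] >= 0 & src[3, ] < sd3[3]
  out <- integer(nrow(idx))
  lin <- 1L + src[1, inb] + sd3[1] * (src[2, inb] + sd3[2] * src[3, inb])
  out[inb] <- lv$data[lin]
  label_volume(array(out, dim = d), target_affine, lv$labels)
}

#' Split a label volume into per-label binary masks
#'
#' @param lv a [label_volume()].
#' @return named list of logical arrays, one per nonzero label present;
#'   the masks partition the foreground voxels.
#' @export
split_labels <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  ids <- sort(unique(as.integer(lv$data)))
  ids <- ids[ids != 0L]
  out <- lapply(ids, function(i) lv$data == i)
  names(out) <- as.character(ids)
  out
}

#' Merge network masks into one
#'
#' Union of the masks for the given ids; used to combine the temporal-pole
#' and orbitofrontal-cortex networks (ids 9 and 10 of the 17-network
#' parcellation) into a single limbic seed.
#'
#' @param masks named list from [split_labels()].
#' @param ids label ids to merge (default `c(9, 10)`).
#' @return logical array, the union.
#' @export
merge_labels <- function(masks, ids = c(9, 10)) {
  key <- as.character(ids)
  if (!all(key %in% names(masks)))
    stop("missing label id(s): ",
         paste(setdiff(key, names(masks)), collapse = ", "))
  Reduce(`|`, masks[key])
}

#' Select networks with adequate cerebellar representation
#'
#' Networks whose canonical cerebellar territory has `threshold` voxels or
#' fewer are excluded from the analysis roster. Ids listed in `merge_ids`
#' are treated as a single merged network (their cerebellar counts summed,
#' counted once). With the 17-network parcellation, its six minimal
#' networks, and the 9+10 limbic merge, this yields 10 seeds.
#'
#' @param cerebellar_counts named numeric vector, id -> cerebellar voxels.
#' @param threshold exclusion bound (voxels; excluded when count <= it).
#' @param merge_ids ids merged into one network (default `c(9, 10)`),
#'   or `NULL`.
#' @return data.frame with columns `id` (character; merged entry named
#'   e.g. `"9+10"`), `cerebellar_voxels`, `retained`.
#' @export
select_networks <- function(cerebellar_counts, threshold = 30,
                            merge_ids = c(9, 10)) {
  stopifnot(all(cerebellar_counts >= 0))
  cnt <- cerebellar_counts
  if (is.null(names(cnt))) names(cnt) <- as.character(seq_along(cnt))
  if (!is.null(merge_ids)) {
    key <- as.character(merge_ids)
    if (all(key %in% names(cnt))) {
      merged <- sum(cnt[key])
      cnt <- cnt[!names(cnt) %in% key]
      cnt[paste(merge_ids, collapse = "+")] <- merged
    }
  }
  out <- data.frame(id = names(cnt),
                    cerebellar_voxels = as.numeric(cnt),
                    retained = as.numeric(cnt) > threshold,
                    stringsAsFactors = FALSE)
  if (!any(out$retained)) warning("no networks retained")
  out
}

#' Erode a binary mask by one voxel layer
#'
#' Morphological erosion: with the default full 3x3x3 structuring element
#' a voxel survives only if it and all 26 neighbours are in the mask
#' (voxels outside the grid count as background). The 6-connectivity
#' cross element is available as an option. Erosion is anti-extensive
#' (output is a subset of input) and monotone.
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (full cube, default) or 6 (cross).
#' @return eroded logical array.
#' @export
erode_one_layer <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (connectivity == 26L) {
    # the full box element is separable: 3-tap min filter along each axis
    out <- mask
    for (ax in 1:3) {
      off_p <- off_m <- c(0L, 0L, 0L)
      off_p[ax] <- 1L; off_m[ax] <- -1L
      out <- out & shift3d(out, off_p) & shift3d(out, off_m)
    }
    out
  } else if (connectivity == 6L) {
    off <- neighbor_offsets(6L)
    out <- mask
    for (r in seq_len(nrow(off))) out <- out & shift3d(mask, off[r, ])
    out
  } else stop("connectivity must be 6 or 26")
}

#' Build the analysis seed set from cortical and cerebellar parcellations
#'
#' The full seed-construction recipe: split the cortical label volume into
#' per-network masks, merge the limbic pair, exclude networks with minimal
#' (`<= threshold` voxels) cerebellar representation, and erode each
#' retained mask by one voxel layer.
#'
#' @param cortical_lv cortical [label_volume()].
#' @param cerebellar_lv canonical cerebellar [label_volume()] (same ids).
#' @param threshold cerebellar-representation exclusion bound (voxels).
#' @param merge_ids ids merged into the limbic seed, or `NULL`.
#' @param connectivity erosion structuring element (26 or 6).
#' @return list of class `seed_set`: `seeds` (named list of eroded logical
#'   masks), `roster` (data.frame: id, name, cerebellar voxels, eroded
#'   voxel count, retained flag).
#' @export
build_seed_set <- function(cortical_lv, cerebellar_lv, threshold = 30,
                           merge_ids = NULL, connectivity = 26L) {
  cort <- split_labels(cortical_lv)
  cere <- split_labels(cerebellar_lv)
  counts <- stats::setNames(numeric(length(cort)), names(cort))
  present <- vapply(cere, sum, numeric(1))
  counts[names(present)] <- present
  sel <- select_networks(counts, threshold = threshold, merge_ids = merge_ids)
  name_of <- function(id) {
    ids <- strsplit(id, "+", fixed = TRUE)[[1]]
    paste(cortical_lv$labels$name[match(as.integer(ids),
                                        cortical_lv$labels$id)],
          collapse = " + ")
  }
  seeds <- list()
  roster <- data.frame(id = sel$id,
                       name = vapply(sel$id, name_of, character(1)),
                       cerebellar_voxels = sel$cerebellar_voxels,
                       eroded_voxels = NA_real_, retained = sel$retained,
                       stringsAsFactors = FALSE)
  for (i in which(sel$retained)) {
    ids <- as.integer(strsplit(sel$id[i], "+", fixed = TRUE)[[1]])
    m <- if (length(ids) > 1L) merge_labels(cort, ids) else
      cort[[as.character(ids)]]
    em <- erode_one_layer(m, connectivity)
    if (!any(em))
      warning("seed ", sel$id[i], " empty after erosion; keeping unretained")
    seeds[[sel$id[i]]] <- em
    roster$eroded_voxels[i] <- sum(em)
  }
  roster$retained <- roster$retained & !is.na(roster$eroded_voxels) &
    roster$eroded_voxels > 0
  structure(list(seeds = seeds[roster$id[roster$retained]], roster = roster),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", sum(x$roster$retained), " retained of ",
      nrow(x$roster), " networks\n", sep = "")
  invisible(x)
}
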