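#' Binarize a z map at an uncorrected one-sided threshold
#'
#' Voxels with one-sided p < alpha (z >= qnorm(1 - alpha)) are set TRUE,
#' restricted to the analysis mask. This is the display-map convention
#' (p < 0.05 uncorrected) used for overlap scoring.
#'
#' @param zmap 3D z array or `group_map`.
#' @param alpha one-sided significance level, in (0, 1) exclusive.
#' @param mask logical 3D mask (e.g. cerebellum); defaults to the
#'   `group_map`'s own mask.
#' @return logical 3D array.
#' @export
binarize_map <- function(zmap, alpha = 0.05, mask = NULL) {
  if (inherits(zmap, "group_map")) {
    if (is.null(mask)) mask <- zmap$mask
    zmap <- zmap$z
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)")
  out <- !is.na(zmap) & zmap >= stats::qnorm(1 - alpha)
  if (!is.null(mask)) out <- out & mask
  out
}

#' Voxel confusion counts of a group map against a canonical map
#'
#' Positive voxels are those inside the canonical network map; negative
#' voxels are cerebellar voxels outside it. True positives are group-map
#' voxels intersecting the canonical map; false positives are group-map
#' voxels in the cerebellum but outside the canonical map; true negatives
#' are the negatives minus the false positives. Group-map voxels outside
#' the cerebellum are ignored.
#'
#' @param group_mask logical 3D group (thresholded) map.
#' @param canonical_mask logical 3D canonical network map; must be a
#'   subset of the cerebellum mask.
#' @param cerebellum_mask logical 3D cerebellum mask.
#' @return list of class `confusion_counts`: tp, fp, tn, fn, p, n.
#' @export
confusion_counts <- function(group_mask, canonical_mask, cerebellum_mask) {
  stopifnot(all(dim(group_mask) == dim(canonical_mask)),
            all(dim(group_mask) == dim(cerebellum_mask)))
  if (any(canonical_mask & !cerebellum_mask))
    stop("canonical map must lie inside the cerebellum mask")
  g <- group_mask & cerebellum_mask
  p <- sum(canonical_mask)
  n <- sum(cerebellum_mask & !canonical_mask)
  tp <- sum(g & canonical_mask)
  fp <- sum(g & !canonical_mask)
  structure(list(tp = tp, fp = fp, tn = n - fp, fn = p - tp, p = p, n = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP ", x$tp, " FP ", x$fp, " TN ", x$tn,
      " FN ", x$fn, " (P ", x$p, ", N ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Overlap accuracy, sensitivity, and specificity
#'
#' accuracy = (TP + TN) / (P + N), sensitivity = TP / P,
#' specificity = TN / N. Metrics whose denominator is zero are returned
#' as NA with a warning.
#'
#' @param cc a [confusion_counts()].
#' @return named list: accuracy, sensitivity, specificity (each in
#'   \[0, 1\] or NA).
#' @export
overlap_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$p == 0 || cc$n == 0)
    warning("undefined overlap metric: P or N is zero")
  list(accuracy = if (cc$p + cc$n > 0) (cc$tp + cc$tn) / (cc$p + cc$n) else NA_real_,
       sensitivity = if (cc$p > 0) cc$tp / cc$p else NA_real_,
       specificity = if (cc$n > 0) cc$tn / cc$n else NA_real_)
}

#' Dice coefficient between two masks
#'
#' 2|A n B| / (|A| + |B|); reported alongside the primary
#' accuracy/sensitivity/specificity metrics and used to score recovery of
#' planted territories.
#'
#' @param a,b logical arrays on one grid.
#' @return Dice coefficient in \[0, 1\] (NA if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}

#' Winner-take-all network assignment
#'
#' Labels every mask voxel with the network whose statistic map is
#' maximal there; exact ties go to the lowest network id and are counted
#' (attribute `n_ties`).
#'
#' @param zmaps named list (>= 2) of 3D stat arrays on one grid; names are
#'   network ids.
#' @param mask logical 3D array of voxels to assign.
#' @return [label_volume()] of assignments; attribute `n_ties` on the
#'   data carries the tie count.
#' @export
winner_take_all <- function(zmaps, mask) {
  if (length(zmaps) < 2) stop("need at least 2 network maps")
  ids <- as.integer(if (is.null(names(zmaps))) seq_along(zmaps)
                    else names(zmaps))
  ord <- order(ids)           # so "first" tie-breaking = lowest network id
  ids <- ids[ord]; zmaps <- zmaps[ord]
  v <- vapply(zmaps, function(m) {
    a <- if (inherits(m, "group_map")) m$z else m
    a[mask]
  }, numeric(sum(mask)))
  v[is.na(v)] <- -Inf
  best <- max.col(v, ties.method = "first")   # lowest list position wins ties
  is_tie <- rowSums(v == v[cbind(seq_len(nrow(v)), best)]) > 1
  lab <- array(0L, dim = dim(mask))
  lab[mask] <- ids[best]
  lv <- label_volume(lab, diag(4),
                     data.frame(id = ids, name = paste0("network_", ids),
                                stringsAsFactors = FALSE))
  attr(lv, "n_ties") <- sum(is_tie)
  lv
}
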