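#' Per-subject cluster connectivity strength
#'
#' Pearson correlation between the mean time course of the combined
#' significant clusters of one contrast and the cortical seed time
#' course, computed on the same preprocessed series as the first level.
#'
#' @param b a preprocessed [bold_series()].
#' @param cluster_masks list of logical 3D cluster masks (all clusters of
#'   one contrast; their union is used), or a single mask.
#' @param seed_tc the seed time course (same length as the series).
#' @return Pearson r (NA with a warning if either series has zero
#'   variance).
#' @export
subject_cluster_fc <- function(b, cluster_masks, seed_tc) {
  if (is.list(cluster_masks)) cluster_masks <- Reduce(`|`, cluster_masks)
  if (!any(cluster_masks)) stop("cluster mask is empty")
  tc <- extract_mean_timecourse(b, cluster_masks)
  if (length(seed_tc) != length(tc))
    stop("seed time course length does not match series")
  if (stats::sd(tc) == 0 || stats::sd(seed_tc) == 0) {
    warning("zero-variance series; correlation undefined")
    return(NA_real_)
  }
  stats::cor(tc, seed_tc)
}

#' Bonferroni-corrected per-test threshold
#'
#' alpha / m; for the study's 5-scale x 7-contrast matrix this is
#' 0.05 / 35 = 0.001428... . `rounded = TRUE` applies the rounded
#' p < 0.001 convention instead.
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests (default 35).
#' @param rounded use the rounded 0.001 cutoff.
#' @return per-test alpha.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 35, rounded = FALSE) {
  if (m < 1) stop("m must be >= 1")
  if (rounded) 0.001 else alpha / m
}

#' Correlate cluster connectivity with symptom scales
#'
#' Pairwise-complete Pearson correlation of each contrast's per-subject
#' connectivity values against each symptom scale, with two-sided p
#' values and Bonferroni control over the whole matrix. Cells with fewer
#' than 3 complete pairs are marked not computable.
#'
#' @param fc_values numeric matrix, subjects x contrasts (column names =
#'   contrast labels).
#' @param scores data.frame, subjects x scales (NA = missing).
#' @param alpha family-wise level (default 0.05).
#' @param rounded use the rounded 0.001 per-test cutoff.
#' @return data.frame of class `correlation_matrix`: scale, contrast, r,
#'   p, n, significant; attributes `threshold`, `m`.
#' @export
correlate_scales <- function(fc_values, scores, alpha = 0.05,
                             rounded = FALSE) {
  fc_values <- as.matrix(fc_values)
  stopifnot(nrow(fc_values) == nrow(scores))
  if (is.null(colnames(fc_values)))
    colnames(fc_values) <- paste0("contrast_", seq_len(ncol(fc_values)))
  m <- ncol(fc_values) * ncol(scores)
  thr <- bonferroni_threshold(alpha, m, rounded)
  out <- expand.grid(scale = colnames(scores),
                     contrast = colnames(fc_values),
                     stringsAsFactors = FALSE)
  out$r <- out$p <- NA_real_
  out$n <- 0L
  for (i in seq_len(nrow(out))) {
    xs <- scores[[out$scale[i]]]
    ys <- fc_values[, out$contrast[i]]
    ok <- stats::complete.cases(xs, ys)
    out$n[i] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(xs[ok]) > 0 && stats::sd(ys[ok]) > 0) {
      ct <- stats::cor.test(xs[ok], ys[ok], alternative = "two.sided")
      out$r[i] <- unname(ct$estimate)
      out$p[i] <- ct$p.value
    }
  }
  out$significant <- !is.na(out$p) & out$p < thr
  attr(out, "threshold") <- thr
  attr(out, "m") <- m
  class(out) <- c("correlation_matrix", class(out))
  out
}
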