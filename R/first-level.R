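# OLS of every column of Y (T x V) on X (T x p); returns beta for one
# column of interest, its t statistic, residual dof, and a zero-variance
# flag. Classical homoskedastic standard errors.
ols_column_t <- function(x, y, col) {
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  xtxinv <- solve(crossprod(x))
  beta <- xtxinv %*% crossprod(x, y)
  res <- y - x %*% beta
  dof <- nrow(x) - ncol(x)
  s2 <- colSums(res^2) / dof
  if (is.character(col)) col <- match(col, colnames(x))
  se <- sqrt(s2 * xtxinv[col, col])
  bb <- beta[col, ]
  # constant (zero-variance) series: t defined as 0, flagged
  vy <- colSums(y^2) - colSums(y)^2 / nrow(y)
  degenerate <- vy < .Machine$double.eps^0.75 * nrow(y)
  tt <- ifelse(degenerate | (se == 0 & bb == 0), 0,
               ifelse(se == 0, sign(bb) * Inf, bb / se))
  list(beta = bb, t = tt, dof = dof, degenerate = degenerate)
}

#' Voxelwise first-level GLM
#'
#' Regresses every voxel's time course inside the mask on the design
#' matrix by ordinary least squares and returns the seed-column beta, its
#' t statistic and the standard-normal z equivalent, with residual
#' degrees of freedom = time points - design columns. Zero-variance
#' voxels get t = 0 and are flagged.
#'
#' @param b a [bold_series()] (typically smoothed + band-passed).
#' @param mask logical 3D array restricting the fit (e.g. cerebellum).
#' @param design design matrix from [build_first_level_design()].
#' @param stat_col name or index of the column of interest (default
#'   `"seed"`).
#' @return object of class `fc_map`: 3D arrays `beta`, `t`, `z` (NA
#'   outside the mask), `dof`, `mask`, logical `degenerate` array.
#' @export
fit_voxelwise_glm <- function(b, mask, design, stat_col = "seed") {
  stopifnot(inherits(b, "bold_series"))
  d <- dim(b$data)
  if (!all(dim(mask) == d[1:3])) stop("mask grid does not match series")
  if (nrow(design) != d[4])
    stop("design rows (", nrow(design), ") != time points (", d[4], ")")
  y <- matrix(b$data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE]
  fit <- ols_column_t(design, t(y), col = stat_col)
  as_vol <- function(v) {
    a <- array(NA_real_, dim = d[1:3]); a[mask] <- v; a
  }
  deg <- array(FALSE, dim = d[1:3]); deg[mask] <- fit$degenerate
  structure(list(beta = as_vol(fit$beta), t = as_vol(fit$t),
                 z = as_vol(t_to_z(fit$t, fit$dof)), dof = fit$dof,
                 mask = mask, degenerate = deg), class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat("<fc_map> ", sum(x$mask), " voxels, dof ", x$dof, ", ",
      sum(x$degenerate), " degenerate\n", sep = "")
  invisible(x)
}

#' Convert t statistics to standard-normal z scores
#'
#' Quantile transform z = qnorm(pt(t; dof)), computed on the log scale in
#' the mirrored tail so extreme t survive without underflow. Monotone and
#' sign-preserving; |z| is clamped at 38 (beyond double-precision tail
#' resolution) with a warning.
#'
#' @param t numeric vector of t statistics.
#' @param dof residual degrees of freedom (>= 1).
#' @return z scores, same length.
#' @export
t_to_z <- function(t, dof) {
  if (dof < 1) stop("dof must be >= 1")
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- -stats::qnorm(stats::pt(t[pos], dof, lower.tail = FALSE,
                                    log.p = TRUE), log.p = TRUE)
  z[!pos & !is.na(t)] <- stats::qnorm(
    stats::pt(t[!pos & !is.na(t)], dof, lower.tail = TRUE, log.p = TRUE),
    log.p = TRUE)
  z[is.na(t)] <- NA_real_
  if (any(abs(z) > 38, na.rm = TRUE)) {
    warning("z scores clamped at |z| = 38")
    z <- pmin(38, pmax(-38, z))
  }
  z
}
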