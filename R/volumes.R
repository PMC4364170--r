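#' Label volume
#'
#' A 3D integer label grid with a voxel-to-world affine and a label table.
#' Label 0 is background. This is the container for parcellations, masks
#' converted to labels, and cluster label maps.
#'
#' @param data 3D integer array (0 = background).
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param labels named integer vector or data.frame mapping label ids to
#'   names. May be `NULL`, in which case names are generated from the ids
#'   present.
#' @return An object of class `label_volume` with elements `data`, `affine`,
#'   `labels` (data.frame with columns `id`, `name`).
#' @export
label_volume <- function(data, affine = diag(4), labels = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (any(data < 0, na.rm = TRUE)) stop("label data must be nonnegative")
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  storage.mode(data) <- "integer"
  ids <- sort(unique(as.integer(data)))
  ids <- ids[ids != 0L]
  if (is.null(labels)) {
    labels <- data.frame(id = ids,
                         name = paste0("label_", ids, recycle0 = TRUE),
                         stringsAsFactors = FALSE)
  } else if (!is.data.frame(labels)) {
    labels <- data.frame(id = as.integer(labels), name = names(labels),
                         stringsAsFactors = FALSE)
  }
  structure(list(data = data, affine = affine, labels = labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = "x"),
      " grid, ", nrow(x$labels), " labels, ",
      sum(x$data != 0L), " foreground voxels\n", sep = "")
  invisible(x)
}

#' BOLD time series
#'
#' A 4D (x, y, z, t) array of BOLD signal in arbitrary units with its
#' repetition time.
#'
#' @param data 4D numeric array, last dimension time.
#' @param tr_seconds repetition time in seconds.
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(data, tr_seconds) {
  stopifnot(length(dim(data)) == 4L, tr_seconds > 0)
  if (dim(data)[4] < 2L) stop("need at least 2 time points")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  structure(list(data = data, tr_seconds = tr_seconds), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_series> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " volumes, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

n_volumes <- function(b) dim(b$data)[4]

# internal constructor for hot paths: skips the finiteness scan, which is
# O(voxels x time) and already guaranteed by the public constructors
new_bold_series <- function(data, tr_seconds)
  structure(list(data = data, tr_seconds = tr_seconds), class = "bold_series")

#' Shift a 3D array by an integer offset, zero/FALSE padding
#'
#' Voxels shifted in from outside the grid take the background value
#' (0 for numeric, FALSE for logical arrays).
#'
#' @param a 3D array.
#' @param off integer offset c(dx, dy, dz): `output[i] = input[i - off]`.
#' @return shifted array, same dim and type.
#' @keywords internal
shift3d <- function(a, off) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { dst[[k]] <- (1 + o):d[k]; src[[k]] <- 1:(d[k] - o) }
    else        { dst[[k]] <- 1:(d[k] + o); src[[k]] <- (1 - o):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# all 26 (or 6) neighbor offsets, excluding the origin
neighbor_offsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    m <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    m <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    m <- m[rowSums(abs(m)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
  unname(m)
}

#' Read a NIfTI file as a label volume
#' @param path NIfTI file.
#' @return `label_volume`.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  label_volume(round(as.array(img)), affine = aff)
}

#' Write a label volume or 3D/4D array to NIfTI
#' @param x `label_volume`, `bold_series`, or array.
#' @param path destination file.
#' @param affine 4x4 affine for plain arrays (defaults to identity).
#' @param tr_seconds time step stored in pixdim\[4\] for 4D data.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, affine = diag(4), tr_seconds = NULL) {
  if (inherits(x, "label_volume")) { arr <- x$data; affine <- x$affine }
  else if (inherits(x, "bold_series")) { arr <- x$data; tr_seconds <- x$tr_seconds }
  else arr <- x
  if (is.logical(arr)) { arr <- array(as.integer(arr), dim = dim(arr)) }
  pd <- if (!is.null(tr_seconds) && length(dim(arr)) == 4L)
    c(rep(abs(diag(affine)[1:3]), 1), tr_seconds) else NULL
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  if (!is.null(pd)) RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a BOLD series
#' @param path NIfTI file.
#' @param tr_seconds override the TR stored in the header (optional).
#' @return `bold_series`.
#' @export
read_bold_series <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else
      stop("TR not stored in header; pass tr_seconds")
  }
  bold_series(as.array(img), tr_seconds)
}
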