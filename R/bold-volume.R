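#' 4D BOLD volume container
#'
#' A `bold_volume` carries a 4D intensity array (x, y, z, time), a 4x4
#' voxel-to-mm affine, and the repetition time. It is the carrier of all
#' voxel-wise computation in the package.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm affine matrix (RAS+; 0-based voxel indices).
#' @param tr_s Repetition time in seconds.
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(data, affine = diag(4), tr_s) {
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 4D array (x, y, z, t), got ",
         length(dim(data)), " dimensions.", call. = FALSE)
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    stop("`affine` must be a 4x4 matrix.", call. = FALSE)
  }
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("`affine` must be invertible.", call. = FALSE)
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    stop("`tr_s` must be a single positive number.", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("BOLD data contain non-finite values.", call. = FALSE)
  }
  structure(
    list(data = data, affine = affine, tr_s = tr_s),
    class = "bold_volume"
  )
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_volume> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  vs <- voxel_size_mm(x$affine)
  cat(sprintf("  voxel size: %g x %g x %g mm\n", vs[1], vs[2], vs[3]))
  invisible(x)
}

#' @export
dim.bold_volume <- function(x) dim(x$data)

n_volumes <- function(bold) dim(bold$data)[4]

#' Voxel size from an affine
#'
#' Column norms of the 3x3 rotation/scaling block, in mm per voxel step.
#'
#' @param affine 4x4 affine matrix.
#' @return Numeric length-3 vector of voxel edge lengths (mm).
#' @export
voxel_size_mm <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Map voxel indices to mm coordinates
#'
#' Applies the affine to 1-based voxel indices (converted internally to the
#' 0-based convention the affine is defined over).
#'
#' @param ijk Integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @param affine 4x4 voxel-to-mm affine.
#' @return Matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  h <- cbind(ijk - 1, 1)             # 0-based homogeneous coordinates
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# Flatten the spatial dimensions: returns t x v matrix of in-mask series.
mask_series <- function(bold, mask) {
  d <- dim(bold$data)
  mat <- matrix(bold$data, prod(d[1:3]), d[4])
  t(mat[as.vector(mask), , drop = FALSE])
}

# Inverse of mask_series for 3D per-voxel statistics.
unmask_map <- function(values, mask) {
  out <- array(0, dim = dim(mask))
  out[mask] <- values
  out
}

#' Read a 4D NIfTI file as a `bold_volume`
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param tr_s Repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header's temporal pixdim.
#' @return A `bold_volume`.
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop("Expected a 4D NIfTI at ", path, ", got ", length(d), "D.",
         call. = FALSE)
  }
  if (is.null(tr_s)) {
    pd <- attr(img, "pixdim")
    tr_s <- if (length(pd) >= 4) pd[4] else NA_real_
    if (!is.finite(tr_s) || tr_s <= 0) {
      stop("TR not recoverable from header of ", path,
           "; pass `tr_s` explicitly.", call. = FALSE)
    }
  }
  bold_volume(array(as.numeric(img), dim = d),
              affine = unclass(RNifti::xform(img)), tr_s = tr_s)
}

#' Write a `bold_volume` or 3D map to NIfTI
#'
#' @param x A `bold_volume`, or a 3D numeric/logical array.
#' @param path Output .nii or .nii.gz path.
#' @param affine Affine for bare arrays (ignored for `bold_volume`).
#' @param tr_s TR recorded in the header for 4D data.
#' @return `path`, invisibly.
#' @export
write_nifti_vol <- function(x, path, affine = diag(4), tr_s = 1) {
  if (inherits(x, "bold_volume")) {
    arr <- x$data; affine <- x$affine; tr_s <- x$tr_s
  } else {
    arr <- x * 1  # logical -> numeric
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  if (length(dim(arr)) == 4L) {
    RNifti::pixdim(img) <- c(voxel_size_mm(affine), tr_s)
  } else {
    RNifti::pixdim(img) <- voxel_size_mm(affine)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D mask NIfTI
#'
#' @param path Path to the mask file.
#' @return Logical 3D array (non-zero voxels are `TRUE`).
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("Expected a 3D mask NIfTI at ", path, ".", call. = FALSE)
  }
  array(as.numeric(img) != 0, dim = dim(img))
}
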