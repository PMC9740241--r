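#' Three-dimensional image volume with grid metadata
#'
#' A `bos_volume` bundles a 3-D numeric array with its voxel spacing (mm) and
#' a 4x4 voxel-to-world affine.  Voxel indices are 0-based in the affine
#' convention: the world position of array element `[i, j, k]` (1-based in R)
#' is `affine %*% c(i - 1, j - 1, k - 1, 1)`.  Voxel centers sit exactly on
#' that lattice.
#'
#' @param voxels 3-D numeric or logical array.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal
#'   spacing matrix with zero origin.
#' @param units free-text unit tag for the voxel values (e.g. "HU",
#'   "mg/cm^3").
#' @return An object of class `bos_volume`.
#' @export
bos_volume <- function(voxels, spacing, affine = NULL, units = "") {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be strictly positive")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         affine = affine, units = units),
    class = "bos_volume"
  )
}

#' @export
print.bos_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bos_volume> %d x %d x %d voxels, spacing %s mm%s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Voxel-index / world-coordinate conversion
#'
#' `voxel_to_world()` maps 1-based R array indices to world mm coordinates;
#' `world_to_voxel()` is its inverse (returning fractional 1-based indices).
#'
#' @param vol a [bos_volume].
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind_matrix(idx)
  h <- cbind(idx - 1, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind_matrix(xyz)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE] + 1
}

rbind_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' World coordinates of every voxel center
#'
#' @param vol a [bos_volume].
#' @return an n-voxel x 3 matrix in array (column-major) order.
#' @keywords internal
voxel_center_grid <- function(vol) {
  d <- dim(vol$voxels)
  idx <- cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2])
  )
  voxel_to_world(vol, idx)
}

#' Trilinear interpolation of a volume at world points
#'
#' Samples outside the grid return `fill`.
#'
#' @param vol a [bos_volume].
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @param fill value returned outside the grid.
#' @return numeric vector of length n.
#' @export
sample_trilinear <- function(vol, xyz, fill = 0) {
  ijk <- world_to_voxel(vol, xyz)
  trilinear_cpp(vol$voxels, ijk, as.numeric(fill))
}

#' Nearest-neighbour sampling of a volume at world points
#' @inheritParams sample_trilinear
#' @export
sample_nearest <- function(vol, xyz, fill = 0) {
  ijk <- round(world_to_voxel(vol, xyz))
  d <- dim(vol$voxels)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- rep(as.numeric(fill), nrow(ijk))
  if (any(ok)) {
    lin <- (ijk[ok, 3] - 1) * d[1] * d[2] + (ijk[ok, 2] - 1) * d[1] + ijk[ok, 1]
    out[ok] <- vol$voxels[lin]
  }
  out
}

# ---------------------------------------------------------------------------
# Minimal single-file NIfTI-1 I/O.  No NIfTI reader is available in the
# dependency set, so the package carries a small writer/reader restricted to
# the subset it produces: uncompressed .nii, float32 or uint8 data, sform
# affine.  Not a general-purpose NIfTI implementation.
# ---------------------------------------------------------------------------

#' Write a volume as an uncompressed NIfTI-1 file
#'
#' @param vol a [bos_volume].
#' @param path output file path (".nii").
#' @param datatype "float32" or "uint8".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  d <- dim(vol$voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(if (datatype == "float32") 16L else 2L, 2) # datatype
  wi(if (datatype == "float32") 32L else 8L, 2) # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, vol$spacing, 0, 0, 0, 0))             # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_duration
  wf(0); wi(c(0L, 0L), 4)                       # toffset, glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 2L), 2)                              # qform_code=0, sform_code=2
  wf(rep(0, 6))                                 # quatern b,c,d + qoffset x,y,z
  A <- vol$affine
  wf(A[1, ]); wf(A[2, ]); wf(A[3, ])            # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  vals <- as.numeric(vol$voxels)
  if (datatype == "float32") {
    writeBin(vals, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(vals)), con, size = 1, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' @param path path to an uncompressed single-file .nii.
#' @return a [bos_volume].
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("not a NIfTI-1 file: ", path)
  dims <- ri(40, 2, 8)
  if (dims[1] != 3L) stop("only 3-D NIfTI volumes are supported")
  d <- dims[2:4]
  dt <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  srow <- rbind(rf(280, 4), rf(296, 4), rf(312, 4), c(0, 0, 0, 1))
  seek(con, where = vox_offset)
  n <- prod(d)
  vals <- switch(as.character(dt),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE,
                              endian = "little")),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    stop("unsupported NIfTI datatype code: ", dt))
  bos_volume(array(vals, dim = d), spacing = pixdim[2:4], affine = srow)
}
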