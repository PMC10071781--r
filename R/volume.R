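#' @title Volume, displacement-field and affine-transform containers
#' @description Lightweight S3 containers used throughout the package. A
#'   `pn_volume` is a 3D scalar grid with voxel spacing (mm) and a 3x4
#'   index-to-world affine (RAS convention, 0-based voxel indices). A
#'   `pn_field` is a dense per-voxel displacement field in voxel units with
#'   pull-warp semantics: the warped image reads the source at `x + u(x)`.
#'   A `pn_affine` maps output-grid voxel coordinates to input-grid voxel
#'   coordinates (also pull semantics).
#' @name volume-classes
NULL

#' Create a volume
#'
#' @param data numeric 3D array; all values must be finite.
#' @param spacing numeric length-3, mm per voxel along each axis; strictly
#'   positive.
#' @param affine 3x4 index-to-world matrix (RAS). Defaults to
#'   `cbind(diag(spacing), 0)`.
#' @param id character label carried through the pipeline.
#' @return A `pn_volume` object.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL, id = "volume") {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got dims: ",
         paste(dim(data), collapse = "x"))
  if (any(dim(data) < 2L))
    stop("all three grid dimensions must be >= 2, got ",
         paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  if (is.null(affine)) affine <- cbind(diag(spacing), c(0, 0, 0))
  affine <- matrix(as.numeric(affine), 3L, 4L)
  if (any(!is.finite(data)))
    stop("volume data contains non-finite values")
  structure(list(data = data, spacing = spacing, affine = affine,
                 id = as.character(id)[1]),
            class = "pn_volume")
}

#' @export
print.pn_volume <- function(x, ...) {
  cat(sprintf("<pn_volume '%s'> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$id, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Dimensions of a volume grid
#' @param x a `pn_volume`
#' @return integer length-3 grid shape.
#' @export
vol_dim <- function(x) dim(x$data)

#' Create a dense displacement field
#'
#' Displacements are in voxel units with 0-based indexing; the field defines
#' a pull warp (output voxel `x` samples the source at `x + u(x)`).
#'
#' @param u numeric 4D array `[nx, ny, nz, 3]`; must be finite everywhere.
#' @return A `pn_field` object.
#' @export
as_field <- function(u) {
  if (is.null(dim(u)) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("displacement field must be a 4D array with 3 components on the ",
         "4th axis, got dims: ", paste(dim(u), collapse = "x"))
  if (any(!is.finite(u))) stop("displacement field contains non-finite values")
  structure(list(u = u), class = "pn_field")
}

#' Zero displacement field on a grid
#' @param grid_shape integer length-3
#' @return A `pn_field` of zeros.
#' @export
zero_field <- function(grid_shape) {
  as_field(array(0, c(grid_shape, 3L)))
}

#' @export
print.pn_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$u, ncol = 3L)^2))
  cat(sprintf("<pn_field> grid %s, |u| max %.4g voxels, mean %.4g\n",
              paste(dim(x$u)[1:3], collapse = "x"), max(mag), mean(mag)))
  invisible(x)
}

#' Grid shape of a displacement field
#' @param x a `pn_field`
#' @return integer length-3.
#' @export
field_dim <- function(x) dim(x$u)[1:3]

#' Create an affine transform in voxel coordinates
#'
#' The transform maps 0-based output voxel coordinates `x` to input voxel
#' coordinates `M x + t` (pull convention, used for resampling).
#'
#' @param matrix 3x3 linear part; must be invertible
#'   (`abs(det) > 1e-9`).
#' @param translation numeric length-3 in voxel units.
#' @return A `pn_affine` object.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  m <- base::matrix(as.numeric(matrix), 3L, 3L)
  tr <- as.numeric(translation)
  if (length(tr) != 3L) stop("translation must have length 3")
  if (any(!is.finite(m)) || any(!is.finite(tr)))
    stop("affine transform must be finite")
  if (abs(det(m)) <= 1e-9)
    stop("affine linear part is singular (|det| <= 1e-9)")
  structure(list(matrix = m, translation = tr), class = "pn_affine")
}

#' Identity affine transform
#' @return A `pn_affine` equal to the identity map.
#' @export
affine_identity <- function() affine_transform(diag(3), c(0, 0, 0))

#' Invert an affine transform
#' @param transform a `pn_affine`
#' @return The inverse `pn_affine`.
#' @export
affine_invert <- function(transform) {
  mi <- solve(transform$matrix)
  affine_transform(mi, -mi %*% transform$translation)
}

#' Compose two affine transforms
#'
#' Returns the transform mapping `x` to `first(second(x))`, i.e. resampling
#' with the result equals resampling with `second` then with `first` applied
#' to the coordinates.
#'
#' @param first,second `pn_affine` objects
#' @return A `pn_affine`.
#' @export
affine_compose <- function(first, second) {
  affine_transform(first$matrix %*% second$matrix,
                   first$matrix %*% second$translation + first$translation)
}

#' Apply an affine transform to coordinate vectors
#' @param transform a `pn_affine`
#' @param px,py,pz numeric vectors of 0-based voxel coordinates
#' @return list with components `x`, `y`, `z`.
#' @keywords internal
affine_map_coords <- function(transform, px, py, pz) {
  m <- transform$matrix; tr <- transform$translation
  list(x = m[1, 1] * px + m[1, 2] * py + m[1, 3] * pz + tr[1],
       y = m[2, 1] * px + m[2, 2] * py + m[2, 3] * pz + tr[2],
       z = m[3, 1] * px + m[3, 2] * py + m[3, 3] * pz + tr[3])
}

#' @export
print.pn_affine <- function(x, ...) {
  cat("<pn_affine> voxel-space pull transform\n")
  print(cbind(x$matrix, t = x$translation))
  invisible(x)
}

# ---- NIfTI I/O ------------------------------------------------------------

.vol_to_nifti <- function(data, spacing, affine, descrip = NULL) {
  im <- RNifti::asNifti(data)
  RNifti::pixdim(im) <- spacing
  xf <- rbind(affine, c(0, 0, 0, 1))
  RNifti::`sform<-`(im, structure(xf, code = 2L))
}

#' Write a volume to a NIfTI-1 file
#' @param vol a `pn_volume`
#' @param path output file path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pn_volume"))
  im <- .vol_to_nifti(vol$data, vol$spacing, vol$affine)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#' @param path file path
#' @param id label for the volume; defaults to the file name
#' @return A `pn_volume`.
#' @export
read_volume <- function(path, id = NULL) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L) stop("expected a 3D NIfTI volume, got ",
                            length(d), " dimensions")
  xf <- RNifti::xform(im)
  as_volume(array(as.numeric(im), d), spacing = RNifti::pixdim(im)[1:3],
            affine = xf[1:3, , drop = FALSE],
            id = if (is.null(id)) basename(path) else id)
}

#' Write a displacement field to a 4D NIfTI-1 file
#'
#' The 4th dimension holds the 3 vector components; values are voxel-unit
#' displacements with pull-warp semantics (documented in the NIfTI
#' description field).
#'
#' @param field a `pn_field`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "pn_field"))
  im <- RNifti::asNifti(
    field$u,
    reference = list(descrip = "displacement field, voxel units, pull warp"))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a displacement field from a 4D NIfTI-1 file
#' @param path file path
#' @return A `pn_field`.
#' @export
read_field <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D NIfTI with 3 components on the 4th axis")
  as_field(array(as.numeric(im), d))
}
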