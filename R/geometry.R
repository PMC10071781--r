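#' @title Warping, field composition and differential checks
#' @description Deterministic geometric core: trilinear / nearest-neighbour
#'   pull-warping, displacement-field composition, Jacobian determinants and
#'   affine resampling. All coordinates are 0-based voxel indices and all
#'   displacements are in voxel units; samples falling outside the source
#'   grid contribute zero (constant padding), matching a zero PET/air
#'   background.
#' @name geometry
NULL

# 0-based coordinate arrays of a grid, first index varies fastest.
.grid_coords <- function(dm) {
  list(x = rep.int(0:(dm[1] - 1L), dm[2] * dm[3]),
       y = rep.int(rep(0:(dm[2] - 1L), each = dm[1]), dm[3]),
       z = rep(0:(dm[3] - 1L), each = dm[1] * dm[2]))
}

# Trilinear sampling of a 3D array at 0-based coordinates; zero outside.
.sample_linear <- function(arr, px, py, pz) {
  dm <- dim(arr); nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  out <- numeric(length(px))
  for (corner in 0:7) {
    dx <- corner %% 2L; dy <- (corner %/% 2L) %% 2L; dz <- corner %/% 4L
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    inb <- (ii >= 0) & (ii < nx) & (jj >= 0) & (jj < ny) & (kk >= 0) & (kk < nz)
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    ii[!inb] <- 0; jj[!inb] <- 0; kk[!inb] <- 0
    out <- out + (w * inb) * arr[1 + ii + nx * (jj + ny * kk)]
  }
  out
}

# Trilinear sampling together with the spatial gradient of the interpolant
# with respect to the sample coordinates. Returns list(val, gx, gy, gz).
.sample_linear_grad <- function(arr, px, py, pz) {
  dm <- dim(arr); nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  val <- gx <- gy <- gz <- numeric(length(px))
  for (corner in 0:7) {
    dx <- corner %% 2L; dy <- (corner %/% 2L) %% 2L; dz <- corner %/% 4L
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    inb <- (ii >= 0) & (ii < nx) & (jj >= 0) & (jj < ny) & (kk >= 0) & (kk < nz)
    wx <- if (dx) fx else 1 - fx
    wy <- if (dy) fy else 1 - fy
    wz <- if (dz) fz else 1 - fz
    sx <- if (dx) 1 else -1; sy <- if (dy) 1 else -1; sz <- if (dz) 1 else -1
    ii[!inb] <- 0; jj[!inb] <- 0; kk[!inb] <- 0
    v <- inb * arr[1 + ii + nx * (jj + ny * kk)]
    val <- val + wx * wy * wz * v
    gx <- gx + sx * wy * wz * v
    gy <- gy + wx * sy * wz * v
    gz <- gz + wx * wy * sz * v
  }
  list(val = val, gx = gx, gy = gy, gz = gz)
}

# Trilinear sampling of several same-shaped arrays at shared coordinates
# (one pass over the 8 corners). Returns a list of value vectors.
.sample_linear_multi <- function(srcs, px, py, pz) {
  dm <- dim(srcs[[1]]); nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  outs <- rep(list(numeric(length(px))), length(srcs))
  for (corner in 0:7) {
    dx <- corner %% 2L; dy <- (corner %/% 2L) %% 2L; dz <- corner %/% 4L
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    inb <- (ii >= 0) & (ii < nx) & (jj >= 0) & (jj < ny) & (kk >= 0) & (kk < nz)
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    ii[!inb] <- 0; jj[!inb] <- 0; kk[!inb] <- 0
    idx <- 1 + ii + nx * (jj + ny * kk)
    w <- w * inb
    for (s in seq_along(srcs)) outs[[s]] <- outs[[s]] + w * srcs[[s]][idx]
  }
  outs
}

# Nearest-neighbour sampling; zero outside.
.sample_nearest <- function(arr, px, py, pz) {
  dm <- dim(arr); nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  ii <- round(px); jj <- round(py); kk <- round(pz)
  inb <- (ii >= 0) & (ii < nx) & (jj >= 0) & (jj < ny) & (kk >= 0) & (kk < nz)
  ii[!inb] <- 0; jj[!inb] <- 0; kk[!inb] <- 0
  inb * arr[1 + ii + nx * (jj + ny * kk)]
}

# Adjoint of trilinear sampling: scatter-add `val` with trilinear weights at
# the given coordinates into a zero grid of shape `dm`. Duplicate targets
# are summed in C via sparse-matrix construction.
.scatter_linear <- function(dm, px, py, pz, val) {
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  idx_all <- vector("list", 8L); val_all <- vector("list", 8L)
  for (corner in 0:7) {
    dx <- corner %% 2L; dy <- (corner %/% 2L) %% 2L; dz <- corner %/% 4L
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    inb <- (ii >= 0) & (ii < nx) & (jj >= 0) & (jj < ny) & (kk >= 0) & (kk < nz)
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    idx_all[[corner + 1L]] <- (1 + ii + nx * (jj + ny * kk))[inb]
    val_all[[corner + 1L]] <- (w * val)[inb]
  }
  idx <- unlist(idx_all, use.names = FALSE)
  if (length(idx) == 0L) return(array(0, dm))
  sm <- Matrix::sparseMatrix(i = idx, j = rep.int(1L, length(idx)),
                             x = unlist(val_all, use.names = FALSE),
                             dims = c(nx * ny * nz, 1L))
  array(as.numeric(sm), dm)
}

#' Warp a volume with a displacement field (pull semantics)
#'
#' The output value at voxel `x` is the source sampled at `x + u(x)` by
#' trilinear (`"linear"`) or nearest-neighbour (`"nearest"`) interpolation;
#' samples outside the source grid return 0. The output grid equals the
#' field grid.
#'
#' @param source a `pn_volume`
#' @param field a `pn_field`; its grid defines the output grid
#' @param mode `"linear"` or `"nearest"`
#' @return A warped `pn_volume` on the field grid.
#' @export
warp_volume <- function(source, field, mode = c("linear", "nearest")) {
  stopifnot(inherits(source, "pn_volume"), inherits(field, "pn_field"))
  mode <- match.arg(mode)
  dm <- field_dim(field)
  g <- .grid_coords(dm)
  n <- prod(dm)
  u <- field$u
  px <- g$x + u[seq_len(n)]
  py <- g$y + u[n + seq_len(n)]
  pz <- g$z + u[2 * n + seq_len(n)]
  vals <- if (mode == "linear") .sample_linear(source$data, px, py, pz)
          else .sample_nearest(source$data, px, py, pz)
  as_volume(array(vals, dm), spacing = source$spacing, affine = source$affine,
            id = source$id)
}

#' Warp an integer label volume (nearest neighbour)
#'
#' Labels are pull-warped by nearest-neighbour interpolation so that label
#' identities are never averaged; output labels are a subset of the input
#' labels plus background 0.
#'
#' @param labels a `pn_volume` holding integer labels
#' @param field a `pn_field`
#' @return A warped label `pn_volume`.
#' @export
warp_labels <- function(labels, field) {
  stopifnot(inherits(labels, "pn_volume"))
  if (any(labels$data != round(labels$data)))
    stop("warp_labels requires an integer label volume")
  warp_volume(labels, field, mode = "nearest")
}

#' Compose two displacement fields
#'
#' Returns `w` with `w(x) = second(x) + first(x + second(x))` (`first`
#' interpolated trilinearly, zero outside). Pull-warping with `w` equals
#' warping with `first` and then warping the result with `second`, up to
#' interpolation error.
#'
#' @param first,second `pn_field` objects on the same grid
#' @return The composed `pn_field`.
#' @export
compose_displacements <- function(first, second) {
  stopifnot(inherits(first, "pn_field"), inherits(second, "pn_field"))
  d1 <- field_dim(first); d2 <- field_dim(second)
  if (!identical(d1, d2))
    stop("field grids differ: ", paste(d1, collapse = "x"), " vs ",
         paste(d2, collapse = "x"))
  g <- .grid_coords(d1)
  n <- prod(d1)
  u2 <- second$u
  px <- g$x + u2[seq_len(n)]
  py <- g$y + u2[n + seq_len(n)]
  pz <- g$z + u2[2 * n + seq_len(n)]
  w <- array(0, c(d1, 3L))
  for (comp in 1:3) {
    w[, , , comp] <- array(u2[(comp - 1) * n + seq_len(n)] +
                             .sample_linear(first$u[, , , comp], px, py, pz),
                           d1)
  }
  as_field(w)
}

# Per-axis derivative with central differences in the interior and
# one-sided differences at the two boundary slices.
.deriv_axis <- function(arr, axis) {
  dm <- dim(arr); n <- dm[axis]
  if (n < 3L) stop("grid must have >= 3 voxels per axis for derivatives")
  idx_p <- c(2:n, n); idx_m <- c(1L, 1:(n - 1L))
  denom <- c(1, rep(2, n - 2L), 1)
  sel <- function(i) switch(axis,
                            arr[i, , , drop = FALSE],
                            arr[, i, , drop = FALSE],
                            arr[, , i, drop = FALSE])
  d <- sel(idx_p) - sel(idx_m)
  shape_denom <- switch(axis,
                        array(denom, dm),
                        array(rep(denom, each = dm[1]), dm),
                        array(rep(denom, each = dm[1] * dm[2]), dm))
  array(d, dm) / shape_denom
}

#' Jacobian determinant of a deformation
#'
#' Computes `det(d(x + u)/dx)` per voxel with central differences in the
#' interior and one-sided differences on the boundary. Values `<= 0`
#' indicate folding of the deformation.
#'
#' @param field a `pn_field` on a grid with at least 3 voxels per axis
#' @return A `pn_volume` of determinants.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "pn_field"))
  dm <- field_dim(field)
  if (any(dm < 3L)) stop("jacobian requires >= 3 voxels per axis")
  # J[r, c] = d(phi_r)/d(x_c), phi = x + u
  J <- vector("list", 9L)
  for (r in 1:3) for (cc in 1:3) {
    d <- .deriv_axis(field$u[, , , r], cc)
    if (r == cc) d <- d + 1
    J[[(r - 1) * 3 + cc]] <- d
  }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
         J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
         J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  as_volume(det, id = "jacobian")
}

#' Resample a volume under an affine transform
#'
#' The output value at 0-based voxel `x` is the input sampled trilinearly at
#' `M x + t` with zero padding. The identity transform with an unchanged
#' grid returns the input bit-exactly.
#'
#' @param volume a `pn_volume`
#' @param transform a `pn_affine` (pull convention: output voxel to input
#'   voxel coordinates)
#' @param out_shape integer length-3 output grid; defaults to the input grid
#' @param mode `"linear"` or `"nearest"`
#' @return A resampled `pn_volume`.
#' @export
apply_affine <- function(volume, transform, out_shape = NULL,
                         mode = c("linear", "nearest")) {
  stopifnot(inherits(volume, "pn_volume"), inherits(transform, "pn_affine"))
  mode <- match.arg(mode)
  if (is.null(out_shape)) out_shape <- vol_dim(volume)
  out_shape <- as.integer(out_shape)
  g <- .grid_coords(out_shape)
  p <- affine_map_coords(transform, g$x, g$y, g$z)
  vals <- if (mode == "linear") .sample_linear(volume$data, p$x, p$y, p$z)
          else .sample_nearest(volume$data, p$x, p$y, p$z)
  as_volume(array(vals, out_shape), spacing = volume$spacing,
            affine = volume$affine, id = volume$id)
}

#' Resample through a deformable-then-affine chain in one interpolation
#'
#' The output value at template voxel `x` is the source sampled at
#' `A(x + u(x))`: the composed mapping of a pull-warp followed by a pull
#' affine, evaluated with a single trilinear interpolation. Composing the
#' chain avoids the cumulative blur of resampling twice; with a zero
#' field the result is exactly the affine resampling.
#'
#' @param source a `pn_volume` (typically individual space)
#' @param field a `pn_field` on the output grid
#' @param transform a `pn_affine` mapping warped coordinates to source
#'   voxel coordinates
#' @param mode `"linear"` or `"nearest"`
#' @return A `pn_volume` on the field grid.
#' @export
resample_chain <- function(source, field, transform,
                           mode = c("linear", "nearest")) {
  stopifnot(inherits(source, "pn_volume"), inherits(field, "pn_field"),
            inherits(transform, "pn_affine"))
  mode <- match.arg(mode)
  dm <- field_dim(field)
  g <- .grid_coords(dm)
  n <- prod(dm)
  u <- field$u
  p <- affine_map_coords(transform, g$x + u[seq_len(n)],
                         g$y + u[n + seq_len(n)],
                         g$z + u[2 * n + seq_len(n)])
  vals <- if (mode == "linear") .sample_linear(source$data, p$x, p$y, p$z)
          else .sample_nearest(source$data, p$x, p$y, p$z)
  as_volume(array(vals, dm), spacing = source$spacing, affine = source$affine,
            id = source$id)
}

#' Displacement field of an affine transform
#'
#' Expresses `M x + t - x` as a dense field on a grid, so affine and
#' deformable components can be composed with [compose_displacements()].
#'
#' @param transform a `pn_affine`
#' @param grid_shape integer length-3
#' @return A `pn_field`.
#' @export
affine_to_field <- function(transform, grid_shape) {
  g <- .grid_coords(grid_shape)
  p <- affine_map_coords(transform, g$x, g$y, g$z)
  u <- array(0, c(grid_shape, 3L))
  u[, , , 1] <- p$x - g$x
  u[, , , 2] <- p$y - g$y
  u[, , , 3] <- p$z - g$z
  as_field(u)
}

#' Numerically invert a displacement field
#'
#' Finds `v` with `v(x) = -u(x + v(x))` by fixed-point iteration, so that
#' composing `u` and `v` is approximately the identity. Accurate for smooth
#' fields with positive Jacobian.
#'
#' @param field a `pn_field`
#' @param n_iter fixed-point iterations (default 30)
#' @return The approximate inverse `pn_field`.
#' @export
invert_displacement <- function(field, n_iter = 30L) {
  dm <- field_dim(field)
  v <- zero_field(dm)
  for (it in seq_len(n_iter)) {
    comp <- compose_displacements(field, v)  # u(x + v(x)) + v(x)
    v <- as_field(v$u - comp$u)              # v <- v - (v + u o (id+v)) = -u o (id+v)
  }
  v
}

#' Mean endpoint error between two template-to-individual mappings
#'
#' Each arm maps a template voxel `x` to individual coordinates
#' `A(x + u(x))` where `A` is the affine resampling transform and `u` the
#' deformable field. Returns the mean Euclidean distance (voxels) between
#' the two mappings over `mask`.
#'
#' @param field_a,field_b `pn_field` objects on the template grid
#' @param affine_a,affine_b `pn_affine` objects (template voxel to
#'   individual voxel)
#' @param mask logical/0-1 array on the template grid; defaults to all voxels
#' @return Mean endpoint error in voxels (scalar).
#' @export
endpoint_error <- function(field_a, affine_a, field_b, affine_b, mask = NULL) {
  dm <- field_dim(field_a)
  stopifnot(identical(dm, field_dim(field_b)))
  g <- .grid_coords(dm)
  n <- prod(dm)
  map_of <- function(field, aff) {
    u <- field$u
    affine_map_coords(aff, g$x + u[seq_len(n)], g$y + u[n + seq_len(n)],
                      g$z + u[2 * n + seq_len(n)])
  }
  pa <- map_of(field_a, affine_a)
  pb <- map_of(field_b, affine_b)
  err <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2 + (pa$z - pb$z)^2)
  if (is.null(mask)) mean(err) else mean(err[as.logical(mask)])
}
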