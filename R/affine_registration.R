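#' @title Affine pre-registration to the template grid
#' @description Estimates the 12-parameter affine (translation, rotation,
#'   anisotropic log-scale, shear) that aligns an individual-space volume to
#'   the template by multi-resolution maximization of global normalized
#'   cross-correlation with gradient-free simplex refinement, initialized
#'   from intensity-centroid alignment. This produces the
#'   "affine-registered" input consumed by the deformable network; the
#'   stage is deliberately conventional and replaceable behind this single
#'   interface.
#' @name affine_registration
NULL

# Average-pool a 3D array by 2 (trailing odd slices are averaged into the
# last block).
.downsample2 <- function(arr) {
  dm <- dim(arr)
  idx <- lapply(dm, function(n) (seq_len(n) + 1L) %/% 2L)
  out <- arr
  # block means via rowsum along each axis in turn
  m1 <- rowsum(matrix(out, dm[1]), idx[[1]]) / as.vector(table(idx[[1]]))
  d1 <- c(max(idx[[1]]), dm[2], dm[3]); out <- array(m1, d1)
  m2 <- rowsum(matrix(aperm(out, c(2, 1, 3)), d1[2]), idx[[2]]) /
    as.vector(table(idx[[2]]))
  d2 <- c(d1[1], max(idx[[2]]), d1[3])
  out <- aperm(array(m2, c(d2[2], d2[1], d2[3])), c(2, 1, 3))
  m3 <- rowsum(matrix(aperm(out, c(3, 1, 2)), d2[3]), idx[[3]]) /
    as.vector(table(idx[[3]]))
  d3 <- c(d2[1], d2[2], max(idx[[3]]))
  aperm(array(m3, c(d3[3], d3[1], d3[2])), c(2, 3, 1))
}

# Build the linear part from rotation (radians), log-scale and shear.
.affine_linear <- function(rot, logscale, shear) {
  rmat <- function(a, axis) {
    R <- diag(3); ix <- setdiff(1:3, axis)
    R[ix[1], ix[1]] <- cos(a); R[ix[2], ix[2]] <- cos(a)
    R[ix[1], ix[2]] <- -sin(a); R[ix[2], ix[1]] <- sin(a)
    R
  }
  H <- diag(3); H[1, 2] <- shear[1]; H[1, 3] <- shear[2]; H[2, 3] <- shear[3]
  rmat(rot[1], 1) %*% rmat(rot[2], 2) %*% rmat(rot[3], 3) %*%
    diag(exp(logscale)) %*% H
}

#' Build a pn_affine from 12 registration parameters
#'
#' Parameters are `c(translation[3], rotation[3] (radians),
#' log_scale[3], shear[3])`; the transform maps fixed-grid voxel `x` to
#' moving-grid voxel `ctr_mov + M (x - ctr_fix) + t`.
#'
#' @param params numeric length-12
#' @param dim_fixed,dim_moving grid shapes defining the rotation centers
#' @return A `pn_affine`.
#' @export
affine_from_params <- function(params, dim_fixed, dim_moving = dim_fixed) {
  M <- .affine_linear(params[4:6], params[7:9], params[10:12])
  cf <- (dim_fixed - 1) / 2; cm <- (dim_moving - 1) / 2
  affine_transform(M, cm - M %*% cf + params[1:3])
}

# Global NCC between `moving` resampled at mapped coordinates and `fixed`,
# evaluated at the voxel subset `sel` (linear indices into the fixed grid).
.affine_ncc <- function(moving, fixed, transform, coords, sel) {
  p <- affine_map_coords(transform, coords$x[sel], coords$y[sel],
                         coords$z[sel])
  a <- .sample_linear(moving, p$x, p$y, p$z)
  b <- fixed[sel]
  sa <- stats::sd(a)
  if (!is.finite(sa) || sa == 0) return(-1)
  stats::cor(a, b)
}

#' Affine registration by multi-resolution NCC maximization
#'
#' @param moving a `pn_volume` to be aligned
#' @param fixed a `pn_volume` defining the target grid (the template)
#' @param levels number of resolution levels (downsampling by 2 per level)
#' @param max_iter simplex iterations at the coarsest level; finer levels
#'   use progressively fewer refinement iterations
#' @param seed reserved for stochastic restart strategies; the default
#'   procedure is deterministic
#' @return A `pn_affine_result` with fields `transform` (fixed-voxel to
#'   moving-voxel pull map), `final_similarity` (global NCC at full
#'   resolution), `levels`, `converged`.
#' @export
register_affine <- function(moving, fixed, levels = 3L, max_iter = 400L,
                            seed = 0L, smooth_sigma = 1) {
  stopifnot(inherits(moving, "pn_volume"), inherits(fixed, "pn_volume"))
  if (levels < 1L) stop("levels must be >= 1")
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("constant volume: similarity undefined")

  # image pyramids, finest first; each level is Gaussian-prefiltered AFTER
  # downsampling so every level is band-limited relative to its own grid
  # (otherwise the NCC optimum is biased by interpolation blur on sharp
  # tissue edges, which penalizes non-identity transforms)
  pyr_m <- list(moving$data); pyr_f <- list(fixed$data)
  for (l in seq_len(levels - 1L)) {
    pyr_m[[l + 1L]] <- .downsample2(pyr_m[[l]])
    pyr_f[[l + 1L]] <- .downsample2(pyr_f[[l]])
  }
  for (l in seq_len(levels)) {
    pyr_m[[l]] <- smooth_gaussian(pyr_m[[l]], smooth_sigma)
    pyr_f[[l]] <- smooth_gaussian(pyr_f[[l]], smooth_sigma)
  }

  # intensity-centroid initialization (full-resolution voxel units)
  centroid <- function(a) {
    g <- .grid_coords(dim(a)); w <- as.vector(a) / sum(a)
    c(sum(g$x * w), sum(g$y * w), sum(g$z * w))
  }
  par <- c(centroid(moving$data) - centroid(fixed$data), rep(0, 9))
  parscale <- c(rep(1, 3), rep(0.05, 9))

  converged <- TRUE
  for (l in seq(levels, 1L)) {
    f <- 2^(l - 1L)
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    dmf <- dim(fx); dmm <- dim(mv)
    coords <- .grid_coords(dmf)
    # keep the objective cost roughly constant per level: ~2-4k samples
    stride <- max(1L, round(prod(dmf)^(1/3) / 14))
    sel <- which(coords$x %% stride == 0 & coords$y %% stride == 0 &
                   coords$z %% stride == 0)
    obj_full <- function(p) {
      pl <- p; pl[1:3] <- p[1:3] / f
      tr <- tryCatch(affine_from_params(pl, dmf, dmm), error = function(e) NULL)
      if (is.null(tr)) return(1)
      -.affine_ncc(mv, fx, tr, coords, sel)
    }
    it <- if (l == levels) max_iter else max(120L, as.integer(max_iter / 2))
    # Coarse levels estimate translation and gross pose only (rigid): small
    # rotations, scales and shears are below the resolution of a
    # downsampled grid and fitting them there latches onto interpolation
    # artifacts. The finest level starts with a coordinate sweep over each
    # rotation axis (the rotation valley is too shallow and curved for a
    # simplex to traverse), then runs the rigid simplex, the full
    # 12-parameter simplex and a quasi-Newton polish.
    obj_rigid <- function(p6) obj_full(c(p6, par[7:12]))
    if (l == 1L) {
      for (ax in 4:6) {
        cand <- par[ax] + seq(-8, 8, by = 1) * pi / 180
        vals <- vapply(cand, function(a) {
          p <- par; p[ax] <- a; obj_full(p)
        }, numeric(1))
        par[ax] <- cand[which.min(vals)]
      }
    }
    res_r <- stats::optim(par[1:6], obj_rigid, method = "Nelder-Mead",
                          control = list(maxit = it, parscale = parscale[1:6],
                                         reltol = 1e-9))
    if (res_r$value <= obj_rigid(par[1:6])) par[1:6] <- res_r$par
    if (l == 1L) {
      res <- stats::optim(par, obj_full, method = "Nelder-Mead",
                          control = list(maxit = it, parscale = parscale,
                                         reltol = 1e-9))
      if (res$value <= obj_full(par)) par <- res$par
      converged <- res$convergence == 0
    }
    res_b <- tryCatch(
      stats::optim(if (l == 1L) par else par[1:6],
                   if (l == 1L) obj_full else obj_rigid, method = "BFGS",
                   control = list(maxit = if (f > 1L) 40L else 12L,
                                  parscale = parscale[if (l == 1L) 1:12 else 1:6],
                                  reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(res_b)) {
      if (l == 1L) {
        if (res_b$value <= obj_full(par)) par <- res_b$par
      } else if (res_b$value <= obj_rigid(par[1:6])) par[1:6] <- res_b$par
    }
  }

  transform <- affine_from_params(par, dim(fixed$data), dim(moving$data))
  coords <- .grid_coords(dim(fixed$data))
  sim <- .affine_ncc(moving$data, fixed$data, transform, coords,
                     seq_along(coords$x))
  structure(list(transform = transform, final_similarity = sim,
                 levels = as.integer(levels), converged = converged,
                 params = par),
            class = "pn_affine_result")
}

#' @export
print.pn_affine_result <- function(x, ...) {
  cat(sprintf("<pn_affine_result> NCC %.4f, %d levels, converged: %s\n",
              x$final_similarity, x$levels, x$converged))
  print(x$transform)
  invisible(x)
}
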