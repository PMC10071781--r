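#' @title Cascaded displacement-field networks
#' @description The deformable stage of the pipeline: a cascade of
#'   encoder-decoder networks that predict dense displacement fields from an
#'   affine-registered PET volume. Stage 1 sees the PET alone; every later
#'   stage sees the PET warped by the accumulated field concatenated with
#'   the original PET and predicts a refinement that is combined by
#'   displacement composition. Training minimizes a local normalized
#'   cross-correlation loss between warped MR carriers and the template,
#'   plus a Dice loss on warped gray-matter segments and a smoothness
#'   penalty on the field; the MR and gray-matter volumes enter only the
#'   loss, never the forward path, so inference needs PET only. Fields are
#'   predicted on a reduced grid (`field_stride`, default 4) from
#'   block-statistic encodings of the images and upsampled, which matches
#'   the smoothness of anatomical deformations and keeps CPU training
#'   fast; the loss is always evaluated at full resolution.
#' @name deformnet
NULL

#' Cascade architecture configuration
#'
#' @param n_stages number of cascaded networks (>= 1)
#' @param base_channels channels of the first encoder level
#' @param levels encoder depth (resolution halvings inside each network)
#' @param field_smoothing_weight weight `lambda` of the squared-gradient
#'   smoothness penalty on the predicted field (0 disables)
#' @param dice_weight weight `beta` of the gray-matter Dice loss
#' @param ncc_window odd cubic window width (voxels) of the local NCC loss
#' @param field_stride power-of-2 factor between the template grid and the
#'   grid on which fields are predicted and composed; anatomical
#'   deformations are smooth on this scale and the reduced grid keeps CPU
#'   training fast. The loss is always evaluated at full resolution.
#' @return A `pn_cascade_config`.
#' @export
cascade_config <- function(n_stages = 2L, base_channels = 8L, levels = 3L,
                           field_smoothing_weight = 1, dice_weight = 1,
                           ncc_window = 9L, field_stride = 4L) {
  if (n_stages < 1L) stop("n_stages must be >= 1")
  if (ncc_window %% 2L != 1L || ncc_window < 3L)
    stop("ncc_window must be odd and >= 3")
  if (field_smoothing_weight < 0 || dice_weight < 0)
    stop("loss weights must be >= 0")
  if (field_stride < 2L || bitwAnd(field_stride, field_stride - 1L) != 0L)
    stop("field_stride must be a power of 2, at least 2")
  structure(list(n_stages = as.integer(n_stages),
                 base_channels = as.integer(base_channels),
                 levels = as.integer(levels),
                 field_smoothing_weight = field_smoothing_weight,
                 dice_weight = dice_weight,
                 ncc_window = as.integer(ncc_window),
                 field_stride = as.integer(field_stride)),
            class = "pn_cascade_config")
}

#' Training configuration
#'
#' Augmentation ranges are half-widths of uniform draws: rotation in
#' degrees, translation in voxels, scale as a fraction, intensity as a
#' multiplicative fraction applied to PET only, elastic amplitude in
#' voxels. All zero disables augmentation.
#'
#' @param epochs training epochs
#' @param batch_size samples per gradient step
#' @param learning_rate Adam step size
#' @param seed master seed for shuffling, augmentation and initialization
#' @param aug_rotation,aug_translation,aug_scale,aug_intensity,aug_elastic
#'   augmentation half-ranges (all >= 0)
#' @param ncc_presmooth Gaussian sigma (voxels) applied once to the MR
#'   carriers and the template image before training; band-limiting both
#'   sides of the NCC roughly doubles its usable dynamic range on
#'   edge-dominated images (0 disables)
#' @param warmup_steps gradient steps over which the learning rate ramps
#'   linearly from 0; Adam's normalized steps on the zero-initialized
#'   field layers otherwise overshoot in the first iterations
#' @return A `pn_train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 1L, learning_rate = 2e-3,
                         seed = 0L, aug_rotation = 3, aug_translation = 1,
                         aug_scale = 0.02, aug_intensity = 0.1,
                         aug_elastic = 0.5, ncc_presmooth = 0.7,
                         warmup_steps = 50L) {
  rng <- c(aug_rotation, aug_translation, aug_scale, aug_intensity,
           aug_elastic)
  if (any(rng < 0)) stop("augmentation ranges must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 aug_rotation = aug_rotation,
                 aug_translation = aug_translation, aug_scale = aug_scale,
                 aug_intensity = aug_intensity, aug_elastic = aug_elastic,
                 ncc_presmooth = ncc_presmooth,
                 warmup_steps = as.integer(warmup_steps)),
            class = "pn_train_config")
}

#' Build an untrained cascade model
#'
#' Each stage is an encoder-decoder network operating on the reduced
#' field grid; the final field convolution of every stage is
#' zero-initialized, so the untrained cascade predicts the zero field and
#' spatial normalization reduces to the affine resampling exactly.
#'
#' @param config a `pn_cascade_config`
#' @param grid_shape template grid (each axis divisible by `2^levels` and
#'   at least `2^levels`)
#' @param seed integer controlling weight initialization
#' @return A `pn_model` list.
#' @export
build_model <- function(config = cascade_config(),
                        grid_shape = c(48, 48, 48), seed = 0L) {
  stopifnot(inherits(config, "pn_cascade_config"))
  grid_shape <- as.integer(grid_shape)
  div <- config$field_stride * 2L^(config$levels - 1L)
  if (any(grid_shape < 2L^config$levels) || any(grid_shape %% div != 0L))
    stop("grid must be at least 2^levels per axis and divisible by ",
         "field_stride * 2^(levels-1) = ", div, ", got ",
         paste(grid_shape, collapse = "x"))
  stages <- vector("list", config$n_stages)
  for (s in seq_len(config$n_stages)) {
    in_ch <- if (s == 1L) 5L else 10L  # block-statistic channels per image
    stages[[s]] <- unet_init(in_ch, config$base_channels, config$levels,
                             seed = derive_seed(seed, s))
  }
  structure(list(stages = stages, config = config, grid_shape = grid_shape,
                 red_shape = grid_shape %/% config$field_stride,
                 up_mats = lapply(1:3, function(ax)
                   upsample_mat(grid_shape[ax], config$field_stride)),
                 trained = FALSE),
            class = "pn_model")
}

#' @export
print.pn_model <- function(x, ...) {
  nw <- sum(unlist(tree_map(function(w) length(w),
                            lapply(x$stages, unet_weights))))
  cat(sprintf("<pn_model> %d-stage cascade, %d levels, %d base channels, %s weights, %s\n",
              x$config$n_stages, x$config$levels, x$config$base_channels,
              format(nw, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Reduced-grid input encoding of a full-resolution volume: per coarse
# block, the mean, the standard deviation and the mean central-difference
# gradient along each axis (5 channels). The field grid is `stride` times
# coarser than the image; without sub-block statistics the deformation
# signal inside each block would be invisible to the network.
.stage_input_features <- function(arr, stride) {
  dm <- dim(arr)
  x4 <- array(arr, c(dm, 1L))
  mean_c <- avgpool_by(x4, stride)
  var_c <- avgpool_by(x4 * x4, stride) - mean_c^2
  sd_c <- sqrt(pmax(var_c, 0))
  grads <- lapply(1:3, function(ax)
    avgpool_by(array(.deriv_axis(arr, ax), c(dm, 1L)), stride))
  out <- array(0, c(dim(mean_c)[1:3], 5L))
  out[, , , 1] <- mean_c; out[, , , 2] <- sd_c
  for (ax in 1:3) out[, , , 2 + ax] <- grads[[ax]]
  out
}

# Linear field upsampling by the model's field_stride as a separable
# matrix map; displacement values are multiplied by the stride because a
# reduced-grid voxel spans `stride` full-grid voxels. The adjoint uses the
# transposed matrices.
.upsample_field <- function(model, u_red) {
  s <- model$config$field_stride
  dm <- model$grid_shape
  u <- array(0, c(dm, 3L))
  for (comp in 1:3)
    u[, , , comp] <- s * apply_sep3(u_red[, , , comp], model$up_mats[[1]],
                                    model$up_mats[[2]], model$up_mats[[3]])
  u
}

.upsample_field_bwd <- function(model, grad_u) {
  s <- model$config$field_stride
  t1 <- t(model$up_mats[[1]]); t2 <- t(model$up_mats[[2]])
  t3 <- t(model$up_mats[[3]])
  gh <- array(0, c(model$red_shape, 3L))
  for (comp in 1:3)
    gh[, , , comp] <- s * apply_sep3(grad_u[, , , comp], t1, t2, t3)
  gh
}

#' Predict the displacement field for an affine-registered PET volume
#'
#' Stage 1 predicts a field from the PET alone; each later stage sees the
#' PET warped by the accumulated field concatenated with the original PET
#' and predicts a refinement, combined with [compose_displacements()]
#' (refinement as `first`, accumulated field as `second`). The forward
#' path takes no MR input by construction.
#'
#' @param model a `pn_model`
#' @param pet_affine a `pn_volume` on the model grid
#' @param keep_cache keep activations for backpropagation (training only)
#' @return A `pn_field` (or a list with `field` and `cache` when
#'   `keep_cache = TRUE`).
#' @export
predict_displacement <- function(model, pet_affine, keep_cache = FALSE) {
  stopifnot(inherits(model, "pn_model"))
  dm <- model$grid_shape
  if (!identical(vol_dim(pet_affine), dm))
    stop("input grid ", paste(vol_dim(pet_affine), collapse = "x"),
         " does not match model grid ", paste(dm, collapse = "x"))
  stride <- model$config$field_stride
  pet_ds <- .stage_input_features(pet_affine$data, stride)
  acc_red <- NULL  # accumulated field on the reduced grid, reduced units
  caches <- vector("list", length(model$stages))
  for (s in seq_along(model$stages)) {
    if (s == 1L) {
      xin <- pet_ds
    } else {
      warped <- warp_volume(pet_affine,
                            as_field(.upsample_field(model, acc_red$u)))
      xin <- concat_ch(.stage_input_features(warped$data, stride), pet_ds)
    }
    fw <- unet_fwd(model$stages[[s]], xin, keep_cache = keep_cache)
    new_f <- as_field(fw$field)
    acc_prev <- acc_red
    acc_red <- if (is.null(acc_red)) new_f
      else compose_displacements(new_f, acc_red)
    if (keep_cache)
      caches[[s]] <- list(unet = fw$cache, refinement = new_f,
                          acc_prev = acc_prev)
  }
  field <- as_field(.upsample_field(model, acc_red$u))
  if (keep_cache) list(field = field, field_red = acc_red, caches = caches)
  else field
}

# Backpropagate a gradient on the final full-resolution field through the
# upsampling and the reduced-grid cascade composition. The
# refinement-sampling position term is kept; the warped-PET input to later
# stages is treated as fixed (standard practice for cascaded registration
# networks: the dominant gradient path is the composition).
.cascade_bwd <- function(model, caches, grad_field) {
  n_stage <- length(model$stages)
  dmr <- model$red_shape
  n <- prod(dmr)
  g <- .upsample_field_bwd(model, grad_field)  # [red grid, 3]
  grads <- vector("list", n_stage)
  for (s in rev(seq_len(n_stage))) {
    ca <- caches[[s]]
    if (s > 1L) {
      # acc = compose(refinement r, acc_prev a): w(x) = a(x) + r(x + a(x))
      a <- ca$acc_prev$u
      r <- ca$refinement$u
      gc <- .grid_coords(dmr)
      px <- gc$x + a[seq_len(n)]
      py <- gc$y + a[n + seq_len(n)]
      pz <- gc$z + a[2 * n + seq_len(n)]
      g_r <- array(0, c(dmr, 3L))
      g_a <- g
      for (comp in 1:3) {
        gcomp <- as.vector(g[, , , comp])
        g_r[, , , comp] <- .scatter_linear(dmr, px, py, pz, gcomp)
        sg <- .sample_linear_grad(r[, , , comp], px, py, pz)
        g_a[, , , 1] <- g_a[, , , 1] + array(gcomp * sg$gx, dmr)
        g_a[, , , 2] <- g_a[, , , 2] + array(gcomp * sg$gy, dmr)
        g_a[, , , 3] <- g_a[, , , 3] + array(gcomp * sg$gz, dmr)
      }
      grads[[s]] <- unet_weights(unet_bwd(model$stages[[s]], ca$unet, g_r))
      g <- g_a
    } else {
      grads[[s]] <- unet_weights(unet_bwd(model$stages[[s]], ca$unet, g))
    }
  }
  grads
}

# ---- losses ---------------------------------------------------------------

.as_arr <- function(x) if (inherits(x, "pn_volume")) x$data else x

# Local NCC loss core: loss = 1 - mean over voxels of the signed windowed
# NCC; windows are clipped at the grid boundary; windows whose variance
# falls below the floor contribute NCC = 0. Optionally returns the
# gradient with respect to `a`.
.ncc_core <- function(a, b, window, eps = 1e-5, with_grad = FALSE) {
  dm <- dim(a)
  nW <- boxcount3(dm, window)
  am <- boxsum3(a, window) / nW
  bm <- boxsum3(b, window) / nW
  cov <- boxsum3(a * b, window) / nW - am * bm
  va <- pmax(boxsum3(a * a, window) / nW - am^2, 0)
  vb <- pmax(boxsum3(b * b, window) / nW - bm^2, 0)
  ok <- va >= eps & vb >= eps
  s <- array(0, dm)
  s[ok] <- 1 / sqrt(va[ok] * vb[ok])
  ncc <- pmin(pmax(cov * s, -1), 1)
  loss <- 1 - mean(ncc)
  if (!with_grad) return(list(loss = loss))
  N <- prod(dm)
  alpha <- s / nW
  beta <- array(0, dm)
  beta[ok] <- ncc[ok] / (va[ok] * nW[ok])
  grad <- -(b * boxsum3(alpha, window) - boxsum3(alpha * bm, window) -
              a * boxsum3(beta, window) + boxsum3(beta * am, window)) / N
  list(loss = loss, grad_a = grad)
}

#' Local normalized cross-correlation loss
#'
#' `1 - mean(NCC)` with signed NCC computed in cubic windows (means and
#' variances over each window, variance floor `1e-5`); ranges over
#' `[0, 2]`. Windows with sub-floor variance contribute NCC = 0, so two
#' constant volumes score loss 1.
#'
#' @param a,b `pn_volume` objects or arrays on the same grid
#' @param window odd cubic window width (clipped at the grid boundary)
#' @return Scalar loss.
#' @export
ncc_loss <- function(a, b, window = 9L) {
  a <- .as_arr(a); b <- .as_arr(b)
  if (!identical(dim(a), dim(b))) stop("grids differ")
  if (window %% 2L != 1L) stop("window must be odd")
  .ncc_core(a, b, window)$loss
}

# Soft Dice loss core with smoothing 1; gradient with respect to p.
.dice_core <- function(p, q, smooth = 1, with_grad = FALSE) {
  num <- 2 * sum(p * q) + smooth
  den <- sum(p) + sum(q) + smooth
  loss <- 1 - num / den
  if (!with_grad) return(list(loss = loss))
  list(loss = loss, grad_p = -(2 * q / den) + num / den^2)
}

#' Soft Dice loss for probabilistic masks
#'
#' `1 - (2 sum(pq) + s) / (sum(p) + sum(q) + s)` with smoothing `s = 1`;
#' defined (and 0-ranged) for empty masks, differentiable everywhere.
#'
#' @param p,q `pn_volume` objects or arrays with values in `[0, 1]`
#' @param smooth additive smoothing
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(p, q, smooth = 1) {
  p <- .as_arr(p); q <- .as_arr(q)
  if (!identical(dim(p), dim(q))) stop("grids differ")
  if (min(p) < 0 || max(p) > 1 || min(q) < 0 || max(q) > 1)
    stop("dice_loss inputs must lie in [0, 1]")
  .dice_core(p, q, smooth)$loss
}

# Mean squared forward-difference gradient of the field; returns the value
# and optionally its gradient with respect to u.
.smoothness_core <- function(u, with_grad = FALSE) {
  dm <- dim(u)[1:3]
  norm <- prod(dm) * 9
  val <- 0
  grad <- if (with_grad) array(0, dim(u)) else NULL
  for (comp in 1:3) {
    uc <- u[, , , comp]
    for (ax in 1:3) {
      n <- dm[ax]
      take <- function(a, idx) switch(ax, a[idx, , , drop = FALSE],
                                      a[, idx, , drop = FALSE],
                                      a[, , idx, drop = FALSE])
      d <- take(uc, 2:n) - take(uc, 1:(n - 1))
      val <- val + sum(d * d)
      if (with_grad) {
        gc <- array(0, dm)
        if (ax == 1) {
          gc[2:n, , ] <- gc[2:n, , ] + 2 * d
          gc[1:(n - 1), , ] <- gc[1:(n - 1), , ] - 2 * d
        } else if (ax == 2) {
          gc[, 2:n, ] <- gc[, 2:n, ] + 2 * d
          gc[, 1:(n - 1), ] <- gc[, 1:(n - 1), ] - 2 * d
        } else {
          gc[, , 2:n] <- gc[, , 2:n] + 2 * d
          gc[, , 1:(n - 1)] <- gc[, , 1:(n - 1)] - 2 * d
        }
        grad[, , , comp] <- grad[, , , comp] + gc
      }
    }
  }
  list(val = val / norm, grad = if (with_grad) grad / norm else NULL)
}

# Pull-warp of two sources by the same field `u` together with the
# gradients of the warped images with respect to the displacement
# components (spatial gradients of the interpolants at the sample
# positions). Sharing one pass over the 8 interpolation corners roughly
# halves the cost of the loss gradient.
.warp2_with_grad <- function(srcA, srcB, u) {
  dm <- dim(u)[1:3]
  n <- prod(dm)
  g <- .grid_coords(dm)
  px <- g$x + u[seq_len(n)]
  py <- g$y + u[n + seq_len(n)]
  pz <- g$z + u[2 * n + seq_len(n)]
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  i0 <- floor(px); j0 <- floor(py); k0 <- floor(pz)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  valA <- gxA <- gyA <- gzA <- numeric(n)
  valB <- gxB <- gyB <- gzB <- numeric(n)
  for (corner in 0:7) {
    dx <- corner %% 2L; dy <- (corner %/% 2L) %% 2L; dz <- corner %/% 4L
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    inb <- (ii >= 0) & (ii < nx) & (jj >= 0) & (jj < ny) & (kk >= 0) & (kk < nz)
    wx <- if (dx) fx else 1 - fx
    wy <- if (dy) fy else 1 - fy
    wz <- if (dz) fz else 1 - fz
    sx <- if (dx) 1 else -1; sy <- if (dy) 1 else -1; sz <- if (dz) 1 else -1
    ii[!inb] <- 0; jj[!inb] <- 0; kk[!inb] <- 0
    idx <- 1 + ii + nx * (jj + ny * kk)
    wxyz <- wx * wy * wz; wyz <- wy * wz; wxz <- wx * wz; wxy <- wx * wy
    vA <- inb * srcA[idx]
    valA <- valA + wxyz * vA
    gxA <- gxA + sx * wyz * vA
    gyA <- gyA + sy * wxz * vA
    gzA <- gzA + sz * wxy * vA
    vB <- inb * srcB[idx]
    valB <- valB + wxyz * vB
    gxB <- gxB + sx * wyz * vB
    gyB <- gyB + sy * wxz * vB
    gzB <- gzB + sz * wxy * vB
  }
  list(A = list(warped = array(valA, dm), gx = gxA, gy = gyA, gz = gzA),
       B = list(warped = array(valB, dm), gx = gxB, gy = gyB, gz = gzB))
}

#' Full registration loss of a displacement field
#'
#' `ncc + beta * dice + lambda * smoothness`, where the NCC term compares
#' the warped MR carrier with the template, the Dice term compares the
#' warped gray-matter segment with the template gray matter, and the
#' smoothness term is the mean squared forward-difference gradient of the
#' field.
#'
#' @param field a `pn_field`
#' @param mr_affine,gm_affine affine-registered MR and gray-matter carriers
#' @param template_mr,template_gm template image and gray-matter probability
#' @param config a `pn_cascade_config` (weights and NCC window)
#' @param with_grad also return the gradient with respect to the field
#' @return list with `total`, `ncc`, `dice`, `smooth` (and `grad_field`).
#' @export
total_loss <- function(field, mr_affine, gm_affine, template_mr, template_gm,
                       config = cascade_config(), with_grad = FALSE) {
  u <- field$u
  mr <- .as_arr(mr_affine); gm <- .as_arr(gm_affine)
  tmr <- .as_arr(template_mr); tgm <- .as_arr(template_gm)
  gm <- pmin(pmax(gm, 0), 1)
  w2 <- .warp2_with_grad(mr, gm, u)
  wm <- w2$A; wg <- w2$B
  wg$warped <- pmin(pmax(wg$warped, 0), 1)
  ncc <- .ncc_core(wm$warped, tmr, config$ncc_window, with_grad = with_grad)
  dce <- .dice_core(wg$warped, tgm, with_grad = with_grad)
  smo <- .smoothness_core(u, with_grad = with_grad)
  out <- list(total = ncc$loss + config$dice_weight * dce$loss +
                config$field_smoothing_weight * smo$val,
              ncc = ncc$loss, dice = dce$loss, smooth = smo$val)
  if (with_grad) {
    dm <- dim(u)[1:3]
    gl_mr <- as.vector(ncc$grad_a)
    gl_gm <- config$dice_weight * as.vector(dce$grad_p)
    grad <- array(0, dim(u))
    grad[, , , 1] <- array(gl_mr * wm$gx + gl_gm * wg$gx, dm)
    grad[, , , 2] <- array(gl_mr * wm$gy + gl_gm * wg$gy, dm)
    grad[, , , 3] <- array(gl_mr * wm$gz + gl_gm * wg$gz, dm)
    grad <- grad + config$field_smoothing_weight * smo$grad
    out$grad_field <- grad
  }
  out
}

# ---- augmentation ---------------------------------------------------------

#' Randomly augment a training sample
#'
#' Applies one random small affine (rotation, translation, isotropic
#' scale) combined with a smooth elastic perturbation identically to the
#' PET, MR and gray-matter carriers, plus a random multiplicative
#' intensity scale on the PET only. Deterministic for a fixed seed; all
#' ranges zero returns the sample unchanged.
#'
#' @param sample list with `pet`, `mr`, `gm` (`pn_volume`s on one grid)
#' @param tc a `pn_train_config` carrying the augmentation ranges
#' @param seed integer
#' @return The augmented sample (same structure).
#' @export
augment_sample <- function(sample, tc, seed) {
  if (tc$aug_rotation == 0 && tc$aug_translation == 0 && tc$aug_scale == 0 &&
      tc$aug_intensity == 0 && tc$aug_elastic == 0)
    return(sample)
  dm <- vol_dim(sample$pet)
  set.seed(derive_seed(seed, 71))
  ang <- stats::runif(3, -tc$aug_rotation, tc$aug_rotation) * pi / 180
  tr <- stats::runif(3, -tc$aug_translation, tc$aug_translation)
  sc <- exp(stats::runif(1, -tc$aug_scale, tc$aug_scale))
  gain <- exp(stats::runif(1, -tc$aug_intensity, tc$aug_intensity))
  amp <- stats::runif(1, 0, tc$aug_elastic)
  aff <- affine_from_params(c(tr, ang, rep(log(sc), 3), 0, 0, 0), dm)
  g <- .grid_coords(dm)
  qx <- g$x; qy <- g$y; qz <- g$z
  if (amp > 0) {
    # elastic perturbation drawn on a 4x-coarser grid and upsampled: the
    # perturbation is smooth by construction and cheap to generate
    dmc <- pmax(dm %/% 4L, 2L)
    set.seed(derive_seed(seed, 72))
    e <- array(stats::rnorm(prod(dmc) * 3), c(dmc, 3))
    for (comp in 1:3) e[, , , comp] <- smooth_gaussian(e[, , , comp], 1)
    mag <- sqrt(e[, , , 1]^2 + e[, , , 2]^2 + e[, , , 3]^2)
    e <- e * (amp / max(mag))
    Ms <- lapply(1:3, function(ax) upsample_mat((dm[ax] %/% dmc[ax]) * dmc[ax],
                                                dm[ax] %/% dmc[ax]))
    qx <- qx + as.vector(apply_sep3(e[, , , 1], Ms[[1]], Ms[[2]], Ms[[3]]))
    qy <- qy + as.vector(apply_sep3(e[, , , 2], Ms[[1]], Ms[[2]], Ms[[3]]))
    qz <- qz + as.vector(apply_sep3(e[, , , 3], Ms[[1]], Ms[[2]], Ms[[3]]))
  }
  p <- affine_map_coords(aff, qx, qy, qz)
  vals <- .sample_linear_multi(list(sample$pet$data, sample$mr$data,
                                    sample$gm$data), p$x, p$y, p$z)
  out <- sample
  out$pet$data <- array(vals[[1]], dm) * gain
  out$mr$data <- array(vals[[2]], dm)
  out$gm$data <- pmin(pmax(array(vals[[3]], dm), 0), 1)
  out
}

# ---- training -------------------------------------------------------------

#' Train the cascade on affine-registered samples
#'
#' Minibatch Adam training of all stages jointly. Each sample is a list
#' with `pet`, `mr`, `gm` on the template grid (see
#' [prepare_training_sample()]); MR and gray matter are used only inside
#' the loss. The best-epoch weights (lowest mean total loss) are restored
#' at the end.
#'
#' @param model an untrained or previously trained `pn_model`
#' @param samples list of training samples
#' @param template template assets from [make_template()]
#' @param tc a `pn_train_config`
#' @return The trained `pn_model` with a `history` data frame
#'   (epoch, total, ncc, dice, smooth).
#' @export
train_model <- function(model, samples, template, tc = train_config()) {
  stopifnot(inherits(model, "pn_model"), length(samples) >= 1L)
  dm <- model$grid_shape
  tmr <- template$template_mr$data
  tgm <- template$gm_probability$data
  if (is.null(tc$ncc_presmooth)) tc$ncc_presmooth <- 0
  if (tc$ncc_presmooth > 0) {
    tmr <- smooth_gaussian(tmr, tc$ncc_presmooth)
    samples <- lapply(samples, function(s) {
      s$mr$data <- smooth_gaussian(s$mr$data, tc$ncc_presmooth)
      s
    })
  }
  weights <- lapply(model$stages, unet_weights)
  opt <- lapply(weights, adam_init)
  history <- data.frame(epoch = integer(), total = numeric(),
                        ncc = numeric(), dice = numeric(),
                        smooth = numeric())
  best <- list(loss = Inf, weights = weights)
  aug_on <- tc$aug_rotation > 0 || tc$aug_translation > 0 ||
    tc$aug_scale > 0 || tc$aug_intensity > 0 || tc$aug_elastic > 0
  step <- 0L
  for (epoch in seq_len(tc$epochs)) {
    set.seed(derive_seed(tc$seed, 1000 + epoch))
    ord <- sample.int(length(samples))
    comp_sum <- c(total = 0, ncc = 0, dice = 0, smooth = 0)
    batch_grads <- NULL
    in_batch <- 0L
    for (ii in seq_along(ord)) {
      smp <- samples[[ord[ii]]]
      if (aug_on)
        smp <- augment_sample(smp, tc,
                              seed = derive_seed(tc$seed,
                                                 epoch * 10000L + ord[ii]))
      for (s in seq_along(model$stages))
        model$stages[[s]][c("enc", "dec", "flow")] <- weights[[s]]
      fw <- predict_displacement(model, smp$pet, keep_cache = TRUE)
      ls <- total_loss(fw$field, smp$mr, smp$gm, tmr, tgm, model$config,
                       with_grad = TRUE)
      if (!is.finite(ls$total))
        stop("non-finite loss at epoch ", epoch, " (sample ", ord[ii], ")")
      comp_sum <- comp_sum + c(ls$total, ls$ncc, ls$dice, ls$smooth)
      grads <- .cascade_bwd(model, fw$caches, ls$grad_field)
      batch_grads <- if (is.null(batch_grads)) grads
        else Map(function(a, b) tree_map(`+`, a, b), batch_grads, grads)
      in_batch <- in_batch + 1L
      if (in_batch == tc$batch_size || ii == length(ord)) {
        wu <- if (is.null(tc$warmup_steps)) 0L else tc$warmup_steps
        lr_t <- tc$learning_rate *
          (if (wu > 0L) min(1, (step + 1) / wu) else 1)
        for (s in seq_along(weights)) {
          gs <- tree_map(function(g) g / in_batch, batch_grads[[s]])
          st <- adam_step(weights[[s]], gs, opt[[s]], lr_t)
          weights[[s]] <- st$weights
          opt[[s]] <- st$state
        }
        batch_grads <- NULL
        in_batch <- 0L
        step <- step + 1L
      }
    }
    mean_comp <- comp_sum / length(ord)
    history <- rbind(history,
                     data.frame(epoch = epoch, total = mean_comp[1],
                                ncc = mean_comp[2], dice = mean_comp[3],
                                smooth = mean_comp[4]))
    if (mean_comp[1] < best$loss)
      best <- list(loss = mean_comp[1], weights = weights)
  }
  for (s in seq_along(model$stages))
    model$stages[[s]][c("enc", "dec", "flow")] <- best$weights[[s]]
  model$trained <- TRUE
  rownames(history) <- NULL
  model$history <- history
  model
}

#' Prepare a training sample from an individual-space phantom
#'
#' Affine-registers the phantom PET to the template and resamples the MR
#' and gray-matter carriers with the same estimated transform (they share
#' the PET's space), producing the `pet`/`mr`/`gm` triple consumed by
#' [train_model()]. The phantom's ground-truth deformation is not used.
#'
#' @param phantom a `pn_phantom`
#' @param template template assets from [make_template()]
#' @param affine_target optional `pn_volume` registration target; defaults
#'   to the status-averaged PET construction of the template
#' @return list with `pet`, `mr`, `gm` (`pn_volume`s) and `affine`.
#' @export
prepare_training_sample <- function(phantom, template,
                                    affine_target = NULL) {
  reg <- if (is.null(affine_target)) .register_to_template(phantom$pet, template)
         else register_affine(phantom$pet, affine_target)
  dm <- vol_dim(template$template_mr)
  out <- list(pet = apply_affine(phantom$pet, reg$transform, dm),
              mr = apply_affine(phantom$mr, reg$transform, dm),
              gm = apply_affine(phantom$gm_segment, reg$transform, dm),
              affine = reg$transform)
  out$gm$data <- pmin(pmax(out$gm$data, 0), 1)
  out
}

#' Save a trained model to a single checkpoint file
#'
#' The checkpoint embeds the cascade configuration, grid shape, weights
#' and training history.
#'
#' @param model a `pn_model`
#' @param path output file path (`.rds`)
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_model()]
#' @return A `pn_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pn_model")) stop("not a petnorm model checkpoint")
  model
}

#' Status-averaged PET template used as the affine registration target
#'
#' The mean of the amyloid-positive and amyloid-negative template-space
#' PET constructions, analogous to registering against an average-uptake
#' PET template when the subject's status is unknown.
#'
#' @param template template assets from [make_template()]
#' @return A `pn_volume`.
#' @export
template_pet_target <- function(template) {
  pos <- phantom_pet_template(template, "positive")
  neg <- phantom_pet_template(template, "negative")
  avg <- (pos$data + neg$data) / 2
  # subject PET carries the template's anatomical uptake modulation; the
  # registration target must carry it too or the estimated affine is
  # biased for subjects whose tissue contrast differs from the average
  if (!is.null(template$pet_texture)) avg <- avg * template$pet_texture
  as_volume(avg, id = "template_pet_avg")
}

#' Spatially normalize an individual-space PET volume
#'
#' The full MRI-less pipeline: affine registration to the template grid,
#' displacement-field prediction by the cascade, and pull-warping of the
#' affine-registered PET into template space. Requires no MR input.
#'
#' @param model a trained `pn_model`
#' @param pet_individual a `pn_volume` in individual space
#' @param template template assets from [make_template()]
#' @return list with `pet` (template-space `pn_volume`), `field`
#'   (`pn_field`), `affine` (`pn_affine`) and `affine_result`.
#' @export
# Register a PET volume to the template grid against the better-matching
# uptake-pattern template (amyloid-negative or -positive construction,
# with the template's uptake texture). A single average template biases
# the pose estimate for subjects whose tissue contrast sits far from the
# average. The pattern is picked with a cheap centroid-aligned NCC probe
# on 4x-downsampled images, then one full registration is run.
.register_to_template <- function(pet_individual, template) {
  targets <- lapply(c("negative", "positive"), function(st) {
    tgt <- phantom_pet_template(template, st)
    if (!is.null(template$pet_texture))
      tgt$data <- tgt$data * template$pet_texture
    tgt
  })
  pet_ds <- avgpool_by(array(pet_individual$data,
                             c(vol_dim(pet_individual), 1L)), 4L)[, , , 1]
  cen <- function(a) {
    g <- .grid_coords(dim(a)); w <- as.vector(a) / sum(a)
    c(sum(g$x * w), sum(g$y * w), sum(g$z * w))
  }
  probe <- vapply(targets, function(tgt) {
    tg_ds <- avgpool_by(array(tgt$data, c(vol_dim(tgt), 1L)), 4L)[, , , 1]
    tr <- affine_transform(diag(3), cen(pet_ds) - cen(tg_ds))
    coords <- .grid_coords(dim(tg_ds))
    .affine_ncc(pet_ds, tg_ds, tr, coords, seq_along(coords$x))
  }, numeric(1))
  register_affine(pet_individual, targets[[which.max(probe)]])
}

spatially_normalize <- function(model, pet_individual, template) {
  reg <- .register_to_template(pet_individual, template)
  pet_aff <- apply_affine(pet_individual, reg$transform,
                          model$grid_shape)
  field <- predict_displacement(model, pet_aff)
  # compose the deformable and affine chains into a single resampling of
  # the original volume: one interpolation instead of two
  pet_sn <- resample_chain(pet_individual, field, reg$transform)
  list(pet = pet_sn, field = field, affine = reg$transform,
       affine_result = reg)
}
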