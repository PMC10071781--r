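#' @title Minimal 3D convolutional network engine
#' @description Building blocks for the displacement-field networks:
#'   3x3x3 convolutions (as a 27-shift BLAS gemm decomposition), ReLU,
#'   2x average pooling, nearest-neighbour upsampling, an encoder-decoder
#'   (U-net style) assembly, and an Adam optimizer. Forward passes cache the
#'   activations needed by the hand-written backward passes. Tensors are 4D
#'   arrays `[nx, ny, nz, channels]`.
#' @name nn
#' @keywords internal
NULL

conv3d_fwd <- function(x, W, b) {
  dm <- dim(x); nx <- dm[1]; ny <- dm[2]; nz <- dm[3]; cin <- dm[4]
  cout <- dim(W)[5]
  xp <- array(0, c(nx + 2L, ny + 2L, nz + 2L, cin))
  xp[2:(nx + 1), 2:(ny + 1), 2:(nz + 1), ] <- x
  n <- nx * ny * nz
  Wm <- array(W, c(27L, cin, cout))
  out <- matrix(b, n, cout, byrow = TRUE)
  o <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    o <- o + 1L
    Xo <- matrix(xp[(1 + dx):(nx + dx), (1 + dy):(ny + dy),
                    (1 + dz):(nz + dz), , drop = FALSE], n, cin)
    out <- out + Xo %*% matrix(Wm[o, , ], cin, cout)
  }
  list(out = array(out, c(nx, ny, nz, cout)), xp = xp)
}

conv3d_bwd <- function(grad_out, xp, W) {
  dmp <- dim(xp); cin <- dmp[4]
  nx <- dmp[1] - 2L; ny <- dmp[2] - 2L; nz <- dmp[3] - 2L
  cout <- dim(W)[5]
  n <- nx * ny * nz
  G <- matrix(grad_out, n, cout)
  Wm <- array(W, c(27L, cin, cout))
  dW <- array(0, c(27L, cin, cout))
  dxp <- array(0, dmp)
  o <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    o <- o + 1L
    sx <- (1 + dx):(nx + dx); sy <- (1 + dy):(ny + dy); sz <- (1 + dz):(nz + dz)
    Xo <- matrix(xp[sx, sy, sz, , drop = FALSE], n, cin)
    dW[o, , ] <- crossprod(Xo, G)
    dxp[sx, sy, sz, ] <- dxp[sx, sy, sz, , drop = FALSE] +
      array(G %*% t(matrix(Wm[o, , ], cin, cout)), c(nx, ny, nz, cin))
  }
  list(dx = dxp[2:(nx + 1), 2:(ny + 1), 2:(nz + 1), , drop = FALSE],
       dW = array(dW, dim(W)), db = colSums(G))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_bwd <- function(grad_out, mask) grad_out * mask

avgpool2_fwd <- function(x) {
  dm <- dim(x)
  stopifnot(dm[1] %% 2 == 0, dm[2] %% 2 == 0, dm[3] %% 2 == 0)
  a <- array(x, c(2L, dm[1] %/% 2L, dm[2], dm[3], dm[4]))
  a <- a[1, , , , , drop = FALSE] + a[2, , , , , drop = FALSE]
  a <- array(a, c(dm[1] %/% 2L, 2L, dm[2] %/% 2L, dm[3], dm[4]))
  a <- a[, 1, , , , drop = FALSE] + a[, 2, , , , drop = FALSE]
  a <- array(a, c(dm[1] %/% 2L, dm[2] %/% 2L, 2L, dm[3] %/% 2L, dm[4]))
  a <- a[, , 1, , , drop = FALSE] + a[, , 2, , , drop = FALSE]
  array(a, c(dm[1] %/% 2L, dm[2] %/% 2L, dm[3] %/% 2L, dm[4])) / 8
}

avgpool2_bwd <- function(grad_out) {
  upsample2_nearest(grad_out) / 8
}

upsample2_nearest <- function(x) {
  dm <- dim(x)
  x[rep(seq_len(dm[1]), each = 2), rep(seq_len(dm[2]), each = 2),
    rep(seq_len(dm[3]), each = 2), , drop = FALSE]
}

upsample2_nearest_bwd <- function(grad_out) {
  avgpool2_fwd(grad_out) * 8
}

# Average-pool by a power-of-2 factor.
avgpool_by <- function(x, s) {
  while (s > 1L) {
    x <- avgpool2_fwd(x)
    s <- s %/% 2L
  }
  x
}

# Separable linear upsampling by integer factor `s` along one axis:
# output row X samples input at (X + 0.5) / s - 0.5, clamped (border
# replicate). Returns the n_out x n_in weight matrix.
upsample_mat <- function(n_out, s) {
  n_in <- n_out %/% s
  M <- matrix(0, n_out, n_in)
  for (X in seq_len(n_out)) {
    c0 <- (X - 1 + 0.5) / s - 0.5
    c0 <- min(max(c0, 0), n_in - 1)
    i0 <- floor(c0); f <- c0 - i0
    M[X, i0 + 1] <- M[X, i0 + 1] + (1 - f)
    if (f > 0) M[X, i0 + 2] <- M[X, i0 + 2] + f
  }
  M
}

# Apply per-axis matrices M1, M2, M3 to a 3D array (linear separable map).
apply_sep3 <- function(a, M1, M2, M3) {
  dm <- dim(a)
  a <- array(M1 %*% matrix(a, dm[1]), c(nrow(M1), dm[2], dm[3]))
  dm <- dim(a)
  a <- aperm(array(M2 %*% matrix(aperm(a, c(2, 1, 3)), dm[2]),
                   c(nrow(M2), dm[1], dm[3])), c(2, 1, 3))
  dm <- dim(a)
  a <- aperm(array(M3 %*% matrix(aperm(a, c(3, 1, 2)), dm[3]),
                   c(nrow(M3), dm[1], dm[2])), c(2, 3, 1))
  a
}

concat_ch <- function(a, b) {
  dma <- dim(a); dmb <- dim(b)
  out <- array(0, c(dma[1:3], dma[4] + dmb[4]))
  out[, , , seq_len(dma[4])] <- a
  out[, , , dma[4] + seq_len(dmb[4])] <- b
  out
}

# ---- U-net ---------------------------------------------------------------

# Encoder-decoder predicting a 3-channel field from `in_ch` input channels.
# Channel widths double per level; the final field convolution is
# zero-initialized so an untrained network predicts the zero field.
unet_init <- function(in_ch, base, levels, seed) {
  set.seed(derive_seed(seed, 11))
  he <- function(cin, cout) {
    array(stats::rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
          c(3, 3, 3, cin, cout))
  }
  lay <- function(cin, cout) list(W = he(cin, cout), b = numeric(cout))
  ch <- base * 2^(seq_len(levels) - 1L)
  enc <- vector("list", levels)
  enc[[1]] <- list(lay(in_ch, ch[1]))
  for (l in seq_len(levels - 1L) + 1L)
    enc[[l]] <- list(lay(ch[l - 1L], ch[l]), lay(ch[l], ch[l]))
  dec <- vector("list", levels - 1L)
  for (l in rev(seq_len(levels - 1L)))
    dec[[l]] <- list(lay(ch[l + 1L] + ch[l], ch[l]))
  flow <- list(W = array(0, c(3, 3, 3, ch[1], 3)), b = numeric(3))
  list(enc = enc, dec = dec, flow = flow, levels = levels, in_ch = in_ch)
}

unet_fwd <- function(params, x, keep_cache = TRUE) {
  levels <- params$levels
  cache <- list(enc = vector("list", levels), dec = vector("list", levels - 1L),
                pool_in = vector("list", levels))
  acts <- vector("list", levels)
  h <- x
  for (l in seq_len(levels)) {
    if (l > 1L) {
      cache$pool_in[[l]] <- dim(h)
      h <- avgpool2_fwd(h)
    }
    lc <- vector("list", length(params$enc[[l]]))
    for (j in seq_along(params$enc[[l]])) {
      cv <- conv3d_fwd(h, params$enc[[l]][[j]]$W, params$enc[[l]][[j]]$b)
      rl <- relu_fwd(cv$out)
      h <- rl$out
      lc[[j]] <- list(xp = cv$xp, mask = rl$mask)
    }
    cache$enc[[l]] <- lc
    acts[[l]] <- h
  }
  for (l in rev(seq_len(levels - 1L))) {
    up <- upsample2_nearest(h)
    cat_in <- concat_ch(up, acts[[l]])
    cv <- conv3d_fwd(cat_in, params$dec[[l]][[1]]$W, params$dec[[l]][[1]]$b)
    rl <- relu_fwd(cv$out)
    h <- rl$out
    cache$dec[[l]] <- list(xp = cv$xp, mask = rl$mask,
                           up_ch = dim(up)[4])
  }
  fl <- conv3d_fwd(h, params$flow$W, params$flow$b)
  cache$flow_xp <- fl$xp
  list(field = fl$out, cache = if (keep_cache) cache else NULL)
}

unet_bwd <- function(params, cache, grad_field) {
  levels <- params$levels
  g <- list(enc = vector("list", levels), dec = vector("list", levels - 1L),
            flow = NULL)
  bw <- conv3d_bwd(grad_field, cache$flow_xp, params$flow$W)
  g$flow <- list(W = bw$dW, b = bw$db)
  gh <- bw$dx
  skip_grads <- vector("list", levels)
  for (l in seq_len(levels - 1L)) {
    dc <- cache$dec[[l]]
    gr <- relu_bwd(gh, dc$mask)
    bw <- conv3d_bwd(gr, dc$xp, params$dec[[l]][[1]]$W)
    g$dec[[l]] <- list(list(W = bw$dW, b = bw$db))
    up_ch <- dc$up_ch
    gup <- bw$dx[, , , seq_len(up_ch), drop = FALSE]
    skip_grads[[l]] <- bw$dx[, , , up_ch + seq_len(dim(bw$dx)[4] - up_ch),
                             drop = FALSE]
    gh <- upsample2_nearest_bwd(gup)
  }
  # gh is now the gradient at the deepest encoder output
  for (l in rev(seq_len(levels))) {
    if (l < levels) gh <- gh + skip_grads[[l]]
    lc <- cache$enc[[l]]
    glayers <- vector("list", length(lc))
    for (j in rev(seq_along(lc))) {
      gr <- relu_bwd(gh, lc[[j]]$mask)
      bw <- conv3d_bwd(gr, lc[[j]]$xp, params$enc[[l]][[j]]$W)
      glayers[[j]] <- list(W = bw$dW, b = bw$db)
      gh <- bw$dx
    }
    g$enc[[l]] <- glayers
    if (l > 1L) gh <- avgpool2_bwd(gh)
  }
  g$input <- gh
  g
}

# ---- parameter-tree utilities and Adam -----------------------------------

# Apply `f` elementwise over the numeric leaves of parallel nested lists.
tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.numeric(a)) return(do.call(f, trees))
  out <- a
  for (nm in seq_along(a)) {
    if (is.null(a[[nm]])) next
    if (is.list(a[[nm]]) || is.numeric(a[[nm]])) {
      sub <- lapply(trees, `[[`, nm)
      if (is.numeric(a[[nm]]) || is.list(a[[nm]]))
        out[[nm]] <- do.call(tree_map, c(list(f), sub))
    }
  }
  out
}

# Restrict a unet parameter tree to its numeric weight leaves (drop
# bookkeeping fields so tree_map stays shape-aligned).
unet_weights <- function(params) params[c("enc", "dec", "flow")]

adam_init <- function(weights) {
  zeros <- function(w) tree_map(function(x) x * 0, w)
  list(m = zeros(weights), v = zeros(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  weights <- tree_map(function(w, m, v) w - lr * (m / bc1) /
                        (sqrt(v / bc2) + eps),
                      weights, state$m, state$v)
  list(weights = weights, state = state)
}
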