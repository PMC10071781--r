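# Independent brute-force oracles used across the suite. These are written
# as plain per-voxel loops, deliberately sharing no code with the package's
# vectorized implementations.

# Naive per-voxel pull-warp with trilinear or nearest interpolation,
# zero padding outside the source grid. Coordinates are 0-based.
oracle_warp <- function(src, u, mode = "linear") {
  dm <- dim(src)
  out <- array(0, dim(u)[1:3])
  for (k in seq_len(dim(u)[3])) for (j in seq_len(dim(u)[2]))
    for (i in seq_len(dim(u)[1])) {
      p <- c(i - 1 + u[i, j, k, 1], j - 1 + u[i, j, k, 2], k - 1 + u[i, j, k, 3])
      if (mode == "nearest") {
        q <- round(p)
        if (all(q >= 0) && all(q < dm)) out[i, j, k] <- src[q[1] + 1, q[2] + 1, q[3] + 1]
      } else {
        b <- floor(p); f <- p - b
        acc <- 0
        for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
          q <- b + c(dx, dy, dz)
          w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
            (if (dz) f[3] else 1 - f[3])
          if (all(q >= 0) && all(q < dm))
            acc <- acc + w * src[q[1] + 1, q[2] + 1, q[3] + 1]
        }
        out[i, j, k] <- acc
      }
    }
  out
}

# Central/one-sided finite-difference Jacobian determinant, per voxel.
oracle_jacdet <- function(u) {
  dm <- dim(u)[1:3]
  out <- array(NA_real_, dm)
  dphi <- function(comp, axis, i, j, k) {
    idx <- c(i, j, k)
    lo <- idx; hi <- idx
    hi[axis] <- min(idx[axis] + 1, dm[axis]); lo[axis] <- max(idx[axis] - 1, 1)
    den <- hi[axis] - lo[axis]
    du <- (u[hi[1], hi[2], hi[3], comp] - u[lo[1], lo[2], lo[3], comp]) / den
    du + as.numeric(comp == axis)
  }
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    J <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3) J[r, cc] <- dphi(r, cc, i, j, k)
    out[i, j, k] <- det(J)
  }
  out
}

# Smooth random displacement field for property tests (independent of the
# package's phantom generator): white noise box-blurred a few times.
random_smooth_field <- function(dm, amplitude, seed) {
  set.seed(seed)
  u <- array(rnorm(prod(dm) * 3), c(dm, 3))
  blur1 <- function(a) {
    n <- length(a)
    (a + c(a[1], a[-n]) + c(a[-1], a[n])) / 3
  }
  for (rep in 1:4) for (comp in 1:3) {
    v <- u[, , , comp]
    v <- aperm(apply(v, c(2, 3), blur1), c(1, 2, 3))
    v <- aperm(apply(v, c(1, 3), blur1), c(2, 1, 3))
    v <- aperm(apply(v, c(1, 2), blur1), c(2, 3, 1))
    u[, , , comp] <- v
  }
  mx <- max(sqrt(apply(u^2, 1:3, sum)))
  if (mx > 0) u <- u * amplitude / mx
  u
}
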