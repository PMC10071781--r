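# Internal array helpers shared by the phantom generator and the losses.

# Separable Gaussian smoothing with truncated, renormalized kernels at the
# edges (constant arrays are preserved exactly).
smooth_gaussian <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  dm <- dim(arr)
  conv_axis <- function(a, axis) {
    n <- dm[axis]
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- which(seq_len(n) + off >= 1 & seq_len(n) + off <= n)
      K[cbind(idx, idx + off)] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    if (axis == 1L) {
      array(K %*% matrix(a, dm[1], dm[2] * dm[3]), dm)
    } else if (axis == 2L) {
      m <- matrix(aperm(a, c(2, 1, 3)), dm[2], dm[1] * dm[3])
      aperm(array(K %*% m, dm[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      m <- matrix(aperm(a, c(3, 1, 2)), dm[3], dm[1] * dm[2])
      aperm(array(K %*% m, dm[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}

# Sliding-window box sum over a cubic window (odd width), as three
# banded-matrix multiplications (one per axis). Windows are clipped at the
# grid boundary (counts handled separately by the caller). The band
# matrices are memoized per (n, window).
.boxmat_cache <- new.env(parent = emptyenv())
.boxmat <- function(n, window) {
  key <- paste0(n, "_", window)
  if (!is.null(.boxmat_cache[[key]])) return(.boxmat_cache[[key]])
  r <- (window - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- which(seq_len(n) + off >= 1 & seq_len(n) + off <= n)
    B[cbind(idx, idx + off)] <- 1
  }
  .boxmat_cache[[key]] <- B
  B
}

boxsum3 <- function(arr, window) {
  dm <- dim(arr)
  B1 <- .boxmat(dm[1], window); B2 <- .boxmat(dm[2], window)
  B3 <- .boxmat(dm[3], window)
  arr <- array(B1 %*% matrix(arr, dm[1]), dm)
  arr <- aperm(array(B2 %*% matrix(aperm(arr, c(2, 1, 3)), dm[2]),
                     dm[c(2, 1, 3)]), c(2, 1, 3))
  aperm(array(B3 %*% matrix(aperm(arr, c(3, 1, 2)), dm[3]),
              dm[c(3, 1, 2)]), c(2, 3, 1))
}

# Number of in-grid voxels in each clipped cubic window.
boxcount3 <- function(dm, window) {
  boxsum3(array(1, dm), window)
}

# Seed derivation for independent substreams; stays inside 32-bit range.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + k * 9973) %% 2147483647
}
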