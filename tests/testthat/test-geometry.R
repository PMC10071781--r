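test_that("warp with a zero field is a bit-exact identity in both modes", {
  set.seed(11)
  vol <- as_volume(array(runif(6 * 7 * 8), c(6, 7, 8)))
  zf <- zero_field(c(6, 7, 8))
  expect_identical(warp_volume(vol, zf, "linear")$data, vol$data)
  expect_identical(warp_volume(vol, zf, "nearest")$data, vol$data)
})

test_that("constant unit displacement shifts a ramp volume by one voxel", {
  dm <- c(8, 5, 5)
  ramp <- as_volume(array(rep(0:(dm[1] - 1), prod(dm) / dm[1]), dm))
  u <- array(0, c(dm, 3)); u[, , , 1] <- 1
  out <- warp_volume(ramp, as_field(u))
  # interior voxels now hold x + 1; the last slice samples outside -> 0
  expect_equal(out$data[1:(dm[1] - 1), , ],
               ramp$data[1:(dm[1] - 1), , ] + 1)
  expect_equal(out$data[dm[1], , ], array(0, dm[2:3]))
})

test_that("half-voxel displacement interpolates linearly between neighbours", {
  vol <- as_volume(array(0, c(3, 3, 3)))
  vol$data[2, 2, 2] <- 2  # neighbour of (1,2,2) along axis 1 holds 2
  u <- array(0, c(3, 3, 3, 3)); u[1, 2, 2, 1] <- 0.5
  out <- warp_volume(vol, as_field(u))
  expect_equal(out$data[1, 2, 2], 1)
})

test_that("warp_volume matches the brute-force per-voxel oracle", {
  set.seed(42)
  for (rep in 1:8) {
    dm <- c(6, 7, 6)
    src <- array(runif(prod(dm)), dm)
    u <- array(runif(prod(dm) * 3, -3, 3), c(dm, 3))
    got <- warp_volume(as_volume(src), as_field(u))$data
    expect_lt(max(abs(got - oracle_warp(src, u, "linear"))), 1e-6)
    gotn <- warp_volume(as_volume(src), as_field(u), "nearest")$data
    expect_identical(gotn, oracle_warp(src, u, "nearest"))
  }
})

test_that("label warping preserves identity, moves labels, zero-pads", {
  dm <- c(6, 6, 6)
  lab <- array(0, dm); lab[3, 3, 3] <- 7; lab[5, 2, 4] <- 2
  labv <- as_volume(lab)
  expect_identical(warp_labels(labv, zero_field(dm))$data, lab)
  # integer translation by (+1, 0, -1): voxel x reads source at x + u
  u <- array(0, c(dm, 3)); u[, , , 1] <- 1; u[, , , 3] <- -1
  out <- warp_labels(labv, as_field(u))$data
  expect_equal(out[2, 3, 4], 7)
  expect_equal(out[4, 2, 5], 2)
  expect_equal(sort(unique(as.vector(out))), c(0, 2, 7))
  # field pointing far outside -> all background
  u[] <- 100
  expect_true(all(warp_labels(labv, as_field(u))$data == 0))
  expect_error(warp_labels(as_volume(lab + 0.5), zero_field(dm)),
               "integer")
})

test_that("composition neutral elements and constant-translation oracle", {
  dm <- c(7, 7, 7)
  u <- array(random_smooth_field(dm, 1.5, seed = 3), c(dm, 3))
  f <- as_field(u); z <- zero_field(dm)
  expect_equal(compose_displacements(f, z)$u, f$u)
  expect_equal(compose_displacements(z, f)$u, f$u)
  a <- c(1.2, -0.4, 0.7); b <- c(-0.5, 0.3, 1.1)
  fa <- as_field(array(rep(a, each = prod(dm)), c(dm, 3)))
  fb <- as_field(array(rep(b, each = prod(dm)), c(dm, 3)))
  comp <- compose_displacements(fa, fb)$u
  # interior voxels (where x + b stays inside) hold exactly a + b
  interior <- comp[3:5, 3:5, 3:5, ]
  for (cc in 1:3)
    expect_equal(interior[, , , cc],
                 array((a + b)[cc], dim(interior)[1:3]))
})

test_that("warping with a composed field matches sequential warping", {
  dm <- c(12, 12, 12)
  g <- expand.grid(x = 0:11, y = 0:11, z = 0:11)
  blob <- function(c0, s) array(exp(-((g$x - c0[1])^2 + (g$y - c0[2])^2 +
                                        (g$z - c0[3])^2) / (2 * s^2)), dm)
  vol <- as_volume(blob(c(4, 5, 6), 2.5) + 0.6 * blob(c(8, 7, 4), 2))
  rng <- diff(range(vol$data))
  for (seed in 1:3) {
    u1 <- as_field(random_smooth_field(dm, 1.2, seed = seed))
    u2 <- as_field(random_smooth_field(dm, 1.2, seed = seed + 50))
    seq_warp <- warp_volume(warp_volume(vol, u1), u2)
    one_warp <- warp_volume(vol, compose_displacements(u1, u2))
    expect_lt(max(abs(seq_warp$data - one_warp$data)) / rng, 0.05)
  }
})

test_that("jacobian determinant: zero field, uniform expansion, fd oracle", {
  dm <- c(7, 6, 8)
  jd <- jacobian_determinant(zero_field(dm))
  expect_equal(jd$data, array(1, dm))
  # u(x) = 0.1 x -> phi = 1.1 x, det = 1.331 everywhere (field is linear)
  g <- expand.grid(x = 0:(dm[1] - 1), y = 0:(dm[2] - 1), z = 0:(dm[3] - 1))
  u <- array(0, c(dm, 3))
  u[, , , 1] <- array(0.1 * g$x, dm)
  u[, , , 2] <- array(0.1 * g$y, dm)
  u[, , , 3] <- array(0.1 * g$z, dm)
  jd2 <- jacobian_determinant(as_field(u))$data
  expect_equal(jd2[2:6, 2:5, 2:7], array(1.1^3, c(5, 4, 6)), tolerance = 1e-12)
  for (seed in c(2, 17)) {
    u <- random_smooth_field(dm, 2, seed = seed)
    got <- jacobian_determinant(as_field(u))$data
    expect_lt(max(abs(got - oracle_jacdet(u))), 1e-6)
  }
})

test_that("affine resampling: identity bit-exact, translation, scaling", {
  set.seed(8)
  dm <- c(9, 8, 7)
  vol <- as_volume(array(runif(prod(dm)), dm))
  expect_identical(apply_affine(vol, affine_identity())$data, vol$data)
  # pure integer translation: out(x) = in(x + t)
  tr <- c(2, -1, 3)
  out <- apply_affine(vol, affine_transform(diag(3), tr))$data
  expect_equal(out[1:7, 2:8, 1:4], vol$data[3:9, 1:7, 4:7])
  expect_true(all(out[8:9, , ] == 0))
  # scaling a uniform volume: interior of mapped support stays uniform
  unif <- as_volume(array(3.5, dm))
  sc <- apply_affine(unif, affine_transform(diag(3) * 0.5))$data
  expect_true(all(abs(sc[1:4, 1:3, 1:3] - 3.5) < 1e-12))
  expect_error(apply_affine(vol, affine_transform(matrix(0, 3, 3))),
               "singular")
})

test_that("field inversion composes to near identity for smooth fields", {
  dm <- c(14, 14, 14)
  u <- as_field(random_smooth_field(dm, 2, seed = 21))
  v <- invert_displacement(u)
  resid <- compose_displacements(u, v)$u  # v(x) + u(x+v(x)) should be ~0
  interior <- resid[4:11, 4:11, 4:11, ]
  expect_lt(max(abs(interior)), 0.05)
})

test_that("shape mismatches are rejected with a diagnostic", {
  f1 <- zero_field(c(5, 5, 5)); f2 <- zero_field(c(5, 5, 6))
  expect_error(compose_displacements(f1, f2), "grids differ")
})
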