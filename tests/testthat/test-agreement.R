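test_that("exact linear relations are recovered by the regression", {
  ids <- paste0("s", 1:6)
  x <- c(1.1, 1.3, 1.5, 1.8, 2.1, 2.4)
  r1 <- pearson_regression(paired_measurements(ids, x, x))
  expect_equal(r1$slope, 1, tolerance = 1e-12)
  expect_equal(r1$intercept, 0, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  r2 <- pearson_regression(paired_measurements(ids, x, 2 * x + 1))
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, 1, tolerance = 1e-12)
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
})

test_that("regression matches a hand-written normal-equations oracle", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(10:20, 1)
    x <- runif(n, 1, 2.5)
    y <- 0.8 * x + 0.2 + rnorm(n, sd = 0.1)
    y <- pmax(y, 0.05)
    r <- pearson_regression(paired_measurements(paste0("s", 1:n), x, y))
    # normal equations
    sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx; intercept <- mean(y) - slope * mean(x)
    r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
    expect_equal(r$slope, slope, tolerance = 1e-10)
    expect_equal(r$intercept, intercept, tolerance = 1e-10)
    expect_equal(r$r_squared, r2, tolerance = 1e-10)
  }
})

test_that("ICC(3,1) is 1 for identity and for constant offsets", {
  ids <- paste0("s", 1:5)
  x <- c(1.2, 1.4, 1.9, 2.2, 1.1)
  expect_equal(icc_consistency(paired_measurements(ids, x, x))$icc, 1,
               tolerance = 1e-12)
  expect_equal(icc_consistency(paired_measurements(ids, x, x + 0.3))$icc, 1,
               tolerance = 1e-12)
  expect_error(icc_consistency(paired_measurements(ids, rep(1.5, 5),
                                                   rep(1.5, 5))),
               "degenerate")
})

test_that("ICC(3,1) matches an aov mean-squares oracle", {
  set.seed(13)
  for (rep in 1:4) {
    n <- sample(6:12, 1)
    x <- runif(n, 1, 2.5)
    y <- pmax(x + rnorm(n, sd = 0.15) + 0.1, 0.05)
    got <- icc_consistency(paired_measurements(paste0("s", 1:n), x, y))$icc
    # independent two-way ANOVA decomposition via aov
    df <- data.frame(value = c(x, y),
                     subject = factor(rep(1:n, 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
    ms_subj <- ms[1]; ms_err <- ms[3]
    expect_equal(got, (ms_subj - ms_err) / (ms_subj + ms_err),
                 tolerance = 1e-10)
  }
})

test_that("Bland-Altman bias and limits match direct computation", {
  ids <- paste0("s", 1:5)
  x <- c(1.2, 1.4, 1.9, 2.2, 1.1)
  b0 <- bland_altman(paired_measurements(ids, x, x))
  expect_equal(b0$bias, 0); expect_equal(b0$sd_diff, 0)
  expect_equal(b0$loa_low, 0); expect_equal(b0$loa_high, 0)
  b1 <- bland_altman(paired_measurements(ids, x, x + 0.1))
  expect_equal(b1$bias, 0.1, tolerance = 1e-12)
  expect_equal(b1$sd_diff, 0, tolerance = 1e-12)
  set.seed(3)
  y <- pmax(x + rnorm(5, sd = 0.2), 0.05)
  b2 <- bland_altman(paired_measurements(ids, x, y))
  d <- y - x
  expect_equal(b2$bias, mean(d), tolerance = 1e-12)
  expect_equal(b2$sd_diff, sqrt(sum((d - mean(d))^2) / 4), tolerance = 1e-12)
  expect_equal(b2$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
})

test_that("limits of agreement cover about 95% of Gaussian differences", {
  set.seed(99)
  n <- 2000
  x <- runif(n, 1, 2)
  y <- x + rnorm(n, mean = 0.05, sd = 0.1)
  y <- pmax(y, 0.01)
  ba <- bland_altman(list(x = x, y = y))
  d <- y - x
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(cover, 0.93); expect_lt(cover, 0.97)
})

test_that("R-squared and ICC invariances hold under rescaling and shifts", {
  set.seed(21)
  n <- 15
  x <- runif(n, 1, 2.5)
  y <- pmax(0.9 * x + 0.1 + rnorm(n, sd = 0.1), 0.05)
  ids <- paste0("s", 1:n)
  r <- pearson_regression(paired_measurements(ids, x, y))
  r_scaled <- pearson_regression(paired_measurements(ids, 2 * x + 0.5,
                                                     0.7 * y + 0.1))
  expect_equal(r$r_squared, r_scaled$r_squared, tolerance = 1e-12)
  i1 <- icc_consistency(paired_measurements(ids, x, y))$icc
  i2 <- icc_consistency(paired_measurements(ids, x, y + 0.4))$icc
  expect_equal(i1, i2, tolerance = 1e-10)
})

test_that("compare_methods joins by subject and region correctly", {
  tmpl <- shared_template()
  aa <- build_phantom_atlas(tmpl$tissue_labels)
  set.seed(17)
  dm <- vol_dim(tmpl$template_mr)
  mk_rep <- function(id, noise) {
    pet <- phantom_pet_template(tmpl, "positive")
    pet$data <- pmax(pet$data * runif(1, 0.9, 1.1) +
                       array(rnorm(prod(dm), sd = noise), dm), 0.01)
    compute_suvr(pet, aa$atlas, aa$voi_map, subject_id = id)
  }
  reps <- lapply(paste0("s", 1:8), mk_rep, noise = 0.05)
  # self-comparison: perfect agreement in every region
  tab <- compare_methods(reps, reps)
  expect_equal(nrow(tab), 6)
  expect_false(any(tab$flagged))
  expect_equal(tab$slope, rep(1, 6), tolerance = 1e-10)
  expect_equal(tab$icc, rep(1, 6), tolerance = 1e-10)
  expect_equal(tab$bias, rep(0, 6), tolerance = 1e-12)
  # one common subject only: all regions flagged
  tab2 <- compare_methods(reps[1], reps[1])
  expect_true(all(tab2$flagged))
  expect_true(all(is.na(tab2$slope)))
})

test_that("an injected linear relation between methods is recovered", {
  set.seed(29)
  n <- 20
  x <- runif(n, 1.0, 2.4)
  y <- pmax(0.9 * x + 0.1 + rnorm(n, sd = 0.05), 0.05)
  ids <- paste0("s", 1:n)
  tx <- data.frame(subject_id = ids, region = "global_cerebral_cortex",
                   suvr = x)
  ty <- data.frame(subject_id = ids, region = "global_cerebral_cortex",
                   suvr = y)
  tab <- compare_methods(tx, ty)
  r <- pearson_regression(paired_measurements(ids, x, y))
  se <- sqrt(sum((y - r$intercept - r$slope * x)^2 / (n - 2)) /
               sum((x - mean(x))^2))
  expect_lt(abs(tab$slope[1] - 0.9), 2 * se + 1e-9)
})
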