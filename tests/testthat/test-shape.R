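test_that("size/shape decomposition matches the hand computation", {
  tab <- measurement_table(
    matrix(c(100, 400), 1, dimnames = list(NULL, c("eye.b", "eye.h"))),
    "s1", "A")
  sh <- shape_decompose(tab)
  expect_equal(sh$isosize[[1]], log(200))
  expect_equal(unname(sh$shape[1, ]), c(-log(2), log(2)))

  # equal measurements: zero shape
  tab2 <- measurement_table(
    matrix(rep(250, 3), 1, dimnames = list(NULL, c("eye.b", "eye.d", "eye.h"))),
    "s1", "A")
  expect_equal(unname(shape_decompose(tab2)$shape[1, ]), rep(0, 3))
})

test_that("doubling a specimen shifts isosize by ln 2 and leaves shape fixed", {
  sim <- simulate_measurements(
    synthetic_config(p = 5, groups = list(list(label = "A", n = 8)),
                     seed = 14))
  sh <- shape_decompose(sim$table)
  tab2 <- sim$table
  tab2$values[3, ] <- 2 * tab2$values[3, ]
  sh2 <- shape_decompose(tab2)
  expect_equal(sh2$isosize[[3]], sh$isosize[[3]] + log(2))
  expect_lt(max(abs(sh2$shape[3, ] - sh$shape[3, ])), 1e-12)
  expect_lt(max(abs(rowSums(sh2$shape))), 1e-9)
})

test_that("shape decomposition refuses missing values", {
  vals <- cbind(eye.b = c(100, NA), eye.d = c(200, 210))
  tab <- measurement_table(vals, c("a", "b"), "A")
  expect_error(shape_decompose(tab), "impute")
})

test_that("proportional specimens have zero shape variance", {
  base <- c(eye.b = 100, eye.d = 230, eye.h = 310)
  vals <- rbind(base, 1.4 * base, 0.8 * base, 2.2 * base)
  tab <- measurement_table(vals, sprintf("s%d", 1:4), "A")
  res <- shape_pca(shape_decompose(tab))
  expect_lt(max(res$eigenvalues), 1e-12)
})

test_that("a planted rank-1 contrast dominates the shape PCA", {
  set.seed(5)
  u <- c(2, -1, -1, 0, 0) / sqrt(6)   # unit contrast, sums to zero
  n <- 40
  scores <- stats::rnorm(n, 0, 0.2)
  noise <- matrix(stats::rnorm(n * 5, 0, 1e-4), n, 5)
  logv <- 6 + outer(scores, u) + noise
  vals <- exp(logv)
  colnames(vals) <- character_registry()$abbreviation[1:5]
  tab <- measurement_table(vals, sprintf("s%d", 1:n), "A")
  res <- shape_pca(shape_decompose(tab))
  expect_gt(res$variance_fraction[1], 0.99)
  expect_gt(variance_explained(res, 1), 0.99)
  angle <- acos(min(1, abs(sum(res$loadings[, 1] * u)))) * 180 / pi
  expect_lt(angle, 1)
  # completeness and bounds of variance_explained
  expect_equal(variance_explained(res, ncol(res$loadings)), 1.0)
  expect_error(variance_explained(res, 0), "out of range")
})

test_that("shape PCA matches a brute-force projected eigendecomposition", {
  for (seed in 1:3) {
    set.seed(seed)
    p <- sample(3:4, 1)
    n <- sample(4:6, 1)
    vals <- exp(matrix(stats::rnorm(n * p, 6, 0.2), n, p))
    colnames(vals) <- character_registry()$abbreviation[seq_len(p)]
    tab <- measurement_table(vals, sprintf("s%d", seq_len(n)), "A")
    sh <- shape_decompose(tab)
    res <- shape_pca(sh)

    # oracle: explicit orthonormal basis of the sum-zero subspace
    H <- qr.Q(qr(cbind(rep(1, p), diag(p))))[, 2:p, drop = FALSE]
    proj <- sh$shape %*% H
    eo <- eigen(stats::cov(proj), symmetric = TRUE)
    expect_equal(res$eigenvalues, pmax(eo$values, 0), tolerance = 1e-8)
    load_oracle <- H %*% eo$vectors
    for (j in seq_len(p - 1)) {
      a <- res$loadings[, j]; b <- load_oracle[, j]
      if (eo$values[j] > 1e-10)
        expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
    }
    # trace conservation
    expect_equal(sum(res$eigenvalues),
                 sum(apply(sh$shape, 2, stats::var)), tolerance = 1e-9)
    # loadings orthogonal to the all-ones vector, scores = shape . loadings
    expect_lt(max(abs(colSums(res$loadings))), 1e-9)
    expect_equal(res$scores, sh$shape %*% res$loadings)
  }
})

test_that("allometry coefficients sum to zero and recover a planted vector", {
  a <- c(0.3, -0.1, -0.2, 0.15, -0.15)
  cfg <- synthetic_config(p = 5, groups = list(list(label = "A", n = 150)),
                          sigma_size = 0.15, allometry = a,
                          sigma_noise = 0.02, seed = 8)
  sim <- simulate_measurements(cfg)
  sh <- shape_decompose(sim$table)
  b <- allometry_coefficients(sh)
  expect_lt(abs(sum(b)), 1e-9)
  sp <- allometry_ratio_spectrum(sh, n_boot = 400, level = 0.95, seed = 2)
  expect_true(all(a >= sp$ci_low - 1e-12 & a <= sp$ci_high + 1e-12))

  # permutation invariance
  idx <- sample(nrow(sh$shape))
  sh_perm <- sh
  sh_perm$shape <- sh$shape[idx, , drop = FALSE]
  sh_perm$isosize <- sh$isosize[idx]
  sh_perm$group <- sh$group[idx]
  sh_perm$specimen_id <- sh$specimen_id[idx]
  expect_equal(allometry_coefficients(sh_perm), b)
})

test_that("isometric data give null allometry and null spectrum", {
  cfg <- synthetic_config(p = 5, groups = list(list(label = "A", n = 200)),
                          sigma_size = 0.15, sigma_noise = 0.02, seed = 18)
  sim <- simulate_measurements(cfg)
  sh <- shape_decompose(sim$table)
  b <- allometry_coefficients(sh)
  # 3 SE bound for the slope of z_k on isosize under the generator
  se <- 0.02 / (0.15 * sqrt(200))
  expect_true(all(abs(b) < 3 * se * sqrt(2)))
  # 99% intervals: a 68% CI misses the true 0 a third of the time per
  # variable by construction, so the joint null check needs wide CIs
  sp <- allometry_ratio_spectrum(sh, n_boot = 300, level = 0.99, seed = 4)
  expect_true(all(sp$ci_low <= 0 & sp$ci_high >= 0))
})

test_that("zero size variance is an error for allometry", {
  vals <- exp(6 + rbind(c(0.1, -0.1, 0), c(0.2, -0.2, 0), c(0, 0, 0)))
  colnames(vals) <- character_registry()$abbreviation[1:3]
  vals <- vals / exp(rowMeans(log(vals)))  # force equal geometric means
  tab <- measurement_table(vals, c("a", "b", "c"), "A")
  sh <- shape_decompose(tab)
  expect_error(allometry_coefficients(sh), "isosize variance")
})

test_that("PCA ratio spectrum: boundary, determinism and extreme recovery", {
  sim <- planted_scenario(p = 6, n = 30, delta_contrast = 0.2,
                          size_offset = 0, seed = 25)
  sh <- shape_decompose(sim$table)
  pca <- shape_pca(sh)

  one <- pca_ratio_spectrum(pca, 1, sh, n_boot = 1, seed = 3)
  expect_equal(unname(one$ci_low), unname(one$ci_high))

  s1 <- pca_ratio_spectrum(pca, 1, sh, n_boot = 50, seed = 6)
  s2 <- pca_ratio_spectrum(pca, 1, sh, n_boot = 50, seed = 6)
  expect_identical(s1$ci_low, s2$ci_low)

  # the planted contrast variables occupy the spectrum extremes
  ex <- spectrum_extremes(s1)
  expect_setequal(ex, character_registry()$abbreviation[1:2])
  expect_true(s1$stratified)
})

test_that("size-shape scatter reports the correlation and degenerates to NA", {
  sim <- planted_scenario(p = 5, n = 40, delta_contrast = 0,
                          size_offset = 0, seed = 33,
                          allometry = c(0.3, -0.3, 0, 0, 0))
  sh <- shape_decompose(sim$table)
  pca <- shape_pca(sh)
  sc <- size_shape_scatter(pca, sh, 1)
  expect_equal(nrow(sc$data), 80)
  expect_gt(abs(sc$r), 0.5)   # strongly allometric PC1 by construction

  sh0 <- sh
  sh0$isosize[] <- 1.0
  expect_true(is.na(size_shape_scatter(pca, sh0, 1)$r))
})
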