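test_that("standard distance follows the pooled-covariance formula", {
  # groups {0.9, 1.1} and {1.9, 2.1} on one log-ratio: means 1 and 2,
  # pooled variance ((1)(0.02)+(1)(0.02))/2 = 0.02
  x <- matrix(c(0.9, 1.1, 1.9, 2.1), ncol = 1)
  g <- c("A", "A", "B", "B")
  cmp <- group_comparison("A", "B")
  D <- standard_distance(1, x, g, cmp)
  expect_equal(D, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(D, oracle_std_dist(x[1:2, 1], x[3:4, 1]))

  # identical group means
  x0 <- matrix(c(1, 2, 3, 3, 2, 1), ncol = 1)
  g0 <- c("A", "A", "A", "B", "B", "B")
  expect_equal(standard_distance(1, x0, g0, cmp), 0)

  # homogeneity in the direction vector
  set.seed(2)
  X <- matrix(stats::rnorm(60), 20, 3)
  g2 <- rep(c("A", "B"), each = 10)
  v <- c(1, -2, 0.5)
  expect_equal(standard_distance(v, X, g2, cmp),
               standard_distance(-7.3 * v, X, g2, cmp))

  # degenerate direction
  Xc <- matrix(1, 20, 2)
  expect_error(standard_distance(c(1, -1), Xc, g2, cmp), "degenerate")
})

test_that("delta is zero for identical isosize and matches the analytic ratio", {
  # both groups share the same isosize values; only shape differs
  set.seed(4)
  n <- 12
  sz <- stats::rnorm(n, 6, 0.1)
  u1 <- stats::rnorm(n, 0, 0.02); u2 <- stats::rnorm(n, 0, 0.02)
  logv <- rbind(cbind(sz + 0.1 + u1, sz - 0.1 - u1),
                cbind(sz - 0.1 + u2, sz + 0.1 - u2))
  g <- rep(c("A", "B"), each = n)
  cmp <- group_comparison("A", "B")
  d <- delta(c(1, -1), logv, g, cmp)
  expect_equal(d, 0, tolerance = 1e-12)

  # Monte-Carlo agreement with the closed-form delta of the generator
  sim <- planted_scenario(p = 6, n = 200, delta_contrast = 0.15,
                          size_offset = 0.08, seed = 44)
  truth <- sim$truth$pairs
  cmp2 <- group_comparison("A", "B")
  dirn <- replace(numeric(6), 1:2, c(1, -1))
  dhat <- delta(dirn, log(sim$table$values), sim$table$group, cmp2)
  expect_equal(dhat, truth$delta[1], tolerance = 0.35)  # ~2 SE at n=200
  expect_gte(dhat, 0)
})

test_that("the extractor maximises marginal D and agrees with a brute-force scan", {
  for (seed in c(3, 17)) {
    sim <- planted_scenario(p = 8, n = 25, delta_contrast = 0.12,
                            seed = seed)
    ex <- extract_best_ratios(sim$table, group_comparison("A", "B"))
    oracle <- oracle_best_pair(sim$table, "A", "B")
    expect_setequal(c(ex$ratios[[1]]$numerator, ex$ratios[[1]]$denominator),
                    oracle$pair)
    expect_equal(ex$ratios[[1]]$D, oracle$D, tolerance = 1e-12)
  }
})

test_that("extracted ratios are oriented with pooled mean ratio >= 1", {
  sim <- planted_scenario(p = 6, n = 30, delta_contrast = 0.2, seed = 51)
  ex <- extract_best_ratios(sim$table, group_comparison("A", "B"))
  for (r in ex$ratios) {
    pooled <- mean(log(sim$table$values[, r$numerator] /
                         sim$table$values[, r$denominator]))
    expect_gte(pooled, 0)
  }
})

test_that("two groups from one distribution trigger the low-separation warning", {
  cfg <- synthetic_config(p = 6, groups = list(list(label = "A", n = 30),
                                               list(label = "B", n = 30)),
                          sigma_noise = 0.02, seed = 61)
  sim <- simulate_measurements(cfg)
  ex <- extract_best_ratios(sim$table, group_comparison("A", "B"))
  expect_true(ex$low_separation)
  expect_lt(ex$ratios[[1]]$D, 1)
})

test_that("D of any log-ratio is invariant to a specimen-wise size shift", {
  sim <- planted_scenario(p = 5, n = 20, seed = 71)
  logv <- log(sim$table$values)
  cmp <- group_comparison("A", "B")
  dirs <- list(c(1, -1, 0, 0, 0), c(0, 1, 0, 0, -1), c(1, 0, -1, 0, 0))
  for (v in dirs) {
    before <- standard_distance(v, logv, sim$table$group, cmp)
    shifted <- logv
    shifted[5, ] <- shifted[5, ] + 0.8   # scale specimen 5 by e^0.8
    after <- standard_distance(v, shifted, sim$table$group, cmp)
    expect_equal(after, before, tolerance = 1e-12)
  }
})

test_that("ratio ranges exclude imputed specimens but D keeps them", {
  sim <- planted_scenario(p = 5, n = 15, delta_contrast = 0.3, seed = 81)
  tab <- sim$table
  # knock out one group-A specimen's denominator and impute it back
  tab$values[2, "eye.d"] <- NA
  tab$missing_mask[2, "eye.d"] <- TRUE
  imp <- impute_missing(tab, seed = 9)
  ex <- extract_best_ratios(imp$table, group_comparison("A", "B"))
  r <- ex$ratios[[1]]
  expect_setequal(c(r$numerator, r$denominator), c("eye.b", "eye.d"))
  rng <- ratio_ranges(imp$table, "A", r$numerator, r$denominator)
  vals <- sim$table$values
  ratios_all <- vals[sim$table$group == "A", r$numerator] /
    vals[sim$table$group == "A", r$denominator]
  ratios_obs <- ratios_all[-2]
  expect_equal(rng, range(ratios_obs))
  # D used all specimens including the imputed one
  logv <- log(imp$table$values)
  x <- logv[, r$numerator] - logv[, r$denominator]
  expect_equal(r$D, oracle_std_dist(x[imp$table$group == "A"],
                                    x[imp$table$group == "B"]))

  # single-specimen group: min = max
  one <- measurement_table(
    matrix(c(100, 50), 1, dimnames = list(NULL, c("eye.b", "eye.d"))),
    "solo", "Z")
  expect_equal(ratio_ranges(one, "Z", "eye.b", "eye.d"), c(2, 2))
})

test_that("the report stars disjoint ranges and is byte-deterministic", {
  sim <- planted_scenario(p = 5, n = 25, delta_contrast = 0.4,
                          sigma_noise = 0.01, seed = 91)
  cmp <- group_comparison("A", "B")
  rep1 <- table2_report(sim$table, list(cmp))
  expect_s3_class(rep1, "data.frame")
  expect_equal(nrow(rep1), 2)
  expect_true(rep1$starred[1])   # planted ranges are essentially disjoint

  # identical groups: equal ranges, no star
  half <- sim$table$values[sim$table$group == "A", ]
  dup <- measurement_table(rbind(half, half),
                           sprintf("s%d", seq_len(2 * nrow(half))),
                           rep(c("G1", "G2"), each = nrow(half)))
  # identical groups have zero pooled mean difference everywhere, D = 0
  rep2 <- table2_report(dup, list(group_comparison("G1", "G2")))
  expect_equal(rep2$range_1, rep2$range_2)
  expect_false(any(rep2$starred))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  utils::write.table(rep1, f1, sep = "\t")
  utils::write.table(table2_report(sim$table, list(cmp)), f2, sep = "\t")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("extractor argument validation", {
  sim <- planted_scenario(p = 4, n = 10, seed = 99)
  cmp <- group_comparison("A", "B")
  expect_error(extract_best_ratios(sim$table, cmp, n_ratios = 4),
               "at most p - 1")
  expect_error(group_comparison("A", "A"), "disjoint")
  holey <- inject_missing(sim$table, 0.05, seed = 3)
  expect_error(extract_best_ratios(holey, cmp), "impute")
})
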