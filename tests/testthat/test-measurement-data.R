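test_that("reading a clean CSV yields a validated table with no missing cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,group,eye.b,eye.d,eye.h",
               "s1,A,100,200,300",
               "s2,A,110,210,310"), f)
  tab <- read_measurement_table(f)
  expect_s3_class(tab, "measurement_table")
  expect_equal(dim(tab), c(2L, 3L))
  expect_false(any(tab$missing_mask))
  expect_false(any(tab$imputed_mask))
})

test_that("empty cells and NA sentinels become missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,group,eye.b,eye.d,eye.h",
               "s1,A,100,,300",
               "s2,A,110,210,nan"), f)
  tab <- read_measurement_table(f)
  expect_equal(sum(tab$missing_mask), 2L)
  expect_true(tab$missing_mask["s1", "eye.d"])
  expect_true(tab$missing_mask["s2", "eye.h"])
})

test_that("parse and validation errors name the offending cell", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,group,eye.b,eye.d",
               "s1,A,100,abc"), f)
  expect_error(read_measurement_table(f), "row 1.*eye.d")
  writeLines(c("specimen_id,group,eye.b,eye.d",
               "s1,A,100,-5"), f)
  expect_error(read_measurement_table(f), "non-positive|non-finite")
  writeLines(c("specimen_id,group,eye.b,eye.d",
               "s1,A,100,200", "s1,A,100,200"), f)
  expect_error(read_measurement_table(f), "duplicate specimen_id")
  writeLines(c("specimen_id,group,eye.b,bogus",
               "s1,A,100,200"), f)
  expect_warning(tab <- read_measurement_table(f), "bogus")
  expect_equal(colnames(tab$values), "eye.b")
})

test_that("a 289 x 20 table round-trips through CSV bit-identically", {
  cfg <- synthetic_config(
    p = 20,
    groups = list(list(label = "calandrae", n = 120),
                  list(label = "quinarius", n = 100),
                  list(label = "apiovorus", n = 69)),
    missing_rate = 0.02, seed = 42)
  tab <- simulate_measurements(cfg)$table
  expect_equal(dim(tab), c(289L, 20L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurement_table(tab, f)
  back <- read_measurement_table(f)
  expect_identical(back$values, tab$values)
  expect_identical(back$missing_mask, tab$missing_mask)
  expect_identical(back$group, tab$group)
})

test_that("a planted noise artifact is flagged at threshold 0.5 and clean multiples are not", {
  sim <- simulate_measurements(
    synthetic_config(p = 8, groups = list(list(label = "A", n = 60)),
                     sigma_size = 0.15, sigma_noise = 0.02, seed = 11))
  corrupted <- inject_artifact(sim$table, "gst.b", fraction = 0.4,
                               noise_sd = 0.5, seed = 12)
  qc <- correlation_qc(corrupted, threshold = 0.5)
  expect_equal(qc$flagged_variables, "gst.b")
  expect_true(isSymmetric(qc$correlation_matrix))
  expect_equal(diag(qc$correlation_matrix), rep(1, 8),
               ignore_attr = TRUE)

  # columns that are exact multiples of one column: all r = 1, no flags
  base <- exp(stats::rnorm(20, 6, 0.1))
  vals <- outer(base, c(1, 2, 0.5, 3))
  colnames(vals) <- c("eye.b", "eye.d", "eye.h", "hea.b")
  tab <- measurement_table(vals, sprintf("s%d", 1:20), "A")
  qc2 <- correlation_qc(tab, threshold = 0.5)
  expect_length(qc2$flagged_variables, 0)
  expect_equal(max(abs(qc2$correlation_matrix - 1)), 0, tolerance = 1e-12)
})

test_that("a zero-variance variable is flagged as constant", {
  vals <- cbind(eye.b = rep(100, 10),
                eye.d = exp(stats::rnorm(10, 5, 0.1)),
                eye.h = exp(stats::rnorm(10, 5, 0.1)))
  tab <- measurement_table(vals, sprintf("s%d", 1:10), "A")
  qc <- suppressWarnings(correlation_qc(tab))
  expect_true("eye.b" %in% qc$flagged_variables)
  expect_equal(unname(qc$flag_reason[["eye.b"]]), "constant")
})

test_that("QC flagging is monotone in the threshold", {
  sim <- simulate_measurements(
    synthetic_config(p = 10, groups = list(list(label = "A", n = 50)),
                     sigma_size = 0.1, sigma_noise = 0.05, seed = 3))
  tab <- inject_artifact(sim$table, "gst.l", 0.5, 0.4, seed = 4)
  for (pair in list(c(0.2, 0.5), c(0.5, 0.8), c(0.3, 0.9))) {
    f1 <- correlation_qc(tab, pair[1])$flagged_variables
    f2 <- correlation_qc(tab, pair[2])$flagged_variables
    expect_true(all(f1 %in% f2))
  }
})

test_that("row-centred log-correlations are invariant to per-specimen scaling", {
  sim <- simulate_measurements(
    synthetic_config(p = 6, groups = list(list(label = "A", n = 25)),
                     seed = 9))
  logv <- log(sim$table$values)
  centred <- logv - rowMeans(logv)
  before <- stats::cor(centred)
  logv2 <- logv
  logv2[7, ] <- logv2[7, ] + log(3.7)   # scale one specimen by 3.7
  centred2 <- logv2 - rowMeans(logv2)
  expect_lt(max(abs(stats::cor(centred2) - before)), 1e-9)
})

test_that("drop_variables handles identity, removal and unknown names", {
  sim <- simulate_measurements(
    synthetic_config(p = 20, groups = list(list(label = "A", n = 10)),
                     seed = 2))
  tab <- sim$table
  expect_identical(drop_variables(tab, character()), tab)
  dropped <- drop_variables(tab, "gst.b")
  expect_equal(ncol(dropped$values), 19L)
  expect_false("gst.b" %in% colnames(dropped$values))
  expect_error(drop_variables(tab, "nope"), "unknown variable")
  # original column order recoverable from the registry order
  reg_order <- character_registry()$abbreviation
  restored <- intersect(reg_order, c(colnames(dropped$values), "gst.b"))
  expect_identical(restored, colnames(tab$values))
})

test_that("imputation is a no-op on complete tables", {
  sim <- simulate_measurements(
    synthetic_config(p = 5, groups = list(list(label = "A", n = 15)),
                     seed = 21))
  out <- impute_missing(sim$table, seed = 1)
  expect_identical(out$table$values, sim$table$values)
  expect_equal(out$log$n_imputed_cells, 0L)
  expect_false(any(out$table$imputed_mask))
})

test_that("ridge imputation beats column-mean imputation and is deterministic", {
  cfg <- synthetic_config(p = 8, groups = list(list(label = "A", n = 80)),
                          sigma_size = 0.15, sigma_noise = 0.03, seed = 31)
  complete <- simulate_measurements(cfg)$table
  holey <- inject_missing(complete, rate = 0.05, seed = 32)
  miss <- holey$missing_mask
  expect_gt(sum(miss), 0)

  out1 <- impute_missing(holey, seed = 5)
  out2 <- impute_missing(holey, seed = 5)
  expect_identical(out1$table$values, out2$table$values)
  expect_equal(sum(out1$table$imputed_mask), out1$log$n_imputed_cells)

  # observed cells untouched
  expect_identical(out1$table$values[!miss], complete$values[!miss])

  truth <- log(complete$values[miss])
  rmse_ridge <- sqrt(mean((log(out1$table$values[miss]) - truth)^2))
  colmean <- log(holey$values)
  for (j in seq_len(ncol(colmean)))
    colmean[miss[, j], j] <- mean(colmean[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((colmean[miss] - truth)^2))
  expect_lt(rmse_ridge, rmse_mean)
})

test_that("imputation rejects fully missing rows and columns", {
  vals <- cbind(eye.b = c(NA, NA, NA), eye.d = c(100, 110, 120))
  tab <- measurement_table(vals, c("a", "b", "c"), "A")
  expect_error(impute_missing(tab), "entirely missing")
  vals2 <- cbind(eye.b = c(NA, 100, 105), eye.d = c(NA, 110, 120))
  tab2 <- measurement_table(vals2, c("a", "b", "c"), "A")
  expect_error(impute_missing(tab2), "entirely missing")
})
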