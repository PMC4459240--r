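#' PCA ratio spectrum with bootstrap confidence intervals
#'
#' Orders the variables by their loading on one shape principal component.
#' Only ratios formed from variables at opposite ends of the spectrum
#' matter for that component: the log-ratio of the two extreme variables
#' is the body ratio that changes most along it. Per-variable confidence
#' intervals come from resampling specimens with replacement (stratified
#' by group when group labels are present), recomputing the loading,
#' aligning its sign with the point estimate, and taking the central
#' `level` interval. Defaults are 1000 replicates at 68% coverage.
#'
#' @param result a [shape_pca()] result.
#' @param pc component index.
#' @param shape the [shape_decompose()] result underlying `result`.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param level central interval coverage fraction.
#' @param seed integer seed; identical seeds give identical intervals.
#' @return An object of class `ratio_spectrum`: `axis_tag`,
#'   `coefficients` (named, in registry order), `ordering` (variables
#'   sorted by coefficient, ascending), `ci_low`, `ci_high`, `n_boot`,
#'   `level`, `n_skipped` (degenerate resamples redrawn).
#' @export
pca_ratio_spectrum <- function(result, pc = 1, shape, n_boot = 1000,
                               level = 0.68, seed = 1L) {
  stopifnot(inherits(result, "shape_pca"), inherits(shape, "shape_table"))
  if (!(pc >= 1 && pc <= ncol(result$loadings))) stop("'pc' out of range")
  point <- result$loadings[, pc]
  stat <- function(idx) {
    sub <- .subset_shape(shape, idx)
    load <- shape_pca(sub)$loadings[, pc]
    # align sign with the point estimate
    if (sum(load * point) < 0) load <- -load
    load
  }
  .spectrum_boot(point, shape, stat, paste0("PC", pc), n_boot, level, seed)
}

#' Allometry ratio spectrum with bootstrap confidence intervals
#'
#' As [pca_ratio_spectrum()] but over the allometry coefficients: the
#' variables are ordered by their slope on isosize, so the ratio of the
#' two extreme variables is the most allometric body ratio. Under
#' isometry all intervals should overlap zero.
#'
#' @inheritParams pca_ratio_spectrum
#' @param shape a [shape_decompose()] result.
#' @return A `ratio_spectrum` with `axis_tag = "allometry"`.
#' @export
allometry_ratio_spectrum <- function(shape, n_boot = 1000, level = 0.68,
                                     seed = 1L) {
  stopifnot(inherits(shape, "shape_table"))
  point <- allometry_coefficients(shape)
  stat <- function(idx) allometry_coefficients(.subset_shape(shape, idx))
  .spectrum_boot(point, shape, stat, "allometry", n_boot, level, seed)
}

# internal: restrict a shape_table to row indices
.subset_shape <- function(shape, idx) {
  structure(list(specimen_id = shape$specimen_id[idx],
                 group = shape$group[idx], strain = shape$strain[idx],
                 isosize = shape$isosize[idx],
                 shape = shape$shape[idx, , drop = FALSE],
                 imputed_specimen = shape$imputed_specimen[idx]),
            class = "shape_table")
}

# internal: stratified specimen bootstrap of a per-variable statistic
.spectrum_boot <- function(point, shape, stat, axis_tag, n_boot, level,
                           seed) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  n <- nrow(shape$shape)
  groups <- shape$group
  strata <- if (length(unique(groups)) > 1L) split(seq_len(n), groups)
            else list(seq_len(n))
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, n_boot, length(point))
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), length(s), replace = TRUE)]),
        use.names = FALSE)
      # a resample where some shape coordinate is constant is degenerate
      if (all(apply(shape$shape[idx, , drop = FALSE], 2, stats::sd) > 0) &&
          stats::sd(shape$isosize[idx]) > 0) break
      n_skipped <- n_skipped + 1L
      if (n_skipped > 100L * n_boot) stop("bootstrap degenerate: data ",
                                          "has (nearly) constant columns")
    }
    reps[b, ] <- stat(idx)
  }
  alpha <- (1 - level) / 2
  ci <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  structure(list(axis_tag = axis_tag, coefficients = point,
                 ordering = names(sort(point)),
                 ci_low = stats::setNames(ci[1, ], names(point)),
                 ci_high = stats::setNames(ci[2, ], names(point)),
                 n_boot = n_boot, level = level, n_skipped = n_skipped,
                 stratified = length(strata) > 1L),
            class = "ratio_spectrum")
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat("Ratio spectrum [", x$axis_tag, "], ", x$n_boot,
      " bootstrap replicates, ", round(100 * x$level), "% CIs",
      if (x$stratified) ", stratified by group", "\n", sep = "")
  ord <- x$ordering
  df <- data.frame(coefficient = x$coefficients[ord],
                   ci_low = x$ci_low[ord], ci_high = x$ci_high[ord])
  print(round(df, 4))
  ex <- c(ord[length(ord)], ord[1])
  cat("Dominant ratio:", ex[1], ":", ex[2], "\n")
  invisible(x)
}

#' Dot-and-bar plot of a ratio spectrum
#'
#' @param x a `ratio_spectrum`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ratio_spectrum <- function(x, ...) {
  ord <- x$ordering
  co <- x$coefficients[ord]
  y <- seq_along(ord)
  graphics::plot(co, y, xlim = range(x$ci_low, x$ci_high), yaxt = "n",
                 xlab = paste("coefficient on", x$axis_tag), ylab = "", ...)
  graphics::axis(2, at = y, labels = ord, las = 1, cex.axis = 0.7)
  graphics::segments(x$ci_low[ord], y, x$ci_high[ord], y)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Variables at the extremes of a spectrum
#'
#' @param spectrum a `ratio_spectrum`.
#' @return Character vector of length 2: the highest- and
#'   lowest-coefficient variables (the dominant ratio, numerator first).
#' @export
spectrum_extremes <- function(spectrum) {
  stopifnot(inherits(spectrum, "ratio_spectrum"))
  ord <- spectrum$ordering
  c(ord[length(ord)], ord[1])
}

#' Write a ratio spectrum as TSV
#'
#' @param spectrum a `ratio_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ratio_spectrum"))
  hdr <- sprintf("# axis=%s n_boot=%d level=%g stratified=%s",
                 spectrum$axis_tag, spectrum$n_boot, spectrum$level,
                 spectrum$stratified)
  ord <- spectrum$ordering
  df <- data.frame(variable = ord,
                   coefficient = spectrum$coefficients[ord],
                   ci_low = spectrum$ci_low[ord],
                   ci_high = spectrum$ci_high[ord],
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
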