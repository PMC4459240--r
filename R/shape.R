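#' Decompose measurements into isometric size and shape
#'
#' Multivariate ratio analysis separates a specimen's overall size from its
#' shape. The isometric size axis (isosize) is the natural log of the
#' geometric mean of all p measurements,
#' \eqn{isosize_i = (1/p) \sum_k \ln x_{ik}}, and the shape coordinates are
#' the log-measurements centred by it,
#' \eqn{z_{ik} = \ln x_{ik} - isosize_i}. Each shape coordinate is a
#' log-ratio of a measurement against the specimen's geometric mean, so any
#' difference of two shape coordinates is an ordinary log body-ratio.
#' Every shape row sums to zero; scaling a specimen's measurements by a
#' common factor shifts only its isosize.
#'
#' @param table a complete [measurement_table()] (impute or drop missing
#'   values first).
#' @return An object of class `shape_table`: list with `specimen_id`,
#'   `group`, `strain`, `isosize` (numeric vector, log scale; the geometric
#'   mean in micrometres is `exp(isosize)`), `shape` (n x p matrix) and
#'   `imputed_specimen` (logical, any imputed cell in the row).
#' @examples
#' tab <- measurement_table(
#'   matrix(c(100, 400), 1, dimnames = list(NULL, c("eye.b", "eye.h"))),
#'   specimen_id = "s1", group = "A")
#' sh <- shape_decompose(tab)
#' exp(sh$isosize)   # geometric mean, 200
#' @export
shape_decompose <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  if (anyNA(table$values))
    stop("table has missing values; impute with impute_missing() or drop ",
         "incomplete specimens first")
  logv <- log(table$values)
  isosize <- rowMeans(logv)
  shape <- logv - isosize
  structure(list(specimen_id = table$specimen_id, group = table$group,
                 strain = table$strain, isosize = isosize, shape = shape,
                 imputed_specimen = rowSums(table$imputed_mask) > 0),
            class = "shape_table")
}

#' @export
print.shape_table <- function(x, ...) {
  cat("Size/shape decomposition:", nrow(x$shape), "specimens x",
      ncol(x$shape), "shape coordinates\n")
  cat("isosize range (log um):",
      sprintf("%.3f - %.3f", min(x$isosize), max(x$isosize)), "\n")
  invisible(x)
}

#' Principal component analysis of shape coordinates
#'
#' PCA of the covariance matrix of the shape coordinates — a PCA in the
#' space of all body ratios. Because every shape row sums to zero the shape
#' space has dimension p - 1 and the decomposition retains the first p - 1
#' components; each loading vector is orthogonal to the all-ones vector.
#' Loading signs are fixed so that each loading's largest-magnitude entry
#' is positive. Covariance (not correlation) PCA is used since all shape
#' coordinates share log-units.
#'
#' @param shape a [shape_decompose()] result with at least 3 specimens.
#' @return An object of class `shape_pca`: `eigenvalues` (non-increasing),
#'   `loadings` (p x (p-1), unit columns), `scores` (shape %*% loadings),
#'   `variance_fraction`, plus the shape table's labels and isosize.
#' @export
shape_pca <- function(shape) {
  stopifnot(inherits(shape, "shape_table"))
  n <- nrow(shape$shape)
  p <- ncol(shape$shape)
  if (n < 3L) stop("need at least 3 specimens for a shape PCA")
  if (p < 2L) stop("need at least 2 variables")
  S <- stats::cov(shape$shape)
  eig <- eigen(S, symmetric = TRUE)
  k <- p - 1L
  values <- pmax(eig$values[seq_len(k)], 0)
  vectors <- eig$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  dimnames(vectors) <- list(colnames(shape$shape), paste0("PC", seq_len(k)))
  scores <- shape$shape %*% vectors
  structure(list(eigenvalues = values, loadings = vectors, scores = scores,
                 variance_fraction = values / sum(eig$values),
                 specimen_id = shape$specimen_id, group = shape$group,
                 strain = shape$strain, isosize = shape$isosize),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "specimens,",
      length(x$eigenvalues), "components\n")
  vf <- x$variance_fraction[seq_len(min(3, length(x$eigenvalues)))]
  cat("Variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  df <- data.frame(component = paste0("PC", seq_along(object$eigenvalues)),
                   eigenvalue = object$eigenvalues,
                   variance_fraction = object$variance_fraction,
                   cumulative = cumsum(object$variance_fraction))
  class(df) <- c("summary.shape_pca", "data.frame")
  df
}

#' Scatterplot of two shape principal components
#'
#' @param x a [shape_pca()] result.
#' @param pcs indices of the two components to plot (default 1, 2).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.shape_pca <- function(x, pcs = c(1, 2), ...) {
  stopifnot(length(pcs) == 2)
  g <- factor(x$group)
  graphics::plot(x$scores[, pcs[1]], x$scores[, pcs[2]],
                 col = as.integer(g), pch = as.integer(g),
                 xlab = sprintf("shape PC%d (%.1f%%)", pcs[1],
                                100 * x$variance_fraction[pcs[1]]),
                 ylab = sprintf("shape PC%d (%.1f%%)", pcs[2],
                                100 * x$variance_fraction[pcs[2]]), ...)
  graphics::legend("topright", legend = levels(g), col = seq_along(levels(g)),
                   pch = seq_along(levels(g)), cex = 0.8)
  invisible(x)
}

#' Cumulative variance explained by the first k shape components
#'
#' @param result a [shape_pca()] result.
#' @param k number of leading components, 1 <= k <= p - 1.
#' @return Fraction in [0, 1].
#' @export
variance_explained <- function(result, k) {
  stopifnot(inherits(result, "shape_pca"))
  if (!(k >= 1 && k <= length(result$eigenvalues)))
    stop("'k' out of range")
  sum(result$variance_fraction[seq_len(k)])
}

#' Allometry coefficients: regression of shape on isosize
#'
#' The correlation of size with shape measures the amount of allometry in
#' the data. For each variable the allometric coefficient is the slope of
#' its shape coordinate on isosize,
#' \eqn{b_k = cov(z_k, isosize) / var(isosize)}; the coefficients sum to
#' zero. A positive coefficient means the variable grows faster than
#' overall size (the body ratio increases with size).
#'
#' @param shape a [shape_decompose()] result with positive isosize
#'   variance.
#' @return Named numeric vector of per-variable slopes, summing to zero.
#' @export
allometry_coefficients <- function(shape) {
  stopifnot(inherits(shape, "shape_table"))
  v <- stats::var(shape$isosize)
  # 1e-20 absorbs pure floating-point jitter on the log scale
  if (!is.finite(v) || v <= 1e-20) stop("isosize variance is zero")
  drop(stats::cov(shape$shape, shape$isosize)) / v
}

#' Isosize against a shape principal component
#'
#' Pairs each specimen's isosize with its score on one shape PC, with
#' their Pearson correlation — the plot used to judge how allometric a
#' shape component is. If isosize is constant the correlation is
#' undefined and reported as `NA`.
#'
#' @param result a [shape_pca()] result.
#' @param shape the [shape_decompose()] result it was computed from.
#' @param pc component index.
#' @return A list with `data` (data frame: specimen_id, group, isosize,
#'   score) and `r` (Pearson correlation or `NA`).
#' @export
size_shape_scatter <- function(result, shape, pc = 1) {
  stopifnot(inherits(result, "shape_pca"), inherits(shape, "shape_table"))
  if (!(pc >= 1 && pc <= ncol(result$scores))) stop("'pc' out of range")
  iso <- shape$isosize
  sc <- result$scores[, pc]
  r <- if (stats::sd(iso) == 0 || stats::sd(sc) == 0) NA_real_ else
    stats::cor(iso, sc)
  list(data = data.frame(specimen_id = shape$specimen_id,
                         group = shape$group, isosize = iso, score = sc,
                         stringsAsFactors = FALSE),
       r = r)
}
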