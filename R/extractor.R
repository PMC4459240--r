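#' Define a two-group comparison
#'
#' Groups two sets of OTU labels for the ratio extractor. Each side may be
#' a union of several OTUs (e.g. `c("calandrae", "cornis")` against the
#' rest). The two sides must be disjoint and each must contain at least 3
#' specimens of the table it is applied to.
#'
#' @param label_1,label_2 display labels for the two sides.
#' @param groups_1,groups_2 character vectors of OTU labels belonging to
#'   each side; default the display label itself.
#' @return An object of class `group_comparison`.
#' @export
group_comparison <- function(label_1, label_2, groups_1 = label_1,
                             groups_2 = label_2) {
  if (length(intersect(groups_1, groups_2)))
    stop("the two sides of a comparison must be disjoint")
  structure(list(label_1 = label_1, label_2 = label_2,
                 groups_1 = groups_1, groups_2 = groups_2),
            class = "group_comparison")
}

# internal: membership indices of the two sides on a label vector.
# The extractor requires >= 3 specimens per side; plain projections
# only need estimable within-group variance (>= 2).
.comparison_idx <- function(comparison, groups, min_n = 2L) {
  i1 <- which(groups %in% comparison$groups_1)
  i2 <- which(groups %in% comparison$groups_2)
  if (length(i1) < min_n || length(i2) < min_n)
    stop("each comparison side needs at least ", min_n, " specimens")
  list(i1 = i1, i2 = i2)
}

#' Standard distance between two groups along a direction
#'
#' The standard distance D of a linear combination `v` of (log or shape)
#' variables is the absolute difference of the two group means of the
#' projection, divided by its pooled within-group standard deviation:
#' \deqn{D = |v'(m_1 - m_2)| / \sqrt{v' S_{pooled} v}}
#' with the pooled covariance using the n1 + n2 - 2 denominator. D is the
#' univariate Mahalanobis distance of the projection and is invariant to
#' rescaling `v`.
#'
#' @param direction numeric p-vector (e.g. a log-ratio contrast
#'   `e_num - e_den`).
#' @param data n x p numeric matrix of log-measurements or shape
#'   coordinates.
#' @param groups vector of group labels, length n.
#' @param comparison a [group_comparison()].
#' @return The standard distance (>= 0).
#' @export
standard_distance <- function(direction, data, groups, comparison) {
  idx <- .comparison_idx(comparison, groups)
  x <- drop(as.matrix(data) %*% direction)
  .std_dist_1d(x[idx$i1], x[idx$i2])
}

# internal: 1-D standard distance from two samples
.std_dist_1d <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) stop("degenerate direction: zero ",
                                        "pooled within-group variance")
  abs(mean(x1) - mean(x2)) / sqrt(sp2)
}

# internal: multivariate standard distance (Mahalanobis with pooled cov)
.std_dist_md <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) /
    (n1 + n2 - 2)
  d <- colMeans(X1) - colMeans(X2)
  q <- tryCatch(drop(crossprod(d, solve(S, d))), error = function(e) NA)
  if (!is.finite(q)) return(NA_real_)
  sqrt(q)
}

#' Size-versus-shape discrimination measure delta
#'
#' delta compares how well overall size separates two groups relative to
#' an extracted ratio: \eqn{\delta = D_{size} / D_{ratio}}, where
#' `D_size` is the standard distance of isosize between the groups and
#' `D_ratio` that of the log-ratio. delta near 0 means the groups are
#' separated by true shape differences rather than indirectly by size.
#'
#' @param ratio_direction numeric p-vector, the log-ratio contrast.
#' @param data n x p matrix of log-measurements.
#' @param groups group labels, length n.
#' @param comparison a [group_comparison()].
#' @return delta (>= 0); 0 iff the group isosize means coincide.
#' @export
delta <- function(ratio_direction, data, groups, comparison) {
  data <- as.matrix(data)
  d_ratio <- standard_distance(ratio_direction, data, groups, comparison)
  if (d_ratio == 0) stop("delta undefined: ratio standard distance is 0")
  iso <- rowMeans(data)
  idx <- .comparison_idx(comparison, groups)
  d_size <- .std_dist_1d(iso[idx$i1], iso[idx$i2])
  d_size / d_ratio
}

#' Extract the best discriminating body ratios for two groups
#'
#' Exhaustive search over all p(p-1)/2 variable pairs for the body ratio
#' whose log-contrast has the largest standard distance D between the two
#' groups. The first ratio maximises the marginal D; the second ratio is
#' the pair that, jointly with the first, maximises the two-dimensional
#' Mahalanobis standard distance (complementarity, not second-largest
#' marginal D). Ties are broken lexicographically by abbreviation pair.
#' Ratios are oriented so the pooled mean ratio is >= 1. Per-group
#' observed ratio ranges are computed on raw values of specimens with no
#' imputed cell in either character, because imputed values can produce
#' outlying ratios; imputed specimens still contribute to D.
#'
#' @param table a complete [measurement_table()] (imputed cells allowed
#'   for fitting).
#' @param comparison a [group_comparison()]; each side >= 3 specimens.
#' @param n_ratios number of ratios to extract (default 2, < p).
#' @return An object of class `ratio_extraction`: `comparison`, `ratios`
#'   (list of extracted ratios with `numerator`, `denominator`, `D`,
#'   `delta`, `range_1`, `range_2`, `overlap_flag`), `D_size` (standard
#'   distance of isosize), and `low_separation` (TRUE when the best
#'   marginal D < 1).
#' @examples
#' cfg <- synthetic_config(p = 6,
#'   groups = list(list(label = "A", n = 20, contrast = c(1, 2),
#'                      contrast_size = 0.15),
#'                 list(label = "B", n = 20)),
#'   sigma_noise = 0.02, seed = 7)
#' sim <- simulate_measurements(cfg)
#' extract_best_ratios(sim$table, group_comparison("A", "B"))
#' @export
extract_best_ratios <- function(table, comparison, n_ratios = 2) {
  stopifnot(inherits(table, "measurement_table"),
            inherits(comparison, "group_comparison"))
  if (anyNA(table$values))
    stop("table has missing values; impute first")
  p <- ncol(table$values)
  if (p < 2L) stop("need at least 2 variables")
  if (n_ratios > p - 1L) stop("'n_ratios' must be at most p - 1")
  logv <- log(table$values)
  vars <- colnames(logv)
  idx <- .comparison_idx(comparison, table$group, min_n = 3L)
  pairs <- utils::combn(seq_len(p), 2)
  # lexicographic candidate order by abbreviation pair (tie-break order)
  key <- apply(pairs, 2, function(ab)
    paste(sort(vars[ab]), collapse = " "))
  pairs <- pairs[, order(key), drop = FALSE]
  lr <- function(ab) logv[, ab[1]] - logv[, ab[2]]
  D_marg <- apply(pairs, 2, function(ab) {
    x <- lr(ab)
    tryCatch(.std_dist_1d(x[idx$i1], x[idx$i2]), error = function(e) NA)
  })
  if (all(is.na(D_marg))) stop("all candidate ratios degenerate")
  best <- which.max(D_marg)  # first max in lexicographic order
  chosen <- list(pairs[, best])
  skipped <- 0L
  if (n_ratios >= 2L) {
    r1 <- lr(chosen[[1]])
    remaining <- setdiff(seq_len(ncol(pairs)), best)
    D_joint <- rep(NA_real_, ncol(pairs))
    for (j in remaining) {
      X <- cbind(r1, lr(pairs[, j]))
      D_joint[j] <- .std_dist_md(X[idx$i1, , drop = FALSE],
                                 X[idx$i2, , drop = FALSE])
    }
    skipped <- sum(is.na(D_joint[remaining]))
    for (k in seq_len(n_ratios - 1L)) {
      if (all(is.na(D_joint))) break
      nxt <- which.max(D_joint)
      chosen[[k + 1L]] <- pairs[, nxt]
      D_joint[nxt] <- NA_real_
    }
  }
  iso <- rowMeans(logv)
  D_size <- .std_dist_1d(iso[idx$i1], iso[idx$i2])
  ok_range <- !(table$imputed_mask)  # per-cell: originally observed
  ratios <- lapply(chosen, function(ab) {
    x <- lr(ab)
    # orient so the pooled mean ratio >= 1
    if (mean(x[c(idx$i1, idx$i2)]) < 0) ab <- rev(ab)
    num <- vars[ab[1]]; den <- vars[ab[2]]
    D <- .std_dist_1d(x[idx$i1], x[idx$i2])
    dl <- if (D > 0) D_size / D else NA_real_
    rng <- function(ii) {
      keep <- ii[ok_range[ii, ab[1]] & ok_range[ii, ab[2]]]
      if (!length(keep)) return(c(NA_real_, NA_real_))
      r <- table$values[keep, ab[1]] / table$values[keep, ab[2]]
      range(r)
    }
    r1 <- rng(idx$i1); r2 <- rng(idx$i2)
    list(numerator = num, denominator = den,
         direction = stats::setNames(
           replace(replace(numeric(p), ab[1], 1), ab[2], -1), vars),
         D = D, delta = dl, range_1 = r1, range_2 = r2,
         overlap_flag = is.finite(r1[1]) && is.finite(r2[1]) &&
           min(r1[2], r2[2]) >= max(r1[1], r2[1]))
  })
  structure(list(comparison = comparison, ratios = ratios, D_size = D_size,
                 low_separation = max(D_marg, na.rm = TRUE) < 1,
                 n_skipped = skipped),
            class = "ratio_extraction")
}

#' @export
print.ratio_extraction <- function(x, ...) {
  cat("Ratio extraction:", x$comparison$label_1, "vs",
      x$comparison$label_2, "\n")
  for (i in seq_along(x$ratios)) {
    r <- x$ratios[[i]]
    cat(sprintf("  %d. %s : %s  D = %.2f  delta = %.2f  [%s: %.2f-%.2f | %s: %.2f-%.2f]\n",
                i, r$numerator, r$denominator, r$D, r$delta,
                x$comparison$label_1, r$range_1[1], r$range_1[2],
                x$comparison$label_2, r$range_2[1], r$range_2[2]))
  }
  cat(sprintf("  isosize D = %.2f\n", x$D_size))
  if (x$low_separation)
    cat("  warning: low separation (best marginal D < 1)\n")
  invisible(x)
}

#' Observed range of a body ratio within a group
#'
#' Min and max of `x_num / x_den` over the group's specimens whose two
#' characters were actually measured — specimens with either character
#' imputed are excluded, because imputed values can produce outlying
#' ratios.
#'
#' @param table a [measurement_table()].
#' @param group group label.
#' @param numerator,denominator character abbreviations.
#' @return Numeric vector `c(min, max)`.
#' @export
ratio_ranges <- function(table, group, numerator, denominator) {
  stopifnot(inherits(table, "measurement_table"))
  stopifnot(all(c(numerator, denominator) %in% colnames(table$values)))
  ii <- which(table$group == group)
  ok <- !table$imputed_mask[ii, numerator] &
    !table$imputed_mask[ii, denominator] &
    !is.na(table$values[ii, numerator]) &
    !is.na(table$values[ii, denominator])
  ii <- ii[ok]
  if (!length(ii))
    stop("no specimen in group '", group,
         "' with both characters observed (non-imputed)")
  r <- table$values[ii, numerator] / table$values[ii, denominator]
  c(min(r), max(r))
}

#' Best-ratio report over several group comparisons
#'
#' Runs [extract_best_ratios()] for each comparison and assembles one row
#' per extracted ratio: the ratio, the observed per-group ranges (2
#' decimals), D and delta (2 decimals), and a star when the two ranges
#' have very little or no overlap — operationalised as overlap length at
#' most 5% of the union length. Starred ratios are eligible for use in
#' identification keys and diagnoses.
#'
#' @param table a complete [measurement_table()].
#' @param comparisons list of [group_comparison()] objects.
#' @param n_ratios ratios per comparison (default 2).
#' @return A data frame of class `ratio_report` with columns `comparison`,
#'   `ratio`, `starred`, `range_1`, `range_2`, `D`, `delta`.
#' @export
table2_report <- function(table, comparisons, n_ratios = 2) {
  rows <- list()
  for (cmp in comparisons) {
    ex <- extract_best_ratios(table, cmp, n_ratios = n_ratios)
    for (r in ex$ratios) {
      star <- FALSE
      if (is.finite(r$range_1[1]) && is.finite(r$range_2[1])) {
        ov <- min(r$range_1[2], r$range_2[2]) -
          max(r$range_1[1], r$range_2[1])
        un <- max(r$range_1[2], r$range_2[2]) -
          min(r$range_1[1], r$range_2[1])
        star <- ov <= 0.05 * un
      }
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(cmp$label_1, "-", cmp$label_2),
        ratio = paste(r$numerator, ":", r$denominator),
        starred = star,
        range_1 = sprintf("%.2f-%.2f", r$range_1[1], r$range_1[2]),
        range_2 = sprintf("%.2f-%.2f", r$range_2[1], r$range_2[2]),
        D = round(r$D, 2), delta = round(r$delta, 2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ratio_report", "data.frame")
  out
}
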