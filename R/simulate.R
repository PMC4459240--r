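#' Configuration for the synthetic measurement generator
#'
#' Describes a population of specimens with the statistical structure the
#' ratio analysis assumes: each group has a mean shape vector (a log-scale
#' contrast summing to zero) and an isometric size offset; all specimens
#' share one dominant log-normal size factor; an allometry vector makes
#' individual variables grow faster or slower than overall size; and
#' i.i.d. Gaussian noise acts on the log scale. Log-measurements are
#' generated as
#' \deqn{\ln x_{ik} = base + \mu_{g(i),k} + (1 + a_k) s_i + offset_{g(i)} + \epsilon_{ik}}
#' with \eqn{s_i \sim N(0, \sigma_{size}^2)} and
#' \eqn{\epsilon_{ik} \sim N(0, \sigma_{noise}^2)}. Because allometry
#' multiplies the size factor, the allometric-coefficient estimand equals
#' exactly `a_k` under this generator. `base = 6` puts measurements near
#' `exp(6)` (about 400 micrometres), a realistic magnitude for pteromalid
#' body parts.
#'
#' @param p number of characters; for `p <= 20` the standard registry
#'   abbreviations are used as column names.
#' @param groups list of group descriptors; each a list with `label`, `n`,
#'   and optionally `mu` (p-vector summing to 0), or the shorthand
#'   `contrast = c(i, j)` with `contrast_size` placing `+contrast_size/2`
#'   on variable `i` and `-contrast_size/2` on variable `j`, and
#'   `size_offset` (log-scale isometric shift, default 0).
#' @param sigma_size SD of the shared log-size factor (default 0.1, i.e.
#'   about 10% size variation).
#' @param allometry p-vector summing to 0 (default isometry, all zeros).
#' @param sigma_noise SD of the i.i.d. log-scale measurement noise
#'   (default 0.02, i.e. about 2% measurement error).
#' @param artifact optional list (`variable`, `fraction`, `noise_sd`)
#'   describing a silently damaged variable; applied by
#'   [inject_artifact()] inside [simulate_measurements()].
#' @param missing_rate MCAR missingness fraction in [0, 1).
#' @param seed integer seed.
#' @param base baseline log-measurement (default 6.0).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(p, groups, sigma_size = 0.1,
                             allometry = NULL, sigma_noise = 0.02,
                             artifact = NULL, missing_rate = 0,
                             seed = 1L, base = 6.0) {
  stopifnot(p >= 2, length(groups) >= 1, sigma_size >= 0,
            sigma_noise >= 0, missing_rate >= 0, missing_rate < 1)
  if (is.null(allometry)) allometry <- numeric(p)
  stopifnot(length(allometry) == p)
  if (abs(sum(allometry)) > 1e-12)
    stop("allometry vector must sum to zero")
  vars <- if (p <= 20L) character_registry()$abbreviation[seq_len(p)]
          else sprintf("v%02d", seq_len(p))
  groups <- lapply(groups, function(g) {
    stopifnot(!is.null(g$label), !is.null(g$n), g$n >= 1)
    if (is.null(g$mu)) {
      g$mu <- numeric(p)
      if (!is.null(g$contrast)) {
        stopifnot(length(g$contrast) == 2)
        d <- if (is.null(g$contrast_size)) 0.1 else g$contrast_size
        g$mu[g$contrast[1]] <- d / 2
        g$mu[g$contrast[2]] <- -d / 2
      }
    }
    stopifnot(length(g$mu) == p)
    if (abs(sum(g$mu)) > 1e-12)
      stop("group mean shape vector must sum to zero")
    if (is.null(g$size_offset)) g$size_offset <- 0
    g
  })
  structure(list(p = p, groups = groups, sigma_size = sigma_size,
                 allometry = allometry, sigma_noise = sigma_noise,
                 artifact = artifact, missing_rate = missing_rate,
                 seed = as.integer(seed), base = base, var_names = vars),
            class = "synthetic_config")
}

#' Simulate a measurement table with known ground truth
#'
#' Draws a [measurement_table()] from a [synthetic_config()], applying the
#' configured damaged-variable artifact and MCAR missingness, and returns
#' the ground truth needed by recovery tests: the true per-specimen
#' log-size, and for each pair of groups the planted discriminating
#' contrast (the two variables with the largest mean-shape difference)
#' with its analytic standard distance and analytic delta under the
#' generator. Identical seeds give identical tables.
#'
#' @param config a [synthetic_config()].
#' @return A list with `table` (a `measurement_table`) and `truth`: a list
#'   with `log_size` (per-specimen true s_i), `config`, and `pairs`, a
#'   data frame with one row per group pair (`group_1`, `group_2`,
#'   `numerator`, `denominator`, `D_ratio`, `D_size`, `delta`, all
#'   analytic).
#' @export
simulate_measurements <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$p
  set.seed(config$seed)
  labels <- vapply(config$groups, `[[`, "", "label")
  ns <- vapply(config$groups, function(g) as.integer(g$n), 1L)
  n <- sum(ns)
  gidx <- rep(seq_along(config$groups), ns)
  s <- stats::rnorm(n, 0, config$sigma_size)
  eps <- matrix(stats::rnorm(n * p, 0, config$sigma_noise), n, p)
  mu <- t(vapply(config$groups, `[[`, numeric(p), "mu"))[gidx, , drop = FALSE]
  offs <- vapply(config$groups, `[[`, 0, "size_offset")[gidx]
  loga <- config$base + mu + outer(s, 1 + config$allometry) + offs + eps
  vals <- exp(loga)
  colnames(vals) <- config$var_names
  tab <- measurement_table(
    vals, specimen_id = sprintf("s%04d", seq_len(n)),
    group = labels[gidx],
    registry = .registry_for(config$var_names))
  if (!is.null(config$artifact)) {
    a <- config$artifact
    tab <- inject_artifact(tab, a$variable, a$fraction, a$noise_sd,
                           seed = config$seed + 1L)
  }
  if (config$missing_rate > 0)
    tab <- inject_missing(tab, config$missing_rate,
                          seed = config$seed + 2L)
  truth <- list(log_size = s, config = config,
                pairs = .analytic_pairs(config))
  list(table = tab, truth = truth)
}

# internal: registry covering arbitrary synthetic variable names
.registry_for <- function(vars) {
  reg <- character_registry()
  if (all(vars %in% reg$abbreviation)) return(reg)
  data.frame(abbreviation = vars, name = vars,
             definition = "synthetic variable", magnification = 1,
             stringsAsFactors = FALSE)
}

# internal: analytic D, D_size and delta per group pair
.analytic_pairs <- function(config) {
  gs <- config$groups
  if (length(gs) < 2L)
    return(data.frame(group_1 = character(), group_2 = character(),
                      numerator = character(), denominator = character(),
                      D_ratio = numeric(), D_size = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE))
  a <- config$allometry
  p <- config$p
  abar <- mean(a)
  var_iso <- (1 + abar)^2 * config$sigma_size^2 + config$sigma_noise^2 / p
  rows <- list()
  cb <- utils::combn(length(gs), 2)
  for (j in seq_len(ncol(cb))) {
    g1 <- gs[[cb[1, j]]]; g2 <- gs[[cb[2, j]]]
    dmu <- g1$mu - g2$mu
    if (all(dmu == 0)) {
      num <- den <- NA_character_; D_ratio <- NA_real_
    } else {
      ia <- which.max(dmu); ib <- which.min(dmu)
      num <- config$var_names[ia]; den <- config$var_names[ib]
      var_lr <- (a[ia] - a[ib])^2 * config$sigma_size^2 +
        2 * config$sigma_noise^2
      D_ratio <- abs(dmu[ia] - dmu[ib]) / sqrt(var_lr)
    }
    D_size <- abs(g1$size_offset - g2$size_offset) / sqrt(var_iso)
    rows[[j]] <- data.frame(group_1 = g1$label, group_2 = g2$label,
                            numerator = num, denominator = den,
                            D_ratio = D_ratio, D_size = D_size,
                            delta = D_size / D_ratio,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Silently corrupt one variable (damaged-specimen artifact)
#'
#' Emulates a deformed body part (e.g. a collapsed gaster): for a seeded
#' random subset of specimens, the variable's value is replaced by the
#' group geometric mean of that variable times `exp(N(0, noise_sd))`.
#' Nothing is marked — the corruption is silent, as in real data — so the
#' correlation QC must detect it.
#'
#' @param table a [measurement_table()].
#' @param variable character abbreviation to corrupt.
#' @param fraction fraction of specimens affected, in [0, 1].
#' @param noise_sd log-scale SD of the replacement noise.
#' @param seed integer seed.
#' @return The corrupted table.
#' @export
inject_artifact <- function(table, variable, fraction, noise_sd,
                            seed = 1L) {
  stopifnot(inherits(table, "measurement_table"),
            fraction >= 0, fraction <= 1, noise_sd >= 0)
  if (!variable %in% colnames(table$values))
    stop("unknown variable: ", variable)
  if (fraction == 0) return(table)
  set.seed(as.integer(seed))
  n <- nrow(table$values)
  hit <- sample.int(n, round(fraction * n))
  gm <- tapply(table$values[, variable], table$group,
               function(v) exp(mean(log(v), na.rm = TRUE)))
  repl <- gm[table$group[hit]] * exp(stats::rnorm(length(hit), 0, noise_sd))
  table$values[hit, variable] <- as.numeric(repl)
  table
}

#' Inject missing-completely-at-random cells
#'
#' Marks a seeded MCAR subset of cells as missing (sets them `NA` and
#' updates the missing mask), resampling whenever a draw would empty an
#' entire specimen or an entire column.
#'
#' @param table a [measurement_table()].
#' @param rate cell-level missingness probability in [0, 1).
#' @param seed integer seed.
#' @return The table with missing cells.
#' @export
inject_missing <- function(table, rate, seed = 1L) {
  stopifnot(inherits(table, "measurement_table"), rate >= 0)
  if (rate >= 1) stop("'rate' must be < 1")
  if (rate == 0) return(table)
  set.seed(as.integer(seed))
  n <- nrow(table$values); p <- ncol(table$values)
  for (attempt in seq_len(1000L)) {
    mask <- matrix(stats::runif(n * p) < rate, n, p)
    mask <- mask & !table$missing_mask
    keep <- !(mask | table$missing_mask)
    if (all(rowSums(keep) > 0L) && all(colSums(keep) > 0L)) {
      table$values[mask] <- NA_real_
      table$missing_mask <- table$missing_mask | mask
      return(table)
    }
  }
  stop("could not draw an MCAR mask leaving every row and column ",
       "partly observed")
}
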