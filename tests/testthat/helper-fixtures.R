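# Shared fixtures and independent oracles for the test suite.

# Independent standard-distance oracle: explicit sums, no var()/cov().
oracle_std_dist <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- sum(x1) / n1; m2 <- sum(x2) / n2
  ss <- sum((x1 - m1)^2) + sum((x2 - m2)^2)
  abs(m1 - m2) / sqrt(ss / (n1 + n2 - 2))
}

# Independent exhaustive best-pair scan on the log-measurements.
oracle_best_pair <- function(table, groups_1, groups_2) {
  logv <- log(table$values)
  i1 <- table$group %in% groups_1
  i2 <- table$group %in% groups_2
  vars <- colnames(logv)
  best <- NULL; bestD <- -Inf
  for (a in seq_along(vars)) for (b in seq_along(vars)) {
    if (a >= b) next
    x <- logv[, a] - logv[, b]
    D <- oracle_std_dist(x[i1], x[i2])
    key <- paste(sort(c(vars[a], vars[b])), collapse = " ")
    if (D > bestD + 1e-12 ||
        (abs(D - bestD) <= 1e-12 && key < best$key)) {
      bestD <- D
      best <- list(pair = sort(c(vars[a], vars[b])), D = D, key = key)
    }
  }
  best
}

# Small deterministic two-group scenario with a planted contrast on the
# first two variables and an isometric size shift between the groups.
planted_scenario <- function(p = 6, n = 30, delta_contrast = 0.15,
                             size_offset = 0.05, sigma_noise = 0.02,
                             seed = 7, ...) {
  cfg <- synthetic_config(
    p = p,
    groups = list(list(label = "A", n = n, contrast = c(1, 2),
                       contrast_size = delta_contrast,
                       size_offset = size_offset),
                  list(label = "B", n = n)),
    sigma_noise = sigma_noise, seed = seed, ...)
  simulate_measurements(cfg)
}

# Ratio vector hitting the midpoint of every printed diagnosis range.
diagnosis_midpoints <- function(species) {
  rg <- diagnosis_ranges(species)
  stats::setNames((rg$lo + rg$hi) / 2, rg$ratio)
}

# A full ratio vector for key walking, with defaults on the calandrae path.
key_ratios_fixture <- function(...) {
  base <- c("hea.b:tb3.l" = 1.40, "eye.h:sct.l" = 1.20,
            "mss.l:ool.l" = 7.00, "hea.b:eye.d" = 1.45,
            "pdl.flg:eye.h" = 2.00, "hea.h:eye.b" = 2.90,
            "tb3.l:mv.l" = 1.90, "sct.l:stv.l" = 1.70,
            "gst.l:ool.l" = 10.0)
  override <- c(...)
  base[names(override)] <- override
  base
}
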