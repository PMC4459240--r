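---
title: "Multivariate ratio analysis of body measurements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate ratio analysis of body measurements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mratio)
```

## The problem

Taxonomists routinely separate morphologically similar insect species by
body *ratios* — head breadth over metatibia length, eye breadth over the
ocellus-to-eye distance, and so on. Ratios remove overall body size, which
in parasitic wasps varies enormously with host quality, and they carry the
information that diagnoses and identification keys are written in.
`mratio` implements a multivariate framework for this practice: it
separates isometric size from shape, asks which ratios carry group
differences, quantifies how well a ratio separates two groups, and feeds
the answers directly into a quantitative identification key. The bundled
case is the genus *Anisopteromalus* (Pteromalidae), where cryptic species
hide under the name of a cosmopolitan stored-product parasitoid and 20
linear measurements per female (Table 1 of the package's character
registry, `character_registry()`) are the raw data.

## Size and shape

All analysis happens on natural logs. For measurements
$x_{i1},\dots,x_{ip}$ of specimen $i$:

* **isosize** $\;s_i = \tfrac1p\sum_k \ln x_{ik}$, the log of the
  geometric mean of all measurements — the isometric size axis;
* **shape coordinates** $\;z_{ik} = \ln x_{ik} - s_i$, each a log-ratio of
  a measurement against the specimen's geometric mean.

Every shape row sums to zero, so shape lives in a $(p-1)$-dimensional
subspace; the difference of any two shape coordinates is an ordinary log
body-ratio, which is what makes all downstream output interpretable as
ratios. Multiplying a specimen's measurements by a common factor moves
only its isosize — this scale invariance is asserted to $10^{-9}$
throughout the test suite. Note the limits of that invariance: quantities
that *are* size (isosize contrasts between groups, the standard distance
of isosize, and therefore $\delta$) are invariant under a common
rescaling of the whole table (a unit change), not under rescaling a
single specimen, which genuinely changes that specimen's size.

**Shape PCA.** A covariance-matrix PCA of the shape coordinates
(covariance, not correlation: all coordinates share log-units). The
package retains the $p-1$ structurally meaningful components; each
loading vector is orthogonal to the all-ones vector, and signs are fixed
so the largest-magnitude entry of each loading is positive. Scores are
`shape %*% loadings`. The number of components worth interpreting is left
to the user (scree inspection); `variance_explained()` reports cumulative
fractions.

**Allometry.** The allometric coefficient of variable $k$ is the slope of
$z_k$ on isosize, $b_k = \mathrm{cov}(z_k, s)/\mathrm{var}(s)$; the
coefficients sum to zero. Under the package's generator (below) the
estimand is exactly the planted allometry vector, which gives the
recovery tests sharp truth. Allometry should be estimated within groups
or on groups without a mean size difference: a group size offset combined
with a group shape difference confounds the pooled regression — the
acceptance script's calibration study therefore uses groups with equal
size distributions.

**Ratio spectra.** A ratio spectrum orders the variables by their
coefficient on an axis — a shape PC loading (`pca_ratio_spectrum()`) or
the allometry vector (`allometry_ratio_spectrum()`). Only ratios formed
from variables at *opposite ends* of the spectrum matter for that axis.
Per-variable confidence intervals come from a specimen bootstrap,
stratified by group when groups are present (strata preserve the group
design; the choice is recorded in the output object), with the resampled
loading's sign aligned to the point estimate before taking the central
interval. Defaults are 1000 replicates at 68% coverage, the conventions
of the spectra this display imitates. Degenerate resamples (a constant
column) are redrawn and counted.

## The ratio extractor, D and delta

For two groups, `extract_best_ratios()` scans all $p(p-1)/2$ variable
pairs exhaustively and ranks the log-ratio contrasts
$e_a - e_b$ by the **standard distance**

$$D = \frac{|v'(m_1 - m_2)|}{\sqrt{v' S_{\text{pooled}}\, v}},$$

the absolute group-mean difference of the projection over its pooled
within-group standard deviation ($n_1 + n_2 - 2$ denominator). The first
extracted ratio maximises marginal $D$; the *second* is the pair that
jointly with the first maximises the two-dimensional Mahalanobis standard
distance — a complementarity criterion, not the runner-up in marginal
$D$, which is why the second ratio's $D$ may be smaller than other
pairs'. Ties are broken lexicographically; ratios are printed with the
pooled mean ratio $\ge 1$. When even the best marginal $D$ is below 1 the
result carries a low-separation flag (that threshold is this package's
own convention).

$$\delta = D_{\text{size}} / D_{\text{ratio}}$$

compares how well isosize separates the groups relative to the extracted
ratio: $\delta$ near zero means the separation is true shape difference,
not an indirect size effect. The identity
$\delta \cdot D_{\text{ratio}} = D_{\text{size}}$ is exact by definition;
the substantive check in the tests is that $\hat\delta$ matches the
generator's closed-form $\delta$ across replicates. On the published
*Anisopteromalus* comparisons this operationalisation is consistent with
the near-constancy of the printed $\delta \cdot D$ products within each
comparison.

**Ranges.** Observed per-group ratio ranges (`ratio_ranges()`,
`table2_report()`) are computed only on specimens whose two characters
were actually measured: imputed values can produce outlying ratios, so
imputed specimens contribute to $D$ (which is a mean/variance statistic)
but never to a printed range. A report row is starred — eligible for keys
and diagnoses — when the two ranges' overlap is at most 5% of their union
length, this package's operationalisation of "very little or no overlap".

## Measurement QC and imputation

Body measurements of related taxa correlate strongly and positively
because a shared size factor dominates. `correlation_qc()` computes
Pearson correlations of the natural-log measurements
(pairwise-complete) and flags a variable whose *median* off-diagonal
correlation falls below a threshold (default 0.5). The log scale is
chosen for consistency with the rest of the pipeline; the flag rule is a
deterministic operationalisation of what is usually done by eye with
matrix scatterplots, and the default separates a damaged variable with
correlations scattered around zero from healthy variables with
correlations near one. Flagging is monotone in the threshold. A
zero-variance variable is flagged with reason `"constant"`.

`impute_missing()` fills missing cells so damaged specimens (name-bearing
types in particular) can enter the multivariate analyses. The procedure
is deterministic given its seed: initial fill with column medians of the
observed log-values plus a tiny seeded jitter, then iterated ridge
regressions of each incomplete column on all others
($\lambda = 10^{-3} \times$ the mean diagonal of the centred
cross-product, so the penalty scales with the data) until the largest
absolute change of an imputed log-value is below $10^{-6}$ or 50 sweeps.
A chained-equations tool at default settings would be stochastic and
tool-specific; a deterministic scheme makes every downstream output
byte-reproducible. Non-convergence is recorded in the imputation log
rather than raised as an error. Tests verify the scheme never touches
observed cells and beats column-mean imputation in RMSE on correlated
log-normal data.

## The identification key

`key_classify()` walks the five printed couplets for *Anisopteromalus*
females. Quantitative ratio thresholds decide; couplets 1, 2 and 5 are
quantitatively exhaustive (the second branch is the printed logical
complement of the first), so gaps can only occur at couplet 3 (the
pedicel-plus-flagellum/eye-height gap between 2.25 and 2.43) and couplet
4. A specimen falling in a gap is `"indeterminate"` unless supplied
qualitative traits (speculum setae, gena carina, flagellum shape, body
colour, tergite margin, scutellum curvature — observer-scored booleans)
unambiguously support one branch; mixed trait evidence is an error, and
the key never guesses. Couplet 4 combines its two thresholds
conjunctively — both must agree, otherwise indeterminate — and the point
values printed for the single measured *A. ceylonensis* specimen are
encoded as ±0.05 bands. Diagnosis ranges for the three fully diagnosed
species are available through `diagnosis_ranges()`/`diagnosis_check()`.
Because the printed calandrae and quinarius ranges touch at their
boundaries (e.g. mesosoma/OOL 8.11–8.14), literal boundary specimens are
ambiguous in the published key itself; the consistency tests therefore
sample the central half of each diagnosis range.

## Sequence distances

`k2p_distance()` implements the Kimura 2-parameter distance
$d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$ with pairwise
deletion: per pair, every site where either sequence has a gap *or* an
ambiguity code is removed before counting transitions ($P$) and
transversions ($Q$). Ambiguity codes are treated as missing by the same
rule as gaps. Saturated pairs ($1-2P-Q \le 0$ or $1-2Q \le 0$) are
flagged `NA` rather than silently clipped. `distance_summary()` reports
per-species intraspecific and per-pair interspecific min/mean/max — the
quantities used to show that interspecific divergence between the two
cryptic species far exceeds intraspecific variation. The implementation
is cross-checked in the tests against an independent K80 implementation
(`ape::dist.dna`), and validated for calibration with a minimal site-wise
pair simulator (`simulate_k2p_pair()`) whose site-pattern probabilities
are the exact K80 ones. Alignment and tree inference are out of scope.

## The synthetic-data generator

`simulate_measurements()` draws tables from

$$\ln x_{ik} = 6 + \mu_{g(i),k} + (1 + a_k)\, s_i +
  \text{offset}_{g(i)} + \varepsilon_{ik},$$

with $s_i \sim N(0, \sigma_{\text{size}}^2)$ the shared log-size factor,
group mean-shape vectors $\mu_g$ (sum zero), allometry vector $a$ (sum
zero) entering multiplicatively on size so that the allometric estimand
is exactly $a_k$, isometric group offsets, and i.i.d. log-scale noise.
The baseline of 6 log-micrometres puts measurements near 400 µm,
realistic for pteromalid body parts. Defaults —
$\sigma_{\text{size}} = 0.1$ (about 10% size variation),
$\sigma_{\text{noise}} = 0.02$ (about 2% measurement error) — are what a
morphometrician would call typical for careful stereomicroscope work on
specimens a few hundred micrometres across; group contrasts of 0.1–0.25
log-units mirror the magnitude of the published between-species ratio
differences. The generator returns ground truth (true log-sizes, the
planted discriminating pair per group pair, closed-form $D$,
$D_{\text{size}}$ and $\delta$), and two corruption operators emulate the
field's failure modes: `inject_artifact()` silently replaces a fraction
of one variable with group-mean-times-lognormal-noise values (a deformed
gaster), and `inject_missing()` adds MCAR missingness without ever
emptying a row or column.

What the generator does *not* emulate: correlated measurement error
between characters measured in the same view, non-Gaussian size
distributions from mixed rearing conditions, allometry that differs
between groups, and missingness concentrated in fragile body parts
(which is missing-not-at-random in real historical material). Passing
recovery tests on this generator therefore demonstrates correctness of
the estimators under the model's assumptions, not robustness to every
property of museum data.

## Numerical choices and problem sizes

* Eigendecompositions use `eigen(symmetric = TRUE)` on the exact shape
  covariance; eigenvalues are clipped at zero and the structurally null
  last component is dropped.
* Bootstrap CIs are central quantile intervals; `n_boot = 1` collapses
  the interval to the single resample (boundary behaviour, tested).
* Ties in the pair scan are broken lexicographically by abbreviation
  pair, making reports byte-deterministic.
* Isosize variance below $10^{-20}$ (pure floating-point jitter) is
  treated as zero and raises the degenerate-size error.
* The test suite and the acceptance script run Monte-Carlo studies at
  sizes chosen to keep the whole suite in seconds while leaving
  comfortable statistical margins: 100-seed recovery/power studies on
  60-specimen groups with 10 characters, 200–300 replicate
  delta-calibration runs, 200-replicate bootstrap intervals within the
  calibration loops, and a 289 x 19/20-specimen table for the round-trip
  and missingness checks, matching the magnitude of the real study's
  sample.

## Known limitations

* The extractor is strictly two-group (unions of OTUs per side are
  allowed); no multi-group discriminant extraction.
* Whether the original extractor ranks candidate ratios by marginal
  standard distance or by correlation with the full discriminant axis is
  not decidable from the published material; this package maximises
  marginal $D$ (the two coincide at the optimum for well-separated
  two-group problems of this kind).
* The printed reference values of the original study derive from its
  deposited raw data; the package reproduces the *procedures* and
  validates them on synthetic ground truth, and its reports reproduce the
  published table structure, not its archived numbers.
* Qualitative couplet characters are observer-supplied booleans; the
  package does not score images.
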