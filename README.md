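# mratio

Multivariate ratio analysis (MRA) of linear body measurements for
morphometric species delimitation, with the parasitoid wasp genus
*Anisopteromalus* (Hymenoptera: Pteromalidae) as the worked case.

Taxonomists describe and key out species in terms of body ratios. This
package puts that practice in a multivariate framework:

* **Size/shape decomposition.** For measurements $x_{i1},\dots,x_{ip}$
  (µm), the isometric size axis is
  $s_i = \frac1p \sum_k \ln x_{ik}$ (log geometric mean, *isosize*) and
  the shape coordinates are $z_{ik} = \ln x_{ik} - s_i$, so that any
  difference of two shape coordinates is a log body-ratio.
* **Shape PCA** in the $(p-1)$-dimensional ratio space, with the **PCA
  ratio spectrum** (variables ordered by loading, 68% specimen-bootstrap
  CIs, 1000 replicates) identifying the ratios that dominate each
  component, and the **allometry ratio spectrum** doing the same for the
  slopes $b_k = \mathrm{cov}(z_k, s)/\mathrm{var}(s)$ of shape on size.
* **LDA ratio extractor.** An exhaustive scan of all $p(p-1)/2$ variable
  pairs ranks log-ratio contrasts between two groups by the standard
  distance
  $D = |v'(m_1 - m_2)| / \sqrt{v' S_{\mathrm{pooled}} v}$;
  a second, complementary ratio maximises the joint 2-D Mahalanobis
  distance with the first. $\delta = D_{\mathrm{size}}/D_{\mathrm{ratio}}$
  measures whether groups separate by shape ($\delta \approx 0$) or
  indirectly by size.
* **Measurement QC** (pairwise log-correlations flag damaged variables,
  e.g. a deformed gaster), **deterministic imputation** of missing cells
  (iterated ridge regression on logs; imputed specimens are excluded from
  printed ratio ranges), a **quantitative identification key** for
  *Anisopteromalus* females with printed-diagnosis checks, **Kimura
  2-parameter** sequence-distance summaries with pairwise deletion, and a
  **synthetic-data generator** with closed-form ground truth used by
  every recovery test.

## Worked example

Simulate a two-species table with a damaged variable and a few missing
cells, then run the full analysis:

```r
library(mratio)

cfg <- synthetic_config(
  p = 8,
  groups = list(list(label = "calandrae", n = 40,
                     mu = c(0.12, rep(0, 6), -0.12)),
                list(label = "quinarius", n = 35,
                     mu = c(-0.12, rep(0, 6), 0.12), size_offset = 0.08)),
  sigma_size = 0.12, sigma_noise = 0.02,
  artifact = list(variable = "gst.b", fraction = 0.4, noise_sd = 0.5),
  missing_rate = 0.02, seed = 17)
tab <- simulate_measurements(cfg)$table

qc <- correlation_qc(tab)
qc
#> Measurement QC (Pearson correlations of log-measurements)
#> Threshold on median off-diagonal r: 0.5
#> Flagged: gst.b [low median correlation]

tab <- drop_variables(tab, qc$flagged_variables)
imp <- impute_missing(tab, seed = 17)
imp$log
#> Imputation (iterated-ridge-log): 5 cell(s), seed 17, converged in 8 sweep(s)

sh  <- shape_decompose(imp$table)
pca <- shape_pca(sh)
pca
#> Shape PCA: 75 specimens, 6 components
#> Variance explained: PC1 92.9%, PC2 1.9%, PC3 1.8%

extract_best_ratios(imp$table, group_comparison("calandrae", "quinarius"))
#> Ratio extraction: calandrae vs quinarius
#>   1. eye.b : msc.b  D = 19.22  delta = 0.04  [calandrae: 1.20-1.34 | quinarius: 0.75-0.82]
#>   2. eye.b : eye.h  D = 7.88  delta = 0.09  [calandrae: 1.05-1.21 | quinarius: 0.83-0.95]
#>   isosize D = 0.70
```

Reading the output: the QC step catches the silently corrupted gaster
breadth (its median correlation with the other log-measurements collapses
while healthy variables correlate near 1) and removes it; five remaining
missing cells are imputed deterministically. The shape PCA concentrates
the planted between-species contrast in PC1, and the extractor recovers
exactly the planted ratio `eye.b : msc.b` with a standard distance of
19.2 pooled within-group standard deviations and non-overlapping
per-species ranges — a ratio one could print in a key couplet.
$\delta = 0.04$ says the species separate by shape, not size, even
though *quinarius* was simulated 8% larger ($D_{\mathrm{size}} = 0.70$).

Specimens can be keyed out directly from measurements:

```r
r <- compute_ratios(c(hea.b = 1400, tb3.l = 1000, eye.h = 1080,
                      sct.l = 900, mss.l = 7000, ool.l = 1000,
                      eye.d = 966, pdl.flg = 2160, hea.h = 2900,
                      eye.b = 1000, mv.l = 527, stv.l = 300,
                      gst.l = 10000))
key_classify(r)
#> Key classification: calandrae
#> Trace: 1b -> 2a -> 3a
```

`run_all(pipeline_config(...))` chains every stage (QC → drop → impute →
shape PCA → spectra → extraction → key) and writes TSV outputs that are
byte-identical across reruns with the same seed.

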