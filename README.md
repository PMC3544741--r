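# decomix

Cell-type deconvolution of bulk tissue expression with clinical-outcome
interactions, plus the companion analyses of a biomarker study:
seed-gene correlation screening, Monte-Carlo enrichment tests, an open
motif-similarity scanner for the EGR response element, weighted
positive-pixel-count quantification of IHC images, and 2^−ΔΔCt qPCR
quantification — all driven by synthetic-data generators so every stage
is verifiable without external downloads.

## The problem and the model

Bulk expression from admixed tissue (e.g. prostatectomy specimens
containing tumor epithelium, stroma and BPH) confounds *which cell type
expresses a gene* with *how much of that cell type the sample
contains*. Given pathologist-assigned cell-type fractions
P<sub>ij</sub> and a binary relapse indicator RS<sub>i</sub>, decomix
fits, per gene,

> y<sub>i</sub> = β₀ + Σ<sub>j</sub> β<sub>j</sub> P<sub>ij</sub> +
> Σ<sub>j</sub> γ<sub>j</sub> P<sub>ij</sub> RS<sub>i</sub> + ε<sub>i</sub>,
> ε<sub>i</sub> ~ N(0, σ²)

where β<sub>j</sub> is the expression contributed by cell type *j* in
non-relapse tissue and γ<sub>j</sub> = β<sub>j,relapse</sub> −
β<sub>j,non-relapse</sub> is its outcome-linked change. A negative
γ<sub>tumor</sub> with a small t-test p-value flags a gene whose tumor
cell expression drops in patients who relapse — a candidate prognostic
marker. One QR factorization is shared across all genes, so genome-scale
matrices fit in seconds.

## Worked example

Simulate a 108-sample cohort at the study's scale, generate the three
EGR-family genes from their published cell-type coefficients (the
`egr_presets()` ground truth), deconvolve, and rank by tumor relapse
differential:

```r
library(decomix)
ch   <- generate_cohort(cohort_spec(seed = 42))
expr <- simulate_expression(ch$composition, ch$relapse, egr_presets(),
                            seed = 42)
fit  <- deconv(expr, ch$composition, ch$relapse,
               modeled_types = c("tumor", "stroma", "BPH"))
round(coef(fit), 3)
#>      (Intercept)  tumor stroma    BPH tumor:RS stroma:RS BPH:RS
#> Egr3       0.504  0.927  1.317 -8.912   -2.557     0.878  7.398
#> Egr1      -0.453 -0.424  0.549  0.865   -1.107     0.464 -0.699
#> Egr2       1.163 -0.399 -1.184 -1.707   -1.106     0.381  1.101
rank_by_gamma(fit, "tumor")
#>   rank gene_id     gamma  se_gamma     p_gamma
#> 1    1    Egr3 -2.556581 0.8420517 0.003048587
#> 2    2    Egr1 -1.107338 0.7551300 0.145640554
#> 3    3    Egr2 -1.106216 0.7304555 0.133042619
```

The seed gene's tumor differential is recovered near its generating
value of −1.921 (single-cohort estimates scatter with SE ≈ 0.84; the
mean over 100 cohorts lands within ±0.25) and is the most negative of
the three, with a significant p — the inference regime the model is
designed to reproduce.

Enrichment of significant differentials in a candidate list (14 of 98
observed against a 6.1% background), with its exact binomial oracle:

```r
significant_fraction_test(seed = 42)
#> Monte-Carlo enrichment test (significant_fraction)
#>   observed statistic: 14
#>   simulations:        10000
#>   as or more extreme: 27
#>   empirical p:        0.0027
#>   exact oracle p:     0.00251
```

Motif scanning with the open ERE matrix (consensus GCG[G/T]GGGCG,
similarity ≥ 0.80 calls a site):

```r
scan_sequence("TTGCGTGGGCGAA", build_ere_matrix())
#>   sequence_id start end strand similarity matched_window
#> 1         seq     2  11      +          1      GCGTGGGCG
```

IHC quantification on a synthetic image — a strongly stained gland
(intensity ~90) on unstained stroma (~230), lumen excluded:

```r
img <- generate_ihc_image(128, 128,
                          list(gland_region(40, 40, 22, 90, lumen = TRUE)),
                          stroma_intensity = 230, seed = 42)
region_scores(img$image, img$masks[c("gland_1", "stroma")])
#>   region_id n_negative n_weak n_medium n_strong n_total nsr weighted_score
#> 1   gland_1          0      0        0     1340    1340   1              3
#> 2    stroma      14867      0        0        0   14867  NA              0
```

The gland scores the maximal weighted intensity of 3 (all pixels
strong) and the stroma 0, with NSR undefined (no positive pixels) and
excluded from group statistics. `run_replication(seed = 1)` chains all
stages end-to-end and is byte-reproducible for a fixed seed.

## Documentation

See the methods vignette (`vignettes/decomix-methods.Rmd`) for the
model, calibration choices, simulation conventions, and known
limitations; every exported function has roxygen documentation.
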