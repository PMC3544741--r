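---
title: "Methods: composition-interaction deconvolution and its companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-interaction deconvolution and its companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decomix)
```

## The problem

Bulk tissue expression profiles are mixtures.  A prostatectomy
specimen contains tumor epithelium, stroma, benign hyperplastic
epithelium (BPH) and smaller compartments, and the measured log2
intensity of every probe set blends their contributions in proportion
to their abundance.  When each sample also carries a clinical outcome
label — here biochemical relapse, the post-surgery return of PSA —
the interesting question is not just *which cell type expresses a
gene* but *in which cell type the gene's expression changes with
outcome*.  decomix answers both with one regression per gene, and
surrounds that core with the screening, enrichment, motif and image
analyses that typically accompany it in a biomarker study.

## The model

With pathologist-assigned cell-type fractions $P_{ij}$ (sample $i$,
cell type $j$) and a relapse indicator $RS_i \in \{0, 1\}$, each
gene's bulk log2 intensity is modeled as

$$y_i = \beta_0 + \sum_j \beta_j P_{ij} + \sum_j \gamma_j P_{ij} RS_i
        + \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2).$$

$\beta_j$ is the expression contributed by cell type $j$ in
non-relapse tissue and $\gamma_j$ is the *change* of that
contribution in relapse tissue.  We use the convention

$$\gamma_j = \beta_{j,\text{relapse}} - \beta_{j,\text{non-relapse}},$$

i.e. the interaction coefficient of the pooled fit; a negative
$\gamma_{\text{tumor}}$ means tumor cells of relapsing patients
express the gene *less*.  (Study reports sometimes state the
difference in the opposite order in prose while tabulating this one;
`deconv()` documents and uses the tabulated arithmetic, e.g.
$-0.796 - 1.125 = -1.921$ for the canonical seed gene.)  Inference on
every coefficient is the usual OLS t-test on $n - p$ residual degrees
of freedom; the significance of $\gamma_j$ uses the coefficient's own
standard error.

Two numerical points matter:

* **Rank.**  The fractions of all compartments sum to 1, so modeling
  every compartment alongside an intercept is exactly collinear.  The
  generator therefore produces four compartments (tumor, stroma, BPH,
  other) and the fit models three; `build_design()` refuses
  rank-deficient designs (condition number above `1e10`) and names
  the offending columns instead of silently pseudo-inverting.
* **Shared design.**  All genes share one design matrix, so
  `deconv()` QR-factorizes once and solves for all genes in a single
  triangular solve; 50,000 genes by 108 samples takes seconds.

A `center_samples` option subtracts each sample's mean over all genes
before fitting, for replicating analyses whose coefficients are
expressed relative to the array-wide mean; it is off by default
because it couples each gene's fit to the rest of the matrix.

## What the synthetic cohort emulates

The generator's defaults encode the study conditions the package is
tested under:

* **108 samples** with a relapse fraction of $38/101 \approx 0.376$
  (fixed count, as in a retrospective cohort).
* **Cell fractions** drawn from a Dirichlet with
  $\alpha = (3, 4.5, 2, 0.5)$ for tumor/stroma/BPH/other.  Real
  pathologist percentage panels have no published distribution;
  Dirichlet is the minimal simplex-valued choice, and this $\alpha$
  gives mean composition 30/45/20/5% with realistic spread.  The
  parameters are exposed in `cohort_spec()` for sensitivity work.
* **Noise** $\sigma = 0.78$ log2 units.  Calibrated once, as follows:
  under the default design the sampling factor
  $\sqrt{[(X^\top X)^{-1}]_{\gamma_t \gamma_t}}$ averages 1.063, so
  $\sigma = 0.78$ puts the standard error of $\gamma_{\text{tumor}}$
  near 0.83 and a true $\gamma_{\text{tumor}} = -1.921$ at a
  two-sided $p \approx 0.023$ — the inference regime the published
  coefficient table reports.  The value is recorded as the default of
  `gene_model()`/`egr_presets()` and not tuned per analysis.
* **Correlated modules** are linear-plus-noise by construction: the
  noise SD `slope * sd(seed) * sqrt(1/R^2 - 1)` makes the population
  correlation with the seed exactly the target, so cutoff behavior of
  the screen can be tested at known truth.

What it does *not* emulate: probe-level (CEL) effects, batch and
platform artifacts, heavy-tailed or heteroscedastic noise,
censoring/time-to-event structure (relapse is binary), and
correlation between composition and outcome beyond what the model
states.  Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to everything real
arrays do.

## Parameter recovery and null calibration

Two study-scale properties are exercised routinely (sizes chosen as
the package's own test conditions): averaging the estimated
$\gamma_{\text{tumor}}$ over 100 simulated cohorts recovers the
generating coefficients within ±0.25 log2 units with 95% t-interval
coverage at the nominal rate (assessed over all coefficients of the
100 fits); and with all $\gamma = 0$ at 10,000 genes the fraction of
genes with a *negative, significant* ($p \le 0.05$, two-sided)
$\gamma_{\text{tumor}}$ sits at the nominal 2.5%, which is the
machinery behind the enrichment background rate.

## The correlation screen

`pearson_screen()` reports, per probe, Pearson's $R$ against a seed
probe, the two-sided $p$ from $t = R\sqrt{(n-2)/(1-R^2)}$, and the
OLS slope of candidate on seed.  Choices made where the convention is
genuinely open:

* $p$ is **two-sided** (the conservative reading of a cutoff applied
  to positive correlations).
* Correlations are computed on the **log2** scale; anti-log fold
  changes are display transforms.
* Missing entries are dropped **pairwise**, with the per-record $n$
  reported.
* `filter_candidates()` keeps $R \ge 0.45$ and $p \le 0.001$
  (inclusive bounds, positive correlations only) and never returns
  the seed itself.
* Cross-platform intersection collapses probes to gene symbols
  case-insensitively; a gene counts once regardless of probe
  multiplicity.

## Monte-Carlo enrichment tests

All three tests follow the same resampling convention: the empirical
$p$ is `count / n_sims`, ties count as extreme ($\ge$), and a zero
count is reported as the resolution bound $< 1/n_{\text{sims}}$.  The
add-one convention `(count+1)/(n_sims+1)` is available by flag.  Each
test carries its closed-form oracle (binomial or hypergeometric upper
tail) computed alongside the simulation, and the suite checks
simulation-oracle agreement within three Monte-Carlo standard errors
on enumerable small cases.  The defaults encode the three published
comparisons: 14 of 98 probe sets significant against a 6.1%
background (exact tail 0.0025); 81 genes at a 62.7% site background
versus 99% observed (tail $\approx 4\times10^{-17}$, below the
simulation floor); and a 43-gene overlap between 80- and 121-gene
lists from a 9,148-gene universe (tail $\approx 10^{-62}$).  The
Bernoulli approximation to drawing real probe sets is exact under
exchangeability; `significant_fraction_test(background_flags = ...)`
offers finite-population resampling when a fitted background table
exists.

## The motif scanner

Proprietary scanners ship curated matrices and per-matrix "optimized"
thresholds that cannot be reproduced; decomix instead defines an
**open** matrix from the printed EGR response element consensus
GCG(G/T)GGGCG.  Bases outside a position's allowed set get
pseudo-frequency $(1-w)/3$ with $w = 0.85$; allowed bases split the
rest (0.85 for a unique base, 0.45/0.45 at the degenerate K
position).  Position weights are information content in bits,
$w_i = 2 + \sum_b f_{ib}\log_2 f_{ib}$, and a window scores

$$\mathrm{sim} = \frac{\sum_i w_i\, f(i, b_i)}
                      {\sum_i w_i\, \max_b f(i, b)} \in [0, 1],$$

reaching 1 exactly at per-position maxima, so conserved positions
dominate.  Sites are called at similarity $\ge 0.80$, the published
decision rule, on both strands, with coordinates reported 0-based
half-open on the forward strand.  Because the matrix is an open
stand-in, *absolute* site fractions on real promoters will differ
from proprietary scans and are never treated as replication targets;
the scanner's correctness is established against exhaustive window
enumeration instead.  Callers supply promoter windows already clipped
(the conventional span is $-1500..+1000$ around the TSS); the scanner
is coordinate-agnostic.

Synthetic promoters make the planted background exact by
construction: `round(site_fraction * n)` records receive an exact
consensus instance, and the remaining records are rejection-sampled
against the scanner itself until motif-free — no assumption that
random sequence lacks chance sites (at 2.5 kb roughly half of random
uniform sequences contain one, so rejection matters).

## IHC quantification

The positive-pixel-count quantifier works on a single 8-bit intensity
channel; darker is stronger (brightfield absorbance).  Bands use the
published thresholds — strong $\le 100$, medium $(100, 175]$, weak
$(175, 220]$, negative $> 220$ — with boundaries inclusive toward
stronger staining so classification at exact threshold values is
deterministic.  Two summary statistics follow their definitions
directly: NSR = strong / (weak + medium + strong), and the weighted
score = $(1\cdot\text{weak} + 2\cdot\text{medium} +
3\cdot\text{strong}) / \text{total pixels}$, a labeling intensity per
unit area in $[0, 3]$.  Pseudocoloring (blue/yellow/orange/red) is a
lossless band encoding and round-trips to identical counts.  Gland
masks drop lumen pixels (intensity above the weak threshold) before
scoring by default, mirroring lumen-aware commercial software.  Hue
deconvolution (hematoxylin/DAB separation) is out of scope: the
quantities of interest are fully defined by intensity bands, and the
hue-based "−1" negative threshold of the commercial algorithm is
deliberately replaced by the band rule above.  Group comparisons use
Welch's two-sided t-test, with $p = 1$ returned for the degenerate
equal-constant case.

## Determinism and problem sizes

Every generator and simulation takes an explicit integer seed and is
bit-reproducible given it; `run_replication()` derives all stage
seeds from one master seed and re-runs to identical numbers.  Routine
test sizes — 100 recovery cohorts, 10,000-gene null calibration,
10,000-draw simulations, 1-kb oracle scans, sub-megapixel images —
were chosen as the smallest scales at which the statistical
properties are sharp; all are package choices and can be scaled up by
argument.

## Known limitations

* Compositions are treated as known; pathologist measurement error in
  $P_{ij}$ (attenuation toward zero of $\beta$, $\gamma$) is not
  modeled.
* Raw per-coefficient p-values are reported genome-wide with no
  multiplicity correction, matching the replication target's
  convention; downstream users should correct when selecting.
* The ERE matrix is a documented stand-in, not a curated
  position-specific scoring model; only *relative* statements
  (enrichment, planted-site recovery) are meaningful on real
  sequence.
* The image model is flat-field with uniform jitter; stain gradients,
  chromatic effects and segmentation error are out of scope (masks
  are inputs).
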