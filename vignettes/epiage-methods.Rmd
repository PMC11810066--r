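---
title: "Methods: the three-CpG ELOVL2 clock, the amplicon caller, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the three-CpG ELOVL2 clock, the amplicon caller, and what the simulations show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiage)
```

## The clock model

The EpiAgePublic clock predicts age as a linear function of methylation
beta values at three CpGs in the *ELOVL2* promoter, the locus with the
strongest and most reproducible age association in human methylation data:

$$\widehat{\mathrm{age}} = 122.70\,\beta_{\mathrm{cg16867657}}
 + 24.45\,\beta_{\mathrm{cg21572722}}
 - 30.44\,\beta_{\mathrm{cg24724428}} - 42.91 \quad [\text{years}]$$

Beta values are *fractions* in $[0,1]$ — the fraction of molecules
methylated at the site. The coefficient magnitudes force this
interpretation: only fraction-scale inputs map the human lifespan onto
roughly 0–103 years. Because percent-scale beta files (0–100) are a common
interchange format, `predict_age()` refuses any input containing values
above 1.5 with a message telling the user to divide by 100, rather than
rescaling silently; silent rescaling hides upstream data errors. Values
slightly outside $[0,1]$ (as produced by some array preprocessing) are
rejected by default and admitted with `strict = FALSE`.

Predictions are deliberately not clamped. The model is linear, and an
estimate of $-1$ year for a newborn is information about the model's
calibration at the boundary; clamping would destroy it.

Epigenetic age acceleration is the plain difference
$\mathrm{EAA} = \widehat{\mathrm{age}} - \mathrm{age}$, positive when the
methylome "runs ahead" of the calendar. Age-group binning for lifespan
summaries uses `0` (under one year), then left-closed brackets
$[19,31), [31,41), \dots, [71,\infty)$. Ages in $[1,19)$ belong to no
published bracket; they are labelled `"unassigned"` instead of being
silently merged into a neighbouring group.

## Refitting and parameter recovery

`fit_clock()` is ordinary least squares of age on the site betas with an
intercept — nothing else. No train/test split, no regularisation, no
covariates, and no logit/M-value transformation of betas: the clock uses
betas directly, so the refit does too. The OLS solution is unique under a
full-rank design, hence invariant to row order and to beta-matrix column
order (sites are matched by CpG id, never by position). Degenerate designs
(collinear betas, or fewer samples than coefficients plus one) are refused
rather than silently pseudo-inverted.

The refit is validated by parameter recovery: `simulate_cohort()` draws
betas i.i.d. uniform on $[0,1]$ and sets
$\mathrm{age} = f(\beta) + \mathcal{N}(0, \sigma^2)$ with $f$ the clock
formula and $\sigma = 5$ years. Under this design the clock is the true
regression function, so the fitted coefficients are unbiased with standard
errors of about $0.39$ years per unit beta at $n = 2000$; the tests check
each coefficient against its $\pm2$ and (over 100 seeds) $\pm3$ standard
error band, and exact recovery to $10^{-6}$ on noise-free data. Reported
ages are clipped at zero (ages are non-negative), each clipped sample is
flagged, and the truth table retains pre-clip values — recovery runs use
the truth ages, since clipping truncates the error distribution and would
bias any estimator.

$R^2$ is reported in-sample by `fit_clock()` and on whatever cohort the
caller passes to `evaluate_fit()` (which therefore can go negative on
held-out data). For a zero-variance age target, $R^2$ is reported as 0.

## The amplicon methylation caller

The caller re-implements a targeted bisulfite-amplicon pipeline for a
single known amplicon, the regime where a specialised exact method is both
simpler and more transparent than a genome-scale aligner:

* **Trimming.** Per mate: a 3' tail exactly matching a prefix (≥ 3 bases)
  of the adapter is removed, then BWA-style quality trimming cuts the
  suffix maximising $\sum (q_{\mathrm{cutoff}} - Q_i)$ (default cutoff
  Q20). The 5' UMI region of read 1 is never trimmed.
* **UMI parsing.** The first `umi_length` bases of read 1 (default 8) are
  the molecular barcode. UMIs containing `N` are kept verbatim as distinct
  keys; no error-correcting UMI clustering is attempted.
* **Alignment.** Both mates are brought to top-strand orientation (read 2
  is reverse-complemented) and scored at *every* offset of the amplicon
  under the bisulfite rule that a reference `C` may be read as `C` or `T`.
  The assay is directional, so both mates read the converted top strand
  and carry C→T conversions; complementary-strand read forms are out of
  scope. The exhaustive scan is exact — no seeding heuristics — and the
  minimal-mismatch offset wins, ties to the smallest start. A mate maps if
  its mismatch fraction is at most 0.1 (default). Alignment is ungapped:
  the amplicon is one short fixed sequence, and indel-bearing reads simply
  exceed the mismatch threshold and drop out.
* **Deduplication.** PCR duplicates are collapsed by the key
  `(UMI, read-1 alignment start)` — the start coordinate guards against
  UMI collisions between molecules — keeping the pair with the highest
  mean base quality, ties by input order. The operation is idempotent.
* **Calling.** At each annotated CpG cytosine covered by a retained pair,
  `C` counts as methylated and `T` as unmethylated (anything else is
  tallied as "other"). Where mates overlap, only read 1 contributes; read 2
  contributes only at positions read 1 does not cover, so each *pair*
  yields at most one call per CpG and overlapping mates are never double
  counted.
* **Depth filter.** A sample passes when at least 100 deduplicated read
  *pairs* remain (configurable). Betas are still reported for failing
  samples but flagged, and the `predict` CLI stage refuses such samples
  unless `--force` is given.

Output formats are the field's standard per-CpG text files: bedGraph
(0-based half-open, methylation percent) and the Bismark-style `.cov`
dialect (1-based inclusive, percent plus methylated/unmethylated counts).
Internally all coordinates are 0-based half-open; the `.cov` writer/reader
converts at the boundary. Reading a `.cov` file back reproduces the counts
exactly.

The packaged reference, `synthetic_amplicon()`, is a deterministic 400 bp
*synthetic* sequence with 13 CpGs whose first three carry the clock's CpG
ids, so pipeline output feeds straight into `predict_age()`. The real
assay's amplicon boundaries, primers and UMI length are not public; the
fixture emulates the geometry (one short amplicon, 13 CpGs, 5' UMI on
read 1) and claims nothing more.

## Replicate precision QC

Technical-replicate precision is summarised two ways:

* **Per-CpG CV**: $100 \times s/\bar\beta$ with the sample ($n-1$) standard
  deviation — the standard CV convention.
* **Per-sample CI range**: the full width of the confidence interval of
  mean EpiAge across replicates,
  $2\, t_{n-1,(1+c)/2}\, s/\sqrt{n}$ at $c = 0.95$. Student-t quantiles
  are the default because the assay's replicate count is small (typically
  $n = 4$, where $t_3 = 3.18$ vs $z = 1.96$ — a normal interval would
  understate the width by a third); a normal-quantile variant sits behind
  `method = "normal"` and the choice is recorded in the QC output
  metadata. Ranges are graded into left-closed bins
  $<1$, $[1,1.5)$, $[1.5,2)$, $[2,3)$, $\ge 3$ years; an exact boundary
  value falls in the higher bin, and the bins partition $[0,\infty)$ so
  every sample lands in exactly one.

## Cohort statistics

The comparison stack mirrors common practice in clock papers:

* `compare_groups()` screens both groups with Shapiro-Wilk at
  $\alpha = 0.05$ and picks the unpaired two-tailed t-test when both pass,
  otherwise the two-tailed Mann-Whitney U test; `force_test` overrides the
  screen, and groups below $n = 3$ (unscreenable) default to t. The choice
  of Shapiro-Wilk is a convention of this package — it is the most common
  omnibus normality screen — and is reported in the result object.
* `pearson_with_ci()` is the product-moment correlation with the Fisher
  z-transform interval.
* `roc_analysis()` computes AUC by the Mann-Whitney rank identity (ties
  count one half), auto-detects the case-enriched direction (AUC ≥ 0.5),
  and reports sensitivity at 100% specificity as the fraction of cases
  *strictly* beyond the most extreme control, with that control value as
  the threshold. The p-value against AUC = 0.5 is the two-sided
  Mann-Whitney p (normal approximation under ties) and is labelled as
  such in the output.
* `covariate_adjusted_association()` is OLS with intercept and per-term
  two-tailed t-tests; rank-deficient designs are refused naming the
  collinear columns.
* `anova_dunnett()` provides ordinary one-way ANOVA with Dunnett contrasts
  against a reference group. Repeated-measures ANOVA with sphericity
  correction is deliberately out of scope.

## What the simulators emulate — and what they do not

`simulate_cohort()` (uniform mode) matches the clock's *statistical
assumptions*, not real cohort structure: real beta distributions are
bimodal and age-correlated, not uniform, and real age errors are neither
homoscedastic nor Gaussian. The `age_driven` mode adds lifelike marginal
trends (two sites rising with age, one falling, matching the weight signs)
for demonstrations. Passing parameter-recovery tests therefore shows the
estimator is correct under its own model, not that the clock generalises
to any real population.

`simulate_reads()` models: per-molecule Bernoulli methylation states,
bisulfite conversion of unmethylated cytosines at a given efficiency (the
non-CpG background is fully unmethylated, so at efficiency 1 every non-CpG
`C` reads `T`), geometric PCR copy numbers (memoryless amplification
approximation) sharing one UMI, uniform substitution errors, and constant
Q37 qualities. It does not model: indels, chimeras, primer artefacts,
strand-specific error profiles, quality decay along the read, UMI errors
(errors are applied to genomic bases only, keeping the truth table exact —
consistent with UMI error correction being out of scope), or the real
ELOVL2 sequence context. Generators are byte-deterministic given their
mandatory seed.

Problem sizes used in the shipped tests — 2000-sample cohorts, 100-seed
coverage sweeps, 200-pair alignment-oracle scans, a 5000-molecule
end-to-end run, 2000 null simulations for test calibration — were chosen
as the smallest sizes at which the sampling error of each check is
comfortably below the effect it verifies.

## Numerical conventions and edge cases

* Beta lookup is by CpG id everywhere; column order never matters.
* Missing betas propagate as missing and fail prediction loudly per
  sample; they are never imputed or zero-filled.
* A CpG with zero methylated + unmethylated coverage has an undefined
  (`NA`) beta, not 0.
* Alignment ties break to the smallest start; dedup ties break to the
  first-seen pair — both make reruns bit-reproducible.
* `compute_eaa()` rejects negative chronological ages; `ci_bin()` rejects
  negative ranges; simulators validate every rate and probability and
  refuse to run without a seed.

## Known limitations

* The caller handles exactly one amplicon per run (the reference is
  data-driven, but panels are out of scope), emits no SAM/BAM, and models
  the top strand of a directional library only.
* No penalised clock construction or probe selection: refitting is OLS on
  a user-given site list.
* The bundled amplicon is synthetic; absolute performance numbers on it do
  not transfer to the real assay's sequence context.
* The CI-range and CV summaries assume exchangeable replicates; no
  outlier-replicate rejection or variance decomposition is attempted.
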