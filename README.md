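# epiage

DNA methylation age from three CpG sites in the *ELOVL2* promoter, plus the
targeted sequencing machinery to measure them.

`epiage` is an R implementation of the **EpiAgePublic** epigenetic clock and
of the analysis stack around it, aimed at labs running targeted
bisulfite-amplicon assays and at anyone who wants a transparent, minimal
methylation clock:

* **Clock evaluation** — predicted epigenetic age from beta values, epigenetic
  age acceleration (EAA = EpiAge − chronological age), lifespan age-group
  binning.
* **Clock refitting** — plain OLS re-estimation of the three-CpG model with
  standard errors, R², and parameter-recovery validation on synthetic
  cohorts.
* **Amplicon methylation calling** — adapter/quality trimming, conversion-aware
  ungapped alignment to a single amplicon, UMI deduplication,
  mate-overlap-aware per-CpG calling, and a 100-read depth filter, with
  bedGraph / Bismark-style `.cov` output.
* **Replicate QC** — per-CpG coefficient of variation and per-sample 95%
  CI-range precision bins across technical replicates.
* **Cohort statistics** — two-group tests with Shapiro normality screening,
  Pearson correlation with Fisher-z intervals, ROC AUC with sensitivity at
  100% specificity, covariate-adjusted regression, stress-score binning,
  one-way ANOVA with Dunnett contrasts.
* **Simulators** — age-structured beta cohorts, technical replicate sets, and
  UMI-tagged bisulfite read pairs with PCR duplicates, incomplete conversion
  and base-call error, all byte-deterministic given a seed.

## The model

The clock is a linear model over the beta values (fraction of methylated
molecules, in [0,1]) of three CpGs:

```
EpiAge = 122.70 * beta(cg16867657)
       +  24.45 * beta(cg21572722)
       -  30.44 * beta(cg24724428)
       -  42.91                      (years)
```

EAA is `EpiAge - chronological age`; positive values mean accelerated
epigenetic aging. Predictions are not clamped — a slightly negative age for
a newborn is an honest extrapolation of the linear model.

## Worked example

```r
library(epiage)

clock <- elovl2_clock()
beta <- rbind(
  newborn = c(cg16867657 = 0.36, cg21572722 = 0.30, cg24724428 = 0.33),
  adult   = c(cg16867657 = 0.62, cg21572722 = 0.55, cg24724428 = 0.30),
  elderly = c(cg16867657 = 0.90, cg21572722 = 0.70, cg24724428 = 0.28))
samples <- data.frame(sample_id = c("newborn", "adult", "elderly"),
                      age = c(0, 42, 78))
estimate_ages(clock, beta, samples)
#>   sample_id  epiage     eaa age_group
#> 1   newborn -1.4482 -1.4482         0
#> 2     adult 37.4795 -4.5205     41-50
#> 3   elderly 76.1118 -1.8882       71+
```

`epiage` is the model's age estimate in years; `eaa` is its difference from
the chronological age in the sample sheet (the adult here is epigenetically
about 4.5 years "younger" than their calendar age); `age_group` is the
lifespan bracket of the chronological age.

Refitting the clock on a synthetic cohort generated from the model itself
recovers the published coefficients within their standard errors:

```r
sim <- simulate_cohort(clock, n = 2000, noise_sd = 5, seed = 1)
fit <- fit_clock(sim$beta, sim$truth$age_pre_clip)
summary(fit)
#> OLS clock refit 'refit' (n = 2000)
#>          term estimate       se
#> 1 (Intercept) -43.0472 0.350349
#> 2  cg16867657 122.1210 0.387959
#> 3  cg21572722  25.0181 0.382829
#> 4  cg24724428 -30.1768 0.396006
#> R-squared 0.9817, MAE 4.04 y
```

And the full sequencing pipeline, from simulated UMI-tagged bisulfite read
pairs to per-CpG calls on the packaged synthetic amplicon:

```r
ref <- synthetic_amplicon()
reads <- simulate_reads(ref, n_molecules = 500, meth_probs = 0.7,
                        duplication_rate = 2, seed = 1)
res <- call_amplicon_sample(reads$pairs, ref)
res$qc$deduplicated      # 500 of 1013 raw pairs survive UMI dedup
head(res$calls, 3)
#>       cpg_id offset methylated unmethylated other coverage  beta
#> 1 cg16867657     34        351          149     0      500 0.702
#> 2 cg21572722     61        335          165     0      500 0.670
#> 3 cg24724428     88        348          152     0      500 0.696
```

The called betas sit on the simulated truth methylation of 0.70, and the
sample passes the 100-deduplicated-pair depth filter.

## Command line

A thin Rscript front end is installed with the package
(`system.file("cli", "epiage", package = "epiage")`), exposing `predict`,
`train`, `call-meth`, `qc`, `compare`, `roc`, `correlate`, `adjust` and
`simulate` subcommands over delimited text, FASTA/FASTQ(.gz), BED and JSON
files. Every run writes a JSON provenance record next to its outputs.

```sh
epiage simulate reads --n-molecules 500 --seed 7 --out sim/
epiage call-meth --r1 sim/reads_R1.fastq --r2 sim/reads_R2.fastq \
       --reference sim/reference.fasta --cpg-bed sim/cpgs.bed --out calls/
epiage predict --betas calls/sample_betas.tsv --qc calls/sample_qc.json \
       --out estimates.tsv
```

## Documentation

The methods vignette (`vignettes/epiage-methods.Rmd`) describes the model
and its assumptions, the pipeline's algorithmic choices (alignment rule,
dedup key, overlap policy), what the simulators do and do not emulate, and
the package's numerical conventions.
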