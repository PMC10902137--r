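---
title: "Methods: germination-stage drought screening, heritability and association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germination-stage drought screening, heritability and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtscreen)
```

## The problem

Drought at the germination stage decides whether a sown field establishes a
stand at all, and screening a diversity panel for germination-stage drought
tolerance is a standard first step toward breeding and mapping. The usual
bench design applies an osmoticum — 15% (w/v) PEG-6000 — next to a pure-water
control, counts newly germinated seeds daily, and asks two questions of the
panel: *which accessions keep germinating under osmotic stress* (screening),
and *where in the genome does that tolerance map* (association). This package
implements the full analysis chain for such a trial, and a seeded simulator
that generates trials with the same design so every stage can be validated
without access to any particular laboratory's raw counts.

## Germination indices

For one trial unit (a genotype x environment x treatment x replicate tray of
`total_seeds` seeds counted over `n_days` days):

* **GR** (germination rate) = cumulative germination through the final day /
  seeds sown x 100. Percent.
* **GE** (germination energy) = cumulative germination through the energy day
  (default day 4) / seeds sown x 100. Percent; an early-vigour measure, so
  GE <= GR by construction.
* **GI** (germination index) = sum over days *t* of
  (seeds newly germinated on day *t*)/*t*. Unitless; front-loads early
  germination.

Relative indices compare drought to control **as ratios of replicate
means** per genotype x environment: RGR = RD/RC, RGE = ED/EC, RGI = ID/IC.
The ratio-of-means convention (not mean-of-ratios) matches the
drought-tolerance coefficient below, which is defined on trait averages. A
genotype whose control mean is zero has an undefined ratio: the value is set
to missing with a warning and excluded from all later min/max scans — ratios
are never clamped, and values above 1 (drought outperforming control) are
retained as observed.

## Membership-function scoring and grading

Scoring runs per environment, in three steps per trait *j* in {GR, GE, GI}:

1. **DTC** (drought-tolerance coefficient): drought mean / control mean x 100.
2. **SFV** (subordinate/membership function value): min–max normalization of
   the DTC column across genotypes,
   (x − min)/(max − min), in [0, 1]. SFV is invariant to positive affine
   transforms of its input, so the x100 in the DTC cancels and raw relative
   indices give identical scores. A column with all values equal carries no
   ranking information; every score is set to 0.5 with a warning.
3. **ASFV**: the arithmetic mean of the three trait SFVs. Higher = more
   drought tolerant.

Grading divides the **observed** ASFV range into five equal intervals,
labelled HDS, DS, MDT, DT, HDT from low to high. With an observed range of
[0, 0.94] the four cut points are 0.188, 0.376, 0.564, 0.752 — displayed
rounded to two decimals (0.19 / 0.38 / 0.56 / 0.75) but classification always
uses the unrounded values. Two conventions were genuinely open and are fixed
here: intervals are left-closed right-open with a closed top interval (the
maximum grades HDT), and a value exactly on an interior boundary goes to the
higher class. Scoring each environment independently and then combining HDT
lists by union/intersection reflects the fact that each environment's range
(and hence scheme) differs; `screen_tolerant()` reports both set operations.

```{r grading}
scheme <- build_grade_scheme(c(0, 0.94))
scheme
assign_grades(c(0.76, 0.40, 0.05), scheme)
```

## Variance components and heritability

Replicate-level relative values (drought replicate over the control
replicate mean of the same genotype x environment) feed a balanced two-way
ANOVA, `value ~ genotype * environment`. On the balanced layout the sums of
squares decompose exactly, and the expected-mean-squares method of moments
gives closed-form components:

σ² = MS_res, σ²_ge = (MS_GxE − MS_res)/r, σ²_g = (MS_G − MS_GxE)/(nr),

with negative estimates clipped to zero (warned). Broad-sense heritability on
the line-mean basis is

h² = σ²_g / (σ²_g + σ²_ge/n + σ²/(nr))

for *n* environments and *r* replicates. Method of moments was preferred to
REML because the balanced design makes it exact, closed-form and trivially
reproducible; for unbalanced data the ANOVA refuses to run rather than
silently switching estimators. Descriptive statistics use the sample (n−1)
SD, CV = SD/mean x 100, and the bias-adjusted (SPSS/Excel-style) skewness and
excess-kurtosis formulas, the conventions under which such trait tables are
usually produced.

## The association scan

The scan fits, per SNP, the mixed model y = μ + sβ + u + e with
cov(u) = σ²_u K and cov(e) = σ²_e I, where K is the VanRaden centred
cross-product kinship matrix K = ZZ′/(2Σp(1−p)). Numerically:

* The variance ratio δ = σ²_e/σ²_u is profiled **once** on the null model by
  restricted maximum likelihood, using the spectrum of K projected orthogonal
  to the fixed effects (a 41-point log-grid bracket followed by golden-section
  refinement over log δ in [−10, 10]).
* With δ fixed, the data are whitened through the eigendecomposition of K and
  every SNP is tested by ordinary least squares on the whitened scale — the
  population-parameters-previously-determined (EMMAX/P3D) approximation that
  standard GWAS packages default to. A per-SNP exact refit (`refit = TRUE`)
  re-profiles δ under each alternative for small data or verification.
* The Wald statistic uses a t reference with n − p residual degrees of
  freedom; with K = I the whole construction collapses to ordinary least
  squares exactly, a reduction the tests exploit.

Significance uses a fixed threshold −log10(p) ≥ 5.0, inclusive at the
boundary; no multiple-testing correction is applied beyond it, matching
common practice for this design (Bonferroni/FDR can be layered on the scan
table afterwards). **PVE**, the percent of phenotypic variation explained by
one SNP, is the likelihood-ratio R² of the SNP term on the whitened scale —
for this Gaussian model exactly the partial R², (RSS0 − RSS1)/RSS0 x 100.
PVE conventions differ between GWAS tools and are rarely stated; this one is
fixed and versioned here. Haplotype comparison at a chosen SNP contrasts the
two homozygote allele classes (heterozygotes excluded by default) with a
one-way ANOVA, starred at p < 0.01 (`**`) and p < 0.001 (`***`).

MAF filtering defaults to 0.05 before kinship and scan.

## What the simulator emulates

`sim_config()` defaults encode the trial design the analysis assumes: 264
genotypes, 2 environments (years), control vs 15% PEG-6000, 3 replicates of
50 seeds, 7 daily counts, energy day 4. Each genotype carries a latent
drought-response liability g + (g x e) + Σ(centred dosage x effect) with
g ~ N(0, σ²_g) and (g x e) ~ N(0, σ²_ge). Under drought, the liability plus a
replicate-level N(0, σ²_res) disturbance shifts the per-seed germination
probability through a logistic link anchored at a baseline of 0.5 (probability
out of (0,1) is clamped with a warning, or is an error under `strict`);
control trays germinate at 0.88 regardless of liability. The two baselines
mirror typical control-vs-stress germination-rate means near 88% and 50% in
such screens. Each germinating seed draws its day from a discretized normal
whose centre starts at 4.5 under drought and moves one day earlier per 1.25
liability units (floor day 1, SD 1.2 days); control trays centre at day 2.5.
Any monotone day-shift model would do; this one is the simplest that is
bounded, seeded and produces realistic GE/GR separation.

The liability variance defaults (σ²_g = 1, σ²_ge = 0.5, σ²_res = 4) were
fixed once so that the realized line-mean heritability of RGR at the full
design is close to 0.5, the scale such germination screens typically report;
the plug-in formula value at these components is 1/(1 + 0.25 + 0.667) ≈ 0.52,
and binomial counting noise takes the realized value slightly below that.
Planting causal SNPs adds genetic variance on top, so configurations with
strong planted QTL (e.g. per-allele effect 1.2, giving a top PVE near 10%)
show higher heritabilities than the no-QTL calibration — both features
cannot be matched simultaneously without an implausibly large replicate
residual, a known limitation.

What the simulator does **not** emulate: linkage disequilibrium (SNPs are
independent given their allele frequencies), population structure or
admixture, dormancy and seed-lot quality effects, fungal losses, or the
multi-million-SNP marker density of a resequencing panel. Passing tests on
synthetic data therefore validate the *arithmetic and the statistical
calibration* of the pipeline — not robustness to structure confounding,
which a kinship-only mixed model mitigates but does not eliminate in real
panels.

## Numerical choices and degenerate inputs

* Min–max normalization requires >= 2 distinct values; all-equal columns score
  0.5 with a warning, single values are an error.
* Grade schemes require a non-degenerate ASFV range; applying a scheme to
  out-of-range data clamps with a warning (supports scoring new material
  against a reference scheme).
* Variance components are clipped at zero with a warning; the heritability of
  an all-zero decomposition is missing, not 0/0.
* Eigenvalues of K below 1e−10 are floored before inversion; dosage columns
  whose whitened residual sum of squares is below 1e−12 (collinear with the
  intercept/covariates) return missing statistics rather than spurious zeros.
* The problem sizes used by the validation suite — e.g. 50 variance-component
  recovery runs at 264 x 2 x 3, one 12,000-SNP null scan at n = 264, twenty
  300-SNP power replicates — were chosen as the smallest sizes at which the
  Monte-Carlo tolerances stated in the tests are comfortably stable.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_genotypes = 264, n_snps = 3000, n_causal = 5,
                  causal_effect_sizes = 1.2, maf_range = c(0.1, 0.5),
                  rng_seed = 1)
report <- run_pipeline(cfg, out_dir = "run1")
report
```

The same orchestration is available from a shell through
`inst/cli/droughtscreen.R` (verbs `simulate`, `indices`, `score`, `stats`,
`gwas`, `all`), a thin wrapper over `run_pipeline()`.
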