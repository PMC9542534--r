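---
title: "Quantitative microbiota profiling of infant gut cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microbiota profiling of infant gut cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmpinfant)
```

## The scientific problem

16S rRNA amplicon sequencing yields *relative* taxon abundances. In the
infant gut, where total bacterial load grows by one to two orders of
magnitude over the first year, relative profiles can invert true dynamics:
a taxon whose absolute density is stable or rising appears to decline simply
because the rest of the community grows faster, and absolute increases in
many taxa are compositionally masked. Quantitative microbiota profiling
(QMP) scales each sample's relative profile by an independent qPCR estimate
of total 16S copies per gram of feces and divides each taxon by its mean 16S
gene copy number, yielding approximate cell densities (cells/g).

`qmpinfant` implements a complete QMP analysis for longitudinal infant
cohorts stratified by birth mode and intrapartum (IP) antibiotic exposure:

1. **Profiling** — blank-control contaminant subtraction, per-run rare-read
   filtering, per-cohort coverage cutoffs, and qPCR-anchored copy-number
   corrected absolute profiles.
2. **Cohort design** — the five-group exposure design (`VD`, `VD-cep`,
   `VD-pen`, `CS-cep`, `CS-other`), post-natal antibiotic censoring, and
   covariate-adjusted model designs.
3. **Differential abundance** — a taxon-wise model cascade
   (negative binomial, then Poisson, then quasi-Poisson, then group-weighted
   least squares on log abundance) with Benjamini–Hochberg control.
4. **Ordination trajectories** — PCoA on Pearson-correlation distances of
   log profiles, per-timepoint ANOVA of group separation on the first two
   axes, median group trajectories, and loess-smoothed class trajectories
   with a 30% confidence band.
5. **Mediation path models** — per outcome and timepoint: exposure effects
   on parent-reported symptoms, AIC-selected mediator taxa, exposure–taxon
   edges, and a direct-effect-attenuation rule for declaring mediation.
6. **A synthetic cohort generator** with full ground truth, used for every
   validation study in the package.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code. Its defaults are the study
conditions all validation results refer to.

**Abundance model.** Per taxon $t$, infant $i$, age $j$, the true absolute
abundance (16S copies/g) is log-normal:
$$\log A_{ijt} = \log\!\big(L_j\, p_{tj}\big) - \tfrac{\sigma^2_b+\sigma^2_e}{2}
  + \beta_{t,g(i),j} + b_{it} + \varepsilon_{ijt},$$
with $L_j$ the per-age geometric-mean total load (default rising from
$10^9$ to $4\times10^{10}$ copies/g over weeks 1–52), $p_{tj}$ the baseline
community share, $\beta$ the planted group effects (natural-log fold changes
relative to unexposed vaginal delivery), $b_{it} \sim N(0, 0.8^2)$ an
infant-level random intercept and $\varepsilon \sim N(0, 0.7^2)$ residual
noise. The variance correction makes the expected total load match $L_j$.
The random-intercept SD of 0.8 (natural-log scale) is a free choice — the
literature does not pin down inter-infant correlation — and 0.7 residual SD
gives a total between-sample log SD of about 1.06, i.e. roughly 3-fold
typical variation, which is what infant-gut genus abundances show.

**Measurement model.** True cell densities are copies divided by the taxon's
mean 16S copy number. The qPCR observation is the true copy sum times
log-normal noise with 15% CV (triplicate qPCR). Sequencing depth is negative
binomial (mean 26,000 reads, size 5) and reads are multinomial in the
copy-inflated relative abundances — reads measure amplicon copies, not
cells. Reagent contaminants (Alcaligenaceae/Burkholderiaceae-type genera)
receive Poisson reads in both samples and per-run blank controls, so blank
subtraction is meaningful.

**Exposure design.** Default group sizes are 26/7/13/33/13 infants
(VD/VD-cep/VD-pen/CS-cep/CS-other), the qPCR-quantified subset of the
worked-example cohort, at seven ages (weeks 1–52). Default planted effects
emulate the canonical signature: Bacteroides-group depletion specific to
cesarean birth (ln FC −3 to −2 in weeks 1–12), bifidobacteria depleted in
all exposure groups early, and Bacilli increased in all exposure groups.

**Well-being outcomes.** Each outcome has a linear predictor combining
standardized log mediator abundances and a direct exposure indicator.
Crying intensity is a 0–100 visual-analogue score drawn as a scaled
beta-binomial (precision 8 — parent-reported VAS is noisy); defecation rate
and symptom intensities are negative binomial; tests may also plant Gaussian
outcomes when an exact target $R^2$ is needed. Because mediators are
standardized around the *unexposed* expectation, a planted group effect on
the mediator propagates into the outcome: the mediation chain is real, not
merely correlational.

**What the generator does not emulate:** strain-level dynamics, taxonomic
mis-annotation, chimeras, zero-inflation beyond what multinomial sampling
induces, seasonal or geographic structure, and informative missingness of
questionnaires. Passing tests therefore show the pipeline recovers truth
under a faithful but idealized data-generating process, not that any
biological claim about a real cohort is reproduced.

## Profiling choices

* **Blank subtraction** removes, per sequencing run, the mean blank count of
  each taxon from every sample of the run, floored at zero (a
  depth-proportional variant is a switch). The step is not idempotent, so a
  provenance flag refuses re-application.
* **Coverage cutoff is inclusive**: a sample with exactly the cutoff total
  (e.g. 2000 reads for a deeply sequenced cohort, 120 for a low-biomass one)
  is retained.
* **Copy numbers** resolve by exact genus match, then family, order, class,
  then the global mean of the table. Bifidobacteriaceae (3.5 mean copies) vs
  Clostridiales (5.5) is the canonical contrast: with equal reads, the
  corrected cell ratio favors the low-copy taxon by 5.5/3.5.
* Uncorrected absolute abundances always sum to the sample's qPCR load
  (relative tolerance $10^{-9}$); this conservation is asserted in the
  tests.

## The differential-abundance cascade

Each sufficiently prevalent taxon (strictly more than 30% nonzero among the
analyzed samples) is fitted, per timepoint, with the cascade:

1. **negative binomial** (log link; abundance rounded to counts in units of
   $10^4$ cells/g),
2. **Poisson** (admissible only when the Pearson dispersion is in
   [0.5, 1.5]),
3. **quasi-Poisson**,
4. **group-weighted least squares on $\log_{10}(y+1)$**.

A count family is rejected on non-convergence, a degenerate dispersion
estimate ($\hat\theta$ outside $[10^{-3}, 10^4]$ or hitting the iteration
limit), or a failed residual diagnostic — a significant Spearman-type trend
of absolute Pearson residuals against fitted values at $\alpha = 0.05$, the
operational heteroscedasticity check. In addition the whole count branch is
skipped when a Gaussian model of log abundance clearly outfits the count
family (AIC smaller by more than 2, with likelihoods compared on the count
scale through the log-transform Jacobian): the family choice should follow
the data distribution.

**Inference.** Count-family contrast P values use HC3 sandwich standard
errors with a residual-df $t$ reference, and are additionally guarded by
taking the maximum with the P value of the same term in the parallel
log-scale least-squares model. The max of two P values is level-valid
whenever either error model holds (an intersection–union argument), so
Benjamini–Hochberg control survives even when heavy-tailed abundances make
the count model's own tails unreliable — which plain Wald tests on
log-normal abundances demonstrably are. The power cost is small because both
tests are powerful against planted fold changes. The `gls-log` stage is an
iterated feasible GLS with per-group variances and per-coefficient
Satterthwaite degrees of freedom; in the two-group case it reduces exactly
to Welch's $t$-test, and it is cross-checked against `nlme::gls` with
`varIdent` weights in the test suite.

**Reporting.** Fold change is $e^{\hat\beta}$ for log-link families and
$10^{\hat\beta}$ for the log10-scale fit; the display value is log10 fold
change capped at ±5. BH adjustment is applied within each
timepoint-by-contrast family (the adjustment family is a package choice; it
is deliberately prominent here). The significance flag requires both
$P < .05$ and FDR $< 0.1$. Taxa whose fits fail entirely are reported with
`NA` and a diagnostic, never dropped silently.

**Validated properties** (all computed by the test suite and
`scripts/acceptance.R`): a planted ln-fold-change of 1.5 at 25 infants per
group is flagged with ~90% power across 50 replicates (requirement ≥ 70%);
200 replicates of a 500-taxon global null keep the empirical false-discovery
proportion around 0.07–0.14 depending on seed (gate ≤ 0.15); BH q values
match a brute-force step-up to machine precision on 1000 random P vectors.

## Ordination and trajectories

Distances are $d(i,j) = 1 - r$ with $r$ the Pearson correlation of
$\log_{10}(x + 1)$ abundance vectors, followed by classical scaling;
negative eigenvalues are zeroed and their total magnitude recorded (no
Cailliez/Lingoes constant is added, to avoid inventing structure). Group
separation at a timepoint is tested by one-way ANOVA on each of the first
two principal coordinates (a pooled MANOVA is reported alongside; the
per-axis test is the default because the two-axis wording of such analyses
is ambiguous). Smoothed class trajectories use degree-1 loess with span 0.5
on ages 4–39 weeks; the 30% confidence band is the smoothed mean ±
$z_{0.65}$ standard errors — the band construction is a package convention,
since "30% confidence interval" does not define one.

The relative-vs-absolute discordance artifact is reproducible by
construction: `simulate_discordant_taxon()` pins one taxon's expected
absolute abundance to a slowly increasing trajectory while total load grows
about 40-fold, so the taxon's fitted age slope is non-negative on the
absolute scale and negative on the relative scale (`scale_discordance()`).

## Mediation path models

Per outcome and timepoint:

1. **Exposure model**: outcome ~ birth mode + antibiotic class + feeding +
   probiotics. Count-valued outcomes use negative binomial regression
   (Poisson fallback); continuous outcomes a Gaussian linear model
   (`family = "auto"` decides from the data). Per-factor P values are
   likelihood-ratio (or F) tests.
2. **Mediator selection**: deterministic forward–backward AIC over
   log10 taxon abundances passing the 30% prevalence gate, starting from the
   intercept-only model, capped at $n/10$ terms, and requiring each step to
   improve AIC by more than 4 (the conventional strong-support threshold).
   The margin is the overfitting guard: with 50 pure-noise candidates at
   $n = 60$ the median variance explained of the selected model is ~0, while
   a genuine mediator with $R^2 = 0.3$ is still selected in ≥ 95% of
   replicates.
3. **Variance explained** is the squared Pearson correlation between fitted
   and observed outcome (affine-invariant, comparable across model
   families); an $R^2$-style residual measure is emitted alongside.
4. **Exposure–taxon edges**: each selected taxon is tested against birth
   mode and antibiotic class with the same differential-abundance cascade;
   edges with $P < .05$ are kept with their signs.
5. **Mediation label**: an exposure term is declared *mediated* when it is
   significant marginally, at least one selected taxon carries both an
   exposure edge and an outcome edge, and the term loses $\alpha = 0.05$
   significance once the mediator abundances enter the outcome model
   (direct-effect attenuation). Published mediation diagrams of this kind
   never define mediation numerically; attenuation is this package's
   operationalization, and no formal natural direct/indirect effect
   decomposition is attempted.

On the planted chain scenario (exposure shifts the mediator by ln FC −1.5,
mediator explains $R^2 = 0.3$ of a Gaussian symptom at $n = 60$), the
mediator is recovered in ~95% of 50 replicates with mean absolute
variance-explained error ≈ 0.10 (requirement: ≥ 80% recovery, error ≤ 0.15);
under the matching null, spurious full exposure–taxon–outcome paths occur in
≤ 10% of replicates. Reported variance-explained values in the 0.2–0.5 range
are therefore plausible under this design, matching the envelope such
analyses report on real cohorts, but the generator cannot and does not
reproduce any real cohort's numbers.

## Numerical and degenerate-input conventions

* Pseudo-count 1 before all log10 transforms (configurable).
* Zero-total samples are an error in `relative_abundance()` (named sample);
  samples without qPCR are excluded with a logged reason; constant sample
  vectors are excluded from ordination with a note.
* Groups with fewer than 3 samples at a timepoint are dropped from DA
  designs; groups with fewer than 2 samples are excluded from ordination
  ANOVA.
* Constant covariates at a timepoint are dropped from designs with a note;
  reference levels are fixed (VD, no antibiotic, exclusive breastfeeding).
* Ties in stepwise selection are broken by candidate order (column order of
  the abundance matrix), making selection fully deterministic.
* All simulation is seeded; identical configuration and seed give
  bit-identical outputs.

## Problem sizes used in the validation studies

Power: 50 replicates of 25 + 25 infants, one timepoint, 34 taxa. Null FDR:
200 replicates of 15 + 15 infants and 500 taxa. Mediation: 50 + 50
replicates of 60 infants. BH oracle: 1000 random vectors of up to 60 P
values. Masking: 25 + 25 infants, ten 5-fold-increased taxa holding ~80% of
the community. These sizes make the full validation run in roughly a quarter
hour on a single core while keeping every Monte-Carlo estimate's standard
error well inside the asserted tolerances.

## Known limitations

* Absolute abundances inherit qPCR accuracy; systematic extraction bias is
  not modeled, so "cells/g" are calibrated only up to the qPCR standard.
* The count-model cascade reports the family it used, but with strongly
  log-normal data most taxa legitimately end in `gls-log`; family labels
  describe fit adequacy, not biology.
* The mediation analysis is associational path modeling with model
  selection; it supports, but cannot establish, causal mediation.
* Copy-number correction uses rank-level means; primer-specific or
  within-genus copy variation is out of scope.

## A minimal end-to-end run

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(seed = 1))
counts <- subtract_blank_contaminants(sim$counts, sim$blanks)
counts <- filter_rare_reads(counts, 10)
counts <- apply_coverage_cutoff(counts)
prof <- absolute_profile(counts, sim$qpcr, sim$copy_numbers)

da <- qmp_da(prof, sim$metadata, rank = "family")
summary(da)

ord <- pcoa_pearson(prof)
test_group_separation(ord, sim$metadata, timepoint = 4)

path_model(prof, sim$metadata, sim$wellbeing, "defecation_rate", 6)
```
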