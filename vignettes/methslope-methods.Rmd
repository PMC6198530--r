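---
title: "Modelling between-individual variation in the rate of DNA methylation change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling between-individual variation in the rate of DNA methylation change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(methslope)
library(dplyr)
```

## The question and the model

Cross-sectional methylome studies treat age as a covariate with a common
effect, implicitly assuming every individual's methylation at a CpG site
drifts at the same rate. `methslope` targets the complementary question: at
which CpG sites does the *rate* of change itself differ between people, and
is that difference under genetic control?

For each probe, the observed (residualized) M-value of individual $i$ at
observation $j$ is modelled as

$$y_{ij} = u_1 + u_2\,t_{ij} + a_i + b_i\,t_{ij} + e_{ij},$$

where $t_{ij}$ is age standardized to mean 0 and variance 1 over the
analysis set, $u_1$ and $u_2$ are the fixed mean level and mean age trend,
$(a_i, b_i)$ is a per-individual random intercept and random slope with

$$\begin{pmatrix} a_i \\ b_i \end{pmatrix} \sim N\!\left(0,\;
\Omega = \begin{pmatrix} \sigma_a^2 & \sigma_{ab} \\ \sigma_{ab} &
\sigma_b^2 \end{pmatrix}\right), \qquad e_{ij} \sim N(0, \sigma_e^2).$$

The default model sets $\sigma_{ab} = 0$; `covariance = TRUE` frees it, and
`quadratic = TRUE` adds a fixed $t^2$ term. The scientific target is
$\sigma_b^2$: a non-zero slope variance means individuals genuinely differ
in their rate of methylation change.

### The boundary-mixture test

$\sigma_b^2 = 0$ lies on the boundary of the parameter space, so the usual
$\chi^2_1$ null for the likelihood-ratio statistic is wrong: asymptotically
the statistic is 0 half the time and $\chi^2_1$ the other half. The package
therefore halves the $\chi^2_1$ tail probability (`lrt_mixture_p()`), which
maps a statistic of 0 to $p = 0.5$ and bounds every p-value by 0.5. Two
consequences worth internalizing:

* under the null, roughly half of all fitted probes should show a
  *numerically zero* statistic — this is a diagnostic, not a failure;
* the *mean* statistic under the null is 0.5 asymptotically, which is the
  reference the permutation calibration (`permutation_calibration()`) and
  the acceptance checks use.

At a few hundred individuals the boundary LRT is mildly conservative: on
null-simulated cohorts of 300 individuals with three waves, the suite
observes a mean statistic a few hundredths below 0.5 and slightly more than
50% zeros. The fitted likelihoods agree with an independent ML fitter
(`lme4`) to eight decimals on matched instances, so this is a property of
the finite-sample distribution, not of the optimizer.

### Fitting: profiled ML with blockwise algebra

All fits use maximum likelihood, not REML: the test compares nested models
with identical fixed effects and the halving rule presumes a genuine
likelihood ratio. Writing $\Gamma = \Omega / \sigma_e^2$, the per-individual
covariance is $V_i = \sigma_e^2 (I + Z_i \Gamma Z_i')$ with
$Z_i = [1, t_{ij}]$, and both the fixed effects and $\sigma_e^2$ profile
out in closed form. The optimizer works on the 1–3 free entries of
$\Gamma$ under box constraints (variance ratios in $[0, 10^8]$; the upper
cap pins degenerate fits where $\sigma_e^2 \to 0$ and the profile
likelihood would otherwise be unbounded). The Woodbury identity reduces
every quantity to $2 \times 2$ algebra per individual, implemented in
compiled code together with the analytic gradient of the profiled
likelihood (an envelope-theorem identity), so that genome-scale scans and
the simulation study run in minutes on one core.

Optimization is deterministic: three fixed starts (method-of-moments from
per-individual OLS lines, an equal variance split, and a near-null start
with the slope ratio at $10^{-4}$), convergence tolerance $10^{-10}$
relative, at most 500 iterations per start. A fit is reported converged
when the optimizer succeeds or when at least two independent starts agree
on the optimum (which covers boundary corners where `nlminb` reports
"false convergence" despite a well-identified maximum). Ties at the
boundary produce a statistic of exactly 0 after clipping at zero.

```{r}
d <- simulate_probe(n_individuals = 150,
                    ages = rep(list(c(-1.1, 0, 1.1)), 150),
                    u1 = 0, u2 = 0.2, sigma_a2 = 1, sigma_b2 = 0.4,
                    sigma_e2 = 0.5, seed = 7)
fit <- fit_slope_model(d$observations)
glance(fit)
```

### Predicted random slopes (BLUPs)

`predict_blups()` returns the conditional means
$(\hat a_i, \hat b_i) = \Omega Z_i' V_i^{-1}(y_i - X_i\hat u)$. These are
shrunken towards zero relative to per-individual OLS slopes — exactly so in
the balanced case — and coincide with the OLS slopes in the
$\sigma_e^2 \to 0$ limit. They are the dependent variable of the downstream
GWAS (`gwas_slope()`), matching the design in which a genome-wide scan is
run on each probe's predicted slopes.

## Preprocessing

The pipeline (`preprocess_meth()`) is fixed in order: clamp M-values to
$[-9.96, 9.96]$ (the M-values of beta 0.001 and 0.999), remove per-probe
outliers beyond 3 SD of the mean (mean and SD computed once, not
iteratively; removal operates on sample-observations, not whole
individuals), then residualize each probe on sex, age, cell counts and the
fixed batch factors with plate and array as random intercepts (ML fit via
`lme4`; both fixed estimates and predicted random effects are subtracted).
Age standardization for the slope model happens afterwards, per probe,
over the retained analysis set. Genotype QC (`filter_genotypes()`) removes
SNPs with MAF < 0.01, Hardy–Weinberg $\chi^2$ p < $10^{-6}$ (computed on
hard calls, i.e. rounded dosages — the test is not dosage-aware), or
missingness > 10%.

## Discovery, replication and calibration

`scan_probes()` fits every probe and returns a tidy table; a probe is
declared significant at the Bonferroni threshold `alpha / n_probes`
(`bonferroni_threshold()`). The replicated set ("rsCpGs") is defined by
`split_replicate()`: individuals are partitioned by their number of
observed timepoints (2–3 versus 4), each group is scanned separately with
age re-standardized within group, and probes passing the same Bonferroni
threshold in *both* groups replicate. Because the groups are disjoint
individuals, the expected number of replicated probes under the null is
essentially zero at genome-wide thresholds.

Supporting procedures:

* `bootstrap_corr_ci()` — percentile bootstrap (default 30,000 resamples)
  for the correlation between per-probe estimates from the two groups;
* `overlap_or_perm()` / `perm_enrichment()` — permutation nulls for
  overlap and annotation enrichment odds ratios, with the add-one
  correction so the smallest attainable p is $1/(B+1)$
  ($3.3\times10^{-5}$ at $B = 30{,}000$);
* `permutation_calibration()` — permutes the sample-level ages jointly
  across all probes (individual structure and observation counts intact)
  and refits, recording the mean statistic per round;
* `lambda_stats()` — inflation summaries. For the mixture LRT the raw mean
  statistic (null expectation 0.5) is the conventional "inflation value";
  the median-based lambda is computed on the non-zero statistics against
  the $\chi^2_1$ median 0.4549. For plain one-df GWAS statistics the
  standard genomic-control `median / 0.4549` applies.

## GWAS on predicted slopes, clumping, enrichment

`gwas_slope()` regresses BLUP slopes on dosage per SNP with no covariates
(the slopes are residualized upstream); monomorphic SNPs are skipped with a
message. Two significance tiers mirror the discovery design: genome-wide
$5\times10^{-8}$ and Bonferroni-over-probes $5\times10^{-8}/|\text{rsCpG}|$.
`clump()` greedily takes the smallest-p significant SNP as an index
(lexicographic `snp_id` tie-break, so output is order-invariant) and
absorbs significant same-chromosome SNPs within 1 Mb whose dosage $r^2$
*exceeds* 0.1 — equality keeps both. `classify_cis_trans()` uses
chromosome identity only.

Annotation enrichment treats probe positions as 1-based points against
0-based half-open BED intervals (a point $p$ is inside $[s, e)$ iff
$s \le p-1 < e$); each scheme (island relation, DMR classes) is tested as
its own family. Gene-set over-representation (`fisher_gene_set()`) is a
two-sided Fisher's exact test with Benjamini–Hochberg control across
classes, with `expected` and `fold` defined from the reference margins.
Nearest-gene assignment minimizes the absolute distance to the gene body
with ties broken by the smaller gene start.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes — it
is the test bed for every downstream stage, not a model of any real
cohort:

* 954 individuals by default, with 283/356/315 observing 2/3/4 waves
  (consecutive from wave 1, a dropout pattern), wave mean ages 70–79 with
  0.6-year within-wave jitter;
* per-probe parameters drawn uniformly from configurable ranges, with a
  configurable fraction of probes at exactly $\sigma_b^2 = 0$;
* additive Gaussian batch effects (plate, array, position, date, set) on
  the M-value scale — additivity is precisely what the residualization
  model assumes, so the generator and the preprocessing are a matched
  pair;
* sex and cell-count effects with per-probe coefficients; cell-count
  fractions carry N(0, 0.02) estimation noise so they do not sum exactly
  to one (exact compositional closure would make the fixed design
  rank-deficient, and reference-based cell-count estimates are noisy in
  practice);
* Hardy–Weinberg dosages at configurable MAFs on 22 synthetic 50-Mb
  chromosomes, with optional causal SNP effects added to the true slopes;
* a CpG-island track with shores (0–2 kb) and shelves (2–4 kb) for the
  enrichment machinery.

What it deliberately does not emulate: linkage disequilibrium between
SNPs (independent draws, unless a test constructs correlated pairs),
probe-probe correlation along the genome, non-Gaussian methylation noise,
and array chemistry. Green tests therefore demonstrate the statistical
machinery is correct under its own assumptions; they do not certify
robustness to, e.g., heavy-tailed noise or spatially correlated probes.

## The SNP-by-age simulation study

The study (`run_sim_study()`) compares three ways of detecting a SNP
effect on the methylation slope, generated as
$y_{ij} = (\beta_k d_{ik} + e_i)\,t_{ij} + e_{ij}$ with HWE dosages
($\mathrm{MAF} \sim U(0.05, 0.5)$), standard-normal $e_i$ and $e_{ij}$,
3000 individuals at three timepoints near ages 60/70/80 (0.5-year jitter;
an exact-ages option exists), and $t$ standardized:

1. regression of the mixed-model BLUP slope on dosage;
2. pooled OLS `y ~ dosage * t` ignoring the repeated measures;
3. the mixed model `y ~ dosage * t` with a per-individual random slope,
   Wald test on the interaction.

Age standardization before simulation matters: with three equally spaced
timepoints and unit-variance $t$, the per-individual sum
$\sum_j t_{ij}^2 \approx 3$, and the expected inflation of method 2's
statistic is $(\sum_j t_{ij}^2 + 1)/2 \approx 2$ — the median-based lambda
near 2 that the acceptance check reproduces. The flag `standardize_t`
exposes this choice because the inflation magnitude depends on the age
scale.

Method 3 has two readings. The default fits the random slope inside the
model. The alternative (`variant = "blup_covariate"`) plugs the predicted
slope times $t$ into OLS as a covariate; the suite shows this variant is
severely *conservative* under the null — the BLUP already absorbs the
dosage-driven slope component, leaving the interaction term nothing to
explain — which is why the mixed-model reading is the default. One SNP is
simulated per replicate; main effects are generated at zero but estimated
freely in methods 2–3.

```{r, eval = FALSE}
study <- run_sim_study(sim_study_config(beta_mode = "zero"),
                       n_reps = 10000, seed = 1)
study$summary
#> method 1 lambda_median ~ 0.99, method 2 ~ 2.0, method 3 ~ 0.99
```

## Numerical choices and limitations

* Tolerances: optimizer relative tolerance $10^{-10}$; LRT statistics
  below numerical zero are clipped; "zero statistic" means $< 10^{-8}$
  in calibration summaries ($< 10^{-5}$ in `lambda_stats()`, matching the
  coarser convention used for reported proportions).
* Problem sizes in the shipped checks: the simulation study runs 10,000
  replicates (larger runs, e.g. hundreds of thousands of replicates, are a
  configuration choice, not the default), the null calibration 5,000
  probes at 300 individuals and three waves.
* Degenerate inputs: monomorphic SNPs are skipped, single-level random
  factors demoted with a warning, rank-deficient fixed designs rejected
  with the collinear columns named, individuals with a single observation
  dropped per probe.
* Known limitations: no kinship/mixed-model GWAS; the HWE filter is not
  dosage-aware; probes are modelled independently (no spatial smoothing or
  cross-probe correlation); BLUP-based GWAS inherits shrinkage, so
  effect-size estimates on slopes are attenuated relative to the
  generative scale even when the test is well calibrated.
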