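---
title: "Methods: mammogram risk scores, polygenic scores, and the twin-family mixed model"
author: "mammotwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mammogram risk scores, polygenic scores, and the twin-family mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammotwin)
```

## The scientific setting

Mammographic density — the white or bright area on a mammogram — predicts
breast cancer risk. Defining "dense" at increasing pixel-brightness
thresholds gives a nested family of measures: the conventional dense area
(Cumulus), the bright area (Altocumulus), and the brightest area
(Cirrocumulus), plus two composites, percent density (dense area over
total breast area) and the "white but not bright" area (Cumulus minus
Altocumulus). Converting a measure into a **mammogram risk score (MRS)** —
the standardized residual of its normality-transformed value after
adjustment for age and inverse BMI — yields a quantitative risk factor
that aggregates in families: MZ twin pairs correlate around 0.6 and DZ
twin and sister pairs around 0.3 on the bright-area score, consistent with
additive genetic factors explaining about 60% of its variance.

`mammotwin` implements the analysis that asks how much of this genetic
component is captured by the known common breast-cancer variants: compute
a **polygenic risk score (PRS)** as a weighted sum of effect-allele
dosages over ~313 SNPs (with weights for overall, ER− and ER+ disease),
then estimate the correlations and mixed-model associations between the
five MRSs and the three PRSs in a twin/sister cohort, compare their
evidence by BIC, re-estimate each association adjusting for the other
MRSs, and screen ~200 individual risk SNPs. Because the underlying
mammograms and genotypes are not redistributable, the package ships a
synthetic-cohort generator that reproduces the relevant statistical
structure, so every stage runs end to end with no external data.

## The synthetic cohort: what it emulates

`simulate_pedigrees()` builds the study's design: MZ and DZ twin pairs
(who share their age) and non-twin sisters grouped into families of 1–3,
with age ~ N(54, 8.4) truncated to [30, 80] and BMI ~ N(26.1, 5.2) —
the published sample's moments. Sister ages scatter around a family mean
with SD 5 years; the study does not report how sisters' ages co-vary, so
this is a modeling default, not a claim about the data.

`simulate_genotypes()` uses explicit parental-gamete simulation: each
family gets two unobserved parents with alleles drawn at the SNP's
frequency, and every child receives one allele from each parent. A single
mechanism therefore yields both MZ genotype identity (one meiosis,
copied) and the DZ/sister identity-by-descent expectation of one half —
which the tests verify against a brute-force enumeration of parental
configurations.

`simulate_density()` treats each transformed density measure as an
additive polygenic trait

$$t = \beta_{age}\,\mathrm{age} + \beta_{1/BMI}\,\mathrm{BMI}^{-1} +
  \gamma\,\mathrm{PRS}^{std} + A + C + E,$$

with $A = A_{family} + A_{seg}$ split half-and-half so that MZ pairs
(who share both parts) correlate $a^2$ and DZ/sister pairs (who share
only $A_{family}$) correlate $a^2/2$, plus a family-shared $C$ and
individual $E$. Defaults are $a^2 = 0.6$, $c^2 = 0$ — the bright-area
twin-model estimates, giving MZ ≈ 0.6 and DZ/sister ≈ 0.3. The PRS
effect $\gamma$ can be a single number or per-measure (so a signal can
be injected into the bright-area trait only, which is how the
mutual-adjustment pattern is exercised).

Across measures, the latents form a **nesting chain** mirroring the
physical containment brightest ⊂ bright ⊂ dense area: each measure's
latent is `measure_cor` (default 0.7) times its parent's latent plus an
independent familial-plus-unique remainder with the same
$a^2/c^2/e^2$ decomposition. Every measure then has exactly the
specified familial correlations, adjacent measures correlate
`measure_cor`, and — crucially — a polygenic effect placed on the
bright-area trait propagates into the dense area scaled by
`measure_cor` and is *fully mediated*: adjusting the dense-area score
for the bright-area score leaves a null (z ~ N(0, 1)) partial
association, reproducing the attenuation-to-null pattern the analysis
is designed to exhibit. (A symmetric construction that shares the
familial component across measures but adds the PRS per measure cannot
do this: conditioning on the bright-area score then opens a collider
path through the shared familial component and produces a spurious
negative partial association — we verified this analytically and by
simulation, and chose the chain for that reason.)

Raw measures are produced by inverting the transformations the analysis
will later select: dense areas are cubes of Gaussian latents, the
brightest area is the exponential of its latent, and total area is
implied by a squared-Gaussian percent-density latent. Location/scale
constants put medians near published magnitudes (Cumulus ≈ 29 cm²,
Altocumulus ≈ 11 cm², Cirrocumulus ≈ 1.6 cm², percent ≈ 30%); they
shape Table-1-style summaries only and carry no inferential weight.
Nesting (Cirrocumulus ≤ Altocumulus ≤ Cumulus ≤ total area) is enforced
by clipping, and areas are floored at a configurable 0.05 cm²; at the
default parameters clipping touches a handful of observations per
thousand, which leaves the calibration checks unaffected.

What the generator does **not** emulate: mammogram images and measurer
variability, linkage disequilibrium between SNPs (SNPs are independent),
population stratification, X-chromosome variants, and case–control
outcomes. A green test therefore establishes that the estimators are
correct and calibrated under the stated family structure — not that any
particular published estimate is reproduced, which would require the
original data.

## Risk-score construction

`boxcox_select()` maximizes the Box–Cox profile log-likelihood over the
interpretable grid {−1, −1/2, 0, 1/3, 1/2, 1}, because reportable named
powers (cube root, square root, log) are the point; a `continuous` flag
polishes to the unrestricted MLE instead. Zeros (possible for the
brightest and white areas) are handled by adding half the smallest
positive value of the column — the source analysis is silent here, and
the offset is recorded in the fit metadata. `compute_mrs()` then
regresses the transformed measure on age and 1/BMI by OLS over the whole
estimation sample and standardizes the residuals with the $n-1$ SD;
women with missing BMI are excluded from estimation and flagged. At the
study's size the grid selection recovers the generating power essentially
always (the acceptance suite requires ≥ 95% over 100 replicates).

`compute_prs()` is the weighted dosage sum $\sum_i \beta_i X_{ij}$ with
allele-orientation flips ($X \to 2-X$) where the panel counts the other
allele, mean-imputation of missing dosages to twice the allele frequency,
and a configurable drop of strand-ambiguous SNPs. Genotype QC
(`qc_filter()`) applies sample filters (call rate < 95%, heterozygosity
beyond 4.89 SD) before SNP filters (call rate < 95%, Hardy–Weinberg exact
p < 1e−7, MAF < 0.01) in that order — the order matters for the counts
and is recorded in the report. Because published PRS weight files include
SNPs rarer than a cohort-level MAF floor, weight-file SNPs can be
exempted from the MAF filter; the exemption is logged. The
Hardy–Weinberg test is the exact conditional test on heterozygote counts;
fractional dosages are hard-called at 0.5/1.5 for QC statistics only.

## The family mixed model

The association model is

$$y = X\beta + u_{family} + u_{zyg} + e,$$

where $u_{family}$ is shared by all members of a family
($\sigma^2_f$) and $u_{zyg}$ is a **zygosity-group** intercept
($\sigma^2_z$): the group is the MZ pair for MZ co-twins and the
individual otherwise. This is the standard twin coding
(`(1|family) + (1|pair-or-individual)` in lme4 terms). MZ covariance
$\sigma^2_f + \sigma^2_z$ exceeds DZ/sister covariance $\sigma^2_f$
while **marginal variances stay equal across zygosity** — a deliberate
design choice: placing $\sigma^2_z$ only inside MZ blocks (the other
reading of "family and zygosity as random effects") makes MZ women more
variable than their sisters, and under an equal-variance generative
world that model cannot recover the MZ ≈ 0.6 / DZ ≈ 0.3 intraclass
correlations (we verified the misspecified fit converges near 0.47/0.33).

Estimation is REML from scratch: components are log-parameterized and
optimized by L-BFGS-B with a small finite-difference step, followed by
an unconditional Nelder–Mead polish (numeric-gradient quasi-Newton
methods can stall or fail their line search on the nearly-flat
directions of this profile surface; the derivative-free polish from the
best point is cheap insurance and is verified against a grid oracle and
lme4 in the tests), with two exact ingredients that make the fit robust
and fast. First, families fall into a handful of covariance
patterns (MZ pair, DZ pair, sister families by size), so each likelihood
evaluation inverts each distinct block once and accumulates the GLS
quadratics pattern-wise — thousands of families cost a few matrix
products. Second, after convergence the overall scale is polished in
closed form ($s = r'V_0^{-1}r/(n-p)$ along $V = sV_0$), which makes the
all-singleton case collapse to OLS to machine precision. Components with
no design information (no MZ pairs; no multi-member families) are fixed
at zero. Fixed effects are GLS at the optimum with Wald normal
inference — no small-sample correction, since intended cohorts have
thousands of women. The tests cross-check coefficients, SEs, variance
components and the REML log-likelihood against `lme4::lmer` and a coarse
grid search.

**BIC** uses the maximum-likelihood log-likelihood evaluated at the REML
components, with $n$ = individuals and parameter count = fixed effects
+ 3 components. Comparisons are only ever made across models of the same
dimension fitted to the same outcome, where both conventions cancel; ML
avoids REML's dependence of the constant on the fixed-effects basis.
On singleton cohorts the reported ML log-likelihood equals the OLS
Gaussian log-likelihood at the REML $\hat\sigma^2$ (not `logLik.lm`'s
$\mathrm{RSS}/n$ plug-in); the oracle test accounts for this. BIC
differences are labeled by the customary grades (< 2 negligible, 2–6
positive, 6–10 strong, ≥ 10 very strong; the half-open-interval
convention is ours).

**Correlations** (`family_corr()`) report the ordinary Pearson estimate
with a percentile bootstrap CI resampling whole families, preserving
within-family dependence. Whether the source analysis accounted for
clustering in its correlation p-values is unstated, so both a
family-clustered Fisher-z p (effective n = number of families) and the
naive version are returned. Table-2-style BICs come from the
one-predictor mixed model without PC covariates; Table-3-style
associations add the first 10 genotype principal components as fixed
effects and are reported per adjusted SD of the PRS (`opera_scale()`:
the coefficient times the SD of the predictor's OLS residuals on the
covariates — scale-invariant in the predictor's units, p-value
unchanged).

## The association pipeline

`run_prs_analysis()` produces the 15-cell correlation and association
grids with per-endpoint minimum-BIC flags; `run_mutual_adjustment()`
refits each association with the other risk scores as fixed effects and
reports attenuation $100(\beta_{unadj} - \beta_{adj})/\beta_{unadj}$;
`run_snp_screen()` fits the per-SNP dosage models, Bonferroni-adjusts by
the number of SNPs actually tested (monomorphic SNPs are skipped and
excluded), counts direction-consistent nominal hits (expected direction
defaults to positive for all five scores, configurable), and computes the
excess-significance one-sided binomial tail $P(K \ge k_{obs})$,
$K \sim \mathrm{Bin}(n_{tests}, \alpha)$. That binomial treats SNPs as
independent; for panels with fine-mapped variants in linkage
disequilibrium it is anti-conservative, as flagged in the function
documentation. Bonferroni (not Holm) matches the source convention.

## Numerical choices and test scaling

- Optimizer bounds span 30 log-units below the outcome variance; random
  effect variances within a factor ~2 of the floor are snapped to exact
  zero, the residual never is (blocks stay positive definite).
- Multi-start is used only on non-convergence; fits are deterministic.
- The acceptance suite scales two long simulations to fit a routine test
  run without changing what they establish: CI coverage of an induced
  r = 0.08 uses 200 replicates with a 50-SNP panel and 200 bootstrap
  draws (the induced correlation is defined on the standardized score,
  so panel size is irrelevant); null calibration checks (a) mixed-model
  p-value uniformity over 400 replicates at a reduced cohort size
  (uniformity holds at any n) and (b) the excess-significance test's
  rejection rate on uniform p-values directly, which composes with (a)
  in place of 500 full screens.

## Known limitations

- Independence of synthetic SNPs means LD-driven behavior of the screen
  (correlated tests, fine-mapped clusters) is untested here.
- The variance-components model assumes Gaussian outcomes; MRSs are
  standardized residuals of normality-transformed measures, which makes
  this reasonable but not guaranteed for real data.
- The percentile bootstrap CI is first-order; for very small family
  counts a BCa or studentized interval would be preferable.
- Heritability-style decompositions (full ACE/ADE structural models) are
  out of scope; the package estimates association, not causation.
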