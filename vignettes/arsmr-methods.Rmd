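---
title: "Methods: arsenic-metabolism Mendelian randomization with arsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arsenic-metabolism Mendelian randomization with arsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsmr)
```

## The scientific problem

People metabolize ingested inorganic arsenic (iAs) by successive
methylation to monomethylarsenate (MMA) and dimethylarsinate (DMA). The
relative percentages of the three species in urine — %iAs, %MMA, %DMA,
which sum to 100 — index metabolism efficiency: high %DMA marks efficient
methylators, high %iAs/%MMA inefficient ones. Inefficient metabolism is a
suspected risk factor for pulmonary dysfunction in populations whose
arsenic exposure comes from diet, chiefly rice. In a cohort where urinary
arsenic was never measured but genotypes are available, the effect of
metabolism efficiency on asthma and spirometry traits can still be
estimated by **two-sample Mendelian randomization (MR)**: variant →
metabolite effects taken from published GWAS of urinary arsenic species
are combined with variant → trait effects estimated in the target cohort,
using the genotype as an instrumental variable.

`arsmr` implements that pipeline end to end: a three-variant literature
instrument (rs9527 and rs11191527 near *AS3MT*, rs61735836 in *FTCD*),
phenotyping rules (smoking strata, asthma categories, spirometry
lower-limit-of-normal thresholds, medication correction, rice-exposure
classification), mixed-model genetic association with kinship, household
and census-block-group random effects, and a correlated-instrument
principal-components IVW estimator. Because the motivating cohort is
access-restricted, the package ships a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, so every stage
is testable.

## The MR estimator

For $J$ variants with exposure effects $\beta_X$ (percentage points of a
urinary metabolite per effect-allele copy), outcome effects $\beta_Y$
(log-odds per copy) with standard errors $\sigma_Y$, and signed LD matrix
$\rho$, the estimator forms

$$\Psi_{kl} = \beta_{Xk}\,\beta_{Xl}\,\rho_{kl}\,/\,(\sigma_{Yk}\sigma_{Yl}),$$

eigen-decomposes $\Psi$, and retains the smallest $k$ components whose
cumulative eigenvalue share reaches a threshold (default 0.99, a config
parameter; no published retention threshold exists for this instrument,
so the eigen report is always returned for audit). With $W$ the retained eigenvectors,
$b_X = W^\top\beta_X$, $b_Y = W^\top\beta_Y$ and
$\Omega = W^\top \Sigma W$ where $\Sigma_{kl} =
\sigma_{Yk}\sigma_{Yl}\rho_{kl}$,

$$\hat\theta = (b_X^\top \Omega^{-1} b_X)^{-1} b_X^\top \Omega^{-1} b_Y,
\qquad \mathrm{se}(\hat\theta) = (b_X^\top \Omega^{-1} b_X)^{-1/2}.$$

$\hat\theta$ is the causal log-odds per percentage point of the
metabolite; `exp(theta)` is reported with a 1.96-multiplier normal CI and
two-sided normal p-value, and no multiplicity adjustment. Exposure-side
standard errors are ignored in the point estimator (the standard
two-sample NOME convention); they are retained in the instrument table.
Three analytic fixed points pin the implementation: one variant gives the
Wald ratio $\beta_Y/\beta_X$; $\rho = I$ at full retention gives textbook
IVW; full retention on any nonsingular input equals the full-rank GLS
oracle `gls_ivw_oracle()`, which is kept as an independent reference
implementation rather than being collapsed into the main path.

A modelling commitment worth making explicit: published GWAS effect sizes
are **marginal** single-variant estimates, and the correlated-instrument
GLS form is consistent exactly when both $\beta_X$ and $\beta_Y$ are
marginal. The synthetic generator therefore solves joint coefficients
$\gamma = C^{-1} D\,\beta$ (with $C$ the expected dosage covariance and
$D$ its diagonal) so that per-variant regressions of %iAs on dosage
reproduce the published betas. Treating the published betas as joint
coefficients instead biases the recovered causal effect by roughly the
amount of LD leakage (~8% for this instrument).

## The association model

Within each stratum, each variant is tested against each trait with a
mixed model whose random effects carry three covariance kernels, all
supplied with unit diagonal: kinship (0.5 for declared full-sibling
pairs), household (same-household indicator) and block group
(same-block-group indicator). Fixed effects are the intercept, the top
five genetic principal components, ancestry-group indicators and the log
of the sampling weight — the weights enter *only* as this covariate,
never as analytic weights. Ancestry fixed effects are refit per stratum
(the alternative, a global fit, is not distinguishable from the
paper-level description; refitting is the conservative choice and is
logged here). Dosages are used as-is, without hard-calling, since two of
the three instrument variants are imputed in the motivating design.

All three kernels are block-diagonal with respect to block group, so
every REML quantity is accumulated block by block; consecutive small
blocks are coalesced into ~64-row superblocks, which changes nothing
numerically (kernels are zero across block groups) and keeps the R-level
loop short. Gaussian traits use REML with analytic gradients under
L-BFGS-B, variance components constrained nonnegative by boundary
projection; a component pinned at zero raises a flag, not an error.
Binary traits use penalized quasi-likelihood: iterate the linearized
working response $z = \eta + (y-\mu)/w$ with $w = \mu(1-\mu)$, estimate
variance components by REML on $z$ with unit dispersion, and update
$\eta$ including the BLUPs until the fit stabilizes. The Wald test of a
variant re-iterates the working response with the dosage *in* the design,
holding the variance components at their null estimates — without this,
per-allele effects of the size this instrument produces (up to ~0.9 on
the log-odds scale under the calibration scenario) would be visibly
attenuated by the null-model linearization. PQL still attenuates
conditional effects slightly (about 4% at the default cluster variances);
this is visible in the parameter-recovery acceptance test as a mean OR of
~1.38 against a generative 1.40, well inside the stated band.

## Phenotyping rules

* **Smoking**: never-smokers reported fewer than 100 lifetime cigarettes;
  former smokers count as ever-smokers; non-responders are excluded.
* **Asthma**: lifetime asthma requires self-report *and* doctor
  diagnosis (the broadened sensitivity definition drops the diagnosis
  requirement); current asthma requires still having asthma or
  anti-asthmatic medication use in the last year; past is the remainder
  of lifetime; missingness propagates to a `missing` category so the four
  categories always partition the cohort.
* **Medication correction**: measured FEV1 and FVC of medicated
  participants are multiplied by 0.88 (an attenuated literature estimate;
  a config constant). Sensitivity modes keep volumes and add the
  indicator as a confounder, or exclude medicated rows. Scaling both
  volumes by the same factor leaves FEV1/FVC invariant by construction.
* **Spirometry inclusion**: maximal effort and FVC quality A/B/C; the
  strict sensitivity mode drops C.
* **LLN**: the lower limit of normal is the 5th percentile of the
  measure's normal reference distribution in the participant's stratum of
  ethnic background × sex × age band × height band. The published
  reference equations for this population are restricted, so the package
  substitutes a transparent parametric reference model (a TSV of
  location/scale per stratum and measure; `default_reference_model()`
  builds a synthetic one with adult-population magnitudes). The
  5th-percentile construction — the scientifically load-bearing part — is
  preserved exactly. Below-LLN uses strict inequality; a value exactly at
  the threshold is normal (ties have probability zero for continuous
  measures, and strict is the conservative direction).
* **Rice exposure**: participants strictly above the 80th percentile
  (linear-interpolation quantile; the estimator is not pinned upstream,
  so the realized cutoff is logged) of summed grain servings over two
  diet recalls are "high inferred consumers of rice". The cutoff is
  computed on the post-exclusion analysis sample — whether it was
  computed before or after exclusions upstream is not stated, so the
  choice is logged in the run report.

## What the synthetic cohort emulates — and what it does not

The generator's stated world: three dosages with the published LD between
the chromosome-10 pair (D′ = 0.87, r² = 0.28; since D′ and the two allele
frequencies determine r², the second frequency is *solved* from the first
— default 0.45, giving 0.2323 — rather than chosen independently);
metabolite percentages that sum to 100 exactly (bivariate normal noise on
%iAs and %MMA, sd 3.5 pp, correlation 0.3 — a placeholder, as no
within-person noise correlation is published — with %DMA by closure and
boundary violations resampled); households of size 1–4 nested in ~40-
household block groups with a fraction of sibling pairs; smoking, diet
and asthma questionnaires with optional completely-at-random
non-response; and spirometry drawn from the reference model by inverse-
CDF conditioning on latent below-LLN indicators, so that a flag's
generative log-odds are exactly the configured ones. Binary-trait
log-odds are `baseline + theta * (genetic %iAs score) + cluster effects`,
with `theta` forced to zero outside the high-rice stratum — the low-rice
stratum is a negative control *by construction*, mirroring the design's
logic that genotype should carry no risk absent exposure.

Two generator choices deserve their rationale spelled out. First, the
causal channel defaults to the genetically driven component of %iAs
rather than the noisy phenotype: a spot-urine measurement is a noisy
proxy of long-run metabolism efficiency, and routing the causal effect
through ~3.5 pp of idiosyncratic noise would, by logistic
non-collapsibility, shrink the estimable marginal effect ~25% below the
generative `theta`, making "the estimator recovers the configured effect"
an impossible statement for any estimator. The phenotype channel remains
available (`causal_channel = "phenotype"`). Second, metabolite means
(13, 14) and sd 3.5 keep simplex-boundary resampling mass near 10⁻³;
larger noise makes the mandated resampling bend the linear model enough
to shift marginal dosage slopes by several Monte-Carlo standard errors.

What a green test does **not** establish: the generator has no
survey-design two-stage sampling (weights are a simulated covariate, not
a design feature), no ancestry-specific LD or genome-wide background, no
real dietary measurement-error structure (high/low rice is nearly
noiseless by construction), gaussian rather than skewed metabolite noise,
and an FEV1 whose below-LLN status is emergent (FEV1 = FVC × ratio / 100,
guaranteeing FEV1 ≤ FVC) rather than directly controlled. Green
acceptance tests certify the estimator and plumbing under the stated
world, not the epidemiology of any real cohort — the motivating study's
odds ratios are not reproduction targets here.

## Numerical choices and degenerate inputs

Variance components are optimized on the natural scale with lower bound
zero; REML convergence tolerance is L-BFGS-B's `factr = 1e9`; PQL outer
iterations stop at a 1e-4 relative change in the linear predictor (max
20) and raise a classed convergence error with the last change if they
fail by a factor of ten. Monomorphic dosages, constant traits,
zero-variance LD columns, unresolvable reference strata, dangling sibling
references, infeasible (MAF, D′) combinations and simplex-resampling
exhaustion all raise classed errors (`arsmr_degenerate_error`,
`arsmr_feasibility_error`, ...) so the pipeline can error-code individual
report cells instead of dying. Eigenvector signs follow a deterministic
convention (largest-magnitude element positive) so component selection is
reproducible; PC retention uses a 1e-12 slack on the cumulative-share
comparison so `threshold = 1` retains all components under floating-point
rounding.

## Reproducibility

Every run takes a single master seed; stage seeds are derived from it and
kept below 2³¹. The run report carries a rolling-hash fingerprint of the
estimates, ledgers and realized cutoffs; the same config and seed
reproduce it byte-for-byte, and the truth record round-trips through its
JSON file byte-identically. The exclusion ledger is conserved by
construction (input n = final n + removals, tracked separately for the
asthma and spirometry arms).

## Known limitations

For binary traits the pipeline's causal estimates are mildly
conservative by construction: each per-variant marginal logistic test
omits the other variants' causal contribution and residual cluster
heterogeneity, and logistic effects do not collapse over omitted latent
variance, so the recovered log-odds per percentage point sits ~4–6%
below the generative value (visible in the parameter-recovery test as a
mean OR of ~1.37 for a generative 1.40). Because this bias does not
shrink with sample size while the standard error does, confidence-
interval coverage of the *generative* parameter degrades as n grows —
at n = 5000 per stratum it plateaus near 89% rather than 95% — even
though coverage of the estimator's own large-sample target stays
nominal. The plain GLS-IVW standard error also ignores the small
between-variant heterogeneity these attenuation factors induce. Both
effects are inherent to marginal per-variant logistic summary statistics
(real two-sample MR of binary outcomes shares them) and are documented
rather than corrected.

PQL's small attenuation of conditional log-odds effects is likewise
documented rather than corrected; no pleiotropy-robust estimators (MR-Egger,
weighted median) are provided; instrument-strength diagnostics beyond the
eigen report are out of scope; the minimal VCF reader only round-trips
this package's own three-site DS/GT output.
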