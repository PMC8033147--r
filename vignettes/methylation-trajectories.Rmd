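---
title: "Modelling longitudinal DNA methylation trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal DNA methylation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Blood DNA methylation at a CpG site, measured as a beta value (the
proportion of methylated signal, in [0, 1]), changes through childhood.
With repeated measures per child one can separate three things that
cross-sectional designs confound: the average change with age, the
child-to-child variation in that change, and non-linearity — slope changes
around school age and around the transition into adolescence. methtraj
implements this analysis for a two-cohort design in which one cohort is
sampled near birth, 6 and 10 years and the other near birth, 7.5 and 17
years, so that jointly the data cover birth to late adolescence even
though neither cohort does alone.

## The models

All models are Gaussian linear mixed models fitted per CpG by maximum
likelihood. With children $i$, visits $j$ and sample plates $k$:

**M1 (linear change)**
$$M_{ijk} = \beta_0 + u_{0i} + (\beta_1 + u_{1i})\,\mathrm{Age}_{ij}
          + u_{0k} + \mathbf{x}_{ij}^\top\boldsymbol\gamma + \epsilon_{ijk}$$

**M2 (piecewise change)** adds slope changes at the knots $\kappa_1 = 6$
and $\kappa_2 = 9$ years through truncated age terms
$(\mathrm{Age}-\kappa)^+ = \max(\mathrm{Age}-\kappa, 0)$, each with a
fixed coefficient ($\beta_2$, $\beta_3$) and a child-level random slope
($u_{2i}$, $u_{3i}$). $\beta_2$ is the change in annual slope at age 6
after accounting for the birth-onward slope; $\beta_3$ likewise at 9.

**M3 (sex-specific change)** is M1 plus a sex main effect and a
sex-by-age interaction.

All random effects are mutually uncorrelated (diagonal random-effects
covariance — the identification choice this design needs, since a child
contributes at most three or four visits), and the plate intercept is
crossed with children. Covariates $\mathbf{x}_{ij}$ are sex, cohort,
z-scored gestational age and five z-scored white-blood-cell fractions;
granulocytes, the largest fraction, are dropped because the six fractions
sum to one and would otherwise be collinear.

## Estimation and testing

The fitter profiles the fixed effects and the residual variance out of
the marginal likelihood and maximizes the profiled deviance numerically
over the log variance ratios $\log(\sigma^2_c/\sigma^2_\epsilon)$
(Nelder–Mead, relative tolerance 1e-8, followed by a BFGS polish and — when
a ratio collapses below $e^{-20}$ — a boundary-collapse re-optimization of
the remaining free ratios, which keeps nested-model likelihood
monotonicity tight). Variances are floored rather than allowed to fail,
so boundary-zero estimates come back as vanishing values with
`converged = TRUE`; genuine optimizer stalls return `converged = FALSE`
and are excluded from summaries with counts reported.

The linear algebra exploits the design rather than using a generic
solver: without the plate term the marginal covariance is block-diagonal
by child and each block inverts through an $r\times r$ core ($r \le 4$
random terms), so all children are processed simultaneously with
vectorized small-matrix Cholesky factorizations; the crossed plate
intercept is then folded in by a Woodbury correction in plate space. A
sparse-matrix reference implementation of the same likelihood is kept
internally and the test-suite checks the two agree to 1e-9; fits are also
cross-checked against lme4's maximum-likelihood estimates.

Fixed effects are tested with two-sided z-tests (no Satterthwaite or
Kenward–Roger correction — with hundreds of children the normal reference
is accurate, and this matches the convention for large epigenome-wide
runs). Random slope variances are tested by refitting without the term
and comparing likelihoods against $\chi^2_1$; testing a variance on its
boundary makes this conservative, which the package documents rather than
corrects. Per-segment slopes (birth–6, 6–9, 9–18) are the contrasts
$\beta_1$, $\beta_1+\beta_2$, $\beta_1+\beta_2+\beta_3$ with standard
errors from the fixed-effect covariance.

## Trajectory classification

Each segment is labelled Positive/Negative when its slope is significant
at the chosen threshold (sign-directed), else Neutral. A segment that
continues the direction of the preceding non-Neutral segment is upgraded
to "More"/"Less" of that direction when the corresponding slope-change
coefficient is itself significant. Consecutive identical states collapse,
so a CpG that rises to age 6 and then flattens is "Positive-Neutral". The
default threshold is the genome-wide Bonferroni value 1e-7; desk-scale
runs should pass `bonferroni_threshold(0.05, m)` for their own panel size
— an honest small-m calibration rather than an impossibly strict one.
Whether the published analysis thresholded the segment contrasts or the
slope-change coefficients directly is not recoverable from its
description; both p-values are emitted so either convention can be
applied.

## Variance partitioning

`variance_partition()` expresses each estimated component (child
intercept, each random slope, plate, residual) as a percentage of their
raw sum. Slope variances are per year² while intercept, plate and
residual variances are in squared beta units, so the raw sum mixes units;
the conventional summary for these models does exactly that, and the
function documents the caveat instead of silently rescaling.

## The synthetic cohort generator

`simulate_cohort()` draws, per child: sex, gestational age
(N(39.7, 1.5²) weeks), leukocyte fractions (Dirichlet around typical
whole-blood composition: 55% granulocytes, 15% CD4+ T, 9% monocytes, 8%
CD8+ T, 8% B, 5% NK), visit ages (cohort A: 0, 6.0 ± 0.5, 9.8 ± 0.3
years; cohort B: 0, 7.5 ± 0.2, 17.1 ± 1.0) and per-visit attendance
(defaults 0.60/0.55/0.55 for A and 0.95/0.95/0.93 for B, chosen so the
expected samples-per-child ratios match the published cohort totals of
2333 samples/1399 children and 2686/949). Plates fill in order of 96
samples within cohort. Beta values come from the M2 linear predictor
plus Gaussian noise, truncated to [0, 1] with truncation counted, because
truncation biases variance recovery near the boundaries. Default variance
components are realistic for array methylation: child intercept 1e-3
(SD ≈ 3%), age slope 1e-6 (SD 1e-3/yr), plate 1e-4, residual 2.5e-4.

What the generator does **not** emulate: probe-level intensities and
normalization artifacts, cross-reactive probes, cell-composition drift
with age, non-Gaussian heavy tails, and cord-versus-peripheral-blood
tissue differences at the birth visit. Passing tests therefore show the
statistical machinery is correct under the model's own assumptions, not
that real data meet those assumptions.

The archetype panel (`simulate_trajectory_panel()`) generates one CpG per
qualitative trajectory with a base slope of 5e-3 per year — in the upper
range of observed annual changes (the most extreme published slopes are
several-fold larger) — calibrated so each generating label is recovered
with probability ≥ 0.95 at the panel's Bonferroni threshold under the
default design. Slope random effects are off in the panel so
classification power reflects the fixed shapes.

## Stability analysis choices

Concordance between the two early visits is computed on residuals of a
per-cohort OLS fit on sex, gestational age, cell fractions and plate
(plate as a categorical fixed effect — a per-time-point residualization
cannot carry the longitudinal model's random plate term, and the fixed
analogue is the closest deterministic equivalent). Age within a visit is
excluded from the residualization by default (within a visit it varies
little and the change analysis handles it explicitly); `include_age`
makes it available. The ICC is the one-way random-effects,
single-measurement form $(MS_B - MS_W)/(MS_B + MS_W)$ for $k = 2$
visits. Agreement across cohorts uses Spearman correlation for the
concordance quantities (not normally distributed) and Pearson for the
change estimates.

## Enrichment choices

The chi-square test of unequal proportions is Pearson's test without
continuity correction — at the table sizes of genome-scale enrichment the
correction is immaterial, and the uncorrected statistic is the
"unequal proportions" convention. Fisher's exact p is the two-sided
probability-mass rule (sum of tables no more probable than the observed
one), the common convention, documented because other two-sided rules
exist; the reported odds ratio is the sample odds ratio, not the
conditional-MLE value. The enrichment grid clusters rows and columns by
average-linkage hierarchical clustering of Euclidean distances on
$-\log_{10} p$ capped at 50, so underflowing p-values cannot create
infinite distances.

## Problem sizes used by the checks

The packaged experiments run at desk scale, chosen to make the
statistical properties measurable with stable rates: parameter recovery
uses 200 CpGs over 500 children with full attendance (truth
$\beta_1 = 10^{-3}$, $\sigma^2_{0i} = 10^{-3}$,
$\sigma^2_\epsilon = 2.5\times10^{-4}$); null calibration uses 500 null
CpGs over 200 children; the classification check uses the 8-archetype
panel at the default two-cohort design; the analysis scripts run 60 CpGs
over 550 children. Genome-scale runs simply loop the same per-CpG
machinery over more rows; the per-design pre-computation is shared across
CpGs for exactly that reason.

## Known limitations

- No REML (maximum likelihood only, as the analysis convention for
  comparing nested models requires); variance estimates carry the usual
  small-sample ML bias, visible as Wald coverage slightly below nominal.
- No correlated random effects and no non-Gaussian response.
- The LRT for variance components is conservative at the boundary.
- Beta values are modelled directly on the proportion scale; no logit
  transform. Truncation of the generator is counted but not corrected.
- A single genome-wide Bonferroni threshold is the only multiplicity
  control offered.
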