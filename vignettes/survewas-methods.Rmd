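---
title: "Methods: epigenome-wide survival meta-analysis with survewas"
author: "survewas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenome-wide survival meta-analysis with survewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`survewas` implements the statistical core of a consortium-style
epigenome-wide association study (EWAS) of blood DNA methylation and
all-cause mortality: per-CpG Cox proportional-hazards screening within
cohorts, consortium probe quality control, inverse-variance-weighted (IVW)
fixed-effects meta-analysis with multiplicity control and heterogeneity /
inflation / sensitivity diagnostics, and the downstream layers such studies
attach — Miettinen's population attributable fraction, two-sample Mendelian
randomization (MR), reference-based leukocyte deconvolution with
neutrophil-lymphocyte-ratio (NLR) models, meQTL/eQTM integration,
genomic-feature enrichment, and epigenetic-clock scoring.  Because real
consortium data are access-restricted, the package ships a first-class
synthetic-data generator that emulates the statistical structure those
analyses assume, and every stage is exercised end-to-end on it.

# The survival model

Within each cohort, for each CpG $j$ the model is a Cox proportional-hazards
regression

$$ h_i(t) = h_0(t)\, \exp\{\beta_j \,\mathrm{meth}_{ij} + \gamma' z_i\}, $$

where $\mathrm{meth}_{ij} \in [0,1]$ is the methylation beta value and
$z_i$ the adjustment set.  Two covariate sets are supported: *basic* (age in
decade categories with the youngest observed decade as reference, sex, and
technical plate/chip/row/column factors) and *full* (additionally education,
recreational physical activity, smoking status, pack-years, BMI, alcohol,
hypertension, diabetes, cancer and coronary-heart-disease history).
Estimated leukocyte proportions always enter as covariates; one fraction
(the largest-mean, in blood the granulocytes) is dropped to break the
sum-to-one collinearity, which the likelihood cannot otherwise identify.
$\beta_j$ is the log hazard ratio per +1.0 beta; results are reported as
HR per 10% methylation, $\exp(0.1\beta_j)$.

Numerical policy: Efron tie handling by default (Breslow available); fits
are declared non-converged — never raised as errors — when the partial
likelihood cannot be maximized, methylation is constant, fewer than two
events are available, exact collinearity leaves undetermined coefficients,
or $|\hat\beta| > 50$ (a divergence bound mirroring the exclusion of
non-converging results at the consortium level).  Sparse nuisance factor
levels whose own coefficients diverge do not invalidate a fit; convergence
is judged on the methylation coefficient.

Cohorts with fewer than 50 deaths use a *two-step residual* variant (the
practice of the smallest cohorts in such consortia): covariates are first
regressed out of each probe by OLS and the Cox model is then fit on the
residual alone.  The open design question of whether step 2 retains any
covariates is resolved as *no* — the residual is the sole predictor,
matching the procedure's description.  Proportional hazards are checked per
CpG by the scaled-Schoenfeld score test against time (identity transform);
the p-value is reported, nothing is auto-excluded.

# Probe quality control

Probes are excluded in a fixed order, each tallied under the first rule
that removes it: control probes; non-CpG probes; allosomal (X/Y); known
cross-reactive probes; probes with a SNP within 10 bp; non-varying probes
(IQR below 0.1%, computed over the per-cohort medians of available values,
which is robust to single-cohort artifacts and deterministic); probes with
at least 10% missingness (judged within the cohorts that assay the probe —
whole-cohort absence is the availability rule's concern); probes flagged
for non-converging fits; and probes observed in fewer than `min_cohorts`
cohorts.  The availability threshold defaults to 4 ("more than three") with
3 ("three or more") supported, since both phrasings appear in the source
literature for this design.

# Meta-analysis

Cohort estimates are pooled per CpG by fixed-effects IVW:
$w_i = 1/\mathrm{se}_i^2$, $\hat\beta = \sum w_i b_i / \sum w_i$,
$\mathrm{se} = (\sum w_i)^{-1/2}$.  Cochran's $Q$ and
$I^2 = \max\{0, (Q-(k-1))/Q\}$ are computed from the same weights and used
purely as heterogeneity diagnostics.  Multiplicity is controlled at 5% by
both Bonferroni and Benjamini-Hochberg FDR, with the testing family being
the CpGs actually pooled (not the array size).  The genomic inflation
factor is $\lambda = \mathrm{median}\{\chi^2_1\text{-quantiles of } 1-p\} /
q_{\chi^2_1}(0.5)$, computed on the pooled p-values and per cohort; it is
computed after probe filtering (the source is silent on the order; both are
reported by the pipeline).  Sensitivity analyses: leave-one-cohort-out
re-pooling, and exclusion of cohorts with death proportion at or above 30%
or cohort $\lambda$ strictly above 1.5 (the boundary $\lambda = 1.5$ is
retained, per the strict-inequality wording).

# Attributable fraction

Exposure is methylation above the within-cohort mean of the CpG (strictly
greater).  Miettinen's case-based formula is used:
$\mathrm{PAF} = p_c\,(\mathrm{RR}-1)/\mathrm{RR}$ with $p_c$ the exposure
prevalence among deaths and RR the adjusted hazard ratio of the
dichotomized exposure.  The case-based form is the standard consistent
choice when the available association measure is a confounder-adjusted
ratio.  Two caveats are documented deliberately: the hazard ratio stands in
for the rate ratio, an approximation that is accurate at moderate
cumulative incidence (the package's oracle comparison uses ~15% cumulative
mortality, where agreement with a counterfactual-elimination simulation is
within 0.03); and dichotomization uses the cohort mean, not a pooled mean
(the source is ambiguous; cohort mean is self-contained).

# Mendelian randomization

Instruments are harmonized by allele alignment (sign flips for swapped
effect/other alleles, strand complements resolved), palindromic SNPs with
exposure allele frequency in (0.42, 0.58) are dropped with a tally, and all
instruments are oriented so the SNP-exposure effect is nonnegative.  Four
estimators are implemented: Wald ratio ($b_y/b_x$, first-order delta SE
$s_y/|b_x|$ — the convention for strong instruments; the second-order term
is negligible there) for single instruments; MR-Egger (WLS of $b_y$ on
$b_x$ with intercept, weights $1/s_y^2$; the intercept tests directional
pleiotropy); weighted median (ratio estimates weighted by $(b_x/s_y)^2$,
cumulative-weight interpolation at 50%, parametric-bootstrap SE, consistent
with up to half invalid weight); and weighted mode (argmax of a weighted
Gaussian KDE over ratios, bandwidth `bandwidth_factor` times the modified
Silverman rule $0.9\min(\mathrm{sd},\mathrm{mad})k^{-1/5}$,
parametric-bootstrap SE).  Bootstrap replicates default to 1000 and are
seeded; binary-outcome estimates exponentiate to odds ratios.

# Deconvolution and NLR

Reference-based (Houseman-style) deconvolution solves a nonnegative
least-squares projection of the sample's beta vector onto cell-type mean
profiles, with total fraction constrained to at most 1 during optimization
and renormalized to 1 for reporting (the projection admits both
conventions; this one keeps the optimization convex and simple).  The NLR
uses the granulocyte compartment as the neutrophil proxy — the 450K blood
reference resolves granulocytes, not neutrophils — over the sum of all
estimated lymphoid fractions (CD4T, naive and memory/effector CD8T, NK, B);
a zero lymphoid sum yields a flagged undefined value, never infinity.
NLR-mortality models are fit in three adjustment modes (without cell
fractions, with them, and with a CpG's methylation added) to reproduce the
attenuation contrast such analyses report.

# QTL layers

The meQTL scan follows the source analysis's stated orientation — SNP
dosage as the dependent variable, methylation as predictor — implemented by
residualizing both matrices on the covariates and correlating residuals
(algebraically the per-pair multiple-regression t-test; the p-value is
orientation-invariant and the conventional direction is available as an
option, since the stated orientation may be a description slip).  Results
are retained at p < 1e-4 and flagged genome-wide significant at p < 1e-14.
A genotype pre-filter drops call rate < 0.98, HWE p < 5e-6, MAF < 0.01.
The eQTM model regresses expression on methylation with covariates and a
random intercept for RNA amplification batch (lmer, Satterthwaite tests);
single-batch data or singular/non-convergent mixed fits degrade to a
fixed-intercept model with batch as a fixed factor, which is exact for
noiseless constructions.  Same-chromosome pairs only; distance is from the
CpG to the gene's [start, end] interval (0 inside, 1-based positions), cis
at or below 500,000 bp, trans beyond.

# Enrichment and clocks

Enrichment of significant CpGs over island-relation and gene-region
categories uses the one-sided (greater) hypergeometric tail with BH-FDR
across categories; the background is all post-QC CpGs.  Published clock
coefficient sets are not bundled (they are not printed in the source
literature); the package reads user-supplied coefficient TSVs and provides
a synthetic demonstration clock.  Scores are
$\mathrm{intercept} + \sum_j w_j \beta_j$ with cohort-mean imputation of
missing clock CpGs and a flag when under half are observed.  Age
acceleration defaults to the difference (clock minus chronological age),
matching the "discrepancy" definition; residual-on-age mode is available.

# The synthetic-data generator

The generator emulates, per cohort: leukocyte fractions from a Dirichlet
centred on typical whole-blood composition (concentration 60); beta values
as fraction-weighted mixtures of reference cell profiles plus logit-scale
Gaussian noise mapped back through the inverse logit (respecting the (0,1)
support without truncation artifacts); harmonized covariates including
decade-binned age (generated continuous, then binned) and desk-scale
technical batch factors (2 plates, 4 chips, 3 rows, 2 columns — enough
levels to exercise the technical adjustment without starving the partial
likelihood of events per parameter at a few hundred samples); exponential
proportional-hazards survival with the causal linear predictor centred at
each CpG's expected mixture beta (so the baseline hazard is that of an
average subject); censoring at the minimum of an administrative bound and a
uniform dropout time; and MCAR missingness.  Each cohort draws from an
independent stream seeded `seed + cohort index`.  Reference matrices carry
a designated block of marker CpGs (0.9 in the owning cell type, 0.1
elsewhere) so the deconvolution problem is well conditioned, with a flag
raised when duplicated profiles make it rank-deficient.

Default study conditions: 4 cohorts of 250 subjects, 500 CpGs, baseline
hazard 0.025/year with 12-year administrative censoring and uniform dropout
on (0, 36) years, giving roughly one fifth to one third deaths — the middle
of the 3%-70% cohort mortality range such consortia report; covariate
effects default to modest age/sex/smoking/BMI log-hazards.  The logit noise
sd defaults to 1.5 (per-CpG beta SD around 0.25).  This is deliberately
larger than the inter-individual variance of most real 450K probes: no
deposited effect-size scale exists for true mortality CpGs, so the default
favours testability — passing tests demonstrate the statistical correctness
of the machinery at desk scale, not field-realistic power.  What the
generator does *not* emulate: familial correlation, batch-specific
normalization artifacts, array chemistry, probe-type effects, and
non-ignorable missingness.

## Study conditions used by the acceptance suite

*Null calibration* runs 20 replicates of the default 4 x 250 x 500
configuration and checks p-value uniformity (Kolmogorov-Smirnov at 1%),
genomic inflation (mean $\lambda$ across replicates within [0.85, 1.15] —
a single 500-CpG $\lambda$ has Monte-Carlo SD near 0.10, so the mean is the
calibration-relevant statistic at this size), and BH false discoveries.
Replicate seeds are spaced by 50 because cohort streams are `seed + index`.

*Effect recovery* places 10 causal CpGs (log-HR 0.5 per unit beta) at
intermediate-methylation non-marker sites (reference base beta in
(0.35, 0.65)) — where real EWAS hits live, and the only sites with enough
variance to carry signal — in 4 cohorts of 6500 subjects at ~32% mortality,
logit noise 0.8, basic model, no covariate effects.  Two properties of the
Cox model shaped these choices, measured in design-phase pilots: per-CpG
hazard-ratio estimates are *non-collapsible* over the hazard variance
contributed by the other causal CpGs (acting as an unmodeled frailty), so
each CpG's variance contribution is kept small enough that the marginal
per-CpG estimand stays within about 2% of the conditional log-HR; and Wald
tests inflate when events-per-parameter drops below roughly 4-5, which also
motivated the desk-scale batch structure above.  At these conditions the
pooled SE per causal CpG is about 0.07-0.08, per-CpG BH detection power is
above 99%, and 95% CI coverage is nominal.

*Attributable fraction* uses ~15% cumulative mortality (see above), 5000
subjects.  *MR consistency* uses 50 instruments, true effect 0.3, no
pleiotropy, 200 replicates, with bootstrap SEs skipped (only point
estimates enter the check).  The enrichment closed form is verified against
exhaustive `choose()` summation over every 2x2 table with margins up to 20.

# Known limitations

Family structure (cluster/frailty variance corrections) and competing
risks are out of scope; the two-step residual variant inherits the usual
slight conservatism of residual-outcome regression; Miettinen's PAF with a
hazard-ratio input overstates attributable fractions at high cumulative
incidence; MR-Egger SEs are model-based WLS with multiplicative dispersion
rather than the random-effect variants some implementations report; and the
weighted-mode bandwidth rule follows the common modified-Silverman choice
without cross-validation.
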