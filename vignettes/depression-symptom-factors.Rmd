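---
title: "Genetic factor models of depression symptoms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic factor models of depression symptoms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Major depressive disorder is diagnosed from nine criteria, two of them
cardinal (depressed mood, anhedonia), of which at least five must be present
including a cardinal one. Because any qualifying combination counts, 227
distinct symptom profiles satisfy the rule (`enumerate_profiles()`), and the
diagnosis conceals real heterogeneity: different symptoms may have partly
different genetic causes. Symptom-level GWAS can expose that structure, but
the data arrive with two awkward properties:

* **Ascertainment.** Clinical cohorts record symptoms only for participants
  diagnosed with depression. Conditioning on the diagnosis (a function of the
  symptoms themselves) truncates and distorts the covariance among symptoms.
* **Gating (skip patterns).** Community surveys ask about non-cardinal
  symptoms only when a cardinal symptom is endorsed, so most of the sample is
  missing for gated items, and the cardinal items are the only ones measured
  on the full population spectrum — often twice, e.g. by both a brief
  touchscreen screen and a full questionnaire.

This package implements the whole analysis chain on summary statistics:
per-symptom GWAS (on simulated cohorts), fixed-effect meta-analysis,
LD-score regression (LDSC) for the genetic covariance structure,
confirmatory factor models that encode the ascertainment and gating design,
per-SNP heterogeneity tests, and genetic regressions on external traits —
validated end to end against simulations with known truth.

## Models and estimators

### LD-score regression

For trait $a$ with effective sample size $N_a$ over $M$ SNPs with LD scores
$\ell_j$, the expected association statistics satisfy

$$E[\chi^2_{aj}] = 1 + \frac{N_a h^2_a \ell_j}{M}, \qquad
  E[z_{aj} z_{bj}] = \frac{\sqrt{N_a N_b}\,\rho_g(a,b)\,\ell_j}{M}
  + \frac{\rho_{ab} N_s}{\sqrt{N_a N_b}},$$

so a regression of $\chi^2$ (or $z_a z_b$) on $\ell_j$ with a free intercept
estimates heritability (or genetic covariance) in its slope while the
intercept absorbs confounding and, in the cross-trait case, sample overlap
($N_s$ shared participants with phenotypic correlation $\rho_{ab}$).
`fit_h2()` / `fit_gencov()` implement this with:

* **Weights** — default two-step LDSC-style heteroskedasticity weights
  $1/(\ell_j (1 + N \hat h^2 \ell_j / M)^2)$ seeded by an unweighted pass;
  `weights = "ols"` is available and exact on collinear toy inputs.
* **Uncertainty** — a delete-a-block jackknife over contiguous blocks
  (default 200; pseudovalue covariance across all $u = k(k+1)/2$ unique
  elements yields the joint sampling covariance $V$ in `build_S_V()`).
  The half-vectorization order of $V$ is fixed: column-major lower triangle,
  diagonal included (`vech()`).
* **Constant LD scores** — when $\ell_j$ is constant the slope and intercept
  are collinear; the regression then fixes the intercept at its theoretical
  null (1 for $\chi^2$, 0 for cross products) and says so. See the simulator
  notes below for why the bundled studies avoid this regime.
* **Liability conversion** — for a binary trait analysed with sample
  prevalence $P$ and population prevalence $K$,
  $h^2_{liab} = h^2_{obs}\, K^2(1-K)^2 / (P(1-P)\phi(z)^2)$ with
  $z = \Phi^{-1}(1-K)$; at $P = K = 1/2$ the multiplier is exactly $\pi/2$.
  Covariance elements scale by the geometric mean of the two traits'
  multipliers, so the diagonal of $S$ equals the univariate liability
  estimates. The prevalence scheme follows the ascertainment design:
  clinical $K$ = sample prevalence × MDD prevalence (0.15); community
  $K$ = sample prevalence × the gate-endorsement proportion (a config
  input, since it depends on the survey).

Negative heritability estimates are retained in LDSC output (flagged) and
excluded from factor analysis by `well_powered_filter()`, mirroring the
inclusion rule $h^2 > 0$, $N_{eff}$ above threshold. $S$ and $V$ are
eigenvalue-clipped to positive semi-definiteness when the elementwise
estimates are jointly indefinite, with a log entry; clipping sacrifices the
exact-diagonal property when it fires.

### Confirmatory factor models (DWLS)

`fit_model()` minimizes the diagonally weighted least squares discrepancy
$(s - \sigma(\theta))' D^{-1} (s - \sigma(\theta))$, $s = \mathrm{vech}(S)$,
$D = \mathrm{diag}(V)$, for an implied structure
$\Sigma(\theta) = \Lambda \Psi \Lambda' + \Theta$. Choices:

* **Identification**: factor variances fixed to 1, all loadings free
  (standardized-loading reporting). Residual variances are unbounded;
  negative values are flagged as Heywood cases, never silently clipped.
* **Scale**: models are fit on the covariance-scale $S$ (liability
  diagonal), not a unit-diagonal correlation. A correlation metric would
  give the fixed diagonal zero sampling variance and degenerate DWLS
  weights; the covariance scale carries identical information and keeps $V$
  full rank. Standardized loadings are reported post hoc.
* **Optimizer**: quasi-Newton (`nlminb`, PORT) with numerical gradients,
  relative tolerance $10^{-10}$, five restarts with seeded jitter, and an
  optional warm `start` (a nested model's solution padded with zeros), which
  guarantees the nesting inequality between model pairs.
* **Test statistic**: the residual-based quadratic form
  $e' [V^+ - V^+ J (J' V^+ J)^{-1} J' V^+]\, e$ with $e = s - \sigma(\hat\theta)$
  and $J = \partial\sigma/\partial\theta$ — zero at saturation and
  asymptotically $\chi^2_{u-q}$ for any consistent estimator, which DWLS is.
  $V^+$ is an eigen pseudo-inverse; for it to be well conditioned the number
  of jackknife blocks must exceed $u$, so the bundled studies use
  $\max(200, u + 30)$ blocks.
* **Fit indices**: $AIC = \chi^2 + 2q$ (relative ranking convention);
  CFI against the diagonal independence model, clipped to $[0, 1]$; SRMR as
  the root mean square of residuals standardized by the observed diagonal,
  unique elements including the diagonal (diagonal residuals are nonzero
  only when residual variances are constrained).

### The model library

`model_library()` encodes the measurement and symptom models over the
standard symptom-by-cohort-class label set: a single common factor (A);
Clinical vs Community factors (B; the touchscreen items grouped with
Community — the survey instrument is community-administered, a documented
interpretation since the split is not dictated by the design); a common
factor plus an **orthogonal Gating factor** on the community and touchscreen
cardinal symptoms (C); both (D); psychological/somatic-style content
groupings (E–H; the ambiguous placement of anhedonia and concentration is
resolved as three distinct fixed variants E, F, G); a directional
Appetite/Vegetative/Cognitive-Mood model (I); and a melancholic/atypical
model (J). Symptom models include the Gating factor by default, and a
variant flag adds cross-cohort residual correlations for the directional
appetite/sleep items and suicidality.

### SNP-level factor meta-analysis and Q_SNP

For each SNP, the common-pathway model routes one effect through the factor
($b = \delta a$, $\delta$ the covariance-scale loadings); the
independent-pathway model fits the $k$ symptom effects freely (exactly).
With $V_b[i,j] = \mathrm{intercept}_{ij}\, se_i\, se_j$ built from the LDSC
intercept matrix (sample overlap on the off-diagonal) and the standard
SNP-variance expansion $2f(1-f)$, the factor effect is the GLS combination
and

$$Q_{SNP} = (b - \delta \hat a)' V_b^{-1} (b - \delta \hat a)
  \sim \chi^2_{k-1}$$

under the common pathway. Significance tiers follow the study convention:
study-wide at $5\times10^{-8}/22$ (the number of symptom meta-analyses),
genome-wide at $5\times10^{-8}$. The "genetic covariance intercept > 1"
entry of the published well-powered filter is directionally ambiguous as
quoted; `well_powered_filter()` therefore exposes it as a configurable rule
(`"above"` / `"below"` / `"none"`) and applies none by default.

### Genetic regression

An external trait appended to $(S, V)$ is regressed on the measurement
model's factors: in the implied covariance the trait is an extra variable
with free paths from the chosen factors, so the multiple-regression
coefficients are partial effects adjusted for the other factors, and single
regressions give marginal effects (only cleanly interpretable when the
one-pathway model fits). Benjamini–Yekutieli FDR (via `p.adjust`,
`method = "BY"`) corrects across tests under arbitrary dependence.

## The simulator: what it emulates, and what it does not

`simulate_individual_cohort()` draws unlinked genotype dosages
(MAF uniform on a configurable range), infinitesimal per-SNP effects
(every SNP causal, Gaussian — the LDSC polygenic assumption), and builds
each symptom's liability as

$$y_i = \sqrt{h^2_i}\, g_i + \sqrt{1 - h^2_i}\, e_i, \qquad
  g_i = \sum_k \lambda_{ik} F_k + \sqrt{\theta_i}\, r_i,$$

with the environmental component following the same factor structure, so
the total liability correlation is $\Lambda\Psi\Lambda' + \Theta$ at every
heritability. A symptom is present when the liability exceeds
$\Phi^{-1}(1-K)$ — the standard liability-threshold convention.

* **Ascertainment**: clinical cohorts retain only individuals meeting the
  DSM rule (≥ 5 of 9 collapsed criteria, ≥ 1 cardinal; directional pairs
  collapse to one criterion).
* **Gating**: community cohorts mask all non-gate symptoms for individuals
  endorsing neither gate; gate symptoms are never masked.
* **Repeat measures**: an ungated second-instrument assessment of a symptom
  (e.g. a touchscreen screen of the cardinal items, reliability 0.8) shares
  the source symptom's full genetic component. This matters: a single
  genetic factor cannot reproduce the cross-instrument covariance of the
  same symptom (which includes the symptom-specific genetic residual), and
  absorbing it is precisely what the orthogonal Gating factor does in the
  measurement-design experiment.
* **Sample overlap**: within a cohort all symptom GWAS share participants;
  across cohorts overlap is zero by default (configurable) — the cross-cohort
  overlap of the real consortia is not published, so zero is the default
  assumption.
* **LD profile**: genotypes are unlinked, but per-SNP effect variances are
  scaled by a synthetic long-tailed profile ($\ell_j = 0.5 +$
  Exponential(mean 0.5), normalized to mean 1) that plays the LD-score role
  exactly, $E[\chi^2_j] = 1 + N h^2 \ell_j / M$. With literally constant
  unit scores the LDSC intercept is not identifiable, and the free
  intercept is essential for absorbing within-cohort sample overlap.

`simulate_sumstats_direct()` skips genotypes and draws $z$-scores from the
sampling distribution above (genetic part scaled by $\ell_j$, overlap part
not); it treats the configured $h^2$ as observed-scale and uses the
liability correlation for the phenotypic-overlap term (an override is
available). It exists for fast, exactly calibrated tests of the estimators.

What the simulator does **not** emulate: real LD panels (no correlated
genotypes), imputation quality, X chromosome, ancestry structure,
relatedness, genotyping batch effects, or non-Gaussian effect-size
distributions. Tests passing on these simulations show the estimators are
correct under the stated model, not that real-data artifacts are handled.

## Study conditions of the bundled demonstration

The demonstration study (`demo_study_config()`) fixes: nine collapsed DSM
criteria symptoms; a single genetic factor with loadings 0.7 (so roughly
half of each symptom's genetic variance is symptom-specific); liability
heritability 0.2; lifetime prevalences 0.10–0.30 with the cardinal symptoms
most prevalent; a community cohort of 10,000 with Dep/Anh gating plus
touchscreen repeats of both (reliability 0.8); a clinical pool of 16,000
ascertained by the DSM rule (retaining roughly one in seven); 1,000 SNPs
with the synthetic LD profile; $\max(200, u+30)$ jackknife blocks. The
effective-sample-size inclusion threshold is scaled to 500 — the published
5,000 presumes biobank-scale cohorts, and the threshold is exposed as a
parameter (default 5,000). Estimator-calibration studies (heritability
recovery, Q_SNP) use 20,000 SNPs and $N_{eff} = 50{,}000$, sizes at which
jackknife standard errors are meaningful while a full run stays in minutes
on one CPU.

These values were chosen once, from the design considerations above, and
define the study; they are not per-run tuning knobs.

## Numerical choices and degenerate inputs

* Rounding of printed prevalence percentages is round-half-up, matching the
  published table convention (base `round()` is banker's rounding).
* Monomorphic SNPs yield flagged records with undefined effects and are
  excluded before LDSC; symptoms with fewer than 30 non-missing phenotypes
  refuse to run a GWAS; a diagnosis rule retaining nobody is an explicit
  "empty ascertained cohort" error.
* Ambiguous palindromic variants (A/T, C/G) are dropped during
  harmonization by default; frequency-based rescue is deliberately not
  implemented. Harmonized tables are rewritten in reference orientation, so
  harmonization is involutive.
* Meta-analysis keeps the union of variants with per-variant contributing-N
  (coverage preserved); INFO/MAF thresholds (0.9 / 0.01) are package
  defaults, configurable, as the per-cohort filters of the original
  consortium pipelines are not part of the published record.
* The published community-cohort table contains one internally inconsistent
  prevalence cell (anhedonia: printed percent vs printed counts); it is
  retained in the bundled table with a note and excluded from golden tests
  rather than silently corrected.

## Known limitations

* The residual-based $\chi^2$ is asymptotic; with few jackknife blocks or
  near-singular $V$ it can misbehave — hence the block-count floor tied to
  $u$.
* Single-regression coefficients on correlated factors are model-dependent
  compromises when the trait truly acts through another factor; only the
  multiple regression isolates factor-specific covariance.
* Clinical-cohort estimates in the demonstration study are intentionally
  weak (strong selection, small retained N), mirroring the real situation;
  their loadings are poorly determined and the cross-cohort factor
  correlation is noisy at desk scale.
* The paper-scale headline numbers (model AICs in the thousands, factor
  correlations with tight errors) require the consortium summary statistics
  and biobank sample sizes; the package reproduces the qualitative
  structure — gating model preferred, appetite symptoms separable — on
  synthetic data, not those numbers.
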