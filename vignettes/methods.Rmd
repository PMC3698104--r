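---
title: "Methods: a hierarchical mixed-treatment-comparison model for heavy menstrual bleeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical mixed-treatment-comparison model for heavy menstrual bleeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmbmtc)
```

## The estimation problem

Heavy menstrual bleeding (HMB) is clinically defined as menstrual blood
loss (MBL) above 80 mL per cycle. Randomised trials of HMB treatments
report efficacy in incompatible ways: some report the number of women
reaching MBL < 80 mL (or a Higham pictorial chart score, PBAC, below 100,
treated as the equivalent response definition), others only a mean and SD,
or a median with range or quartiles, at follow-up times anywhere between 1
and 36 months. Direct head-to-head evidence is thin: among eight treatment
classes (combined oral contraceptives, danazol, endometrial ablation, the
levonorgestrel-releasing intrauterine system LNG-IUS, placebo, luteal-phase
progestogens given < 2 of 4 weeks, longer-course progestogens ~3 of 4
weeks, and tranexamic acid) most class pairs have at most one comparing
trial, and at some follow-up times the comparison graph is disconnected.

`hmbmtc` estimates the *absolute* efficacy — the percentage of women below
the threshold per treatment class and follow-up time — by pooling all of
this evidence in one Bayesian hierarchical model (a mixed treatment
comparison), rather than estimating pairwise relative effects.

## From reported summaries to effective observations

Every arm record is converted to a proportion below threshold with a
standard error, then to "effective" binomial counts.

- **Counts** (y of n below threshold) are used directly. A continuity
  constant c = 0.5 is added only when y is 0 or n, keeping the logit
  finite without biasing interior proportions: p = (y + c)/(n + 2c).
- **Mean and SD**: the outcome distribution is assumed lognormal by
  default (blood-loss measures are positive and right-skewed; a normal
  family is selectable per run as a sensitivity switch, and the choice is
  recorded in the output). The family is moment-matched to the reported
  (mean, SD) and the proportion is its CDF at the threshold. The standard
  error comes from the delta method, propagating var(mean) = s²/n and
  var(SD) ≈ s²/(2(n−1)), treated as independent because aggregate data
  carry no covariance information. Derivatives are analytic for the
  normal family and central finite differences for the lognormal.
- **Median + min + max**: (mean, SD) are first recovered with the Hozo
  estimator — mean = (min + 2·median + max)/4 and an SD rule whose
  divisor depends on n (a small-sample formula for n ≤ 15, range/4 for
  n ≤ 70, range/6 beyond) — applied on the log scale when the family is
  lognormal.
- **Median + quartiles**: Wan-type rules, mean = (q1 + median + q3)/3 and
  SD = (q3 − q1)/1.349 (1.349 being the normal interquartile width in SD
  units), again on the log scale for the lognormal family.

Quantile-based moments are noisier than directly reported ones, so the
delta-method variance components are inflated by fixed relative-efficiency
factors: π/2 on the mean term (the asymptotic efficiency of a median
against a mean) and 2.0 (range) or 2.7 (IQR, the inverse asymptotic
efficiency of an IQR-based scale estimate against a sample SD) on the SD
term. The exact conversion procedures used in the original analysis of
this literature are not publicly documented; the estimators here are
standard meta-analytic practice, derived independently and flagged by a
provenance column so any single form can be audited or swapped.

Each derived estimate enters the model as the effective count pair
n_eff = p(1−p)/se² (capped at the arm size — a summary can never be more
informative than the patients behind it) and y_eff = p·n_eff. Effective
counts are deliberately kept real-valued and the likelihood uses the
continuous binomial generalization (gamma-function coefficient); rounding
would discard information and split the likelihood into two code paths.

## The hierarchical binomial-logit model

For study i, class j, time t:

- y_ijt ~ Binomial(n_ijt, p_ijt)
- logit(p_ijt) = α₀ + η_i + θ_ij + γ_jt

η_i ~ N(0, σ_η²) is a study effect (preserving within-study
randomisation), θ_ij ~ N(δ_j + α₁·x_ij, τ_j²) a study-by-class effect
around the class effect δ_j adjusted by the standardized baseline mean MBL
x_ij, and γ_jt a class-by-time effect that exists only for (class, time)
cells observed in the data — the model never extrapolates to unobserved
cells. Studies followed at several times share η_i and θ_ij; only γ_jt
varies.

Priors are proper but weakly informative: α₀, δ_j ~ N(0, 10⁴); γ_jt ~
N(0, 100); α₁ ~ U(−5, 5); τ_j ~ U(0, 100); 1/σ_η² ~ Gamma(0.1, 0.1)
(shape–rate, the BUGS convention). Baselines are standardized by the mean
and SD over study arms with non-missing values; missing standardized
baselines get a N(0, 1) prior and are imputed by joint sampling
(missing-at-random), so the data pull their posteriors away from zero.
Two arms of the same class within a study (several ablation trials
compared two ablation techniques) are pooled by summing effective counts
before indexing, since the model has a single θ per (study, class).
Where studies report arm-specific baselines, x is indexed per (study,
class), matching the random-effects specification.

### Identifiability

The parameterization is deliberately redundant: α₀, δ_j and γ_jt all
carry vague priors with no contrast constraint, so only sums such as
α₀ + δ_j + γ_jt are identifiable. The package keeps the redundant
parameterization as the default for fidelity, reports **only**
identifiable functionals (every prediction uses α₀ + δ_j + α₁x* + γ_jt),
and verifies by test that predictions are invariant to the shift symmetry.
An optional corner constraint (`constrain = TRUE`: δ = 0 for the placebo
class, γ = 0 at each class's earliest observed time) removes the flat
directions without changing any identifiable sum, which makes
raw-parameter diagnostics interpretable. It does not necessarily speed up
mixing of the quantities that matter: in the default mode the class
levels are moved by exact Gibbs steps on δ, whereas under the constraint
the same information must travel through random-walk updates of the
intercept. In both modes, convergence should be judged on the
identifiable sums — `convergence_report()` computes the Brooks–Gelman
statistic for exactly those — rather than on α₀, δ or γ individually.

## Sampling

The posterior is explored with a blocked Metropolis-within-Gibbs sampler
built directly over the package's own joint log-density:

- vectorised single-site random-walk Metropolis for α₀, η, θ, γ and τ
  (valid as independent blocks because studies, study-class pairs and
  class-time cells partition the observations);
- exact Gibbs draws where conjugacy allows it: δ_j (normal–normal given
  θ), α₁ (normal truncated to (−5, 5)), the study-effect precision
  (gamma), and missing baselines (normal).

Proposal scales adapt towards 44% acceptance (the optimal single-site
rate) in windows of 50 iterations during burn-in, with a diminishing
1/√window step, and are frozen afterwards so the saved chain is a fixed
Markov kernel. Initial values are drawn from the priors truncated to
[−2, 2] on location parameters (vague normals truncated to that interval
are indistinguishable from a uniform, which is what is drawn), with up to
10 retries if the density is non-finite. Probabilities inside the
likelihood are clipped 10⁻¹² from each boundary — far below reportable
precision — as a numerical guard. Runs are bit-reproducible from (seed,
configuration).

Prior-only runs (`prior_only = TRUE`) do not run the Markov chain at all:
the joint prior is a directed model, so it is sampled exactly by ancestral
simulation. This gives an exact reference for validating the stated prior
spreads.

The full protocol of the source analysis (3 chains, 60,000 burn-in,
60,000 saved, as run in BUGS-family Gibbs software) is available as the
`"paper"` preset; the algorithm is not dictated by that protocol, and
correctness is checked distributionally (conjugate closed forms, prior
spreads, parameter recovery) rather than by software identity. The
`"desk"` preset
(3 × 2,000 + 2,000) is the default for interactive work and testing.
Convergence is assessed with the Brooks–Gelman corrected potential scale
reduction factor (flagged above 1.1, a common working threshold — no
numeric criterion is inherited) and deterministic trace statistics
(segment means, lag-1 autocorrelation).

## Posterior summaries

Efficacy per (class, time) is reported as the posterior median and the
equal-tailed 95% credible interval — 2.5/50/97.5 percentiles with linear
interpolation (type 7), the same convention everywhere — of
100·logit⁻¹(α₀ + δ_j + α₁x* + γ_jt), at a reference baseline standardized
to x* (x* = 0 at the covariate centre). The default prediction is the
plug-in "typical study" (η = 0, θ at its conditional mean), which matches
a point-prediction reading; a marginal mode that adds N(0, σ_η²) and
N(0, τ_j²) noise per draw is exposed as a sensitivity option, since the
original report does not state which was used. Tables are sorted by
descending median within time and rendered in the conventional
"87.5 (77.6–93.9)" layout.

## The synthetic-data generator

Because the underlying extracted trial table is not publicly deposited,
validation runs on synthetic networks with known truth. The generator
simulates from exactly the model above, under the documented study
conditions: 34 trials whose designs follow the observed pair/time
sparsity template (including the two-arms-same-class ablation trials, a
pair observed only at disjoint times, and single-relevant-arm trials),
arm sizes lognormal around a median of 33 clamped to 9–164, baselines
uniform on 90.3–300 mL with study-level missingness of 19/34, and the
observed reporting mix of roughly 11:8:4:11 (MBL counts : mean+SD :
median forms : PBAC counts). Summary-form arms are re-encoded from
simulated individual outcomes drawn lognormal with log-SD 0.5 (a
realistic right-skew for blood-loss data, chosen once) parameterized so
the below-threshold probability equals the arm's true p_ijt — making the
estimator chain's target well-defined. Missingness is independent of
outcomes by construction (missing at random, matching the model's
assumption; the test suite verifies the mask can be changed without
touching a single outcome). The default truth preset orders classes
plausibly (intrauterine system and ablation high, placebo and short-course
progestogens low) and is illustrative, not a reproduction of any fitted
result.

What the generator does *not* emulate: real within-class heterogeneity of
distinct drugs or devices, non-lognormal outcome shapes, informative
missingness, attrition over follow-up, or outcome-measurement error in
PBAC scoring. Passing recovery tests therefore demonstrates internal
calibration of the estimator-model-sampler chain under the stated
conditions, not agreement with any particular reanalysis of the real
trials.

## Validation scales and numerical choices

The published efficacy table itself is not desk-reproducible (the
extracted per-study data are available from the original authors only on
request), so the package's calibration claim is a parameter-recovery
experiment: 50 synthetic networks at the default 34-study conditions,
each fitted with the desk preset, checking that 95% credible intervals
for the identifiable sums α₀ + δ_j + γ_jt cover the generating values at
a rate inside the exact binomial 95% band for 50 replicates,
[0.86, 1.00]. Proportion estimators are checked against ≥10⁵ Monte-Carlo
draws per parameter set (100 random sets per estimator and family, 3
Monte-Carlo SEs), the joint log-density against an independent
term-by-term reimplementation at 10⁻¹⁰, the Metropolis kernel against a
conjugate Beta closed form, prior spreads against their stated values
within 5%, and the Brooks–Gelman statistic against designed iid and
separated chains. These sizes keep the full suite in the minutes range
on a single CPU while leaving every check statistically sharp.

Remaining judgment calls, recorded here as the package's own choices: a
pair's "total patients" is the sum over comparing trials of each arm's
largest reported size (so a pair compared only at disjoint times still
counts its patients); follow-up times are exact integer months with no
windowing; an optional integer `arm` column distinguishes same-class arms
within a study (the published schema has no such field, but the data
contain such trials); and canonical class codes are matched
case-insensitively with separator tolerance.

## Limitations

Class-level pooling cannot express within-class differences between
drugs or devices. Cells never observed in any trial have no γ parameter
and are deliberately unpredictable. The redundant default
parameterization makes single-parameter convergence diagnostics
uninformative for α₀, δ and γ individually — diagnose identifiable sums,
or use the constrained mode. Credible intervals inherit every modelled
source of uncertainty, including the summary-statistics conversions, and
are wide where the network is thin; that width is a faithful property of
the evidence, not an artefact to be tuned away.
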