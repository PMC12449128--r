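---
title: "Models and methods: belief uncertainty and BOLD variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: belief uncertainty and BOLD variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(beliefvar)
```

`beliefvar` implements a complete analysis chain for one scientific
question: does across-trial BOLD signal variability compress as an
observer's belief about a latent environmental state becomes more precise,
and do individual differences in that compression track inference accuracy?
This vignette is the package's account of its models, its tunable
parameters, its numerical choices, and what its synthetic validation does
and does not establish.

## The task and the observer models

In the marble task an observer watches five successive samples drawn (with
replacement) from an unseen jar of blue and red marbles and then reports
the jar's blue-marble proportion on a 0–1 grid with step 0.01. Eighteen
jars with proportions evenly spanning 0.1–0.91 are each presented once per
block; sample sizes of 1, 5 or 9 marbles manipulate informativeness. Each
jar's sample set is drawn once and re-used across blocks in permuted order,
so every simulated subject sees identical evidence.

The Bayesian observer holds a Beta(α, β) belief over the proportion.
Because the beta distribution is conjugate to the binomial sample
likelihood, each sample updates the belief in closed form:

* **prior width ρ ≥ 1** — the trial-initial belief is Beta(ρ, ρ). ρ = 1 is
  the flat (unbiased) prior; larger ρ concentrates prior mass on 0.5 and
  biases estimates of extreme jars toward the middle.
* **evidence weight δ ≥ 0** — counts enter as B^δ and R^δ; δ < 1
  underweights large samples, δ = 1 is exact Bayes. We define 0^δ = 0 for
  every δ, including δ = 0: a zero count carries no evidence, so it must
  not add a pseudo-count.

Two choice rules map the final belief to a report. The *noisy* rule draws
from a normal distribution centered on the posterior mean with free SD σ,
truncated (renormalized, not censored — a report can never leave \[0, 1\],
so no probability mass should pile at the bounds) to the unit interval.
The *posterior-draw* rule reports a draw from the final beta distribution.
Since reports live on a 1/100 grid, the draw-rule likelihood is the beta
probability mass of the half-open response bin around the grid value
(half-width bins at 0 and 1), which keeps the likelihood a proper
probability; a density evaluated at the grid point would not integrate to
one over the response space. The Rescorla–Wagner comparison model updates
only a point estimate with a free learning rate and shares the
truncated-normal response rule.

The model set mirrors the study's: {ρ}, {δ} with the draw rule, {ρ, σ},
{δ, σ} with the noisy rule, and Rescorla–Wagner {lr, σ}. The combined
ρ + δ + σ observer is deliberately not in the default set (it harms model
recovery), but `observer_spec()` can compose it for recovery experiments.

**Experienced proportion.** The per-trial target θ_t for the estimation
error is the proportion actually shown, not the jar's true proportion. Two
readings of "the mean across samples" are implemented: pooled counts
(total blue / total marbles; the default, since it is the sufficient
statistic the ideal observer tracks) and the unweighted mean of per-sample
proportions (`method = "mean_of_samples"`).

## Fitting, comparison, recovery

`fit_observer()` minimizes the dataset negative log-likelihood with
bounded L-BFGS-B from 10 random interior starts; the best converged
solution wins. Box bounds are ρ ∈ \[1, 50\], δ ∈ \[0, 5\],
σ ∈ \[10⁻³, 1\], learning rate ∈ \[0, 1\] — the one-sided scientific
constraints plus generous upper bounds well beyond empirically fitted
values. Starts are drawn uniformly over the plausible sub-box (ρ ≤ 10,
δ ≤ 2, σ ≤ 0.5) so the multi-start search concentrates where solutions
live while the optimizer can still reach the full bounds. Trials with
missing responses are dropped before fitting, and BIC uses n = number of
valid trials (the likelihood has exactly one response per trial).

All randomness flows through one master seed: `derive_seed()` derives
named sub-streams ("task", "agents", "bold", "perm", "boot", per-subject
and per-start offsets), so any stage is replayable in isolation and a full
pipeline run is byte-reproducible.

The recovery machinery (`recovery_study()`, `model_recovery_study()`)
simulates agents with known parameters (uniform over ρ ∈ \[1, 10\],
σ ∈ \[0.03, 0.2\] by default), refits, and reports recovered-vs-true
correlations, median absolute errors, and the summed-BIC confusion across
families.

## Behavioral metrics

Estimation error is |θ_t − report_t|; the subject summary is its median.
The extreme-jar bias is the unstandardized least-squares slope of
trial-wise error on |p_blue − 0.5| (the jar's *true* distance from 50:50,
which is the designed manipulation, rather than the experienced one). The
group-level test enters subject identity as fixed indicator covariates and
reports the distance term's F when entered last, with semi-partial η² =
SS(distance entered last) / SS(total); a random-intercept mixed model is a
natural alternative but with balanced designs the fixed-effects covariate
absorbs exactly the same between-subject variance. Winsorization uses
Tukey fences (1.5 IQR beyond the quartiles, linear-interpolation
quantiles) and imputes the most extreme non-outlying value, which makes it
idempotent.

Even the flat-prior observer shows a small positive extreme-jar bias:
its posterior mean (ρ + B)/(2ρ + N) is shrunk toward 0.5 by the prior
pseudo-counts, so "unbiased" means *small relative to narrow-prior
agents*, not exactly zero.

## The synthetic BOLD generator

The generator is the package's ground truth, not a fixture. For each
scanner run (one per block) it lays out the session's events (five 1 s
samples with 2–6 s fixation gaps in 0.5 s steps, a 7 s estimation phase
and a 2.5 s gambling nuisance phase per trial), draws a per-event,
per-voxel amplitude, convolves with the canonical HRF, and adds white scan
noise. In "effect" voxels the across-trial amplitude SD at sample period
s is

sd_s = base_sd + gain · Var_s / (1/12),

where Var_s is the coupled observer's posterior variance after sample s
and 1/12 is the flat-prior variance used as a fixed reference. Normalizing
by a fixed reference rather than each subject's own prior variance is
essential for the group-level prediction: with subject-specific
normalization, narrow-prior (high-ρ) agents would show the *largest*
relative uncertainty reduction, inverting the mechanism being modeled
(flatter prior → more absolute uncertainty to reduce → steeper
variability compression). "Null" voxels keep a flat base_sd dispersion at
every period. Estimation and gambling events receive amplitude
variability energy-matched per unit regressor to a baseline sample event,
so the trial-wise variance environment seen by the estimator is roughly
stationary across the trial.

Defaults (chosen once as the study conditions): a 12×12×12 grid with a
spherical ~200-voxel mask and a contiguous inner effect sphere, TR
0.645 s, 3 runs × 18 trials, base_sd 0.3, gain 2, scan-noise SD 0.5,
event amplitude mean 1 (arbitrary signal units). The agent population is
log-normal around the fitted group medians — ρ median 2.45 (truncated to
\[1, 20\]), σ median 0.10 (truncated to \[0.03, 0.3\]). The ρ log-SD
(1.1) is calibrated so the population SD matches the reported fitted
spread (≈ 4.2, i.e. a heavy right tail of narrow-prior subjects). The σ
log-SD (0.15) is deliberately narrower than the fitted σ spread: a
substantial share of fitted response-noise variability reflects
estimation noise and model misfit rather than generative heterogeneity,
and the defining feature of the behavioral results — prior width, not
response noise, dominating estimation error — only emerges when
between-subject response-noise heterogeneity is modest. Both choices were
made by matching behavior-only simulations to the published behavioral
effect structure (ρ-dominant semi-partial η², the error range, and the
group medians), not to any downstream neural result.

What the generator does **not** emulate: vascular or physiological noise,
spatial autocorrelation, motion, scanner drift (optional sinusoidal drift
is available but off by default), registration error, or hemodynamic
nonlinearity. Passing tests therefore establish that the analysis chain
is *correct and calibrated under its own assumptions*, not that those
assumptions hold in real data.

## GLM and SD-BOLD estimation

The canonical HRF is the double-gamma convention (gamma densities with
shapes 6 and 16, rate 1, undershoot ratio 1/6; the resulting peak is near
5 s), with a temporal derivative (finite difference over a 0.1 s onset
shift) and a dispersion derivative (finite difference in the rate
parameter), each peak-normalized. Events are modeled as boxcars at their
stated duration on a 16× oversampled microtime grid and sampled at scan
onsets.

LS-S estimates one beta per event: a GLM with the single event's three
basis regressors, the pooled "all other events" regressors (also three
basis functions — the full-basis choice keeps the nuisance space matched
to the target's), and a run constant. The canonical beta is retained; the
derivative betas act as nuisance. Events with onsets in the final 20 s of
a run are not estimated (HRF truncation) but still contribute to the
pooled regressor — their signal exists whether or not it is estimated.
SD-BOLD is the sample SD (n − 1) of the canonical trial betas per
condition and voxel, pooled across runs; ΔSD-BOLD is the per-voxel
least-squares slope over the five ordered sample periods. Estimation is
OLS throughout: with white synthetic noise, ReML/AR(1) prewhitening would
change nothing, and the equivalence is part of the generator's stated
scope.

### What LS-S does to dense designs — and how the validation handles it

With ~5 s between events and a slow HRF, the pooled-others regressor
cannot absorb each neighbor's amplitude deviation, so a single-event beta
leaks a substantial share of its temporal neighbors' amplitude variance
(leakage SD around 0.7 per unit neighbor SD at this event density). Two
consequences matter for validation:

1. *Period asymmetry.* The final sample period borders the estimation
   phase rather than another sample, so its leakage environment differs
   systematically; raw SD maps carry a small design-driven period profile
   even in null voxels.
2. *Cross-period correlation.* Adjacent periods share leakage sources, so
   their SD estimates are positively correlated within a voxel, which
   inflates a naive per-voxel trend test.

The package's calibrated change test therefore (a) estimates each
period's SD from disjoint, interleaved trial subsets, making the five
estimates independent, and (b) divides by a null period profile measured
on an independent zero-coupling calibration replicate generated through
the identical design — a standard simulation-based calibration that uses
no ground-truth voxel labels from the test data. With both elements the
null-voxel false-positive rate of the slope test sits at the nominal α;
with neither it is inflated several-fold. Effect-voxel *recovery*
(monotone decline, negative slopes) is assessed on the raw pooled SDs,
where the injected decline dominates. `lss_noise_scale()` additionally
exposes the design-implied white-noise variance multiplier per condition,
computable from the design matrix alone.

The validation uses a linear amplitude-SD decline spanning 2.7 → 0.4
signal units across the five periods — strong enough that monotonicity of
five SD estimates from 54 trials (each with sampling SE ≈ SD/√106) is
resolvable — pooled over two session (fixation-jitter) realizations so no
single ITI draw drives the result.

## PLS and latent regressions

Task PLS mean-centers each subject's condition × voxel matrix on the
subject's per-voxel grand mean, averages across subjects, and decomposes
by SVD; behavioral PLS decomposes the behavior × voxel cross-correlation
matrix (correlation rather than covariance by default, so voxels with
large dispersion do not dominate). Both blocks are column-wise
rank-transformed (average ranks for ties) before behavioral PLS, so
latent relationships are monotone and the latent correlation is
Spearman-type. Brain scores are plain projections of a subject's data on
the voxel saliences.

Permutation inference permutes behavior rows (behavioral PLS) or
condition labels within subject (task PLS) and counts permuted singular
values of the same rank order at or above the observed one, with the
(b + 1)/(B + 1) correction — a reported "p = 0" is rendered as
p < 1/(B + 1). Bootstrap salience ratios resample subjects with
replacement and align each resample's LV to the original by the sign of
the salience dot product (a full Procrustes rotation is unnecessary at
these LV separations); BSR = original salience / bootstrap SE, with
|BSR| > 3 as the robustness criterion and 25-voxel minimum clusters under
6-connectivity (face adjacency — the conservative choice). Cook's
distance > 4/n flags multivariate outliers before latent regressions.

Latent regressions run on column-wise ranks by default and report
per-predictor t, p, and semi-partial η² (sum of squares when entered
last over total). Orthogonal polynomial contrasts over the five sample
periods use the standard zero-sum weights in a model with subject
indicator covariates.

The full pipeline applies two robustness steps before the latent
analyses: subjects flagged by Cook's distance (> 4/n) on the latent
change-in-SD / error relationship are removed from that and all
downstream latent analyses, and the fitted model parameters are
winsorized (like the behavioral summary measures) before entering the
regressions. A caution for interpretation: ρ̂ and σ̂ have negatively
correlated estimation errors at 54 trials (a narrower-than-estimated
prior inflates the apparent response noise), so σ̂ can act as a
suppressor variable in the joint regression; rank transforms and
winsorization temper, but do not eliminate, this.

## Pipeline, problem sizes, and limitations

`run_full_pipeline()` chains every stage from one validated configuration
(YAML-compatible; unknown keys rejected; normalization idempotent) and
writes a machine-readable JSON report; identical seeds give byte-identical
reports. The test suite exercises the full replica at desk scale — 30
subjects, 54 trials, a 56-voxel layout, 500 permutations — and the
component validations at up to the 208-voxel default layout; these sizes
were chosen so the entire validation runs comfortably on a laptop while
keeping every statistical check adequately powered (binomial CIs around
the calibration targets are quoted in the tests).

Known limitations: the fixed-effects subject covariate stands in for a
random-intercept mixed model; OLS stands in for ReML (exact only under
white noise); the LS-S leakage analysis above means raw SD-BOLD period
profiles should not be interpreted voxel-wise without calibration in any
application to real data; and the synthetic generator's noise model is
deliberately minimal, so real-data preprocessing (filtering, ICA
denoising, registration) is entirely out of scope.
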