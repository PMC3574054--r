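---
title: "Models and methods for heading-estimation bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for heading-estimation bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headingbias)
```

`headingbias` measures and models systematic inaccuracy in human heading
estimation in the earth-horizontal plane. This vignette documents the
models, the conventions, the tunable parameters and the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Conventions

Headings are degrees on (−180°, 180°], 0° straight forward, positive
clockwise (rightward) viewed from above. Every wrap goes through
`wrap_angle()`; no other code touches the discontinuity. The head-fixed
frame is x forward, y leftward, z up, so the unit vector of heading θ is
(cos θ, −sin θ, 0).

All simulation entry points take one explicit integer seed and restore the
caller's RNG state; identical inputs give byte-identical outputs.

## Stimulus kinematics

A translation of duration $T$ and displacement $D$ has Gaussian speed
profile $v(t) = A\,e^{-(t-T/2)^2/2\sigma^2}$ with $\sigma = T/6$,
truncated to zero outside $[0, T]$ (±3 SD), and $A$ chosen so
$\int_0^T v\,dt = D$. Peak velocity is $A$; peak acceleration is
$A e^{-1/2}/\sigma$ at the inflection points $T/2 \pm \sigma$. The ±3σ
truncation with σ = T/6 is a design choice: it is the assignment under
which a 1 s, 13 cm translation reproduces the standard laboratory triplet
(peak velocity ≈ 0.31 m/s, peak acceleration ≈ 1.13 m/s²)
simultaneously; wider or narrower truncations do not.

## Identification analysis

Per heading, the perceived direction is the circular mean of the repeated
indicated directions (10 presentations under the default 5-block × 2-rep ×
48-heading design). Bias is the wrapped difference from the stimulus;
variability is the wrapped-normal-equivalent circular SD
$\sqrt{-2\ln\bar R}$ (in degrees), which coincides with the ordinary SD of
wrapped deviations at small dispersion. When $\bar R$ is within $10^{-10}$
of 1 the log formula loses precision and the RMS wrapped deviation is used
instead — without this, near-noiseless samples would report SD 0 and the
outlier filter would misfire.

**Outlier exclusion.** Chauvenet's rule is applied as a *single pass* with
*circular* mean and SD: responses deviating more than 2.4 circular SDs are
excluded. Whether the original procedure iterated, or used linear SD, is
not determinable; single-pass circular is the documented choice (iteration
changes nothing on clean data and risks cascading exclusions on
small samples).

**Interpolation.** The stimulus–response curve is fitted with a degree-12
polynomial by least squares, after (a) unwrapping responses onto the
identity line (`response = stimulus + wrapped bias`), because a
polynomial cannot represent the 360° discontinuity, and (b) scaling
stimuli to [−1, 1], which keeps the degree-12 Vandermonde system
well-conditioned. On the 48-heading grid the fit reproduces a 6 sin 2θ
bias curve to < 0.01°. Evaluation outside the fitted stimulus range is an
error rather than an extrapolation: degree-12 polynomials diverge
immediately beyond the data.

## Discrimination analysis

Transformed up-down staircases raise the stimulus after $n_{up}$
consecutive "counter-clockwise" responses and lower it after $n_{down}$
consecutive "clockwise" responses (4° steps by default). Two staircases of
the same rule are interleaved in strict alternation (the simplest
reproducible reading of "interleaved"), starting above and below the
reference (±26° for 35-trial 1U1D blocks, ±18° for 40-trial 2U1D/1U2D
blocks). The consecutive-response counter resets after each step
(reset-on-step; the alternative, reset on any opposite response, is not
what the counters-since-last-step formulation computes). A reversal is a
step opposite in direction to the staircase's previous step; the first
trial cannot be a reversal. Staircase levels are tracked on the unwrapped
real line so blocks near ±180° are not corrupted; only final estimates are
wrapped.

The PSE is estimated two ways: the mean of reversal levels after
discarding the first four per staircase, and the mean of a
maximum-likelihood cumulative-Gaussian fit
$P(cw\,|\,x) = \Phi((x - \mathrm{PSE})/\mathrm{JND})$ to the pooled
binomial counts (an exact probit GLM; a fixed small lapse rate, e.g. 0.01,
is available as a robustness switch and is fitted by direct likelihood
maximization). On simulated observers the two agree in expectation within
a fraction of a degree, and the 1U1D/2U1D/1U2D rules converge to the
50% / 29.3% / 70.7% points of the observer's psychometric function.

## Population-vector decoding

An otolith afferent fires at $d = s\,(F \cdot P) + d_0$ with $F$ the
gravito-inertial force in g. The information a neuron conveys about a
transient translation is its peak-to-trough modulation: the rate at
maximum acceleration minus the rate at maximum deceleration, which for the
linear model collapses to $2 s\,a_{peak}(u(\theta)\cdot P)$ — gravity and
resting discharge cancel exactly. Both the closed form and a time-resolved
evaluation (rates at the numerically located acceleration extrema of the
sampled profile) are implemented; they agree to numerical precision, and
the decoded angle is provably invariant to the gravity magnitude, to
uniform sensitivity scaling, and to resting discharges.

Decoding multiplies each neuron's scalar response by its polarization
vector, sums, and takes the angle of the horizontal projection. Rates are
*not* rectified by default (the linear model is decoded as-is; rectification
is a flag for sensitivity analysis), and sensitivities are not normalized
before summation. Left-labyrinth populations are mirrored across the
mid-sagittal plane before decoding, which makes the decode exactly
unbiased at 0° and 180° and exactly antisymmetric in heading.

The synthetic afferent population draws azimuths from a wrapped normal
centered at +50° (SD 30°, a choice that reproduces the lateral-peak /
fore-aft-trough histogram shape after mirroring), elevations uniform on
±60°, log-normal sensitivities around 35 spikes/s/g and resting discharges
around 90 spikes/s — plausible otolith magnitudes whose exact values are
immaterial to decoded angles. The default size of 313 neurons matches the
classical afferent sample. MSTd-like populations are horizontal
cosine-tuned units with preferred directions from a two-component mixture
at ±90°; because $u(\theta)\cdot P = \cos(\theta - a)$ for horizontal
units, the same peak-to-trough decoder applies unchanged. Mirror symmetry
is enforced exactly by construction (draw half, mirror), and an infinite
spread gives the uniform, unbiased special case.

## Bayesian observer

The likelihood for stimulus θ is a wrapped Gaussian centered at θ whose SD
grows with eccentricity, supplied as a piecewise-linear node table in
|heading|. The SD is evaluated at the *stimulus* angle, not the hypothesis
angle — the simplest reading of a stimulus-conditioned likelihood; the
node tables are editable configuration (YAML), and the shipped vestibular
(4° → 30°) and visual (1.5° → 24°) tables are illustrative, anchored to
the ~4°/~1° forward discrimination thresholds of the two modalities. The
prior is two wrapped Gaussians at ±90° with common SD σ_prior.

The MAP estimate is the argmax of likelihood × prior on a 0.1° wrapped
grid. Wrapping both densities avoids edge artifacts at ±180° (the
replication count adapts to the SD; SDs above 5000° are numerically
uniform). Ties within a relative tolerance of 10⁻¹² are broken toward the
stimulus; an exactly symmetric pair of maxima — the generic situation at
0° and 180° — resolves to the stimulus itself, so predicted bias is zero
there. Negative stimuli are evaluated through the model's exact mirror
symmetry, making predicted curves antisymmetric by construction and
halving the computation.

`fit_sigma_prior()` minimizes the sum of squared bias residuals over a
0.5° scan of σ_prior (default range 5–120°), then refines by
golden-section search in the bracketing interval. Because predictions are
independent of the observed data, `sigma_prior_scan()` precomputes the
prediction table once and makes Monte-Carlo recovery studies cheap. R² is
reported about the mean observed bias (the about-zero variant is also
returned); it can be negative, and a fit at the scan boundary is flagged
rather than silently returned — a flat observed curve, for instance,
legitimately drives σ_prior to the top of the range with R² = 0.
Noiseless parameter recovery is exact at scan-grid points; narrower priors
monotonically produce larger peak predicted bias, which is what makes the
one-parameter fit well-posed.

## Comparison statistics

Cross-task and model-versus-data comparisons use Spearman rank correlation
(average ranks; two-sided p from the large-sample approximation), a type
II regression slope for errors-in-both-variables data — realized as the
standardized major axis, $\mathrm{sign}(r)\,s_y/s_x$, which is symmetric
under axis exchange; the major-axis variant is a flag — and
$R^2 = 1 - SS_{res}/SS_{tot}$ against an external prediction. The 0° and
180° headings, unbiased by symmetry, are excluded from correlations by a
caller-side filter.

## What the generators emulate, and what they do not

Simulated identification observers compose a deterministic bias function
(default 6 sin 2θ: overestimation forward, underestimation backward, zeros
at 0/±90/180, 6° peaks — the magnitude of the largest observed biases)
with wrapped-normal response noise and a uniform lapse process. Simulated
2AFC observers are exactly cumulative-Gaussian. Real observers are
messier: left/right asymmetries (observed vestibular biases are asymmetric
backward), response-device attraction to dial reference marks, adaptation
across repeated same-direction movements, and oblique effects in
variability are all absent. Passing tests therefore demonstrate that the
*analysis machinery* is correct and that the models behave as designed —
not that real behavioral data follow the generating forms.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use desk-scale problem sizes
chosen to make Monte-Carlo tolerances meaningful at interactive runtimes:
500 seeded blocks per staircase rule for convergence points, 200 seeds for
PSE/JND recovery, 25 seeds per generating σ_prior (at four values) for
noisy prior recovery with a precomputed scan table, and 10⁴-unit
populations for uniform-decoding checks. The full suite runs in well under
a minute of compute-dominated time.

## Known limitations

- The degree-12 interpolation is faithful to the original analysis but is
  a global polynomial: it cannot be evaluated outside the sampled range
  and will ring if headings are sparse. A periodic (Fourier) fit would be
  the natural alternative.
- The reversal-average PSE inherits the small asymmetric-rule offsets of
  transformed staircases (order half a step for 2U1D/1U2D); the
  psychometric fit does not, which is why both are provided.
- The Bayesian observer is deterministic (MAP of a noiseless internal
  representation); it predicts bias, not trial-to-trial variability.
- Likelihood-SD tables and the afferent elevation/sensitivity/resting
  ranges are plausible defaults, not fitted quantities; conclusions that
  depend on their exact values should treat them as free configuration.
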