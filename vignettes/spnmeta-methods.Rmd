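---
title: "Models and methods behind spnmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spnmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spnmeta)
```

This vignette is the package's own account of the statistical machinery: the
models it fits, the conventions it fixes where the field leaves choices
open, what the synthetic catalogue does and does not emulate, and the known
limitations of each method.

## The measurement model

The unit of analysis is a *condition-averaged epoch*: one matrix of
electrodes × time samples (microvolts) per participant and condition,
time-locked to stimulus onset. Epochs default to −200…2000 ms at 128 Hz
(282 samples) with a −200…0 ms baseline. The SPN for one participant is the
regular-minus-random difference of windowed cluster means, so a genuine SPN
is negative.

Two conventions are fixed once and used everywhere:

* **Windows are half-open** `[start, end)` in ms, mapped to 0-based samples
  by `ceil((t − epoch_start)·rate/1000)`. For a −200 ms epoch at 128 Hz the
  canonical 300–1000 ms window selects samples 64…153 (90 samples). Half-open
  windows are idempotent under concatenation — `[300,650)` and `[650,1000)`
  tile `[300,1000)` without overlap — which closed windows are not.
* **Cluster means are plain arithmetic means** over the electrode subset,
  and peak/trough amplitudes are extrema of the cluster-averaged waveform
  (not means of per-electrode extrema). Both are the standard ERP
  conventions and are deterministic. When a bilateral cluster has unequal
  hemisphere sizes the mean still weights electrodes, not hemispheres,
  equally.

Per-experiment summaries report mean, SD, SE, Cohen's
$d_z = \bar{x}/s$ (SD with denominator $n-1$), $t = \bar{x}/(s/\sqrt n)$
with $n-1$ df, the two-tailed p against zero, and the *directional
proportion*: the fraction of participants with difference < 0. Exact zeros
count as non-directional, which is the conservative choice for the binomial
sign-test analysis downstream.

## The montage

Electrode positions are idealized unit-sphere coordinates for the standard
64-channel (Biosemi/10-05 naming) cap, shipped as a plain TSV. Adjacency is
great-circle distance ≤ a threshold, default 0.63 rad. The threshold was
chosen under two constraints: the median neighbour count should sit in the
6–8 range typical of published EEG adjacency definitions, and the canonical
bilateral posterior cluster PO7/O1/O2/PO8 should be *connected* — O1 and O2
sit 0.628 rad apart across the midline, so any threshold below that splits
bilateral occipital activity into two spatial components and a
spatio-temporal cluster can never span both hemispheres without a bridging
electrode. At 0.63 the median degree is 8, inside the target band.

## The synthetic catalogue generator

The generator produces stage-v data — trial-averaged condition epochs — not
raw EEG. Its defaults encode the study conditions the analyses assume:

* experiments per catalogue: 40; participants per experiment uniform on
  12–48; two conditions (regular, random) per participant;
* expected grand-average amplitude from the two-predictor regression
  `0.071 − 1.669·W − 0.416·Task` (µV), with W uniform on [0,1] and Task
  Bernoulli(½); a `Normal(0, 0.75)` between-experiment residual leaves the
  predictors explaining roughly a third of amplitude variance;
* per-participant true amplitudes `Normal(true, between_sd·(1+h·|true|))`
  with `between_sd = 1.6` µV and `h = 0` by default (setting `h > 0`
  recreates the curvature of the amplitude→effect-size relationship, since
  stronger SPNs then carry proportionally more between-subject spread);
* waveforms: P1 as a +5 µV Gaussian bump at 110 ms and N1 as −8 µV at
  170 ms (widths 25 ms), magnitudes echoing typical posterior grand
  averages; the sustained negativity as a plateau over 250–1000 ms with
  50 ms raised-cosine edges; all components scaled by a posterior
  topography (weight 1 at PO7/O1/O2/PO8, Gaussian falloff in great-circle
  distance, scale 0.5 rad);
* measurement noise: independent Gaussian per sample and electrode at the
  condition-average level with SD `noise_sd/√n_trials` (defaults 1 µV and
  60 trials — the typical per-condition trial count);
* publication: `P(published) = logistic(−2·(amplitude + 1))`, i.e. stronger
  SPNs are likelier to be flagged published, centred near the catalogue-scale
  mean amplitude of about −1 µV.

The SPN template is normalized so that its mean over the calibration
cluster and window is exactly 1; an injected amplitude is therefore
recovered *exactly* by windowed extraction when noise is zero. This is what
makes generator truth usable as a test oracle.

Randomness uses one root seed; each experiment gets a deterministically
derived child seed, so generating a 40-experiment catalogue and a
4-experiment catalogue with the same root seed produces identical early
experiments.

What the generator does **not** emulate: temporal autocorrelation and 1/f
structure of real EEG noise, artifacts and their removal, volume-conduction
correlations beyond the shared topography, non-Gaussian between-participant
distributions, and laterality differences. Tests passing on synthetic
catalogues therefore validate the *statistical machinery* under its stated
assumptions, not the preprocessing pipeline of any real dataset.

## Power, sample size, sign tests

Power of the one-sample (paired) t-test is computed exactly from the
noncentral t distribution: ncp $= |d|\sqrt n$, df $= n-1$, both rejection
regions for two-tailed tests. The minimal-n solver brackets by doubling and
bisects (power is monotone in n), and asserts the boundary property
`power(n) ≥ target > power(n−1)` before returning. Two anchors worth
stating: $d = 0.469$ needs $n = 38$ for 80% power and gives 60% at
$n = 24$; $d = 0.4$ needs $n = 52$.

The binomial sign-test threshold is the smallest k with
$2\,P(X \ge k) \le \alpha$ for $X \sim \mathrm{Bin}(n, \tfrac12)$ —
the tail-doubling convention, which yields 18/24 and 32/48 at the 5% level.
The "exact" small-p two-tailed convention is exposed as an option; for a
symmetric null the two coincide.

The amplitude→effect-size map is an ordinary least squares quadratic
$\hat d = a x^2 + b x + c$. The quadratic captures the empirical
levelling-off of $d_z$ for strong SPNs (if between-subject SD grows with
amplitude, $d_z = \mu/\sigma(\mu)$ is concave in $\mu$). It is descriptive;
extrapolation beyond the fitted amplitude range is unreliable, which is why
required-N tables warn rather than refuse outside it.

Observed ("post-hoc") power of repeated-measures ANOVA effects uses the
noncentral F with ncp $= F \cdot df_1$ at $\alpha = .05$ — the convention
of common statistical packages. It is a monotone transform of the p-value
and is reported as a descriptive screening quantity, never as an inference.
Sphericity corrections are not applied by default.

## Publication-bias diagnostics

Group contrasts use Welch's t (equal variances not assumed, Satterthwaite
df) plus Mann-Whitney. Meta-analytic pooling is DerSimonian–Laird
random-effects (via `metafor::rma`, method `"DL"`): moment-based τ²,
weights $1/(se_i^2+\tau^2)$, normal-theory CI. Funnel asymmetry is Egger's
classic regression of the standardized effect on precision, with a t-test
on the intercept; Egger's test is known to be mildly anti-conservative,
and the package's validity tests allow up to a 10% type-I rate at nominal
5%. Cumulative distributions use per-study t critical values for the CI
bands (the choice between t and normal bands is unstated in common
practice; t is the conservative one), and the CI-excludes-zero criterion is
exactly the two-tailed t-test at 5%.

## The spatio-temporal cluster permutation test

The test makes no electrode or window selection. At every
(electrode, sample) point a one-sample t is computed across participants'
difference waves. Points with $|t|$ at or above the two-tailed critical
value at the cluster-forming level (default .05, df $= n-1$) are grouped
into connected components under the relation: same electrode and
$|\Delta \text{sample}| = 1$, or same sample and montage-adjacent
electrodes. No temporal gap-bridging. The cluster statistic is the mass
$\sum t$; alternatives (extent, max) are deliberately not implemented.

The null distribution flips the sign of each participant's whole difference
wave — exchangeable under the null of no condition difference — and records
the maximum positive mass and maximum |negative| mass per permutation,
separately, so each sign is tested against its own null. The p-value is
$(\#\{\text{null} \ge \text{observed}\} + 1)/(B + 1)$, which is valid and
bounded below by $1/(B+1)$. Permutations are seeded and chunked; the
per-permutation t-field costs one matrix product because the pointwise sum
of squares is sign-flip invariant.

"Most significant negative cluster" means: among negative clusters with
p < .05, the largest |mass|; ties break by earliest onset sample, then
lexicographic electrode label, making extraction deterministic.

**A caution on re-extracting amplitudes from detected clusters.** The
data-driven SPN takes the cluster's member electrodes and its sample span
as a rectangle and re-runs windowed extraction there. Cluster boundaries
are not measurements: at the default forming threshold, any zero-signal
electrode bordering a strong cluster has, say, 90 member samples × 2.5%
pointwise chances to contribute a supra-threshold point and join, so
detected clusters systematically accrete low-signal electrodes and the
rectangle mean *understates* the true amplitude (in simulations with a
confined −3 µV source, by a factor of two or more). With a strict forming
threshold (e.g. .001) accretion is negligible and planted amplitudes are
recovered within a few percent. This mirrors the general warning that
cluster-based inference licenses claims about the existence of an effect,
not about its precise spatial extent — and is one reason data-driven
amplitudes correlate with, but sit below, a priori cluster amplitudes.

## Vibration analysis

Every experiment is recomputed over the named clusters plus its own
original cluster, with a shared window, and two-tailed 5% significance is
tallied per cluster. Homogeneity of the counts is Pearson's chi-square
without continuity correction (the correction is exposed as an option);
cross-cluster agreement is the Pearson correlation of per-experiment mean
amplitudes. On catalogues with smooth posterior topography these
correlations exceed .99, so a low correlation on real data is informative
about topographic heterogeneity, not a package artifact.

## Numerical and degenerate-input choices

* Zero-variance difference vectors raise a "degenerate sample" error rather
  than returning infinite t — silent infinities would propagate into
  meta-analysis weights.
* The repeated-measures ANOVA returns F = 0, p = 1 when both the condition
  and residual sums of squares are numerically zero (conditions identical
  per participant), and errors when residual variance alone vanishes.
* Catalogue serialization writes 10 significant digits; a load/save cycle
  is byte-stable after the first round trip.
* The permutation t-field clamps tiny negative variances (floating-point
  cancellation) to zero and maps 0/0 points to t = 0.

## Problem sizes used in the shipped tests

The validity simulations run at deliberately modest sizes chosen to give
stable verdicts: type-I control of the cluster test uses 200 null datasets
(n = 12, the 16-electrode posterior subset, 282 samples, 500 permutations);
the analytic-vs-Monte-Carlo power grid uses 10⁵ replicates per (d, n) cell;
DL coverage uses 500 meta-analyses of 40 studies, matching the
catalogue-scale strata the estimator is meant for; parameter-recovery
catalogues use 8–30 experiments. Integration tests use 4–12 experiment
catalogues with 3–12 participants each.

## Known limitations

* The generator's noise is white; methods whose calibration depends on
  temporal autocorrelation (e.g. cluster extent under smoothed noise) are
  exercised only under the white-noise null.
* Between-subject designs, >2-condition a priori power, trim-and-fill and
  selection models, TFCE, and frequency-domain clustering are out of scope.
* The W-load predictor is an input metadata field; the package does not
  compute perceptual-goodness weights from stimuli.
* Reported observed power is descriptive; planning should use the
  prospective noncentral-t functions.
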