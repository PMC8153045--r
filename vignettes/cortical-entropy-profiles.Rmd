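---
title: "Cortical entropy profiles: model, pipeline and design choices"
author: "cortexEntropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical entropy profiles: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexEntropy)
```

# The measure

`cortexEntropy` quantifies the temporal complexity of parcellated
resting-state brain signals with *dispersion entropy*: the Shannon entropy of
the empirical distribution of symbolic "dispersion patterns". A signal
$s_1,\dots,s_T$ is first standardized by its own mean $M$ and standard
deviation $D$ and pushed through the normal CDF,
$\theta_i = \Phi\!\big((s_i - M)/D\big)$, then quantized into $c$ classes,
$z_i = \mathrm{round}(c\,\theta_i + 0.5)$, clamped to $[1, c]$. Windows of
$m$ labels spaced $\tau$ samples apart (consecutive windows advancing by one
sample) form the patterns, and

$$\mathrm{EN} = -\sum_k p_k \log p_k \in [0,\ \log c^m]$$

with natural logarithms, where $p_k$ is the relative frequency of pattern
$k$. The estimator is $O(T)$, robust to moderate noise, and — because $M$ and
$D$ rescale with the signal — exactly invariant under positive affine
transforms of the input. Throughout the package the default setting is
$c = 3$, $m = 2$, $\tau = 1$ (`DispersionParams()`), giving a ceiling of
$\log 9 \approx 2.197$ nats that is approached by white noise. The ROI
ranking of entropy profiles is insensitive to this choice
(`rankStability()`), which is why a single fixed setting is defensible.

Two conventions are deliberately pinned down and tested:

* **Standard deviation**: the sample convention ($n-1$), matching R's `sd()`
  and the reference implementations of dispersion entropy in the time-series
  literature.
* **Rounding**: half-away-from-zero, with labels clamped to $[1, c]$ to guard
  the $\theta \to 1$ float edge. Internally the quantization is evaluated by
  comparing standardized values against $\Phi^{-1}(k/c)$ thresholds, which is
  algebraically identical and avoids evaluating $\Phi$ per sample.

A constant signal has undefined standardization and raises an error rather
than silently returning zero.

# From runs to profiles

The study design the package emulates has two sessions (REST1, REST2) of
two runs each, with roughly 1200 samples per run. Entropy is computed per
run and averaged within a session (`entropyProfiles()`); the two session
matrices are averaged element-wise (`sessionAverage()`) where a single
profile per subject is needed (prediction, structure analyses). Averaging
runs rather than concatenating them keeps each entropy estimate within a
stationary stretch of signal; a different aggregation can be obtained by
assembling profiles from single-run `RoiTimeSeries` objects if needed.
Profiles live in an `EntropyProfiles` container (a `SummarizedExperiment`
with one ROI-by-subject assay per session), so parcellation metadata travels
with the values.

# Fingerprinting and differentiation power

Identification treats one session's profiles as a database and the other
session's as targets: a target subject is predicted to be the database
subject with the maximal Pearson profile correlation
(`identifyProfiles()`). `fingerprintTest()` runs both directions, builds a
permutation null by shuffling target identities (500 permutations per
direction, pooled to 1000), and reports the probability of a null accuracy at
least as large as the observed one. Because the two directions share one
pooled null but have two observed accuracies, the single reported p-value is
the larger (more conservative) of the two per-direction values. Chance-level
accuracy is routinely "significant" at large $N$, so a fixed 60% accuracy
criterion is additionally exposed: only identification above it is treated as
satisfactory.

Differentiation power (`differentiationPower()`) decomposes the Pearson
similarity into per-ROI products of z-scored profiles
$\varphi_{ij}(n) = z^{d1}_i(n)\, z^{d2}_j(n)$ — z-scored per subject across
ROIs, the decomposition that makes the sum of products equal the correlation
— and asks how often a cross-subject product beats the within-subject one:
$P_i(n)$, estimated with strict inequalities over both orderings, and
$\mathrm{DP}(n) = -\log \overline{P_i(n)}$. The mean (rather than sum) form
shifts every ROI by $\log N$ and leaves the ranking unchanged; when
$\overline{P}$ is exactly zero it is replaced by $1/(2N(N-1))$, the smallest
attainable nonzero value, keeping DP finite.

# Reliability screening

Per-ROI test–retest reliability is the cross-subject Pearson correlation of
entropy between sessions. Entropy is a randomness measure and saturates on
noise, so low reliability coupled with ceiling entropy marks ROIs whose
signal is noise-dominated. The screen (`flagUnreliableRois()`) flags an ROI
only when **both** hold: reliability below the 5th percentile of the
empirical reliability distribution, and grand-mean entropy above the 5th
percentile of a permuted-signal null (`permutedEntropyNull()`: each
first-session run shuffled once per subject and ROI, entropy recomputed
through the same run-averaging path). "Fifth quantile" is implemented as the
type-7 percentile (linear interpolation between order statistics), fixed by
tests. The grand-mean entropy uses both sessions and all subjects while the
null uses session 1 only — an asymmetry kept deliberately because the two
quantities play different roles (a stable per-ROI location versus a null
distribution). Flagged ROIs are removed from all downstream
reliable-profile analyses.

# Predicting cognition

Cognitive factor scores (a general factor plus visuospatial, crystallized,
memory and speed facets) are predicted from session-averaged reliable
profiles by closed-form ridge regression,
$\tilde b = (X^\top X + \lambda I)^{-1} X^\top y$, under leave-one-family-out
cross-validation: all siblings form one held-out fold, so kinship never
straddles the train/test split. Inside each training fold the predictors and
the outcome are z-scored (test predictions are mapped back through the
fold's moments); optional correlation-based feature screening is available
but off by default, since its effect on accuracy is erratic. The penalty is
selected from a logarithmic grid $10^{-2},\dots,10^{5}$ as the value
maximizing the correlation between observed and out-of-fold predicted
scores. That selection reuses the correlation it reports, so the reported
accuracy carries a mild optimism; this mirrors the stated selection procedure
and is documented rather than corrected. A negative observed–predicted
correlation carries no predictive meaning and is clamped to zero; the
unclamped value, its $t$-based p-value and a subject-resampling bootstrap CI
are returned alongside. Per-ROI importance is summarized by the mean
absolute standardized coefficient across folds, and per-network predictions
repeat the fit on each network's ROIs with Benjamini–Hochberg correction
across the network-by-outcome family.

# Structural basis: blueprint versus fingerprint

Directed connective probabilities are symmetrized by reciprocal averaging
$w_{ij} = (p_{ij} + p_{ji})/2$ and thresholded at $w_{ij} = 0.001$ (roughly
10% link retention on realistic matrices); node strength is the row sum and
degree the suprathreshold link count (`symmetrizeThreshold()`,
`nodeMetrics()`).

Two complementary questions are asked of the structural data. The
*blueprint* question correlates group-mean entropy with group-mean structural
properties across ROIs (`blueprintCorrelations()`; bootstrap CIs resample
ROIs, the observation unit of that correlation). The *fingerprint* question
asks whether individual deviations in structure explain individual deviations
in entropy: per-ROI cross-subject correlations
(`regionalStructureCorrelations()`; bootstrap over subjects) and, more
stringently, `structureToEntropyPrediction()`: per-ROI univariate OLS maps
one structural property to entropy under LOFOV, the out-of-fold regional
predictions are assembled into predicted profiles, and the predicted set
serves as the database for fingerprint identification of the observed
profiles. High per-subject similarity arises from blueprint tracking alone;
identification specificity above 60% (with a 1000-permutation p-value)
requires genuinely individual structural information. One property is
modelled at a time because the per-property read-outs are the scientific
quantity of interest; a joint model would blur the attribution.

# The synthetic cohort generator

Every analysis stage is exercised on cohorts with known ground truth
(`generateCohort()`). The generator is the package's definition of the study
conditions, not a tuning knob; its defaults are fixed once and the tests
inherit them.

* **Signals.** Each subject-by-ROI signal is a stationary AR(1) process with
  unit-variance innovations, fresh innovations per run, and a session-level
  Gaussian jitter on the AR coefficient shared by a session's runs. AR(1) is
  the minimal stationary process with a scalar irregularity knob; dispersion
  entropy is strictly decreasing in the coefficient (a tested invariant), so
  "irregularity" maps monotonically to entropy. The baseline coefficient is
  0.3, a realistic lag-1 autocorrelation for high-pass-filtered fast-TR
  fMRI.
* **Latent irregularity.** A latent field $a_{i,n}$ combines (i) a cross-ROI
  blueprint driven by standardized structural blueprints through signed
  couplings (thickness positive; myelin, curvature, sulcal depth,
  connectivity strength and degree negative), (ii) individual structural
  deviations through a second set of couplings (myelin, curvature and sulcal
  depth by default — the properties that should carry fingerprint
  information), (iii) shared latent factors with a geometrically decaying
  spectrum (15 factors, decay 0.85), and (iv) an idiosyncratic term. The
  decaying spectrum mirrors the fast-decaying eigenspectra of individual
  differences in real neuroimaging features and makes a small number of
  modes carry most shared variance. The AR coefficient is a logistic squash
  of $-a_{i,n}$ into $(0, 0.95)$.
* **Noise ROIs.** A configurable fraction (default 5%) of ROIs — placed in
  the limbic-like network first, mirroring where fMRI signal quality is
  poorest — are i.i.d. white noise in every run with no subject effect:
  ceiling entropy, near-zero reliability.
* **Families.** Family sizes 1–3 (probabilities 0.55/0.30/0.15); siblings
  share half the variance of the shared individual components.
* **Connectivity.** Per-subject directed probabilities follow a
  propensity-weighted dense random graph with log-normal weights, calibrated
  per subject so that symmetrization and thresholding at 0.001 retains ~10%
  of links; node strength and degree computed from these matrices (through
  the same code path the pipeline uses) are the connectivity entries of the
  structural profiles, keeping generator and pipeline self-consistent.
* **Cognition.** Each outcome loads on the expected entropy profile through
  a weight vector built from the leading three latent factors, with Gaussian
  noise calibrated so the population $R^2$ matches the configuration
  (default 0.30 for the general factor). Cognition loading on the dominant
  modes of brain variance is both realistic and what makes the planted
  $R^2$ recoverable at a few hundred subjects.
* **Session jitter 0.04** puts per-ROI test–retest reliability near 0.7,
  typical of regional resting-state entropy measures.

What the generator does *not* emulate: hemodynamic convolution, spatial
autocorrelation between ROIs' signals, head motion, scanner drifts, or
non-Gaussian marginals. Tests passing on these cohorts therefore validate
the statistical machinery and its calibration, not robustness to fMRI
artefacts — on real data the preprocessing stack carries that burden.

# Numerical and design notes

* Percentiles everywhere use R's type-7 convention (linear interpolation).
* Similarity ties in identification break towards the lowest subject index
  with a warning; ties have measure zero on continuous data.
* Bootstrap intervals are percentile intervals (2.5/97.5); a statistic
  failing on a resample triggers a redraw with a warning. The
  identification-accuracy bootstrap resamples target subjects.
* Ridge with $\lambda = 0$ reduces exactly to OLS and raises an informative
  error on singular systems.
* ROIs whose training-fold standard deviation is zero are mapped to zero
  predictors (prediction) or predicted by the training mean (per-ROI
  structure regressions), each with a warning.
* All randomness flows through R's RNG: one seed makes cohorts, permutation
  nulls, bootstraps and the full pipeline byte-reproducible. The pipeline
  writes no timestamps into its reports for the same reason.

# Problem sizes used in the validation suite

The test suite exercises the pipeline at sizes where its statistical claims
are sharp but cheap to compute: oracle checks on 1200-sample signals;
identification on cohorts of 50 subjects; the noise-ROI screen and the
reliability attenuation law on 200 subjects and 100 ROIs; planted-$R^2$
recovery on 20 cohorts of 300 subjects; the structural dissociation on 100
subjects. These sizes are the package's validation design; the functions
themselves are agnostic to cohort size.

# Known limitations

* Run-to-session aggregation is fixed to run averaging; concatenation is not
  offered because entropy of concatenated runs mixes within-run dynamics
  with between-run level shifts.
* The permutation null for identification shuffles target identities against
  fixed predictions; it does not re-run profile matching per permutation
  (the similarity matrix is permutation-invariant, so this is exact and
  fast).
* The ridge path recomputes fold moments per penalty grid point from cached
  cross-products; for very large ROI counts a specialised solver would be
  preferable.
* Factor-score estimation for the cognitive battery is upstream of this
  package: scores arrive as data.
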