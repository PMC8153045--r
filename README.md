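# cortexEntropy

Individual cortical entropy profiles from parcellated resting-state time
series: test–retest reliability screening, fingerprint identification,
prediction of cognitive ability, and the structural basis of regional
entropy.

## The problem

The irregularity of spontaneous brain activity — quantified by entropy — is
an individual trait: each person's vector of per-region entropies (their
*entropy profile*) is stable across scanning sessions and differs between
people. Working with such profiles raises four linked questions that this
package answers as a single tested pipeline:

1. **Is the profile reliable?** Entropy saturates on noise, so regions with
   noise-dominated signal must be detected and excluded before any
   individual-differences claim.
2. **Is it person-specific?** Can a subject be identified across sessions by
   matching profiles, and which regions carry the identifying information?
3. **Is it cognitively meaningful?** Does the profile predict cognitive
   factor scores in held-out individuals?
4. **Where does it come from?** Which structural properties explain the
   *blueprint* (the cross-region shape of the group-mean profile) versus the
   *fingerprint* (individual deviations from it)?

## The measure and the models

Dispersion entropy of a signal $s_1,\dots,s_T$: standardize by the signal's
mean and SD, map through the normal CDF
$\theta_i = \Phi\big((s_i - M)/D\big)$, quantize to $c$ classes
$z_i = \mathrm{round}(c\theta_i + 0.5)$, collect patterns of $m$ labels
spaced $\tau$ samples apart, and take the Shannon entropy of the pattern
frequencies, $\mathrm{EN} = -\sum_k p_k \log p_k \in [0, \log c^m]$ (nats;
defaults $c=3, m=2, \tau=1$).

Downstream: fingerprint identification by maximal Pearson profile
correlation with a permutation null and per-ROI differentiation power
$\mathrm{DP}(n) = -\log \overline{P_i(n)}$; a two-threshold unreliable-ROI
screen (5th-percentile reliability AND entropy above the 5th percentile of a
permuted-signal null); closed-form ridge regression
$\tilde b = (X^\top X + \lambda I)^{-1} X^\top y$ under leave-one-family-out
cross-validation; and per-ROI structure→entropy regressions whose
identification specificity separates blueprint from fingerprint
contributions. A synthetic cohort generator with known ground truth (AR(1)
signals whose coefficient is a logistic squash of a latent irregularity
field coupled to structural properties) makes every stage testable without
restricted data. The methods vignette
(`vignettes/cortical-entropy-profiles.Rmd`) documents all models,
conventions and design choices.

## Worked example

```r
library(cortexEntropy)

co <- generateCohort(cohortConfig(nSubjects = 50), seed = 11)
ep <- entropyProfiles(co@timeseries, parcellation = co@parcellation)
d1 <- profileMatrix(ep, "REST1")
d2 <- profileMatrix(ep, "REST2")

fingerprintTest(d1, d2, nPerm = 500, seed = 3)
#> FingerprintResult
#>   R1->R2: accuracy 100.00% [100.00%, 100.00%], satisfied: TRUE
#>   R2->R1: accuracy 100.00% [100.00%, 100.00%], satisfied: TRUE
#>   permutation p = 0 (1000 permutations pooled)

fit <- lofovPredict(sessionAverage(ep), co@scores$g, co@scores$family_id,
                    seed = 4)
fit
#> LOFOV ridge prediction: accuracy r = 0.463 (raw 0.463), p = 0.000703,
#>   lambda = 100, 38 families
```

Every subject is re-identified across sessions from their entropy profile
alone (chance is 1/50 = 2%), and the permutation null never reaches the
observed accuracy. The general-ability score of held-out families correlates
r = 0.46 with its ridge prediction, against a planted population ceiling of
√0.3 ≈ 0.55.

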