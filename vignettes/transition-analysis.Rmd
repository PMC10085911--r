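---
title: "Transition analysis for clavicle-based forensic age estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition analysis for clavicle-based forensic age estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossage)
library(dplyr)
```

## The problem

Forensic age assessment of living individuals turns on legal thresholds —
most often 18 years. Once the hand skeleton is fully developed, the
ossification state of the medial clavicular epiphysis is the standard
skeletal marker for the late-teens/early-twenties window. The epiphysis is
staged on the 5-stage Schmeling scheme refined by the Kellinghaus
substages, giving the ordered 9-level scale

> 1 < 2a < 2b < 2c < 3a < 3b < 3c < 4 < 5,

from "ossification centre not ossified" through progressive
epiphyseal-metaphyseal fusion to full fusion with (stage 4) and without
(stage 5) a visible epiphyseal scar. Clavicles that cannot be staged —
motion artefacts or anatomical shape variants such as fish-mouth-like
depressions — are marked *not evaluable* (`NE`) and excluded.

The naive approach — report the empirical age range observed per stage —
inherits the age composition of the reference sample: if the sample
over-represents 18-year-olds, every stage's "typical age" is dragged
toward 18. This *age mimicry* is the motivation for **transition
analysis**: model the stage-given-age process, which is a property of
human maturation rather than of the sample's age structure, and invert it
into age-given-stage statements.

## The model

Stage groups are a coarsening of a latent developmental scale. With
groups $j = 1, \dots, J$ and cutpoints
$\tau_1 < \dots < \tau_{J-1}$, the cumulative probit model is

$$ P(\text{group} \le j \mid a) = \Phi\!\big(\tau_j - \beta\, t(a)\big), $$

where $t(\cdot)$ is an age transform and $\beta > 0$ the slope tying
development to age. Category probabilities are successive differences of
these curves and sum to one at every age. The *mean transition age*
between groups $j$ and $j+1$ is $t^{-1}(\tau_j / \beta)$.

Because substages 2a–c are rare and stage 5 scarce below 25 years, the
model is fitted on collapsed groups **1, 2, 3a, 3b, 3c, 4/5** — the
collapsing is total and order-preserving, and happens only at the
transition-analysis boundary; the side-comparison and agreement analyses
stay on the full 9-level scale.

### Estimation choices

* **Age transform.** Default `log`: development is relatively faster at
  younger ages, and the log transform is the standard choice in the
  transition-analysis literature. `identity` is available via the
  `transform` argument; all reported ages are back-transformed to years.
* **Parameterisation.** The optimiser works on
  $(\tau_1, \log \text{gaps}, \log \beta)$, so cutpoint ordering and slope
  positivity hold by construction without constrained optimisation.
* **Starting values.** Cutpoints from probit-transformed empirical
  cumulative group frequencies anchored at the mean transformed age;
  $\beta = 1$.
* **Convergence.** BFGS with an analytic gradient, then Newton polishing
  until the gradient max-norm is below $10^{-6}$, with three
  deterministic perturbed restarts before a fit is declared unconverged.
  Near-deterministic data (complete separation) are caught by a
  parameter-magnitude guard and flagged with a warning rather than
  failing silently.
* **One latent scale.** A single common slope is fitted
  (homoskedastic latent scale); the Lagrange-multiplier fit test below
  probes exactly this restriction.

### Fit diagnostics

`lm_fit_test()` is a score test evaluated at the restricted MLE of the
relaxed alternative $P(\text{group} \le j) = \Phi(\tau_j - \beta_j t(a))$
with one slope per cutpoint; under the common-slope restriction the
statistic is asymptotically $\chi^2_{J-2}$. The alternative hypothesis of
the published test is not documented anywhere we could follow, so this
package's choice — the standard non-proportionality relaxation — is its
own, stated design decision. `pseudo_r2()` is the Cragg–Uhler value
$[1 - (L_0/L_1)^{2/n}] / [1 - L_0^{2/n}]$ against the intercept-only
(marginal multinomial) model.

## From model to age statements

For each stage group the **normed likelihood curve** is
$L_j(a) = P(j \mid a)$ over a fine age grid, divided by its maximum, so
every curve peaks at exactly 1. Then:

* the **point prediction (MLA)** is the curve's argmax. The lowest and
  highest groups have no interior maximum — their curves are monotone —
  so their MLA is substituted by the sample minimum and maximum age and
  flagged `terminal`;
* the **95 % prediction interval** collects ages with normed likelihood
  at or above `normed_threshold(0.95)` $= e^{-\chi^2_{1,0.95}/2} =
  0.1465$ (Wilks inversion), with the grid crossing refined by linear
  interpolation and terminal ends clipped to the sample age range;
* **minor/adult classification** applies the point rule: adult iff
  MLA $\ge 18.0$ years. The tie at exactly 18.0 counts as adult — the
  boundary convention is ours and is stated here because no standard
  fixes it. Accuracy, specificity (correctly classified minors) and
  sensitivity (correctly classified adults) are reported as percentages;
  a component undefined for the sample (no minors, or no adults) is
  reported missing, never as zero.

The default age grid runs over the sample age range in steps of 0.01 y —
fine enough that the argmax error is an order of magnitude below the 2-dp
reporting precision (a refinement-stability test asserts this).
The curve is a pure likelihood: no age prior enters, so the machinery
stays free of the reference sample's age composition.

## Multi-rater staging and agreement

The final stage of each clavicle is a **majority vote** of three blinded
raters, with `NE` counting as an ordinary vote category (two `NE` votes
exclude the clavicle, not the subject). When all three raters disagree,
the adjudicating third rater re-evaluates the case knowing all
assignments; in this package that re-evaluated stage travels in the
`adjudicated_stage` input column, keeping the pipeline deterministic.

Agreement is quantified with the usual chance-corrected panel:
unweighted Fleiss' kappa over all clavicles with `NE` as a tenth
category; linearly weighted Fleiss' kappa (the mean-pairwise-weighted
generalisation, each pairwise sub-computation coinciding with weighted
Cohen agreement) over clavicles staged by all three raters; ordinal
Krippendorff's alpha, whose coincidence-matrix construction handles
missing ratings natively; and pairwise linearly weighted Cohen's kappa
per rater pair. Weighted schemes require the ordinal scale and therefore
exclude `NE`. The ordinal difference function is the default for alpha
because the staging scale is ordered; nominal is available.

## Side comparison

Left-right concordance partitions subjects with both sides staged by the
absolute rank difference on the **full 9-level scale** (a substage step
counts as one step — the source material does not state its convention,
so ours is explicit). A paired Wilcoxon signed-rank test on the stage
ranks probes for a systematic developmental lead of one side; zero
differences are dropped (classic Wilcoxon). With concordance near 80 %
most pairs are ties, so the zero-handling convention materially affects
the effective sample — which is why it is stated and tested.

Quartiles in the descriptive table use R's default type-7
linear-interpolation convention, exposed as `quantile_type` because
published tables rarely state theirs; this affects only the quartiles,
never the model.

## Validation designs

Seven constellations probe generalisation: 10-fold cross-validation on
the right clavicles, the left clavicles, the merged whole set (both
clavicles per subject), and the per-subject half sets carrying the more
(`halfmax`) or less (`halfmin`) advanced side; plus the two cross-side
designs (train right / test left and vice versa). Folds are assigned at
the subject level — both rows of a subject share a fold in the whole-set
design — and stratified by stage group so training folds rarely lose a
whole group; test rows whose group is absent from the training fold are
counted as skipped rather than guessed at. Absolute and squared errors
(chronological age minus MLA, with terminal substitution using the
*training fold's* age extremes to avoid leakage) are pooled across folds
into one MAE and RMSE per constellation. The final, detailed model
refits the best-performing convention — the highest reached stage per
subject — on all subjects with at least one staged side.

## The synthetic cohort generator

No raw study data accompany this package, so `simulate_cohort()` and
`simulate_raters()` generate cohorts with the statistical structure the
analysis assumes, and every module is tested against them:

* ages uniform over [13, 25) years, 338 subjects by default;
* one latent developmental value $\beta \log a + \varepsilon$ per
  subject ($\varepsilon$ standard normal, $\beta = 14$), cut at fixed
  stage-boundary ages (15.7, 16.4, 16.9, 17.1, 19.5, 21.0, 22.4,
  24.2 y) into the 9-level stage. The boundary spacing makes substages
  2a–c brief and stage 5 rare, and the implied within-stage age spread
  (roughly $a/\beta \approx 1.3$ y) matches what staging studies report;
* each side independently shifts one substage with probability 0.10,
  reproducing the ~80 % left-right concordance such cohorts show;
* 11 % of clavicles are not evaluable (3 % motion, 8 % shape variant),
  drawn at the clavicle level so the consensus exclusion fraction equals
  the target;
* each rater misreads by one adjacent substage with probability 0.55,
  drawn per (rater, subject) and applied to both sides. Two properties
  fix this design: the rate reproduces both the ~13 % three-way-split
  frequency and a moderate (~0.43) unweighted multi-rater kappa, and
  subject-level (rather than per-clavicle) errors keep the *consensus*
  left-right concordance near 80 % — with independent per-clavicle
  errors at this rate, consensus noise would push observed concordance
  toward 50 %, which real consensus data do not show. Rater perception
  bias attaching to a subject's anatomy is also what reported
  rater- and institute-dependent reading behaviour suggests;
* the intra-rater re-read's second pass perturbs the rater's own first
  impression (instability 0.15), not the truth, so intra-rater agreement
  runs above inter-rater agreement, as staging studies consistently find.

What the generator deliberately does **not** emulate: the mild
non-uniformity of real recruitment age distributions (uniform ages are
the cleaner test of age-mimicry robustness, and a non-uniform sampler
can be layered on by filtering), distant confusions (stage 1 mistaken
for 4/5 — errors are adjacent-only by default, which makes synthetic
*weighted* agreement and ordinal alpha run higher than values reported
from real readings), anatomical detail behind the `NE` label, and any
secular or population effect. Passing tests therefore certify the
statistical machinery, not the transferability of any particular fitted
numbers to a real population.

Because the three raters stay noisy after consensus (~20 % of consensus
stages sit one substage off the truth at the default confusion), narrow
groups blur: the fitted 1|2 boundary attenuates downward by up to about
a year in end-to-end runs, while wide groups' boundaries stay within a
few tenths. The integration test asserts exactly this asymmetry rather
than pretending consensus noise is free.

## A worked run

```{r example, eval = FALSE}
params <- simulation_params()
cohort <- simulate_cohort(params)
ratings <- simulate_raters(cohort, params)

consensus <- consensus_ratings(ratings)
obs <- stage_observations(consensus, cohort_subjects(cohort))

side_concordance(obs)
fit <- fit_transition_model(max_stage_observations(obs))
fit
age_predictions(fit)
autoplot(fit)
```

Problem sizes used throughout the test suite — cohorts of 150–600
subjects, 10-seed recovery batteries at $n = 600$, 500-replicate null
simulations for the score test's size, and 2000-subject coverage checks
— are the package's chosen working points: large enough that Monte-Carlo
error is small against the tolerances tested (recovery within 0.3 y,
coverage within 2 percentage points, size within the binomial band), and
small enough to re-run routinely.

## Known limitations

* The model carries age as its only covariate, one common slope and no
  bilateral random effect; sides are handled through the validation
  constellations instead.
* Prediction intervals invert a single ordinal observation through
  Wilks' theorem; their ~95 % calibration is verified by simulation
  under the model, not guaranteed by asymptotics.
* Agreement p-values use large-sample normal approximations; for very
  small tables a permutation approach would be preferable.
* Terminal stages are open-ended by construction: their point
  predictions and outer interval bounds reflect the sample's age window,
  not biology, and must be read as such in casework.
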