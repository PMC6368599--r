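---
title: "Models and methods behind comotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind comotraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hospital registries record, for millions of patients, every inpatient,
outpatient and emergency contact together with its diagnosis codes.
`comotraj` implements a population-wide, sex-stratified analysis of
disease progression on such data: how often is each diagnosis made
(incidence, standardized for age), at what age is it first made in men
versus women, which diagnosis pairs co-occur in a preferred temporal
order with an elevated risk, how do those directional pairs differ
between the sexes, and how do they chain into multi-step disease
trajectories. Because real national registries are access-restricted,
the package ships a synthetic registry generator with known ground
truth, so every stage of the pipeline can be exercised and validated
end to end without any data access.

## Preprocessing

Raw admission rows are reduced to one *first occurrence* per patient
and level-3 code. The rules, in order: inpatient records whose
admission date is at most one day after the previous discharge are
merged (ward transfers and next-day re-admissions); referral diagnoses
are dropped; codes are truncated to their first three characters;
codes from chapters 20-22 are removed; the event date is the record's
discharge date, or the date of the last recorded diagnosis for open
outpatient contacts; among several records carrying a code the
earliest assigned date wins. Dates have day resolution and all
intervals are closed; same-day pairs of diagnoses are never ordered.

Two conventions deserve note. First, when a diagnosis is only recorded
inside a merged ward-transfer chain, the merged record's final
discharge date is used (the merge yields a single record and single
date). Second, merging is applied to inpatient contacts only;
outpatient and emergency contacts are never chained.

## The incidence model

Counts per (diagnosis, ESP2013 age group, sex) stratum follow a
Poisson regression with a log link,

y_i ~ Poisson(exp(eta_i)),
eta_i = beta_0 + beta_age[g] + beta_sex * x_sex + log(offset_i),

with per-diagnosis coefficients partially pooled through half-normal
scale hyperpriors shared across diagnoses: N+(0,3) for the intercept
scale, N+(0,1) for the age scale and N+(0,0.5) for the sex scale.
The intercept together with a complete set of 21 age indicators is
redundant (only their sums enter the likelihood), so for sampling the
intercept is marginalised analytically: the 21 age-level coefficients
of each diagnosis then carry a compound-symmetry multivariate normal
prior, sigma_age^2 I + sigma_0^2 J. This is an exact reformulation,
not an approximation, and it removes a likelihood ridge that a
diagonal-metric sampler cannot traverse.

The offset is the population at risk, implemented as person-years per
(age group, sex) computed exactly from birth dates and the study
window. Person-time (rather than head counts) is what makes a
constant hazard of r events per person-year come back as an
age-adjusted rate of r, which is also how the generator's ground-truth
rates are defined.

From the posterior we form age-adjusted incidence rates per 100,000
person-years by weighting the age-specific rates with the European
Standard Population 2013 weights (21 groups summing to 100,000),
per draw, for men, women, and both ("all" uses the person-time-
weighted mix of the sex-specific rates). The sex contrast is the
relative difference d = (AIR_men - AIR_women) / mean(AIR_men,
AIR_women), a number in [-2, 2]; |d| > 0.1 flags a difference. Sex-
specific diagnoses (for instance prostate hyperplasia) are fitted in
single-sex batches without the sex term, which their design cannot
identify.

Diagnoses are fitted in batches of at most 50 with independent
hyperpriors per batch. This is a tractability deviation from a single
joint fit; the test suite verifies on a shared 20-diagnosis instance
that split fits and the joint fit agree (median absolute difference of
the sex-coefficient medians below 0.05).

## Matched-cohort co-occurrence

For an ordered pair (exposure A, event B), every patient with a first
occurrence of A is matched to up to five control patients who (i) are
in the same ESP2013 age group at their matching discharge, (ii) have a
discharge from the same encounter type, and (iii) are discharged
within three calendar months of the index discharge; the month window
is allowed to cross year boundaries, since a same-calendar-year
restriction would truncate it asymmetrically at year edges. Controls
are never diagnosed with A at any time during the observation period
-- the strictest definition of non-exposure, chosen to exclude
exposure misclassification. The control's index date is its matched discharge
date, the only anchoring event a control has. Sampling is uniform
without replacement within one exposed patient's control set and
independent across exposed patients. One matched cohort is built per
exposure code and shared by every pair using that exposure; this is a
desk-scale efficiency choice that leaves each pair's sampling
distribution unchanged while introducing benign correlation between
pairs sharing an exposure.

Exposed patients are tabulated by whether their first B falls strictly
after their first A; controls by whether their first B falls strictly
after their index date. The four cells per sex feed everything
downstream.

A cheap prescreen runs before any model fitting: the crude relative
risk RR = (n_ab/(n_ab+n_a)) / (n_b/(n_b+n_0)) with the Morris-Gardner
standard error of log RR, sqrt(1/n_ab - 1/(n_ab+n_a) + 1/n_b -
1/(n_b+n_0)). A pair continues iff any of its six interval lower
bounds (two directions, men/women/combined) strictly exceeds 1.01. No
multiplicity correction is applied at this stage, by design. A
configuration switch reproduces a plus-sign variant of the standard
error's second term for comparison with sources that print it that
way; the cited-source minus convention is the default.

## The hierarchical pair model

Each surviving (exposure, event) direction contributes eight cells
(exposure x event x sex) modelled as Poisson counts with offset equal
to the exposure-group size within sex, and a saturated coefficient
vector (intercept, sex, exposure, event and all interactions), each
coefficient pooled across the designs of a batch under a half-normal(0,2)
scale hyperprior. The exact cell/offset semantics are the main
interpretive choice in this part of the analysis: decisions are made
from posterior-predictive counts rather than from coefficients, which
makes them insensitive to the parameterization chosen. Designs
involving a sex-specific code are restricted to the affected sex and
fitted with a reduced four-cell design in separate batches, because
the missing sex's structurally empty cells would otherwise leave the
sex-interaction coefficients unidentified.

From each fitted design we simulate posterior-predictive cell counts.
Per draw:

- directionality Pr(A->B) = N_ab / (N_ab + N_ba), using the
  exposed-with-later-event cells of the two opposite designs; its
  complement is exact by construction. Draws where both counts are
  zero are skipped and counted.
- the joint relative risk combines the two sex strata with the
  Cochran-Mantel-Haenszel weighting; the per-sex relative risks use
  the single-stratum form, to which the CMH expression reduces
  algebraically when a stratum is empty.

Posterior summaries are medians with 95% highest-density intervals
(HDIs, computed by the shortest-sorted-window method). A pair is a
*directional pair* in a grouping (joint, men, women) iff the
directionality HDI excludes the region of practical equivalence
(0.49, 0.51) and the preferred direction's relative-risk HDI lower
bound strictly exceeds 1.1. The sex difference in relative risk is
the draw-wise difference RR_men - RR_women along the preferred
direction, significant iff its HDI excludes (-0.1, 0.1) -- evaluated
only when more than five men or women were observed diagnosed in the
preferred direction; otherwise the decision is withheld rather than
reported as "no difference". Direction-strength contrasts
omega_men = Pr_joint - Pr_men (and likewise for women) are summarized
per pair by their posterior medians, and the two resulting samples
across pairs are compared with a variance-ratio F test. A pair is
*reversed* when it is directional in both sexes with the two
directionality HDIs on opposite sides of 0.5.

Decisions are only issued for converged fits; non-converged batches
propagate an NA flag, never a silent summary.

## Time between diagnoses and trajectories

For directional pairs found in both sexes, the per-patient day counts
from the first to the second diagnosis (along each sex's own preferred
direction) are compared with the two-sided Mann-Whitney U test (exact
for small tieless samples, normal approximation with tie correction
otherwise), with Benjamini-Hochberg adjustment across pairs. The
effect is the difference of sample medians, women minus men, so a
negative value means the transition progresses faster in women.
The difference-of-medians was chosen over the Hodges-Lehmann estimator
as the plainer summary of an unpaired comparison.

Trajectories chain directional pairs into ordered sequences. A patient
supports a sequence iff they carry every code with strictly increasing
first-occurrence dates; support is monotone non-increasing under
extension, which prunes the depth-first search. Reported trajectories
have at least four diagnoses and strictly more than 100 supporters
(the pair-level inclusion threshold, by contrast, is at least 100
co-diagnosed patients -- both boundaries are unit-tested). Codes never
repeat within a trajectory, and the search caps trajectory length at
eight codes by default to bound the search space. Merged networks show
each directional pair once, with per-sex relative-risk medians and a
sex attribution (elevated in women / elevated in men / present in one
sex only) on the edges; GraphML export round-trips all attributes.

## Posterior computation

All Bayesian models belong to one family -- grouped hierarchical
Poisson regression -- and are fitted by a sampler written for exactly
this family:

- the coefficients are updated with the No-U-Turn sampler (the
  doubling, slice-sampling variant with dual-averaging step-size
  adaptation, target acceptance 0.8, divergence threshold of 1000 on
  the Hamiltonian error, maximum tree depth 10);
- the scale parameters are updated by exact 1-d slice-Gibbs moves on
  their full conditionals, followed by an interweaved non-centered
  re-update (holding coefficient-to-scale ratios fixed, the scale is
  slice-sampled against the likelihood and the coefficients are
  rescaled). The interweaving is what lets the sampler traverse the
  funnel that appears when a scale is near zero and many of its
  coefficients are weakly identified;
- the diagonal metric is the Poisson Fisher information: the
  likelihood part sum(x^2 mu) is evaluated at a reference point
  refreshed during warm-up, and the prior precision part is recombined
  with the current scales at every iteration. For this family each
  coefficient's conditional posterior is close to Gaussian with
  exactly this precision, so empirical variance estimation during
  warm-up is unnecessary; the metric may depend on the scales (held
  fixed during the coefficient update) without affecting validity.

Convergence is declared iff all split R-hat values are below 1.1, no
post-warmup iteration saturated the maximum tree depth, and there were
zero post-warmup divergences. Defaults are four chains with 500
warm-up and 1000 retained iterations; the internal pipeline stages use
reduced settings (250-300 warm-up, 200-500 retained) that the test
suite shows are sufficient at these problem sizes. One master seed
deterministically fans out per-chain seeds, and every stochastic stage
of the pipeline takes an explicit seed, so a full run is reproducible
bit for bit.

The conjugate Gamma-Poisson single-rate model is used as an
independent closed-form oracle for the sampler, and a coverage
experiment -- registries simulated from the incidence model's own
generative process, refitted, and scored on whether the true sex
coefficients fall inside their 95% HDIs -- provides an exact
calibration check: when the sampler is correct that coverage is 95%
by construction, averaged over the generative distribution.

## The synthetic registry

The generator emulates the structure of a national hospital registry:
patients with sex and birth dates; one admission row per diagnosis per
contact with inpatient/outpatient/emergency types; open outpatient
contacts without a discharge date; referral-role rows; seasonal
variation in admission volume; a terminology table with chapters,
sex-specific flags, chronic flags and one dagger-asterisk partnership;
and routine background contacts carrying an encounter code from
chapter 21, at a default 1.5 contacts per person-year (hospital
systems with heavy outpatient activity average well above one contact
per person-year). The background contacts matter more than they might
seem: control eligibility requires a discharge in the three-month
matching window, so at sparse contact rates the eligible controls are
selected on their own morbidity -- often anchored on the very event
diagnosis under study -- which biases the null relative risk upward.
At the default rate the null calibration of the crude relative risk
holds (the test suite checks interval coverage of 1.0 across 100
replicate null registries).

Disease events are drawn from piecewise-constant hazards per calendar
year and ESP2013 age group, scaled by a men/women rate ratio and 21
age multipliers. Default conditions are 20,000 patients followed
1994-2014 (21 calendar years, a typical national-registry span), equal
sexes, an ESP2013-shaped age structure, a 20-code panel with rates of
0.002-0.015 events per person-year, and two planted pairs: one with
relative risk 3 and a target A-first fraction of 0.8, one with
relative risk 2 and a two-fold female risk modifier. Pipeline-level
tests use 5,000-patient registries from the same process.

Planted pairs add *induced* events of the second code after the first
code's date, with probability (rr - 1) times the patient's remaining
baseline cumulative hazard, and a log-normal lag (median 180 days).
Induced events are always forward in time -- a disease-promoting
effect is -- which is what makes the matched-cohort relative risk
track the planted rr. The ordering target `direction_prob` is
optional: when set, the generator re-places a computed random subset
of co-diagnosed second-code dates so the realized A-first fraction
matches the target exactly (up to rounding); this perturbs the
realized relative risk in proportion to the adjustment, and planted
effects can also induce secondary associations in other pairs by
shifting age profiles. Recovery tests therefore use natural-direction
pairs for relative-risk checks and calibrated pairs for
directionality checks.

What the generator does not emulate: patient-level frailty (diseases
are independent given age, sex and the planted effects), death and
emigration, primary-care contacts, realistic national demography, and
coding-practice changes over time. Passing tests on synthetic data
therefore demonstrate that the statistical machinery recovers known
truth under the stated generative assumptions -- not that those
assumptions hold in any particular real registry.

## Degenerate inputs and tie-breaks

Same-day diagnosis pairs are never ordered and never counted. Zero
event cells make the crude estimate undefined and fail the prescreen.
Predictive draws with empty denominators (both order counts zero, or
a zero risk denominator) are skipped and counted. Both rates zero
makes the relative difference undefined (reported as 0 with a
warning and an NA flag). An exposed patient with no eligible controls
is excluded from that cohort and counted. The HDI of constant draws
is a zero-width interval. The ROPE comparison treats the region as
open: an interval touching the ROPE boundary excludes it, while the
relative-risk bound of 1.1 and the prescreen bound of 1.01 are
strict inequalities on the lower interval limit.

## Known limitations

Batched hyperprior pooling is an approximation to one joint
hierarchical fit (validated at desk scale, see above). The matched
cohorts reuse one control set per exposure code. The Mann-Whitney
effect is a plain difference of medians, not a paired or
Hodges-Lehmann construct. The trajectory search caps at eight codes.
Age grouping reuses the 21 standardization groups for matching, for
internal consistency. The generator's admission model attaches one
contact per disease event plus background contacts; it does not model
repeat admissions for the same condition.
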