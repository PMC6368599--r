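# comotraj

Sex-stratified temporal comorbidity and disease-trajectory analysis for
hospital registry data.

`comotraj` is for epidemiologists and biostatisticians who work with
patient-level hospital registries (one table of patients, one table of
admission rows with diagnosis codes) and want a tested, reproducible
pipeline for four connected questions:

1. **Incidence.** How often is each level-3 diagnosis made, by sex,
   standardized for age? A hierarchical Bayesian Poisson model,
   `y ~ Poisson(exp(b0 + b_age[g] + b_sex x + log offset))`, with
   half-normal scale hyperpriors shared across diagnoses
   (`sigma_0 ~ N+(0,3)`, `sigma_age ~ N+(0,1)`, `sigma_sex ~ N+(0,0.5)`),
   yields age-adjusted rates per 100,000 person-years under the
   European Standard Population 2013, and the relative sex difference
   `d = (AIR_m - AIR_f) / ((AIR_m + AIR_f)/2)` with |d| > 0.1 flagging
   a difference.
2. **Age at first diagnosis.** Welch's t test per code on the mean age
   at first occurrence (women minus men), Benjamini-Hochberg adjusted,
   with patient-count-weighted chapter summaries.
3. **Temporal co-occurrence.** For each diagnosis pair (A, B) occurring
   in at least 100 patients on distinct days, matched cohorts (five
   controls per exposed patient, matched on age group, encounter type
   and discharge month within three months) are tabulated in both
   directions; a crude relative-risk prescreen
   (`RR = (n_ab/(n_ab+n_a))/(n_b/(n_b+n_0))`, Morris-Gardner standard
   error, lower bound > 1.01) gates a hierarchical Bayesian Poisson
   model over the eight exposure x event x sex cells. From
   posterior-predictive counts the pipeline derives the directionality
   `Pr(A->B) = N_ab/(N_ab + N_ba)` with a ROPE of (0.49, 0.51), the
   Cochran-Mantel-Haenszel sex-adjusted relative risk with per-sex
   components, the directional-pair decision (direction HDI excludes
   the ROPE and the RR HDI lower bound exceeds 1.1), the sex
   difference in RR (HDI excludes (-0.1, 0.1)), reversed pairs, and
   chapter-combination enrichment.
4. **Trajectories.** Directional pairs chain into linear trajectories
   (at least four diagnoses, followed by more than 100 patients with
   strictly increasing first-occurrence dates) and merge into networks
   with sex-attributed edges, exported as GraphML or DOT.

Because national registries are access-restricted, the package
includes a synthetic registry generator with known ground truth
(planted directional pairs with target relative risks, lags and
ordering fractions; age- and sex-dependent incidence; open outpatient
contacts; seasonal admission volume; routine background contacts), so
the entire pipeline is testable end to end. All posterior computation
runs on a purpose-built No-U-Turn HMC sampler for grouped hierarchical
Poisson models (Rcpp/RcppArmadillo) with slice-Gibbs and interweaved
updates for the scale parameters, split R-hat / divergence /
tree-depth diagnostics, and exact seed-level reproducibility.

## A worked example

```r
library(comotraj)

cfg <- pipeline_config(
  registry = registry_config(n_patients = 5000, seed = 7),
  sampler  = sampler_control(n_warmup = 250, n_draws = 400, seed = 2),
  seed     = 11)
run <- run_pipeline(cfg, "run1")
```

The log traces every stage and the filter funnel:

```
simulate: 5000 patients, 179587 admission rows
preprocess: 21697 first-occurrence events, 20 codes
incidence: 20 diagnoses fitted (of 20 codes), converged: TRUE
age: 18 codes compared, 0 significant at q < 0.05
pairs funnel: candidate_pairs=127, prescreen_survivors=38, analyzed_pairs=38, directional_pairs=3
```

The default synthetic registry plants two directional pairs:
hypertension preceding atrial fibrillation (relative risk 3, A-first
fraction 0.8) and alcohol dependence preceding forearm fracture
(relative risk 2, doubled in women). Their rows in
`run$pairs$decisions`:

```
code_a code_b dir_joint rr_ab_joint rr_diff
   I10    I48      0.80        2.38   -0.26
   F10    S52      0.75        2.84   -1.39
```

`dir_joint` is the posterior median of Pr(A->B): I10 precedes I48 in
~80% of co-diagnosed patients (planted: 0.8). `rr_ab_joint` is the
sex-adjusted relative risk of the later diagnosis given the earlier
one. Negative `rr_diff` (RR_men - RR_women) for F10->S52 reflects the
planted two-fold female risk modifier (men's RR near the planted 2,
women's near 4, pooling to the 2.84 joint estimate).

`run$incidence` holds the per-diagnosis age-adjusted rates, e.g. for
the planted hypertension code I10 an AIR near its closed-form truth
(`ground_truth_summary(run$registry)$codes`), and `run$summary$counts`
the directional-pair bookkeeping (men / women / shared / reversed).

## Package layout

- `R/synthetic_registry.R` - generator and ground truth
- `R/registry_core.R` - record merging, first occurrences, person-years
- `R/hbpois.R`, `src/nuts.cpp` - the Bayesian engine (NUTS + slice-Gibbs)
- `R/incidence.R` - incidence model, age standardization, sex contrast
- `R/age_at_first.R` - age-at-first-diagnosis comparisons
- `R/cooccurrence.R` - matched cohorts, prescreen, pair model, decisions
- `R/time_between.R` - diagnosis-to-diagnosis timespans
- `R/trajectories.R` - trajectory search and network export
- `R/pipeline.R` - end-to-end orchestration and reports
- `vignettes/methods.Rmd` - the full model and design account
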