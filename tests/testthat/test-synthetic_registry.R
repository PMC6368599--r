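# Synthetic registry generator: contracts and ground-truth recovery

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(registry_config(n_patients = 0), "n_patients")
  expect_error(registry_config(study_start = "2010-01-01",
                               study_end = "2000-01-01"), "study_start")
  expect_error(registry_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(registry_config(age_distribution = rep(1, 5)),
               "age_distribution")
  expect_error(registry_config(admission_type_probs =
                                 c(inpatient = 0.5, outpatient = 0.5,
                                   emergency = 0.5)),
               "admission_type_probs")
  expect_error(registry_config(open_contact_prob = -0.1),
               "open_contact_prob")
  expect_error(registry_config(pair_specs = list(
    pair_spec("I10", "QQQ", rr = 2))), "pair_specs")
  expect_error(pair_spec("A", "B", rr = 0.5), "rr")
  expect_error(disease_spec("X01", 1, base_rate = -1), "base_rate")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- registry_config(n_patients = 800, seed = 42)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$admissions, r2$admissions)
  expect_identical(r1$terminology, r2$terminology)
})

test_that("admission dates stay inside the study window and open contacts exist", {
  fx <- fixture_registry()
  adm <- fx$reg$admissions
  expect_true(all(adm$admission_date >= fx$cfg$study_start))
  expect_true(all(adm$admission_date <= fx$cfg$study_end))
  expect_true(all(is.na(adm$discharge_date) |
                    adm$discharge_date <= fx$cfg$study_end))
  expect_gt(sum(is.na(adm$discharge_date)), 0)
  expect_true(all(adm$admission_type[is.na(adm$discharge_date)] ==
                    "outpatient"))
  expect_true(any(adm$role == "referral"))
})

test_that("sex symmetry holds when every rate ratio is one and no pairs are planted", {
  specs <- lapply(c("Q10", "Q20", "Q30"), function(cd)
    disease_spec(cd, 1, base_rate = 0.01))
  cfg <- registry_config(n_patients = 10000, disease_specs = specs,
                         pair_specs = list(), seed = 5)
  reg <- generate_registry(cfg)
  ev <- extract_first_occurrences(reg$admissions, reg$patients,
                                  reg$terminology, cfg$study_start,
                                  cfg$study_end)
  for (cd in c("Q10", "Q20", "Q30")) {
    n_m <- sum(ev$code == cd & ev$sex == "M")
    n_f <- sum(ev$code == cd & ev$sex == "F")
    # two binomial halves of the same total: 4-sigma band
    tot <- n_m + n_f
    expect_lt(abs(n_m - n_f), 4 * sqrt(tot))
  }
})

test_that("per-(code, sex) event counts match the hazard model expectation", {
  # independent oracle: accumulate each patient's yearly hazards directly
  specs <- list(disease_spec("Q77", 1, base_rate = 0.008,
                             sex_rate_ratio = 1.5,
                             age_rate_multipliers = seq(0.5, 2.5,
                                                        length.out = 21)))
  cfg <- registry_config(n_patients = 8000, disease_specs = specs,
                         pair_specs = list(), seed = 77)
  reg <- generate_registry(cfg)
  ev <- extract_first_occurrences(reg$admissions, reg$patients,
                                  reg$terminology, cfg$study_start,
                                  cfg$study_end)
  esp <- esp2013()
  age0 <- as.numeric(cfg$study_start - reg$patients$birth_date) / 365.25
  for (s in c("M", "F")) {
    in_sex <- reg$patients$sex == s
    mult <- if (s == "M") 1.5 else 1
    lam <- vapply(age0[in_sex], function(a) {
      gs <- esp_age_group(pmin(a + (1:21) - 0.5, 99.9))
      sum(0.008 * mult * seq(0.5, 2.5, length.out = 21)[gs])
    }, 1)
    p_event <- 1 - exp(-lam)
    expected <- sum(p_event)
    v <- sum(p_event * (1 - p_event))
    obs <- sum(ev$code == "Q77" & ev$sex == s)
    expect_gt(expected, 20)
    expect_lt(abs(obs - expected) / sqrt(v), 4)
  }
})

test_that("a planted ordering target is recovered among co-diagnosed patients", {
  fx <- fixture_registry()
  ev <- fx$events
  w <- merge(ev[ev$code == "I10", c("patient_id", "event_date")],
             ev[ev$code == "I48", c("patient_id", "event_date")],
             by = "patient_id")
  w <- w[w$event_date.x != w$event_date.y, ]
  expect_gt(nrow(w), 1000)
  expect_lt(abs(mean(w$event_date.x < w$event_date.y) - 0.8), 0.05)
})

test_that("ground truth summary carries closed-form rates and planted parameters", {
  fx <- fixture_registry()
  gt <- ground_truth_summary(fx$reg)
  expect_equal(nrow(gt$pairs), 2)
  expect_equal(gt$pairs$rr[gt$pairs$code_a == "I10"], 3)
  # uniform multipliers, ratio 1: true AIR = base_rate per person-year,
  # scaled per 100,000
  spec1 <- list(disease_spec("R55", 1, base_rate = 0.004))
  cfg <- registry_config(n_patients = 500, disease_specs = spec1,
                         pair_specs = list(), seed = 2)
  reg <- generate_registry(cfg)
  gt1 <- ground_truth_summary(reg)
  expect_equal(gt1$codes$true_air_women, 0.004 * 1e5)
  expect_equal(gt1$codes$true_air_men, 0.004 * 1e5)
  expect_equal(nrow(gt1$pairs), 0)
  expect_error(ground_truth_summary(list()), "ground truth")
})

test_that("crude relative risk of unplanted code pairs is null-calibrated", {
  # with no planted pairs the matched-cohort crude RR interval should
  # cover 1.0 at ~95% across replicate registries
  specs <- list(
    disease_spec("Q10", 1, 0.012, 1.2, seq(0.5, 2, length.out = 21)),
    disease_spec("Q20", 2, 0.015, 0.8, rep(1, 21)),
    disease_spec("Q30", 3, 0.012, 1.0, seq(2, 0.5, length.out = 21)))
  hits <- 0L; total <- 0L
  for (r in 1:100) {
    cfg <- registry_config(n_patients = 2500, disease_specs = specs,
                           pair_specs = list(), seed = 9000 + r)
    reg <- generate_registry(cfg)
    adm <- merge_admissions(reg$admissions)
    ev <- extract_first_occurrences(adm, reg$patients, reg$terminology,
                                    cfg$study_start, cfg$study_end)
    co <- sample_matched_controls("Q10", ev, adm, reg$patients, k = 5,
                                  seed = r)
    cr <- crude_rr_ci(tabulate_pair(co, "Q20", ev))
    ci <- cr[cr$group == "combined", ]
    if (!is.na(ci$ci_lower)) {
      total <- total + 1L
      hits <- hits + (ci$ci_lower <= 1 && 1 <= ci$ci_upper)
    }
  }
  expect_gt(total, 90)
  expect_gt(hits / total, 0.89)  # 95% with +-6 point tolerance
})

test_that("registries round-trip through the delimited writers", {
  cfg <- registry_config(n_patients = 300, seed = 8)
  reg <- generate_registry(cfg)
  dir <- file.path(tempdir(), "regio")
  write_registry(reg, dir)
  back <- read_registry(dir)
  expect_equal(back$patients$patient_id, reg$patients$patient_id)
  expect_equal(back$admissions$admission_date, reg$admissions$admission_date)
  expect_equal(back$terminology$code, reg$terminology$code)
  expect_equal(back$truth_pairs$rr, reg$truth_pairs$rr)
})
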