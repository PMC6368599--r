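# Matched cohorts, crude RR, pair model and decision rules

test_that("candidate pairs respect the distinct-day threshold and dagger exclusion", {
  mk <- function(code, ids, dates) data.frame(
    patient_id = ids, code = code, event_date = as.Date(dates),
    sex = "M", encounter_type = "outpatient", age_years = 40,
    age_group = 10, stringsAsFactors = FALSE)
  ids <- sprintf("P%03d", 1:120)
  # 120 co-diagnosed but every instance same-day: excluded
  ev_same <- rbind(mk("AAA", ids, "2000-01-01"),
                   mk("BBB", ids, "2000-01-01"))
  term <- mini_terminology()
  term <- rbind(term, data.frame(code = c("AAA", "BBB"), chapter = 2,
                                 sex_specific = "none", chronic = FALSE,
                                 dagger_asterisk_role = "none",
                                 dagger_asterisk_partner = NA))
  expect_equal(nrow(enumerate_candidate_pairs(ev_same, term)$pairs), 0)
  # 100 on distinct days: included (threshold is at least 100)
  ev_ok <- rbind(mk("AAA", ids[1:100], "2000-01-01"),
                 mk("BBB", ids[1:100], "2000-05-01"))
  got <- enumerate_candidate_pairs(ev_ok, term)$pairs
  expect_equal(nrow(got), 1)
  expect_equal(got$n_a_first, 100)
  # 99 distinct days: excluded
  ev_few <- rbind(mk("AAA", ids[1:99], "2000-01-01"),
                  mk("BBB", ids[1:99], "2000-05-01"))
  expect_equal(nrow(enumerate_candidate_pairs(ev_few, term)$pairs), 0)
  # dagger-asterisk partners go to the side list
  ev_dag <- rbind(mk("A46", ids[1:150], "2000-01-01"),
                  mk("B95", ids[1:150], "2001-01-01"))
  out <- enumerate_candidate_pairs(ev_dag, term)
  expect_equal(nrow(out$pairs), 0)
  expect_equal(nrow(out$excluded_dagger), 1)
})

test_that("matched controls satisfy all three matching criteria", {
  fx <- fixture_registry()
  co <- sample_matched_controls("I21", fx$events, fx$adm,
                                fx$reg$patients, k = 5, seed = 55)
  expect_gt(nrow(co$exposed), 100)
  # exactly five controls whenever the eligible pool allows it
  ample <- co$exposed$n_eligible >= 5
  expect_gt(mean(ample), 0.95)
  expect_true(all(co$exposed$n_controls[ample] == 5))
  expect_true(all(co$exposed$n_controls <=
                    pmin(5, co$exposed$n_eligible)))
  # controls never carry the exposure
  carriers <- fx$events$patient_id[fx$events$code == "I21"]
  expect_false(any(co$controls$control_id %in% carriers))
  # matching criteria: age group, encounter type, month window
  ex_at <- match(co$controls$exposed_id, co$exposed$patient_id)
  expect_true(all(co$controls$age_group == co$exposed$age_group[ex_at]))
  expect_true(all(co$controls$encounter_type ==
                    co$exposed$encounter_type[ex_at]))
  mdiff <- abs(floor(co$controls$index_date / 30.4375) -
                 floor(as.numeric(co$exposed$event_date[ex_at]) / 30.4375))
  expect_true(all(mdiff <= 3))
  # the control's index discharge really exists in the discharge pool
  pool <- comotraj:::.discharge_index(fx$adm, fx$reg$patients)
  expect_true(all(paste(co$controls$control_id, co$controls$index_date)
                  %in% paste(pool$patient_id, pool$index_date)))
  # reproducible under the seed
  co2 <- sample_matched_controls("I21", fx$events, fx$adm,
                                 fx$reg$patients, k = 5, seed = 55)
  expect_identical(co$controls, co2$controls)
})

test_that("a depleted pool yields fewer controls and exclusions are counted", {
  d <- function(x) as.Date(x)
  ev <- data.frame(
    patient_id = c("E1", "C1", "C2", "C3"),
    code = c("AAA", "BBB", "BBB", "BBB"),
    event_date = d(rep("2000-06-15", 4)),
    encounter_type = "outpatient", sex = "M",
    age_years = 42, age_group = 10, stringsAsFactors = FALSE)
  adm <- data.frame(
    admission_id = paste0("A", 1:4),
    patient_id = c("E1", "C1", "C2", "C3"),
    admission_type = "outpatient",
    admission_date = d(rep("2000-06-15", 4)),
    discharge_date = d(rep("2000-06-15", 4)),
    code = c("AAA.1", "BBB.1", "BBB.1", "BBB.1"),
    role = "other", date_recorded = d(rep("2000-06-15", 4)),
    stringsAsFactors = FALSE)
  pats <- data.frame(patient_id = c("E1", "C1", "C2", "C3"), sex = "M",
                     birth_date = d(rep("1958-01-01", 4)),
                     stringsAsFactors = FALSE)
  co <- sample_matched_controls("AAA", ev, adm, pats, k = 5, seed = 1)
  expect_equal(nrow(co$controls), 3)
  expect_equal(sort(unique(co$controls$control_id)),
               c("C1", "C2", "C3"))
  # exposure carriers are never eligible: exposed with no pool at all
  co2 <- sample_matched_controls("BBB", ev, adm, pats, k = 5, seed = 1)
  # only E1 is a non-carrier; it is eligible for all three exposed
  expect_true(all(co2$controls$control_id == "E1"))
})

test_that("pair tabulation follows the strict-ordering cell contracts", {
  fx <- fixture_registry()
  co <- sample_matched_controls("I10", fx$events, fx$adm,
                                fx$reg$patients, k = 5, seed = 19)
  expect_error(tabulate_pair(co, "I10", fx$events), "differ")
  cnt <- tabulate_pair(co, "I48", fx$events)
  expect_equal(cnt$n_ab + cnt$n_a,
               as.vector(table(factor(co$exposed$sex,
                                      c("M", "F")))[c("M", "F")]))
  expect_equal(cnt$n_b + cnt$n_0,
               as.vector(table(factor(co$controls$sex,
                                      c("M", "F")))[c("M", "F")]))
  # absent event code: zero event cells
  ev_nob <- fx$events[fx$events$code != "I48", ]
  cnt0 <- tabulate_pair(co, "I48", ev_nob)
  expect_true(all(cnt0$n_ab == 0) && all(cnt0$n_b == 0))
  # a control whose only event-code occurrence is before its index date
  # lands in n_0: verified on a constructed instance
  d <- function(x) as.Date(x)
  cohort <- structure(list(
    exposure = "AAA",
    exposed = data.frame(patient_id = "E1", sex = "M",
                         event_date = d("2005-01-01"), age_group = 10,
                         encounter_type = "outpatient"),
    controls = data.frame(exposed_id = "E1", control_id = "C1",
                          index_date = as.numeric(d("2005-01-01")),
                          sex = "M")), class = "matched_cohort")
  ev2 <- data.frame(patient_id = c("E1", "C1"), code = "BBB",
                    event_date = d(c("2006-01-01", "2004-06-01")),
                    encounter_type = "outpatient", sex = "M",
                    age_years = 50, age_group = 11,
                    stringsAsFactors = FALSE)
  cnt2 <- tabulate_pair(cohort, "BBB", ev2)
  m <- cnt2[cnt2$sex == "M", ]
  expect_equal(unname(unlist(m[c("n_ab", "n_a", "n_b", "n_0")])),
               c(1, 0, 0, 1))
})

test_that("crude RR and its interval match hand evaluation", {
  mk_counts <- function(n_ab, n_a, n_b, n_0) {
    out <- data.frame(sex = c("M", "F"),
                      n_ab = c(n_ab, 0), n_a = c(n_a, 0),
                      n_b = c(n_b, 0), n_0 = c(n_0, 0))
    class(out) <- c("pair_counts", "data.frame")
    out
  }
  flat <- crude_rr_ci(mk_counts(10, 90, 50, 450))
  expect_equal(flat$rr[flat$group == "men"], 1)
  r <- crude_rr_ci(mk_counts(20, 80, 50, 450))
  men <- r[r$group == "men", ]
  expect_equal(men$rr, 2)
  se <- sqrt(1 / 20 - 1 / 100 + 1 / 50 - 1 / 500)
  expect_equal(men$se_log_rr, se, tolerance = 1e-12)
  expect_equal(men$ci_lower, exp(log(2) - qnorm(0.975) * se),
               tolerance = 1e-10)
  expect_equal(round(men$ci_lower, 2), 1.25)
  expect_equal(round(men$ci_upper, 2), 3.21)
  # printed-form switch flips the sign of the second term
  rp <- crude_rr_ci(mk_counts(20, 80, 50, 450), printed_form = TRUE)
  expect_equal(rp$se_log_rr[rp$group == "men"],
               sqrt(1 / 20 + 1 / 100 + 1 / 50 - 1 / 500),
               tolerance = 1e-12)
  # prescreen bound is strict: passing means the lower limit exceeds it
  grid <- crude_rr_ci(mk_counts(20, 80, 50, 450))
  expect_equal(grid$passes,
               !is.na(grid$ci_lower) & grid$ci_lower > 1.01)
  exact <- crude_rr_ci(mk_counts(20, 80, 50, 450),
                       threshold = men$ci_lower)
  expect_false(exact$passes[exact$group == "men"])
  # zero event cells: undefined estimate, prescreen fails
  z <- crude_rr_ci(mk_counts(0, 100, 50, 450))
  expect_true(is.na(z$rr[z$group == "men"]))
  expect_false(any(z$passes))
})

test_that("prescreen passing is monotone in the exposed-event cell", {
  mk <- function(n_ab) {
    out <- data.frame(sex = c("M", "F"), n_ab = c(n_ab, n_ab),
                      n_a = c(200 - n_ab, 200 - n_ab),
                      n_b = c(40, 40), n_0 = c(760, 760))
    class(out) <- c("pair_counts", "data.frame")
    out
  }
  passed <- vapply(5:60, function(n_ab)
    any(crude_rr_ci(mk(n_ab))$passes), TRUE)
  # once passing, increasing n_ab never turns it off
  expect_true(all(diff(as.integer(passed)) >= 0))
})

test_that("directionality point counts give the exact fraction and complement identity", {
  d <- directionality(rep(4, 200), rep(1, 200))
  expect_equal(d$median, 0.8)
  expect_equal(d$hdi$lower, 0.8)
  expect_equal(d$decision, "excludes")
  eq <- directionality(rep(7, 200), rep(7, 200))
  expect_equal(eq$median, 0.5)
  expect_equal(eq$decision, "overlaps")
  one <- directionality(rep(3, 200), rep(0, 200))
  expect_equal(one$median, 1)
  # complement identity holds exactly, draw by draw
  set.seed(3)
  a <- rpois(500, 8); b <- rpois(500, 5)
  keep <- (a + b) > 0
  pr_ab <- directionality(a, b)$draws
  pr_ba <- directionality(b, a)$draws
  expect_equal(pr_ab + pr_ba, rep(1, sum(keep)))
  # draws with both counts zero are skipped and counted
  z <- directionality(c(rep(2, 150), 0), c(rep(1, 150), 0))
  expect_equal(z$n_skipped, 1L)
})

test_that("the CMH combination reduces to the single-sex RR when one stratum is empty", {
  set.seed(7)
  for (i in 1:20) {
    cells <- matrix(rpois(4, c(30, 170, 40, 760)) + 1, 1)
    viaCMH <- comotraj:::.cmh_rr(cells, NULL)
    viaSex <- comotraj:::.sex_rr(cells)
    expect_equal(viaCMH, viaSex, tolerance = 1e-12)
  }
  # identical strata: CMH equals the common stratum RR
  cells <- matrix(c(30, 170, 40, 760), 1)
  expect_equal(comotraj:::.cmh_rr(cells, cells),
               comotraj:::.sex_rr(cells), tolerance = 1e-12)
})

test_that("adjusted RR recovers a known ratio and applies the strict 1.1 bound", {
  set.seed(15)
  n <- 600
  # exposed risk 0.30 vs control 0.10: RR 3
  cm <- cbind(rbinom(n, 1000, 0.3), 0, rbinom(n, 5000, 0.1), 0)
  cm[, 2] <- 1000 - cm[, 1]; cm[, 4] <- 5000 - cm[, 3]
  r <- adjusted_rr(cm, cm)
  expect_equal(r$joint$median, 3, tolerance = 0.1)
  expect_true(r$joint$elevated)
  expect_equal(r$men$median, r$women$median, tolerance = 0.2)
  # null cells: not elevated
  cm0 <- cbind(rbinom(n, 1000, 0.1), 0, rbinom(n, 5000, 0.1), 0)
  cm0[, 2] <- 1000 - cm0[, 1]; cm0[, 4] <- 5000 - cm0[, 3]
  r0 <- adjusted_rr(cm0, cm0)
  expect_false(r0$joint$elevated)
})

test_that("the RR sex-difference rule uses the ROPE and the count filter", {
  set.seed(22)
  base <- rnorm(800, 2, 0.05)
  same <- rr_sex_difference(base, base)
  expect_equal(same$median, 0)
  expect_false(same$significant)
  shifted <- rr_sex_difference(base + 0.5, base)
  expect_true(shifted$significant)
  withheld <- rr_sex_difference(base + 0.5, base, n_dir_men = 3,
                                n_dir_women = 4)
  expect_true(is.na(withheld$significant))
  # boundary: filter requires strictly more than five of either sex
  at6 <- rr_sex_difference(base + 0.5, base, n_dir_men = 6,
                           n_dir_women = 0)
  expect_true(at6$significant)
})

test_that("direction-strength contrasts obey their identities", {
  set.seed(25)
  pj <- runif(500, 0.4, 0.9)
  pm <- runif(500, 0.4, 0.9)
  pw <- runif(500, 0.4, 0.9)
  om <- direction_strength(pj, pm, pw)
  expect_equal(om$omega_men, pj - pm)
  zero <- direction_strength(pj, pj, pw)
  expect_true(all(zero$omega_men == 0))
  swapped <- direction_strength(pj, pw, pm)
  expect_equal(swapped$omega_men, om$omega_women)
  expect_equal(swapped$omega_women, om$omega_men)
  # noisier effects in women give a variance ratio below one
  set.seed(26)
  omm <- rnorm(200, 0, 0.02); omw <- rnorm(200, 0, 0.06)
  tr <- direction_strength_test(omm, omw)
  expect_lt(tr$effect, 1)
  expect_lt(tr$p_value, 0.05)
})

test_that("reversed pairs require opposite-side per-sex intervals", {
  base <- make_decisions("R33", "N30", dir_men = 0.61, dir_women = 0.42,
                         half_width = 0.015)
  out <- classify_reversed(base)
  expect_equal(nrow(out), 1)
  same_side <- make_decisions("R33", "N30", dir_men = 0.60,
                              dir_women = 0.57, half_width = 0.02)
  expect_equal(nrow(classify_reversed(same_side)), 0)
  not_dir <- make_decisions("R33", "N30", dir_men = 0.61,
                            dir_women = 0.42, half_width = 0.015,
                            directional_women = FALSE)
  expect_equal(nrow(classify_reversed(not_dir)), 0)
})

test_that("chapter enrichment flags asymmetric combinations only", {
  term <- data.frame(code = sprintf("C%02d", 1:8),
                     chapter = c(1, 1, 2, 2, 3, 3, 4, 4),
                     stringsAsFactors = FALSE)
  mk_pairs <- function(n, a, b) data.frame(
    code_a = rep(a, n), code_b = rep(b, n), stringsAsFactors = FALSE)
  # identical sets: nothing significant
  same <- rbind(mk_pairs(30, "C01", "C03"), mk_pairs(30, "C05", "C07"))
  out <- chapter_enrichment(same, same, term)
  expect_false(any(out$significant))
  # a combination present 50 times in men only (totals 500 per sex)
  men <- rbind(mk_pairs(50, "C01", "C03"), mk_pairs(450, "C05", "C07"))
  women <- mk_pairs(500, "C05", "C07")
  out2 <- chapter_enrichment(men, women, term)
  expect_true(out2$significant[out2$combo == "1+2"])
  # degenerate single pair
  out3 <- chapter_enrichment(mk_pairs(1, "C01", "C03"),
                             mk_pairs(1, "C01", "C03"), term)
  expect_true(all(out3$p > 0.9))
})
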