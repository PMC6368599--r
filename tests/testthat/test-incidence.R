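# Incidence model: strata, standardization, sex contrast, recovery

test_that("the standard population has 21 groups summing to 100,000", {
  esp <- esp2013()
  expect_equal(nrow(esp), 21)
  expect_equal(sum(esp$weight), 100000)
  expect_equal(esp_age_group(c(0.5, 1, 4.9, 5, 94.9, 95, 120)),
               c(1, 2, 2, 3, 20, 21, 21))
  expect_error(esp_age_group(-1), "negative")
})

test_that("strata inclusion threshold is at least 100 patients", {
  set.seed(3)
  mk_events <- function(code, n) data.frame(
    patient_id = sprintf("%s%04d", code, seq_len(n)), code = code,
    event_date = as.Date("2000-06-01"), encounter_type = "outpatient",
    sex = rep(c("M", "F"), length.out = n),
    age_years = runif(n, 20, 70), stringsAsFactors = FALSE)
  ev <- rbind(mk_events("AAA", 99), mk_events("BBB", 100))
  ev$age_group <- esp_age_group(ev$age_years)
  pats <- data.frame(patient_id = unique(ev$patient_id),
                     sex = ev$sex[match(unique(ev$patient_id),
                                        ev$patient_id)],
                     stringsAsFactors = FALSE)
  pats$birth_date <- as.Date("2000-06-01") -
    round(ev$age_years[match(pats$patient_id, ev$patient_id)] * 365.25)
  term <- data.frame(code = c("AAA", "BBB"), chapter = 1,
                     sex_specific = "none", stringsAsFactors = FALSE)
  st <- build_strata(ev, pats, term, "1994-01-01", "2014-12-31",
                     min_patients = 100)
  expect_equal(st$codes, "BBB")
  # at-risk person-time is censored at the first occurrence
  full <- person_years(pats, "1994-01-01", "2014-12-31")
  expect_lt(sum(st$offset[1, , ]), sum(full$person_years))
  # male-specific codes get male-only strata
  term$sex_specific <- c("none", "male")
  ev2 <- mk_events("BBB", 150); ev2$sex <- "M"
  ev2$age_group <- esp_age_group(ev2$age_years)
  pats2 <- data.frame(patient_id = ev2$patient_id, sex = "M",
                      birth_date = as.Date("2000-06-01") -
                        round(ev2$age_years * 365.25),
                      stringsAsFactors = FALSE)
  st2 <- build_strata(ev2, pats2, term, "1994-01-01", "2014-12-31",
                      min_patients = 100)
  expect_equal(st2$sex_specific, "male")
  expect_true(all(st2$y[1, , "F"] == 0))
})

test_that("age adjustment is a standard-weighted mean per 100,000", {
  # constant rates pass through
  expect_equal(age_adjusted_rate(rep(0.004, 21)), 0.004 * 1e5)
  # single active group: hand evaluation (weight 1000 in group 1)
  r <- c(0.001, rep(0, 20))
  expect_equal(age_adjusted_rate(r), 0.001 * 1000 / 100000 * 1e5)
  # homogeneity of degree zero in the weights
  esp <- esp2013()
  scaled <- esp; scaled$weight <- esp$weight * 7
  rates <- runif(21, 0, 0.01)
  expect_equal(age_adjusted_rate(rates, esp),
               age_adjusted_rate(rates, scaled))
  # draws matrix: one AIR per draw
  m <- rbind(rep(0.001, 21), rep(0.002, 21))
  expect_equal(age_adjusted_rate(m), c(100, 200))
  expect_error(age_adjusted_rate(rep(1, 20)), "age group")
})

test_that("relative difference follows the signed, bounded contract", {
  r <- relative_difference(110, 90)
  expect_equal(r$d, 0.2)
  expect_true(r$flag)
  expect_equal(relative_difference(100, 100)$d, 0)
  expect_false(relative_difference(100, 100)$flag)
  expect_equal(relative_difference(0, 50)$d, -2)
  # antisymmetry
  for (i in 1:5) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    expect_equal(relative_difference(a, b)$d,
                 -relative_difference(b, a)$d)
    expect_lte(abs(relative_difference(a, b)$d), 2)
  }
  expect_warning(r0 <- relative_difference(0, 0), "zero")
  expect_true(is.na(r0$flag))
})

test_that("a planted sex rate ratio is recovered by the fitted model", {
  fx <- fixture_registry()
  fit <- fixture_incidence_fit()
  st <- fit$strata
  expect_true(fit$converged)
  # F10 planted with men/women ratio 2.2
  rd <- incidence_rate_draws(fit, "F10")
  expect_equal(median(exp(rd$beta_sex)), 2.2, tolerance = 0.15)
  res <- incidence_results(fit)
  expect_equal(nrow(res), length(st$codes))
  row <- res[res$code == "F10", ]
  expect_gt(row$d, 0.1)            # markedly higher in men
  expect_true(row$flag_different)
  row2 <- res[res$code == "F32", ] # planted ratio 0.55: higher in women
  expect_lt(row2$d, -0.1)
  # sex-specific codes carry single-sex rates and no d
  rowm <- res[res$code == "N40", ]
  expect_true(is.na(rowm$air_women) && !is.na(rowm$air_men))
  expect_true(is.na(rowm$d))
  # estimated AIR tracks the closed-form truth
  gt <- ground_truth_summary(fx$reg)$codes
  for (cd in c("I10", "J18")) {
    est <- res$air_men[res$code == cd]
    tru <- gt$true_air_men[gt$code == cd]
    expect_lt(abs(est - tru) / tru, 0.15)
  }
})

test_that("posterior-predictive counts center on observations and are overdispersed", {
  fit <- fixture_incidence_fit()
  pp <- simulate_case_counts(fit, seed = 6)[[1]]
  b <- fit$batches[[1]]
  y_obs <- matrix(0, length(b$idx), dim(pp)[3])
  for (j in seq_along(b$idx))
    y_obs[j, ] <- as.vector(fit$strata$y[b$idx[j], , b$sexes])
  mu_hat <- apply(pp, c(2, 3), mean)
  sd_hat <- apply(pp, c(2, 3), sd)
  big <- y_obs >= 25
  z <- (y_obs[big] - mu_hat[big]) / pmax(sd_hat[big], 1e-9)
  expect_lt(max(abs(z)), 3.5)
  # predictive variance at least the predictive mean (Poisson mixture)
  v <- apply(pp, c(2, 3), var)
  expect_gt(mean(v[big] >= 0.8 * mu_hat[big]), 0.95)
})

test_that("partial pooling shrinks small-count sex effects toward zero", {
  set.seed(21)
  U <- 30
  bsex_true <- rnorm(U, 0, 0.3)
  X <- cbind(sapply(1:21, function(g) as.numeric(rep(1:21, 2) == g)),
             male = rep(c(0, 1), each = 21))
  off <- matrix(60, U, 42)           # small offsets: ~100-200 cases/code
  eta <- matrix(log(0.05), U, 42) + bsex_true %o% rep(c(0, 1), each = 21)
  y <- matrix(rpois(U * 42, exp(eta) * off), U, 42)
  fit <- hbpois(y, off, X, coef_groups = c(rep("age", 21), "sex"),
                group_scales = c(age = 1, sex = 0.5),
                between_scales = c(age = 3),
                control = sampler_control(n_warmup = 300, n_draws = 300,
                                          seed = 9))
  post <- apply(coef_draws(fit)[, , 22], 2, median)
  ym <- rowSums(y[, 22:42]); yf <- rowSums(y[, 1:21])
  mle <- log(pmax(ym, 0.5) / pmax(yf, 0.5))
  shrunk <- abs(post) <= abs(mle) + 1e-9
  expect_gte(mean(shrunk), 0.9)
})

test_that("the fitted batches agree with a joint fit on a shared instance", {
  # batching deviation check: split 20 diagnoses into two batches of 10
  # and compare against the joint 20-diagnosis fit
  set.seed(31)
  U <- 20
  X <- cbind(sapply(1:21, function(g) as.numeric(rep(1:21, 2) == g)),
             male = rep(c(0, 1), each = 21))
  off <- matrix(5000, U, 42)
  b0 <- rnorm(U, -5, 1); bs <- rnorm(U, 0, 0.3)
  eta <- b0 %o% rep(1, 42) + bs %o% rep(c(0, 1), each = 21) + log(5000)
  y <- matrix(rpois(U * 42, exp(eta)), U, 42)
  ctl <- sampler_control(n_warmup = 250, n_draws = 250, seed = 13)
  fit_all <- hbpois(y, off, X, coef_groups = c(rep("age", 21), "sex"),
                    group_scales = c(age = 1, sex = 0.5),
                    between_scales = c(age = 3), control = ctl)
  med_all <- apply(coef_draws(fit_all)[, , 22], 2, median)
  med_split <- unlist(lapply(list(1:10, 11:20), function(ix) {
    f <- hbpois(y[ix, ], off[ix, ], X,
                coef_groups = c(rep("age", 21), "sex"),
                group_scales = c(age = 1, sex = 0.5),
                between_scales = c(age = 3), control = ctl)
    apply(coef_draws(f)[, , 22], 2, median)
  }))
  expect_lt(median(abs(med_all - med_split)), 0.05)
})
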