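#' Matched-cohort temporal diagnosis co-occurrence
#'
#' The analytical core: for each candidate diagnosis pair (A, B), matched
#' cohorts are built in both exposure directions, crude relative risks
#' prescreen the pairs, a hierarchical Bayesian Poisson model over the
#' eight (exposure x event x sex) cells refines the estimates, and
#' posterior-predictive counts drive the directionality (ROPE on
#' Pr(A->B)), relative-risk (HDI lower bound above 1.1), sex-difference
#' and reversed-pair decision rules.
#'
#' @name cooccurrence
NULL

#' Enumerate candidate diagnosis pairs
#'
#' Unordered pairs of codes co-occurring (on distinct days) in at least
#' `min_patients` patients. Dagger-asterisk partnerships are excluded from
#' the candidate list and reported separately.
#'
#' @param events first-occurrence events.
#' @param terminology terminology table.
#' @param min_patients inclusion threshold on distinct-day co-diagnosed
#'   patients.
#' @return list with `pairs` (data.frame: codes, co-diagnosis counts per
#'   ordering) and `excluded_dagger` (same shape).
#' @export
enumerate_candidate_pairs <- function(events, terminology,
                                      min_patients = 100) {
  codes <- sort(unique(events$code))
  by_code <- split(events[, c("patient_id", "event_date")], events$code)
  rows <- list(); drows <- list()
  for (i in seq_along(codes)) for (j in seq_len(i - 1)) {
    a <- codes[j]; b <- codes[i]
    m <- merge(by_code[[a]], by_code[[b]], by = "patient_id")
    if (!nrow(m)) next
    same <- m$event_date.x == m$event_date.y
    n_ab <- sum(m$event_date.x < m$event_date.y)
    n_ba <- sum(m$event_date.x > m$event_date.y)
    if (n_ab + n_ba < min_patients) next
    row <- data.frame(code_a = a, code_b = b, n_both = n_ab + n_ba,
                      n_a_first = n_ab, n_b_first = n_ba,
                      n_same_day = sum(same), stringsAsFactors = FALSE)
    if (is_dagger_asterisk_pair(a, b, terminology))
      drows[[length(drows) + 1]] <- row
    else rows[[length(rows) + 1]] <- row
  }
  empty <- data.frame(code_a = character(), code_b = character(),
                      n_both = integer(), n_a_first = integer(),
                      n_b_first = integer(), n_same_day = integer())
  list(pairs = if (length(rows)) do.call(rbind, rows) else empty,
       excluded_dagger = if (length(drows)) do.call(rbind, drows) else empty)
}

# contact-level discharge index used for matching: one row per contact
# with its assigned date (discharge, or last recorded diagnosis for open
# contacts), encounter type and the patient's age group at that date
.discharge_index <- function(admissions, patients) {
  cl <- admissions[!duplicated(admissions$admission_id), ]
  idx_date <- as.numeric(cl$discharge_date)
  open <- is.na(idx_date)
  if (any(open)) {
    sub <- admissions[admissions$admission_id %in%
                        cl$admission_id[open], ]
    last_dx <- tapply(as.numeric(sub$date_recorded), sub$admission_id,
                      max, na.rm = TRUE)
    idx_date[open] <- last_dx[cl$admission_id[open]]
  }
  pm <- match(cl$patient_id, patients$patient_id)
  age <- (idx_date - as.numeric(patients$birth_date[pm])) / 365.25
  data.frame(patient_id = cl$patient_id,
             sex = patients$sex[pm],
             encounter_type = cl$admission_type,
             index_date = idx_date,
             age_group = esp_age_group(pmax(age, 0)),
             month_key = floor(idx_date / 30.4375),
             stringsAsFactors = FALSE)
}

#' Sample matched controls for an exposure diagnosis
#'
#' For every patient with a first occurrence of the exposure code, up to
#' `k` control patients are sampled uniformly without replacement from the
#' patient-discharges that (i) fall in the same ESP2013 age group, (ii)
#' come from the same encounter type, and (iii) are discharged within
#' three calendar months of the index discharge (the window may cross
#' year boundaries). Controls are never diagnosed with the exposure at
#' any time. The control's index date is its matched discharge date.
#'
#' @param exposure_code the exposure diagnosis A.
#' @param events first-occurrence events.
#' @param admissions admissions table (for the discharge pool).
#' @param patients patients table.
#' @param k controls per exposed patient (default 5).
#' @param seed RNG seed; sampling is deterministic given it.
#' @param discharge_pool optional precomputed `.discharge_index` result,
#'   reused across exposures for speed.
#' @return object of class `"matched_cohort"`: `exposed` (one row per
#'   exposed patient kept, with the eligible-pool size and realized
#'   control count), `controls` (one row per sampled control with its
#'   matching variables), the realized control ratio and the number of
#'   exposed excluded for lack of eligible controls.
#' @export
sample_matched_controls <- function(exposure_code, events, admissions,
                                    patients, k = 5, seed = 1,
                                    discharge_pool = NULL) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                          .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  ex <- events[events$code == exposure_code, ]
  if (!nrow(ex)) stop("no events for the exposure code")
  if (is.null(discharge_pool))
    discharge_pool <- .discharge_index(admissions, patients)
  carriers <- unique(ex$patient_id)
  pool <- discharge_pool[!(discharge_pool$patient_id %in% carriers), ]

  ex$index_date <- as.numeric(ex$event_date)
  ex$month_key <- floor(ex$index_date / 30.4375)
  ex_key <- paste(ex$age_group, ex$encounter_type, ex$month_key)
  pool_key <- paste(pool$age_group, pool$encounter_type, pool$month_key)
  pool_by_key <- split(seq_len(nrow(pool)), pool_key)

  ctrl <- vector("list", length(unique(ex_key)))
  kept <- logical(nrow(ex))
  ratio_n <- integer(nrow(ex))
  n_eligible <- integer(nrow(ex))
  uk <- unique(ex_key)
  for (u in seq_along(uk)) {
    parts <- strsplit(uk[u], " ", fixed = TRUE)[[1]]
    mks <- as.numeric(parts[3]) + (-3:3)
    keys <- paste(parts[1], parts[2], mks)
    rows <- unlist(pool_by_key[keys], use.names = FALSE)
    who <- which(ex_key == uk[u])
    if (!length(rows)) next
    # one random discharge per eligible patient
    rows <- rows[sample.int(length(rows))]
    rows <- rows[!duplicated(pool$patient_id[rows])]
    npat <- length(rows)
    picks <- lapply(who, function(w) rows[sample.int(npat, min(k, npat))])
    kept[who] <- TRUE
    ratio_n[who] <- lengths(picks)
    n_eligible[who] <- npat
    pk <- unlist(picks)
    ctrl[[u]] <- data.frame(
      exposed_id = rep(ex$patient_id[who], lengths(picks)),
      control_id = pool$patient_id[pk],
      index_date = pool$index_date[pk],
      sex = pool$sex[pk],
      age_group = pool$age_group[pk],
      encounter_type = pool$encounter_type[pk],
      stringsAsFactors = FALSE)
  }
  controls <- do.call(rbind, ctrl[!vapply(ctrl, is.null, TRUE)])
  exposed <- ex[kept, c("patient_id", "sex", "event_date", "age_group",
                        "encounter_type")]
  exposed$n_eligible <- n_eligible[kept]
  exposed$n_controls <- ratio_n[kept]
  structure(list(
    exposure = exposure_code,
    exposed = exposed,
    controls = controls,
    realized_ratio = if (any(kept)) mean(ratio_n[kept]) else NA_real_,
    n_excluded = sum(!kept)),
    class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "Matched cohort for %s: %d exposed, %d controls (ratio %.2f), %d excluded\n",
    x$exposure, nrow(x$exposed),
    if (is.null(x$controls)) 0L else nrow(x$controls), x$realized_ratio,
    x$n_excluded))
  invisible(x)
}

#' Tabulate exposure/event cells for a matched cohort
#'
#' Exposed patients count toward `n_ab` iff their first occurrence of the
#' event code is strictly after their first occurrence of the exposure
#' (day resolution; same-day does not count), else `n_a`. Controls count
#' toward `n_b` iff their first event occurrence is strictly after their
#' matched index date, else `n_0`. Cells are kept per sex.
#'
#' @param cohort a [sample_matched_controls()] result for exposure A.
#' @param event_code the event diagnosis B (different from A).
#' @param events first-occurrence events.
#' @return data.frame of class `"pair_counts"`: one row per sex with the
#'   four cells.
#' @export
tabulate_pair <- function(cohort, event_code, events) {
  if (identical(event_code, cohort$exposure))
    stop("event code must differ from the exposure code")
  b <- events[events$code == event_code, ]
  b_date <- as.numeric(b$event_date)[match(
    c(cohort$exposed$patient_id, cohort$controls$control_id),
    b$patient_id)]
  ne <- nrow(cohort$exposed)
  b_ex <- b_date[seq_len(ne)]
  b_ct <- b_date[-seq_len(ne)]
  ex_after <- !is.na(b_ex) & b_ex > as.numeric(cohort$exposed$event_date)
  ct_after <- !is.na(b_ct) & b_ct > cohort$controls$index_date
  out <- do.call(rbind, lapply(c("M", "F"), function(s) {
    se <- cohort$exposed$sex == s
    sc <- cohort$controls$sex == s
    data.frame(sex = s,
               n_ab = sum(ex_after & se), n_a = sum(!ex_after & se),
               n_b = sum(ct_after & sc), n_0 = sum(!ct_after & sc),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("pair_counts", "data.frame")
  out
}

#' Crude relative risk with confidence interval
#'
#' \eqn{RR = (n_{ab}/(n_{ab}+n_a)) / (n_b/(n_b+n_0))} with the
#' Morris-Gardner standard error of log RR,
#' \eqn{\sqrt{1/n_{ab} - 1/(n_{ab}+n_a) + 1/n_b - 1/(n_b+n_0)}}, and the
#' normal-theory interval on the log scale. Estimates are produced for
#' men, women and both sexes combined; the prescreen passes iff any lower
#' bound strictly exceeds `threshold`.
#'
#' @param counts a `pair_counts` table (one direction).
#' @param alpha interval level (default 0.05 for 95%).
#' @param threshold prescreen bound on the CI lower limit (default 1.01).
#' @param printed_form if `TRUE`, uses a plus sign on the
#'   \eqn{1/(n_{ab}+n_a)} term instead of the cited-source minus sign.
#' @return data.frame: one row per grouping with `rr`, `se_log_rr`,
#'   `ci_lower`, `ci_upper`, `passes`.
#' @export
crude_rr_ci <- function(counts, alpha = 0.05, threshold = 1.01,
                        printed_form = FALSE) {
  z <- stats::qnorm(1 - alpha / 2)
  s2 <- if (printed_form) +1 else -1
  one <- function(n_ab, n_a, n_b, n_0, label) {
    if (n_ab == 0 || n_b == 0 || (n_ab + n_a) == 0 || (n_b + n_0) == 0)
      return(data.frame(group = label, rr = NA_real_,
                        se_log_rr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, passes = FALSE,
                        stringsAsFactors = FALSE))
    rr <- (n_ab / (n_ab + n_a)) / (n_b / (n_b + n_0))
    se <- sqrt(1 / n_ab + s2 / (n_ab + n_a) + 1 / n_b - 1 / (n_b + n_0))
    lo <- exp(log(rr) - z * se); hi <- exp(log(rr) + z * se)
    data.frame(group = label, rr = rr, se_log_rr = se, ci_lower = lo,
               ci_upper = hi, passes = lo > threshold,
               stringsAsFactors = FALSE)
  }
  m <- counts[counts$sex == "M", ]; f <- counts[counts$sex == "F", ]
  out <- rbind(
    one(m$n_ab, m$n_a, m$n_b, m$n_0, "men"),
    one(f$n_ab, f$n_a, f$n_b, f$n_0, "women"),
    one(m$n_ab + f$n_ab, m$n_a + f$n_a, m$n_b + f$n_b, m$n_0 + f$n_0,
        "combined"))
  rownames(out) <- NULL
  out
}

#' Pair-model prior scales
#'
#' All eight coefficient-scale hyperpriors are half-normal(0, 2).
#' @param scale common half-normal scale.
#' @export
pair_model_priors <- function(scale = 2) {
  stopifnot(scale > 0)
  rep(scale, 8)
}

# 8-cell design shared by every (exposure, event) unit:
# rows ordered (Ex, Ev, Sex): 000,010,100,110,001,011,101,111 with
# Sex = 1 for women
.pair_design <- function() {
  g <- expand.grid(ex = 0:1, ev = 0:1, female = 0:1)
  g <- g[order(g$female, g$ex, g$ev), ]
  X <- cbind(intercept = 1, female = g$female, ex = g$ex, ev = g$ev,
             ex_female = g$ex * g$female, ev_female = g$ev * g$female,
             ex_ev = g$ex * g$ev, ex_ev_female = g$ex * g$ev * g$female)
  rownames(X) <- paste0("ex", g$ex, "ev", g$ev,
                        ifelse(g$female == 1, "F", "M"))
  X
}

# cell vector (length 8, .pair_design row order) from a pair_counts table
.pair_cells <- function(counts) {
  m <- counts[counts$sex == "M", ]; f <- counts[counts$sex == "F", ]
  y <- c(m$n_0, m$n_b, m$n_a, m$n_ab, f$n_0, f$n_b, f$n_a, f$n_ab)
  off <- c(rep(m$n_b + m$n_0, 2), rep(m$n_ab + m$n_a, 2),
           rep(f$n_b + f$n_0, 2), rep(f$n_ab + f$n_a, 2))
  list(y = y, offset = off)
}

# reduced single-sex layout: 4 cells (Ex x Ev) of the active sex; used
# for designs touching a sex-specific code, where the sex-interaction
# columns of the full design would be collinear with their main effects
.pair_design_single <- function() {
  g <- expand.grid(ex = 0:1, ev = 0:1)
  g <- g[order(g$ex, g$ev), ]
  X <- cbind(intercept = 1, ex = g$ex, ev = g$ev, ex_ev = g$ex * g$ev)
  rownames(X) <- paste0("ex", g$ex, "ev", g$ev)
  X
}

.pair_cells_single <- function(counts, sex) {
  s <- counts[counts$sex == sex, ]
  list(y = c(s$n_0, s$n_b, s$n_a, s$n_ab),
       offset = c(rep(s$n_b + s$n_0, 2), rep(s$n_ab + s$n_a, 2)))
}

# which sexes have any usable (nonzero-offset) cells
.pair_signature <- function(counts) {
  act <- vapply(c("M", "F"), function(s) {
    r <- counts[counts$sex == s, ]
    (r$n_ab + r$n_a) > 0 || (r$n_b + r$n_0) > 0
  }, TRUE)
  if (all(act)) "both" else if (act["M"]) "M" else "F"
}

#' Fit the hierarchical pair model for a batch of designs
#'
#' Each design (an exposure-event direction of one pair) contributes the
#' eight (exposure x event x sex) cell counts with the per-sex group
#' sizes as offsets; the eight coefficients per design (intercept, sex,
#' exposure, event and their interactions) share half-normal(0, 2) scale
#' hyperpriors across the designs of the batch.
#'
#' @param count_list named list of `pair_counts` tables (one per design;
#'   names like `"A->B"`).
#' @param priors [pair_model_priors()].
#' @param control a [sampler_control()].
#' @return object of class `"pair_model_fit"` wrapping the [hbpois()] fit.
#' @export
fit_pair_model <- function(count_list, priors = pair_model_priors(),
                           control = sampler_control()) {
  stopifnot(length(count_list) >= 1)
  sig <- vapply(count_list, .pair_signature, "")
  if (length(unique(sig)) > 1)
    stop("mixed single-sex and both-sex designs in one batch; split them")
  layout <- sig[1]
  if (layout == "both") {
    X <- .pair_design()
    cells <- lapply(count_list, .pair_cells)
  } else {
    X <- .pair_design_single()
    cells <- lapply(count_list, .pair_cells_single, sex = layout)
  }
  U <- length(count_list)
  y <- matrix(0, U, nrow(X), dimnames = list(names(count_list),
                                             rownames(X)))
  off <- matrix(0, U, nrow(X))
  for (u in seq_len(U)) {
    y[u, ] <- cells[[u]]$y; off[u, ] <- cells[[u]]$offset
  }
  fit <- hbpois(y, off, X, coef_groups = colnames(X),
                group_scales = stats::setNames(priors[seq_len(ncol(X))],
                                               colnames(X)),
                control = control)
  structure(list(fit = fit, designs = names(count_list),
                 counts = count_list, layout = layout),
            class = "pair_model_fit")
}

#' @export
print.pair_model_fit <- function(x, ...) {
  cat(sprintf("Pair model fit: %d designs; converged: %s\n",
              length(x$designs), x$fit$converged))
  print(x$fit$convergence)
  invisible(x)
}

#' Posterior-predictive cell counts for the designs of a pair-model fit
#'
#' @param pfit a `pair_model_fit`.
#' @param seed seed for the predictive Poisson draws.
#' @return array draws x designs x 8 cells (named as in the design).
#' @export
pair_predictive_cells <- function(pfit, seed = NULL) {
  pp <- simulate(pfit$fit, seed = seed)
  cells <- if (pfit$layout == "both") rownames(.pair_design())
    else paste0(rownames(.pair_design_single()), pfit$layout)
  dimnames(pp) <- list(NULL, pfit$designs, cells)
  pp
}

#' Directionality of a pair from posterior-predictive order counts
#'
#' \eqn{\Pr(A \to B) = N_{A\to B} / (N_{A\to B} + N_{B\to A})} per draw;
#' \eqn{\Pr(B \to A)} is its exact complement. The decision compares the
#' HDI with the ROPE (0.49, 0.51).
#'
#' @param n_ab_draws,n_ba_draws posterior-predictive counts of patients
#'   diagnosed in each order (one value per draw).
#' @param rope ROPE bounds.
#' @param mass HDI mass.
#' @return list: `draws`, `median`, `hdi`, `decision`
#'   (`"excludes"`/`"overlaps"`), `n_skipped` (draws with both counts 0).
#' @export
directionality <- function(n_ab_draws, n_ba_draws,
                           rope = c(0.49, 0.51), mass = 0.95) {
  if (is.null(n_ab_draws) || is.null(n_ba_draws))
    return(list(draws = numeric(0), median = NA_real_, hdi = NULL,
                decision = NA_character_, n_skipped = 0L))
  tot <- n_ab_draws + n_ba_draws
  skip <- is.na(tot) | tot == 0
  pr <- n_ab_draws[!skip] / tot[!skip]
  if (length(pr) < 100)
    return(list(draws = pr, median = NA_real_, hdi = NULL,
                decision = NA_character_, n_skipped = sum(skip)))
  h <- hdi(pr, mass)
  list(draws = pr, median = stats::median(pr), hdi = h,
       decision = rope_decision(h, list(lower = rope[1], upper = rope[2])),
       n_skipped = sum(skip))
}

# Cochran-Mantel-Haenszel relative risk across the two sex strata,
# vectorized over draws; cells_* are draws x 4 matrices (n_ab, n_a, n_b,
# n_0)
.cmh_rr <- function(cells_m, cells_f) {
  num <- den <- 0
  for (cl in list(cells_m, cells_f)) {
    if (is.null(cl)) next
    N <- rowSums(cl)
    num <- num + cl[, 1] * (cl[, 3] + cl[, 4]) / N
    den <- den + cl[, 3] * (cl[, 1] + cl[, 2]) / N
  }
  num / den
}

.sex_rr <- function(cells) {
  (cells[, 1] / (cells[, 1] + cells[, 2])) /
    (cells[, 3] / (cells[, 3] + cells[, 4]))
}

#' Adjusted relative risk from posterior-predictive cells
#'
#' Combines the two sex strata per draw with the Cochran-Mantel-Haenszel
#' weighting for the joint estimate and reports the per-sex relative
#' risks; the elevated-risk decision requires the HDI lower bound to
#' exceed `rr_bound` (strictly).
#'
#' @param cells_m,cells_f draws x 4 matrices (`n_ab`, `n_a`, `n_b`,
#'   `n_0`) of posterior-predictive counts per sex (either may be NULL).
#' @param rr_bound lower-bound threshold (default 1.1).
#' @param mass HDI mass.
#' @return list of summaries (`joint`, `men`, `women`), each with draws,
#'   median, HDI, `elevated` flag and skipped-draw count.
#' @export
adjusted_rr <- function(cells_m, cells_f, rr_bound = 1.1, mass = 0.95) {
  summ <- function(draws) {
    ok <- is.finite(draws) & draws > 0
    if (sum(ok) < 100)
      return(list(draws = draws[ok], median = NA_real_, hdi = NULL,
                  elevated = NA, n_skipped = sum(!ok)))
    h <- hdi(draws[ok], mass)
    list(draws = draws[ok], median = stats::median(draws[ok]), hdi = h,
         elevated = h$lower > rr_bound, n_skipped = sum(!ok))
  }
  list(joint = summ(.cmh_rr(cells_m, cells_f)),
       men = if (!is.null(cells_m)) summ(.sex_rr(cells_m)),
       women = if (!is.null(cells_f)) summ(.sex_rr(cells_f)))
}

#' Sex difference in relative risk
#'
#' Subtracts the women's from the men's posterior RR draws; the
#' difference is significant iff its HDI excludes the ROPE (-0.1, 0.1).
#' The decision is withheld (NA) unless more than `min_count` men or
#' women were observed diagnosed in the preferred direction.
#'
#' @param rr_men_draws,rr_women_draws posterior RR draws per sex.
#' @param n_dir_men,n_dir_women observed patients of each sex diagnosed
#'   in the preferred direction.
#' @param rope equivalence region for the difference.
#' @param min_count count filter (strictly more than this required).
#' @param mass HDI mass.
#' @return list: `draws`, `median`, `hdi`, `significant`
#'   (TRUE/FALSE/NA when withheld).
#' @export
rr_sex_difference <- function(rr_men_draws, rr_women_draws,
                              n_dir_men = Inf, n_dir_women = Inf,
                              rope = c(-0.1, 0.1), min_count = 5,
                              mass = 0.95) {
  n <- min(length(rr_men_draws), length(rr_women_draws))
  d <- rr_men_draws[seq_len(n)] - rr_women_draws[seq_len(n)]
  d <- d[is.finite(d)]
  if (length(d) < 100)
    return(list(draws = d, median = NA_real_, hdi = NULL,
                significant = NA))
  h <- hdi(d, mass)
  sig <- if (n_dir_men > min_count || n_dir_women > min_count)
    rope_decision(h, list(lower = rope[1], upper = rope[2])) == "excludes"
  else NA
  list(draws = d, median = stats::median(d), hdi = h, significant = sig)
}

#' Direction-strength contrasts between the joint and per-sex posteriors
#'
#' \eqn{\omega_{men} = \Pr(A\to B)_{joint} - \Pr(A\to B)_{men}} per draw
#' (and likewise for women). Across many pairs, the per-pair median
#' omegas form the two samples compared with the variance-ratio F test.
#'
#' @param pr_joint,pr_men,pr_women directionality draws from the same
#'   pair.
#' @return list with `omega_men` and `omega_women` draw vectors.
#' @export
direction_strength <- function(pr_joint, pr_men, pr_women) {
  n <- min(length(pr_joint), length(pr_men), length(pr_women))
  list(omega_men = pr_joint[seq_len(n)] - pr_men[seq_len(n)],
       omega_women = pr_joint[seq_len(n)] - pr_women[seq_len(n)])
}

#' Variance-ratio test on per-pair direction-strength medians
#'
#' @param omega_men_medians,omega_women_medians per-pair median omega
#'   values.
#' @return a `test_result` (effect = var(men)/var(women)).
#' @export
direction_strength_test <- function(omega_men_medians,
                                    omega_women_medians) {
  variance_ratio_f(omega_men_medians, omega_women_medians)
}

#' Classify reversed directional pairs
#'
#' A pair is reversed iff it is directional in both sexes with the two
#' directionality HDIs on opposite sides of 0.5. Rows are annotated with
#' whether the joint decision is absent or agrees with one sex.
#'
#' @param decisions a pair-decision table (see [analyze_pairs()]) with
#'   per-sex directional flags and directionality HDI bounds.
#' @return subset of `decisions` (possibly empty) with a `joint_status`
#'   column.
#' @export
classify_reversed <- function(decisions) {
  d <- decisions
  rev_rows <- !is.na(d$directional_men) & !is.na(d$directional_women) &
    d$directional_men & d$directional_women &
    ((d$dir_men_hi < 0.5 & d$dir_women_lo > 0.5) |
       (d$dir_men_lo > 0.5 & d$dir_women_hi < 0.5))
  out <- d[which(rev_rows), , drop = FALSE]
  if (nrow(out)) {
    out$joint_status <- ifelse(is.na(out$directional_joint) |
                                 !out$directional_joint,
                               "no joint direction",
      ifelse((out$dir_joint_lo > 0.5) == (out$dir_men_lo > 0.5),
             "joint matches men", "joint matches women"))
  }
  rownames(out) <- NULL
  out
}

#' Chapter-combination enrichment of sex-unique directional pairs
#'
#' For each unordered chapter combination, tests with Fisher's exact test
#' whether the combination is unequally represented among the men-unique
#' versus women-unique directional pairs; p values are BH-adjusted.
#' Sex-specific codes should be removed upstream.
#'
#' @param pairs_men,pairs_women data.frames with `code_a`, `code_b`
#'   (directional pairs unique to each sex).
#' @param terminology terminology table.
#' @param fdr significance threshold.
#' @return data.frame per chapter combination with counts, odds ratio,
#'   p, q.
#' @export
chapter_enrichment <- function(pairs_men, pairs_women, terminology,
                               fdr = 0.05) {
  combo <- function(df) {
    if (is.null(df) || !nrow(df)) return(character(0))
    c1 <- terminology$chapter[match(df$code_a, terminology$code)]
    c2 <- terminology$chapter[match(df$code_b, terminology$code)]
    paste(pmin(c1, c2), pmax(c1, c2), sep = "+")
  }
  cm <- combo(pairs_men); cf <- combo(pairs_women)
  levs <- sort(unique(c(cm, cf)))
  if (!length(levs))
    return(data.frame(combo = character(), n_men = integer(),
                      n_women = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  rows <- lapply(levs, function(lv) {
    a <- sum(cm == lv); b <- length(cm) - a
    c_ <- sum(cf == lv); d <- length(cf) - c_
    tr <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    data.frame(combo = lv, n_men = a, n_women = c_,
               odds_ratio = tr$effect, p = tr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  out
}

#' Run the full pair-analysis stage
#'
#' Enumerates candidate pairs, builds matched cohorts (one per exposure
#' code, shared by every pair using that exposure), applies the crude-RR
#' prescreen in both directions, fits the hierarchical pair model in
#' batches, and derives all decisions: directionality (joint and per
#' sex), elevated relative risk, directional-pair flags, the
#' sex-difference in RR, and direction-strength contrasts.
#'
#' @param events first-occurrence events.
#' @param admissions admissions table.
#' @param patients patients table.
#' @param terminology terminology table.
#' @param min_patients candidate-pair inclusion threshold.
#' @param k matched controls per exposed patient.
#' @param seed master seed for matching and predictive draws.
#' @param priors [pair_model_priors()].
#' @param control [sampler_control()] for the pair-model batches.
#' @param batch_size maximum designs per joint fit.
#' @param prescreen_threshold crude-RR CI lower bound the prescreen must
#'   exceed (default 1.01).
#' @param rr_bound posterior RR HDI lower bound required for a
#'   directional pair (default 1.1).
#' @param dir_rope ROPE on the directionality probability.
#' @param rrdiff_rope ROPE on the RR sex difference.
#' @return list of class `"pair_analysis"`: `decisions` (one row per
#'   analyzed pair), `candidates`, `excluded_dagger`, `funnel` (filter
#'   counts), `omega` (per-pair direction-strength medians) and
#'   `strength_test` (variance-ratio result, when enough pairs).
#' @export
analyze_pairs <- function(events, admissions, patients, terminology,
                          min_patients = 100, k = 5, seed = 1,
                          priors = pair_model_priors(),
                          control = sampler_control(),
                          batch_size = 50, prescreen_threshold = 1.01,
                          rr_bound = 1.1, dir_rope = c(0.49, 0.51),
                          rrdiff_rope = c(-0.1, 0.1)) {
  cands <- enumerate_candidate_pairs(events, terminology, min_patients)
  pairs <- cands$pairs
  funnel <- c(candidate_pairs = nrow(pairs))
  if (!nrow(pairs))
    return(structure(list(decisions = NULL, candidates = cands$pairs,
                          excluded_dagger = cands$excluded_dagger,
                          funnel = c(funnel, prescreen_survivors = 0L,
                                     analyzed_pairs = 0L,
                                     directional_pairs = 0L),
                          omega = NULL, strength_test = NULL),
                     class = "pair_analysis"))

  pool <- .discharge_index(admissions, patients)
  exp_codes <- sort(unique(c(pairs$code_a, pairs$code_b)))
  cohorts <- list()
  for (i in seq_along(exp_codes))
    cohorts[[exp_codes[i]]] <- sample_matched_controls(
      exp_codes[i], events, admissions, patients, k = k,
      seed = (seed * 7919 + i) %% 2147483647, discharge_pool = pool)

  # per-sex ordering counts (observed, used by the count filter)
  by_code <- split(events[, c("patient_id", "event_date", "sex")],
                   events$code)
  order_counts <- function(a, b) {
    m <- merge(by_code[[a]], by_code[[b]], by = "patient_id")
    list(ab_m = sum(m$sex.x == "M" & m$event_date.x < m$event_date.y),
         ab_f = sum(m$sex.x == "F" & m$event_date.x < m$event_date.y),
         ba_m = sum(m$sex.x == "M" & m$event_date.x > m$event_date.y),
         ba_f = sum(m$sex.x == "F" & m$event_date.x > m$event_date.y))
  }

  # designs touching a sex-specific code are restricted to that sex:
  # the other sex has no possible events, and leaving its structurally
  # empty cells in the model puts the shared scale hyperpriors on an
  # unbounded ridge
  sspec_of <- function(cd) {
    s <- terminology$sex_specific[match(cd, terminology$code)]
    if (is.na(s)) "none" else s
  }
  restrict_sex <- function(cnt, a, b) {
    ss <- c(sspec_of(a), sspec_of(b))
    cells <- c("n_ab", "n_a", "n_b", "n_0")
    if ("male" %in% ss) cnt[cnt$sex == "F", cells] <- 0L
    if ("female" %in% ss) cnt[cnt$sex == "M", cells] <- 0L
    cnt
  }

  counts_ab <- counts_ba <- vector("list", nrow(pairs))
  passes <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$code_a[i]; b <- pairs$code_b[i]
    counts_ab[[i]] <- restrict_sex(tabulate_pair(cohorts[[a]], b, events),
                                   a, b)
    counts_ba[[i]] <- restrict_sex(tabulate_pair(cohorts[[b]], a, events),
                                   b, a)
    cr_ab <- crude_rr_ci(counts_ab[[i]], threshold = prescreen_threshold)
    cr_ba <- crude_rr_ci(counts_ba[[i]], threshold = prescreen_threshold)
    passes[i] <- any(cr_ab$passes) || any(cr_ba$passes)
  }
  funnel["prescreen_survivors"] <- sum(passes)
  surv <- which(passes)
  if (!length(surv))
    return(structure(list(decisions = NULL, candidates = pairs,
                          excluded_dagger = cands$excluded_dagger,
                          funnel = c(funnel, analyzed_pairs = 0L,
                                     directional_pairs = 0L),
                          omega = NULL, strength_test = NULL),
                     class = "pair_analysis"))

  # batched hierarchical fits over all surviving designs
  designs <- list()
  for (i in surv) {
    designs[[paste0(pairs$code_a[i], "->", pairs$code_b[i])]] <-
      counts_ab[[i]]
    designs[[paste0(pairs$code_b[i], "->", pairs$code_a[i])]] <-
      counts_ba[[i]]
  }
  # designs restricted to one sex (sex-specific codes) use a reduced
  # 4-cell layout and are batched separately from the both-sex designs
  sig <- vapply(designs, .pair_signature, "")
  pred <- conv <- list()
  bi_global <- 0
  for (sg in unique(sig)) {
    dn_all <- names(designs)[sig == sg]
    nb <- ceiling(length(dn_all) / batch_size)
    for (bi in seq_len(nb)) {
      bi_global <- bi_global + 1
      dn <- dn_all[((bi - 1) * batch_size + 1):
                     min(bi * batch_size, length(dn_all))]
      ctl <- control
      ctl$seed <- (control$seed * 104729 + bi_global) %% 2147483647
      pfit <- fit_pair_model(designs[dn], priors, ctl)
      pp <- pair_predictive_cells(pfit, seed = ctl$seed)
      for (d in dn) {
        pred[[d]] <- pp[, d, ]
        conv[[d]] <- pfit$fit$converged
      }
    }
  }

  cell_mat <- function(pp, sexchar) {
    cols <- paste0(c("ex1ev1", "ex1ev0", "ex0ev1", "ex0ev0"), sexchar)
    if (!all(cols %in% colnames(pp))) return(NULL)
    pp[, cols, drop = FALSE]
  }
  dsum <- function(x) if (is.null(x$hdi)) c(NA, NA, NA) else
    c(x$median, x$hdi$lower, x$hdi$upper)

  rows <- list(); omega_m <- omega_f <- numeric(0)
  for (i in surv) {
    a <- pairs$code_a[i]; b <- pairs$code_b[i]
    nm_ab <- paste0(a, "->", b); nm_ba <- paste0(b, "->", a)
    pp_ab <- pred[[nm_ab]]; pp_ba <- pred[[nm_ba]]
    converged <- conv[[nm_ab]] && conv[[nm_ba]]
    cm_ab <- cell_mat(pp_ab, "M"); cf_ab <- cell_mat(pp_ab, "F")
    cm_ba <- cell_mat(pp_ba, "M"); cf_ba <- cell_mat(pp_ba, "F")
    # a sex entirely masked (sex-specific codes) contributes nothing
    strip <- function(x) if (is.null(x) || all(is.na(x))) NULL else x
    add0 <- function(x, y) if (is.null(x)) y else if (is.null(y)) x
      else x + y
    c1 <- function(x) if (is.null(x)) NULL else x[, 1]

    dir_joint <- directionality(
      add0(c1(strip(cm_ab)), c1(strip(cf_ab))),
      add0(c1(strip(cm_ba)), c1(strip(cf_ba))), dir_rope)
    dir_men <- directionality(c1(strip(cm_ab)), c1(strip(cm_ba)),
                              dir_rope)
    dir_women <- directionality(c1(strip(cf_ab)), c1(strip(cf_ba)),
                                dir_rope)
    rr_ab <- adjusted_rr(strip(cm_ab), strip(cf_ab), rr_bound)
    rr_ba <- adjusted_rr(strip(cm_ba), strip(cf_ba), rr_bound)

    # a grouping is directional iff its direction HDI excludes the ROPE
    # and the RR HDI lower bound of that direction exceeds the bound
    dir_flag <- function(dir, rr_ab_g, rr_ba_g) {
      if (!converged || is.na(dir$median) || is.null(dir$hdi))
        return(NA)
      if (dir$decision != "excludes") return(FALSE)
      fw <- dir$hdi$lower > 0.5
      rr_g <- if (fw) rr_ab_g else rr_ba_g
      if (is.null(rr_g) || is.na(rr_g$elevated)) return(NA)
      rr_g$elevated
    }
    d_j <- dir_flag(dir_joint, rr_ab$joint, rr_ba$joint)
    d_m <- dir_flag(dir_men, rr_ab$men, rr_ba$men)
    d_w <- dir_flag(dir_women, rr_ab$women, rr_ba$women)

    oc <- order_counts(a, b)
    # sex difference in RR, evaluated along the preferred direction
    pref_fwd <- if (!is.na(d_j) && d_j) dir_joint$hdi$lower > 0.5
      else if (!is.na(d_m) && d_m) dir_men$hdi$lower > 0.5
      else if (!is.na(d_w) && d_w) dir_women$hdi$lower > 0.5
      else NA
    if (!is.na(pref_fwd)) {
      rr_pref <- if (pref_fwd) rr_ab else rr_ba
      n_dm <- if (pref_fwd) oc$ab_m else oc$ba_m
      n_df <- if (pref_fwd) oc$ab_f else oc$ba_f
      rrd <- rr_sex_difference(rr_pref$men$draws, rr_pref$women$draws,
                               n_dm, n_df, rrdiff_rope)
    } else {
      rrd <- list(median = NA_real_, hdi = NULL, significant = NA)
    }

    om <- direction_strength(dir_joint$draws, dir_men$draws,
                             dir_women$draws)
    omega_m <- c(omega_m, stats::median(om$omega_men))
    omega_f <- c(omega_f, stats::median(om$omega_women))

    sj <- dsum(dir_joint); sm <- dsum(dir_men); sw <- dsum(dir_women)
    rj_ab <- dsum(rr_ab$joint); rm_ab <- dsum(rr_ab$men)
    rw_ab <- dsum(rr_ab$women)
    rj_ba <- dsum(rr_ba$joint); rm_ba <- dsum(rr_ba$men)
    rw_ba <- dsum(rr_ba$women)
    rd <- dsum(rrd)
    rows[[length(rows) + 1]] <- data.frame(
      code_a = a, code_b = b,
      n_men = oc$ab_m + oc$ba_m, n_women = oc$ab_f + oc$ba_f,
      n_ab_men = oc$ab_m, n_ab_women = oc$ab_f,
      n_ba_men = oc$ba_m, n_ba_women = oc$ba_f,
      dir_joint = sj[1], dir_joint_lo = sj[2], dir_joint_hi = sj[3],
      dir_men = sm[1], dir_men_lo = sm[2], dir_men_hi = sm[3],
      dir_women = sw[1], dir_women_lo = sw[2], dir_women_hi = sw[3],
      rr_ab_joint = rj_ab[1], rr_ab_joint_lo = rj_ab[2],
      rr_ab_joint_hi = rj_ab[3],
      rr_ab_men = rm_ab[1], rr_ab_men_lo = rm_ab[2],
      rr_ab_men_hi = rm_ab[3],
      rr_ab_women = rw_ab[1], rr_ab_women_lo = rw_ab[2],
      rr_ab_women_hi = rw_ab[3],
      rr_ba_joint = rj_ba[1], rr_ba_joint_lo = rj_ba[2],
      rr_ba_joint_hi = rj_ba[3],
      rr_ba_men = rm_ba[1], rr_ba_men_lo = rm_ba[2],
      rr_ba_men_hi = rm_ba[3],
      rr_ba_women = rw_ba[1], rr_ba_women_lo = rw_ba[2],
      rr_ba_women_hi = rw_ba[3],
      directional_joint = d_j, directional_men = d_m,
      directional_women = d_w,
      preferred_forward = pref_fwd,
      rr_diff = rd[1], rr_diff_lo = rd[2], rr_diff_hi = rd[3],
      rr_diff_significant = rrd$significant,
      omega_men = stats::median(om$omega_men),
      omega_women = stats::median(om$omega_women),
      converged = converged,
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, rows)
  rownames(decisions) <- NULL
  funnel["analyzed_pairs"] <- nrow(decisions)
  funnel["directional_pairs"] <- sum(
    decisions$directional_joint | decisions$directional_men |
      decisions$directional_women, na.rm = TRUE)

  om_ok <- is.finite(omega_m) & is.finite(omega_f)
  strength <- if (sum(om_ok) >= 3 && stats::var(omega_f[om_ok]) > 0)
    direction_strength_test(omega_m[om_ok], omega_f[om_ok]) else NULL
  structure(list(decisions = decisions, candidates = pairs,
                 excluded_dagger = cands$excluded_dagger,
                 funnel = funnel,
                 omega = data.frame(code_a = pairs$code_a[surv],
                                    code_b = pairs$code_b[surv],
                                    omega_men = omega_m,
                                    omega_women = omega_f),
                 strength_test = strength),
            class = "pair_analysis")
}

#' @export
print.pair_analysis <- function(x, ...) {
  cat("Pair analysis funnel:\n")
  print(x$funnel)
  invisible(x)
}
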