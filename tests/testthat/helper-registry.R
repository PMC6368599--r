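# Shared fixtures, generated in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

# default-conditions synthetic registry (20,000 patients), preprocessed
fixture_registry <- function() {
  if (is.null(.fixture_env$reg)) {
    cfg <- registry_config(n_patients = 20000, seed = 313)
    reg <- generate_registry(cfg)
    adm <- merge_admissions(reg$admissions)
    ev <- extract_first_occurrences(adm, reg$patients, reg$terminology,
                                    cfg$study_start, cfg$study_end)
    .fixture_env$reg <- list(cfg = cfg, reg = reg, adm = adm, events = ev)
  }
  .fixture_env$reg
}

# incidence fit on the default fixture registry, cached
fixture_incidence_fit <- function() {
  if (is.null(.fixture_env$ifit)) {
    fx <- fixture_registry()
    st <- build_strata(fx$events, fx$reg$patients, fx$reg$terminology,
                       fx$cfg$study_start, fx$cfg$study_end)
    .fixture_env$ifit <- fit_incidence(
      st, control = sampler_control(n_warmup = 300, n_draws = 300,
                                    seed = 4))
  }
  .fixture_env$ifit
}

# a hand-built miniature admissions table exercising the merge and
# date-assignment rules
mini_admissions <- function() {
  d <- function(x) as.Date(x)
  data.frame(
    admission_id = c("A1", "A2", "A2", "A3", "A4", "A5", "A6", "A7"),
    patient_id = c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P3"),
    admission_type = c("inpatient", "inpatient", "inpatient", "inpatient",
                       "outpatient", "outpatient", "emergency",
                       "outpatient"),
    admission_date = d(c("2001-03-01", "2001-03-05", "2001-03-05",
                         "2005-06-01", "2010-01-02", "2011-05-01",
                         "2012-02-01", "2000-04-01")),
    discharge_date = d(c("2001-03-04", "2001-03-09", "2001-03-09",
                         "2005-06-07", NA, "2011-05-01", "2012-02-01",
                         "2000-04-02")),
    code = c("I10.2", "I10.9", "E11.0", "I10.1", "J45.9", "J45.1",
             "K35.0", "X99.1"),
    role = c("other", "other", "other", "other", "other", "other",
             "referral", "other"),
    date_recorded = d(c("2001-03-04", "2001-03-09", "2001-03-09",
                        "2005-06-07", "2010-01-15", "2011-05-01",
                        "2012-02-01", "2000-04-02")),
    stringsAsFactors = FALSE)
}

mini_patients <- function() {
  data.frame(patient_id = c("P1", "P2", "P3"),
             sex = c("M", "F", "F"),
             birth_date = as.Date(c("1950-06-15", "1980-01-01",
                                    "1995-12-31")),
             stringsAsFactors = FALSE)
}

mini_terminology <- function() {
  data.frame(
    code = c("I10", "E11", "J45", "K35", "X99", "A46", "B95"),
    chapter = c(9L, 4L, 10L, 11L, 20L, 1L, 1L),
    sex_specific = "none",
    chronic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    dagger_asterisk_role = c("none", "none", "none", "none", "none",
                             "asterisk", "dagger"),
    dagger_asterisk_partner = c(NA, NA, NA, NA, NA, "B95", "A46"),
    stringsAsFactors = FALSE)
}

# a fake pair-decision table with the columns classify_reversed and the
# trajectory search rely on
make_decisions <- function(code_a, code_b, dir_joint = 0.6,
                           dir_men = 0.6, dir_women = 0.6,
                           directional_joint = TRUE,
                           directional_men = TRUE,
                           directional_women = TRUE,
                           rr = 2, half_width = 0.02) {
  n <- length(code_a)
  rep_n <- function(x) rep_len(x, n)
  data.frame(
    code_a = code_a, code_b = code_b,
    n_men = rep_n(500L), n_women = rep_n(500L),
    dir_joint = rep_n(dir_joint),
    dir_joint_lo = rep_n(dir_joint - half_width),
    dir_joint_hi = rep_n(dir_joint + half_width),
    dir_men = rep_n(dir_men),
    dir_men_lo = rep_n(dir_men - half_width),
    dir_men_hi = rep_n(dir_men + half_width),
    dir_women = rep_n(dir_women),
    dir_women_lo = rep_n(dir_women - half_width),
    dir_women_hi = rep_n(dir_women + half_width),
    rr_ab_men = rep_n(rr), rr_ab_women = rep_n(rr),
    rr_ba_men = rep_n(1 / rr), rr_ba_women = rep_n(1 / rr),
    directional_joint = rep_n(directional_joint),
    directional_men = rep_n(directional_men),
    directional_women = rep_n(directional_women),
    stringsAsFactors = FALSE)
}

# events table for hand-built trajectory scenarios: `paths` is a list of
# character vectors of codes; each path is followed by `n_each` patients
# with strictly increasing dates
make_path_events <- function(paths, n_each, gap_days = 30) {
  rows <- list()
  pid <- 0
  for (p in seq_along(paths)) {
    codes <- paths[[p]]
    for (i in seq_len(n_each[p])) {
      pid <- pid + 1
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("T%05d", pid),
        sex = if (pid %% 2 == 0) "M" else "F",
        code = codes,
        event_date = as.Date("2000-01-01") + seq_along(codes) * gap_days +
          (pid %% 7),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# exhaustive trajectory oracle: enumerate every ordered subset of codes
# (length >= min_len) and count supporting patients directly
oracle_trajectories <- function(edges, events, min_support = 100,
                                min_len = 4, max_len = 8) {
  codes <- sort(unique(c(edges$from, edges$to)))
  edge_key <- paste(edges$from, edges$to)
  date_of <- lapply(codes, function(cd) {
    e <- events[events$code == cd, ]
    stats::setNames(as.numeric(e$event_date), e$patient_id)
  })
  names(date_of) <- codes
  patients <- unique(events$patient_id)
  res <- list()
  recurse <- function(path) {
    if (length(path) >= 2 &&
        !(paste(path[length(path) - 1], path[length(path)]) %in% edge_key))
      return()
    if (length(path) >= min_len) {
      sup <- sum(vapply(patients, function(p) {
        dd <- vapply(path, function(cd) {
          v <- date_of[[cd]][p]
          if (is.na(v)) return(NA_real_)
          v
        }, 1)
        !anyNA(dd) && all(diff(dd) > 0)
      }, TRUE))
      if (sup > min_support)
        res[[length(res) + 1]] <<- data.frame(
          trajectory = paste(path, collapse = "->"), support = sup,
          stringsAsFactors = FALSE)
    }
    if (length(path) >= max_len) return()
    for (nxt in setdiff(codes, path)) recurse(c(path, nxt))
  }
  for (cd in codes) recurse(cd)
  if (length(res)) do.call(rbind, res) else
    data.frame(trajectory = character(), support = integer())
}
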