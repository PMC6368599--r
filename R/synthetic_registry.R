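#' Synthetic hospital registry with known ground truth
#'
#' Generates a patient-level registry emulating the structure of a national
#' hospital register: patients (id, sex, birth date), admission rows (one
#' row per diagnosis code per contact, with inpatient/outpatient/emergency
#' types, discharge dates, open outpatient contacts and referral
#' diagnoses), a terminology table (level-3 codes with chapter,
#' sex-specific flag, chronic flag and dagger-asterisk partners), and a
#' ground-truth table recording every planted parameter so downstream
#' estimates can be checked against the truth.
#'
#' Disease events are drawn from piecewise-constant hazards (per calendar
#' year and ESP2013 age group) scaled by a men/women rate ratio and 21 age
#' multipliers. Planted directional pairs give patients with diagnosis A an
#' elevated chance of a later B: an induced B event is added with
#' probability `(rr - 1) * Lambda_B(remaining)` (the patient's remaining
#' baseline cumulative hazard of B) at a log-normal lag after A, which
#' makes the matched-cohort relative risk track `rr`. When a
#' `direction_prob` target is set, the generator additionally re-places a
#' computed random subset of co-diagnosed B dates so the realized A-first
#' fraction matches the target.
#'
#' @name synthetic_registry
NULL

#' Disease specification for the synthetic registry
#'
#' @param code level-3 diagnosis code string (e.g. `"C50"`).
#' @param chapter chapter number 1-19.
#' @param base_rate events per person-year in women (or in the only
#'   affected sex for sex-specific codes).
#' @param sex_rate_ratio men/women rate ratio (ignored for sex-specific
#'   codes).
#' @param age_rate_multipliers 21 positive multipliers, one per ESP2013
#'   age group.
#' @param sex_specific `"none"`, `"male"` or `"female"`.
#' @param chronic logical chronic-condition flag.
#' @param dagger_partner optional partnered code; this code is marked as
#'   the dagger (etiology) member and the partner as the asterisk
#'   (manifestation) member of a dual-coding pair.
#' @export
disease_spec <- function(code, chapter, base_rate, sex_rate_ratio = 1,
                         age_rate_multipliers = rep(1, 21),
                         sex_specific = c("none", "male", "female"),
                         chronic = FALSE, dagger_partner = NULL) {
  sex_specific <- match.arg(sex_specific)
  if (base_rate <= 0) stop("disease_spec: base_rate must be positive")
  if (sex_rate_ratio <= 0) stop("disease_spec: sex_rate_ratio must be positive")
  if (length(age_rate_multipliers) != 21 || any(age_rate_multipliers <= 0))
    stop("disease_spec: age_rate_multipliers must be 21 positive values")
  structure(list(code = code, chapter = as.integer(chapter),
                 base_rate = base_rate, sex_rate_ratio = sex_rate_ratio,
                 age_rate_multipliers = age_rate_multipliers,
                 sex_specific = sex_specific, chronic = isTRUE(chronic),
                 dagger_partner = dagger_partner),
            class = "disease_spec")
}

#' Planted directional pair specification
#'
#' @param code_a,code_b the exposure and event codes.
#' @param rr target relative risk of B given prior A (at least 1 for a
#'   planted positive).
#' @param direction_prob target fraction of co-diagnosed patients with A
#'   first, in `[0, 1]`, or `NULL` (default) to keep the ordering that
#'   arises naturally from forward-induced events plus background
#'   co-occurrence. When set, the generator calibrates the realized
#'   fraction empirically by re-placing a random subset of co-diagnosed B
#'   dates, which perturbs the realized relative risk away from `rr` in
#'   proportion to the adjustment.
#' @param lag lag distribution for induced events, a list with `dist`
#'   (only `"lognormal"`) and its parameters; default median 180 days.
#' @param sex_modifier multiplies `rr` in women.
#' @export
pair_spec <- function(code_a, code_b, rr, direction_prob = NULL,
                      lag = list(dist = "lognormal", meanlog = log(180),
                                 sdlog = 0.6),
                      sex_modifier = 1) {
  if (rr < 1) stop("pair_spec: rr must be >= 1 for a planted pair")
  if (!is.null(direction_prob) &&
      (direction_prob < 0 || direction_prob > 1))
    stop("pair_spec: direction_prob must be in [0, 1]")
  if (!identical(lag$dist, "lognormal"))
    stop("pair_spec: only lognormal lags are supported")
  if (sex_modifier <= 0) stop("pair_spec: sex_modifier must be positive")
  structure(list(code_a = code_a, code_b = code_b, rr = rr,
                 direction_prob = direction_prob, lag = lag,
                 sex_modifier = sex_modifier),
            class = "pair_spec")
}

#' Default disease panel for the synthetic registry
#'
#' Twenty level-3 codes across chapters with base rates spanning roughly
#' 0.002-0.02 events per person-year, age profiles that rise with age for
#' degenerative codes and peak young for injuries, a few codes with
#' marked sex differences, two sex-specific codes and one dagger-asterisk
#' partnership.
#'
#' @param n_codes number of codes from the panel (2 to 20).
#' @export
default_disease_specs <- function(n_codes = 20) {
  rising <- function(k) (seq(0.2, 3, length.out = 21))^k
  flat <- rep(1, 21)
  young <- c(seq(2, 0.6, length.out = 10), seq(0.55, 0.3, length.out = 11))
  panel <- list(
    disease_spec("A09", 1, 0.010, 1.0, young),
    disease_spec("C34", 2, 0.004, 1.6, rising(1.5), chronic = TRUE),
    disease_spec("C50", 2, 0.006, 1.0, rising(1), sex_specific = "female",
                 chronic = TRUE),
    disease_spec("D12", 2, 0.005, 1.1, rising(1)),
    disease_spec("E11", 4, 0.008, 1.3, rising(1.2), chronic = TRUE),
    disease_spec("E66", 4, 0.007, 0.8, flat, chronic = TRUE),
    disease_spec("F10", 5, 0.006, 2.2, flat, chronic = TRUE),
    disease_spec("F32", 5, 0.009, 0.55, flat, chronic = TRUE),
    disease_spec("G40", 6, 0.004, 1.1, flat, chronic = TRUE),
    disease_spec("I10", 9, 0.015, 1.2, rising(1.3), chronic = TRUE),
    disease_spec("I21", 9, 0.006, 1.9, rising(1.6), chronic = TRUE),
    disease_spec("I48", 9, 0.007, 1.5, rising(1.8), chronic = TRUE),
    disease_spec("J18", 10, 0.012, 1.1, rising(1)),
    disease_spec("J45", 10, 0.008, 0.9, young, chronic = TRUE),
    disease_spec("K35", 11, 0.004, 1.1, young),
    disease_spec("K80", 11, 0.007, 0.6, rising(1)),
    disease_spec("M16", 13, 0.005, 0.7, rising(2), chronic = TRUE),
    disease_spec("N20", 14, 0.005, 2.0, rising(1)),
    disease_spec("N40", 14, 0.006, 1.0, rising(2.5), sex_specific = "male",
                 chronic = TRUE),
    disease_spec("S52", 19, 0.009, 0.8, young)
  )
  stopifnot(n_codes >= 2, n_codes <= length(panel))
  panel[seq_len(n_codes)]
}

#' Registry generator configuration
#'
#' Defaults describe the desk-scale study conditions: 20,000 patients
#' followed 1994-2014 (21 calendar years), equal sexes, an age structure
#' matching the ESP2013 weights, the 20-code default disease panel, two
#' planted directional pairs, mostly outpatient contacts, 5% open
#' outpatient contacts and mild seasonality in admission dates.
#'
#' @param n_patients positive integer.
#' @param study_start,study_end calendar dates (coerced by `as.Date`).
#' @param sex_ratio fraction of men, in (0, 1).
#' @param age_distribution 21 non-negative weights over the ESP2013 age
#'   groups for age at study start (normalized internally).
#' @param disease_specs list of [disease_spec()].
#' @param pair_specs list of [pair_spec()].
#' @param admission_type_probs simplex over inpatient, outpatient,
#'   emergency.
#' @param open_contact_prob fraction of outpatient contacts left open
#'   (no discharge date).
#' @param seasonal_amplitude non-negative sinusoidal modulation of
#'   admission day-of-year frequency.
#' @param background_contact_rate routine contacts per person-year,
#'   coded with the encounter code `"Z00"` (chapter 21, so they are
#'   excluded from the analyzed events by the chapter filter but remain
#'   in the admission table as matching anchors -- without them every
#'   discharge would be a disease event and matched controls would be
#'   selected on their own morbidity).
#' @param seed integer RNG seed; all generation is deterministic given it.
#' @export
registry_config <- function(n_patients = 20000,
                            study_start = "1994-01-01",
                            study_end = "2014-12-31",
                            sex_ratio = 0.5,
                            age_distribution = esp2013()$weight,
                            disease_specs = default_disease_specs(),
                            pair_specs = list(
                              pair_spec("I10", "I48", rr = 3,
                                        direction_prob = 0.8),
                              pair_spec("F10", "S52", rr = 2,
                                        sex_modifier = 2)),
                            admission_type_probs = c(inpatient = 0.30,
                                                     outpatient = 0.55,
                                                     emergency = 0.15),
                            open_contact_prob = 0.05,
                            seasonal_amplitude = 0.2,
                            background_contact_rate = 1.5,
                            seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              sex_ratio = sex_ratio, age_distribution = age_distribution,
              disease_specs = disease_specs, pair_specs = pair_specs,
              admission_type_probs = admission_type_probs,
              open_contact_prob = open_contact_prob,
              seasonal_amplitude = seasonal_amplitude,
              background_contact_rate = background_contact_rate,
              seed = seed)
  .validate_registry_config(cfg)
  structure(cfg, class = "registry_config")
}

.validate_registry_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid registry config: field `%s` %s", field, msg),
         call. = FALSE)
  if (!is.finite(cfg$n_patients) || cfg$n_patients < 1)
    fail("n_patients", "must be a positive integer")
  if (is.na(cfg$study_start) || is.na(cfg$study_end) ||
      !(cfg$study_start < cfg$study_end))
    fail("study_start/study_end", "must satisfy study_start < study_end")
  if (cfg$sex_ratio <= 0 || cfg$sex_ratio >= 1)
    fail("sex_ratio", "must be in (0, 1)")
  if (length(cfg$age_distribution) != 21 || any(cfg$age_distribution < 0) ||
      sum(cfg$age_distribution) <= 0)
    fail("age_distribution", "must be 21 non-negative weights")
  if (abs(sum(cfg$admission_type_probs) - 1) > 1e-9 ||
      any(cfg$admission_type_probs < 0))
    fail("admission_type_probs", "must be a simplex over the three types")
  if (cfg$open_contact_prob < 0 || cfg$open_contact_prob > 1)
    fail("open_contact_prob", "must be in [0, 1]")
  if (cfg$seasonal_amplitude < 0)
    fail("seasonal_amplitude", "must be non-negative")
  if (is.null(cfg$background_contact_rate) ||
      cfg$background_contact_rate < 0)
    fail("background_contact_rate", "must be non-negative")
  codes <- vapply(cfg$disease_specs, `[[`, "", "code")
  if (anyDuplicated(codes)) fail("disease_specs", "has duplicated codes")
  for (ps in cfg$pair_specs) {
    if (!(ps$code_a %in% codes) || !(ps$code_b %in% codes))
      fail("pair_specs", "refers to a code absent from disease_specs")
    if (ps$code_a == ps$code_b) fail("pair_specs", "pairs a code with itself")
  }
  invisible(TRUE)
}

#' Generate a synthetic registry
#'
#' @param config a [registry_config()].
#' @return list of class `"synthetic_registry"` with data.frames
#'   `patients`, `admissions`, `terminology`, `truth_codes`,
#'   `truth_pairs`, plus the `config`. Dates are `Date`; the admissions
#'   table has one row per diagnosis code per contact.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  .validate_registry_config(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                          .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(config$seed)

  n <- config$n_patients
  start <- config$study_start; end <- config$study_end
  years <- seq(as.integer(format(start, "%Y")),
               as.integer(format(end, "%Y")))
  ny <- length(years)
  esp <- esp2013()

  ## patients ---------------------------------------------------------
  sex <- ifelse(runif(n) < config$sex_ratio, "M", "F")
  grp0 <- sample.int(21, n, replace = TRUE,
                     prob = config$age_distribution / sum(config$age_distribution))
  span <- ifelse(is.finite(esp$age_high), esp$age_high - esp$age_low + 1, 5)
  age0 <- esp$age_low[grp0] + runif(n) * span[grp0]
  birth <- start - round(age0 * 365.25)
  patients <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                         sex = sex, birth_date = birth,
                         stringsAsFactors = FALSE)

  # age group per (patient, calendar year), mid-year reference
  age_mid <- outer(as.numeric(start - birth) / 365.25, seq_len(ny) - 0.5, `+`)
  grp_py <- matrix(esp_age_group(pmin(age_mid, 99.9)), n, ny)

  ## disease events ---------------------------------------------------
  codes <- vapply(config$disease_specs, `[[`, "", "code")
  # numeric days since 1970-01-01 (matrices cannot carry the Date class)
  event_date <- matrix(NA_real_, n, length(codes),
                       dimnames = list(NULL, codes))
  cumhaz <- vector("list", length(codes))  # n x ny cumulative hazards
  for (d in seq_along(config$disease_specs)) {
    ds <- config$disease_specs[[d]]
    sexmult <- ifelse(sex == "M", ds$sex_rate_ratio, 1)
    if (ds$sex_specific == "male") sexmult[sex == "F"] <- 0
    if (ds$sex_specific == "female") sexmult[sex == "M"] <- 0
    rate_py <- matrix(ds$age_rate_multipliers[grp_py], n, ny) *
      ds$base_rate * sexmult
    ch <- rate_py
    for (j in 2:ny) ch[, j] <- ch[, j - 1] + rate_py[, j]
    cumhaz[[d]] <- ch
    E <- stats::rexp(n)
    hit <- E < ch[, ny]
    yidx <- rowSums(ch < E) + 1L
    idx <- which(hit)
    if (length(idx)) {
      doy <- .seasonal_doy(length(idx), config$seasonal_amplitude)
      ed <- as.Date(sprintf("%d-01-01", years[yidx[idx]])) + doy - 1
      ed <- pmin(ed, end)
      event_date[idx, d] <- as.numeric(ed)
    }
  }

  ## planted pairs ----------------------------------------------------
  for (ps in config$pair_specs) {
    ia <- match(ps$code_a, codes); ib <- match(ps$code_b, codes)
    has_a <- which(!is.na(event_date[, ia]))
    if (!length(has_a)) next
    t_a <- as.Date(event_date[has_a, ia], origin = "1970-01-01")
    rr_eff <- ps$rr * ifelse(sex[has_a] == "F", ps$sex_modifier, 1)
    # remaining baseline cumulative hazard of B from t_a to study end
    ch_b <- cumhaz[[ib]][has_a, , drop = FALSE]
    ya <- pmin(pmax(as.integer(format(t_a, "%Y")) - years[1] + 1L, 1L), ny)
    frac <- as.numeric(t_a - as.Date(sprintf("%d-01-01", years[ya]))) / 365
    ch_at_a <- ifelse(ya > 1, ch_b[cbind(seq_along(ya), pmax(ya - 1, 1))], 0) +
      frac * (ch_b[cbind(seq_along(ya), ya)] -
                ifelse(ya > 1, ch_b[cbind(seq_along(ya), pmax(ya - 1, 1))], 0))
    lam_rem <- pmax(ch_b[, ny] - ch_at_a, 0)
    q <- pmin(0.95, (rr_eff - 1) * lam_rem)
    induced <- runif(length(has_a)) < q
    idx <- which(induced)
    if (length(idx)) {
      # induced events are forward in time: a disease-promoting effect
      lag <- pmax(round(stats::rlnorm(length(idx), ps$lag$meanlog,
                                      ps$lag$sdlog)), 1)
      t_b <- t_a[idx] + lag
      keep <- t_b <= end
      pid <- has_a[idx[keep]]
      new_b <- as.numeric(t_b[keep])
      old_b <- event_date[pid, ib]
      event_date[pid, ib] <- ifelse(is.na(old_b), new_b, pmin(old_b, new_b))
    }
    # optional empirical ordering calibration among all co-diagnosed
    if (!is.null(ps$direction_prob)) {
      co <- which(!is.na(event_date[, ia]) & !is.na(event_date[, ib]) &
                    event_date[, ia] != event_date[, ib])
      if (length(co)) {
        fwd_now <- event_date[co, ia] < event_date[co, ib]
        n_target <- round(ps$direction_prob * length(co))
        n_flip <- n_target - sum(fwd_now)
        flip <- integer(0)
        if (n_flip > 0) {
          cand <- co[!fwd_now]
          flip <- cand[sample.int(length(cand), min(n_flip, length(cand)))]
          dirn <- +1
        } else if (n_flip < 0) {
          cand <- co[fwd_now]
          flip <- cand[sample.int(length(cand), min(-n_flip, length(cand)))]
          dirn <- -1
        }
        if (length(flip)) {
          lag2 <- pmax(round(stats::rlnorm(length(flip), ps$lag$meanlog,
                                           ps$lag$sdlog)), 1)
          nb <- event_date[flip, ia] + dirn * lag2
          nb <- pmin(pmax(nb, as.numeric(start)), as.numeric(end))
          ok <- nb != event_date[flip, ia] &
            (sign(nb - event_date[flip, ia]) == dirn)
          event_date[flip[ok], ib] <- nb[ok]
        }
      }
    }
  }

  ## admissions -------------------------------------------------------
  ev <- which(!is.na(event_date), arr.ind = TRUE)
  ne <- nrow(ev)
  type <- sample(names(config$admission_type_probs), ne, replace = TRUE,
                 prob = config$admission_type_probs)
  disch <- as.Date(event_date[ev], origin = "1970-01-01")
  stay <- ifelse(type == "inpatient", pmin(stats::rgeom(ne, 0.3), 30L), 0L)
  adm <- pmax(disch - stay, start)
  open <- type == "outpatient" & runif(ne) < config$open_contact_prob
  admissions <- data.frame(
    admission_id = sprintf("A%07d", seq_len(ne)),
    patient_id = patients$patient_id[ev[, 1]],
    admission_type = type,
    admission_date = adm,
    discharge_date = as.Date(ifelse(open, NA, disch), origin = "1970-01-01"),
    code = paste0(codes[ev[, 2]],
                  sprintf(".%d", sample.int(9, ne, replace = TRUE))),
    role = "other",
    date_recorded = disch,
    stringsAsFactors = FALSE)

  # referral-role noise rows (excluded downstream by contract)
  n_ref <- max(1L, round(0.02 * ne))
  ref_rows <- sample.int(ne, n_ref)
  referrals <- admissions[ref_rows, ]
  referrals$code <- paste0(sample(codes, n_ref, replace = TRUE),
                           sprintf(".%d", sample.int(9, n_ref,
                                                     replace = TRUE)))
  referrals$role <- "referral"

  # routine background contacts (encounter code, chapter 21): excluded
  # from analyzed events by the chapter filter, but they anchor control
  # matching so that a control's discharge is not itself a disease event
  background <- NULL
  n_bg_tot <- 0L
  if (config$background_contact_rate > 0) {
    n_bg <- stats::rpois(n, config$background_contact_rate * ny)
    n_bg_tot <- sum(n_bg)
  }
  if (n_bg_tot > 0) {
    bg_pat <- rep(seq_len(n), n_bg)
    bg_year <- sample(years, n_bg_tot, replace = TRUE)
    bg_doy <- .seasonal_doy(n_bg_tot, config$seasonal_amplitude)
    bg_disch <- pmin(as.Date(sprintf("%d-01-01", bg_year)) + bg_doy - 1,
                     end)
    bg_type <- sample(names(config$admission_type_probs), n_bg_tot,
                      replace = TRUE, prob = config$admission_type_probs)
    bg_stay <- ifelse(bg_type == "inpatient",
                      pmin(stats::rgeom(n_bg_tot, 0.5), 14L), 0L)
    bg_open <- bg_type == "outpatient" &
      runif(n_bg_tot) < config$open_contact_prob
    background <- data.frame(
      admission_id = sprintf("B%07d", seq_len(n_bg_tot)),
      patient_id = patients$patient_id[bg_pat],
      admission_type = bg_type,
      admission_date = pmax(bg_disch - bg_stay, start),
      discharge_date = as.Date(ifelse(bg_open, NA, bg_disch),
                               origin = "1970-01-01"),
      code = "Z00.0",
      role = "other",
      date_recorded = bg_disch,
      stringsAsFactors = FALSE)
  }
  admissions <- rbind(admissions, referrals, background)
  admissions <- admissions[order(admissions$patient_id,
                                 admissions$admission_date,
                                 admissions$admission_id), ]
  rownames(admissions) <- NULL

  ## terminology ------------------------------------------------------
  dag <- vapply(config$disease_specs, function(d)
    if (is.null(d$dagger_partner)) NA_character_ else d$dagger_partner, "")
  terminology <- data.frame(
    code = codes,
    chapter = vapply(config$disease_specs, `[[`, 1L, "chapter"),
    sex_specific = vapply(config$disease_specs, `[[`, "", "sex_specific"),
    chronic = vapply(config$disease_specs, `[[`, TRUE, "chronic"),
    dagger_asterisk_role = ifelse(is.na(dag), "none", "dagger"),
    dagger_asterisk_partner = dag,
    stringsAsFactors = FALSE)
  ast <- which(terminology$code %in% stats::na.omit(dag))
  if (length(ast)) {
    terminology$dagger_asterisk_role[ast] <- "asterisk"
    terminology$dagger_asterisk_partner[ast] <-
      terminology$code[match(terminology$code[ast], dag)]
  }
  terminology <- rbind(terminology, data.frame(
    code = "Z00", chapter = 21L, sex_specific = "none", chronic = FALSE,
    dagger_asterisk_role = "none", dagger_asterisk_partner = NA_character_,
    stringsAsFactors = FALSE))

  ## ground truth -----------------------------------------------------
  truth_codes <- do.call(rbind, lapply(config$disease_specs, function(d) {
    rate_f <- d$base_rate * d$age_rate_multipliers
    rate_m <- rate_f * d$sex_rate_ratio
    if (d$sex_specific == "male") rate_f <- rep(0, 21)
    if (d$sex_specific == "female") rate_m <- rep(0, 21)
    w <- esp$weight
    data.frame(code = d$code, chapter = d$chapter,
               base_rate = d$base_rate, sex_rate_ratio = d$sex_rate_ratio,
               sex_specific = d$sex_specific, chronic = d$chronic,
               true_air_men = sum(rate_m * w),
               true_air_women = sum(rate_f * w),
               true_air_all = sum((rate_m + rate_f) / 2 * w),
               stringsAsFactors = FALSE)
  }))
  truth_pairs <- if (length(config$pair_specs)) {
    do.call(rbind, lapply(config$pair_specs, function(p)
      data.frame(code_a = p$code_a, code_b = p$code_b, rr = p$rr,
                 direction_prob = if (is.null(p$direction_prob))
                   NA_real_ else p$direction_prob,
                 sex_modifier = p$sex_modifier,
                 lag_meanlog = p$lag$meanlog, lag_sdlog = p$lag$sdlog,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(code_a = character(), code_b = character(), rr = numeric(),
               direction_prob = numeric(), sex_modifier = numeric(),
               lag_meanlog = numeric(), lag_sdlog = numeric())
  }

  structure(list(patients = patients, admissions = admissions,
                 terminology = terminology, truth_codes = truth_codes,
                 truth_pairs = truth_pairs, config = config),
            class = "synthetic_registry")
}

# day-of-year with sinusoidal volume modulation (peak in winter)
.seasonal_doy <- function(n, amplitude) {
  doy <- seq_len(365)
  w <- 1 + amplitude * cos(2 * pi * (doy - 15) / 365)
  sample(doy, n, replace = TRUE, prob = w / sum(w))
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf(
    "Synthetic registry: %d patients, %d admission rows, %d codes, %d planted pairs\n",
    nrow(x$patients), nrow(x$admissions), nrow(x$terminology),
    nrow(x$truth_pairs)))
  invisible(x)
}

#' Ground-truth summary keyed for joining with pipeline estimates
#'
#' @param registry a `synthetic_registry` (or its `truth_codes` /
#'   `truth_pairs` pair as a list).
#' @return list with `codes` (one row per code, including the true
#'   age-adjusted incidence rate per 100,000 person-years computable in
#'   closed form from the disease specification and ESP2013 weights) and `pairs` (one row
#'   per planted pair with its target rr, direction and sex modifier).
#' @export
ground_truth_summary <- function(registry) {
  if (is.null(registry$truth_codes))
    stop("ground truth table missing; pass a generated registry")
  list(codes = registry$truth_codes, pairs = registry$truth_pairs)
}

#' Write a registry to delimited files
#'
#' Writes `patients.tsv`, `admissions.tsv`, `terminology.tsv`,
#' `truth_codes.tsv`, `truth_pairs.tsv` (tab-separated, ISO-8601 dates).
#'
#' @param registry a `synthetic_registry`.
#' @param dir output directory (created if needed).
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "admissions", "terminology", "truth_codes",
               "truth_pairs"))
    utils::write.table(registry[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a registry written by [write_registry()]
#' @param dir directory containing the delimited tables.
#' @export
read_registry <- function(dir) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) return(NULL)
    utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  out <- list(patients = rd("patients"), admissions = rd("admissions"),
              terminology = rd("terminology"), truth_codes = rd("truth_codes"),
              truth_pairs = rd("truth_pairs"))
  for (col in c("birth_date")) out$patients[[col]] <- as.Date(out$patients[[col]])
  for (col in c("admission_date", "discharge_date", "date_recorded"))
    out$admissions[[col]] <- as.Date(out$admissions[[col]])
  class(out) <- "synthetic_registry"
  out
}
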