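#' Registry preprocessing
#'
#' Turns raw admission rows into per-patient first-occurrence diagnosis
#' events: ward-transfer/re-admission merging for inpatient contacts,
#' referral-diagnosis exclusion, level-3 code truncation, chapter
#' filtering, date assignment (discharge date, or the date of the last
#' recorded diagnosis for open contacts) and ESP2013 age grouping.
#' Dates have day resolution; intervals are in days and closed on both
#' ends.
#'
#' @name registry_core
NULL

#' Merge contiguous inpatient admission records
#'
#' For each patient, inpatient records whose admission date is at most one
#' day after the previous record's discharge date are combined into one
#' record (ward transfers and next-day re-admissions): the merged record
#' takes the earliest admission date, the latest discharge date and the
#' union of diagnosis rows. Outpatient and emergency contacts are never
#' chained. The operation is idempotent.
#'
#' @param admissions admissions table (one row per diagnosis code) with
#'   columns `admission_id`, `patient_id`, `admission_type`,
#'   `admission_date`, `discharge_date`, plus diagnosis columns.
#' @return the table with merged records sharing an `admission_id` and
#'   updated dates.
#' @export
merge_admissions <- function(admissions) {
  adm <- admissions
  if (length(unique(paste(adm$admission_id, adm$patient_id))) >
      length(unique(adm$admission_id)))
    stop("inconsistent patient ids within an admission_id")
  cl <- adm[!duplicated(adm$admission_id),
            c("admission_id", "patient_id", "admission_type",
              "admission_date", "discharge_date")]
  ip <- cl[cl$admission_type == "inpatient" & !is.na(cl$discharge_date), ]
  if (nrow(ip)) {
    ip <- ip[order(ip$patient_id, ip$admission_date, ip$discharge_date), ]
    # a record starts a new chain unless it begins at most one day
    # after the running maximum discharge of its patient's chain so far
    dis <- as.numeric(ip$discharge_date)
    adm_d <- as.numeric(ip$admission_date)
    runmax <- ave(dis, ip$patient_id, FUN = cummax)
    prevmax <- c(-Inf, runmax[-length(runmax)])
    new_patient <- c(TRUE, ip$patient_id[-1] !=
                       ip$patient_id[-nrow(ip)])
    breaks <- new_patient | (adm_d > prevmax + 1)
    chain <- cumsum(breaks)
    lead_id <- ip$admission_id[breaks][chain]
    agg_adm <- tapply(adm_d, chain, min)[chain]
    agg_dis <- tapply(dis, chain, max)[chain]
    map <- match(adm$admission_id, ip$admission_id)
    hit <- !is.na(map)
    adm$admission_id[hit] <- lead_id[map[hit]]
    adm$admission_date[hit] <- as.Date(agg_adm[map[hit]],
                                       origin = "1970-01-01")
    adm$discharge_date[hit] <- as.Date(agg_dis[map[hit]],
                                       origin = "1970-01-01")
  }
  adm
}

#' Extract per-patient first-occurrence diagnosis events
#'
#' Applies the preprocessing contract: referral diagnoses are dropped,
#' codes are truncated to their first three characters, codes from
#' chapters 20-22 (or absent from the terminology) are removed, the event
#' date is the record's discharge date -- or the date of the last recorded
#' diagnosis for open contacts -- and for codes appearing in several
#' records the earliest assigned date wins. Ages are computed at the event
#' date and grouped by the 21 ESP2013 groups.
#'
#' @param admissions (merged) admissions table.
#' @param patients patients table with `patient_id`, `sex`, `birth_date`.
#' @param terminology terminology table (see [generate_registry()]).
#' @param study_start,study_end window; events outside are dropped.
#' @return data.frame of events: `patient_id`, `sex`, `code`,
#'   `event_date`, `encounter_type`, `age_years`, `age_group`; one row
#'   per (patient, code).
#' @export
extract_first_occurrences <- function(admissions, patients, terminology,
                                      study_start, study_end) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  adm <- admissions[admissions$role != "referral", , drop = FALSE]
  adm$code3 <- substr(adm$code, 1, 3)

  known <- adm$code3 %in% terminology$code
  if (any(!known)) {
    warning(sprintf("dropping %d diagnosis rows with unknown codes (%s)",
                    sum(!known),
                    paste(utils::head(unique(adm$code3[!known]), 5),
                          collapse = ", ")))
    adm <- adm[known, , drop = FALSE]
  }
  chap <- terminology$chapter[match(adm$code3, terminology$code)]
  adm <- adm[chap < 20, , drop = FALSE]
  if (!nrow(adm)) return(.empty_events())

  # assigned date: discharge date, else date of the last diagnosis of
  # the (open) contact
  assigned <- as.numeric(adm$discharge_date)
  open <- is.na(assigned)
  if (any(open)) {
    sub <- adm[adm$admission_id %in% adm$admission_id[open], ]
    last_dx <- tapply(as.numeric(sub$date_recorded), sub$admission_id,
                      max, na.rm = TRUE)
    assigned[open] <- last_dx[adm$admission_id[open]]
  }
  adm$assigned_date <- assigned

  ord <- order(adm$patient_id, adm$code3, adm$assigned_date)
  adm <- adm[ord, ]
  first <- !duplicated(adm[, c("patient_id", "code3")])
  ev <- adm[first, c("patient_id", "code3", "assigned_date",
                     "admission_type")]
  names(ev) <- c("patient_id", "code", "event_date", "encounter_type")
  ev$event_date <- as.Date(ev$event_date, origin = "1970-01-01")
  ev <- ev[ev$event_date >= study_start & ev$event_date <= study_end, ,
           drop = FALSE]

  pm <- match(ev$patient_id, patients$patient_id)
  if (anyNA(pm)) stop("admission rows reference unknown patients")
  ev$sex <- patients$sex[pm]
  ev$age_years <- as.numeric(ev$event_date - patients$birth_date[pm]) / 365.25
  if (any(ev$age_years < 0)) stop("diagnosis event before patient birth")
  ev$age_group <- esp_age_group(ev$age_years)
  rownames(ev) <- NULL
  ev
}

.empty_events <- function() {
  data.frame(patient_id = character(), code = character(),
             event_date = as.Date(character()),
             encounter_type = character(), sex = character(),
             age_years = numeric(), age_group = integer())
}

#' Dagger-asterisk partnership test
#'
#' True iff the two codes are partnered members of an ICD-10 dual-coding
#' (dagger = etiology, asterisk = manifestation) pair, in either order.
#'
#' @param code_a,code_b level-3 codes present in the terminology.
#' @param terminology terminology table.
#' @export
is_dagger_asterisk_pair <- function(code_a, code_b, terminology) {
  ia <- match(code_a, terminology$code)
  ib <- match(code_b, terminology$code)
  if (is.na(ia) || is.na(ib)) stop("both codes must be in the terminology")
  if (code_a == code_b) return(FALSE)
  isTRUE(terminology$dagger_asterisk_partner[ia] == code_b) ||
    isTRUE(terminology$dagger_asterisk_partner[ib] == code_a)
}

#' Person-years at risk per (ESP2013 age group, sex)
#'
#' Exact person-time each patient spends in each age group during the
#' study window, from birth dates; used as the population-at-risk
#' offsets of the incidence model. With `censor_dates`, each patient's
#' observation ends at their censoring date (e.g. the first occurrence
#' of the diagnosis under study), giving the at-risk time for a
#' first-occurrence rate.
#'
#' @param patients patients table.
#' @param study_start,study_end window dates.
#' @param censor_dates optional per-patient end dates (`NA` for none);
#'   observation stops at `min(censor_date, study_end)`.
#' @return data.frame `age_group`, `sex`, `person_years` (42 rows).
#' @export
person_years <- function(patients, study_start, study_end,
                         censor_dates = NULL) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  esp <- esp2013()
  age_start <- as.numeric(study_start - patients$birth_date) / 365.25
  end <- rep(as.numeric(study_end) + 1, nrow(patients))
  if (!is.null(censor_dates)) {
    cd <- as.numeric(as.Date(censor_dates))
    end <- pmin(end, ifelse(is.na(cd), end, cd))
  }
  age_end <- (end - as.numeric(patients$birth_date)) / 365.25
  out <- expand.grid(age_group = seq_len(21), sex = c("F", "M"),
                     stringsAsFactors = FALSE)
  py <- numeric(nrow(out))
  for (g in seq_len(21)) {
    lo <- esp$age_low[g]
    hi <- if (is.finite(esp$age_high[g])) esp$age_high[g] + 1 else 200
    ov <- pmax(pmin(age_end, hi) - pmax(age_start, lo), 0)
    for (s in c("F", "M"))
      py[out$age_group == g & out$sex == s] <- sum(ov[patients$sex == s])
  }
  out$person_years <- py
  out
}
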