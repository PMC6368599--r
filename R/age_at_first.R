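#' Sex differences in age at first hospital diagnosis
#'
#' Mean age at the first occurrence of each diagnosis is compared between
#' the sexes with Welch's t test on per-(code, sex) summaries; p values
#' are Benjamini-Hochberg adjusted, and chapter-level effects are
#' patient-count-weighted means of the per-code effects with the standard
#' error of the mean.
#'
#' @name age_at_first
NULL

#' Summarize age at first diagnosis per (code, sex)
#'
#' @param events first-occurrence events with `age_years`.
#' @return data.frame with `code`, `sex`, `n`, `mean_age`, `sd_age`,
#'   `sem_age`.
#' @export
summarize_age <- function(events) {
  sp <- split(events$age_years, list(events$code, events$sex), drop = TRUE)
  key <- strsplit(names(sp), ".", fixed = TRUE)
  out <- data.frame(
    code = vapply(key, `[[`, "", 1),
    sex = vapply(key, `[[`, "", 2),
    n = vapply(sp, length, 1L),
    mean_age = vapply(sp, mean, 1),
    sd_age = vapply(sp, function(x) if (length(x) > 1) stats::sd(x) else 0,
                    1),
    stringsAsFactors = FALSE)
  out$sem_age <- out$sd_age / sqrt(out$n)
  out <- out[order(out$code, out$sex), ]
  rownames(out) <- NULL
  out
}

#' Compare mean age at first diagnosis between the sexes
#'
#' Welch's t test per code, with effect = mean age in women minus mean age
#' in men (positive means women are diagnosed later), and BH-adjusted q
#' values. Codes present in only one sex (or with n < 2 in either) are
#' skipped.
#'
#' @param age_summary output of [summarize_age()].
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame per testable code: means, effect with 95% CI,
#'   p, q, significance flag.
#' @export
compare_age <- function(age_summary, fdr = 0.05) {
  codes <- unique(age_summary$code)
  rows <- lapply(codes, function(cd) {
    f <- age_summary[age_summary$code == cd & age_summary$sex == "F", ]
    m <- age_summary[age_summary$code == cd & age_summary$sex == "M", ]
    if (nrow(f) != 1 || nrow(m) != 1 || f$n < 2 || m$n < 2) return(NULL)
    tr <- welch_t(c(f$n, f$mean_age, f$sd_age), c(m$n, m$mean_age, m$sd_age))
    data.frame(code = cd, n_women = f$n, n_men = m$n,
               mean_age_women = f$mean_age, mean_age_men = m$mean_age,
               effect = tr$effect, ci_lower = tr$ci_lower,
               ci_upper = tr$ci_upper, statistic = tr$statistic,
               p = tr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out
}

#' Chapter-level weighted mean age difference
#'
#' Aggregates per-code effects to chapters using the total number of
#' patients per code as the weight, with the (unweighted) standard error
#' of the mean of the per-code effects per chapter.
#'
#' @param age_diff output of [compare_age()].
#' @param terminology terminology table (for the chapter of each code).
#' @return data.frame `chapter`, `n_codes`, `effect`, `sem`.
#' @export
chapter_weighted_mean <- function(age_diff, terminology) {
  if (is.null(age_diff) || !nrow(age_diff)) {
    return(data.frame(chapter = integer(), n_codes = integer(),
                      effect = numeric(), sem = numeric()))
  }
  chap <- terminology$chapter[match(age_diff$code, terminology$code)]
  w <- age_diff$n_women + age_diff$n_men
  keep <- !is.na(chap)
  sp <- split(seq_len(nrow(age_diff))[keep], chap[keep])
  out <- data.frame(
    chapter = as.integer(names(sp)),
    n_codes = vapply(sp, length, 1L),
    effect = vapply(sp, function(i)
      sum(age_diff$effect[i] * w[i]) / sum(w[i]), 1),
    sem = vapply(sp, function(i)
      if (length(i) > 1) stats::sd(age_diff$effect[i]) / sqrt(length(i))
      else 0, 1))
  rownames(out) <- NULL
  out
}
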