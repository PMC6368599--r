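#' Time between the diagnoses of directional pairs
#'
#' For directional pairs found in both sexes, the distribution of days
#' from the first diagnosis to the second (along the preferred direction)
#' is compared between men and women with the two-sided Mann-Whitney U
#' test; effects are differences of medians with the convention that a
#' negative value means the transition progresses faster in women.
#'
#' @name time_between
NULL

#' Collect per-pair diagnosis timespans
#'
#' One row per directional pair present in both sexes, with the day
#' counts from the first to the second diagnosis (preferred direction)
#' for every patient of each sex diagnosed in that order. Same-day
#' instances never appear (day counts are at least 1).
#'
#' @param events first-occurrence events.
#' @param decisions pair-decision table from [analyze_pairs()].
#' @return list of class `"pair_timespans"`: per pair, `days_men` and
#'   `days_women` vectors.
#' @export
collect_timespans <- function(events, decisions) {
  d <- decisions[!is.na(decisions$directional_men) &
                   !is.na(decisions$directional_women) &
                   decisions$directional_men & decisions$directional_women, ,
                 drop = FALSE]
  by_code <- split(events[, c("patient_id", "event_date", "sex")],
                   events$code)
  out <- list()
  for (i in seq_len(nrow(d))) {
    # per-sex preferred direction (they may disagree for reversed pairs)
    fw_m <- d$dir_men_lo[i] > 0.5
    fw_w <- d$dir_women_lo[i] > 0.5
    m <- merge(by_code[[d$code_a[i]]], by_code[[d$code_b[i]]],
               by = "patient_id")
    gap <- as.numeric(m$event_date.y - m$event_date.x)  # B minus A
    men <- m$sex.x == "M"
    days_men <- if (fw_m) gap[men & gap > 0] else -gap[men & gap < 0]
    days_women <- if (fw_w) gap[!men & gap > 0] else -gap[!men & gap < 0]
    out[[paste0(d$code_a[i], "->", d$code_b[i])]] <-
      list(code_a = d$code_a[i], code_b = d$code_b[i],
           forward_men = fw_m, forward_women = fw_w,
           days_men = days_men, days_women = days_women)
  }
  structure(out, class = "pair_timespans")
}

#' Compare diagnosis timespans between the sexes
#'
#' Mann-Whitney U per pair with BH adjustment across pairs. The effect is
#' median(women's days) - median(men's days): negative values indicate
#' faster progression in women.
#'
#' @param timespans a [collect_timespans()] result.
#' @param fdr significance threshold on q.
#' @return data.frame per pair: medians per sex, effect, U statistic, p,
#'   q, significance.
#' @export
compare_timespans <- function(timespans, fdr = 0.05) {
  rows <- lapply(timespans, function(ts) {
    if (!length(ts$days_men) || !length(ts$days_women)) return(NULL)
    tr <- mann_whitney_u(ts$days_women, ts$days_men)
    data.frame(code_a = ts$code_a, code_b = ts$code_b,
               n_men = length(ts$days_men), n_women = length(ts$days_women),
               median_men = stats::median(ts$days_men),
               median_women = stats::median(ts$days_women),
               effect = tr$effect, statistic = tr$statistic,
               p = tr$p_value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(code_a = character(), code_b = character(),
                      n_men = integer(), n_women = integer(),
                      median_men = numeric(), median_women = numeric(),
                      effect = numeric(), statistic = numeric(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  out
}
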