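#' End-to-end pipeline with configuration, logging and reports
#'
#' Runs the stages in dependency order -- simulate, preprocess, incidence,
#' age, pairs, timespans, trajectories, report -- writing every stage
#' output as a delimited table in a run directory, together with a log
#' that records the counts at every filter (the candidate-pair /
#' prescreen / analyzed / directional funnel) and the resolved
#' configuration.
#'
#' @name cli_reporting
NULL

#' Pipeline configuration
#'
#' Thresholds default to the analysis constants used throughout: pair and
#' diagnosis inclusion at 100 patients, five matched controls, crude-RR
#' prescreen bound 1.01, posterior RR bound 1.1, directionality ROPE
#' (0.49, 0.51), RR-difference ROPE (-0.1, 0.1), FDR 0.05, trajectory
#' support above 100 with at least 4 diagnoses.
#'
#' @param registry a [registry_config()] describing the synthetic input
#'   (ignored when `input_dir` points at existing registry tables).
#' @param input_dir optional directory of registry tables to use instead
#'   of simulating.
#' @param stages named logical vector toggling `simulate`, `incidence`,
#'   `age`, `pairs`, `timespans`, `trajectories`.
#' @param sampler a [sampler_control()] used by the model stages.
#' @param min_patients inclusion threshold (codes and pairs).
#' @param k matched controls per exposed.
#' @param prescreen_threshold crude-RR prescreen bound.
#' @param rr_bound posterior RR HDI lower bound for directional pairs.
#' @param dir_rope,rrdiff_rope ROPE intervals.
#' @param fdr FDR threshold for the frequentist stages.
#' @param traj_min_support,traj_min_len,traj_max_len trajectory search
#'   parameters.
#' @param privacy_mask if `TRUE`, rows with fewer than 5 patients of
#'   either sex are masked in exported pair tables.
#' @param seed master seed.
#' @export
pipeline_config <- function(registry = registry_config(n_patients = 5000),
                            input_dir = NULL,
                            stages = c(simulate = TRUE, incidence = TRUE,
                                       age = TRUE, pairs = TRUE,
                                       timespans = TRUE,
                                       trajectories = TRUE),
                            sampler = sampler_control(n_warmup = 300,
                                                      n_draws = 500),
                            min_patients = 100, k = 5,
                            prescreen_threshold = 1.01, rr_bound = 1.1,
                            dir_rope = c(0.49, 0.51),
                            rrdiff_rope = c(-0.1, 0.1), fdr = 0.05,
                            traj_min_support = 100, traj_min_len = 4,
                            traj_max_len = 8, privacy_mask = FALSE,
                            seed = 1) {
  structure(list(registry = registry, input_dir = input_dir,
                 stages = stages, sampler = sampler,
                 min_patients = min_patients, k = k,
                 prescreen_threshold = prescreen_threshold,
                 rr_bound = rr_bound, dir_rope = dir_rope,
                 rrdiff_rope = rrdiff_rope, fdr = fdr,
                 traj_min_support = traj_min_support,
                 traj_min_len = traj_min_len, traj_max_len = traj_max_len,
                 privacy_mask = privacy_mask, seed = seed),
            class = "pipeline_config")
}

.stage_error <- function(stage, msg) {
  stop(structure(class = c("comotraj_stage_error", "error", "condition"),
                 list(message = sprintf("[stage %s] %s", stage, msg),
                      call = NULL, stage = stage)))
}

#' Run the pipeline
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (created). Every stage writes its
#'   tables there; a `run.log` records filter counts and timings and
#'   `config.txt` the resolved configuration.
#' @return list of class `"pipeline_run"` with the in-memory stage
#'   results and `run_dir`.
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(run_dir, "run.log")
  logline <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", sep = "", file = logf, append = TRUE)
    message(line)
  }
  dput(config, file.path(run_dir, "config.txt"))
  wt <- function(df, nm) utils::write.table(
    df, file.path(run_dir, paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  on <- function(s) isTRUE(config$stages[[s]])

  ## simulate ----------------------------------------------------------
  if (on("simulate") && is.null(config$input_dir)) {
    reg <- generate_registry(config$registry)
    write_registry(reg, file.path(run_dir, "registry"))
    logline("simulate: %d patients, %d admission rows", nrow(reg$patients),
            nrow(reg$admissions))
  } else {
    src <- if (!is.null(config$input_dir)) config$input_dir
      else file.path(run_dir, "registry")
    if (!file.exists(file.path(src, "patients.tsv")))
      .stage_error("simulate", "no registry tables available")
    reg <- read_registry(src)
    logline("loaded registry from %s", src)
  }

  ## preprocess --------------------------------------------------------
  window <- c(config$registry$study_start, config$registry$study_end)
  adm <- merge_admissions(reg$admissions)
  events <- extract_first_occurrences(adm, reg$patients, reg$terminology,
                                      window[1], window[2])
  wt(events, "events")
  logline("preprocess: %d first-occurrence events, %d codes",
          nrow(events), length(unique(events$code)))

  res <- list(registry = reg, events = events, run_dir = run_dir,
              config = config)

  ## incidence ---------------------------------------------------------
  if (on("incidence")) {
    strata <- build_strata(events, reg$patients, reg$terminology,
                           window[1], window[2], config$min_patients)
    ifit <- fit_incidence(strata, control = config$sampler)
    inc <- incidence_results(ifit)
    wt(inc, "incidence")
    logline("incidence: %d diagnoses fitted (of %d codes), converged: %s",
            length(strata$codes), length(unique(events$code)),
            ifit$converged)
    res$incidence <- inc
    res$incidence_fit <- ifit
  }

  ## age at first diagnosis -------------------------------------------
  if (on("age")) {
    asum <- summarize_age(events)
    acomp <- compare_age(asum, config$fdr)
    achap <- chapter_weighted_mean(acomp, reg$terminology)
    wt(asum, "age_summary"); wt(achap, "age_chapter")
    if (!is.null(acomp)) wt(acomp, "age_compare")
    logline("age: %d codes compared, %d significant at q < %.2f",
            if (is.null(acomp)) 0L else nrow(acomp),
            if (is.null(acomp)) 0L else sum(acomp$significant),
            config$fdr)
    res$age <- acomp
    res$age_chapter <- achap
  }

  ## pairs --------------------------------------------------------------
  if (on("pairs")) {
    pa <- analyze_pairs(events, adm, reg$patients, reg$terminology,
                        min_patients = config$min_patients, k = config$k,
                        seed = config$seed, control = config$sampler,
                        prescreen_threshold = config$prescreen_threshold,
                        rr_bound = config$rr_bound,
                        dir_rope = config$dir_rope,
                        rrdiff_rope = config$rrdiff_rope)
    logline("pairs funnel: %s",
            paste(names(pa$funnel), pa$funnel, sep = "=", collapse = ", "))
    if (!is.null(pa$decisions)) {
      dec_out <- pa$decisions
      if (config$privacy_mask) {
        small <- dec_out$n_men < 5 | dec_out$n_women < 5
        dec_out[small, !(names(dec_out) %in% c("code_a", "code_b"))] <- NA
      }
      wt(dec_out, "pair_decisions")
      rev_tab <- classify_reversed(pa$decisions)
      if (nrow(rev_tab)) wt(rev_tab, "reversed_pairs")
      res$reversed <- rev_tab
    }
    res$pairs <- pa
  }

  ## timespans ----------------------------------------------------------
  if (on("timespans")) {
    if (is.null(res$pairs))
      .stage_error("timespans", "pairs stage output missing")
    ts <- collect_timespans(events, res$pairs$decisions)
    tcomp <- compare_timespans(ts, config$fdr)
    wt(tcomp, "timespans")
    logline("timespans: %d pairs compared, %d significant", nrow(tcomp),
            sum(tcomp$significant))
    res$timespans <- tcomp
  }

  ## trajectories -------------------------------------------------------
  if (on("trajectories")) {
    if (is.null(res$pairs))
      .stage_error("trajectories", "pairs stage output missing")
    tr <- do.call(rbind, lapply(c("all", "men", "women"), function(s)
      enumerate_trajectories(res$pairs$decisions, events, s,
                             config$traj_min_support, config$traj_min_len,
                             config$traj_max_len)))
    wt(tr, "trajectories")
    net <- merge_network(tr, res$pairs$decisions)
    export_network(net, file.path(run_dir, "network.graphml"), "graphml")
    logline("trajectories: %d linear trajectories, network with %d nodes / %d edges",
            nrow(tr), igraph::vcount(net), igraph::ecount(net))
    res$trajectories <- tr
    res$network <- net
  }

  res$summary <- summarize_run(res)
  wt(res$summary$counts, "summary_counts")
  logline("done")
  class(res) <- "pipeline_run"
  res
}

#' Summarize a pipeline run
#'
#' Report tables derived purely from the stage outputs: directional-pair
#' counts per stratum (men / women / shared), the chronic / nonchronic
#' breakdown of directional pairs, the reversed-pair table, the pairs
#' with the largest sex difference in relative risk, and the correlation
#' between the numbers of men and women diagnosed with each pair.
#'
#' @param run a `pipeline_run` (or a list with `pairs` and `registry`).
#' @return list with `counts` (key-value data.frame), `reversed`,
#'   `top_rr_difference`, `patient_count_correlation`.
#' @export
summarize_run <- function(run) {
  dec <- if (!is.null(run$pairs)) run$pairs$decisions
  counts <- data.frame(key = character(), value = numeric())
  add <- function(k, v) counts <<- rbind(counts,
                                         data.frame(key = k, value = v))
  if (!is.null(run$pairs)) for (k in names(run$pairs$funnel))
    add(k, unname(run$pairs$funnel[k]))
  reversed <- NULL; toprr <- NULL; corr <- NULL
  if (!is.null(dec) && nrow(dec)) {
    dm <- !is.na(dec$directional_men) & dec$directional_men
    dw <- !is.na(dec$directional_women) & dec$directional_women
    dj <- !is.na(dec$directional_joint) & dec$directional_joint
    add("directional_men", sum(dm))
    add("directional_women", sum(dw))
    add("directional_shared", sum(dm & dw))
    add("directional_men_unique", sum(dm & !dw))
    add("directional_women_unique", sum(dw & !dm))
    add("directional_joint", sum(dj))
    term <- run$registry$terminology
    if (!is.null(term)) {
      chronic <- function(cd) isTRUE(term$chronic[match(cd, term$code)])
      anydir <- dm | dw | dj
      nonchr <- vapply(which(anydir), function(i)
        !chronic(dec$code_a[i]) || !chronic(dec$code_b[i]), TRUE)
      add("directional_with_nonchronic", sum(nonchr))
    }
    reversed <- classify_reversed(dec)
    add("reversed_pairs", nrow(reversed))
    hasd <- which(!is.na(dec$rr_diff))
    if (length(hasd)) {
      ord <- hasd[order(-abs(dec$rr_diff[hasd]))]
      toprr <- dec[utils::head(ord, 10),
                   c("code_a", "code_b", "n_men", "n_women", "rr_diff",
                     "rr_diff_lo", "rr_diff_hi", "rr_diff_significant")]
      rownames(toprr) <- NULL
    }
    anydir <- dm | dw | dj
    if (sum(anydir) >= 4 && stats::sd(dec$n_men[anydir]) > 0 &&
        stats::sd(dec$n_women[anydir]) > 0)
      corr <- pearson_r(dec$n_men[anydir], dec$n_women[anydir])
  }
  list(counts = counts, reversed = reversed, top_rr_difference = toprr,
       patient_count_correlation = corr)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run in %s\n", x$run_dir))
  if (!is.null(x$summary)) print(x$summary$counts)
  invisible(x)
}
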