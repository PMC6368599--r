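#' Multi-step diagnosis trajectories and merged networks
#'
#' Directional pairs are chained into linear trajectories (ordered code
#' sequences of at least four diagnoses whose consecutive pairs are all
#' directional and that more than 100 patients follow with strictly
#' increasing first-occurrence dates), then merged into a network that
#' shows each directional pair once, with sex-attributed edges.
#'
#' @name trajectories
NULL

# directed edge list (from, to) of directional pairs for a stratum
.directed_pairs <- function(decisions, stratum = c("all", "men", "women")) {
  stratum <- match.arg(stratum)
  flag <- switch(stratum, all = decisions$directional_joint,
                 men = decisions$directional_men,
                 women = decisions$directional_women)
  lo <- switch(stratum, all = decisions$dir_joint_lo,
               men = decisions$dir_men_lo, women = decisions$dir_women_lo)
  keep <- which(!is.na(flag) & flag)
  if (!length(keep))
    return(data.frame(from = character(), to = character()))
  fw <- lo[keep] > 0.5
  data.frame(from = ifelse(fw, decisions$code_a[keep],
                           decisions$code_b[keep]),
             to = ifelse(fw, decisions$code_b[keep],
                         decisions$code_a[keep]),
             stringsAsFactors = FALSE)
}

#' Enumerate supported linear trajectories
#'
#' Depth-first extension over the directed graph of directional pairs.
#' A patient supports a trajectory iff they have every code with strictly
#' increasing first-occurrence dates; support is monotone non-increasing
#' under extension, so prefixes below the threshold prune the search.
#' Codes never repeat within a trajectory.
#'
#' @param decisions pair-decision table from [analyze_pairs()] (or a
#'   data.frame with `from`/`to` columns when `stratum = "edges"`).
#' @param events first-occurrence events (the stratum's patients are
#'   selected by sex for the sex strata).
#' @param stratum `"all"`, `"men"` or `"women"`: which directional flags
#'   and which patients to use.
#' @param min_support trajectories must be followed by strictly more than
#'   this many patients (default 100).
#' @param min_len minimum number of diagnoses (default 4).
#' @param max_len search cap on trajectory length (default 8).
#' @return data.frame: `trajectory` (codes joined by `"->"`), `length`,
#'   `support`, `stratum`.
#' @export
enumerate_trajectories <- function(decisions, events,
                                   stratum = c("all", "men", "women"),
                                   min_support = 100, min_len = 4,
                                   max_len = 8) {
  stratum <- match.arg(stratum)
  edges <- .directed_pairs(decisions, stratum)
  ev <- switch(stratum, all = events,
               men = events[events$sex == "M", ],
               women = events[events$sex == "F", ])
  out <- data.frame(trajectory = character(), length = integer(),
                    support = integer(), stratum = character())
  if (!nrow(edges)) return(out)

  # per-code patient -> date lookup
  codes <- unique(c(edges$from, edges$to))
  date_of <- lapply(codes, function(cd) {
    e <- ev[ev$code == cd, ]
    stats::setNames(as.numeric(e$event_date), e$patient_id)
  })
  names(date_of) <- codes
  succ <- split(edges$to, factor(edges$from, levels = codes))

  results <- list()
  # state: ordered codes so far; supporters = named date vector (patient
  # -> date of the LAST code in the path, over supporting patients)
  extend <- function(path, supporters) {
    if (length(supporters) <= min_support) return()
    if (length(path) >= min_len)
      results[[length(results) + 1]] <<- data.frame(
        trajectory = paste(path, collapse = "->"),
        length = length(path), support = length(supporters),
        stratum = stratum, stringsAsFactors = FALSE)
    if (length(path) >= max_len) return()
    for (nxt in succ[[path[length(path)]]]) {
      if (nxt %in% path) next
      d_next <- date_of[[nxt]][names(supporters)]
      ok <- !is.na(d_next) & d_next > supporters
      if (sum(ok) <= min_support) next
      extend(c(path, nxt), d_next[ok])
    }
  }
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    da <- date_of[[a]]; db <- date_of[[b]][names(da)]
    ok <- !is.na(db) & db > da
    if (sum(ok) <= min_support) next
    extend(c(a, b), db[ok])
  }
  if (length(results)) out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}

#' Merge trajectories into a sex-attributed network
#'
#' Union of the nodes and consecutive-pair edges of the given
#' trajectories; each directional pair appears as one edge, annotated
#' with the per-sex RR medians and a sex attribution: elevated in women,
#' elevated in men, or present in only one sex.
#'
#' @param trajectories output of [enumerate_trajectories()] (possibly
#'   several strata row-bound).
#' @param decisions pair-decision table (for the edge attributes).
#' @return an [igraph::graph] with edge attributes `rr_men`, `rr_women`,
#'   `sex_attribution`.
#' @export
merge_network <- function(trajectories, decisions) {
  if (!nrow(trajectories))
    return(igraph::make_empty_graph(directed = TRUE))
  steps <- lapply(strsplit(trajectories$trajectory, "->", fixed = TRUE),
                  function(cs) cbind(utils::head(cs, -1),
                                     utils::tail(cs, -1)))
  edges <- unique(do.call(rbind, steps))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = TRUE)

  attr_of <- function(fr, to) {
    i <- which((decisions$code_a == fr & decisions$code_b == to) |
                 (decisions$code_a == to & decisions$code_b == fr))[1]
    if (is.na(i)) return(c(NA_real_, NA_real_, NA))
    fwd <- decisions$code_a[i] == fr
    rr_m <- if (fwd) decisions$rr_ab_men[i] else decisions$rr_ba_men[i]
    rr_w <- if (fwd) decisions$rr_ab_women[i] else decisions$rr_ba_women[i]
    dm <- decisions$directional_men[i]; dw <- decisions$directional_women[i]
    attribution <- if (isTRUE(dm) && !isTRUE(dw)) "men only"
      else if (isTRUE(dw) && !isTRUE(dm)) "women only"
      else if (is.na(rr_m) || is.na(rr_w)) NA_character_
      else if (rr_w > rr_m) "elevated in women" else "elevated in men"
    list(rr_m, rr_w, attribution)
  }
  at <- mapply(attr_of, edges[, 1], edges[, 2], SIMPLIFY = FALSE)
  igraph::E(g)$rr_men <- vapply(at, function(x) as.numeric(x[[1]]), 1)
  igraph::E(g)$rr_women <- vapply(at, function(x) as.numeric(x[[2]]), 1)
  igraph::E(g)$sex_attribution <- vapply(at, function(x)
    as.character(x[[3]]), "")
  g
}

#' Export a trajectory network
#'
#' GraphML (lossless round-trip of nodes, edges and attributes) or DOT
#' (for rendering).
#'
#' @param network an igraph object from [merge_network()].
#' @param file output path.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_network <- function(network, file, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(network, file, format = format)
  invisible(file)
}

#' Import a GraphML network written by [export_network()]
#' @param file path to a GraphML file.
#' @export
import_network <- function(file) {
  igraph::read_graph(file, format = "graphml")
}
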