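#' Run one per-target screening funnel
#'
#' Applies a configured sequence of filter stages to a library and
#' records the survivor set after each stage. A stage is a named
#' function taking the surviving records and returning the kept subset
#' (any extra columns it adds are carried along). Targets screened
#' without docking (the MMP-1-style branch) simply configure fewer
#' stages.
#'
#' @param library molecule-record `data.frame`.
#' @param stages named list of stage functions, applied in order.
#' @param target target id for the report.
#' @return Object of class `vs_funnel_report`: per-stage survivor counts
#'   and id sets (first entry is the initial library).
#' @export
run_target_funnel <- function(library, stages, target = "target") {
  stopifnot(is.data.frame(library), length(stages) >= 1,
            !is.null(names(stages)), all(nzchar(names(stages))))
  counts <- c(initial = nrow(library))
  ids <- list(initial = library$id)
  cur <- library
  for (nm in names(stages)) {
    cur <- tryCatch(stages[[nm]](cur),
                    error = function(e) stop("stage ", sQuote(nm),
                                             " failed: ",
                                             conditionMessage(e)))
    if (!all(cur$id %in% ids[[length(ids)]]))
      stop("stage ", sQuote(nm), " returned compounds not in its input")
    counts[nm] <- nrow(cur)
    ids[[nm]] <- cur$id
  }
  structure(list(target = target, stages = names(stages), counts = counts,
                 survivors = ids, final = cur),
            class = "vs_funnel_report")
}

#' @export
print.vs_funnel_report <- function(x, ...) {
  cat("Screening funnel for", x$target, "\n")
  print(x$counts)
  invisible(x)
}

#' Tabulate funnel reports across targets
#'
#' Stage-by-target survivor counts, stages as rows in first-seen order;
#' `NA` where a target does not run a stage.
#'
#' @param reports list of `vs_funnel_report`.
#' @return `data.frame` (stage x target).
#' @export
funnel_table <- function(reports) {
  stages <- unique(unlist(lapply(reports, function(r) names(r$counts))))
  out <- data.frame(stage = stages, stringsAsFactors = FALSE)
  for (r in reports)
    out[[r$target]] <- unname(r$counts[match(stages, names(r$counts))])
  out
}

#' Consensus hits across per-target funnels
#'
#' Compounds surviving the full funnel (final stage) in at least
#' `min_targets` targets. The workflow's main selection uses 2; a value
#' of 3 reproduces the stricter inspection tier.
#'
#' @param reports list of `vs_funnel_report` (at least 2).
#' @param min_targets minimum number of funnels a hit must survive.
#' @return `data.frame`: `compound_id`, one logical column per target,
#'   `n_targets_hit`; sorted by decreasing `n_targets_hit`, then id.
#' @export
collect_consensus <- function(reports, min_targets = 2) {
  stopifnot(length(reports) >= 2)
  targets <- vapply(reports, `[[`, "", "target")
  finals <- lapply(reports, function(r) r$survivors[[length(r$survivors)]])
  all_ids <- sort(unique(unlist(finals)))
  flags <- vapply(finals, function(s) all_ids %in% s,
                  logical(length(all_ids)))
  if (length(all_ids) == 1) flags <- matrix(flags, nrow = 1)
  colnames(flags) <- targets
  n_hit <- rowSums(flags)
  keep <- n_hit >= min_targets
  out <- data.frame(compound_id = all_ids[keep],
                    flags[keep, , drop = FALSE],
                    n_targets_hit = n_hit[keep],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out[order(-out$n_targets_hit, out$compound_id), , drop = FALSE]
}

#' Cluster hits together with known actives
#'
#' Groups consensus hits and known active compounds by structural
#' similarity: single-linkage hierarchical clustering over Jaccard
#' (1 - Tanimoto) distances on Morgan fingerprints, cut at
#' `dist_cutoff`, so two compounds share a cluster iff they are joined
#' by a chain of pairs each at least `1 - dist_cutoff` similar. Clusters
#' smaller than `min_cluster_size` are treated as noise: each member
#' becomes its own singleton cluster (and stays eligible for selection,
#' since a structurally isolated hit is exactly what the novelty step
#' wants to keep). Clusters containing a known active are flagged.
#'
#' @param hits molecule-record `data.frame` of consensus hits.
#' @param known_actives molecule-record `data.frame`.
#' @param min_cluster_size smallest group kept as a real cluster.
#' @param dist_cutoff Jaccard distance below which compounds join a
#'   cluster (0.6, i.e. Tanimoto similarity 0.4).
#' @param radius,nbits fingerprint parameters.
#' @return `data.frame`: `compound_id`, `is_hit`, `cluster` (label),
#'   `is_noise`, `contains_known_active`.
#' @export
cluster_with_known_actives <- function(hits, known_actives,
                                       min_cluster_size = 2,
                                       dist_cutoff = 0.6,
                                       radius = 2, nbits = 2048) {
  recs <- rbind(hits[, c("id", "smiles")], known_actives[, c("id", "smiles")])
  is_hit <- rep(c(TRUE, FALSE), c(nrow(hits), nrow(known_actives)))
  n <- nrow(recs)
  stopifnot(n >= 1, !anyDuplicated(recs$id))
  if (n < min_cluster_size) {
    lab <- paste0("singleton_", seq_len(n))
    noise <- rep(TRUE, n)
  } else {
    fp <- fingerprint_matrix(recs, radius, nbits)
    sim <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      sim[i, j] <- tanimoto_similarity(fp[i, ], fp[j, ])
    d <- as.dist(1 - sim)
    lab0 <- if (n == 1) 1L else cutree(hclust(d, method = "single"),
                                       h = dist_cutoff)
    sizes <- table(lab0)
    noise <- sizes[as.character(lab0)] < min_cluster_size
    lab <- ifelse(noise, paste0("singleton_", seq_len(n)),
                  paste0("cluster_", lab0))
  }
  flagged <- tapply(!is_hit, lab, any)
  data.frame(compound_id = recs$id, is_hit = is_hit, cluster = lab,
             is_noise = as.vector(noise),
             contains_known_active = as.vector(flagged[lab]),
             stringsAsFactors = FALSE)
}

#' Select novel hits from clustered consensus compounds
#'
#' Eligible hits sit in clusters without any known active; at most one
#' compound is taken per cluster, prioritized by the number of funnels
#' it survived (descending) with ties broken by compound id, and the top
#' `n_select` are returned.
#'
#' @param assignments output of [cluster_with_known_actives()].
#' @param hits output of [collect_consensus()] (supplies
#'   `n_targets_hit`).
#' @param n_select selection size (20 in the workflow's purchase list).
#' @return `data.frame`: `compound_id`, `cluster`, `n_targets_hit`,
#'   ranked.
#' @export
select_novel_hits <- function(assignments, hits, n_select = 20) {
  a <- assignments[assignments$is_hit & !assignments$contains_known_active,
                   , drop = FALSE]
  a$n_targets_hit <- hits$n_targets_hit[match(a$compound_id,
                                              hits$compound_id)]
  a <- a[!is.na(a$n_targets_hit), , drop = FALSE]
  a <- a[order(-a$n_targets_hit, a$compound_id), , drop = FALSE]
  a <- a[!duplicated(a$cluster), , drop = FALSE]
  out <- head(a[, c("compound_id", "cluster", "n_targets_hit")], n_select)
  rownames(out) <- NULL
  out
}

#' Write a selection report with PAINS flags
#'
#' @param selection output of [select_novel_hits()].
#' @param records molecule-record `data.frame` supplying structures.
#' @param path output TSV path.
#' @return The report `data.frame`, invisibly.
#' @export
write_selection_tsv <- function(selection, records, path) {
  m <- match(selection$compound_id, records$id)
  pf <- pains_flag(records[m, , drop = FALSE])
  rep <- cbind(selection, smiles = records$smiles[m],
               pains = pf$flagged, pains_alerts = pf$matched_alerts)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
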