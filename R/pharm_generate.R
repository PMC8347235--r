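#' Generate fragment-derived (e-pharmacophore style) hypotheses
#'
#' Pools the pharmacophoric features of scored fragment poses docked
#' into one binding site, clusters them kind-wise in space into at most
#' `n_clusters` groups, scores each cluster by the sum of its
#' contributing poses' docking scores (lower = better, so densely
#' populated, well-scored regions win), and turns the best clusters into
#' sites placed at score-weighted centroids. One hypothesis is emitted
#' per site count from 1 up to `max_sites`, each containing the top
#' clusters.
#'
#' @param fragment_poses list of `vs_pose`, each with a docking `score`
#'   and features.
#' @param n_clusters total spatial clusters formed across kinds (15 in
#'   the screening workflow).
#' @param max_sites largest hypothesis size (8 in the workflow).
#' @param tolerance site tolerance in Angstrom given to emitted sites.
#' @param cluster_radius spatial extent (Angstrom, complete linkage)
#'   above which same-kind features are never merged.
#' @return List of `vs_hypothesis` (length `min(max_sites, n clusters
#'   formed)`), largest last.
#' @export
generate_epharmacophore <- function(fragment_poses, n_clusters = 15,
                                    max_sites = 8, tolerance = 2.0,
                                    cluster_radius = 2.0) {
  stopifnot(length(fragment_poses) >= 1)
  rows <- list()
  for (p in fragment_poses) {
    if (is.na(p$score)) stop("pose ", p$pose_id, " has no docking score")
    f <- if (!is.null(p$features)) p$features else perceive_features(p)
    if (nrow(f))
      rows[[length(rows) + 1]] <- cbind(f, score = p$score,
                                        pose = p$pose_id)
  }
  feats <- do.call(rbind, rows)
  if (is.null(feats) || nrow(feats) == 0)
    stop("fragment poses carry no features")

  # allocate cluster counts to kinds proportionally to feature counts
  kinds <- sort(unique(feats$kind))
  nk <- vapply(kinds, function(k) sum(feats$kind == k), 0L)
  alloc <- pmax(1L, round(n_clusters * nk / sum(nk)))
  while (sum(alloc) > n_clusters && any(alloc > 1))
    alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  if (sum(pmin(alloc, nk)) < min(n_clusters, sum(nk)) &&
      sum(nk) < n_clusters)
    warning("fewer feature points (", sum(nk), ") than requested clusters (",
            n_clusters, "); forming ", sum(nk), " clusters")

  clusters <- list()
  for (i in seq_along(kinds)) {
    sub <- feats[feats$kind == kinds[i], , drop = FALSE]
    k <- min(alloc[i], nrow(sub))
    lab <- if (nrow(sub) == 1) 1L else {
      hc <- hclust(dist(sub[, c("x", "y", "z")]), method = "complete")
      # never merge beyond cluster_radius even if fewer clusters result
      lab_r <- cutree(hc, h = cluster_radius)
      if (length(unique(lab_r)) > k) cutree(hc, k = k) else lab_r
    }
    for (l in unique(lab)) {
      m <- sub[lab == l, , drop = FALSE]
      w <- abs(m$score)
      if (all(w == 0)) w <- rep(1, nrow(m))
      clusters[[length(clusters) + 1]] <- data.frame(
        kind = kinds[i],
        x = sum(m$x * w) / sum(w), y = sum(m$y * w) / sum(w),
        z = sum(m$z * w) / sum(w),
        score = sum(m$score), n = nrow(m), stringsAsFactors = FALSE)
    }
  }
  cl <- do.call(rbind, clusters)
  cl <- cl[order(cl$score), , drop = FALSE]  # lowest (best) total first

  n_emit <- min(max_sites, nrow(cl))
  lapply(seq_len(n_emit), function(k) {
    sites <- data.frame(kind = cl$kind[seq_len(k)], x = cl$x[seq_len(k)],
                        y = cl$y[seq_len(k)], z = cl$z[seq_len(k)],
                        tolerance = tolerance, required = TRUE,
                        weight = -cl$score[seq_len(k)],
                        stringsAsFactors = FALSE)
    hypothesis(sites, id = paste0("eph_", k), provenance = "structure_based")
  })
}

#' Generate ligand-based hypotheses from active conformers
#'
#' Ligand-common-feature hypothesis search: candidate site sets are
#' drawn from the feature arrangements of a reference active and kept
#' when, screened flexibly, they match at least `min_active_fraction` of
#' the actives. Used for targets screened without docked poses (the
#' MMP-1-style workflow branch).
#'
#' @param conformers named list: per active compound, a list of at most
#'   `max_conformers` `vs_pose` conformers.
#' @param min_active_fraction fraction of actives a hypothesis must
#'   match (0.5 in the workflow).
#' @param n_features allowed hypothesis sizes (3 to 5 in the workflow).
#' @param tolerance site tolerance in Angstrom.
#' @param max_conformers conformer cap per ligand (10 in the workflow).
#' @param max_candidates cap on enumerated candidate site sets.
#' @return List of `vs_hypothesis` sorted by decreasing match fraction,
#'   then decreasing size; each carries attributes `match_fraction` and
#'   `matched`. Empty list (with a warning) when no arrangement is
#'   shared.
#' @export
generate_ligand_hypothesis <- function(conformers, min_active_fraction = 0.5,
                                       n_features = 3:5, tolerance = 2.0,
                                       max_conformers = 10,
                                       max_candidates = 2000) {
  stopifnot(length(conformers) >= 1, !is.null(names(conformers)))
  if (any(lengths(conformers) > max_conformers))
    stop("each active may carry at most ", max_conformers, " conformers")
  ref <- conformers[[1]][[1]]
  rf <- if (!is.null(ref$features)) ref$features else perceive_features(ref)
  out <- list()
  n_act <- length(conformers)
  for (k in sort(n_features, decreasing = TRUE)) {
    if (nrow(rf) < k) next
    subsets <- asplit(combn(seq_len(nrow(rf)), k), 2)
    if (length(subsets) > max_candidates)
      subsets <- subsets[seq_len(max_candidates)]
    for (ss in subsets) {
      sites <- data.frame(kind = rf$kind[ss], x = rf$x[ss], y = rf$y[ss],
                          z = rf$z[ss], tolerance = tolerance,
                          required = TRUE, weight = 1,
                          stringsAsFactors = FALSE)
      hyp <- hypothesis(sites, id = paste0("lig_", k, "_",
                                           paste(ss, collapse = ".")),
                        provenance = "ligand_based")
      res <- screen_flexible(hyp, conformers, max_conformers,
                             tolerance_default = tolerance)
      frac <- nrow(res) / n_act
      if (frac >= min_active_fraction) {
        attr(hyp, "match_fraction") <- frac
        attr(hyp, "matched") <- res$compound_id
        out[[length(out) + 1]] <- hyp
      }
    }
  }
  if (!length(out)) {
    warning("no common feature arrangement matches ",
            min_active_fraction * 100, "% of actives")
    return(list())
  }
  fr <- vapply(out, function(h) attr(h, "match_fraction"), 0)
  sz <- vapply(out, function(h) nrow(h$sites), 0)
  out[order(-fr, -sz)]
}
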