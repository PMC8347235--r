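# --- site-feature assignment search ------------------------------------
# A pose matches a hypothesis iff there is an injective assignment of
# sites to same-kind features in which every required site is assigned
# within its tolerance and at least `min_optional_matches` optional
# sites are also satisfied. Backtracking over sites (required first,
# fewest candidates first), exact over these small instances.

.match_assignment <- function(sites, feats, min_opt) {
  ns <- nrow(sites)
  cand <- vector("list", ns)
  for (s in seq_len(ns)) {
    same <- which(feats$kind == sites$kind[s])
    if (length(same)) {
      d <- sqrt((feats$x[same] - sites$x[s])^2 +
                  (feats$y[same] - sites$y[s])^2 +
                  (feats$z[same] - sites$z[s])^2)
      cand[[s]] <- same[d <= sites$tolerance[s]]
    } else cand[[s]] <- integer(0)
  }
  req <- which(sites$required)
  opt <- which(!sites$required)
  if (any(lengths(cand[req]) == 0)) return(NULL)
  ord <- c(req[order(lengths(cand[req]))], opt[order(lengths(cand[opt]))])
  n_opt_total <- length(opt)
  best <- NULL
  assign_rec <- function(pos, used, picked, n_opt_matched, n_opt_left) {
    if (!is.null(best)) return()
    if (pos > length(ord)) {
      if (n_opt_matched >= min_opt) best <<- picked
      return()
    }
    s <- ord[pos]
    is_opt <- !sites$required[s]
    if (is_opt && n_opt_matched + n_opt_left < min_opt) return()
    for (f in setdiff(cand[[s]], used)) {
      assign_rec(pos + 1, c(used, f), c(picked, setNames(f, s)),
                 n_opt_matched + is_opt,
                 n_opt_left - is_opt)
      if (!is.null(best)) return()
    }
    if (is_opt)  # skipping an optional site is allowed
      assign_rec(pos + 1, used, picked, n_opt_matched, n_opt_left - 1)
  }
  assign_rec(1, integer(0), integer(0), 0, n_opt_total)
  best
}

.assignment_rmsd <- function(sites, feats, picked) {
  if (!length(picked)) return(0)
  s <- as.integer(names(picked))
  d2 <- (feats$x[picked] - sites$x[s])^2 +
    (feats$y[picked] - sites$y[s])^2 + (feats$z[picked] - sites$z[s])^2
  sqrt(mean(d2))
}

.assignment_string <- function(picked) {
  if (!length(picked)) return("")
  paste(paste0(names(picked), ":", picked), collapse = ";")
}

.prepare_sites <- function(hyp, tolerance_default) {
  sites <- hyp$sites
  if (any(!is.finite(sites$x) | !is.finite(sites$y) | !is.finite(sites$z)))
    stop("hypothesis ", hyp$id, " has sites without coordinates")
  if (is.null(sites$tolerance)) sites$tolerance <- NA_real_
  sites$tolerance[is.na(sites$tolerance)] <- tolerance_default
  sites
}

#' Screen docked poses in place against a hypothesis
#'
#' Matches poses without re-alignment: the docked coordinates are used
#' as-is, so hypothesis and poses must share a frame (poses docked to
#' superposed receptor structures). A pose matches iff every required
#' site finds a distinct same-kind feature within its tolerance and at
#' least `min_optional_matches` optional sites are also satisfied.
#'
#' @param hyp a `vs_hypothesis` with coordinates.
#' @param poses list of `vs_pose` (each carrying features, or perceived
#'   on the fly when a pose has none but was built from a structure).
#' @param tolerance_default tolerance in Angstrom for sites without one
#'   (2 by default).
#' @return `data.frame` of matches: `compound_id`, `pose_id`, `rmsd`
#'   (site-feature fit RMSD over assigned sites) and `assignment`
#'   (`site:feature` index pairs).
#' @export
screen_inplace <- function(hyp, poses, tolerance_default = 2.0) {
  sites <- .prepare_sites(hyp, tolerance_default)
  out <- list()
  for (p in poses) {
    feats <- if (!is.null(p$features)) p$features else perceive_features(p)
    picked <- .match_assignment(sites, feats, hyp$min_optional_matches)
    if (!is.null(picked))
      out[[length(out) + 1]] <- data.frame(
        compound_id = p$compound_id, pose_id = p$pose_id,
        rmsd = .assignment_rmsd(sites, feats, picked),
        assignment = .assignment_string(picked), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(compound_id = character(0), pose_id = character(0),
                      rmsd = numeric(0), assignment = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Kabsch: proper rotation (det = +1) and translation minimizing RMSD of
# P onto Q (n x 3 matrices).
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

.apply_kabsch <- function(k, P) {
  sweep(sweep(P, 2, k$cp) %*% t(k$R), 2, k$cq, "+")
}

#' Screen flexible conformers against a hypothesis
#'
#' For each compound, every conformer (up to `max_conformers`) is tested
#' by rigid-body least-squares superposition: candidate same-kind
#' feature subsets are aligned onto the sites (proper rotations only, so
#' mirror images do not match) and accepted when every assigned site
#' lies within its tolerance after alignment. The best (lowest-RMSD)
#' matching conformer is reported per compound.
#'
#' @param hyp a `vs_hypothesis` with coordinates.
#' @param conformers named list: per compound, a list of `vs_pose`
#'   conformers.
#' @param max_conformers cap on conformers considered per compound (10
#'   in the screening workflow).
#' @param tolerance_default fallback site tolerance in Angstrom.
#' @return As [screen_inplace()], one row per matching compound.
#' @export
screen_flexible <- function(hyp, conformers, max_conformers = 10,
                            tolerance_default = 2.0) {
  sites <- .prepare_sites(hyp, tolerance_default)
  min_opt <- hyp$min_optional_matches
  out <- list()
  for (cid in names(conformers)) {
    confs <- conformers[[cid]]
    if (!length(confs)) next
    confs <- confs[seq_len(min(length(confs), max_conformers))]
    best <- NULL
    for (p in confs) {
      feats <- if (!is.null(p$features)) p$features else perceive_features(p)
      hit <- .flexible_match(sites, feats, min_opt)
      if (!is.null(hit) && (is.null(best) || hit$rmsd < best$rmsd)) {
        best <- hit
        best$pose_id <- p$pose_id
      }
    }
    if (!is.null(best))
      out[[length(out) + 1]] <- data.frame(
        compound_id = cid, pose_id = best$pose_id, rmsd = best$rmsd,
        assignment = best$assignment, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(compound_id = character(0), pose_id = character(0),
                      rmsd = numeric(0), assignment = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Enumerate injective kind-compatible assignments (required sites always
# assigned; optional subsets meeting the quota), superpose each, accept
# if all assigned sites fall within tolerance; return the lowest-RMSD
# acceptable alignment.
.flexible_match <- function(sites, feats, min_opt) {
  ns <- nrow(sites)
  cand <- lapply(seq_len(ns), function(s) which(feats$kind == sites$kind[s]))
  req <- which(sites$required)
  if (any(lengths(cand[req]) == 0)) return(NULL)
  best <- NULL
  try_assign <- function(svec, fvec) {
    if (length(svec) < 3) return()  # need 3+ points for a rigid frame
    P <- as.matrix(feats[fvec, c("x", "y", "z")])
    Q <- as.matrix(sites[svec, c("x", "y", "z")])
    k <- .kabsch(P, Q)
    Pa <- .apply_kabsch(k, P)
    d <- sqrt(rowSums((Pa - Q)^2))
    if (all(d <= sites$tolerance[svec])) {
      rmsd <- sqrt(mean(d^2))
      if (is.null(best) || rmsd < best$rmsd)
        best <<- list(rmsd = rmsd,
                      assignment = .assignment_string(setNames(fvec, svec)))
    }
  }
  opt <- which(!sites$required)
  opt_subsets <- list(integer(0))
  if (length(opt))
    opt_subsets <- unlist(lapply(seq(0, length(opt)), function(k)
      if (k == 0) list(integer(0)) else
        asplit(combn(opt, k), 2)), recursive = FALSE)
  for (os in opt_subsets) {
    if (length(os) < min_opt) next
    svec <- c(req, as.integer(os))
    rec <- function(i, used, fvec) {
      if (i > length(svec)) { try_assign(svec, fvec); return() }
      for (f in setdiff(cand[[svec[i]]], used))
        rec(i + 1, c(used, f), c(fvec, f))
    }
    rec(1, integer(0), integer(0))
  }
  best
}

#' Validate hypotheses and select the best
#'
#' Fills a confusion matrix per hypothesis from screening results over a
#' labelled validation set (a matched compound is a predicted active)
#' and selects the winner by highest sensitivity -- the selection rule of
#' the screening workflow, which deliberately prioritizes not losing
#' actives over specificity -- with ties broken by specificity, then by
#' fewer sites.
#'
#' @param hyps list of `vs_hypothesis`.
#' @param active_matches,decoy_matches lists (parallel to `hyps`) of
#'   matched compound ids among actives resp. decoys.
#' @param n_actives,n_decoys validation set sizes (both > 0).
#' @return `list(best, metrics)`: the selected hypothesis and a named
#'   list of `classifier_metrics`.
#' @export
validate_and_select <- function(hyps, active_matches, decoy_matches,
                                n_actives, n_decoys) {
  stopifnot(length(hyps) >= 1, length(active_matches) == length(hyps),
            length(decoy_matches) == length(hyps))
  if (n_actives == 0 || n_decoys == 0)
    stop("empty validation set")
  metrics <- vector("list", length(hyps))
  key <- matrix(NA_real_, length(hyps), 3)
  for (i in seq_along(hyps)) {
    tp <- length(unique(active_matches[[i]]))
    fp <- length(unique(decoy_matches[[i]]))
    m <- compute_metrics(tp = tp, fp = fp, tn = n_decoys - fp,
                         fn = n_actives - tp)
    metrics[[i]] <- m
    key[i, ] <- c(m["sensitivity"], m["specificity"], -nrow(hyps[[i]]$sites))
  }
  names(metrics) <- vapply(hyps, `[[`, "", "id")
  ord <- order(key[, 1], key[, 2], key[, 3], decreasing = TRUE)
  list(best = hyps[[ord[1]]], metrics = metrics)
}
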