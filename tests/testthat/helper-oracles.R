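# Independent oracles the implementation is checked against.

# Metrics by explicit label/prediction counting: expand the confusion
# matrix into vectors and count, rather than using ratio formulas.
oracle_metrics <- function(tp, fp, tn, fn) {
  truth <- rep(c(1, 1, 0, 0), c(tp, fn, tn, fp))
  pred <- rep(c(1, 0, 0, 1), c(tp, fn, tn, fp))
  rate <- function(num, den) if (den == 0) NaN else num / den
  sens <- rate(sum(pred == 1 & truth == 1), sum(truth == 1))
  spec <- rate(sum(pred == 0 & truth == 0), sum(truth == 0))
  prec <- rate(sum(pred == 1 & truth == 1), sum(pred == 1))
  acc <- mean(pred == truth)
  f1 <- rate(2 * sum(pred & truth), 2 * sum(pred & truth) +
               sum(pred != truth))
  num <- sum(pred & truth) * sum(!pred & !truth) -
    sum(pred & !truth) * sum(!pred & truth)
  den <- sqrt(sum(pred)) * sqrt(sum(truth)) * sqrt(sum(!pred)) *
    sqrt(sum(!truth))
  mcc <- if (den == 0) NaN else num / den
  c(sensitivity = sens, specificity = spec, precision = prec,
    fall_out = 1 - spec, false_negative_rate = 1 - sens,
    false_discovery_rate = 1 - prec, accuracy = acc, f1_score = f1,
    matthews_cc = mcc)
}

# Exhaustive pharmacophore matcher: enumerate every injective
# site -> feature assignment (optional sites may be skipped) and test
# the acceptance condition directly.
oracle_match <- function(sites, feats, min_opt = 0) {
  ns <- nrow(sites)
  ok_pair <- function(s, f) {
    feats$kind[f] == sites$kind[s] &&
      sqrt((feats$x[f] - sites$x[s])^2 + (feats$y[f] - sites$y[s])^2 +
             (feats$z[f] - sites$z[s])^2) <= sites$tolerance[s]
  }
  found <- FALSE
  rec <- function(s, used, n_opt) {
    if (found) return()
    if (s > ns) {
      if (n_opt >= min_opt) found <<- TRUE
      return()
    }
    for (f in setdiff(seq_len(nrow(feats)), used)) {
      if (ok_pair(s, f))
        rec(s + 1, c(used, f), n_opt + !sites$required[s])
    }
    if (!sites$required[s]) rec(s + 1, used, n_opt)
  }
  rec(1, integer(0), 0)
  found
}

random_match_instance <- function() {
  ns <- sample(1:4, 1)
  nf <- sample(1:8, 1)
  kinds <- c("A", "D", "R", "N", "H", "P")
  sites <- data.frame(kind = sample(kinds[1:3], ns, replace = TRUE),
                      x = runif(ns, -4, 4), y = runif(ns, -4, 4),
                      z = runif(ns, -4, 4),
                      tolerance = runif(ns, 0.5, 3),
                      required = sample(c(TRUE, FALSE), ns, replace = TRUE),
                      weight = 1)
  feats <- data.frame(kind = sample(kinds[1:3], nf, replace = TRUE),
                      x = runif(nf, -4, 4), y = runif(nf, -4, 4),
                      z = runif(nf, -4, 4))
  min_opt <- if (any(!sites$required))
    sample(0:sum(!sites$required), 1) else 0
  list(sites = sites, feats = feats, min_opt = min_opt)
}

# Pose wrapping a bare feature table (atoms mirror the features).
feature_pose <- function(feats, compound_id, pose_id = paste0(compound_id, "_1")) {
  pose(data.frame(element = "C", x = feats$x, y = feats$y, z = feats$z,
                  charge = 0),
       compound_id = compound_id, pose_id = pose_id, features = feats)
}

# Consensus by direct counting over a logical membership matrix.
oracle_consensus <- function(membership, min_targets) {
  n_hit <- rowSums(membership)
  ids <- rownames(membership)[n_hit >= min_targets]
  data.frame(compound_id = ids,
             n_targets_hit = n_hit[n_hit >= min_targets])
}

# Youden cutoff by brute-force enumeration of midpoint candidates.
oracle_cutoff <- function(act, dec) {
  vals <- sort(unique(c(act, dec)))
  cand <- (head(vals, -1) + vals[-1]) / 2
  J <- sapply(cand, function(cu) mean(act >= cu) + mean(dec < cu) - 1)
  spec <- sapply(cand, function(cu) mean(dec < cu))
  cand[order(-J, -spec, cand)][1]
}

rigid_rotate <- function(xyz, angles = c(0.3, 1.1, -0.7), shift = c(5, -3, 2)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  sweep(as.matrix(xyz) %*% t(Rz %*% Ry %*% Rx), 2, shift, "+")
}
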