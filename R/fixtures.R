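# Seeded generators for every synthetic input used by tests and
# examples. Fixture chemistry is deliberately simple and valence-legal
# (sulfonamide-scaffold "actives" vs branched-alkane "decoys"): the
# generators test the pipeline's contracts, not pharmacology.

# random branched alkane with n carbons as SMILES (formula CnH2n+2
# regardless of branching, so mass is exact in n)
.rand_alkane <- function(n) {
  if (n <= 1) return("C")
  k <- sample(1:min(3, n - 1), 1)  # number of branches
  sizes <- rep(1, k)
  extra <- n - 1 - k
  while (extra > 0) {
    i <- sample(k, 1)
    sizes[i] <- sizes[i] + 1
    extra <- extra - 1
  }
  paste0("C", paste0(vapply(sizes, function(s)
    paste0("(", .rand_alkane(s), ")"), ""), collapse = ""))
}

#' Generate a separable active/decoy classification set
#'
#' Actives decorate a shared benzenesulfonamide scaffold (guaranteeing
#' shared fingerprint bits), decoys are scaffold-free branched alkanes
#' matched to active molecular weights within 25 Da. All compounds fall
#' in the 300-600 Da screening window by construction. Active pX values
#' are drawn over the curated 1-13 range with fixed stratum proportions
#' (20% pX < 4, 40% 4-7, 40% > 7).
#'
#' @param n_actives,n_decoys class sizes (>= 1 each).
#' @param seed integer seed; identical calls give identical sets.
#' @return Molecule-record `data.frame` with roles `active`/`decoy`.
#' @export
make_classification_set <- function(n_actives, n_decoys, seed) {
  stopifnot(n_actives >= 1, n_decoys >= 1)
  frags <- c("CCCC", "CCCCCC", "CCCCCCCC", "OC", "OCCC", "Cl", "Br",
             "C(C)C", "c2ccccc2")
  fmw <- c(56.1, 84.2, 112.2, 30.0, 58.1, 34.5, 78.9, 42.1, 76.1)
  with_seed(seed, {
    act_smi <- character(n_actives)
    for (i in seq_len(n_actives)) {
      repeat {
        f <- sample(length(frags), 2, replace = TRUE)
        if (sum(fmw[f]) >= 70 && sum(fmw[f]) <= 360) break
      }
      act_smi[i] <- paste0("O=S(=O)(Nc1ccc(", frags[f[1]], ")cc1)c1ccc(",
                           frags[f[2]], ")cc1")
    }
    actives <- molecule_records(paste0("act", seq_len(n_actives)), act_smi,
                                role = "active", source = "fixture")
    strata <- sample(c("lt4", "mid", "gt7"), n_actives, replace = TRUE,
                     prob = c(0.2, 0.4, 0.4))
    actives$px <- ifelse(strata == "lt4", runif(n_actives, 1, 4),
                         ifelse(strata == "mid", runif(n_actives, 4, 7),
                                runif(n_actives, 7, 13)))
    targets <- sample(actives$mw, n_decoys, replace = TRUE) +
      runif(n_decoys, -7, 7)
    nC <- pmax(22, round((targets - 2.016) / 14.027))
    dec_smi <- vapply(nC, .rand_alkane, "")
    decoys <- molecule_records(paste0("dec", seq_len(n_decoys)), dec_smi,
                               role = "decoy", source = "fixture")
    rbind(actives, decoys)
  })
}

#' Plant matching and non-matching poses for a hypothesis
#'
#' Matching poses carry a same-kind feature within tolerance of every
#' required site (plus optional-site features and far-away distractors);
#' non-matching poses displace every feature of one required site's kind
#' beyond `tolerance + 0.5` Angstrom. Assumes hypothesis sites are
#' mutually separated by more than twice their tolerance (warned
#' otherwise), so planted labels are unambiguous ground truth.
#'
#' @param hyp `vs_hypothesis` with coordinates and tolerances.
#' @param n_match,n_nonmatch pose counts.
#' @param seed integer seed.
#' @return `list(poses, labels)`: poses (compound ids `match_i` /
#'   `nonmatch_i`) and the planted logical labels.
#' @export
make_planted_pose_set <- function(hyp, n_match, n_nonmatch, seed) {
  sites <- hyp$sites
  stopifnot(all(is.finite(sites$x)))
  tol <- sites$tolerance
  tol[is.na(tol)] <- 2.0
  sxyz <- as.matrix(sites[, c("x", "y", "z")])
  if (nrow(sites) > 1) {
    dmin <- min(dist(sxyz))
    if (dmin <= 2 * max(tol))
      warning("hypothesis sites closer than twice the tolerance; ",
              "planted labels may be ambiguous")
  }
  rand_dir <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  mk_pose <- function(id, feats) {
    atoms <- data.frame(element = "C", x = feats$x, y = feats$y,
                        z = feats$z, charge = 0)
    pose(atoms, compound_id = id, pose_id = paste0(id, "_p1"),
         features = feats)
  }
  with_seed(seed, {
    poses <- list()
    req <- which(sites$required)
    if (!length(req)) req <- seq_len(nrow(sites))
    for (i in seq_len(n_match)) {
      feats <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s) {
        off <- rand_dir() * runif(1, 0, 0.45 * tol[s])
        .feature_row(sites$kind[s], sxyz[s, ] + off)
      }))
      # far-away distractor of a random kind
      feats <- rbind(feats, .feature_row(
        sample(c("A", "D", "R", "N", "H", "P"), 1),
        colMeans(sxyz) + rand_dir() * (max(tol) + 15)))
      poses[[length(poses) + 1]] <- mk_pose(paste0("match_", i), feats)
    }
    for (i in seq_len(n_nonmatch)) {
      v <- sample(req, 1)
      feats <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s) {
        if (sites$kind[s] == sites$kind[v]) {
          off <- rand_dir() * (tol[s] + 0.5 + runif(1, 0.2, 1.5))
        } else {
          off <- rand_dir() * runif(1, 0, 0.45 * tol[s])
        }
        .feature_row(sites$kind[s], sxyz[s, ] + off)
      }))
      poses[[length(poses) + 1]] <- mk_pose(paste0("nonmatch_", i), feats)
    }
    list(poses = poses,
         labels = rep(c(TRUE, FALSE), c(n_match, n_nonmatch)))
  })
}

#' Generate a random charged toy pose
#'
#' Carbon atoms at uniform random coordinates in a cubic box with
#' charges per profile: `neutral` (Gaussian charges recentred to sum
#' zero), `dipolar` (half +0.3 e, half -0.3 e) or `monopolar` (all
#' +0.2 e). The workhorse fixture for electrostatic Tanimoto algebra.
#'
#' @param n_atoms number of atoms (>= 1).
#' @param charge_profile charge pattern.
#' @param seed integer seed.
#' @param box box edge in Angstrom.
#' @return A `vs_pose`.
#' @export
make_charged_pose <- function(n_atoms, charge_profile = c("neutral",
                                                          "dipolar",
                                                          "monopolar"),
                              seed, box = 10) {
  charge_profile <- match.arg(charge_profile)
  stopifnot(n_atoms >= 1)
  with_seed(seed, {
    xyz <- matrix(runif(n_atoms * 3, 0, box), ncol = 3)
    q <- switch(charge_profile,
                neutral = { z <- rnorm(n_atoms, 0, 0.3); z - mean(z) },
                dipolar = rep(c(0.3, -0.3), length.out = n_atoms),
                monopolar = rep(0.2, n_atoms))
    pose(data.frame(element = "C", x = xyz[, 1], y = xyz[, 2],
                    z = xyz[, 3], charge = q),
         compound_id = paste0("toy_", charge_profile, "_", seed))
  })
}

# truncated-normal sampler on [lo, hi] via inverse CDF
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate synthetic electrostatic-similarity validation scores
#'
#' Emulates a per-reference validation distribution: decoy et_pb values
#' follow Normal(0.3, 0.1) truncated to the metric's range; actives are
#' stratified by pX (20% < 4, 40% 4-7, 40% > 7) with the pX > 7 stratum
#' shifted up by `shift` (half-shift for the middle stratum), so `shift`
#' directly controls how separable potent actives are from decoys.
#'
#' @param n_act,n_dec stratum totals.
#' @param shift upward shift of the potent-active distribution.
#' @param seed integer seed.
#' @return `data.frame`: `id`, `role`, `px`, `et_pb`.
#' @export
make_et_validation_set <- function(n_act, n_dec, shift, seed) {
  stopifnot(shift >= 0)
  lo <- -1 / 3
  with_seed(seed, {
    strata <- sample(c("lt4", "mid", "gt7"), n_act, replace = TRUE,
                     prob = c(0.2, 0.4, 0.4))
    px <- ifelse(strata == "lt4", runif(n_act, 1, 4),
                 ifelse(strata == "mid", runif(n_act, 4, 7),
                        runif(n_act, 7, 13)))
    mu <- 0.3 + ifelse(strata == "gt7", shift,
                       ifelse(strata == "mid", shift / 2, 0))
    et_a <- vapply(mu, function(m) .rtnorm(1, m, 0.1, lo, 1), 0)
    et_d <- .rtnorm(n_dec, 0.3, 0.1, lo, 1)
    data.frame(
      id = c(paste0("act", seq_len(n_act)), paste0("dec", seq_len(n_dec))),
      role = rep(c("active", "decoy"), c(n_act, n_dec)),
      px = c(px, rep(NA_real_, n_dec)),
      et_pb = c(et_a, et_d), stringsAsFactors = FALSE)
  })
}

#' Simulate a dose-response curve
#'
#' `vi/vo` from the single-site model with multiplicative Gaussian
#' noise, floored at zero.
#'
#' @param ic50 true IC50 (micromolar).
#' @param concentrations inhibitor concentrations (micromolar).
#' @param noise_sd multiplicative noise SD (0 = exact curve).
#' @param seed integer seed.
#' @return Measurement `data.frame`: `concentration_uM`, `vi_over_vo`,
#'   `replicate`.
#' @export
make_inhibition_curve <- function(ic50, concentrations, noise_sd = 0,
                                  seed = 1) {
  stopifnot(ic50 > 0)
  with_seed(seed, {
    r <- predict_velocity_ratio(ic50, concentrations)
    if (noise_sd > 0)
      r <- pmax(0, r * (1 + rnorm(length(r), 0, noise_sd)))
    data.frame(concentration_uM = concentrations, vi_over_vo = r,
               replicate = 1L)
  })
}
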