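#' Assign partial charges to a pose
#'
#' Fills per-atom partial charges by a named empirical scheme:
#' \describe{
#'   \item{`as-given`}{trust the charges already on the pose (the
#'     default throughout: input charge states are trusted, matching
#'     the workflow's trusted-protonation policy).}
#'   \item{`formal`}{formal charges from the connection table.}
#'   \item{`eneg`}{formal charges plus electronegativity-difference bond
#'     increments (0.08 e per Pauling unit per bond order): a simple,
#'     deterministic dipole-generating scheme that conserves net charge
#'     exactly.}
#' }
#' The two structure-based schemes need connectivity, supplied as a
#' molblock structure or single-molecule `SDF`.
#'
#' @param p a `vs_pose`.
#' @param method charge scheme id.
#' @param structure connectivity source for `formal`/`eneg` (an `SDF`,
#'   `SDFset` of length 1, or SMILES whose atom order matches the pose).
#' @return The pose with `atoms$charge` filled.
#' @export
assign_partial_charges <- function(p, method = c("as-given", "formal",
                                                 "eneg"),
                                   structure = NULL) {
  method <- match.arg(method)
  if (method == "as-given") return(p)
  if (is.null(structure))
    stop("method ", sQuote(method), " needs connectivity (structure=)")
  mb <- if (is.list(structure) && !is.null(structure$bonds)) structure
        else .as_molblock(structure)
  g <- .mol_graph(mb)
  if (g$n != nrow(p$atoms))
    stop("structure heavy-atom count does not match pose atoms")
  q <- as.numeric(g$charge)
  if (method == "eneg") {
    chi <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
             Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66,
             Se = 2.55)
    x <- unname(chi[g$elem]); x[is.na(x)] <- 2.55
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
      dq <- 0.08 * (x[j] - x[i]) * g$order[k]
      q[i] <- q[i] + dq; q[j] <- q[j] - dq
    }
    # implicit hydrogens carry no charge of their own, so increments run
    # between heavy atoms only -- net charge is conserved exactly
  }
  p$atoms$charge <- q
  p
}

#' Compute an electrostatic potential grid for a pose
#'
#' Samples the potential of the pose's point charges on a regular grid:
#' `V(r) = sum_i q_i / (eps(d_i) d_i)` with a distance-dependent
#' dielectric `eps(d) = 4 d` by default (`"vacuum"`: `eps = 1`;
#' `"constant"`: a fixed value). Grid points inside the van der Waals
#' envelope of any masking pose are masked out, which removes the
#' near-singular interior region from all comparisons. Values are in
#' consistent arbitrary units (e / Angstrom under vacuum).
#'
#' @param p a `vs_pose` with charges.
#' @param spacing grid spacing in Angstrom.
#' @param padding box padding around the atom bounding box in Angstrom.
#' @param bounds optional shared box, `list(lo=, hi=)` of xyz vectors
#'   (overrides padding; use [shared_grid_bounds()] when comparing two
#'   poses).
#' @param mask_poses poses whose vdW envelope defines the mask (default:
#'   the pose itself; pass both molecules for a pairwise comparison).
#' @param dielectric `"distance"`, `"vacuum"` or `"constant"`.
#' @param eps dielectric constant for `dielectric = "constant"`, or the
#'   slope for `"distance"` (`eps(d) = eps * d`).
#' @return Object of class `potential_grid`.
#' @export
compute_potential_grid <- function(p, spacing = 0.5, padding = 4.0,
                                   bounds = NULL, mask_poses = list(p),
                                   dielectric = c("distance", "vacuum",
                                                  "constant"),
                                   eps = 4) {
  dielectric <- match.arg(dielectric)
  stopifnot(inherits(p, "vs_pose"), spacing > 0)
  if (nrow(p$atoms) == 0) stop("empty pose")
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
  if (is.null(bounds)) {
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
  } else {
    lo <- bounds$lo; hi <- bounds$hi
  }
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
  dims <- lengths(ax)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  v <- numeric(nrow(pts))
  for (i in seq_len(nrow(xyz))) {
    d <- sqrt((pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
                (pts[, 3] - xyz[i, 3])^2)
    d <- pmax(d, 1e-6)
    v <- v + switch(dielectric,
                    vacuum = p$atoms$charge[i] / d,
                    constant = p$atoms$charge[i] / (eps * d),
                    distance = p$atoms$charge[i] / (eps * d * d))
  }
  mask <- rep(TRUE, nrow(pts))
  for (mp in mask_poses) {
    mxyz <- as.matrix(mp$atoms[, c("x", "y", "z")])
    for (i in seq_len(nrow(mxyz))) {
      d2 <- (pts[, 1] - mxyz[i, 1])^2 + (pts[, 2] - mxyz[i, 2])^2 +
        (pts[, 3] - mxyz[i, 3])^2
      mask <- mask & d2 > mp$atoms$radius[i]^2
    }
  }
  v[!mask] <- 0
  structure(list(origin = c(lo[1], lo[2], lo[3]), spacing = spacing,
                 dims = dims, values = v, mask = mask),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat("Potential grid", paste(x$dims, collapse = " x "), "at",
      x$spacing, "A spacing;", sum(x$mask), "of", length(x$values),
      "points unmasked\n")
  invisible(x)
}

#' Shared grid box for a set of poses
#'
#' Union bounding box of all atoms, padded. Pass as `bounds=` to
#' [compute_potential_grid()] so two compared poses live on one grid.
#'
#' @param poses list of `vs_pose`.
#' @param padding Angstrom.
#' @return `list(lo, hi)`.
#' @export
shared_grid_bounds <- function(poses, padding = 4.0) {
  xyz <- do.call(rbind, lapply(poses, function(p)
    as.matrix(p$atoms[, c("x", "y", "z")])))
  list(lo = apply(xyz, 2, min) - padding,
       hi = apply(xyz, 2, max) + padding)
}

#' Continuous electrostatic Tanimoto of two potential grids
#'
#' `T = sum(ab) / (sum(a^2) + sum(b^2) - sum(ab))` over the common
#' unmasked points. Bounded between -1/3 (exactly opposite fields) and 1
#' (identical fields); symmetric.
#'
#' @param a,b `potential_grid`s with identical origin, spacing and
#'   dimensions (masks are intersected).
#' @return Numeric scalar in `[-1/3, 1]`.
#' @export
electrostatic_tanimoto <- function(a, b) {
  stopifnot(inherits(a, "potential_grid"), inherits(b, "potential_grid"))
  if (!isTRUE(all.equal(a$dims, b$dims)) ||
      max(abs(a$origin - b$origin)) > 1e-9 ||
      abs(a$spacing - b$spacing) > 1e-9)
    stop("grids are not compatible (origin/spacing/dimensions differ)")
  m <- a$mask & b$mask
  va <- a$values[m]; vb <- b$values[m]
  saa <- sum(va * va); sbb <- sum(vb * vb); sab <- sum(va * vb)
  if (saa + sbb == 0)
    stop("both fields are identically zero on the common grid")
  sab / (saa + sbb - sab)
}

#' Best-reference electrostatic similarity per compound
#'
#' Evaluates every (pose, reference) pair on a shared grid and keeps,
#' for each compound, the single docked pose with the highest
#' electrostatic Tanimoto across all references jointly -- one pose per
#' compound regardless of which reference produced it.
#'
#' @param poses list of `vs_pose` (may span several compounds; grouped
#'   by `compound_id`).
#' @param references list of reference `vs_pose` (non-empty), in the
#'   same coordinate frame.
#' @param spacing,padding,dielectric,eps grid settings, see
#'   [compute_potential_grid()].
#' @return `data.frame` with one row per compound: `compound_id`,
#'   `best_reference`, `et_pb`, `pose_id`.
#' @export
best_reference_similarity <- function(poses, references, spacing = 0.5,
                                      padding = 4.0,
                                      dielectric = "distance", eps = 4) {
  if (!length(references)) stop("empty reference list")
  ids <- vapply(poses, `[[`, "", "compound_id")
  out <- list()
  for (cid in unique(ids)) {
    best <- NULL
    for (p in poses[ids == cid]) {
      for (r in references) {
        bb <- shared_grid_bounds(list(p, r), padding)
        ga <- compute_potential_grid(p, spacing, bounds = bb,
                                     mask_poses = list(p, r),
                                     dielectric = dielectric, eps = eps)
        gb <- compute_potential_grid(r, spacing, bounds = bb,
                                     mask_poses = list(p, r),
                                     dielectric = dielectric, eps = eps)
        et <- electrostatic_tanimoto(ga, gb)
        key <- c(et, r$pose_id, p$pose_id)
        if (is.null(best) || et > best$et + 1e-15 ||
            (abs(et - best$et) <= 1e-15 &&
             paste(r$pose_id, p$pose_id) < paste(best$ref, best$pose)))
          best <- list(et = et, ref = r$pose_id, pose = p$pose_id)
      }
    }
    out[[length(out) + 1]] <- data.frame(
      compound_id = cid, best_reference = best$ref, et_pb = best$et,
      pose_id = best$pose, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
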