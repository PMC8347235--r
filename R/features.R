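#' Pharmacophoric feature perception
#'
#' Locates pharmacophoric features on a 3D (or 2D) structure:
#' \describe{
#'   \item{D}{hydrogen-bond donor: N or O carrying at least one H, at
#'     the heavy atom.}
#'   \item{A}{hydrogen-bond acceptor: N or O, excluding amide and
#'     protonated/quaternary nitrogens and aromatic N-H, at the heavy
#'     atom.}
#'   \item{N}{negatively ionizable group: deprotonated oxo-acid
#'     (carboxylate, sulfonate, phosphonate) at the group centroid,
#'     tetrazolate at the ring centroid, other anionic atoms at the
#'     atom.}
#'   \item{P}{positively charged atom.}
#'   \item{R}{aromatic ring, at the ring centroid.}
#'   \item{H}{hydrophobic cluster: a connected set of three or more
#'     apolar, non-aromatic carbons, at the cluster centroid.}
#' }
#' Perception is rule-based on the molecular graph and fully
#' deterministic.
#'
#' @param x a `vs_pose` carrying precomputed features, a single-molecule
#'   `SDF`/`SDFset`, or a SMILES string (2D coordinates are generated
#'   for the SMILES case).
#' @return `data.frame` with columns `kind`, `x`, `y`, `z`.
#' @examples
#' perceive_features("c1ccccc1")   # one R feature at the ring centroid
#' @export
perceive_features <- function(x) {
  if (inherits(x, "vs_pose")) {
    if (!is.null(x$features)) return(x$features)
    stop("pose carries no features and no connectivity; ",
         "perceive from the source SDF instead")
  }
  if (inherits(x, "SDFset")) {
    stopifnot(length(x) == 1)
    return(.perceive_from_molblock(.molblock_from_sdf(x[[1]])))
  }
  if (inherits(x, "SDF"))
    return(.perceive_from_molblock(.molblock_from_sdf(x)))
  stopifnot(is.character(x), length(x) == 1)
  .perceive_from_molblock(.molblocks_from_smiles(x, gen2d = TRUE)[[1]])
}

.empty_features <- function() {
  data.frame(kind = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), stringsAsFactors = FALSE)
}

.feature_row <- function(kind, xyz) {
  data.frame(kind = kind, x = xyz[1], y = xyz[2], z = xyz[3],
             stringsAsFactors = FALSE)
}

.perceive_from_molblock <- function(mb) {
  g <- .mol_graph(mb)
  if (g$n == 0) return(.empty_features())
  xyz <- g$xyz
  centroid <- function(idx) colMeans(xyz[idx, , drop = FALSE])
  feats <- .empty_features()
  add <- function(kind, pos) {
    feats <<- rbind(feats, .feature_row(kind, as.numeric(pos)))
  }

  rings <- .cycle_basis(g)
  arom <- vapply(rings, function(r) .is_aromatic_ring(g, r), TRUE)
  arom_atoms <- unique(unlist(rings[arom]))

  has_double_O <- function(a) {  # atom has a double-bonded oxygen
    for (k in seq_along(g$adj[[a]])) {
      nb <- g$adj[[a]][k]
      if (g$elem[nb] == "O" && g$order[g$bidx[[a]][k]] == 2) return(TRUE)
    }
    FALSE
  }

  # donors and acceptors
  for (a in seq_len(g$n)) {
    el <- g$elem[a]
    if (!(el %in% c("N", "O"))) next
    if (g$nH[a] >= 1) add("D", xyz[a, ])
    acceptor <- if (el == "O") g$charge[a] <= 0 else {
      amide <- any(vapply(g$adj[[a]], has_double_O, TRUE) &
                     g$elem[g$adj[[a]]] == "C")
      g$charge[a] <= 0 && g$degree[a] <= 3 && !amide &&
        !(a %in% arom_atoms && g$nH[a] >= 1)
    }
    if (acceptor) add("A", xyz[a, ])
  }

  # negatively ionizable groups
  used_neg <- integer(0)
  for (a in seq_len(g$n)) {
    if (!(g$elem[a] %in% c("C", "S", "P"))) next
    nb <- g$adj[[a]]
    anionic_O <- nb[g$elem[nb] == "O" & g$charge[nb] < 0]
    if (!length(anionic_O)) next
    term_O <- nb[g$elem[nb] == "O" & g$degree[nb] == 1]
    grp <- unique(c(a, term_O))
    add("N", centroid(grp))
    used_neg <- c(used_neg, grp)
  }
  for (r in rings[arom]) {  # tetrazolate-style anionic aromatic ring
    if (length(r) == 5 && sum(g$elem[r] == "N") >= 4 &&
        any(g$charge[r] < 0)) {
      add("N", centroid(r))
      used_neg <- c(used_neg, r)
    }
  }
  for (a in which(g$charge < 0)) {
    if (!(a %in% used_neg) && !(g$elem[a] == "O"))  # O- handled above
      add("N", xyz[a, ])
  }

  # positively charged atoms
  for (a in which(g$charge > 0)) add("P", xyz[a, ])

  # aromatic rings
  for (r in rings[arom]) add("R", centroid(r))

  # hydrophobic clusters: apolar non-aromatic carbons, components >= 3
  polar_nbr <- vapply(seq_len(g$n), function(a)
    any(g$elem[g$adj[[a]]] %in% c("N", "O", "S", "P")) ||
      any(g$charge[g$adj[[a]]] != 0), TRUE)
  apolar <- which(g$elem == "C" & g$charge == 0 & !polar_nbr &
                    !(seq_len(g$n) %in% arom_atoms))
  for (comp in .components(g, apolar)) {
    if (length(comp) >= 3) add("H", centroid(comp))
  }
  rownames(feats) <- NULL
  feats
}

# Cycle basis via BFS spanning forest; cycles longer than 7 atoms are
# not treated as candidate rings.
.cycle_basis <- function(g, max_size = 7) {
  n <- g$n
  if (n == 0 || nrow(g$bonds) == 0) return(list())
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  tree_edge <- rep(FALSE, nrow(g$bonds))
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE; depth[root] <- 0L
    q <- root
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (k in seq_along(g$adj[[v]])) {
        w <- g$adj[[v]][k]; e <- g$bidx[[v]][k]
        if (!visited[w]) {
          visited[w] <- TRUE; parent[w] <- v; depth[w] <- depth[v] + 1L
          tree_edge[e] <- TRUE
          q <- c(q, w)
        }
      }
    }
  }
  path_up <- function(a, b) {  # nodes on tree path a..b
    pa <- a; pb <- b
    da <- depth[a]; db <- depth[b]
    la <- a; lb <- b
    while (da > db) { la <- parent[la]; da <- da - 1; pa <- c(pa, la) }
    while (db > da) { lb <- parent[lb]; db <- db - 1; pb <- c(pb, lb) }
    while (la != lb) {
      la <- parent[la]; lb <- parent[lb]
      pa <- c(pa, la); pb <- c(pb, lb)
    }
    c(pa, rev(pb[-length(pb)]))
  }
  rings <- list()
  for (e in which(!tree_edge)) {
    cyc <- path_up(g$bonds[e, 1], g$bonds[e, 2])
    if (length(cyc) <= max_size) rings[[length(rings) + 1]] <- cyc
  }
  rings
}

# Kekulized aromaticity rule: 5-7 ring of C/N/O/S whose in-ring double
# bond count matches the alternating pattern (floor(n/2)), or any
# in-ring bond flagged aromatic.
.is_aromatic_ring <- function(g, ring) {
  n <- length(ring)
  if (n < 5 || n > 7) return(FALSE)
  if (!all(g$elem[ring] %in% c("C", "N", "O", "S"))) return(FALSE)
  orders <- numeric(0)
  for (i in seq_len(n)) {
    a <- ring[i]; b <- ring[if (i == n) 1 else i + 1]
    k <- which(g$adj[[a]] == b)
    if (!length(k)) return(FALSE)
    orders <- c(orders, g$order[g$bidx[[a]][k[1]]])
  }
  if (any(orders == 1.5)) return(TRUE)
  sum(orders == 2) == n %/% 2
}

# Connected components of the subgraph induced by `keep` atoms.
.components <- function(g, keep) {
  comps <- list()
  left <- keep
  while (length(left)) {
    q <- left[1]; comp <- q; left <- left[-1]
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- intersect(g$adj[[v]], left)
      if (length(nb)) {
        comp <- c(comp, nb)
        left <- setdiff(left, nb)
        q <- c(q, nb)
      }
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}
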