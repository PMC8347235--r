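# --- molblock structures -----------------------------------------------
# The graph layer works from a plain molblock structure: elements, xyz,
# formal charges and a bond matrix (i, j, order). Structures come either
# from V2000 text (one fixed-format read; robust for bond-free molecules,
# which ChemmineR's reader rejects) or from a parsed ChemmineR SDF.

.parse_molblock <- function(lines) {
  na <- as.integer(substr(lines[4], 1, 3))
  nb <- as.integer(substr(lines[4], 4, 6))
  at <- lines[4 + seq_len(na)]
  xyz <- cbind(x = as.numeric(substr(at, 1, 10)),
               y = as.numeric(substr(at, 11, 20)),
               z = as.numeric(substr(at, 21, 30)))
  elem <- trimws(substr(at, 32, 34))
  code <- suppressWarnings(as.integer(substr(at, 37, 39)))
  code[is.na(code)] <- 0L
  charge <- ifelse(code == 0 | code == 4, 0, 4 - code)
  bonds <- matrix(numeric(0), 0, 3)
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
  }
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "[ ]+")[[1]])
    k <- f[1]
    for (p in seq_len(k)) charge[f[2 * p]] <- f[2 * p + 1]
  }
  list(elem = elem, xyz = xyz, charge = charge, bonds = bonds)
}

# Batch SMILES -> molblock structures via one OpenBabel conversion.
.molblocks_from_smiles <- function(smiles, gen2d = FALSE) {
  if (is.null(names(smiles))) names(smiles) <- paste0("m", seq_along(smiles))
  inp <- paste0(paste(smiles, names(smiles), sep = "\t"), collapse = "\n")
  txt <- if (gen2d) {
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(inp, "\n"),
      options = data.frame(names = "gen2D", args = "")))
  } else {
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF",
                                               paste0(inp, "\n")))
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) != length(smiles))
    stop("unparseable structure(s) in SMILES input")
  starts <- c(1L, head(ends, -1) + 1L)
  out <- vector("list", length(ends))
  for (i in seq_along(ends))
    out[[i]] <- .parse_molblock(lines[starts[i]:ends[i]])
  names(out) <- names(smiles)
  out
}

.molblock_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_[0-9]+$", "", rownames(ab))
  chg_code <- if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0, length(elem))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
    matrix(numeric(0), 0, 3) else unname(bb[, 1:3, drop = FALSE])
  list(elem = elem, xyz = unname(ab[, 1:3, drop = FALSE]),
       charge = ifelse(chg_code == 0 | chg_code == 4, 0, 4 - chg_code),
       bonds = bonds)
}

# Heavy-atom molecular graph from a molblock structure: adds
# implicit+explicit H counts, heavy-atom degree, ring membership,
# adjacency and incident-bond lists.
.mol_graph <- function(mb) {
  elem <- mb$elem
  n <- length(elem)
  xyz <- mb$xyz
  charge <- mb$charge
  bonds <- mb$bonds
  order <- if (nrow(bonds)) bonds[, 3] else numeric(0)
  order[order == 4] <- 1.5  # aromatic bond code, rarely emitted by OpenBabel

  heavy <- elem != "H"
  idx <- cumsum(heavy)  # old -> new index for heavy atoms
  bsum <- numeric(n)
  nH_exp <- integer(n)
  keep_bond <- logical(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    bsum[i] <- bsum[i] + order[k]; bsum[j] <- bsum[j] + order[k]
    if (heavy[i] && heavy[j]) keep_bond[k] <- TRUE
    else if (heavy[i] && !heavy[j]) nH_exp[i] <- nH_exp[i] + 1L
    else if (heavy[j] && !heavy[i]) nH_exp[j] <- nH_exp[j] + 1L
  }
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
           B = 3, Si = 4, Se = 2)
  dv <- unname(val[elem]); dv[is.na(dv)] <- 0
  adj_val <- ifelse(elem %in% c("N", "P", "O", "S", "Se"), dv + charge,
                    ifelse(elem == "C", dv - abs(charge), dv))
  nH <- pmax(0, round(adj_val - bsum)) + nH_exp
  hb <- bonds[keep_bond, , drop = FALSE]
  if (nrow(hb)) {
    hb[, 1] <- idx[hb[, 1]]; hb[, 2] <- idx[hb[, 2]]
  }
  horder <- order[keep_bond]
  m <- sum(heavy)
  deg <- integer(m)
  adj <- vector("list", m)
  bidx <- vector("list", m)  # incident bond indices
  for (k in seq_len(nrow(hb))) {
    i <- hb[k, 1]; j <- hb[k, 2]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    bidx[[i]] <- c(bidx[[i]], k); bidx[[j]] <- c(bidx[[j]], k)
  }
  in_ring <- .ring_atoms(m, hb)
  list(n = m, elem = elem[heavy], charge = charge[heavy], nH = nH[heavy],
       degree = deg, in_ring = in_ring, xyz = xyz[heavy, , drop = FALSE],
       bonds = hb, order = horder, adj = adj, bidx = bidx)
}

# Atoms lying on at least one cycle: an atom is in a ring iff it has an
# incident non-bridge edge (bridges found by DFS low-link).
.ring_atoms <- function(n, bonds) {
  in_ring <- logical(n)
  if (n == 0 || nrow(bonds) == 0) return(in_ring)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, k))
    adj[[j]] <- rbind(adj[[j]], c(i, k))
  }
  disc <- rep(NA_integer_, n); low <- integer(n); timer <- 0L
  bridge <- logical(nrow(bonds))
  for (root in seq_len(n)) {
    if (!is.na(disc[root])) next
    stack <- list(list(v = root, pe = 0L, i = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i == 1L) {
        timer <- timer + 1L; disc[v] <- timer; low[v] <- timer
      }
      nb <- adj[[v]]
      if (is.null(nb) || fr$i > nrow(nb)) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pf <- stack[[length(stack)]]
          u <- pf$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridge[fr$pe] <- TRUE
        }
        next
      }
      to <- nb[fr$i, 1]; eid <- nb[fr$i, 2]
      stack[[length(stack)]]$i <- fr$i + 1L
      if (eid == fr$pe) next
      if (!is.na(disc[to])) {
        low[v] <- min(low[v], disc[to])
      } else {
        stack[[length(stack) + 1L]] <- list(v = to, pe = eid, i = 1L)
      }
    }
  }
  for (k in seq_len(nrow(bonds))) if (!bridge[k]) {
    in_ring[bonds[k, 1]] <- TRUE; in_ring[bonds[k, 2]] <- TRUE
  }
  in_ring
}

# Deterministic polynomial hash of a non-negative integer vector,
# modulo the Mersenne prime 2^31 - 1 (exact in double arithmetic).
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + x) %% 2147483647
  h
}

.elem_num <- function(elem) {
  z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
         Cl = 17, Se = 34, Br = 35, I = 53)
  out <- unname(z[elem])
  out[is.na(out)] <- 0
  out
}

# On-bit indices (1-based) of the hashed circular fingerprint for a
# parsed molecular graph.
.morgan_bits <- function(g, radius, nbits) {
  if (g$n == 0) return(integer(0))
  ids <- vapply(seq_len(g$n), function(a) .hash_ints(
    c(.elem_num(g$elem[a]), g$degree[a], g$nH[a], g$charge[a] + 5,
      as.integer(g$in_ring[a]))), 0)
  emitted <- ids  # radius-0 identifiers, always kept
  if (radius > 0 && nrow(g$bonds) > 0) {
    dmat <- .bfs_dist(g)
    seen_keys <- character(0)
    prev_key <- rep("", g$n)
    alive <- rep(TRUE, g$n)
    for (t in seq_len(radius)) {
      new_ids <- ids
      for (a in seq_len(g$n)) {
        nbr <- g$adj[[a]]
        if (!length(nbr)) next
        ord <- round(g$order[g$bidx[[a]]] * 2)  # 2/4/6, aromatic 3
        o <- order(ord, ids[nbr])
        new_ids[a] <- .hash_ints(c(t, ids[a], as.vector(rbind(ord[o], ids[nbr][o]))))
      }
      for (a in seq_len(g$n)) {
        if (!alive[a]) next
        d <- dmat[a, ]
        inb <- which(pmin(d[g$bonds[, 1]], d[g$bonds[, 2]]) < t)
        key <- paste(inb, collapse = ",")
        if (identical(key, prev_key[a])) { alive[a] <- FALSE; next }
        prev_key[a] <- key
        if (key %in% seen_keys) next
        seen_keys <- c(seen_keys, key)
        emitted <- c(emitted, new_ids[a])
      }
      ids <- new_ids
    }
  }
  sort(unique(emitted %% nbits + 1))
}

.bfs_dist <- function(g) {
  n <- g$n
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in g$adj[[v]]) if (d[s, w] > d[s, v] + 1) {
        d[s, w] <- d[s, v] + 1
        q <- c(q, w)
      }
    }
  }
  d
}

#' Morgan (circular) fingerprint
#'
#' Hashed circular fingerprint over atom environments of increasing
#' radius, in the style of the extended-connectivity (ECFP) family.
#' Atom invariants are element, heavy-atom degree, hydrogen count,
#' formal charge and ring membership; identifiers are iteratively
#' rehashed with neighbour identifiers and folded into `nbits` bits.
#' Environments that cover no new bonds are not re-emitted, so e.g.
#' methane sets exactly one bit. Deterministic for a given canonical
#' structure, radius and length.
#'
#' @param x a SMILES string, a one-row molecule-record `data.frame`, or
#'   a single-molecule `SDFset`/`SDF`.
#' @param radius environment radius in bonds (2 throughout the screening
#'   workflow).
#' @param nbits fingerprint length.
#' @return An object of class `morgan_fp`: logical bit vector plus
#'   `nbits` and `radius`.
#' @export
morgan_fingerprint <- function(x, radius = 2, nbits = 2048) {
  g <- .mol_graph(.as_molblock(x))
  on <- .morgan_bits(g, radius, nbits)
  bits <- logical(nbits)
  bits[on] <- TRUE
  structure(list(bits = bits, nbits = nbits, radius = radius),
            class = "morgan_fp")
}

.as_molblock <- function(x) {
  if (inherits(x, "SDF")) return(.molblock_from_sdf(x))
  if (inherits(x, "SDFset")) {
    stopifnot(length(x) == 1)
    return(.molblock_from_sdf(x[[1]]))
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- x$smiles
  }
  stopifnot(is.character(x), length(x) == 1)
  .molblocks_from_smiles(x)[[1]]
}

#' @export
print.morgan_fp <- function(x, ...) {
  cat("Morgan fingerprint: radius", x$radius, "/", x$nbits, "bits,",
      sum(x$bits), "set\n")
  invisible(x)
}

#' Fingerprint matrix for a set of molecule records
#'
#' @param records molecule-record `data.frame`.
#' @inheritParams morgan_fingerprint
#' @return Logical matrix (compounds x bits) with row names from `records$id`.
#' @export
fingerprint_matrix <- function(records, radius = 2, nbits = 2048) {
  mbs <- .molblocks_from_smiles(setNames(records$smiles, records$id))
  m <- matrix(FALSE, nrow(records), nbits,
              dimnames = list(records$id, NULL))
  for (i in seq_len(nrow(records))) {
    g <- .mol_graph(mbs[[i]])
    m[i, .morgan_bits(g, radius, nbits)] <- TRUE
  }
  m
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a & b| / |a | b|`; symmetric, in `[0, 1]`. Two all-zero vectors are
#' defined to have similarity 0 (avoiding 0/0).
#'
#' @param a,b `morgan_fp` objects or logical bit vectors of equal length.
#' @return Numeric scalar in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  av <- if (inherits(a, "morgan_fp")) a$bits else as.logical(a)
  bv <- if (inherits(b, "morgan_fp")) b$bits else as.logical(b)
  if (length(av) != length(bv))
    stop("fingerprints have different lengths (", length(av), " vs ",
         length(bv), ")")
  u <- sum(av | bv)
  if (u == 0) return(0)
  sum(av & bv) / u
}
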