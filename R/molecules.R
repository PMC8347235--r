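#' Canonicalize SMILES strings
#'
#' Converts SMILES to the OpenBabel canonical form, so that any two valid
#' notations of the same molecule map to one representation. The operation
#' is idempotent: canonicalizing a canonical SMILES returns it unchanged.
#'
#' @param smiles character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length and names.
#' @examples
#' standardize_smiles(c("c1ccccc1", "C1=CC=CC=C1"))  # identical output
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  n <- length(smiles)
  ids <- paste0("m", seq_len(n))
  inp <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(inp, "\n")))
  parsed <- .parse_smi_lines(out)
  # OpenBabel stops at the first unparseable record; fall back to
  # per-molecule conversion to name every offender.
  if (length(parsed$smiles) != n || !identical(parsed$id, ids)) {
    can <- character(n)
    bad <- character(0)
    for (i in seq_len(n)) {
      o <- suppressWarnings(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[i], "\t", ids[i], "\n")))
      p <- .parse_smi_lines(o)
      if (length(p$smiles) != 1) bad <- c(bad, smiles[i]) else can[i] <- p$smiles
    }
    if (length(bad))
      stop("unparseable structure(s): ", paste(sQuote(bad), collapse = ", "))
    names(can) <- names(smiles)
    return(can)
  }
  can <- parsed$smiles
  names(can) <- names(smiles)
  can
}

.parse_smi_lines <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  list(smiles = vapply(parts, `[`, "", 1L),
       id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""))
}

#' Build a table of standardized molecule records
#'
#' The compound container used throughout the package: one row per
#' molecule with columns `id`, `smiles` (canonical), `mw` (Da), `role`
#' (`library`, `active` or `decoy`), `px` (optional potency as
#' -log10(IC50 or Ki) in molar) and `source`.
#'
#' @param id character ids (unique).
#' @param smiles SMILES strings; canonicalized unless `standardize = FALSE`.
#' @param role one of `"library"`, `"active"`, `"decoy"` (recycled).
#' @param px optional numeric potency (pX); `NA` where unknown. Curated
#'   actives are expected in the 1-13 range.
#' @param source free-text provenance tag.
#' @param standardize canonicalize and compute molecular weight via
#'   OpenBabel (set `FALSE` only if `smiles` is already canonical and
#'   `mw` is supplied).
#' @param mw molecular weights in Da, computed from structure when `NULL`.
#' @return A `data.frame` of molecule records.
#' @export
molecule_records <- function(id, smiles, role = "library", px = NA_real_,
                             source = "", standardize = TRUE, mw = NULL) {
  stopifnot(length(id) == length(smiles), !anyDuplicated(id))
  role <- rep_len(role, length(id))
  px <- rep_len(as.numeric(px), length(id))
  source <- rep_len(source, length(id))
  if (!all(role %in% c("library", "active", "decoy")))
    stop("role must be one of 'library', 'active', 'decoy'")
  if (standardize) smiles <- unname(standardize_smiles(smiles))
  if (is.null(mw)) mw <- molecular_weight(smiles)
  stopifnot(all(mw > 0))
  data.frame(id = as.character(id), smiles = smiles, mw = as.numeric(mw),
             role = role, px = px, source = source, stringsAsFactors = FALSE)
}

#' Molecular weight from SMILES
#'
#' Average molecular mass in Da (standard atomic weights, implicit
#' hydrogens included), computed with OpenBabel.
#'
#' @param smiles character vector of SMILES.
#' @return Numeric vector of masses in Da.
#' @export
molecular_weight <- function(smiles) {
  inp <- paste0(paste(smiles, paste0("m", seq_along(smiles)), sep = "\t"),
                collapse = "\n")
  mw <- ChemmineOB::forEachMol("SMILES", inp,
                               function(m) ChemmineOB::prop_OB(m)$MW)
  if (length(mw) != length(smiles))
    stop("unparseable structure(s) in SMILES input")
  unlist(mw, use.names = FALSE)
}

#' Convert SMILES to a ChemmineR SDFset
#'
#' @param smiles character vector (names become compound ids).
#' @return An [ChemmineR::SDFset] with one molecule per input.
#' @export
smiles_to_sdf <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- paste0("m", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  if (!inherits(sdf, "SDFset") || length(sdf) != length(smiles))
    stop("unparseable structure(s) in SMILES input")
  sdf
}

#' Filter molecule records by molecular weight
#'
#' Keeps records with `lo <= mw <= hi`; both bounds are inclusive, so the
#' default drug-like window retains compounds of exactly 300 or 600 Da.
#'
#' @param records a molecule-record `data.frame` (see [molecule_records()]).
#' @param lo,hi window bounds in Da (`lo < hi`).
#' @return The subset of `records` inside the window, original order.
#' @export
mw_filter <- function(records, lo = 300, hi = 600) {
  stopifnot(is.data.frame(records), lo < hi)
  records[records$mw >= lo & records$mw <= hi, , drop = FALSE]
}

#' Select molecular-weight-matched decoys
#'
#' For each active, draws up to `ratio` compounds from `pool` whose
#' molecular weight lies within `tol` Da of the active's, without
#' replacement across actives. An audit table reports per-active
#' shortfalls when the pool is locally exhausted.
#'
#' @param actives,pool molecule-record data frames; `pool` must be
#'   disjoint from `actives` by canonical SMILES.
#' @param tol matching tolerance in Da.
#' @param ratio decoys requested per active.
#' @param seed integer seed (required; selection is randomized).
#' @return `list(decoys, audit)`: the selected records (role set to
#'   `"decoy"`) and a per-active audit `data.frame`.
#' @export
select_mw_decoys <- function(actives, pool, tol = 25, ratio = 1, seed) {
  stopifnot(is.data.frame(actives), is.data.frame(pool), tol > 0, ratio >= 1)
  if (missing(seed)) stop("seed is required for decoy selection")
  if (any(pool$smiles %in% actives$smiles))
    stop("pool contains structures that are also actives")
  taken <- logical(nrow(pool))
  picks <- integer(0)
  audit <- data.frame(active_id = actives$id, n_requested = ratio,
                      n_found = 0L, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (i in seq_len(nrow(actives))) {
      elig <- which(!taken & abs(pool$mw - actives$mw[i]) <= tol)
      k <- min(ratio, length(elig))
      if (k > 0) {
        sel <- if (length(elig) == 1) elig else sample(elig, k)
        taken[sel] <- TRUE
        picks <- c(picks, sel)
        audit$n_found[i] <- k
      }
    }
  })
  decoys <- pool[picks, , drop = FALSE]
  if (nrow(decoys)) decoys$role <- "decoy"
  audit$shortfall <- audit$n_requested - audit$n_found
  list(decoys = decoys, audit = audit)
}

#' Read a SMILES file
#'
#' One record per line, `SMILES<TAB>id`.
#'
#' @param path file path.
#' @param ... passed to [molecule_records()].
#' @return A molecule-record `data.frame`.
#' @export
read_smiles_file <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  id[is.na(id)] <- paste0("mol", which(is.na(id)))
  molecule_records(id = id, smiles = smi, ...)
}

#' Write molecule records as a SMILES file
#'
#' @param records molecule-record `data.frame`.
#' @param path output path.
#' @export
write_smiles_file <- function(records, path) {
  writeLines(paste(records$smiles, records$id, sep = "\t"), path)
}

#' Read a validation set CSV
#'
#' Expected header: `id,smiles,role,px` with role `active` or `decoy`.
#'
#' @param path file path.
#' @param standardize canonicalize structures on read.
#' @return A molecule-record `data.frame`.
#' @export
read_validation_csv <- function(path, standardize = TRUE) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "role", "px")
  if (!all(need %in% names(x)))
    stop("validation CSV must have columns ", paste(need, collapse = ", "))
  molecule_records(id = x$id, smiles = x$smiles, role = x$role, px = x$px,
                   source = if ("source" %in% names(x)) x$source else "",
                   standardize = standardize)
}

#' Write the decoy-selection audit as TSV
#'
#' @param audit the `audit` element returned by [select_mw_decoys()].
#' @param path output path.
#' @export
write_decoy_audit <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
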