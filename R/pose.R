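#' Construct a 3D ligand pose
#'
#' A pose ties a compound to one 3D conformation: per-atom coordinates,
#' partial charges and van der Waals radii, an optional docking score
#' (lower = better) and, optionally, precomputed pharmacophoric
#' features. All downstream 3D stages (pharmacophore screening,
#' electrostatics) operate on poses that already share one coordinate
#' frame.
#'
#' @param atoms `data.frame` with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (elementary charges) and `radius` (Angstrom;
#'   filled from Bondi radii when absent).
#' @param compound_id,pose_id identifiers.
#' @param target target id (e.g. an MMP name), optional.
#' @param score docking score, optional.
#' @param features optional `data.frame` of pharmacophoric features
#'   (`kind`, `x`, `y`, `z`); computed by [perceive_features()] when the
#'   pose comes from a real structure.
#' @return Object of class `vs_pose`.
#' @export
pose <- function(atoms, compound_id, pose_id = paste0(compound_id, "_1"),
                 target = NA_character_, score = NA_real_, features = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$element)
  stopifnot(all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))),
            all(is.finite(atoms$charge)))
  structure(list(compound_id = compound_id, pose_id = pose_id,
                 target = target, score = score, atoms = atoms,
                 features = features),
            class = "vs_pose")
}

#' @export
print.vs_pose <- function(x, ...) {
  cat("Pose", x$pose_id, "of compound", x$compound_id,
      if (!is.na(x$target)) paste0("(target ", x$target, ")") else "", "\n")
  cat(" ", nrow(x$atoms), "atoms; net charge",
      round(sum(x$atoms$charge), 3),
      if (!is.na(x$score)) paste0("; score ", x$score) else "", "\n")
  if (!is.null(x$features))
    cat("  features:", paste(x$features$kind, collapse = " "), "\n")
  invisible(x)
}

#' Bondi van der Waals radii
#'
#' @param element character vector of element symbols.
#' @return Radii in Angstrom (1.7, the carbon value, for elements not in
#'   the table).
#' @export
vdw_radius <- function(element) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
         S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90, B = 1.92,
         Si = 2.10)
  out <- unname(r[element])
  out[is.na(out)] <- 1.70
  out
}

#' Read ligand poses from an SDF file
#'
#' Each SDF record becomes one pose. Partial charges are taken from a
#' named data field holding one charge per atom (whitespace-separated),
#' falling back to formal charges from the connection table; a data
#' field with the docking score is read when present.
#'
#' @param path SDF file (V2000).
#' @param charge_field,score_field data-field names.
#' @param target target id stored on each pose.
#' @param perceive also run [perceive_features()] on each pose.
#' @return List of `vs_pose`.
#' @export
read_poses_sdf <- function(path, charge_field = "PARTIAL_CHARGES",
                           score_field = "DOCKING_SCORE",
                           target = NA_character_, perceive = FALSE) {
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) stop("no SDF records in ", path)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    rec <- lines[starts[i]:ends[i]]
    mb <- .parse_molblock(rec)
    db <- .parse_sdf_datafields(rec)
    id <- trimws(rec[1])
    if (!nzchar(id)) id <- paste0("pose", i)
    atoms <- data.frame(element = mb$elem, x = mb$xyz[, 1], y = mb$xyz[, 2],
                        z = mb$xyz[, 3], charge = mb$charge,
                        stringsAsFactors = FALSE)
    if (charge_field %in% names(db)) {
      q <- as.numeric(strsplit(trimws(db[[charge_field]]), "[ \t]+")[[1]])
      if (length(q) != nrow(atoms))
        stop("charge field length mismatch in record ", id)
      atoms$charge <- q
    }
    score <- if (score_field %in% names(db))
      as.numeric(db[[score_field]]) else NA_real_
    p <- pose(atoms, compound_id = id, pose_id = paste0(id, "_", i),
              target = target, score = score)
    if (perceive) p$features <- .perceive_from_molblock(mb)
    out[[i]] <- p
  }
  out
}

# "> <NAME>" data fields of one SDF record; values joined by newline.
.parse_sdf_datafields <- function(rec) {
  hdr <- grep("^> *<", rec)
  out <- list()
  for (h in hdr) {
    name <- sub("^> *<([^>]*)>.*$", "\\1", rec[h])
    j <- h + 1
    val <- character(0)
    while (j <= length(rec) && nzchar(trimws(rec[j])) &&
           !startsWith(rec[j], "$$$$")) {
      val <- c(val, rec[j]); j <- j + 1
    }
    out[[name]] <- paste(val, collapse = "\n")
  }
  out
}

#' Write poses to an SDF file
#'
#' Inverse of [read_poses_sdf()]: coordinates in the connection table,
#' partial charges and score as data fields.
#'
#' @param poses list of `vs_pose`.
#' @param path output path.
#' @param charge_field,score_field data-field names.
#' @export
write_poses_sdf <- function(poses, path,
                            charge_field = "PARTIAL_CHARGES",
                            score_field = "DOCKING_SCORE") {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    a <- p$atoms
    n <- nrow(a)
    lines <- c(p$compound_id, "  vsfunnel", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              a$x, a$y, a$z, a$element))
    lines <- c(lines, "M  END",
               paste0(">  <", charge_field, ">"),
               paste(format(a$charge, trim = TRUE), collapse = " "), "")
    if (!is.na(p$score))
      lines <- c(lines, paste0(">  <", score_field, ">"), p$score, "")
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
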