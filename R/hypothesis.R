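#' Construct a pharmacophore hypothesis
#'
#' An ordered set of pharmacophoric sites. Each site has a feature kind
#' (`A`, `D`, `R`, `N`, `H`, `P`), a position in Angstrom, a matching
#' tolerance radius, a required flag (`+` sites must be matched; `-`
#' sites are optional) and a weight.
#'
#' @param sites `data.frame` with columns `kind`, `x`, `y`, `z`,
#'   `tolerance`, `required` (and optionally `weight`).
#' @param id hypothesis identifier.
#' @param provenance `"structure_based"` (fragment-derived) or
#'   `"ligand_based"`.
#' @param min_optional_matches how many optional sites a pose must
#'   additionally satisfy (0 by default: optional sites never reject).
#' @return Object of class `vs_hypothesis`.
#' @export
hypothesis <- function(sites, id = "hyp", provenance = c("structure_based",
                                                         "ligand_based"),
                       min_optional_matches = 0) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(sites), nrow(sites) >= 1)
  kinds <- c("A", "D", "R", "N", "H", "P")
  if (!all(sites$kind %in% kinds))
    stop("unknown feature kind(s): ",
         paste(setdiff(sites$kind, kinds), collapse = ", "))
  if (is.null(sites$weight)) sites$weight <- 1
  if (!is.null(sites$tolerance) && any(!is.na(sites$tolerance) &
                                       sites$tolerance <= 0))
    stop("site tolerances must be positive")
  if (provenance == "structure_based" && nrow(sites) > 8)
    stop("structure-based hypotheses carry at most 8 sites")
  if (provenance == "ligand_based" &&
      !(nrow(sites) >= 3 && nrow(sites) <= 5))
    stop("ligand-based hypotheses carry 3-5 features")
  structure(list(id = id, sites = sites, provenance = provenance,
                 min_optional_matches = min_optional_matches),
            class = "vs_hypothesis")
}

#' @export
print.vs_hypothesis <- function(x, ...) {
  cat("Pharmacophore hypothesis", x$id, paste0("(", x$provenance, ")\n"))
  tag <- ifelse(x$sites$required, "(+)", "(-)")
  cat(" ", paste(x$sites$kind, tag, collapse = " "), "\n")
  if (!all(is.na(x$sites$x)))
    cat("  with coordinates; tolerances:",
        paste(x$sites$tolerance, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a hypothesis string
#'
#' Parses compact hypothesis notation such as `"A (+) A (-) R (+)"`
#' into a hypothesis skeleton: feature kinds and required flags, without
#' coordinates (to be filled in from a generated hypothesis or a
#' serialized file). `+` marks a required site, `-` (ASCII or Unicode
#' minus) an optional one.
#'
#' @param text the hypothesis string.
#' @param id hypothesis identifier.
#' @param provenance passed to [hypothesis()].
#' @return A `vs_hypothesis` skeleton with `NA` coordinates.
#' @examples
#' parse_hypothesis_string("A (+) A (+) R (+)")
#' @export
parse_hypothesis_string <- function(text, id = "hyp",
                                    provenance = "structure_based") {
  text <- gsub("−|–", "-", text)
  tokens <- regmatches(text, gregexpr("[A-Za-z]+\\s*\\(\\s*[+-]\\s*\\)",
                                      text))[[1]]
  if (!length(tokens)) stop("no KIND(+/-) tokens found in ", sQuote(text))
  residue <- gsub("[A-Za-z]+\\s*\\(\\s*[+-]\\s*\\)|\\s", "", text)
  if (nzchar(residue))
    stop("unparsed text in hypothesis string: ", sQuote(residue))
  kind <- sub("\\s*\\(.*$", "", tokens)
  bad <- setdiff(kind, c("A", "D", "R", "N", "H", "P"))
  if (length(bad))
    stop("unknown feature kind in token(s): ",
         paste(sQuote(tokens[kind %in% bad]), collapse = ", "))
  required <- grepl("\\+", tokens)
  sites <- data.frame(kind = kind, x = NA_real_, y = NA_real_, z = NA_real_,
                      tolerance = NA_real_, required = required,
                      weight = 1, stringsAsFactors = FALSE)
  hypothesis(sites, id = id, provenance = provenance)
}

#' Serialize hypotheses to JSON
#'
#' @param hyps a `vs_hypothesis` or list of them.
#' @param path output path.
#' @export
write_hypotheses_json <- function(hyps, path) {
  if (inherits(hyps, "vs_hypothesis")) hyps <- list(hyps)
  out <- lapply(hyps, function(h)
    list(id = h$id, provenance = h$provenance,
         min_optional_matches = h$min_optional_matches, sites = h$sites))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read hypotheses from JSON
#'
#' @param path file written by [write_hypotheses_json()].
#' @return List of `vs_hypothesis`.
#' @export
read_hypotheses_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(raw)), function(i) {
    sites <- raw$sites[[i]]
    hypothesis(sites, id = raw$id[i], provenance = raw$provenance[i],
               min_optional_matches = raw$min_optional_matches[i])
  })
}
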