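#' Load a PAINS alert catalogue
#'
#' Reads a tab-separated alert catalogue (`id`, `smarts`, `description`;
#' `#` comment lines ignored). The bundled default is a curated subset of
#' the widely used pan-assay interference (PAINS) alerts.
#'
#' @param path catalogue file; default is the bundled catalogue.
#' @return `data.frame` with columns `id`, `smarts`, `description`.
#' @export
pains_catalogue <- function(path = system.file("extdata", "pains_alerts.tsv",
                                               package = "vsfunnel")) {
  lines <- readLines(path)
  # '#' only marks comments at line start: it is a bond symbol in SMARTS
  lines <- lines[!startsWith(trimws(lines), "#")]
  read.delim(text = paste(lines, collapse = "\n"), stringsAsFactors = FALSE)
}

#' Flag pan-assay interference (PAINS) substructures
#'
#' Substructure search of each record against an alert catalogue.
#' Matching is deterministic; a compound is flagged if any alert SMARTS
#' occurs in its structure.
#'
#' @param records molecule-record `data.frame` (or character SMILES).
#' @param catalogue alert catalogue from [pains_catalogue()].
#' @return `data.frame` with columns `id`, `flagged` (logical) and
#'   `matched_alerts` (comma-separated alert ids, `""` when clean).
#' @export
pains_flag <- function(records, catalogue = pains_catalogue()) {
  if (is.character(records))
    records <- data.frame(id = if (is.null(names(records)))
      paste0("m", seq_along(records)) else names(records),
      smiles = records, stringsAsFactors = FALSE)
  sdf <- smiles_to_sdf(setNames(records$smiles, records$id))
  hits <- matrix(FALSE, nrow(records), nrow(catalogue))
  for (j in seq_len(nrow(catalogue))) {
    cnt <- suppressWarnings(
      ChemmineR::smartsSearchOB(sdf, catalogue$smarts[j], uniqueMatches = TRUE))
    hits[, j] <- cnt > 0
  }
  matched <- apply(hits, 1, function(h)
    paste(catalogue$id[h], collapse = ","))
  data.frame(id = records$id, flagged = rowSums(hits) > 0,
             matched_alerts = matched, stringsAsFactors = FALSE)
}
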