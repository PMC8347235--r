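#' Triage reference ligands by active/decoy separation
#'
#' A crystallographic reference is only useful for electrostatic
#' filtering if the similarity distribution of potent actives against it
#' separates from that of decoys; references for which the two
#' distributions are close are discarded. Separation is quantified by
#' the two-sample Kolmogorov-Smirnov statistic between the et_pb values
#' of high-potency actives (pX > 7) and of decoys.
#'
#' @param validation named list, one entry per reference: a `data.frame`
#'   with columns `role` (`active`/`decoy`), `px` and `et_pb`.
#' @param min_separation KS statistic at or above which a reference is
#'   kept (0.25 by default).
#' @return `list(kept, audit)`: kept reference names and a per-reference
#'   audit `data.frame` (`reference`, `ks`, `n_active_gt7`, `n_decoy`,
#'   `kept`, `note`).
#' @export
triage_references <- function(validation, min_separation = 0.25) {
  stopifnot(is.list(validation), !is.null(names(validation)))
  audit <- data.frame(reference = names(validation), ks = NA_real_,
                      n_active_gt7 = 0L, n_decoy = 0L, kept = FALSE,
                      note = "", stringsAsFactors = FALSE)
  for (i in seq_along(validation)) {
    v <- validation[[i]]
    act <- v$et_pb[v$role == "active" & !is.na(v$px) & v$px > 7]
    dec <- v$et_pb[v$role == "decoy"]
    audit$n_active_gt7[i] <- length(act)
    audit$n_decoy[i] <- length(dec)
    if (!length(act) || !length(dec)) {
      audit$note[i] <- "empty stratum; reference skipped"
      next
    }
    ks <- suppressWarnings(ks.test(act, dec)$statistic)
    audit$ks[i] <- unname(ks)
    audit$kept[i] <- ks >= min_separation
    if (!audit$kept[i]) audit$note[i] <- "active/decoy distributions similar"
  }
  list(kept = audit$reference[audit$kept], audit = audit)
}

#' Calibrate the electrostatic similarity cutoff
#'
#' Chooses the et_pb cutoff separating high-potency actives (pX > 7)
#' from decoys: candidate cutoffs are the midpoints between adjacent
#' observed values, and the one maximizing Youden's J (sensitivity +
#' specificity - 1) is selected (ties: highest specificity, then lowest
#' cutoff). Histogram bin data over the et_pb range, with actives
#' stratified by pX (< 4, 4-7, > 7), is emitted for plotting. A manual
#' override replaces the automatic choice (provenance `"manual"`), as
#' when a cutoff is read off the published histograms.
#'
#' @param results `data.frame` with columns `role`, `px`, `et_pb`.
#' @param override optional manual cutoff value.
#' @param bin_width histogram bin width (0.05).
#' @param min_youden J value below which the calibration is flagged
#'   non-discriminating.
#' @return Object of class `et_calibration`: cutoff, provenance,
#'   `youden`, `discriminating` flag, stratum counts and `histogram`
#'   (`bin_left`, `decoy_count`, `act_lt4`, `act_4to7`, `act_gt7`).
#' @export
calibrate_cutoff <- function(results, override = NULL, bin_width = 0.05,
                             min_youden = 0.2) {
  stopifnot(all(c("role", "px", "et_pb") %in% names(results)))
  act <- results[results$role == "active", , drop = FALSE]
  dec <- results$et_pb[results$role == "decoy"]
  gt7 <- act$et_pb[!is.na(act$px) & act$px > 7]
  missing <- c(if (!length(dec)) "decoys",
               if (!length(gt7)) "actives with pX > 7")
  if (length(missing))
    stop("empty stratum: ", paste(missing, collapse = " and "))

  vals <- sort(unique(c(gt7, dec)))
  cand <- if (length(vals) > 1) (head(vals, -1) + vals[-1]) / 2
          else vals
  J <- vapply(cand, function(cu)
    mean(gt7 >= cu) + mean(dec < cu) - 1, 0)
  spec <- vapply(cand, function(cu) mean(dec < cu), 0)
  ord <- order(-J, -spec, cand)
  best <- ord[1]

  lo <- -1 / 3
  breaks <- seq(lo, 1 + bin_width, by = bin_width)
  bin_count <- function(x) {
    x <- pmin(pmax(x, lo), 1)
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  }
  hist_df <- data.frame(
    bin_left = head(breaks, -1),
    decoy_count = bin_count(dec),
    act_lt4 = bin_count(act$et_pb[!is.na(act$px) & act$px < 4]),
    act_4to7 = bin_count(act$et_pb[!is.na(act$px) & act$px >= 4 &
                                     act$px <= 7]),
    act_gt7 = bin_count(gt7))

  cutoff <- if (!is.null(override)) override else cand[best]
  structure(list(
    cutoff = cutoff,
    provenance = if (!is.null(override)) "manual" else "youden",
    youden = J[best],
    discriminating = J[best] >= min_youden,
    n = c(decoys = length(dec), act_lt4 = sum(!is.na(act$px) & act$px < 4),
          act_4to7 = sum(!is.na(act$px) & act$px >= 4 & act$px <= 7),
          act_gt7 = length(gt7)),
    histogram = hist_df), class = "et_calibration")
}

#' @export
print.et_calibration <- function(x, ...) {
  cat("Electrostatic similarity cutoff:", round(x$cutoff, 4),
      paste0("(", x$provenance, ")\n"))
  cat("  Youden J:", round(x$youden, 3),
      if (!x$discriminating) " [non-discriminating]" else "", "\n")
  cat("  strata:", paste(names(x$n), x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Apply an electrostatic similarity cutoff
#'
#' Keeps results whose et_pb is at least the cutoff (the boundary value
#' passes).
#'
#' @param results `data.frame` with an `et_pb` column (e.g. from
#'   [best_reference_similarity()]).
#' @param cutoff numeric cutoff or an `et_calibration`.
#' @return The passing subset of `results`.
#' @export
apply_cutoff <- function(results, cutoff) {
  if (inherits(cutoff, "et_calibration")) cutoff <- cutoff$cutoff
  results[results$et_pb >= cutoff, , drop = FALSE]
}

#' Write calibration histogram as TSV
#'
#' @param calibration an `et_calibration`.
#' @param path output path.
#' @export
write_calibration_tsv <- function(calibration, path) {
  write.table(calibration$histogram, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
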