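#' Configuration for the random-forest bioactivity filter
#'
#' @param n_trees trees in the ensemble (100 in the screening workflow).
#' @param fp_radius,fp_nbits Morgan fingerprint parameters (radius 2;
#'   2048 bits by default).
#' @param probability_threshold calibrated-probability threshold below
#'   which library compounds are excluded (0.20: compounds with a
#'   less-than-20% probability of activity are discarded).
#' @param cv_folds folds for stratified cross-validation (5, i.e. 80/20
#'   train/test splits).
#' @param seed integer seed controlling fold assignment and tree growth.
#' @return List of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100, fp_radius = 2, fp_nbits = 2048,
                      probability_threshold = 0.20, cv_folds = 5, seed = 1) {
  stopifnot(n_trees >= 1, probability_threshold > 0,
            probability_threshold < 1, cv_folds >= 2)
  structure(list(n_trees = n_trees, fp_radius = fp_radius,
                 fp_nbits = fp_nbits,
                 probability_threshold = probability_threshold,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "rf_config")
}

# Platt's sigmoid calibration: fit p = 1/(1 + exp(A f + B)) by
# penalized maximum likelihood with Platt's soft targets, which keeps
# the fit finite on perfectly separated scores.
.platt_fit <- function(scores, labels) {
  ok <- is.finite(scores) & !is.na(labels)
  f <- scores[ok]; y <- labels[ok]
  np <- sum(y == 1); nn <- sum(y == 0)
  t <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # -sum(t*log(p) + (1-t)*log(1-p)) with p = 1/(1+exp(z)), stable form:
    # log(1+e^z) = max(z,0) + log1p(e^-|z|)
    sum(pmax(z, 0) + log1p(exp(-abs(z))) - (1 - t) * z)
  }
  fit <- optim(c(-1, 0), nll, method = "BFGS")
  c(A = fit$par[1], B = fit$par[2])
}

.platt_apply <- function(platt, scores) {
  1 / (1 + exp(platt["A"] * scores + platt["B"]))
}

.check_two_class <- function(actives, decoys) {
  if (is.null(actives) || nrow(actives) == 0 ||
      is.null(decoys) || nrow(decoys) == 0)
    stop("both an active and a decoy class are required")
}

#' Train the Platt-calibrated random-forest bioactivity filter
#'
#' Grows a probability forest on Morgan fingerprints of actives vs
#' decoys and calibrates the ensemble vote fractions with Platt's
#' sigmoid, fitted on out-of-bag votes (held-out scores obtained without
#' an extra cross-validation layer). Reproducible under the config seed.
#'
#' @param actives,decoys molecule-record data frames (both non-empty).
#' @param config an [rf_config()].
#' @return Object of class `vs_rf_model` with a [predict()] method that
#'   returns calibrated probabilities of activity.
#' @export
train_calibrated_rf <- function(actives, decoys, config = rf_config()) {
  .check_two_class(actives, decoys)
  recs <- rbind(actives, decoys)
  x <- fingerprint_matrix(recs, config$fp_radius, config$fp_nbits)
  y <- factor(rep(c("active", "decoy"), c(nrow(actives), nrow(decoys))))
  .train_on_matrix(x, y, config)
}

.train_on_matrix <- function(x, y, config) {
  storage.mode(x) <- "double"
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  forest <- ranger::ranger(x = x, y = y, num.trees = config$n_trees,
                           probability = TRUE, seed = config$seed,
                           num.threads = 1)
  oob <- forest$predictions[, "active"]
  platt <- .platt_fit(oob, as.integer(y == "active"))
  structure(list(forest = forest, platt = platt, config = config,
                 n_actives = sum(y == "active"),
                 n_decoys = sum(y == "decoy")),
            class = "vs_rf_model")
}

#' @export
print.vs_rf_model <- function(x, ...) {
  cat("Calibrated random-forest bioactivity filter\n")
  cat("  trees:", x$config$n_trees,
      " fingerprint: radius", x$config$fp_radius, "/",
      x$config$fp_nbits, "bits\n")
  cat("  trained on", x$n_actives, "actives /", x$n_decoys, "decoys\n")
  cat("  Platt sigmoid: A =", signif(x$platt["A"], 4),
      " B =", signif(x$platt["B"], 4), "\n")
  invisible(x)
}

#' Calibrated activity probabilities
#'
#' @param object a `vs_rf_model`.
#' @param newdata molecule-record `data.frame` or a fingerprint matrix
#'   with the model's bit length.
#' @param raw return uncalibrated ensemble vote fractions instead.
#' @param ... ignored.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predict.vs_rf_model <- function(object, newdata, raw = FALSE, ...) {
  x <- if (is.matrix(newdata)) newdata
       else fingerprint_matrix(newdata, object$config$fp_radius,
                               object$config$fp_nbits)
  storage.mode(x) <- "double"
  ids <- rownames(x)
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  votes <- predict(object$forest, data = x,
                   num.threads = 1)$predictions[, "active"]
  out <- if (raw) votes else .platt_apply(object$platt, votes)
  setNames(as.numeric(out), ids)
}

#' Stratified cross-validation of the bioactivity filter
#'
#' Splits each class into `config$cv_folds` stratified folds (seeded),
#' trains on the remaining folds and classifies the held-out compounds
#' (calibrated probability >= `classify_threshold` counts as predicted
#' active), then averages the per-fold confusion-matrix metrics.
#'
#' @inheritParams train_calibrated_rf
#' @param classify_threshold probability defining the predicted-active
#'   class when filling the confusion matrix.
#' @return `list(mean, folds)`: fold-mean `classifier_metrics` and the
#'   per-fold list.
#' @export
cross_validate <- function(actives, decoys, config = rf_config(),
                           classify_threshold = 0.5) {
  .check_two_class(actives, decoys)
  k <- config$cv_folds
  if (nrow(actives) < k || nrow(decoys) < k)
    stop("each class needs at least ", k, " compounds for ", k, "-fold CV")
  recs <- rbind(actives, decoys)
  x <- fingerprint_matrix(recs, config$fp_radius, config$fp_nbits)
  y <- factor(rep(c("active", "decoy"), c(nrow(actives), nrow(decoys))))
  fold <- integer(length(y))
  with_seed(config$seed, {
    for (cl in levels(y)) {
      i <- which(y == cl)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- .train_on_matrix(x[tr, , drop = FALSE], y[tr], config)
    p <- predict(model, x[!tr, , drop = FALSE])
    pred_act <- p >= classify_threshold
    truth_act <- y[!tr] == "active"
    folds[[f]] <- compute_metrics(tp = sum(pred_act & truth_act),
                                  fp = sum(pred_act & !truth_act),
                                  tn = sum(!pred_act & !truth_act),
                                  fn = sum(!pred_act & truth_act))
  }
  list(mean = mean_metrics(folds), folds = folds)
}

#' Apply the probability filter to a screening library
#'
#' Retains compounds whose calibrated probability of activity is at
#' least `threshold`. The boundary is kept: with the workflow's 20%
#' setting, compounds with a less-than-20% probability are excluded and
#' a compound at exactly 0.20 survives.
#'
#' @param model a `vs_rf_model`, or a named numeric vector of
#'   precomputed probabilities (one per library record).
#' @param library molecule-record `data.frame`.
#' @param threshold retention threshold (default 0.20).
#' @return `library` rows that pass, with a `probability` column.
#' @export
apply_probability_filter <- function(model, library, threshold = 0.20) {
  if (nrow(library) == 0) {
    library$probability <- numeric(0)
    return(library)
  }
  p <- if (is.numeric(model)) {
    stopifnot(length(model) == nrow(library))
    as.numeric(model)
  } else predict(model, library)
  keep <- p >= threshold
  out <- library[keep, , drop = FALSE]
  out$probability <- p[keep]
  out
}
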