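#' Percent inhibition from reaction velocities
#'
#' `100 (1 - vi/vo)`, where `vi` is the initial substrate-cleavage
#' velocity with inhibitor and `vo` the uninhibited control velocity.
#'
#' @param vi,vo velocities in matching units (`vo > 0`).
#' @return Percent inhibition (vectorized).
#' @export
percent_inhibition <- function(vi, vo) {
  if (any(vo <= 0)) stop("control velocity vo must be positive")
  100 * (1 - vi / vo)
}

#' Velocity ratio predicted by the single-site binding model
#'
#' `vi/vo = 1 / (1 + [I]/IC50)`: at `[I] = IC50` the reaction runs at
#' half speed.
#'
#' @param ic50 half-maximal inhibitory concentration, in the same units
#'   as `concentration` (micromolar throughout the package).
#' @param concentration inhibitor concentration `[I]`.
#' @return Predicted `vi/vo` (vectorized).
#' @export
predict_velocity_ratio <- function(ic50, concentration) {
  stopifnot(all(ic50 > 0), all(concentration >= 0))
  1 / (1 + concentration / ic50)
}

#' Fit an IC50 to velocity-ratio measurements
#'
#' Least-squares fit of the single parameter IC50 in
#' `vi/vo = 1/(1 + [I]/IC50)`. Only measurements whose observed
#' inhibition lies in the 10-90% window qualify, and at least five
#' distinct qualifying concentrations are required -- the acceptance rule
#' used when IC50s are determined experimentally. The initial guess is
#' the concentration whose inhibition is nearest 50%; the reported
#' standard deviation is the fit uncertainty from the linearized
#' covariance at the optimum (not an inter-experiment SD).
#'
#' @param measurements `data.frame` with columns `concentration_uM` and
#'   `vi_over_vo` (replicate rows allowed).
#' @return Object of class `ic50_fit`: `ic50` and `sd` in micromolar,
#'   `n` points used, `converged` flag.
#' @export
fit_ic50 <- function(measurements) {
  stopifnot(all(c("concentration_uM", "vi_over_vo") %in%
                  names(measurements)))
  m <- measurements[is.finite(measurements$concentration_uM) &
                      is.finite(measurements$vi_over_vo), , drop = FALSE]
  inh <- percent_inhibition(m$vi_over_vo, 1)
  qual <- inh >= 10 & inh <= 90
  if (length(unique(m$concentration_uM[qual])) < 5)
    stop("need at least five distinct concentrations with inhibition ",
         "in the 10-90% window (", length(unique(m$concentration_uM[qual])),
         " found)")
  m <- m[qual, , drop = FALSE]
  start <- m$concentration_uM[which.min(abs(inh[qual] - 50))]
  fit <- minpack.lm::nlsLM(
    vi_over_vo ~ 1 / (1 + concentration_uM / ic50), data = m,
    start = list(ic50 = start), lower = 1e-9,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)[["ic50"]]
  se <- tryCatch(summary(fit)$coefficients["ic50", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(ic50 = est, sd = se, n = nrow(m),
                 converged = fit$convInfo$isConv,
                 residuals = as.numeric(residuals(fit))),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 3, ...) {
  cat("IC50 fit: ", signif(x$ic50, digits), " uM (fit SD ",
      signif(x$sd, digits), "), n = ", x$n,
      if (!x$converged) " [did not converge]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) c(ic50 = object$ic50)

#' Predicted velocity ratios from a fitted IC50
#'
#' @param object an `ic50_fit`.
#' @param concentration concentrations in micromolar.
#' @param ... ignored.
#' @return Predicted `vi/vo` values.
#' @export
predict.ic50_fit <- function(object, concentration, ...) {
  predict_velocity_ratio(object$ic50, concentration)
}

#' Read a dose-response CSV
#'
#' Expected header: `concentration_uM,vi_over_vo,replicate`.
#'
#' @param path file path.
#' @return `data.frame` of measurements.
#' @export
read_inhibition_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_uM", "vi_over_vo")
  if (!all(need %in% names(x)))
    stop("dose-response CSV must have columns ",
         paste(need, collapse = ", "))
  x
}
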