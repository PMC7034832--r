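#' Dual-colour EMSA normalized binding signal
#'
#' Competition EMSA quantification against an internal reference probe: the
#' ratio of bound fractions in the two fluorescence channels, corrected for
#' loading by the inverse ratio of total signals,
#' `(bound_550 / bound_647) * (total_647 / total_550)`. A value of 1 means
#' the probe of interest binds like the internal control; 2 is a two-fold
#' preference. The ratio is scale-invariant within each channel, so gain
#' differences between dyes cancel.
#'
#' @param bound_550,bound_647 bound-fraction signals of the probe and the
#'   internal control channel.
#' @param total_550,total_647 total lane signals per channel (> 0).
#' @return normalized ratio (dimensionless), vectorized over lanes.
#' @export
emsa_normalized_signal <- function(bound_550, bound_647, total_550, total_647) {
  if (any(total_550 <= 0) || any(total_647 <= 0))
    stop_dyadmd("total signals must be > 0")
  if (any(bound_550 > total_550) || any(bound_647 > total_647))
    stop_dyadmd("bound signal exceeds total signal")
  if (any(bound_647 == 0))
    stop_dyadmd("undefined ratio: bound_647 is zero (flag the lane, do not impute)")
  (bound_550 / bound_647) * (total_647 / total_550)
}

#' Fit a 1:1 binding isotherm
#'
#' Nonlinear least squares of `response = baseline + amplitude * c /
#' (c + kd)` (non-depleting hyperbolic model; a quadratic ligand-depletion
#' model is available via `model = "quadratic"` when the fixed binding
#' partner concentration is not negligible against the K_D). The K_D start
#' value is the concentration nearest half-amplitude, making the fit
#' deterministic given the data.
#'
#' @param concentrations titration concentrations (same units as the
#'   returned K_D; >= 5 points spanning the transition).
#' @param responses measured responses.
#' @param model `"hyperbolic"` (default) or `"quadratic"`.
#' @param protein_conc fixed-partner concentration, required for the
#'   quadratic model.
#' @return object of class `"titration_fit"`: list with `kd`, `kd_se`,
#'   `amplitude`, `baseline`, `residuals`, and the underlying `nls` fit.
#' @export
fit_kd <- function(concentrations, responses,
                   model = c("hyperbolic", "quadratic"),
                   protein_conc = NULL) {
  model <- match.arg(model)
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 5)
    stop_dyadmd("need at least 5 titration points")
  if (stats::sd(responses) == 0)
    stop_dyadmd("fit not identifiable: responses are constant")
  baseline0 <- min(responses)
  amplitude0 <- max(responses) - min(responses)
  half <- baseline0 + amplitude0 / 2
  kd0 <- concentrations[which.min(abs(responses - half))]
  df <- data.frame(c = concentrations, y = responses)
  fit <- tryCatch({
    if (model == "hyperbolic") {
      minpack.lm::nlsLM(y ~ baseline + amplitude * c / (c + kd), data = df,
                        start = list(baseline = baseline0,
                                     amplitude = amplitude0, kd = kd0),
                        lower = c(-Inf, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      if (is.null(protein_conc) || protein_conc <= 0)
        stop_dyadmd("quadratic model needs protein_conc > 0")
      P <- protein_conc
      minpack.lm::nlsLM(
        y ~ baseline + amplitude *
          ((P + c + kd) - sqrt((P + c + kd)^2 - 4 * P * c)) / (2 * P),
        data = df,
        start = list(baseline = baseline0, amplitude = amplitude0, kd = kd0),
        lower = c(-Inf, -Inf, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e)
    stop_dyadmd("K_D fit did not converge: ", conditionMessage(e)))
  co <- summary(fit)$coefficients
  if (!is.finite(co["kd", "Estimate"]) || co["kd", "Estimate"] <= 0)
    stop_dyadmd("K_D fit did not converge to a positive estimate")
  structure(list(kd = co["kd", "Estimate"],
                 kd_se = co["kd", "Std. Error"],
                 amplitude = co["amplitude", "Estimate"],
                 baseline = co["baseline", "Estimate"],
                 residuals = stats::residuals(fit),
                 model = model, fit = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("1:1 isotherm fit (%s): K_D = %.4g +/- %.2g, amplitude %.4g, baseline %.4g\n",
              x$model, x$kd, x$kd_se, x$amplitude, x$baseline))
  invisible(x)
}

#' Shuffle lane labels for blinded analysis
#'
#' Assigns random pseudonyms to lane/gel labels so quantification can be
#' performed blind; returns the key needed to unblind.
#'
#' @param labels character vector of lane identifiers.
#' @param seed RNG seed.
#' @return data.frame mapping `blinded` to the original `label`.
#' @export
blind_labels <- function(labels, seed = 1) {
  pseudo <- with_seed(seed, sample(sprintf("sample_%03d", seq_along(labels))))
  data.frame(blinded = pseudo, label = labels, stringsAsFactors = FALSE)
}
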