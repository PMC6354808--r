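#' Assay error model: polynomial SD with multiplicative inflation
#'
#' The observation SD is a first-order polynomial in the observed
#' concentration, per output channel, inflated by a single multiplicative
#' factor gamma shared by both channels:
#' `SD(Y) = gamma * (C0 + C1 * Y)`.
#' The defaults are the assay-informed coefficients used for the cefepime
#' study: plasma C0 = 0.25, C1 = 0.15; CSF C0 = 0.0625, C1 = 0.15; gamma = 1.
#'
#' @param plasma_c0,plasma_c1 Plasma intercept (ug/ml) and slope (unitless).
#' @param csf_c0,csf_c1 CSF intercept (ug/ml) and slope (unitless).
#' @param gamma Multiplicative error inflation, > 0.
#' @return An object of class `error_model`.
#' @export
errorModel <- function(plasma_c0 = 0.25, plasma_c1 = 0.15,
                       csf_c0 = 0.0625, csf_c1 = 0.15, gamma = 1) {
  stopifnot(plasma_c0 >= 0, plasma_c1 >= 0, csf_c0 >= 0, csf_c1 >= 0,
            gamma > 0)
  structure(list(plasma = c(c0 = plasma_c0, c1 = plasma_c1),
                 csf = c(c0 = csf_c0, c1 = csf_c1), gamma = gamma),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> SD(Y) = gamma * (C0 + C1 * Y)\n")
  cat(sprintf("  plasma: C0 = %g, C1 = %g\n", x$plasma["c0"], x$plasma["c1"]))
  cat(sprintf("  csf:    C0 = %g, C1 = %g\n", x$csf["c0"], x$csf["c1"]))
  cat(sprintf("  gamma:  %g\n", x$gamma))
  invisible(x)
}

#' Observation standard deviation under the error model
#'
#' @param value Observed concentration(s), ug/ml, >= 0.
#' @param output Output channel, `"plasma"` or `"csf"` (recycled).
#' @param errmod An [errorModel()].
#' @return SD(s) in ug/ml.
#' @export
observationSD <- function(value, output, errmod = errorModel()) {
  if (any(value < 0)) stop("negative observation value")
  poly <- rbind(plasma = errmod$plasma, csf = errmod$csf)[output, ,
                                                          drop = FALSE]
  errmod$gamma * (poly[, "c0"] + poly[, "c1"] * value)
}

# Precomputed per-subject quantities reused across many likelihood
# evaluations: non-excluded observations, their SDs (without gamma), the
# union of observation times and the state/volume map per observation.
subject_context <- function(subject, structure, errmod) {
  obs <- subject$observations
  obs <- obs[obs$excluded == 0, , drop = FALSE]
  if (nrow(obs) == 0) return(NULL)
  ord <- order(obs$time)
  obs <- obs[ord, , drop = FALSE]
  times <- sort(unique(obs$time))
  row_of <- match(obs$time, times)
  st <- vapply(obs$output, function(o) structure$outputs[[o]]$state, 1L)
  vol <- vapply(obs$output, function(o) structure$outputs[[o]]$volume, "")
  sd0 <- observationSD(obs$value, obs$output, errmod) / errmod$gamma
  list(id = subject$id, times = times, row = row_of, state = st, vol = vol,
       value = obs$value, output = obs$output, sd0 = sd0, n = nrow(obs),
       doses = as_dose_matrix(subject$doses),
       const = sum(log(2 * pi * sd0^2)))
}

# Predicted concentrations at a context's observation rows for one parameter
# vector; A prebuilt to amortise over subjects.
context_predict <- function(ctx, A, params) {
  am <- solve_amounts_cpp(A, ctx$doses, ctx$times)
  pred <- am[cbind(ctx$row, ctx$state)] / unclass(params)[ctx$vol]
  pmax(pred, 0)
}

# Weighted residual sum of squares sum(((obs - pred)/sd0)^2); together with
# ctx$const and n this determines -2LL for any gamma:
#   -2LL(gamma) = const + 2 n log(gamma) + ss / gamma^2
context_ss <- function(ctx, pred) sum(((ctx$value - pred) / ctx$sd0)^2)

neg2ll_from_ss <- function(ss, ctx_const, n, gamma) {
  ctx_const + 2 * n * log(gamma) + ss / gamma^2
}

#' -2 log-likelihood contribution of one subject
#'
#' Observations are modelled as independent Gaussians centred on the model
#' prediction with SD from [observationSD()] evaluated at the observed value.
#' Excluded observations are skipped.
#'
#' @inheritParams buildRateMatrix
#' @param subject A [subjectRecord()] with at least one non-excluded
#'   observation.
#' @param errmod An [errorModel()].
#' @return The scalar -2 log-likelihood.
#' @export
subjectNeg2LL <- function(params, subject, structure,
                          errmod = errorModel()) {
  ctx <- subject_context(subject, structure, errmod)
  if (is.null(ctx)) stop("all observations excluded: likelihood undefined")
  A <- buildRateMatrix(params, structure)
  ss <- context_ss(ctx, context_predict(ctx, A, params))
  neg2ll_from_ss(ss, ctx$const, ctx$n, errmod$gamma)
}

#' Akaike information criterion
#'
#' @param neg2ll -2 log-likelihood of the fitted model.
#' @param n_fitted_params Number of fitted parameters, >= 1. For the
#'   candidate structures this package counts the active structural
#'   parameters plus one for gamma (see [nFittedParams()]).
#' @return `neg2ll + 2 * n_fitted_params`.
#' @export
modelAIC <- function(neg2ll, n_fitted_params) {
  stopifnot(n_fitted_params >= 1)
  neg2ll + 2 * n_fitted_params
}

#' Fitted-parameter count of a structure (structural parameters + gamma)
#' @param structure A [pk_structure()].
#' @return Integer count used in [modelAIC()].
#' @export
nFittedParams <- function(structure) length(structure$active_params) + 1L

#' Bias, imprecision and R-squared of observed-versus-predicted pairs
#'
#' Bias is the weighted mean prediction error (predicted minus observed),
#' imprecision the bias-adjusted weighted mean squared error, both with
#' weights 1/SD^2 by default (unit weights available), and R-squared comes
#' from the least-squares regression of predicted on observed.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 points).
#' @param sds Observation SDs; required for inverse-variance weighting.
#' @param weighting `"inverse_variance"` or `"unit"`.
#' @return List with `bias` (ug/ml), `imprecision` ((ug/ml)^2), `r2`.
#' @export
predictiveDiagnostics <- function(observed, predicted, sds = NULL,
                                  weighting = c("inverse_variance", "unit")) {
  weighting <- match.arg(weighting)
  n <- length(observed)
  stopifnot(length(predicted) == n, n >= 2)
  w <- if (weighting == "inverse_variance") {
    stopifnot(!is.null(sds), all(sds > 0)); 1 / sds^2
  } else rep(1, n)
  w <- w / sum(w)
  e <- predicted - observed
  bias <- sum(w * e)
  imprecision <- sum(w * (e - bias)^2)
  if (stats::var(observed) == 0) {
    stop("r2 undefined: zero variance in observed values")
  }
  r2 <- suppressWarnings(summary(stats::lm(predicted ~ observed))$r.squared)
  list(bias = bias, imprecision = imprecision, r2 = r2)
}
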