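# Inverse probability weighting for unit nonresponse: a logistic propensity
# model for completeness, trimmed reciprocal-propensity weights among
# complete cases, and combination with an external survey weight.

#' Fit the completeness propensity model
#'
#' Logistic regression of the complete-case flag on fully observed
#' covariates, fitted by iteratively reweighted least squares.
#'
#' @param covariates data.frame or matrix of covariates (no missing values).
#' @param complete_flag 0/1 vector.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return List of class `completeness_model`: `coef`, `propensity` (fitted
#'   probabilities), `converged`, `iterations`.
#' @export
fit_completeness_model <- function(covariates, complete_flag,
                                   tol = 1e-8, max_iter = 100L) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  y <- as.numeric(complete_flag)
  if (anyNA(X)) stop("covariates must be fully observed")
  if (!all(y %in% c(0, 1))) stop("complete_flag must be binary 0/1")
  if (all(y == 1) || all(y == 0)) {
    warning("complete_flag is constant; no propensity model needed")
    return(structure(list(coef = c(`(Intercept)` = stats::qlogis(mean(y) * 0.9999 + 5e-5)),
                          propensity = rep(mean(y), length(y)),
                          converged = TRUE, iterations = 0L),
                     class = "completeness_model"))
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    if (any(w < 1e-10)) w <- pmax(w, 1e-10)
    z <- eta + (y - p) / w
    fit <- tryCatch(
      solve(crossprod(X, X * w), crossprod(X, w * z)),
      error = function(e) stop("propensity model is singular (perfect ",
                               "separation?); consider removing a covariate")
    )
    new_beta <- drop(fit)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
    if (max(abs(beta)) > 30) {
      stop("propensity coefficients diverging (perfect separation?); ",
           "consider removing a covariate")
    }
  }
  names(beta) <- colnames(X)
  p <- stats::plogis(drop(X %*% beta))
  structure(list(coef = beta, propensity = p, converged = converged,
                 iterations = it),
            class = "completeness_model")
}

#' Inverse probability weights from propensities
#'
#' `1/propensity` among complete cases, capped at the given quantile of the
#' untrimmed complete-case IPW distribution. Incomplete cases receive `NA`
#' (they are excluded from analysis, not down-weighted).
#'
#' @param propensities Fitted completeness probabilities in (0, 1].
#' @param complete_flag 0/1 vector; `NULL` treats all cases as complete.
#' @param trim_quantile Cap quantile (default 0.99); `1` disables trimming.
#' @return Numeric vector of IPWs (`NA` for incomplete cases).
#' @export
make_ipw <- function(propensities, complete_flag = NULL, trim_quantile = 0.99) {
  if (any(propensities <= 0)) stop("propensities must be positive")
  if (any(propensities > 1)) stop("propensities must not exceed 1")
  if (is.null(complete_flag)) complete_flag <- rep(1, length(propensities))
  ipw <- ifelse(complete_flag == 1, 1 / propensities, NA_real_)
  obs <- ipw[!is.na(ipw)]
  if (length(obs) && trim_quantile < 1) {
    cap <- stats::quantile(obs, trim_quantile, names = FALSE, type = 7)
    ipw <- pmin(ipw, cap)
  }
  ipw
}

#' Combine IPW with a survey weight
#'
#' Elementwise product of the nonresponse IPW and the external survey
#' weight, rescaled to mean 1 over analysed (non-`NA`) cases so that point
#' estimates are unchanged and sandwich standard errors stay on an
#' interpretable scale.
#'
#' @param ipw IPW vector (`NA` for excluded cases).
#' @param survey_weight Positive survey weights, same length.
#' @return Combined weights with mean 1 over non-`NA` entries.
#' @export
combine_weights <- function(ipw, survey_weight) {
  if (length(ipw) != length(survey_weight)) stop("weight vectors differ in length")
  if (any(!is.na(ipw) & is.na(survey_weight))) stop("survey weight missing for an analysed case")
  if (any(!is.na(survey_weight) & survey_weight <= 0)) stop("survey weights must be positive")
  w <- ipw * survey_weight
  w / mean(w, na.rm = TRUE)
}

#' Build analysis weights for a dyad dataset
#'
#' Convenience wrapper: fits the completeness model on the given covariate
#' columns, builds trimmed IPWs, and combines them with the `svywt` column.
#'
#' @param d Dyad data.frame (needs `complete`, `svywt`, and the covariates).
#' @param covariate_cols Covariate column names for the propensity model.
#' @param trim_quantile Passed to [make_ipw()].
#' @return List of class `weight_set`: `ipw`, `combined`, `model`.
#' @export
build_weights <- function(d, covariate_cols = c("sex", "edu"), trim_quantile = 0.99) {
  fit <- fit_completeness_model(d[, covariate_cols, drop = FALSE], d$complete)
  ipw <- make_ipw(fit$propensity, d$complete, trim_quantile)
  combined <- combine_weights(ipw, d$svywt)
  structure(list(ipw = ipw, combined = combined, model = fit),
            class = "weight_set")
}
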