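# Fit indices: CFI, RMSEA (noncentrality-based), SRMR (correlation-metric
# residuals, covariance elements only), and the chi-square difference test
# used by the invariance ladder.

#' Incremental and noncentrality fit indices
#'
#' `CFI = 1 - max(T - df, 0) / max(T0 - df0, T - df, 0)` and
#' `RMSEA = sqrt(max(T - df, 0) / (df * N)) * sqrt(G)` (the group multiplier
#' follows the independent-groups convention and is 1 when `G = 1`).
#'
#' @param T,df Test statistic and degrees of freedom of the target model.
#' @param T0,df0 Same for the baseline (independence) model.
#' @param N Total sample size.
#' @param G Number of groups.
#' @return List with `CFI` and `RMSEA` (RMSEA is 0 with a `saturated`
#'   attribute when `df = 0`).
#' @export
fit_indices <- function(T, df, T0, df0, N, G = 1) {
  if (df0 < df) stop("baseline df0 must be >= model df")
  num <- max(T - df, 0)
  den <- max(T0 - df0, T - df, 0)
  CFI <- if (den == 0) 1 else 1 - num / den
  if (df == 0) {
    RMSEA <- 0
    attr(RMSEA, "saturated") <- TRUE
  } else {
    RMSEA <- sqrt(num / (df * N)) * sqrt(G)
  }
  list(CFI = CFI, RMSEA = RMSEA)
}

#' Standardized root mean squared residual
#'
#' Root mean square of the correlation-metric residuals
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)` over the lower triangle including
#' the diagonal (covariance elements only; mean residuals excluded).
#'
#' @param S Sample covariance.
#' @param Sigma Implied covariance.
#' @return SRMR value.
#' @export
srmr <- function(S, Sigma) {
  sd_ <- sqrt(diag(S))
  R <- (S - Sigma) / outer(sd_, sd_)
  lt <- R[lower.tri(R, diag = TRUE)]
  sqrt(mean(lt^2))
}

# n-weighted average SRMR across groups
srmr_groups <- function(gm, impl) {
  vals <- vapply(seq_along(gm), function(g) srmr(gm[[g]]$S, impl[[g]]$Sigma), 0)
  ns <- vapply(gm, `[[`, 0, "n")
  sum(ns * vals) / sum(ns)
}

#' Chi-square difference between nested fits
#'
#' @param nested_fit Fit of the more constrained model.
#' @param parent_fit Fit of the less constrained model (free parameters a
#'   superset of the nested model's).
#' @return List with `dT`, `ddf`, `dCFI` (parent CFI minus nested CFI),
#'   `dRMSEA` (nested minus parent), `dSRMR`.
#' @export
chisq_diff <- function(nested_fit, parent_fit) {
  if (nested_fit$fit$df < parent_fit$fit$df) {
    stop("models are not nested: the 'nested' fit has more free parameters")
  }
  if (!identical(lapply(nested_fit$specs, `[[`, "observed"),
                 lapply(parent_fit$specs, `[[`, "observed"))) {
    stop("models are not nested: observed variable sets differ")
  }
  dT <- nested_fit$fit$T - parent_fit$fit$T
  if (dT < -1e-6 * max(1, parent_fit$fit$T)) {
    warning("nested model fits better than parent (dT = ", format(dT),
            "); check convergence")
  }
  list(dT = max(dT, 0),
       ddf = nested_fit$fit$df - parent_fit$fit$df,
       dCFI = parent_fit$fit$CFI - nested_fit$fit$CFI,
       dRMSEA = nested_fit$fit$RMSEA - parent_fit$fit$RMSEA,
       dSRMR = nested_fit$fit$SRMR - parent_fit$fit$SRMR)
}
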