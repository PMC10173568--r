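# Latent difference score models: the parent-report factor is regressed on
# the self-report factor with a unit path and loads a second-order
# difference factor with a unit loading; the parent factor's own mean and
# disturbance are fixed to zero, so the difference factor carries the true
# parent-minus-self discrepancy, free of measurement error. Positive
# discrepancy means higher parent-reported ratings.

#' Build an (unconditional) LDS spec from an accepted invariance model
#'
#' Takes the accepted (partial-)scalar joint-dyad spec — the measurement
#' part, including any freed items, is carried over verbatim — and
#' reparameterizes the structural part: `eta_parent` mean fixed to 0,
#' regression `eta_parent ~ 1*eta_self + 1*delta`, `delta` with free mean
#' (`al_d`), variance (`phi_d`) and covariance with the self factor
#' (`psi_sd`); the parent factor's disturbance is fixed to 0.
#'
#' @param x An `invariance_report` with scalar-level invariance established
#'   (anything less is refused), or a joint-dyad `sem_spec` (trusted as
#'   accepted).
#' @return A `sem_spec` with latent variables
#'   `eta_self`, `eta_parent`, `delta`.
#' @export
build_lds_spec <- function(x) {
  if (inherits(x, "invariance_report")) {
    if (!isTRUE(x$scalar_established)) {
      stop("LDS models require (partial) scalar invariance; the ladder for '",
           x$construct, "' stopped at ", x$accepted)
    }
    if (x$mode != "joint-dyad") stop("LDS specs are built from joint-dyad invariance models")
    base <- x$accepted_spec
  } else if (inherits(x, "sem_spec")) {
    base <- x
  } else stop("x must be an invariance_report or sem_spec")
  if (!all(c("eta_self", "eta_parent") %in% base$latent)) {
    stop("spec must contain latent variables eta_self and eta_parent")
  }

  sp <- sem_spec(base$observed, c("eta_self", "eta_parent", "delta"))
  # measurement part carried over verbatim
  for (j in seq_along(base$observed)) {
    for (fcol in c("eta_self", "eta_parent")) {
      lab <- base$lambda$label[j, fcol]
      val <- base$lambda$value[j, fcol]
      if (!is.na(lab)) sp <- sp_free(sp, "lambda", j, fcol, lab, val)
      else if (val != 0) sp <- sp_fix(sp, "lambda", j, fcol, val)
    }
    lab <- base$nu$label[j, 1]
    if (!is.na(lab)) sp <- sp_free(sp, "nu", j, NULL, lab, base$nu$value[j, 1])
    else sp <- sp_fix(sp, "nu", j, NULL, base$nu$value[j, 1])
  }
  for (i in seq_along(base$observed)) for (j in i:length(base$observed)) {
    lab <- base$theta$label[i, j]
    if (!is.na(lab)) sp <- sp_free(sp, "theta", i, j, lab, base$theta$value[i, j])
    else if (base$theta$value[i, j] != 0) sp <- sp_fix(sp, "theta", i, j, base$theta$value[i, j])
  }
  # structural LDS part
  sp <- sp_fix(sp, "beta", "eta_parent", "eta_self", 1)
  sp <- sp_fix(sp, "beta", "eta_parent", "delta", 1)
  sp <- sp_free(sp, "psi", "eta_self", "eta_self", "psi_s")
  sp <- sp_free(sp, "psi", "delta", "delta", "phi_d", 0.1)
  sp <- sp_free(sp, "psi", "eta_self", "delta", "psi_sd", 0)
  sp <- sp_fix(sp, "psi", "eta_parent", "eta_parent", 0)
  sp <- sp_free(sp, "alpha", "eta_self", NULL, "al_s")
  sp <- sp_fix(sp, "alpha", "eta_parent", NULL, 0)
  sp <- sp_free(sp, "alpha", "delta", NULL, "al_d", 0)
  sp
}

#' Add a binary moderator to an LDS spec
#'
#' Regresses both the self-report factor and the discrepancy factor on an
#' exogenous binary covariate (carried as a pseudo-latent variable equal to
#' the observed column). The effect on the discrepancy is therefore net of
#' the covariate's effect on the self-report. One covariate per model;
#' moderators are analysed in separate models, never jointly.
#'
#' @param spec An unconditional LDS spec from [build_lds_spec()].
#' @param covariate Name of the binary 0/1 column (reference = 0; female,
#'   low distress and lower education are the reference categories).
#' @return The conditional `sem_spec`.
#' @export
build_conditional_lds <- function(spec, covariate) {
  if ("delta" %in% spec$latent == FALSE) stop("spec is not an LDS spec")
  if (covariate %in% spec$observed) stop("covariate already in the model")
  xl <- paste0(covariate, "_lat")
  sp <- sem_spec(c(spec$observed, covariate), c(spec$latent, xl))
  # copy everything from the LDS spec
  for (mn in c("lambda", "nu", "theta", "beta", "psi", "alpha")) {
    lab <- spec[[mn]]$label; val <- spec[[mn]]$value
    for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
      if (mn %in% c("theta", "psi") && j < i) next
      rn <- rownames(lab)[i]
      cn <- if (mn %in% c("nu", "alpha")) NULL else colnames(lab)[j]
      if (!is.na(lab[i, j])) sp <- sp_free(sp, mn, rn, cn, lab[i, j], val[i, j])
      else if (val[i, j] != 0) sp <- sp_fix(sp, mn, rn, cn, val[i, j])
    }
  }
  # pseudo-latent carrying the observed covariate
  sp <- sp_fix(sp, "lambda", covariate, xl, 1)
  sp <- sp_fix(sp, "theta", covariate, covariate, 0)
  sp <- sp_fix(sp, "nu", covariate, NULL, 0)
  sp <- sp_free(sp, "alpha", xl, NULL, "al_x")
  sp <- sp_free(sp, "psi", xl, xl, "psi_x", 0.25)
  sp <- sp_free(sp, "beta", "eta_self", xl, "b_self_x", 0)
  sp <- sp_free(sp, "beta", "delta", xl, "b_delta_x", 0)
  sp
}

# delta-method SE of h(theta) with gradient grad (named by parameters)
.delta_se <- function(grad, vcov) {
  nm <- names(grad)
  if (is.null(vcov) || !all(nm %in% rownames(vcov))) return(NA_real_)
  sqrt(max(drop(t(grad) %*% vcov[nm, nm] %*% grad), 0))
}

.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
}

#' Fit an unconditional LDS model
#'
#' @param data Dyad data.frame.
#' @param spec LDS spec from [build_lds_spec()].
#' @param weights Optional case weights (sandwich SEs are used when they are
#'   informative).
#' @param estimation `"moments"` (weighted ML, complete case) or `"fiml"`.
#' @param ... Passed to [fit_ml()].
#' @return An `lds_result`: `estimates` (raw and standardized discrepancy
#'   mean, variance, covariance with self, with SEs/p-values), `fit`
#'   (the underlying `sem_fit`), `n`.
#' @export
fit_lds <- function(data, spec, weights = NULL,
                    estimation = c("moments", "fiml"), ...) {
  estimation <- match.arg(estimation)
  fit <- fit_ml(spec, data, weights = weights, mode = estimation, ...)
  th <- fit$est; vc <- fit$vcov
  al_d <- unname(th["al_d"]); phi_d <- unname(th["phi_d"])
  psi_sd <- unname(th["psi_sd"]); psi_s <- unname(th["psi_s"])
  degenerate <- phi_d <= 2e-6
  if (degenerate) {
    warning("discrepancy variance at its lower bound; standardized mean suppressed")
  }
  sdd <- sqrt(phi_d); sds <- sqrt(psi_s)
  mean_std <- if (degenerate) NA_real_ else al_d / sdd
  cov_std <- if (degenerate) NA_real_ else psi_sd / (sdd * sds)
  g_mean <- c(al_d = 1 / sdd, phi_d = -al_d / (2 * phi_d^1.5))
  g_cov <- c(psi_sd = 1 / (sdd * sds),
             phi_d = -psi_sd / (2 * phi_d^1.5 * sds),
             psi_s = -psi_sd / (2 * sdd * psi_s^1.5))
  se_raw <- function(lab) if (!is.null(vc)) sqrt(max(vc[lab, lab], 0)) else NA_real_
  est <- data.frame(
    quantity = c("mean_raw", "mean_std", "variance", "covariance_raw",
                 "covariance_std", "self_variance"),
    value = unname(c(al_d, mean_std, phi_d, psi_sd, cov_std, psi_s)),
    se = c(se_raw("al_d"),
           if (degenerate) NA_real_ else .delta_se(g_mean, vc),
           se_raw("phi_d"), se_raw("psi_sd"),
           if (degenerate) NA_real_ else .delta_se(g_cov, vc),
           se_raw("psi_s")),
    stringsAsFactors = FALSE)
  est$z <- est$value / est$se
  est$pvalue <- 2 * stats::pnorm(-abs(est$z))
  est$stars <- .stars(est$pvalue)
  structure(list(estimates = est, fit = fit, n = fit$n,
                 degenerate = degenerate), class = "lds_result")
}

#' Fit a conditional LDS model and extract per-level estimates
#'
#' @param data Dyad data.frame containing the covariate column.
#' @param spec Conditional spec from [build_conditional_lds()].
#' @param covariate Covariate column name.
#' @param weights,estimation,... As [fit_lds()].
#' @return A `conditional_lds_result`: `main_effects` (standardized effects
#'   of the covariate on the self and discrepancy factors), `group_estimates`
#'   (per-level standardized discrepancy with delta-method 95% CIs),
#'   `predicted_means` (per-level factor means for both reporters), `fit`.
#' @export
fit_conditional_lds <- function(data, spec, covariate, weights = NULL,
                                estimation = c("moments", "fiml"), ...) {
  estimation <- match.arg(estimation)
  xv <- data[[covariate]]
  if (!all(stats::na.omit(xv) %in% c(0, 1))) stop("moderators must be binary 0/1")
  fit <- fit_ml(spec, data, weights = weights, mode = estimation, ...)
  res <- conditional_group_estimates(fit, covariate)
  res$fit <- fit
  res
}

#' Per-level standardized discrepancy estimates with 95% CIs
#'
#' The reference level's standardized discrepancy is `al_d / sqrt(phi_d)`;
#' the other level's is `(al_d + b_delta_x) / sqrt(phi_d)`, where `phi_d` is
#' the discrepancy disturbance variance — the model-implied discrepancy SD
#' at the reference level. CIs by the delta method on the full nonlinear
#' combination (including the square-root denominator). Effects are
#' standardized by the respective factor's reference-level (disturbance) SD.
#'
#' @param fit A converged conditional LDS `sem_fit`.
#' @param covariate Covariate name (labelling only).
#' @return A `conditional_lds_result` (without `$fit`).
#' @export
conditional_group_estimates <- function(fit, covariate) {
  th <- fit$est; vc <- fit$vcov
  al_d <- unname(th["al_d"]); b_d <- unname(th["b_delta_x"]); phi_d <- unname(th["phi_d"])
  al_s <- unname(th["al_s"]); b_s <- unname(th["b_self_x"]); psi_s <- unname(th["psi_s"])
  sdd <- sqrt(phi_d); sds <- sqrt(psi_s)

  main <- data.frame(
    factor = c("self", "discrepancy"),
    beta_raw = unname(c(b_s, b_d)),
    beta_std = unname(c(b_s / sds, b_d / sdd)),
    se_raw = c(if (!is.null(vc)) sqrt(vc["b_self_x", "b_self_x"]) else NA,
               if (!is.null(vc)) sqrt(vc["b_delta_x", "b_delta_x"]) else NA),
    se_std = c(.delta_se(c(b_self_x = 1 / sds,
                           psi_s = -b_s / (2 * psi_s^1.5)), vc),
               .delta_se(c(b_delta_x = 1 / sdd,
                           phi_d = -b_d / (2 * phi_d^1.5)), vc)),
    stringsAsFactors = FALSE)
  main$z <- main$beta_raw / main$se_raw
  main$pvalue <- 2 * stats::pnorm(-abs(main$z))
  main$stars <- .stars(main$pvalue)

  lv <- function(level) {
    num <- al_d + level * b_d
    est <- num / sdd
    g <- c(al_d = 1 / sdd, b_delta_x = level / sdd,
           phi_d = -num / (2 * phi_d^1.5))
    sev <- .delta_se(g, vc)
    c(est = unname(est), se = sev,
      lo = unname(est - 1.96 * sev), hi = unname(est + 1.96 * sev))
  }
  ge <- rbind(reference = lv(0), other = lv(1))
  ge <- data.frame(level = c("reference", "other"), ge, row.names = NULL)

  pm <- data.frame(
    level = c("reference", "other"),
    self_mean = unname(c(al_s, al_s + b_s)),
    parent_mean = unname(c(al_s + al_d, al_s + b_s + al_d + b_d)),
    stringsAsFactors = FALSE)

  structure(list(covariate = covariate, main_effects = main,
                 group_estimates = ge, predicted_means = pm),
            class = "conditional_lds_result")
}

#' @export
print.lds_result <- function(x, ...) {
  cat("LDS model (n =", x$n, ")\n")
  e <- x$estimates
  e$value <- round(e$value, 4); e$se <- round(e$se, 4)
  print(e[, c("quantity", "value", "se", "stars")], row.names = FALSE)
  cat(sprintf("fit: CFI = %.3f RMSEA = %.3f SRMR = %.3f\n",
              x$fit$fit$CFI, x$fit$fit$RMSEA, x$fit$fit$SRMR))
  invisible(x)
}

#' @export
print.conditional_lds_result <- function(x, ...) {
  cat("Conditional LDS:", x$covariate, "\n")
  print(x$main_effects[, c("factor", "beta_std", "se_std", "stars")], row.names = FALSE)
  print(x$group_estimates, row.names = FALSE)
  invisible(x)
}
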