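# Shared fixture builders. Everything is generated in code at test time;
# sample sizes are scaled to keep the default run inside its time budget
# (noted per test where a larger canonical size exists).

zero_betas <- c(sex = 0, distress = 0, edu = 0)

# generator config with no covariate effects, no non-invariance and no
# missingness: the clean recovery world
clean_config <- function(construct = "conduct", n = 2000, seed = 1,
                         alpha_std = NULL, ...) {
  cc <- construct_config(construct, beta_self = zero_betas,
                         beta_delta = zero_betas, ...)
  if (!is.null(alpha_std)) cc$alpha_delta <- alpha_std * cc$phi_delta_sd
  cfgs <- stats::setNames(list(cc), construct)
  generator_config(n_dyads = n, seed = seed, constructs = construct,
                   construct_configs = cfgs, noninvariance = NULL,
                   missingness = list(intercept = 20, coef = zero_betas,
                                      item_mcar = 0),
                   svywt_log_sd = 0)
}

# a small one-factor spec: 3-5 indicators, marker identification
one_factor_spec <- function(p = 3, names_ = paste0("y", seq_len(p))) {
  sp <- sem_spec(names_, "f")
  sp <- sp_fix(sp, "lambda", 1, 1, 1)
  sp <- sp_fix(sp, "nu", 1, NULL, 0)
  for (i in seq_len(p)) {
    if (i > 1) {
      sp <- sp_free(sp, "lambda", i, 1, paste0("l", i))
      sp <- sp_free(sp, "nu", i, NULL, paste0("n", i))
    }
    sp <- sp_free(sp, "theta", i, i, paste0("t", i))
  }
  sp <- sp_free(sp, "psi", 1, 1, "psi")
  sp <- sp_free(sp, "alpha", 1, NULL, "a")
  sp
}

# draw data from a one-factor model
one_factor_data <- function(n, lambda, nu, theta_sd, psi_sd = 1, alpha = 0) {
  f <- stats::rnorm(n, alpha, psi_sd)
  Y <- vapply(seq_along(lambda), function(j) {
    nu[j] + lambda[j] * f + stats::rnorm(n, 0, theta_sd[j])
  }, numeric(n))
  colnames(Y) <- paste0("y", seq_along(lambda))
  Y
}
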