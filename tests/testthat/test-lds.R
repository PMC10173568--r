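# LDS models: reparameterization identity, sign and standardization
# contracts, conditional effects, degenerate inputs.

test_that("LDS spec construction enforces its preconditions and parameter count", {
  expect_error(build_lds_spec(42), "invariance_report or sem_spec")
  sp_cfa <- build_invariance_spec("conduct", "scalar")
  sp_lds <- build_lds_spec(sp_cfa)
  # reparameterization adds no free parameters beyond the CFA's factor moments
  expect_equal(length(dyadlds:::spec_labels(sp_lds)),
               length(dyadlds:::spec_labels(sp_cfa)))
  # fixed unit paths and zero parent disturbance
  expect_equal(sp_lds$beta$value["eta_parent", "eta_self"], 1)
  expect_equal(sp_lds$beta$value["eta_parent", "delta"], 1)
  expect_equal(sp_lds$psi$value["eta_parent", "eta_parent"], 0)
  expect_equal(sp_lds$alpha$value["eta_parent", 1], 0)
  # implied parent-factor mean is self mean + discrepancy mean
  im <- implied_moments(sp_lds, c(l2 = 0.9, l3 = 0.7, l4 = 0.8, l5 = 0.7,
                                  nu2 = 0.6, nu3 = 0.2, nu4 = 0.2, nu5 = 0.1,
                                  th_s1 = 0.2, th_s2 = 0.2, th_s3 = 0.2,
                                  th_s4 = 0.2, th_s5 = 0.2,
                                  th_p1 = 0.2, th_p2 = 0.2, th_p3 = 0.2,
                                  th_p4 = 0.2, th_p5 = 0.2,
                                  psi_s = 0.2, phi_d = 0.1, psi_sd = -0.05,
                                  al_s = 0.5, al_d = -0.3))
  expect_equal(unname(im$mu[6]), 0.5 - 0.3)  # parent marker mean
})

test_that("LDS and the free-means CFA are the same model (reparameterization)", {
  cfg <- clean_config(n = 1500, seed = 71)
  d <- generate_dyads(cfg)$data
  cfa <- fit_ml(build_invariance_spec("conduct", "scalar"), d, se = "none")
  lds <- fit_lds(d, build_lds_spec(build_invariance_spec("conduct", "scalar")),
                 se = "none")
  expect_equal(lds$fit$fit$loglik, cfa$fit$loglik, tolerance = 1e-6)
  expect_equal(unname(lds$fit$est["al_d"]),
               unname(cfa$est["al_p"] - cfa$est["al_s"]), tolerance = 1e-6)
  expect_equal(unname(lds$fit$est["phi_d"]),
               unname(cfa$est["psi_s"] + cfa$est["psi_p"] - 2 * cfa$est["psi_sp"]),
               tolerance = 1e-5)
})

test_that("sign contract: parents rating lower gives a negative discrepancy mean", {
  cfg <- clean_config(n = 2000, seed = 72, alpha_std = -0.9)
  d <- generate_dyads(cfg)$data
  r <- fit_lds(d, build_lds_spec(build_invariance_spec("conduct", "scalar")),
               se = "none")
  expect_lt(r$estimates$value[r$estimates$quantity == "mean_raw"], 0)
  # and the reverse world flips the sign
  cfg2 <- clean_config(n = 2000, seed = 72, alpha_std = +0.9)
  d2 <- generate_dyads(cfg2)$data
  r2 <- fit_lds(d2, build_lds_spec(build_invariance_spec("conduct", "scalar")),
                se = "none")
  expect_gt(r2$estimates$value[r2$estimates$quantity == "mean_raw"], 0)
})

test_that("standardization is internally consistent and SEs propagate", {
  cfg <- clean_config(n = 2500, seed = 73)
  d <- generate_dyads(cfg)$data
  r <- fit_lds(d, build_lds_spec(build_invariance_spec("conduct", "scalar")))
  e <- r$estimates
  gv <- function(q, col = "value") e[[col]][e$quantity == q]
  expect_equal(gv("mean_std") * sqrt(gv("variance")), gv("mean_raw"),
               tolerance = 1e-8)
  expect_equal(gv("covariance_std") * sqrt(gv("variance") * gv("self_variance")),
               gv("covariance_raw"), tolerance = 1e-8)
  expect_true(all(is.finite(e$se)))
  expect_true(abs(gv("covariance_std")) <= 1)
  expect_equal(e$stars[e$quantity == "mean_raw"], "***")
})

test_that("identical parent and self reports flag a degenerate discrepancy", {
  cc <- construct_config("conduct", beta_self = zero_betas,
                         beta_delta = zero_betas, alpha_delta = 0,
                         phi_delta_sd = 0, sigma_sdelta = 0)
  cfg <- generator_config(n_dyads = 800, seed = 74, constructs = "conduct",
                          construct_configs = list(conduct = cc),
                          noninvariance = NULL,
                          missingness = list(intercept = 20, coef = zero_betas,
                                             item_mcar = 0))
  d <- generate_dyads(cfg)$data
  # parent items literally copied from self items
  for (j in 1:5) d[[item_cols("conduct", "parent")[j]]] <- d[[item_cols("conduct", "self")[j]]]
  expect_warning(
    r <- fit_lds(d, build_lds_spec(build_invariance_spec("conduct", "scalar")),
                 se = "none"),
    "lower bound|Heywood")
  expect_true(r$degenerate)
  expect_true(is.na(r$estimates$value[r$estimates$quantity == "mean_std"]))
})

test_that("conditional LDS recovers group contrasts and the per-level identity", {
  cc <- construct_config("conduct",
                         beta_self = c(sex = 0.3, distress = 0, edu = 0),
                         beta_delta = c(sex = -0.15, distress = 0, edu = 0))
  cfg <- generator_config(n_dyads = 4000, seed = 75, constructs = "conduct",
                          construct_configs = list(conduct = cc),
                          noninvariance = NULL,
                          missingness = list(intercept = 20, coef = zero_betas,
                                             item_mcar = 0))
  d <- generate_dyads(cfg)$data
  sp <- build_conditional_lds(build_lds_spec(build_invariance_spec("conduct", "scalar")),
                              "sex")
  r <- fit_conditional_lds(d, sp, "sex")
  me <- r$main_effects
  b_s <- me$beta_raw[me$factor == "self"]
  b_d <- me$beta_raw[me$factor == "discrepancy"]
  expect_lt(abs(b_s - 0.3), 3 * me$se_raw[me$factor == "self"] + 0.02)
  expect_lt(abs(b_d - (-0.15)), 3 * me$se_raw[me$factor == "discrepancy"] + 0.02)
  # per-level standardized estimates differ by exactly the raw effect / sd
  ge <- r$group_estimates
  phi <- unname(r$fit$est["phi_d"])
  expect_equal((ge$est[2] - ge$est[1]) * sqrt(phi), b_d, tolerance = 1e-8)
  expect_error(fit_conditional_lds(transform(d, sex = sex + 1), sp, "sex"),
               "binary")
})

test_that("per-level arithmetic matches the worked example", {
  # raw intercept -0.2, effect -0.1, variance 0.09 -> -0.667 and -1.0
  fake <- list(est = c(al_d = -0.2, b_delta_x = -0.1, phi_d = 0.09,
                       al_s = 0.5, b_self_x = 0.2, psi_s = 0.25),
               vcov = NULL)
  ge <- conditional_group_estimates(fake, "x")$group_estimates
  expect_equal(ge$est, c(-0.2 / 0.3, -0.3 / 0.3), tolerance = 1e-12)
  pm <- conditional_group_estimates(fake, "x")$predicted_means
  expect_equal(pm$self_mean, c(0.5, 0.7))
  expect_equal(pm$parent_mean, c(0.3, 0.4))
})

test_that("a null moderator effect gives matching levels and CIs", {
  cfg <- clean_config(n = 2500, seed = 76)
  d <- generate_dyads(cfg)$data
  sp <- build_conditional_lds(build_lds_spec(build_invariance_spec("conduct", "scalar")),
                              "edu")
  r <- fit_conditional_lds(d, sp, "edu")
  ge <- r$group_estimates
  # the effect is 0 in truth: levels agree within sampling error
  b_se <- r$main_effects$se_raw[r$main_effects$factor == "discrepancy"]
  expect_lt(abs(unname(r$fit$est["b_delta_x"])), 3 * b_se)
  expect_lt(abs(ge$est[1] - ge$est[2]), 0.3)
})

test_that("delta-method CIs agree with a parametric bootstrap", {
  cfg <- clean_config(n = 2500, seed = 77)
  d <- generate_dyads(cfg)$data
  sp <- build_conditional_lds(build_lds_spec(build_invariance_spec("conduct", "scalar")),
                              "sex")
  r <- fit_conditional_lds(d, sp, "sex")
  ge <- r$group_estimates
  # draw parameters from the estimator's asymptotic normal and recompute the
  # nonlinear combination (2000 draws)
  th <- r$fit$est; vc <- r$fit$vcov
  nm <- c("al_d", "b_delta_x", "phi_d")
  set.seed(771)
  L <- chol(vc[nm, nm])
  draws <- matrix(stats::rnorm(2000 * 3), 2000) %*% L
  draws <- sweep(draws, 2, th[nm], "+")
  draws <- draws[draws[, 3] > 0, ]
  boot_ref <- draws[, 1] / sqrt(draws[, 3])
  boot_oth <- (draws[, 1] + draws[, 2]) / sqrt(draws[, 3])
  bq <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  ci_ref <- bq(boot_ref); ci_oth <- bq(boot_oth)
  width <- function(ci) ci[2] - ci[1]
  expect_lt(abs(ge$lo[1] - ci_ref[1]), 0.1 * width(ci_ref))
  expect_lt(abs(ge$hi[1] - ci_ref[2]), 0.1 * width(ci_ref))
  expect_lt(abs(ge$lo[2] - ci_oth[1]), 0.1 * width(ci_oth))
  expect_lt(abs(ge$hi[2] - ci_oth[2]), 0.1 * width(ci_oth))
})

test_that("the estimator is centered on the pseudo-true projection (coarsening)", {
  # Ordinal items analysed as continuous make the LDS a projection: the
  # estimand is the pseudo-true parameter, not the generating latent value.
  # Pseudo-true standardized mean computed once at n = 400k (seed 99) with
  # the same construct defaults: conduct -0.846 (generating -0.898).
  reps <- 20
  ests <- numeric(reps)
  sp <- build_lds_spec(build_invariance_spec("conduct", "scalar"))
  for (r in seq_len(reps)) {
    cfg <- clean_config(n = 6700, seed = 7800 + r)
    d <- generate_dyads(cfg)$data
    fit <- fit_lds(d, sp, se = "none")
    ests[r] <- fit$estimates$value[fit$estimates$quantity == "mean_std"]
  }
  mcse <- sqrt(stats::var(ests) / reps + 0.004^2)  # + oracle MC error
  expect_lt(abs(mean(ests) - (-0.846)), 3 * mcse)
  # and visibly biased for the generating value: the deliberate measurement
  # mismatch, quantified
  expect_gt(abs(mean(ests) - (-0.898)), 3 * mcse)
})
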