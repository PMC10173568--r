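# Generator: determinism, degenerate cases, moment convergence, covariate
# and missingness mechanics, moment calibration.

test_that("identical seeds give byte-identical CSVs; different seeds differ", {
  cfg <- clean_config(n = 200, seed = 11)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dyads(generate_dyads(cfg)$data, f1)
  write_dyads(generate_dyads(cfg)$data, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- clean_config(n = 200, seed = 12)
  f3 <- tempfile(fileext = ".csv")
  write_dyads(generate_dyads(cfg2)$data, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("zero discrepancy and identical measurement make reports identical", {
  cc <- construct_config("conduct", beta_self = zero_betas,
                         beta_delta = zero_betas,
                         alpha_delta = 0, phi_delta_sd = 0, sigma_sdelta = 0,
                         theta_self = rep(0, 5), theta_parent = rep(0, 5))
  cfg <- generator_config(n_dyads = 300, seed = 3, constructs = "conduct",
                          construct_configs = list(conduct = cc),
                          noninvariance = NULL,
                          missingness = list(intercept = 20, coef = zero_betas,
                                             item_mcar = 0))
  d <- generate_dyads(cfg)$data
  for (j in 1:5) {
    expect_identical(d[[paste0("conduct_self_i", j)]],
                     d[[paste0("conduct_parent_i", j)]])
  }
})

test_that("latent truth obeys eta_parent = eta_self + delta and the LLN", {
  cfg <- clean_config(n = 5000, seed = 7, alpha_std = -0.5)
  g <- generate_dyads(cfg)
  lat <- g$truth$latents$conduct
  expect_equal(lat$eta_parent, lat$eta_self + lat$delta)
  cc <- cfg$construct_configs$conduct
  target <- -0.5 * cc$phi_delta_sd
  mcse <- cc$phi_delta_sd / sqrt(5000)
  expect_lt(abs(mean(lat$delta) - target), 3 * mcse)
  # empirical latent covariance converges to the configured one
  emp <- stats::cov(cbind(lat$eta_self, lat$delta))
  expect_lt(abs(emp[1, 2] - cc$sigma_sdelta), 3 * 0.01)
  expect_lt(abs(emp[1, 1] - cc$psi_self_sd^2), 3 * 0.01)
})

test_that("an intercept offset moves only the targeted item's mean", {
  n <- 20000
  base <- clean_config(n = n, seed = 21)
  off <- base
  off$noninvariance <- data.frame(construct = "conduct", reporter = "parent",
                                  pos = 2L, parameter = "intercept", offset = 0.6)
  d0 <- generate_dyads(base)$data
  d1 <- generate_dyads(off)$data   # same seed: same latents and errors
  m0 <- vapply(1:5, function(j) mean(d0[[paste0("conduct_parent_i", j)]]), 0)
  m1 <- vapply(1:5, function(j) mean(d1[[paste0("conduct_parent_i", j)]]), 0)
  expect_gt(m1[2] - m0[2], 0.1)
  expect_equal(m1[-2], m0[-2], tolerance = 1e-12)  # same draws elsewhere
  s0 <- vapply(1:5, function(j) mean(d0[[paste0("conduct_self_i", j)]]), 0)
  s1 <- vapply(1:5, function(j) mean(d1[[paste0("conduct_self_i", j)]]), 0)
  expect_equal(s1, s0, tolerance = 1e-12)
})

test_that("ordinal item means are monotone in the intercept", {
  for (nu1 in c(0.2, 0.6, 1.0, 1.4)) {
    cc <- construct_config("conduct", beta_self = zero_betas, beta_delta = zero_betas)
    cc$nu$self[1] <- nu1
    cfg <- generator_config(n_dyads = 5000, seed = 9, constructs = "conduct",
                            construct_configs = list(conduct = cc),
                            noninvariance = NULL,
                            missingness = list(intercept = 20, coef = zero_betas,
                                               item_mcar = 0))
    m <- mean(generate_dyads(cfg)$data$conduct_self_i1)
    if (nu1 > 0.2) expect_gt(m, last_m)
    last_m <- m
  }
})

test_that("impose_missingness hits its targets and respects covariates", {
  # no missingness when p = 1 and MCAR rate 0
  cfg <- clean_config(n = 500, seed = 13)
  d <- generate_dyads(cfg)$data
  expect_true(all(d$complete == 1))
  expect_false(anyNA(d[, item_cols("conduct", "self")]))
  # marginal completeness ~ 67% via a pure-intercept model
  n <- 5000
  cfg2 <- clean_config(n = n, seed = 14)
  cfg2$missingness <- list(intercept = stats::qlogis(0.67),
                           coef = zero_betas, item_mcar = 0)
  d2 <- generate_dyads(cfg2)$data
  expect_lt(abs(mean(d2$complete) - 0.67), 2 * sqrt(0.67 * 0.33 / n))
  # negative education effect: high-education dyads less complete
  cfg3 <- clean_config(n = 20000, seed = 15)
  cfg3$missingness <- list(intercept = 0.5,
                           coef = c(sex = 0, distress = 0, edu = -1),
                           item_mcar = 0)
  d3 <- generate_dyads(cfg3)$data
  expect_lt(mean(d3$complete[d3$edu == 1]), mean(d3$complete[d3$edu == 0]))
  # item MCAR applies only to complete cases, at about the stated rate
  cfg4 <- clean_config(n = 4000, seed = 16)
  cfg4$missingness <- list(intercept = 0.6, coef = zero_betas, item_mcar = 0.1)
  d4 <- generate_dyads(cfg4)$data
  icols <- c(item_cols("conduct", "self"), item_cols("conduct", "parent"))
  r_inc <- as.matrix(d4[d4$complete == 0, icols])
  expect_true(all(is.na(r_inc)))
  rate <- mean(is.na(as.matrix(d4[d4$complete == 1, icols])))
  expect_lt(abs(rate - 0.1), 0.01)
  cfg_bad <- cfg4
  cfg_bad$missingness$item_mcar <- 2
  expect_error(impose_missingness(d4, cfg_bad), "item_mcar")
})

test_that("covariate effects shift the latent means of the affected groups", {
  cc <- construct_config("conduct",
                         beta_self = c(sex = 0.4, distress = 0, edu = 0),
                         beta_delta = c(sex = -0.2, distress = 0, edu = 0))
  cfg <- generator_config(n_dyads = 20000, seed = 17, constructs = "conduct",
                          construct_configs = list(conduct = cc),
                          noninvariance = NULL,
                          missingness = list(intercept = 20, coef = zero_betas,
                                             item_mcar = 0))
  g <- generate_dyads(cfg)
  lat <- g$truth$latents$conduct
  sx <- g$truth$covariates$sex
  expect_lt(abs((mean(lat$eta_self[sx == 1]) - mean(lat$eta_self[sx == 0])) - 0.4), 0.05)
  expect_lt(abs((mean(lat$delta[sx == 1]) - mean(lat$delta[sx == 0])) - (-0.2)), 0.05)
  # centering: marginal delta mean still matches the configured alpha
  expect_lt(abs(mean(lat$delta) - cc$alpha_delta), 3 * 0.35 / sqrt(20000) + 0.01)
})

test_that("calibrate_to_moments reproduces printed item moments within 0.05", {
  # canonical check is n = 50000; the tolerance is on population moments so
  # the sample size only adds MC noise
  targets <- data.frame(
    construct = c("conduct", "emotion"), reporter = c("parent", "self"),
    pos = c(1, 2), mean = c(0.40, 1.07), sd = c(0.63, 0.77))
  cfg <- calibrate_to_moments(targets)
  ach <- attr(cfg, "achieved")
  expect_true(all(abs(ach$mean_achieved - ach$mean) < 0.05))
  expect_true(all(abs(ach$sd_achieved - ach$sd) < 0.05))
  cfg$n_dyads <- 50000L; cfg$seed <- 18L
  cfg$missingness <- list(intercept = 20, coef = zero_betas, item_mcar = 0)
  d <- generate_dyads(cfg)$data
  expect_lt(abs(mean(d$conduct_parent_i1) - 0.40), 0.05)
  expect_lt(abs(stats::sd(d$conduct_parent_i1) - 0.63), 0.05)
  expect_lt(abs(mean(d$emotion_self_i2) - 1.07), 0.05)
  expect_lt(abs(stats::sd(d$emotion_self_i2) - 0.77), 0.05)
})

test_that("calibration handles degenerate and infeasible targets", {
  deg <- data.frame(construct = "conduct", reporter = "self", pos = 3,
                    mean = 1.0, sd = 0)
  cfg <- calibrate_to_moments(deg)
  cc <- cfg$construct_configs$conduct
  expect_lt(cc$theta$self[3], 1e-6)   # all mass at category 1
  bad <- data.frame(construct = "conduct", reporter = "self", pos = 3,
                    mean = 0.1, sd = 1.5)
  expect_error(calibrate_to_moments(bad), "infeasible")
})

test_that("the default world matches its stated rates", {
  cfg <- generator_config(n_dyads = 8000, seed = 19, constructs = "conduct")
  g <- generate_dyads(cfg)
  d <- g$data
  expect_lt(abs(mean(g$truth$covariates$distress) - 0.346), 0.02)
  expect_lt(abs(mean(d$complete) - 0.646), 0.02)
  expect_lt(abs(mean(d$sex) - 0.507), 0.02)
  expect_lt(abs(mean(d$edu) - 0.563), 0.02)
  expect_equal(mean(d$svywt), 1, tolerance = 1e-9)
})
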