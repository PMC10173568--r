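# SEM engine: implied moments, discrepancy, estimation identities, fit
# indices, difference tests, modification indices.

test_that("implied moments match hand algebra", {
  sp <- sem_spec(paste0("y", 1:3), "f")
  for (i in 1:3) {
    sp <- sp_fix(sp, "lambda", i, 1, 1)
    sp <- sp_free(sp, "theta", i, i, paste0("t", i), 1)
  }
  sp <- sp_free(sp, "psi", 1, 1, "psi", 1)
  im <- implied_moments(sp)
  expect_equal(im$Sigma, matrix(1, 3, 3) + diag(3), ignore_attr = TRUE)
  expect_equal(im$mu, rep(0, 3), ignore_attr = TRUE)
  # B = 0 reduces to Lambda Psi Lambda' + Theta with arbitrary loadings
  sp2 <- one_factor_spec(4)
  th <- c(l2 = 0.8, l3 = 1.2, l4 = 0.5, n2 = 0.1, n3 = -0.2, n4 = 0.3,
          t1 = 0.5, t2 = 0.4, t3 = 0.6, t4 = 0.3, psi = 0.9, a = 0.25)
  im2 <- implied_moments(sp2, th)
  lam <- c(1, 0.8, 1.2, 0.5)
  expect_equal(im2$Sigma, 0.9 * outer(lam, lam) + diag(c(0.5, 0.4, 0.6, 0.3)),
               ignore_attr = TRUE)
  expect_equal(im2$mu, c(0, 0.1, -0.2, 0.3) + lam * 0.25, ignore_attr = TRUE)
})

test_that("a cyclic latent regression is rejected", {
  sp <- sem_spec(paste0("y", 1:4), c("f1", "f2"))
  sp <- sp_fix(sp, "beta", "f1", "f2", 1)
  sp <- sp_fix(sp, "beta", "f2", "f1", 1)
  expect_error(implied_moments(sp), "cyclic")
})

test_that("fml_discrepancy has its closed-form values", {
  S <- diag(2); m <- c(0, 0)
  expect_equal(fml_discrepancy(S, m, S, m), 0)
  # p = 1: S = 2, Sigma = 1 -> 1 - log 2
  expect_equal(fml_discrepancy(matrix(2), 0, matrix(1), 0), 1 - log(2))
  # mean-only misfit with Sigma = I adds exactly the squared distance
  S3 <- diag(3)
  expect_equal(fml_discrepancy(S3, c(1, 0, 0), S3, c(0, 0, 0)), 1)
  expect_error(fml_discrepancy(matrix(-1), 0, matrix(1), 0), "positive definite")
})

test_that("analytic and numerical gradients agree at random admissible points", {
  set.seed(51)
  sp <- build_lds_spec(build_invariance_spec("conduct", "scalar"))
  cspec <- dyadlds:::compile_spec(sp)
  cfg <- clean_config(n = 300, seed = 51)
  Y <- as.matrix(generate_dyads(cfg)$data[, sp$observed])
  mom <- dyadlds:::weighted_moments(Y)
  mom$logdetS <- as.numeric(determinant(mom$S)$modulus)
  gm <- list(mom)
  for (rep_i in 1:3) {
    th <- dyadlds:::.auto_starts(cspec, gm)
    th <- th * stats::runif(length(th), 0.9, 1.1) + stats::rnorm(length(th), 0, 0.02)
    th <- pmax(th, cspec$lower + 0.01)
    o <- dyadlds:::.obj_moments(th, cspec, gm)
    ng <- vapply(seq_along(th), function(j) {
      h <- 1e-6 * max(1, abs(th[j]))
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      (dyadlds:::.obj_moments(tp, cspec, gm)$value -
         dyadlds:::.obj_moments(tm, cspec, gm)$value) / (2 * h)
    }, 0)
    expect_lt(max(abs(o$grad - ng)) / max(1, max(abs(ng))), 1e-5)
  }
})

test_that("the saturated model recovers the weighted sample moments", {
  set.seed(52)
  Y <- one_factor_data(300, c(1, 0.8, 1.2), c(0, 0.2, -0.1), rep(0.6, 3),
                       alpha = 0.4)
  w <- stats::runif(300, 0.5, 2)
  p <- 3
  sp <- sem_spec(colnames(Y), paste0("g", 1:p))
  for (i in 1:p) {
    sp <- sp_fix(sp, "lambda", i, i, 1)
    sp <- sp_free(sp, "alpha", i, NULL, paste0("a", i))
    for (j in i:p) sp <- sp_free(sp, "psi", i, j, paste0("v", i, j))
  }
  fit <- fit_ml(sp, Y, weights = w, se = "none")
  mom <- dyadlds:::weighted_moments(Y, w / mean(w))
  expect_equal(fit$fit$T, 0, tolerance = 1e-6)
  expect_equal(fit$implied[[1]]$Sigma, mom$S, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$implied[[1]]$mu, mom$mbar, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("reordering observed variables leaves estimates and indices unchanged", {
  set.seed(53)
  Y <- one_factor_data(400, c(1, 0.8, 1.2, 0.6), c(0, 0.2, -0.1, 0.4),
                       rep(0.6, 4), alpha = 0.3)
  sp <- one_factor_spec(4)
  fit1 <- fit_ml(sp, Y, se = "none")
  perm <- c(3, 1, 4, 2)
  sp2 <- sem_spec(colnames(Y)[perm], "f")
  for (i in 1:4) {
    nm <- colnames(Y)[i]
    if (i == 1) {
      sp2 <- sp_fix(sp2, "lambda", nm, "f", 1)
      sp2 <- sp_fix(sp2, "nu", nm, NULL, 0)
    } else {
      sp2 <- sp_free(sp2, "lambda", nm, "f", paste0("l", i))
      sp2 <- sp_free(sp2, "nu", nm, NULL, paste0("n", i))
    }
    sp2 <- sp_free(sp2, "theta", nm, nm, paste0("t", i))
  }
  sp2 <- sp_free(sp2, "psi", 1, 1, "psi")
  sp2 <- sp_free(sp2, "alpha", 1, NULL, "a")
  fit2 <- fit_ml(sp2, Y[, perm], se = "none")
  expect_equal(fit1$est[names(fit2$est)], fit2$est, tolerance = 1e-6)
  expect_equal(fit1$fit$T, fit2$fit$T, tolerance = 1e-6)
  expect_equal(fit1$fit$SRMR, fit2$fit$SRMR, tolerance = 1e-8)
})

test_that("fit_indices implements its definitions", {
  expect_equal(fit_indices(5, 10, 200, 20, 500)$CFI, 1)
  expect_equal(fit_indices(5, 10, 200, 20, 500)$RMSEA, 0)
  fi <- fit_indices(20, 10, 200, 20, 1000)
  expect_equal(fi$RMSEA, sqrt(10 / 10000))
  # T0 - df0 = 100, T - df = 25 -> CFI = 0.75
  expect_equal(fit_indices(35, 10, 120, 20, 1000)$CFI, 0.75)
  sat <- fit_indices(0, 0, 100, 10, 500)
  expect_equal(sat$RMSEA, 0, ignore_attr = TRUE)
  expect_true(isTRUE(attr(sat$RMSEA, "saturated")))
  expect_error(fit_indices(10, 30, 100, 20, 500), "df0")
})

test_that("srmr matches hand arithmetic and is scale invariant", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(srmr(S, S), 0)
  Sig <- matrix(c(1, 0.4, 0.4, 1), 2)   # correlation residual 0.1 off-diagonal
  expect_equal(srmr(S, Sig), sqrt(0.01 / 3))
  D <- diag(c(10, 1))
  expect_equal(srmr(D %*% S %*% D, D %*% Sig %*% D), srmr(S, Sig))
})

test_that("chisq_diff subtracts and refuses non-nested fits", {
  set.seed(54)
  cfg <- clean_config(n = 500, seed = 54)
  d <- generate_dyads(cfg)$data
  conf <- fit_ml(build_invariance_spec("conduct", "configural"), d, se = "none")
  scal <- fit_ml(build_invariance_spec("conduct", "scalar"), d, se = "none")
  dd <- chisq_diff(scal, conf)
  expect_equal(dd$dT, scal$fit$T - conf$fit$T, tolerance = 1e-10)
  expect_equal(dd$ddf, 8)
  expect_equal(dd$dCFI, conf$fit$CFI - scal$fit$CFI)
  expect_equal(dd$dRMSEA, scal$fit$RMSEA - conf$fit$RMSEA)
  same <- chisq_diff(conf, conf)
  expect_equal(same$dT, 0)
  expect_equal(same$dCFI, 0)
  expect_error(chisq_diff(conf, scal), "not nested")
})

test_that("the difference statistic is chi-square distributed under the null", {
  # one-factor model, constrain l3 = l2: 1 df; canonical check uses 500
  # replications, reduced here for run time
  set.seed(55)
  reps <- 120
  dT <- numeric(reps)
  lam <- c(1, 0.8, 0.8, 0.6)
  spF <- one_factor_spec(4)
  spC <- spF
  spC <- sp_free(spC, "lambda", 3, 1, "l2")  # same label as item 2
  for (r in seq_len(reps)) {
    Y <- one_factor_data(400, lam, c(0, 0.1, 0.2, 0.3), rep(0.6, 4))
    f1 <- fit_ml(spF, Y, se = "none")
    f0 <- fit_ml(spC, Y, se = "none")
    dT[r] <- chisq_diff(f0, f1)$dT
  }
  expect_equal(mean(dT), 1, tolerance = 3 * sqrt(2 / reps))
  expect_gt(mean(dT > stats::qchisq(0.95, 1)), 0.01)
  expect_lt(mean(dT > stats::qchisq(0.95, 1)), 0.12)
})

test_that("modification indices: free candidates score zero, constrained ones predict the refit", {
  set.seed(56)
  # data with one cross-group unequal intercept, scalar-constrained fit
  cfg <- clean_config(n = 1500, seed = 56)
  cfg$noninvariance <- data.frame(construct = "conduct", reporter = "parent",
                                  pos = 3L, parameter = "intercept", offset = 0.4)
  d <- generate_dyads(cfg)$data
  fit <- fit_ml(build_invariance_spec("conduct", "scalar"), d, se = "none")
  cand <- data.frame(group = 1L, matrix = "nu",
                     row = item_cols("conduct", "parent")[2:5],
                     col = NA, stringsAsFactors = FALSE)
  mi <- modification_indices(fit, cand)
  # the offending intercept has the largest MI
  expect_equal(mi$row[1], "conduct_parent_i3")
  # MI approximates the chi-square drop from actually freeing the parameter
  freed <- build_invariance_spec("conduct", "scalar",
                                 freed = data.frame(parameter = "intercept", pos = 3L))
  fit2 <- fit_ml(freed, d, se = "none")
  dT <- fit$fit$T - fit2$fit$T
  expect_lt(abs(mi$mi[1] - dT) / dT, 0.10)
  # a candidate that is already free scores zero
  cand2 <- data.frame(group = 1L, matrix = "nu",
                      row = item_cols("conduct", "parent")[3],
                      col = NA, stringsAsFactors = FALSE)
  mi2 <- modification_indices(fit2, cand2)
  expect_equal(mi2$mi, 0)
})

test_that("sandwich standard errors track the sampling spread under informative weights", {
  set.seed(57)
  reps <- 60
  est <- se <- numeric(reps)
  sp <- one_factor_spec(4)
  for (r in seq_len(reps)) {
    f <- stats::rnorm(800, 0.3, 1)
    Y <- vapply(c(1, 0.8, 1.2, 0.6), function(l) l * f + stats::rnorm(800, 0, 0.6),
                numeric(800))
    Y[, 2] <- Y[, 2] + 0.1; colnames(Y) <- paste0("y", 1:4)
    w <- stats::plogis(Y[, 1]) + 0.3   # weights correlated with the data
    fit <- fit_ml(sp, Y, weights = w, se = "sandwich")
    est[r] <- fit$est["a"]
    se[r] <- fit$partable$se[fit$partable$label == "a"][1]
  }
  ratio <- mean(se) / stats::sd(est)
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.3)
})

test_that("model specs round-trip through the text format", {
  sp <- build_lds_spec(build_invariance_spec("conduct", "scalar",
    freed = data.frame(parameter = "intercept", pos = 4L)))
  f <- tempfile(fileext = ".txt")
  write_spec(sp, f)
  sp2 <- read_spec(f)
  expect_equal(sp2$observed, sp$observed)
  expect_equal(sp2$latent, sp$latent)
  for (mn in c("lambda", "nu", "theta", "beta", "psi", "alpha")) {
    expect_equal(sp2[[mn]]$label, sp[[mn]]$label)
    expect_equal(sp2[[mn]]$value, sp[[mn]]$value)
  }
})
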