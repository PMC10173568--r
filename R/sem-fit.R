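# Maximum-likelihood estimation of a sem_spec: weighted-moments mode
# (normal-theory discrepancy on weighted sample moments) and FIML mode
# (casewise likelihood over each case's observed subset). Standard errors
# from the inverse observed information, or a sandwich estimator when
# weights are informative.

# weighted mean and ML covariance (divisor sum of weights)
weighted_moments <- function(Y, w = NULL) {
  Y <- as.matrix(Y)
  if (is.null(w)) w <- rep(1, nrow(Y))
  sw <- sum(w)
  mbar <- drop(crossprod(w, Y)) / sw
  Yc <- sweep(Y, 2, mbar)
  S <- crossprod(Yc * w, Yc) / sw
  list(mbar = mbar, S = (S + t(S)) / 2, n = nrow(Y))
}

# total-scale objective (T scale) and gradient for moments mode
.obj_moments <- function(th, cspec, gm) {
  total <- 0; grad <- numeric(length(th)); ok <- TRUE
  for (g in seq_along(gm)) {
    mats <- fill_matrices(cspec, th, g)
    imp <- .implied(mats)
    ch <- tryCatch(chol(imp$Sigma), error = function(e) NULL)
    if (is.null(ch)) {
      ev <- min(eigen(imp$Sigma, symmetric = TRUE, only.values = TRUE)$values)
      return(list(value = 1e10 * (1 + abs(ev)), grad = NULL, ok = FALSE))
    }
    Sinv <- chol2inv(ch)
    S <- gm[[g]]$S; mbar <- gm[[g]]$mbar; n_g <- gm[[g]]$n
    d <- mbar - imp$mu
    Fg <- 2 * sum(log(diag(ch))) + sum(Sinv * S) - gm[[g]]$logdetS -
      nrow(S) + drop(crossprod(d, Sinv %*% d))
    W <- Sinv - Sinv %*% (S + outer(d, d)) %*% Sinv
    v <- -2 * drop(Sinv %*% d)
    derivs <- param_moment_derivs(cspec, mats, imp, g)
    total <- total + n_g * Fg
    grad <- grad + n_g * chain_gradient(derivs, W, v)
  }
  list(value = total, grad = grad, ok = ok)
}

# split rows of Y by missingness pattern; returns list of (cols, rows)
.split_patterns <- function(Y) {
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  idx <- split(seq_len(nrow(Y)), key)
  lapply(idx, function(rows) list(cols = which(obs[rows[1], ]), rows = rows))
}

# total-scale objective (-2 * weighted loglik) and gradient for FIML mode
.obj_fiml <- function(th, cspec, gd) {
  total <- 0; grad <- numeric(length(th))
  for (g in seq_along(gd)) {
    mats <- fill_matrices(cspec, th, g)
    imp <- .implied(mats)
    p <- nrow(imp$Sigma)
    Wtot <- matrix(0, p, p); vtot <- numeric(p)
    for (pat in gd[[g]]$patterns) {
      o <- pat$cols
      So <- imp$Sigma[o, o, drop = FALSE]
      ch <- tryCatch(chol(So), error = function(e) NULL)
      if (is.null(ch)) {
        ev <- min(eigen(So, symmetric = TRUE, only.values = TRUE)$values)
        return(list(value = 1e10 * (1 + abs(ev)), grad = NULL, ok = FALSE))
      }
      Sinv <- chol2inv(ch)
      D <- gd[[g]]$Y[pat$rows, o, drop = FALSE]
      w <- gd[[g]]$w[pat$rows]
      D <- sweep(D, 2, imp$mu[o])
      sw <- sum(w)
      U <- D %*% Sinv
      quad <- rowSums(U * D)
      total <- total + sw * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch)))) +
        sum(w * quad)
      M <- crossprod(D * w, D)
      Wp <- sw * Sinv - Sinv %*% M %*% Sinv
      vp <- -2 * drop(crossprod(U, w))
      Wtot[o, o] <- Wtot[o, o] + Wp
      vtot[o] <- vtot[o] + vp
    }
    derivs <- param_moment_derivs(cspec, fill_matrices(cspec, th, g), imp, g)
    grad <- grad + chain_gradient(derivs, Wtot, vtot)
  }
  list(value = total, grad = grad, ok = TRUE)
}

# central-difference Hessian of the analytic gradient
.numeric_hessian <- function(fn_grad, th, h = 1e-5) {
  k <- length(th)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hj <- h * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + hj
    tm <- th; tm[j] <- tm[j] - hj
    H[, j] <- (fn_grad(tp) - fn_grad(tm)) / (2 * hj)
  }
  (H + t(H)) / 2
}

# data-driven start values for free parameters without explicit starts
.auto_starts <- function(cspec, gm) {
  th <- cspec$start
  mbar <- gm[[1]]$mbar; dS <- diag(gm[[1]]$S)
  sp <- cspec$specs[[1]]
  # marker indicator per latent: first observed with loading fixed at 1
  markers <- rep(NA_integer_, length(sp$latent))
  for (j in seq_along(sp$latent)) {
    fixed1 <- which(is.na(sp$lambda$label[, j]) & sp$lambda$value[, j] == 1)
    if (length(fixed1)) markers[j] <- fixed1[1]
  }
  for (g in seq_along(cspec$maps)) {
    mb <- gm[[min(g, length(gm))]]$mbar; dSg <- diag(gm[[min(g, length(gm))]]$S)
    for (cell in cspec$maps[[g]]) {
      pid <- cell$param
      if (!is.na(th[pid])) next
      th[pid] <- switch(cell$matrix,
        lambda = 0.8,
        nu = mb[cell$i],
        theta = if (cell$i == cell$j) 0.5 * dSg[cell$i] else 0,
        beta = 0,
        psi = if (cell$i == cell$j) {
          mk <- markers[cell$i]
          if (!is.na(mk)) 0.4 * dSg[mk] else 0.2 * mean(dSg)
        } else 0,
        alpha = {
          mk <- markers[cell$j]
          if (!is.na(mk)) mb[mk] else 0
        })
    }
  }
  th
}

#' Fit a structural equation model
#'
#' Minimizes the normal-theory ML discrepancy over (possibly weighted)
#' sample moments, or maximizes the casewise (full-information) likelihood
#' over each case's observed variables.
#'
#' @param spec A [sem_spec()] or list of them (one per group; parameter
#'   labels shared across groups are constrained equal).
#' @param data data.frame/matrix containing `spec$observed` columns, or a
#'   list of them for multiple groups. In `"moments"` mode, rows with any
#'   missing observed variable are dropped (complete-case); in `"fiml"` mode
#'   every row with at least one observed variable contributes.
#' @param weights Optional case weights (vector, or list per group);
#'   internally rescaled to mean 1 over analysed cases.
#' @param mode `"moments"` (weighted ML on sample moments) or `"fiml"`.
#' @param se `"auto"` (sandwich when weights are informative, otherwise
#'   observed-information), `"info"`, `"sandwich"`, or `"none"`.
#' @param indices Compute baseline-based fit indices (in FIML mode this
#'   fits saturated and independence models numerically; set `FALSE` to
#'   skip).
#' @param max_iter,reltol Optimizer budget and relative tolerance.
#' @param restarts Jittered restarts on nonconvergence.
#' @return An object of class `sem_fit`: parameter table, covariance matrix
#'   of the estimates, fit statistics (`$fit`), and bookkeeping needed by
#'   [modification_indices()].
#' @export
fit_ml <- function(spec, data, weights = NULL,
                   mode = c("moments", "fiml"),
                   se = c("auto", "info", "sandwich", "none"),
                   indices = TRUE,
                   max_iter = 500L, reltol = 1e-8, restarts = 3L) {
  mode <- match.arg(mode)
  se <- match.arg(se)
  specs <- if (inherits(spec, "sem_spec")) list(spec) else spec
  datal <- if (is.list(data) && !is.data.frame(data)) data else list(data)
  if (length(datal) != length(specs)) stop("number of data groups must match number of specs")
  wl <- if (is.null(weights)) lapply(datal, function(d) rep(1, nrow(as.matrix(d))))
  else if (is.list(weights)) weights else list(weights)

  cspec <- compile_spec(specs)
  k <- length(cspec$params)
  G <- length(specs)

  gm <- list(); gd <- list()
  for (g in seq_len(G)) {
    obs <- specs[[g]]$observed
    d <- datal[[g]]
    miss_col <- setdiff(obs, colnames(d))
    if (length(miss_col)) stop("data lacks observed variables: ", paste(miss_col, collapse = ", "))
    Y <- as.matrix(as.data.frame(d)[, obs, drop = FALSE])
    w <- wl[[g]]
    keep <- !is.na(w)
    if (mode == "moments") keep <- keep & stats::complete.cases(Y)
    else keep <- keep & rowSums(!is.na(Y)) > 0
    Y <- Y[keep, , drop = FALSE]; w <- w[keep]
    if (nrow(Y) <= k) stop("fewer analysed cases than free parameters")
    w <- w / mean(w)
    if (mode == "moments") {
      mom <- weighted_moments(Y, w)
      mom$logdetS <- as.numeric(determinant(mom$S)$modulus)
      if (!is.finite(mom$logdetS)) {
        # singular sample covariance (e.g. duplicated columns): log|S| is a
        # constant, so estimation proceeds; T keeps only the relative part
        warning("sample covariance is singular; discrepancy statistics are ",
                "relative (log|S| term dropped)")
        mom$logdetS <- 0
      }
      gm[[g]] <- mom
      gd[[g]] <- list(Y = Y, w = w, patterns = .split_patterns(Y))
    } else {
      cc <- stats::complete.cases(Y)
      mom <- if (sum(cc) > ncol(Y)) weighted_moments(Y[cc, , drop = FALSE], w[cc])
      else list(mbar = colMeans(Y, na.rm = TRUE),
                S = diag(apply(Y, 2, stats::var, na.rm = TRUE)), n = nrow(Y))
      mom$n <- nrow(Y)
      mom$logdetS <- NA_real_
      gm[[g]] <- mom
      gd[[g]] <- list(Y = Y, w = w, patterns = .split_patterns(Y))
    }
  }
  n_tot <- sum(vapply(gm, `[[`, 0, "n"))

  th0 <- .auto_starts(cspec, gm)
  objfun <- if (mode == "moments") function(th) .obj_moments(th, cspec, gm)
  else function(th) .obj_fiml(th, cspec, gd)

  cache <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    key <- paste(format(th, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$res)
    res <- objfun(th)
    cache$key <- key; cache$res <- res
    res
  }
  fn <- function(th) eval_at(th)$value / n_tot
  gr <- function(th) {
    res <- eval_at(th)
    if (is.null(res$grad)) numeric(length(th)) else res$grad / n_tot
  }

  best <- NULL
  set_jitter <- function(th, i) if (i == 1) th else th * stats::runif(length(th), 0.85, 1.15) +
    stats::rnorm(length(th), 0, 0.01)
  for (attempt in seq_len(restarts)) {
    st <- pmax(set_jitter(th0, attempt), cspec$lower + 1e-6)
    opt <- tryCatch(
      stats::optim(st, fn, gr, method = "L-BFGS-B", lower = cspec$lower,
                   control = list(maxit = max_iter, pgtol = 1e-9,
                                  factr = reltol / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("optimization failed in all restarts")
  converged <- best$convergence == 0
  if (!converged) warning("optimizer did not converge (code ", best$convergence, ")")
  th <- best$par
  names(th) <- cspec$params

  # Newton polish: tighten the solution beyond L-BFGS-B's stopping rule
  grad_total_fn <- function(t2) {
    r <- objfun(t2)
    if (is.null(r$grad)) rep(NA_real_, length(t2)) else r$grad
  }
  if (k <= 80) {
    for (polish in 1:2) {
      res <- objfun(th)
      if (is.null(res$grad) || max(abs(res$grad)) / n_tot < 1e-11) break
      Hp <- .numeric_hessian(grad_total_fn, th)
      step <- tryCatch(solve(Hp, res$grad), error = function(e) NULL)
      if (is.null(step) || anyNA(step)) break
      cand <- pmax(th - step, cspec$lower)
      rc <- objfun(cand)
      if (rc$ok && rc$value <= res$value + 1e-10) th <- cand else break
    }
  }

  at_bound <- cspec$params[abs(th - cspec$lower) < 1e-8 & is.finite(cspec$lower)]
  if (length(at_bound)) {
    warning("variance estimate(s) at the lower bound (Heywood): ",
            paste(at_bound, collapse = ", "))
  }

  final <- objfun(th)
  T_stat <- if (mode == "moments") final$value else NA_real_
  loglik <- if (mode == "fiml") -final$value / 2 else {
    # complete-data loglik at the solution via the casewise machinery
    -.obj_fiml(th, cspec, gd)$value / 2
  }

  p <- length(specs[[1]]$observed)
  df <- G * p * (p + 3) / 2 - k

  impl <- lapply(seq_len(G), function(g) .implied(fill_matrices(cspec, th, g)))

  fitres <- list(T = T_stat, df = df, T0 = NA_real_, df0 = NA_real_,
                 CFI = NA_real_, RMSEA = NA_real_, SRMR = NA_real_,
                 N = n_tot, G = G, loglik = loglik, mode = mode,
                 converged = converged,
                 weighted = any(vapply(gd, function(x) stats::sd(x$w) > 1e-12, TRUE)))
  if (mode == "moments") {
    F0 <- vapply(seq_len(G), function(g) {
      S <- gm[[g]]$S
      sum(log(diag(S))) - gm[[g]]$logdetS
    }, 0)
    fitres$T0 <- sum(vapply(gm, `[[`, 0, "n") * F0)
    fitres$df0 <- G * p * (p + 3) / 2 - G * 2 * p
    fi <- fit_indices(fitres$T, fitres$df, fitres$T0, fitres$df0, n_tot, G)
    fitres$CFI <- fi$CFI; fitres$RMSEA <- fi$RMSEA
    fitres$SRMR <- srmr_groups(gm, impl)
  } else if (indices) {
    ll_sat <- .fiml_reference_loglik(specs[[1]]$observed, gd, "saturated")
    ll_base <- .fiml_reference_loglik(specs[[1]]$observed, gd, "baseline")
    fitres$T <- max(0, 2 * (ll_sat - loglik))
    fitres$T0 <- max(0, 2 * (ll_sat - ll_base))
    fitres$df0 <- G * p * (p + 3) / 2 - G * 2 * p
    fi <- fit_indices(fitres$T, fitres$df, fitres$T0, fitres$df0, n_tot, G)
    fitres$CFI <- fi$CFI; fitres$RMSEA <- fi$RMSEA
    ccg <- lapply(seq_len(G), function(g) {
      Y <- gd[[g]]$Y; w <- gd[[g]]$w; cc <- stats::complete.cases(Y)
      if (sum(cc) > p + 1) {
        mom <- weighted_moments(Y[cc, , drop = FALSE], w[cc]); mom$n <- sum(cc); mom
      } else NULL
    })
    if (!any(vapply(ccg, is.null, TRUE))) fitres$SRMR <- srmr_groups(ccg, impl)
  }

  vc <- NULL; se_type <- "none"
  if (se != "none") {
    grad_total <- function(t2) {
      r <- objfun(t2)
      if (is.null(r$grad)) rep(NA_real_, length(t2)) else r$grad
    }
    H <- .numeric_hessian(grad_total, th)
    A <- H / 2    # observed information on the loglik scale
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) {
      warning("information matrix is singular; standard errors unavailable")
    } else {
      use_sandwich <- se == "sandwich" || (se == "auto" && fitres$weighted)
      if (use_sandwich) {
        Bm <- matrix(0, k, k)
        for (g in seq_len(G)) {
          sc <- casewise_scores(cspec, th, gd[[g]], g)
          sw <- sc * gd[[g]]$w
          Bm <- Bm + crossprod(sw)
        }
        vc <- Ainv %*% Bm %*% Ainv
        se_type <- "sandwich"
      } else {
        vc <- Ainv
        se_type <- "info"
      }
      dimnames(vc) <- list(cspec$params, cspec$params)
    }
  }

  pt <- build_partable(cspec, th, vc, impl)

  structure(list(
    specs = specs, cspec = cspec, mode = mode, est = th,
    partable = pt, vcov = vc, se_type = se_type, fit = fitres,
    moments = gm, implied = impl, data = gd, objective = final$value,
    n = n_tot
  ), class = "sem_fit")
}

# casewise score matrix (n x k) for group g at th: d loglik_i / d theta
casewise_scores <- function(cspec, th, gdat, g = 1L) {
  mats <- fill_matrices(cspec, th, g)
  imp <- .implied(mats)
  derivs <- param_moment_derivs(cspec, mats, imp, g)
  k <- length(cspec$params)
  n <- nrow(gdat$Y)
  out <- matrix(0, n, k)
  for (pat in gdat$patterns) {
    o <- pat$cols
    So <- imp$Sigma[o, o, drop = FALSE]
    Sinv <- chol2inv(chol(So))
    D <- sweep(gdat$Y[pat$rows, o, drop = FALSE], 2, imp$mu[o])
    U <- D %*% Sinv
    for (pid in seq_len(k)) {
      dv <- derivs[[pid]]
      if (is.null(dv)) next
      dS <- dv$dSigma[o, o, drop = FALSE]
      dm <- dv$dmu[o]
      t1 <- -0.5 * sum(Sinv * dS)
      t2 <- 0.5 * rowSums((U %*% dS) * U)
      t3 <- drop(U %*% dm)
      out[pat$rows, pid] <- t1 + t2 + t3
    }
  }
  out
}

# saturated / independence-model FIML loglik via the same optimizer
.fiml_reference_loglik <- function(observed, gd, kind = c("saturated", "baseline")) {
  kind <- match.arg(kind)
  p <- length(observed)
  G <- length(gd)
  specs <- lapply(seq_len(G), function(g) {
    sp <- sem_spec(observed, paste0("f_", observed))
    for (i in seq_len(p)) {
      sp <- sp_fix(sp, "lambda", i, i, 1)
      sp <- sp_free(sp, "alpha", i, NULL, paste0("a", g, "_", i))
      sp <- sp_free(sp, "psi", i, i, paste0("v", g, "_", i))
      if (kind == "saturated") {
        for (j in seq_len(p)) if (j > i) {
          sp <- sp_free(sp, "psi", i, j, paste0("c", g, "_", i, "_", j))
        }
      }
    }
    sp
  })
  cspec <- compile_spec(specs)
  # starts from available-case moments
  th0 <- cspec$start
  for (g in seq_len(G)) {
    Y <- gd[[g]]$Y
    mb <- colMeans(Y, na.rm = TRUE)
    vv <- apply(Y, 2, stats::var, na.rm = TRUE)
    Cv <- stats::cov(Y, use = "pairwise.complete.obs")
    Cv[is.na(Cv)] <- 0
    for (i in seq_len(p)) {
      th0[paste0("a", g, "_", i)] <- mb[i]
      th0[paste0("v", g, "_", i)] <- vv[i]
      if (kind == "saturated") for (j in seq_len(p)) if (j > i) {
        th0[paste0("c", g, "_", i, "_", j)] <- 0.9 * Cv[i, j]
      }
    }
  }
  n_tot <- sum(vapply(gd, function(x) nrow(x$Y), 0))
  fn <- function(th) .obj_fiml(th, cspec, gd)$value / n_tot
  gr <- function(th) {
    r <- .obj_fiml(th, cspec, gd)
    if (is.null(r$grad)) numeric(length(th)) else r$grad / n_tot
  }
  opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B", lower = cspec$lower,
                      control = list(maxit = 1000, factr = 1e7))
  -opt$value * n_tot / 2
}

# parameter table with estimates, SEs, z, p, standardized values
build_partable <- function(cspec, th, vc, impl) {
  rows <- list()
  for (g in seq_along(cspec$maps)) {
    sp <- cspec$specs[[g]]
    imp <- impl[[g]]
    sd_lat <- sqrt(pmax(diag(imp$P), 0))
    sd_obs <- sqrt(pmax(diag(imp$Sigma), 0))
    names(sd_lat) <- sp$latent; names(sd_obs) <- sp$observed
    for (cell in cspec$maps[[g]]) {
      mn <- cell$matrix; i <- cell$i; j <- cell$j
      lab <- cspec$params[cell$param]
      est <- th[cell$param]
      sev <- if (!is.null(vc)) sqrt(max(vc[lab, lab], 0)) else NA_real_
      rn <- rownames(sp[[mn]]$label)[i]
      cn <- if (mn %in% c("nu", "alpha")) NA_character_ else colnames(sp[[mn]]$label)[j]
      std <- switch(mn,
        lambda = est * sd_lat[cn] / sd_obs[rn],
        nu = est / sd_obs[rn],
        theta = est / (sd_obs[rn] * sd_obs[colnames(sp$theta$label)[j]]),
        beta = est * sd_lat[cn] / sd_lat[rn],
        psi = est / (sd_lat[rn] * sd_lat[colnames(sp$psi$label)[j]]),
        alpha = est / sd_lat[rn])
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, matrix = mn, row = rn, col = cn, label = lab,
        est = est, se = sev, z = est / sev,
        pvalue = 2 * stats::pnorm(-abs(est / sev)),
        std = unname(std), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("sem_fit (", x$mode, " mode, ", x$fit$G, " group(s), N = ", x$n, ")\n", sep = "")
  cat("  convention: marker identification; T = sum_g n_g F_g\n")
  cat(sprintf("  T = %.3f on df = %d | CFI = %.3f RMSEA = %.3f SRMR = %.3f\n",
              x$fit$T, x$fit$df,
              ifelse(is.na(x$fit$CFI), NaN, x$fit$CFI),
              ifelse(is.na(x$fit$RMSEA), NaN, x$fit$RMSEA),
              ifelse(is.na(x$fit$SRMR), NaN, x$fit$SRMR)))
  cat("  free parameters:", length(x$est), "| SEs:", x$se_type, "\n")
  invisible(x)
}
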