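# Implied moments, the ML discrepancy function, and analytic derivatives.

#' Model-implied moments
#'
#' Computes `Sigma = L (I-B)^-1 Psi (I-B)^-T L' + Theta` and
#' `mu = nu + L (I-B)^-1 alpha` at a parameter vector.
#'
#' @param spec A [sem_spec()].
#' @param theta Named parameter vector (names = spec labels); free cells
#'   without a supplied value use their spec start values.
#' @return List with `Sigma` (p x p) and `mu` (length p).
#' @export
implied_moments <- function(spec, theta = NULL) {
  cspec <- compile_spec(spec)
  th <- cspec$start
  if (!is.null(theta)) th[names(theta)] <- theta
  if (anyNA(th)) stop("no value for parameter(s): ",
                      paste(names(th)[is.na(th)], collapse = ", "))
  mats <- fill_matrices(cspec, th, 1L)
  .implied(mats)
}

# core implied-moment computation from numeric matrices
.implied <- function(mats) {
  m <- ncol(mats$lambda)
  ImB <- diag(m) - mats$beta
  A <- tryCatch(solve(ImB), error = function(e) {
    stop("(I - B) is singular: the latent regression structure is cyclic")
  })
  G <- mats$lambda %*% A                 # p x m
  P <- A %*% mats$psi %*% t(A)           # latent covariance (total)
  a <- A %*% mats$alpha                  # latent means (total)
  Sigma <- G %*% mats$psi %*% t(G) + mats$theta
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- drop(mats$nu + mats$lambda %*% a)
  list(Sigma = Sigma, mu = mu, G = G, A = A, P = P, a = drop(a))
}

#' ML discrepancy function
#'
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p + (m - mu)' Sigma^-1 (m - mu)`,
#' zero iff the implied moments reproduce the sample moments.
#'
#' @param S Sample covariance (ML divisor), positive definite.
#' @param mbar Sample mean vector.
#' @param Sigma Implied covariance, positive definite.
#' @param mu Implied mean vector.
#' @return The discrepancy value (nonnegative).
#' @export
fml_discrepancy <- function(S, mbar, Sigma, mu) {
  p <- nrow(S)
  cS <- tryCatch(chol(S), error = function(e) stop("sample covariance S is not positive definite"))
  cSg <- tryCatch(chol(Sigma), error = function(e) stop("implied covariance Sigma is not positive definite"))
  Sinv <- chol2inv(cSg)
  d <- mbar - mu
  val <- 2 * sum(log(diag(cSg))) + sum(Sinv * S) - 2 * sum(log(diag(cS))) - p +
    drop(crossprod(d, Sinv %*% d))
  max(val, 0)
}

# Per-free-parameter derivative matrices of (Sigma, mu) at filled matrices.
# Returns list of k elements: dSigma (p x p), dmu (p). Cells sharing a label
# accumulate. imp = .implied(mats).
param_moment_derivs <- function(cspec, mats, imp, g = 1L) {
  p <- nrow(mats$lambda); k <- length(cspec$params)
  G <- imp$G; A <- imp$A; a <- imp$a
  out <- vector("list", k)
  add <- function(pid, dS, dm) {
    if (is.null(out[[pid]])) {
      out[[pid]] <<- list(dSigma = dS, dmu = dm)
    } else {
      out[[pid]]$dSigma <<- out[[pid]]$dSigma + dS
      out[[pid]]$dmu <<- out[[pid]]$dmu + dm
    }
  }
  zS <- matrix(0, p, p); zm <- numeric(p)
  for (cell in cspec$maps[[g]]) {
    i <- cell$i; j <- cell$j
    dS <- zS; dm <- zm
    switch(cell$matrix,
      lambda = {
        # dSigma = e_i (Lambda P)_{.,j}' + (Lambda P)_{.,j} e_i'
        v <- (mats$lambda %*% imp$P)[, j]
        dS[i, ] <- v
        dS[, i] <- dS[, i] + v
        dm[i] <- a[j]
      },
      nu = { dm[i] <- 1 },
      theta = {
        dS[i, j] <- dS[i, j] + 1
        dS[j, i] <- dS[j, i] + 1
        if (i == j) dS[i, i] <- 1
      },
      beta = {
        # dG = G_{.,i} A_{j,.} ; dSigma = dG Psi G' + G Psi dG' ; dmu = G_{.,i} a_j
        dG_row <- A[j, , drop = FALSE]                   # 1 x m
        u <- G[, i]                                      # p
        w <- drop(dG_row %*% mats$psi %*% t(G))          # p  (A_{j,.} Psi G')
        dS <- outer(u, w) + outer(w, u)
        dm <- u * a[j]
      },
      psi = {
        gi <- G[, i]; gj <- G[, j]
        dS <- if (i == j) outer(gi, gi) else outer(gi, gj) + outer(gj, gi)
      },
      alpha = { dm <- G[, i] }   # alpha is m x 1: i indexes the latent
    )
    add(cell$param, dS, dm)
  }
  out
}

# Gradient of a moment functional given W = dF/dSigma (full-matrix,
# independent-entry convention) and v = dF/dmu, via the per-parameter
# derivative matrices.
chain_gradient <- function(derivs, W, v) {
  k <- length(derivs)
  g <- numeric(k)
  for (pid in seq_len(k)) {
    d <- derivs[[pid]]
    if (is.null(d)) next
    g[pid] <- sum(W * d$dSigma) + sum(v * d$dmu)
  }
  g
}
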