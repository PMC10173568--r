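# Modification indices: univariate score (Lagrange multiplier) tests for
# currently fixed or equality-constrained cells, computed at the constrained
# solution without refitting.

#' Modification indices
#'
#' For each candidate cell, the expected chi-square(1) improvement from
#' freeing it (splitting its equality label, or freeing a fixed cell),
#' computed as the score statistic `MI = g' I^-1 g / 2` restricted to the
#' free parameters plus the candidate, where `g` and `I` are the gradient
#' and observed information of the fitted objective at the constrained
#' solution. Candidates that are already free score 0; candidates with a
#' singular information block are skipped with a warning.
#'
#' @param fit A converged [fit_ml()] result.
#' @param candidates data.frame with columns `group`, `matrix`, `row`,
#'   `col` (variable names; `col` ignored for `nu`/`alpha`).
#' @return The `candidates` data.frame with columns `current` (label or
#'   `"fixed"`) and `mi`, sorted by decreasing `mi`.
#' @export
modification_indices <- function(fit, candidates) {
  stopifnot(inherits(fit, "sem_fit"))
  n_c <- nrow(candidates)
  current <- character(n_c)
  mi <- numeric(n_c)

  # count cells per label to recognize singleton (already-free) labels
  label_cells <- table(unlist(lapply(seq_along(fit$specs), function(g) {
    vapply(fit$cspec$maps[[g]], function(cell) fit$cspec$params[cell$param], "")
  })))

  # each candidate gets its own one-parameter extension: splitting a label
  # changes what the remaining label ties, so candidates must not share an
  # extended space
  for (i in seq_len(n_c)) {
    g <- candidates$group[i]
    mn <- candidates$matrix[i]
    sp <- fit$specs[[g]]
    col_i <- if (mn %in% c("nu", "alpha")) NULL else candidates$col[i]
    ij <- .sp_idx(sp, mn, candidates$row[i], col_i)
    lab <- sp[[mn]]$label[ij[1], ij[2]]
    if (is.na(lab)) {
      current[i] <- "fixed"
    } else {
      current[i] <- lab
      if (label_cells[lab] == 1L) { mi[i] <- 0; next }
    }
    specs_ext <- fit$specs
    specs_ext[[g]] <- sp_free(sp, mn, candidates$row[i], col_i, "..mi", NA_real_)
    cspec_ext <- compile_spec(specs_ext)
    th_ext <- numeric(length(cspec_ext$params))
    names(th_ext) <- cspec_ext$params
    th_ext[names(fit$est)] <- fit$est
    th_ext["..mi"] <- if (is.na(lab)) sp[[mn]]$value[ij[1], ij[2]] else fit$est[lab]
    g_ext <- if (fit$mode == "moments") {
      .obj_moments(th_ext, cspec_ext, fit$moments)$grad
    } else {
      .obj_fiml(th_ext, cspec_ext, fit$data)$grad
    }
    I_ext <- .expected_information(cspec_ext, th_ext, fit)
    s_ext <- -g_ext / 2                     # score on the loglik scale
    sol <- tryCatch(solve(I_ext, s_ext), error = function(e) NULL)
    if (is.null(sol)) {
      warning("singular information for candidate ", i, "; skipped")
      mi[i] <- NA_real_
      next
    }
    mi[i] <- max(0, drop(crossprod(s_ext, sol)))
  }
  out <- candidates
  out$current <- current
  out$mi <- mi
  out[order(-replace(out$mi, is.na(out$mi), -Inf)), , drop = FALSE]
}

# Expected (Fisher) information of the loglik at th, per parameter pair:
# I_ij = sum_g n-weighted [ tr(Sinv dSigma_i Sinv dSigma_j)/2
#                           + dmu_i' Sinv dmu_j ],
# with missing data handled pattern-wise (FIML mode).
.expected_information <- function(cspec, th, fit) {
  k <- length(cspec$params)
  I_tot <- matrix(0, k, k)
  for (g in seq_along(cspec$maps)) {
    mats <- fill_matrices(cspec, th, g)
    imp <- .implied(mats)
    derivs <- param_moment_derivs(cspec, mats, imp, g)
    active <- which(!vapply(derivs, is.null, TRUE))
    blocks <- if (fit$mode == "moments") {
      list(list(cols = seq_len(nrow(imp$Sigma)), n = fit$moments[[g]]$n))
    } else {
      lapply(fit$data[[g]]$patterns, function(pat) {
        list(cols = pat$cols, n = sum(fit$data[[g]]$w[pat$rows]))
      })
    }
    for (bl in blocks) {
      o <- bl$cols
      Sinv <- chol2inv(chol(imp$Sigma[o, o, drop = FALSE]))
      E <- lapply(active, function(pid) Sinv %*% derivs[[pid]]$dSigma[o, o, drop = FALSE])
      M <- lapply(active, function(pid) drop(Sinv %*% derivs[[pid]]$dmu[o]))
      for (ii in seq_along(active)) for (jj in ii:length(active)) {
        val <- bl$n * (0.5 * sum(E[[ii]] * t(E[[jj]])) +
                         sum(derivs[[active[ii]]]$dmu[o] * M[[jj]]))
        I_tot[active[ii], active[jj]] <- I_tot[active[ii], active[jj]] + val
        if (ii != jj) I_tot[active[jj], active[ii]] <- I_tot[active[jj], active[ii]] + val
      }
    }
  }
  I_tot
}
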