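# Measurement-invariance ladder across reporters: configural -> metric ->
# scalar, with delta-fit acceptance rules and a capped partial-invariance
# search driven by modification indices.

#' Build the invariance ladder specs for one construct
#'
#' In `joint-dyad` mode both reporter factors live in one model fitted to
#' the dyads (correlated factors, optional same-item residual covariances),
#' respecting the within-dyad dependence the LDS model requires. In
#' `two-group` mode the reporters are treated as independent samples of a
#' single-factor model. Identification is by the marker convention: the
#' first item's loading is fixed to 1 and its intercept to 0, so latent
#' means stay estimable; marker parameters are never equality candidates.
#'
#' @param construct Construct name.
#' @param level `"configural"`, `"metric"` or `"scalar"`.
#' @param freed data.frame of parent-side measurement parameters freed from
#'   cross-reporter equality: columns `parameter` (`"loading"`/`"intercept"`)
#'   and `pos` (2-5).
#' @param mode `"joint-dyad"` or `"two-group"`.
#' @param resid_cov In joint-dyad mode, free same-item residual covariances
#'   across reporters (default off).
#' @return A `sem_spec` (joint-dyad) or list of two `sem_spec`s (two-group).
#' @export
build_invariance_spec <- function(construct, level = c("configural", "metric", "scalar"),
                                  freed = NULL, mode = c("joint-dyad", "two-group"),
                                  resid_cov = FALSE) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  is_freed <- function(par, j) {
    !is.null(freed) && nrow(freed) > 0 &&
      any(freed$parameter == par & freed$pos == j)
  }
  share_load <- level %in% c("metric", "scalar")
  share_int <- level == "scalar"

  if (mode == "joint-dyad") {
    obs <- c(item_cols(construct, "self"), item_cols(construct, "parent"))
    sp <- sem_spec(obs, c("eta_self", "eta_parent"))
    for (r in c("self", "parent")) {
      fac <- if (r == "self") "eta_self" else "eta_parent"
      cols <- item_cols(construct, r)
      for (j in 1:5) {
        if (j == 1) {
          sp <- sp_fix(sp, "lambda", cols[j], fac, 1)
          sp <- sp_fix(sp, "nu", cols[j], NULL, 0)
        } else {
          llab <- if (share_load && !is_freed("loading", j)) paste0("l", j)
          else paste0("l_", substr(r, 1, 1), j)
          nlab <- if (share_int && !is_freed("intercept", j)) paste0("nu", j)
          else paste0("nu_", substr(r, 1, 1), j)
          sp <- sp_free(sp, "lambda", cols[j], fac, llab)
          sp <- sp_free(sp, "nu", cols[j], NULL, nlab)
        }
        sp <- sp_free(sp, "theta", cols[j], cols[j], paste0("th_", substr(r, 1, 1), j))
      }
    }
    if (resid_cov) {
      cs <- item_cols(construct, "self"); cp <- item_cols(construct, "parent")
      for (j in 1:5) sp <- sp_free(sp, "theta", cs[j], cp[j], paste0("thc", j), 0)
    }
    sp <- sp_free(sp, "psi", "eta_self", "eta_self", "psi_s")
    sp <- sp_free(sp, "psi", "eta_parent", "eta_parent", "psi_p")
    sp <- sp_free(sp, "psi", "eta_self", "eta_parent", "psi_sp", 0)
    sp <- sp_free(sp, "alpha", "eta_self", NULL, "al_s")
    sp <- sp_free(sp, "alpha", "eta_parent", NULL, "al_p")
    return(sp)
  }

  # two-group mode: generic item names i1..i5 in both groups
  specs <- lapply(c("self", "parent"), function(r) {
    sp <- sem_spec(paste0("i", 1:5), "eta")
    for (j in 1:5) {
      if (j == 1) {
        sp <- sp_fix(sp, "lambda", "i1", "eta", 1)
        sp <- sp_fix(sp, "nu", "i1", NULL, 0)
      } else {
        llab <- if (share_load && !is_freed("loading", j)) paste0("l", j)
        else paste0("l_", substr(r, 1, 1), j)
        nlab <- if (share_int && !is_freed("intercept", j)) paste0("nu", j)
        else paste0("nu_", substr(r, 1, 1), j)
        sp <- sp_free(sp, "lambda", paste0("i", j), "eta", llab)
        sp <- sp_free(sp, "nu", paste0("i", j), NULL, nlab)
      }
      sp <- sp_free(sp, "theta", paste0("i", j), paste0("i", j),
                    paste0("th_", substr(r, 1, 1), j))
    }
    sp <- sp_free(sp, "psi", "eta", "eta", paste0("psi_", substr(r, 1, 1)))
    sp <- sp_free(sp, "alpha", "eta", NULL, paste0("al_", substr(r, 1, 1)))
    sp
  })
  specs
}

#' @rdname build_invariance_spec
#' @param data Dyad data.frame (used in two-group mode to split reporters).
#' @return For `ladder_data()`: data in the shape `fit_ml()` expects for the
#'   given mode.
#' @export
ladder_data <- function(data, construct, mode = c("joint-dyad", "two-group")) {
  mode <- match.arg(mode)
  if (mode == "joint-dyad") return(data)
  out <- lapply(c("self", "parent"), function(r) {
    Y <- as.matrix(as.data.frame(data)[, item_cols(construct, r)])
    colnames(Y) <- paste0("i", 1:5)
    Y
  })
  out
}

#' Run the invariance ladder for one construct
#'
#' Fits configural, metric and scalar models in sequence. A step is accepted
#' iff the loss of fit versus the previously accepted step satisfies both
#' criteria (`dCFI <= 0.010` and `dRMSEA <= 0.015` by default; dSRMR is
#' reported but not used for acceptance). On failure the capped partial
#' search ([partial_search()]) is invoked before declaring non-invariance.
#'
#' @param data Dyad data.frame.
#' @param construct Construct name.
#' @param weights Optional case weights.
#' @param criteria Named list: `dCFI`, `dRMSEA`.
#' @param mode `"joint-dyad"` (default) or `"two-group"`.
#' @param max_free Maximum freed parameters per class (loadings,
#'   intercepts); the cap is two out of five.
#' @param resid_cov Passed to [build_invariance_spec()].
#' @param estimation Passed to [fit_ml()] `mode`.
#' @return An `invariance_report`: `steps` (per-step fit and delta table),
#'   `freed`, `accepted` (step label), `accepted_spec`, `fits`.
#' @export
run_ladder <- function(data, construct, weights = NULL,
                       criteria = list(dCFI = 0.010, dRMSEA = 0.015),
                       mode = c("joint-dyad", "two-group"),
                       max_free = 2L, resid_cov = FALSE,
                       estimation = c("moments", "fiml")) {
  mode <- match.arg(mode)
  estimation <- match.arg(estimation)
  dat <- ladder_data(data, construct, mode)
  wts <- if (mode == "two-group" && !is.null(weights)) list(weights, weights) else weights

  fit_step <- function(level, freed) {
    sp <- build_invariance_spec(construct, level, freed, mode, resid_cov)
    fit_ml(sp, dat, weights = wts, mode = estimation, se = "none")
  }
  passes <- function(delta) {
    delta$dCFI <= criteria$dCFI && delta$dRMSEA <= criteria$dRMSEA
  }

  steps <- list(); fits <- list(); freed <- list()
  add_step <- function(name, fit, ref_fit) {
    delta <- if (is.null(ref_fit)) list(dT = NA, ddf = NA, dCFI = NA, dRMSEA = NA, dSRMR = NA)
    else chisq_diff(fit, ref_fit)
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, T = fit$fit$T, df = fit$fit$df,
      CFI = fit$fit$CFI, RMSEA = fit$fit$RMSEA, SRMR = fit$fit$SRMR,
      dCFI = delta$dCFI, dRMSEA = delta$dRMSEA, dSRMR = delta$dSRMR,
      stringsAsFactors = FALSE)
    fits[[name]] <<- fit
    delta
  }

  conf <- fit_step("configural", NULL)
  if (!conf$fit$converged) stop("configural model did not converge; ladder aborted")
  add_step("configural", conf, NULL)
  accepted <- "configural"
  accepted_fit <- conf
  accepted_freed <- data.frame(parameter = character(), pos = integer())

  for (level in c("metric", "scalar")) {
    fit_lv <- fit_step(level, accepted_freed)
    delta <- add_step(level, fit_lv, accepted_fit)
    if (passes(delta)) {
      accepted <- level; accepted_fit <- fit_lv
      next
    }
    ps <- partial_search(
      construct = construct, level = level, data = dat, weights = wts,
      base_freed = accepted_freed, accepted_fit = accepted_fit,
      criteria = criteria, mode = mode, max_free = max_free,
      resid_cov = resid_cov, estimation = estimation)
    if (!is.null(ps$fit)) {
      nm <- paste0(level, "-partial")
      add_step(nm, ps$fit, accepted_fit)
      if (ps$accepted) {
        accepted <- nm; accepted_fit <- ps$fit; accepted_freed <- ps$freed
        next
      }
    }
    # cap reached without acceptance: stop the ladder here
    accepted_freed <- if (!is.null(ps$fit)) ps$freed else accepted_freed
    attr(accepted, "stopped_at") <- level
    break
  }

  structure(list(
    construct = construct, mode = mode, criteria = criteria,
    steps = do.call(rbind, steps), freed = accepted_freed,
    accepted = accepted,
    scalar_established = accepted %in% c("scalar", "scalar-partial"),
    accepted_spec = if (mode == "joint-dyad")
      build_invariance_spec(construct,
                            sub("-partial", "", accepted), accepted_freed,
                            mode, resid_cov) else NULL,
    fits = fits
  ), class = "invariance_report")
}

#' Capped partial-invariance search
#'
#' Starting from a failed ladder step, iteratively frees the
#' equality-constrained measurement parameter (of the class introduced at
#' that step: loadings for metric, intercepts for scalar) with the largest
#' modification index, refits, and re-evaluates the delta criteria against
#' the last accepted step. Stops at acceptance or when the cap is reached;
#' ties are broken by item order; markers are never candidates. The freeing
#' rule is delta-criteria-driven: the largest-MI parameter is freed even if
#' its MI is below the chi-square(1) critical value.
#'
#' @param construct,data,weights,mode,resid_cov,estimation As [run_ladder()].
#' @param level The failing step (`"metric"` or `"scalar"`).
#' @param base_freed Parameters already freed at previously accepted steps.
#' @param accepted_fit Fit of the last accepted step (delta reference).
#' @param criteria Acceptance criteria.
#' @param max_free Cap per parameter class.
#' @return List: `fit` (best partial fit or `NULL`), `freed` (data.frame),
#'   `accepted` (logical), `order` (labels in the order they were freed).
#' @export
partial_search <- function(construct, level, data, weights, base_freed,
                           accepted_fit, criteria, mode = "joint-dyad",
                           max_free = 2L, resid_cov = FALSE,
                           estimation = "moments") {
  par_class <- if (level == "metric") "loading" else "intercept"
  freed <- base_freed
  order_freed <- character(0)
  fit <- NULL
  accepted <- FALSE
  n_freed_class <- sum(freed$parameter == par_class)

  while (n_freed_class < max_free) {
    sp <- build_invariance_spec(construct, level, freed, mode, resid_cov)
    fit <- fit_ml(sp, data, weights = weights, mode = estimation, se = "none")
    delta <- chisq_diff(fit, accepted_fit)
    if (delta$dCFI <= criteria$dCFI && delta$dRMSEA <= criteria$dRMSEA) {
      accepted <- TRUE
      break
    }
    # candidates: parent-side cells of the constrained class, items 2-5
    cand_pos <- setdiff(2:5, freed$pos[freed$parameter == par_class])
    if (!length(cand_pos)) break
    if (mode == "joint-dyad") {
      rows <- item_cols(construct, "parent")[cand_pos]
      cand <- data.frame(group = 1L,
                         matrix = if (par_class == "loading") "lambda" else "nu",
                         row = rows,
                         col = if (par_class == "loading") "eta_parent" else NA,
                         stringsAsFactors = FALSE)
    } else {
      cand <- data.frame(group = 2L,
                         matrix = if (par_class == "loading") "lambda" else "nu",
                         row = paste0("i", cand_pos),
                         col = if (par_class == "loading") "eta" else NA,
                         stringsAsFactors = FALSE)
    }
    mi <- modification_indices(fit, cand)
    mi_pos <- cand_pos[match(mi$row, cand$row)]
    # largest MI, ties broken by item order
    best_i <- order(-round(mi$mi, 6), mi_pos)[1]
    freed <- rbind(freed, data.frame(parameter = par_class, pos = mi_pos[best_i]))
    order_freed <- c(order_freed, paste0(par_class, "_", mi_pos[best_i]))
    n_freed_class <- n_freed_class + 1L
  }
  # refit with the final freed set if the loop exited after freeing
  if (!accepted && nrow(freed) > nrow(base_freed)) {
    sp <- build_invariance_spec(construct, level, freed, mode, resid_cov)
    fit <- fit_ml(sp, data, weights = weights, mode = estimation, se = "none")
    delta <- chisq_diff(fit, accepted_fit)
    accepted <- delta$dCFI <= criteria$dCFI && delta$dRMSEA <= criteria$dRMSEA
  }
  list(fit = fit, freed = freed, accepted = accepted, order = order_freed)
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("Invariance ladder:", x$construct, "(", x$mode, ")\n")
  df <- x$steps
  df[, c("CFI", "RMSEA", "SRMR", "dCFI", "dRMSEA", "dSRMR")] <-
    round(df[, c("CFI", "RMSEA", "SRMR", "dCFI", "dRMSEA", "dSRMR")], 3)
  print(df, row.names = FALSE)
  cat("accepted:", x$accepted, "\n")
  if (nrow(x$freed)) {
    cat("freed:", paste(x$freed$parameter, x$freed$pos, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Format an invariance report as a markdown table
#'
#' Mirrors the usual report layout: fit block (CFI, RMSEA, SRMR) and
#' fit-difference block per ladder step, with freed items footnoted.
#'
#' @param report An `invariance_report`.
#' @return Character vector of markdown lines.
#' @export
format_invariance <- function(report) {
  s <- report$steps
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.3f", v))
  lines <- c(
    paste0("### ", report$construct),
    "",
    "| Step | CFI | RMSEA | SRMR | dCFI | dRMSEA | dSRMR |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(s)), function(i) {
      star <- if (s$step[i] == report$accepted) "**" else ""
      paste0("| ", star, s$step[i], star, " | ", fmt(s$CFI[i]), " | ",
             fmt(s$RMSEA[i]), " | ", fmt(s$SRMR[i]), " | ", fmt(s$dCFI[i]),
             " | ", fmt(s$dRMSEA[i]), " | ", fmt(s$dSRMR[i]), " |")
    }, ""))
  if (nrow(report$freed)) {
    dict <- sdq_items(report$construct)
    notes <- vapply(seq_len(nrow(report$freed)), function(i) {
      j <- report$freed$pos[i]
      paste0(report$freed$parameter[i], " of item ", dict$item[j],
             " (\"", dict$parent_text[j], "\")")
    }, "")
    lines <- c(lines, "", paste0("Freed across reporters: ",
                                 paste(notes, collapse = "; "), "."))
  }
  lines
}
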