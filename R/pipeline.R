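# Config-driven orchestration: univariate CFA gating, invariance ladders,
# unconditional and conditional LDS models, FIML sensitivity rerun, and
# table writers.

#' Univariate CFA gate for one construct
#'
#' Fits a single-factor model per reporter and passes the construct only if
#' both meet the fit gate (defaults `CFI >= 0.90` and `RMSEA <= 0.08`,
#' conventional cutoffs; configurable). Failing constructs are excluded from
#' all downstream stages — multidimensional subscales (the usual fate of
#' hyperactivity-inattention in older adolescents) never reach the ladder.
#'
#' @param construct Construct name.
#' @param data Dyad data.frame.
#' @param weights Optional case weights.
#' @param cfi_min,rmsea_max Gate thresholds.
#' @return List: `pass`, per-reporter `fits` (CFI/RMSEA/T/df), thresholds.
#' @export
gate_univariate_cfa <- function(construct, data, weights = NULL,
                                cfi_min = 0.90, rmsea_max = 0.08) {
  out <- list()
  for (r in c("self", "parent")) {
    sp <- sem_spec(paste0("i", 1:5), "eta")
    for (j in 1:5) {
      if (j == 1) {
        sp <- sp_fix(sp, "lambda", "i1", "eta", 1)
        sp <- sp_fix(sp, "nu", "i1", NULL, 0)
      } else {
        sp <- sp_free(sp, "lambda", paste0("i", j), "eta", paste0("l", j))
        sp <- sp_free(sp, "nu", paste0("i", j), NULL, paste0("n", j))
      }
      sp <- sp_free(sp, "theta", paste0("i", j), paste0("i", j), paste0("t", j))
    }
    sp <- sp_free(sp, "psi", "eta", "eta", "psi")
    sp <- sp_free(sp, "alpha", "eta", NULL, "al")
    Y <- as.matrix(as.data.frame(data)[, item_cols(construct, r)])
    colnames(Y) <- paste0("i", 1:5)
    fit <- tryCatch(fit_ml(sp, Y, weights = weights, se = "none"),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$fit$converged) {
      out[[r]] <- list(converged = FALSE, CFI = NA, RMSEA = NA, T = NA, df = NA)
    } else {
      out[[r]] <- list(converged = TRUE, CFI = fit$fit$CFI,
                       RMSEA = fit$fit$RMSEA, T = fit$fit$T, df = fit$fit$df)
    }
  }
  pass <- all(vapply(out, function(x) {
    isTRUE(x$converged) && x$CFI >= cfi_min && x$RMSEA <= rmsea_max
  }, TRUE))
  list(construct = construct, pass = pass, fits = out,
       thresholds = c(cfi_min = cfi_min, rmsea_max = rmsea_max))
}

#' Study configuration
#'
#' @param input CSV path with dyad data, or `NULL` to generate synthetically.
#' @param generator [generator_config()] used when `input` is `NULL`.
#' @param constructs Constructs to analyse.
#' @param estimation `"moments"` (weighted ML) or `"fiml"`.
#' @param invariance_mode `"joint-dyad"` or `"two-group"`.
#' @param criteria Delta-fit acceptance criteria.
#' @param ipw_covariates Covariates for the nonresponse propensity model;
#'   `NULL` disables IPW (survey weights only).
#' @param moderators Binary moderators for conditional models, any of
#'   `"sex"`, `"distress"`, `"edu"` (empty vector disables Tables 4-6
#'   analogues).
#' @param gate Univariate CFA gate thresholds.
#' @param sensitivity_fiml Rerun unconditional LDS models with FIML and
#'   report side-by-side deltas.
#' @param out_dir Output directory (`NULL`: nothing written to disk).
#' @param seed Seed for any generation step.
#' @return A `study_config` list.
#' @export
study_config <- function(input = NULL, generator = NULL,
                         constructs = c("conduct", "emotion", "peer", "prosocial"),
                         estimation = c("moments", "fiml"),
                         invariance_mode = c("joint-dyad", "two-group"),
                         criteria = list(dCFI = 0.010, dRMSEA = 0.015),
                         ipw_covariates = c("sex", "edu"),
                         moderators = c("sex", "distress", "edu"),
                         gate = c(cfi_min = 0.90, rmsea_max = 0.08),
                         sensitivity_fiml = TRUE,
                         out_dir = NULL, seed = 20181L) {
  estimation <- match.arg(estimation)
  invariance_mode <- match.arg(invariance_mode)
  constructs <- match.arg(constructs, sdq_constructs(), several.ok = TRUE)
  if (length(moderators)) {
    moderators <- match.arg(moderators, c("sex", "distress", "edu"), several.ok = TRUE)
  }
  structure(list(input = input, generator = generator, constructs = constructs,
                 estimation = estimation, invariance_mode = invariance_mode,
                 criteria = criteria, ipw_covariates = ipw_covariates,
                 moderators = moderators, gate = gate,
                 sensitivity_fiml = sensitivity_fiml,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full discrepancy study
#'
#' Reproduces the analysis sequence end-to-end: data (read or generated),
#' weights (IPW x survey weight), item descriptives, univariate CFA gates,
#' invariance ladders, unconditional LDS models, conditional LDS models per
#' moderator, and an optional FIML sensitivity rerun. All randomness flows
#' from `config$seed`.
#'
#' @param config A [study_config()].
#' @return A `study_bundle` list; if `config$out_dir` is set, tables (CSV +
#'   markdown) and a JSON manifest are written there.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  errors <- list()
  set.seed(config$seed)

  truth <- NULL
  if (!is.null(config$input)) {
    d <- read_dyads(config$input, constructs = config$constructs)
  } else {
    gen <- if (!is.null(config$generator)) config$generator
    else generator_config(constructs = config$constructs, seed = config$seed)
    g <- generate_dyads(gen)
    d <- g$data
    truth <- g$truth
  }

  # distress covariate from the K6 screen
  k6 <- score_kessler6(as.matrix(as.data.frame(d)[, k6_cols()]))
  d$distress <- as.integer(k6$total >= 5)

  # weights
  if (!is.null(config$ipw_covariates) && any(d$complete == 0)) {
    ws <- build_weights(d, covariate_cols = config$ipw_covariates)
    w_all <- ws$combined
    weight_note <- "IPW x survey weight, mean 1 over analysed cases"
  } else {
    ws <- NULL
    w_all <- ifelse(d$complete == 1, d$svywt / mean(d$svywt[d$complete == 1]), NA)
    weight_note <- "survey weight only"
  }
  da <- d[d$complete == 1, , drop = FALSE]
  wa <- w_all[d$complete == 1]

  descriptives <- describe_items(da, config$constructs, weights = wa)

  gates <- list(); ladders <- list(); lds <- list(); conditional <- list()
  sensitivity <- list()
  for (k in config$constructs) {
    gates[[k]] <- tryCatch(
      gate_univariate_cfa(k, da, weights = wa,
                          cfi_min = config$gate[["cfi_min"]],
                          rmsea_max = config$gate[["rmsea_max"]]),
      error = function(e) { errors[[k]] <<- conditionMessage(e); list(pass = FALSE) })
    if (!isTRUE(gates[[k]]$pass)) next

    ladders[[k]] <- tryCatch(
      run_ladder(da, k, weights = wa, criteria = config$criteria,
                 mode = config$invariance_mode, estimation = config$estimation),
      error = function(e) { errors[[k]] <<- conditionMessage(e); NULL })
    if (is.null(ladders[[k]]) || !ladders[[k]]$scalar_established) next

    sp_lds <- build_lds_spec(ladders[[k]])
    lds[[k]] <- tryCatch(
      fit_lds(da, sp_lds, weights = wa, estimation = config$estimation),
      error = function(e) { errors[[k]] <<- conditionMessage(e); NULL })
    if (is.null(lds[[k]])) next

    for (mod in config$moderators) {
      sp_c <- build_conditional_lds(sp_lds, mod)
      conditional[[mod]][[k]] <- tryCatch(
        fit_conditional_lds(da, sp_c, mod, weights = wa,
                            estimation = config$estimation),
        error = function(e) {
          errors[[paste(k, mod, sep = ":")]] <<- conditionMessage(e); NULL })
    }

    if (config$sensitivity_fiml && config$estimation == "moments") {
      sensitivity[[k]] <- tryCatch(
        fit_lds(d, sp_lds, weights = NULL, estimation = "fiml"),
        error = function(e) {
          errors[[paste0(k, ":fiml")]] <<- conditionMessage(e); NULL })
    }
  }

  bundle <- structure(list(
    config = config, data_n = nrow(d), analysed_n = nrow(da),
    weight_note = weight_note, weights = ws,
    descriptives = descriptives, gates = gates, ladders = ladders,
    lds = lds, conditional = conditional, sensitivity = sensitivity,
    truth = truth, errors = errors
  ), class = "study_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' LDS results as a flat table
#'
#' @param bundle A `study_bundle` (or named list of `lds_result`s).
#' @return data.frame mirroring the unconditional-LDS report layout.
#' @export
lds_table <- function(bundle) {
  lst <- if (inherits(bundle, "study_bundle")) bundle$lds else bundle
  rows <- lapply(names(lst), function(k) {
    r <- lst[[k]]
    if (is.null(r)) return(NULL)
    e <- r$estimates
    gv <- function(q, col = "value") e[[col]][e$quantity == q]
    data.frame(construct = k, n = r$n,
               CFI = r$fit$fit$CFI, RMSEA = r$fit$fit$RMSEA, SRMR = r$fit$fit$SRMR,
               mean_std = gv("mean_std"), mean_std_stars = gv("mean_std", "stars"),
               variance = gv("variance"), variance_stars = gv("variance", "stars"),
               cov_std = gv("covariance_std"), cov_std_stars = gv("covariance_std", "stars"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Conditional-LDS results as a flat table
#'
#' @param bundle A `study_bundle`.
#' @param moderator Moderator name.
#' @return data.frame mirroring the conditional-model report layout (main
#'   standardized effects plus per-level estimates).
#' @export
conditional_table <- function(bundle, moderator) {
  lst <- bundle$conditional[[moderator]]
  rows <- lapply(names(lst), function(k) {
    r <- lst[[k]]
    if (is.null(r)) return(NULL)
    me <- r$main_effects; ge <- r$group_estimates
    data.frame(construct = k, moderator = moderator,
               beta_self_std = me$beta_std[me$factor == "self"],
               beta_self_stars = me$stars[me$factor == "self"],
               beta_delta_std = me$beta_std[me$factor == "discrepancy"],
               beta_delta_stars = me$stars[me$factor == "discrepancy"],
               ref_est = ge$est[ge$level == "reference"],
               ref_lo = ge$lo[ge$level == "reference"],
               ref_hi = ge$hi[ge$level == "reference"],
               other_est = ge$est[ge$level == "other"],
               other_lo = ge$lo[ge$level == "other"],
               other_hi = ge$hi[ge$level == "other"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# markdown renderer for a data.frame
.md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "-", formatC(round(x, digits), format = "fg"))
    else ifelse(is.na(x), "-", as.character(x))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Write a study bundle to disk
#'
#' CSV tables, markdown report, and a JSON manifest (seeds, sample sizes,
#' conventions, error log).
#'
#' @param bundle A `study_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$descriptives, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  md <- c("# Informant discrepancy study report", "",
          paste0("Analysed dyads: ", bundle$analysed_n, " of ", bundle$data_n,
                 " (", bundle$weight_note, ")"), "",
          "Conventions: marker identification; T = sum_g n_g * F_g; SRMR over",
          "covariance residuals only.", "")
  inv_rows <- list()
  for (k in names(bundle$ladders)) {
    rep <- bundle$ladders[[k]]
    if (is.null(rep)) next
    md <- c(md, format_invariance(rep), "")
    s <- rep$steps; s$construct <- k
    inv_rows[[k]] <- s
  }
  if (length(inv_rows)) {
    utils::write.csv(do.call(rbind, inv_rows), file.path(out_dir, "invariance.csv"),
                     row.names = FALSE)
  }
  lt <- lds_table(bundle)
  if (!is.null(lt)) {
    utils::write.csv(lt, file.path(out_dir, "lds.csv"), row.names = FALSE)
    md <- c(md, "## Latent difference scores", "", .md_table(lt), "")
  }
  for (mod in names(bundle$conditional)) {
    ct <- conditional_table(bundle, mod)
    if (is.null(ct)) next
    utils::write.csv(ct, file.path(out_dir, paste0("conditional_", mod, ".csv")),
                     row.names = FALSE)
    md <- c(md, paste0("## Conditional on ", mod), "", .md_table(ct), "")
  }
  if (length(bundle$sensitivity)) {
    st <- lds_table(bundle$sensitivity)
    if (!is.null(st) && nrow(st)) {
      mt <- lds_table(bundle)
      st$mean_std_delta <- st$mean_std - mt$mean_std[match(st$construct, mt$construct)]
      utils::write.csv(st, file.path(out_dir, "sensitivity_fiml.csv"), row.names = FALSE)
      md <- c(md, "## Sensitivity: FIML estimation", "", .md_table(st), "")
    }
  }
  writeLines(md, file.path(out_dir, "report.md"))
  manifest <- list(
    seed = bundle$config$seed,
    constructs = bundle$config$constructs,
    estimation = bundle$config$estimation,
    invariance_mode = bundle$config$invariance_mode,
    criteria = bundle$config$criteria,
    n_total = bundle$data_n, n_analysed = bundle$analysed_n,
    gates = lapply(bundle$gates, function(g) g$pass),
    accepted_steps = lapply(bundle$ladders, function(l) if (!is.null(l)) l$accepted),
    errors = bundle$errors
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(out_dir)
}
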