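# Synthetic dyad generator: two correlated reporter-specific latent factors
# per construct with a latent discrepancy, thresholded 3-point items,
# binary covariate effects on latent means, unit nonresponse and item MCAR.
#
# Generative model per construct and dyad i:
#   (eta_S, delta) ~ BVN((mu_S + b_S'x_i, alpha_d + b_d'x_i),
#                        [[psi_S^2, sigma_sd], [sigma_sd, phi_d^2]])
#   eta_P = eta_S + delta
#   y*_jr = nu_jr + lambda_jr * eta_r + e_jr,  e ~ N(0, theta_jr^2)
#   item  = #{tau < y*} in {0,1,2}, thresholds (0.5, 1.5) by default so the
#           ordinal item is the rounded continuous response clipped to 0..2.
# Items are generated ordinally but analysed as continuous downstream; that
# deliberate mismatch is the realistic test condition.

# Discrepancy truth defaults: standardized mean, variance of the difference
# factor, standardized self/difference covariance (difficulties negative,
# pro-social positive).
.construct_truth_defaults <- data.frame(
  construct = c("conduct", "emotion", "peer", "prosocial", "hyperactivity"),
  alpha_std = c(-0.898, -0.424, -0.195, 0.506, -0.60),
  phi_var   = c(0.097, 0.081, 0.105, 0.066, 0.090),
  cov_std   = c(-0.490, -0.579, -0.349, -0.477, -0.45),
  stringsAsFactors = FALSE
)

# Self-report item intercepts (0-2 metric), scored direction.
.construct_nu_defaults <- list(
  conduct       = c(0.53, 0.65, 0.15, 0.19, 0.11),
  emotion       = c(0.45, 1.07, 0.47, 1.05, 0.49),
  peer          = c(0.58, 0.16, 0.51, 0.13, 0.70),
  prosocial     = c(1.79, 1.49, 1.65, 1.77, 1.19),
  hyperactivity = c(0.90, 0.64, 0.93, 0.68, 0.77)
)

# Raw-metric covariate effects (male=1 / high distress=1 / high education=1)
# on the self factor and on the discrepancy factor, per construct.
.construct_beta_defaults <- list(
  conduct   = list(beta_self  = c(sex =  0.33, distress =  0.26, edu = -0.11),
                   beta_delta = c(sex = -0.05, distress =  0.05, edu = -0.04)),
  emotion   = list(beta_self  = c(sex = -0.69, distress =  0.16, edu =  0.01),
                   beta_delta = c(sex =  0.11, distress =  0.10, edu = -0.05)),
  peer      = list(beta_self  = c(sex = -0.04, distress =  0.28, edu = -0.23),
                   beta_delta = c(sex =  0.03, distress =  0.08, edu =  0.00)),
  prosocial = list(beta_self  = c(sex = -0.58, distress = -0.13, edu =  0.12),
                   beta_delta = c(sex =  0.07, distress = -0.02, edu = -0.01)),
  hyperactivity = list(beta_self  = c(sex = 0, distress = 0, edu = 0),
                       beta_delta = c(sex = 0, distress = 0, edu = 0))
)

# Freed-item pattern emulated by default: one loading and up to two
# intercepts per construct shifted on the parent side. Emotion and peer
# offsets sit on the items that were freed in the motivating analysis; the
# conduct and pro-social intercept offsets are moved off the first item
# because the marker convention pins its intercept (an offset there would be
# unrecoverable by partial invariance and would bias the latent means).
.default_noninvariance <- data.frame(
  construct = c("conduct", "conduct", "conduct", "emotion", "emotion",
                "peer", "peer", "prosocial"),
  reporter  = "parent",
  pos       = c(3L, 5L, 4L, 2L, 4L, 3L, 4L, 2L),
  parameter = c("loading", "intercept", "intercept", "intercept", "intercept",
                "intercept", "intercept", "intercept"),
  offset    = c(-0.25, 0.12, -0.10, -0.18, -0.22, -0.15, 0.10, 0.10),
  stringsAsFactors = FALSE
)

# K6 measurement: item = #{tau < 0.8*eta_D + 0.6*eps}; thresholds calibrated
# so that P(total >= 5) = 0.346.
.k6_loading <- 0.8
.k6_resid_sd <- 0.6
.k6_thresholds <- c(0.179, 0.979, 1.579, 2.079)

# Unit-nonresponse logistic defaults: intercept calibrated so marginal
# completeness is 0.646 (analysed dyads / wave sample) under the default
# covariate prevalences.
.default_missingness <- list(
  intercept = 0.4855,
  coef = c(sex = -0.1, distress = -0.3, edu = 0.5),
  item_mcar = 0.02
)

#' Per-construct generator settings
#'
#' Measurement and latent-truth settings for one construct. Defaults give a
#' marker-scaled factor (first loading 1) in the 0-2 item metric, with
#' discrepancy moments matching the magnitudes reported for the respective
#' SDQ subscale.
#'
#' @param construct Construct name.
#' @param lambda_self,lambda_parent Loadings (length 5, first is the marker).
#' @param nu_self,nu_parent Item intercepts (length 5).
#' @param theta_self,theta_parent Residual SDs (length 5, positive).
#' @param mu_self Latent self-report mean.
#' @param psi_self_sd Latent self-report SD (> 0).
#' @param alpha_delta Raw discrepancy mean (parent minus self).
#' @param phi_delta_sd Discrepancy SD (> 0).
#' @param sigma_sdelta Covariance of self factor and discrepancy.
#' @param tau Ordinal thresholds, strictly increasing length-2.
#' @param beta_self,beta_delta Named covariate effects (raw metric) on the
#'   self factor and on the discrepancy; names in `sex`, `distress`, `edu`.
#' @return A list of class `construct_config`.
#' @export
construct_config <- function(construct,
                             lambda_self = c(1, 0.9, 0.7, 0.8, 0.7),
                             lambda_parent = lambda_self,
                             nu_self = .construct_nu_defaults[[construct]],
                             nu_parent = nu_self,
                             theta_self = rep(0.45, 5),
                             theta_parent = theta_self,
                             mu_self = 0,
                             psi_self_sd = 0.45,
                             alpha_delta = NULL,
                             phi_delta_sd = NULL,
                             sigma_sdelta = NULL,
                             tau = c(0.5, 1.5),
                             beta_self = .construct_beta_defaults[[construct]]$beta_self,
                             beta_delta = .construct_beta_defaults[[construct]]$beta_delta) {
  construct <- match.arg(construct, sdq_constructs())
  tr <- .construct_truth_defaults[.construct_truth_defaults$construct == construct, ]
  if (is.null(phi_delta_sd)) phi_delta_sd <- sqrt(tr$phi_var)
  if (is.null(alpha_delta)) alpha_delta <- tr$alpha_std * phi_delta_sd
  if (is.null(sigma_sdelta)) sigma_sdelta <- tr$cov_std * phi_delta_sd * psi_self_sd
  stopifnot(length(lambda_self) == 5, length(lambda_parent) == 5,
            length(nu_self) == 5, length(nu_parent) == 5,
            length(theta_self) == 5, length(theta_parent) == 5,
            all(theta_self >= 0), all(theta_parent >= 0))
  if (psi_self_sd <= 0) stop("psi_self_sd must be positive")
  if (phi_delta_sd < 0) stop("phi_delta_sd must be nonnegative")
  if (abs(sigma_sdelta) > psi_self_sd * phi_delta_sd + 1e-12) {
    stop("invalid covariance: |sigma_sdelta| exceeds psi_self_sd * phi_delta_sd")
  }
  if (length(tau) != 2 || diff(tau) <= 0) stop("thresholds must be strictly increasing")
  structure(list(
    construct = construct,
    lambda = list(self = lambda_self, parent = lambda_parent),
    nu = list(self = nu_self, parent = nu_parent),
    theta = list(self = theta_self, parent = theta_parent),
    mu_self = mu_self, psi_self_sd = psi_self_sd,
    alpha_delta = alpha_delta, phi_delta_sd = phi_delta_sd,
    sigma_sdelta = sigma_sdelta, tau = tau,
    beta_self = beta_self, beta_delta = beta_delta
  ), class = "construct_config")
}

#' Generator configuration
#'
#' The full stated world of the synthetic cohort: sample size, per-construct
#' truth, covariate prevalences, measurement non-invariance, and the
#' missingness mechanism.
#'
#' @param n_dyads Number of dyads sampled (before unit nonresponse).
#' @param seed Integer RNG seed; everything downstream is deterministic in it.
#' @param constructs Constructs to generate.
#' @param construct_configs Optional named list of [construct_config()]
#'   overrides.
#' @param prevalence Named covariate prevalences: `sex` (male), `edu` (high);
#'   the high-distress rate is implied by the K6 measurement model (0.346 at
#'   default settings).
#' @param noninvariance data.frame with columns `construct`, `reporter`,
#'   `pos`, `parameter` (`"loading"`/`"intercept"`), `offset`; `NULL` for
#'   fully invariant measurement. Defaults emulate the freed-item pattern of
#'   the motivating analysis.
#' @param missingness List with `intercept`, `coef` (named logistic
#'   coefficients on `sex`, `distress`, `edu` for being a complete case) and
#'   `item_mcar` (item-level blanking rate among complete cases).
#' @param svywt_log_sd SD of the log-normal survey weight (mean 1 after
#'   normalization); 0 for unit weights.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_dyads = 10757, seed = 20181L,
                             constructs = c("conduct", "emotion", "peer", "prosocial"),
                             construct_configs = NULL,
                             prevalence = c(sex = 0.507, edu = 0.563),
                             noninvariance = .default_noninvariance,
                             missingness = .default_missingness,
                             svywt_log_sd = 0.3) {
  constructs <- match.arg(constructs, sdq_constructs(), several.ok = TRUE)
  cfgs <- lapply(constructs, construct_config)
  names(cfgs) <- constructs
  if (!is.null(construct_configs)) {
    for (k in names(construct_configs)) cfgs[[k]] <- construct_configs[[k]]
  }
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalences must lie in [0,1]")
  if (!is.null(noninvariance) && nrow(noninvariance)) {
    stopifnot(all(c("construct", "reporter", "pos", "parameter", "offset") %in%
                    names(noninvariance)))
    noninvariance <- noninvariance[noninvariance$construct %in% constructs, , drop = FALSE]
  }
  if (missingness$item_mcar < 0 || missingness$item_mcar > 1) {
    stop("item_mcar rate must lie in [0,1]")
  }
  structure(list(
    n_dyads = as.integer(n_dyads), seed = as.integer(seed),
    constructs = constructs, construct_configs = cfgs,
    prevalence = prevalence, noninvariance = noninvariance,
    missingness = missingness, svywt_log_sd = svywt_log_sd
  ), class = "generator_config")
}

# apply noninvariance offsets to one construct's measurement
.apply_offsets <- function(cc, noninv) {
  if (is.null(noninv) || !nrow(noninv)) return(cc)
  rows <- noninv[noninv$construct == cc$construct, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    r <- rows$reporter[i]; j <- rows$pos[i]
    if (rows$parameter[i] == "loading") {
      cc$lambda[[r]][j] <- cc$lambda[[r]][j] + rows$offset[i]
    } else if (rows$parameter[i] == "intercept") {
      cc$nu[[r]][j] <- cc$nu[[r]][j] + rows$offset[i]
    } else stop("unknown noninvariance parameter: ", rows$parameter[i])
  }
  cc
}

#' Generate a synthetic dyad cohort
#'
#' Draws covariates, latent factors, and thresholded ordinal items for
#' `config$n_dyads` dyads, then applies unit nonresponse and item-level
#' MCAR via [impose_missingness()]. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param apply_missingness Apply the missingness mechanism (default `TRUE`).
#' @return List with `data` (a `dyad_data` data.frame) and `truth` (class
#'   `synthetic_truth`: per-dyad latent draws, realized covariates, config,
#'   and missingness masks).
#' @export
generate_dyads <- function(config, apply_missingness = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_dyads

  # covariates: sex and education exogenous; distress derived from K6 items
  sex <- stats::rbinom(n, 1, config$prevalence[["sex"]])
  edu <- stats::rbinom(n, 1, config$prevalence[["edu"]])
  eta_d <- stats::rnorm(n)
  k6 <- matrix(0L, n, 6, dimnames = list(NULL, k6_cols()))
  for (j in 1:6) {
    ystar <- .k6_loading * eta_d + stats::rnorm(n, 0, .k6_resid_sd)
    k6[, j] <- as.integer(rowSums(outer(ystar, .k6_thresholds, ">")))
  }
  distress <- as.integer(rowSums(k6) >= 5)
  x <- cbind(sex = sex, distress = distress, edu = edu)

  svywt <- if (config$svywt_log_sd > 0) {
    w <- stats::rlnorm(n, 0, config$svywt_log_sd); w / mean(w)
  } else rep(1, n)

  d <- data.frame(dyad_id = seq_len(n))
  truth_lat <- list()
  for (k in config$constructs) {
    cc0 <- config$construct_configs[[k]]
    cc <- .apply_offsets(cc0, config$noninvariance)
    # covariate effects enter centered (x minus its design prevalence), so
    # the configured latent means stay the marginal moments
    prev <- c(sex = config$prevalence[["sex"]], distress = 0.346,
              edu = config$prevalence[["edu"]])
    xc <- sweep(x, 2, prev[colnames(x)])
    mu_s <- cc$mu_self + drop(xc[, names(cc$beta_self), drop = FALSE] %*% cc$beta_self)
    mu_d <- cc$alpha_delta + drop(xc[, names(cc$beta_delta), drop = FALSE] %*% cc$beta_delta)
    # bivariate normal via Cholesky
    S11 <- cc$psi_self_sd^2; S22 <- cc$phi_delta_sd^2; S12 <- cc$sigma_sdelta
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    l11 <- sqrt(S11)
    l21 <- if (l11 > 0) S12 / l11 else 0
    l22 <- sqrt(max(S22 - l21^2, 0))
    eta_s <- mu_s + l11 * z1
    delta <- mu_d + l21 * z1 + l22 * z2
    eta_p <- eta_s + delta
    truth_lat[[k]] <- data.frame(eta_self = eta_s, delta = delta, eta_parent = eta_p)
    for (r in c("self", "parent")) {
      eta <- if (r == "self") eta_s else eta_p
      cols <- item_cols(k, r)
      for (j in 1:5) {
        ystar <- cc$nu[[r]][j] + cc$lambda[[r]][j] * eta +
          stats::rnorm(n, 0, cc$theta[[r]][j])
        d[[cols[j]]] <- as.integer((ystar > cc$tau[1]) + (ystar > cc$tau[2]))
      }
    }
  }
  for (j in 1:6) d[[k6_cols()[j]]] <- k6[, j]
  d$sex <- sex; d$edu <- edu; d$svywt <- svywt; d$complete <- 1L

  truth <- structure(list(
    config = config, latents = truth_lat,
    covariates = data.frame(sex = sex, distress = distress, edu = edu),
    masks = NULL
  ), class = "synthetic_truth")

  if (apply_missingness) {
    res <- impose_missingness(d, config, covariates = truth$covariates)
    d <- res$data
    truth$masks <- res$masks
  }
  d <- validate_dyads(d, constructs = config$constructs)
  list(data = d, truth = truth)
}

#' Apply unit nonresponse and item-level MCAR
#'
#' Unit completeness is drawn from a logistic model on the observed
#' covariates; among complete cases, item cells are blanked independently at
#' the MCAR rate. Incomplete cases keep their covariates but lose all item
#' responses (they enter only the completeness model).
#'
#' @param d Dyad data.frame with all items observed.
#' @param config A [generator_config()] (its `missingness` entry is used).
#' @param covariates data.frame with `sex`, `distress`, `edu` per dyad; if
#'   `NULL`, distress is scored from the K6 columns.
#' @return List with `data` (masked) and `masks` (list: `complete` logical
#'   vector, `item` logical matrix of blanked cells).
#' @export
impose_missingness <- function(d, config, covariates = NULL) {
  mi <- config$missingness
  if (mi$item_mcar < 0 || mi$item_mcar > 1) stop("item_mcar rate must lie in [0,1]")
  if (is.null(covariates)) {
    distress <- as.integer(score_kessler6(as.matrix(d[, k6_cols()]))$total >= 5)
    covariates <- data.frame(sex = d$sex, distress = distress, edu = d$edu)
  }
  n <- nrow(d)
  lin <- mi$intercept +
    drop(as.matrix(covariates[, names(mi$coef), drop = FALSE]) %*% mi$coef)
  complete <- stats::rbinom(n, 1, stats::plogis(lin)) == 1
  itemcols <- unlist(lapply(config$constructs, function(k) {
    c(item_cols(k, "self"), item_cols(k, "parent"))
  }))
  mask <- matrix(FALSE, n, length(itemcols), dimnames = list(NULL, itemcols))
  if (mi$item_mcar > 0) {
    mask[complete, ] <- matrix(stats::runif(sum(complete) * length(itemcols)) < mi$item_mcar,
                               nrow = sum(complete))
  }
  for (cn in itemcols) {
    v <- d[[cn]]
    v[!complete] <- NA
    v[mask[, cn]] <- NA
    d[[cn]] <- v
  }
  d$complete <- as.integer(complete)
  list(data = d, masks = list(complete = complete, item = mask))
}

#' Calibrate the generator to target item moments
#'
#' Moment-matching for the ordinal marginals: for each targeted item, finds
#' the intercept `nu` and total continuous SD `s` such that the thresholded
#' 3-point variable has the target mean and SD, then splits `s` into factor
#' and residual parts (communality capped at 0.6 so residual SDs stay
#' positive). Item means/SDs are monotone in `nu`/`s`, so a 2-d root search
#' converges reliably.
#'
#' @param targets data.frame with columns `construct`, `reporter`, `pos`,
#'   `mean`, `sd` (e.g. the packaged `sdq_item_moments.csv`).
#' @param config Base [generator_config()] to calibrate; defaults to the
#'   package defaults restricted to the targeted constructs.
#' @param tol Tolerance on achieved population moments.
#' @return The calibrated `generator_config`; achieved population moments in
#'   attribute `"achieved"`.
#' @export
calibrate_to_moments <- function(targets, config = NULL, tol = 0.05) {
  stopifnot(all(c("construct", "reporter", "pos", "mean", "sd") %in% names(targets)))
  if (is.null(config)) {
    config <- generator_config(constructs = unique(targets$construct),
                               noninvariance = NULL)
  }
  achieved <- targets
  achieved$mean_achieved <- NA_real_
  achieved$sd_achieved <- NA_real_
  for (i in seq_len(nrow(targets))) {
    k <- targets$construct[i]; r <- targets$reporter[i]; j <- targets$pos[i]
    m <- targets$mean[i]; s <- targets$sd[i]
    if (m < 0 || m > 2) stop("infeasible target mean ", m, " for a 0-2 item")
    # Bhatia-Davis bound for a variable on [0,2]
    if (s^2 > m * (2 - m) + 1e-9) {
      stop("infeasible target: SD ", s, " exceeds the 3-point maximum for mean ", m)
    }
    cc <- config$construct_configs[[k]]
    sol <- .solve_item_moments(m, s, cc$tau)
    lam <- cc$lambda[[r]][j]
    lat_sd <- if (r == "self") cc$psi_self_sd else
      sqrt(cc$psi_self_sd^2 + cc$phi_delta_sd^2 + 2 * cc$sigma_sdelta)
    # mean of the latent this item loads on (self mean is mu_self; parent adds alpha)
    lat_mu <- cc$mu_self + if (r == "parent") cc$alpha_delta else 0
    # cap communality so theta^2 > 0
    if ((lam * lat_sd)^2 > 0.6 * sol$s^2) {
      lam <- sqrt(0.6) * sol$s / lat_sd
      cc$lambda[[r]][j] <- lam
    }
    cc$theta[[r]][j] <- sqrt(sol$s^2 - (lam * lat_sd)^2)
    cc$nu[[r]][j] <- sol$nu - lam * lat_mu
    config$construct_configs[[k]] <- cc
    mm <- .ordinal_moments(sol$nu, sol$s, cc$tau)
    achieved$mean_achieved[i] <- mm$mean
    achieved$sd_achieved[i] <- mm$sd
    if (abs(mm$mean - m) > tol || abs(mm$sd - s) > tol) {
      stop("calibration failed for ", k, " ", r, " item ", j,
           ": achieved (", round(mm$mean, 3), ", ", round(mm$sd, 3), ")")
    }
  }
  attr(config, "achieved") <- achieved
  config
}

# population mean/sd of #{tau < N(nu, s^2)}
.ordinal_moments <- function(nu, s, tau) {
  if (s < 1e-8) {
    v <- (nu > tau[1]) + (nu > tau[2])
    return(list(mean = v, sd = 0))
  }
  p1 <- stats::pnorm((nu - tau[1]) / s)  # P(X >= 1)
  p2 <- stats::pnorm((nu - tau[2]) / s)  # P(X = 2)
  m <- p1 + p2
  list(mean = m, sd = sqrt(p1 + 3 * p2 - m^2))
}

# invert .ordinal_moments for (nu, s)
.solve_item_moments <- function(m, s, tau) {
  if (s < 1e-8) {
    # degenerate: all mass in one category; place nu inside the band
    nu <- if (m < 0.5) tau[1] - 1 else if (m < 1.5) 0.5 * sum(tau) else tau[2] + 1
    return(list(nu = nu, s = 1e-9))
  }
  obj <- function(par) {
    mm <- .ordinal_moments(par[1], exp(par[2]), tau)
    (mm$mean - m)^2 + (mm$sd - s)^2
  }
  best <- NULL
  for (s0 in c(log(s), log(s) + 0.5, log(s) - 0.5)) {
    o <- stats::optim(c(m, s0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(nu = best$par[1], s = exp(best$par[2]))
}

#' Write the truth sidecar
#'
#' Serializes a `synthetic_truth` (config and per-dyad latent draws) to JSON
#' next to the generated CSV.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    config = unclass_recursive(truth$config),
    covariates = truth$covariates,
    latents = truth$latents,
    complete = if (!is.null(truth$masks)) truth$masks$complete else NULL
  )
  jsonlite::write_json(out, path, digits = 10, auto_unbox = TRUE)
  invisible(path)
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}
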