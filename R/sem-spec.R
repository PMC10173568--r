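# Symbolic SEM specification with mean structure.
#
# A spec holds six pattern matrices in LISREL all-y form:
#   lambda (p x m loadings), nu (p intercepts), theta (p x p residual
#   covariance), beta (m x m latent regressions), psi (m x m latent
#   disturbance covariance), alpha (m latent intercepts/means).
# Each cell carries a label (character; NA = fixed) and a value (the fixed
# value, or a start value for free cells; NA = auto start). Cells sharing a
# label are constrained equal -- within and across groups, which is how
# cross-reporter equality is expressed. Implied moments:
#   Sigma = L (I-B)^-1 Psi (I-B)^-T L' + Theta
#   mu    = nu + L (I-B)^-1 alpha

#' Create an empty SEM specification
#'
#' All cells start fixed at 0; use [sp_free()] and [sp_fix()] to populate.
#'
#' @param observed Character vector of observed variable names.
#' @param latent Character vector of latent variable names.
#' @return An object of class `sem_spec`.
#' @export
sem_spec <- function(observed, latent) {
  p <- length(observed); m <- length(latent)
  if (anyDuplicated(c(observed, latent))) stop("variable names must be unique")
  mk <- function(nr, nc, rn, cn) {
    list(label = matrix(NA_character_, nr, nc, dimnames = list(rn, cn)),
         value = matrix(0, nr, nc, dimnames = list(rn, cn)))
  }
  structure(list(
    observed = observed, latent = latent,
    lambda = mk(p, m, observed, latent),
    nu     = mk(p, 1, observed, "nu"),
    theta  = mk(p, p, observed, observed),
    beta   = mk(m, m, latent, latent),
    psi    = mk(m, m, latent, latent),
    alpha  = mk(m, 1, latent, "alpha")
  ), class = "sem_spec")
}

.sp_idx <- function(spec, matrix, row, col) {
  M <- spec[[matrix]]
  i <- if (is.character(row)) match(row, rownames(M$label)) else row
  j <- if (is.null(col)) 1L else if (is.character(col)) match(col, colnames(M$label)) else col
  if (is.na(i) || is.na(j)) stop("unknown variable in ", matrix, ": ", row, ", ", col)
  c(i, j)
}

#' Fix or free a spec cell
#'
#' `sp_fix()` fixes a cell to a value; `sp_free()` frees it under a label
#' (cells sharing a label are constrained equal). For the symmetric
#' matrices (`theta`, `psi`) both (i,j) and (j,i) are set.
#'
#' @param spec A [sem_spec()].
#' @param matrix One of `"lambda"`, `"nu"`, `"theta"`, `"beta"`, `"psi"`,
#'   `"alpha"`.
#' @param row,col Variable names (or indices); `col` is ignored for the
#'   vector matrices `nu` and `alpha`.
#' @param value Fixed value (`sp_fix`).
#' @param label Parameter label (`sp_free`).
#' @param start Optional start value (`NA` = data-driven default).
#' @return The modified spec.
#' @export
sp_fix <- function(spec, matrix, row, col = NULL, value = 0) {
  ij <- .sp_idx(spec, matrix, row, col)
  spec[[matrix]]$label[ij[1], ij[2]] <- NA_character_
  spec[[matrix]]$value[ij[1], ij[2]] <- value
  if (matrix %in% c("theta", "psi")) {
    spec[[matrix]]$label[ij[2], ij[1]] <- NA_character_
    spec[[matrix]]$value[ij[2], ij[1]] <- value
  }
  spec
}

#' @rdname sp_fix
#' @export
sp_free <- function(spec, matrix, row, col = NULL, label, start = NA_real_) {
  ij <- .sp_idx(spec, matrix, row, col)
  spec[[matrix]]$label[ij[1], ij[2]] <- label
  spec[[matrix]]$value[ij[1], ij[2]] <- start
  if (matrix %in% c("theta", "psi")) {
    spec[[matrix]]$label[ij[2], ij[1]] <- label
    spec[[matrix]]$value[ij[2], ij[1]] <- start
  }
  spec
}

# all labels used in a spec (or list of specs), in first-appearance order
spec_labels <- function(specs) {
  if (inherits(specs, "sem_spec")) specs <- list(specs)
  out <- character(0)
  for (sp in specs) {
    for (mn in c("lambda", "nu", "theta", "beta", "psi", "alpha")) {
      lab <- sp[[mn]]$label
      lab <- lab[!is.na(lab)]
      out <- c(out, lab[!(lab %in% out)])
      out <- unique(out)
    }
  }
  out
}

# Compile one or more group specs into the internal form used by the
# optimizer: global parameter vector + per-group cell maps.
compile_spec <- function(specs) {
  if (inherits(specs, "sem_spec")) specs <- list(specs)
  params <- spec_labels(specs)
  k <- length(params)
  start <- rep(NA_real_, k); names(start) <- params
  lower <- rep(-Inf, k); names(lower) <- params
  maps <- vector("list", length(specs))
  for (g in seq_along(specs)) {
    sp <- specs[[g]]
    cells <- list()
    for (mn in c("lambda", "nu", "theta", "beta", "psi", "alpha")) {
      lab <- sp[[mn]]$label
      idx <- which(!is.na(lab), arr.ind = TRUE)
      if (!nrow(idx)) next
      if (mn %in% c("theta", "psi")) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        pid <- match(lab[i, j], params)
        cells[[length(cells) + 1L]] <- list(matrix = mn, i = i, j = j, param = pid)
        v <- sp[[mn]]$value[i, j]
        if (!is.na(v) && is.na(start[pid])) start[pid] <- v
        if (mn %in% c("theta", "psi") && i == j) lower[pid] <- 1e-6
      }
    }
    maps[[g]] <- cells
  }
  list(specs = specs, params = params, start = start, lower = lower, maps = maps)
}

# materialize numeric matrices for group g at parameter vector th
fill_matrices <- function(cspec, th, g = 1L) {
  sp <- cspec$specs[[g]]
  mats <- list(lambda = sp$lambda$value, nu = sp$nu$value, theta = sp$theta$value,
               beta = sp$beta$value, psi = sp$psi$value, alpha = sp$alpha$value)
  for (cell in cspec$maps[[g]]) {
    v <- th[cell$param]
    mats[[cell$matrix]][cell$i, cell$j] <- v
    if (cell$matrix %in% c("theta", "psi")) mats[[cell$matrix]][cell$j, cell$i] <- v
  }
  mats
}

#' Serialize / read a spec as plain text
#'
#' One line per non-trivial cell: `matrix row col kind value`, where `kind`
#' is `fixed` or the parameter label. Round-trips through [read_spec()].
#'
#' @param spec A [sem_spec()].
#' @param path Output/input file path.
#' @return `path` invisibly (`write_spec`); a `sem_spec` (`read_spec`).
#' @export
write_spec <- function(spec, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat("# sem_spec", length(spec$observed), length(spec$latent), "\n", file = con)
  cat("observed", paste(spec$observed, collapse = ","), "\n", file = con)
  cat("latent", paste(spec$latent, collapse = ","), "\n", file = con)
  for (mn in c("lambda", "nu", "theta", "beta", "psi", "alpha")) {
    lab <- spec[[mn]]$label; val <- spec[[mn]]$value
    for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
      if (mn %in% c("theta", "psi") && j < i) next
      if (is.na(lab[i, j]) && val[i, j] == 0) next
      kind <- if (is.na(lab[i, j])) "fixed" else lab[i, j]
      cat(mn, rownames(lab)[i], colnames(lab)[j], kind,
          format(val[i, j], digits = 12), "\n", file = con)
    }
  }
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  lines <- readLines(path)
  obs <- strsplit(sub("^observed ", "", lines[grepl("^observed ", lines)]), ",")[[1]]
  lat <- strsplit(sub("^latent ", "", lines[grepl("^latent ", lines)]), ",")[[1]]
  obs <- trimws(obs); lat <- trimws(lat)
  spec <- sem_spec(obs, lat)
  body <- lines[!grepl("^(#|observed |latent )", lines) & nzchar(lines)]
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    mn <- f[1]; row <- f[2]; col <- f[3]; kind <- f[4]
    value <- if (f[5] == "NA") NA_real_ else as.numeric(f[5])
    col2 <- if (mn %in% c("nu", "alpha")) NULL else col
    spec <- if (kind == "fixed") sp_fix(spec, mn, row, col2, value)
    else sp_free(spec, mn, row, col2, kind, value)
  }
  spec
}
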