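# Dyad-level CSV dialect: one row per parent-adolescent dyad.
# Columns: dyad_id, <construct>_<reporter>_i{1..5}, k6_i{1..6},
# sex, edu, svywt, complete. Missing cells are blank.

#' Item column names for a construct/reporter pair
#'
#' @param construct Subscale name.
#' @param reporter `"self"` or `"parent"`.
#' @return Character vector of 5 column names.
#' @export
item_cols <- function(construct, reporter = c("self", "parent")) {
  construct <- match.arg(construct, sdq_constructs())
  reporter <- match.arg(reporter)
  paste0(construct, "_", reporter, "_i", 1:5)
}

k6_cols <- function() paste0("k6_i", 1:6)

#' Read a dyad CSV
#'
#' Reads and validates the package's dyad-level CSV dialect. Ratings are
#' checked against their declared ranges (0-2 for subscale items, 0-4 for
#' distress items); `sex`/`edu` must be coded 0/1 (female and lower
#' education are the reference categories); survey weights must be
#' nonnegative.
#'
#' @param path CSV file path.
#' @param constructs Constructs whose item columns must be present.
#' @return A validated data.frame of class `dyad_data`.
#' @export
read_dyads <- function(path, constructs = c("conduct", "emotion", "peer", "prosocial")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dyads(d, constructs = constructs)
}

#' Validate a dyad data.frame
#'
#' @param d data.frame in the dyad dialect.
#' @param constructs Constructs whose item columns must be present.
#' @return `d` with class `dyad_data` prepended.
#' @export
validate_dyads <- function(d, constructs = c("conduct", "emotion", "peer", "prosocial")) {
  constructs <- match.arg(constructs, sdq_constructs(), several.ok = TRUE)
  need <- c("dyad_id", unlist(lapply(constructs, function(k) {
    c(item_cols(k, "self"), item_cols(k, "parent"))
  })), k6_cols(), "sex", "edu", "svywt", "complete")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (k in constructs) for (r in c("self", "parent")) {
    for (cn in item_cols(k, r)) {
      v <- d[[cn]]
      if (any(!is.na(v) & (v < 0 | v > 2 | v != round(v)))) {
        stop("rating out of range 0..2 in column ", cn)
      }
    }
  }
  for (cn in k6_cols()) {
    v <- d[[cn]]
    if (any(!is.na(v) & (v < 0 | v > 4 | v != round(v)))) {
      stop("rating out of range 0..4 in column ", cn)
    }
  }
  for (cn in c("sex", "edu")) {
    v <- d[[cn]]
    if (any(!is.na(v) & !(v %in% c(0, 1)))) stop(cn, " must be coded 0/1")
  }
  if (any(!is.na(d$svywt) & d$svywt < 0)) stop("survey weights must be nonnegative")
  if (any(!is.na(d$complete) & !(d$complete %in% c(0, 1)))) {
    stop("complete flag must be coded 0/1")
  }
  class(d) <- unique(c("dyad_data", class(d)))
  d
}

#' Write a dyad CSV
#'
#' Deterministic writer (fixed column order, no row names, blank for `NA`)
#' so identical data produce byte-identical files.
#'
#' @param d Dyad data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dyads <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Item-level descriptives
#'
#' Item means and standard deviations per construct and reporter, computed
#' on available (pairwise-complete) ratings among complete dyads.
#'
#' @param d Dyad data.frame.
#' @param constructs Constructs to describe.
#' @param weights Optional nonnegative weights (length `nrow(d)`).
#' @return data.frame with `construct`, `reporter`, `item`, `pos`, `mean`, `sd`, `n`.
#' @export
describe_items <- function(d, constructs = c("conduct", "emotion", "peer", "prosocial"),
                           weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(d))
  out <- list()
  for (k in constructs) {
    dict <- sdq_items(k)
    for (r in c("parent", "self")) {
      cols <- item_cols(k, r)
      for (j in 1:5) {
        v <- d[[cols[j]]]
        ok <- !is.na(v) & !is.na(weights)
        w <- weights[ok]; x <- v[ok]
        mu <- sum(w * x) / sum(w)
        sdv <- sqrt(sum(w * (x - mu)^2) / sum(w))
        out[[length(out) + 1L]] <- data.frame(
          construct = k, reporter = r, item = dict$item[j], pos = j,
          mean = mu, sd = sdv, n = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
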