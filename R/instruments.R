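# SDQ-style subscale definitions and deterministic scoring, plus the
# Kessler-6 distress screen and covariate recoding.

#' SDQ subscale dictionary
#'
#' Returns the built-in item dictionary for the five 5-item SDQ subscales:
#' item numbers on the 25-item form, reverse-scoring flags, and the parent-
#' and self-report item wording. Items are matched by position/id throughout
#' the package; the wording is metadata only.
#'
#' @param construct Optional subscale name; one of `"conduct"`, `"emotion"`,
#'   `"peer"`, `"prosocial"`, `"hyperactivity"`. If `NULL`, the full
#'   dictionary is returned.
#' @return A data.frame with columns `construct`, `item` (form item number),
#'   `pos` (1-5 within subscale), `reverse` (logical), `parent_text`,
#'   `self_text`.
#' @export
sdq_items <- function(construct = NULL) {
  d <- sdq_item_dictionary
  if (!is.null(construct)) {
    construct <- match.arg(construct, sdq_constructs())
    d <- d[d$construct == construct, , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

#' @rdname sdq_items
#' @export
sdq_constructs <- function() {
  c("conduct", "emotion", "peer", "prosocial", "hyperactivity")
}

# internal dictionary; wording follows the wave-7 parent and self forms
sdq_item_dictionary <- local({
  rows <- list(
    # construct, item, pos, reverse, parent text, self text
    list("conduct",        5, 1, FALSE, "Often has temper tantrums or hot tempers", "I get very angry"),
    list("conduct",        7, 2, TRUE,  "Generally obedient",                        "I usually do as I am told"),
    list("conduct",       12, 3, FALSE, "Often fights with other children",          "I fight a lot"),
    list("conduct",       18, 4, FALSE, "Often lies or cheats",                      "I am often accused of lying or cheating"),
    list("conduct",       22, 5, FALSE, "Steals from home, school, or elsewhere",    "I take things that are not mine"),
    list("emotion",        3, 1, FALSE, "Often complains of headaches",              "I get a lot of headaches"),
    list("emotion",        8, 2, FALSE, "Many worries",                              "I worry a lot"),
    list("emotion",       13, 3, FALSE, "Often unhappy, downhearted",                "I am often unhappy"),
    list("emotion",       16, 4, FALSE, "Nervous or clingy in new situations",       "I am nervous in new situations"),
    list("emotion",       24, 5, FALSE, "Many fears, easily scared",                 "I have many fears"),
    list("peer",           6, 1, FALSE, "Rather solitary, tends to play alone",      "I am usually on my own"),
    list("peer",          11, 2, TRUE,  "Has at least one good friend",              "I have one good friend or more"),
    list("peer",          14, 3, TRUE,  "Generally liked by other children",         "Other people my age generally like me"),
    list("peer",          19, 4, FALSE, "Picked on or bullied by other children",    "Other children or young people pick on me"),
    list("peer",          23, 5, FALSE, "Gets on better with adults than with other children", "I get on better with adults than with people my age"),
    list("prosocial",      1, 1, FALSE, "Considerate of other people's feelings",    "I try to be nice to other people"),
    list("prosocial",      4, 2, FALSE, "Shares readily with other children",        "I usually share with others"),
    list("prosocial",      9, 3, FALSE, "Helpful if someone is hurt",                "I am helpful if someone is hurt"),
    list("prosocial",     17, 4, FALSE, "Kind to younger children",                  "I am kind to younger children"),
    list("prosocial",     20, 5, FALSE, "Often volunteers to help others",           "I often volunteer to help others"),
    list("hyperactivity",  2, 1, FALSE, "Restless, overactive",                      "I am restless"),
    list("hyperactivity", 10, 2, FALSE, "Constantly fidgeting or squirming",         "I am constantly fidgeting"),
    list("hyperactivity", 15, 3, FALSE, "Easily distracted, concentration wanders",  "I am easily distracted"),
    list("hyperactivity", 21, 4, TRUE,  "Thinks things out before acting",           "I think before I do things"),
    list("hyperactivity", 25, 5, TRUE,  "Sees tasks through to the end",             "I finish the work I am doing")
  )
  data.frame(
    construct   = vapply(rows, `[[`, "", 1),
    item        = vapply(rows, `[[`, 0, 2),
    pos         = vapply(rows, `[[`, 0, 3),
    reverse     = vapply(rows, `[[`, TRUE, 4),
    parent_text = vapply(rows, `[[`, "", 5),
    self_text   = vapply(rows, `[[`, "", 6),
    stringsAsFactors = FALSE
  )
})

#' Subscale definition
#'
#' Bundles the scoring metadata for one reporter-specific 5-item subscale.
#'
#' @param name Subscale name (one of [sdq_constructs()]).
#' @param reporter `"self"` or `"parent"`.
#' @param item_ids Optional ordered item labels; defaults to the dictionary's
#'   form item numbers.
#' @param reverse_mask Optional logical vector of length 5; defaults to the
#'   dictionary flags.
#' @return An object of class `subscale_definition`.
#' @export
subscale_definition <- function(name, reporter = c("self", "parent"),
                                item_ids = NULL, reverse_mask = NULL) {
  name <- match.arg(name, sdq_constructs())
  reporter <- match.arg(reporter)
  dict <- sdq_items(name)
  if (is.null(item_ids)) item_ids <- paste0(name, "_", reporter, "_i", dict$pos)
  if (is.null(reverse_mask)) reverse_mask <- dict$reverse
  if (length(item_ids) != 5L) stop("a subscale has exactly 5 items, got ", length(item_ids))
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  if (length(reverse_mask) != 5L || !is.logical(reverse_mask)) {
    stop("reverse_mask must be 5 logical values")
  }
  structure(
    list(name = name, reporter = reporter, item_ids = item_ids,
         reverse_mask = reverse_mask),
    class = "subscale_definition"
  )
}

#' Reverse-score an item rating
#'
#' Reflects a frequency rating about the midpoint of its scale:
#' `max_value - value`. Missing values propagate.
#'
#' @param value Integer rating(s), `0..max_value`, `NA` allowed.
#' @param max_value Top of the rating scale (2 for SDQ items, 4 for K6).
#' @param item Optional item label used in error messages.
#' @return The reflected rating(s).
#' @export
reverse_score <- function(value, max_value, item = NULL) {
  bad <- !is.na(value) & (value < 0 | value > max_value | value != round(value))
  if (any(bad)) {
    stop("rating out of range 0..", max_value,
         if (!is.null(item)) paste0(" for item ", item) else "",
         ": ", paste(value[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  }
  max_value - value
}

#' Score a 5-item subscale
#'
#' Sum score on 0-10 after applying the definition's reverse mask.
#' Any missing item yields a missing score (complete-case scoring; the
#' latent pipeline, not pro-rating, is the package's missing-data strategy).
#'
#' @param items Numeric vector of 5 ratings in 0-2 (`NA` allowed), or a
#'   data.frame/matrix whose columns are the definition's `item_ids`.
#' @param def A [subscale_definition()].
#' @return Sum score(s) 0-10, `NA` where any item is missing.
#' @export
score_subscale <- function(items, def) {
  stopifnot(inherits(def, "subscale_definition"))
  if (is.data.frame(items) || is.matrix(items)) {
    cols <- colnames(items)
    if (is.null(cols) || !all(def$item_ids %in% cols)) {
      stop("items must carry the definition's item_ids as column names; ",
           "positional input without ids is refused")
    }
    m <- as.matrix(items[, def$item_ids, drop = FALSE])
  } else {
    if (length(items) != 5L) stop("a subscale score needs exactly 5 items, got ", length(items))
    m <- matrix(items, nrow = 1)
    colnames(m) <- def$item_ids
  }
  for (j in seq_len(5L)) {
    v <- m[, j]
    bad <- !is.na(v) & (v < 0 | v > 2 | v != round(v))
    if (any(bad)) stop("rating out of range 0..2 for item ", def$item_ids[j])
    if (def$reverse_mask[j]) m[, j] <- 2 - v
  }
  out <- rowSums(m)           # NA propagates
  if (length(items) == 5L && !is.data.frame(items) && !is.matrix(items)) out <- unname(out)
  out
}

#' Score the Kessler-6 distress screen
#'
#' Sums six 0-4 frequency items to a 0-24 total and applies the
#' greater-than-moderate cutoff (total >= 5) to classify distress.
#'
#' @param items Numeric vector of 6 ratings in 0-4, or a matrix/data.frame
#'   with 6 columns (one row per respondent). `NA` allowed; any missing item
#'   yields a missing total and class.
#' @param cutoff Total at or above which distress is classed `"high"`.
#' @return A list (vector input) or data.frame (matrix input) with `total`
#'   (0-24) and `distress` (`"low"`/`"high"`, `NA` if total missing).
#' @export
score_kessler6 <- function(items, cutoff = 5) {
  vec_in <- !(is.data.frame(items) || is.matrix(items))
  m <- if (vec_in) matrix(items, nrow = 1) else as.matrix(items)
  if (ncol(m) != 6L) stop("the distress screen has exactly 6 items, got ", ncol(m))
  bad <- !is.na(m) & (m < 0 | m > 4 | m != round(m))
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, 2]
    stop("distress rating out of range 0..4 in item ", j)
  }
  total <- rowSums(m)
  cls <- ifelse(is.na(total), NA_character_, ifelse(total >= cutoff, "high", "low"))
  if (vec_in) list(total = unname(total), distress = unname(cls))
  else data.frame(total = total, distress = cls, stringsAsFactors = FALSE)
}

#' Binarize parental education
#'
#' Maps NVQ-equivalent qualification codes to the low/high contrast used for
#' conditioning: `"high"` for NVQ level 4 and above (degree or equivalent),
#' `"low"` for level 3 and below or no qualification.
#'
#' @param level Integer code(s) 1-5, the string `"none"`, or `NA`.
#' @return Character vector `"low"`/`"high"` (`NA` propagates).
#' @export
binarize_education <- function(level) {
  out <- rep(NA_character_, length(level))
  for (i in seq_along(level)) {
    x <- level[[i]]
    if (is.na(x)) next
    if (identical(x, "none") || identical(x, 0) || identical(x, 0L)) {
      out[i] <- "low"
    } else if (is.numeric(x) && x == round(x) && x >= 1 && x <= 5) {
      out[i] <- if (x >= 4) "high" else "low"
    } else {
      stop("unknown qualification code: ", format(x))
    }
  }
  out
}
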