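#' Read a reference association list from TSV
#'
#' Two columns, `pathogen_id` and `disease_id`, one pair per line; lines
#' starting with `#` are comments. Identifiers must already use the same
#' CURIE spaces as the extraction output.
#'
#' @param path TSV file.
#' @param name Name for the reference set (defaults to the file stem).
#' @return A `reference_set`: list with `name` and `pairs` (character
#'   vector of tab-separated id pairs).
#' @export
read_reference_tsv <- function(path, name = sub("\\.[^.]*$", "",
                                                basename(path))) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          quote = "")
  if (nrow(df) && identical(tolower(df[1, 1]), "pathogen_id")) {
    df <- df[-1, , drop = FALSE]
  }
  structure(list(name = name,
                 pairs = unique(pair_key(df[[1]], df[[2]]))),
            class = "reference_set")
}

#' Build a reference set from id pairs
#'
#' @param pathogen_ids,disease_ids Parallel character vectors.
#' @param name Set name.
#' @return A `reference_set`.
#' @export
reference_set <- function(pathogen_ids, disease_ids, name = "reference") {
  structure(list(name = name,
                 pairs = unique(pair_key(pathogen_ids, disease_ids))),
            class = "reference_set")
}

assoc_pairs <- function(x) {
  if (inherits(x, "reference_set")) return(x$pairs)
  if (is.data.frame(x)) return(unique(pair_key(x$pathogen_id, x$disease_id)))
  unique(as.character(x))
}

#' Recall of extracted associations against one reference resource
#'
#' @param extracted Extracted pairs: a data.frame with `pathogen_id` and
#'   `disease_id`, a `reference_set`, or a character vector of pair keys.
#' @param ref A non-empty `reference_set`.
#' @return List with `recall` (fraction of reference pairs recovered),
#'   `found` and `missed` (character vectors partitioning `ref$pairs`).
#'   Matching is strict at the exact-class level; no credit is given for
#'   ancestor or descendant near-misses.
#' @export
recall_against <- function(extracted, ref) {
  stopifnot(inherits(ref, "reference_set"))
  if (!length(ref$pairs)) stop("empty reference set: ", ref$name)
  ex <- assoc_pairs(extracted)
  found <- intersect(ref$pairs, ex)
  list(recall = length(found) / length(ref$pairs),
       found = found,
       missed = setdiff(ref$pairs, found))
}

#' Overlap partition of several pair sets
#'
#' For every non-empty membership signature (which of the named sets a
#' pair belongs to), the number of pairs with exactly that signature —
#' the counts behind a Venn/upset diagram of literature-mined versus
#' curated associations. Signature names are the member set names joined
#' with `+` in input order.
#'
#' @param sets Named list (length >= 2) of pair collections (each a
#'   data.frame, `reference_set`, or character vector of pair keys).
#' @return Named integer vector: signature -> count. Counts sum to the
#'   size of the union of all sets.
#' @export
overlap_partition <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  members <- lapply(sets, assoc_pairs)
  universe <- unique(unlist(members, use.names = FALSE))
  if (!length(universe)) return(stats::setNames(integer(0), character(0)))
  sig <- vapply(universe, function(p) {
    paste(names(sets)[vapply(members, function(m) p %in% m, logical(1))],
          collapse = "+")
  }, character(1))
  tab <- table(sig)
  stats::setNames(as.integer(tab), names(tab))
}

#' Score a manually labeled sample of predictions
#'
#' Each prediction is an accepted/rejected call for a pair; each label
#' says whether the pair is a true association. Standard confusion
#' counts follow, with precision, recall and F1. Degenerate denominators
#' yield `NaN` with a warning rather than an error.
#'
#' @param predictions Data.frame with columns `pathogen_id`, `disease_id`,
#'   `accepted` (logical).
#' @param labels Data.frame with columns `pathogen_id`, `disease_id`,
#'   `true_association` (logical). Every prediction must be labeled.
#' @return List with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f_score`.
#' @export
score_labeled_sample <- function(predictions, labels) {
  pk <- pair_key(predictions$pathogen_id, predictions$disease_id)
  lk <- pair_key(labels$pathogen_id, labels$disease_id)
  if (anyDuplicated(lk)) stop("duplicate labels for a pair")
  miss <- setdiff(pk, lk)
  if (length(miss)) {
    stop("unlabeled prediction(s): ",
         paste(gsub("\t", "/", utils::head(miss, 3)), collapse = ", "))
  }
  truth <- labels$true_association[match(pk, lk)]
  acc <- predictions$accepted
  tp <- sum(acc & truth)
  fp <- sum(acc & !truth)
  fn <- sum(!acc & truth)
  tn <- sum(!acc & !truth)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f_score <- if (is.nan(precision) || is.nan(recall) ||
                 (precision + recall) == 0) {
    if (!is.nan(precision) && !is.nan(recall)) {
      warning("f_score undefined (zero denominator)", call. = FALSE)
    }
    NaN
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f_score = f_score)
}
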