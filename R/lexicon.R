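#' Normalize a surface form for dictionary keying
#'
#' Trims, collapses internal whitespace, and lowercases — except that
#' all-uppercase forms of at most `max_upper` characters are preserved
#' verbatim. Short all-caps strings are typically abbreviations (e.g.
#' "ALS"), and folding their case would merge them with unrelated common
#' words; they are therefore matched case-sensitively downstream.
#'
#' @param x Character vector of surface forms.
#' @param max_upper Maximum length of an all-uppercase form kept verbatim.
#' @return Character vector of normalized forms.
#' @export
normalize_term <- function(x, max_upper = 5L) {
  x <- gsub("[[:space:]]+", " ", trimws(x))
  keep <- nchar(x) <= max_upper & grepl("^[A-Z0-9]+$", x) & grepl("[A-Z]", x)
  x[!keep] <- tolower(x[!keep])
  x
}

is_case_sensitive_form <- function(x, max_upper = 5L) {
  nchar(x) <= max_upper & grepl("^[A-Z0-9]+$", x) & grepl("[A-Z]", x)
}

#' Refine a set of candidate dictionary terms
#'
#' Drops terms shorter than `min_length` characters (after whitespace
#' trimming) and terms whose normalized form is on the stoplist. The
#' stoplist guards against ontology labels that collide with common
#' English words or geographic names ("Arabia" as a taxon synonym);
#' matching against it is case-insensitive.
#'
#' @param terms Character vector of candidate terms.
#' @param min_length Minimum term length in characters (default 3).
#' @param stoplist Character vector of words to exclude; compared after
#'   lowercasing and whitespace collapsing.
#' @return Character vector: the surviving terms (a subset of the input,
#'   original spelling preserved).
#' @export
refine_terms <- function(terms, min_length = 3L, stoplist = character(0)) {
  stopifnot(min_length >= 1L)
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (!length(terms)) return(character(0))
  norm <- tolower(gsub("[[:space:]]+", " ", terms))
  stop_norm <- tolower(gsub("[[:space:]]+", " ", trimws(stoplist)))
  keep <- nchar(terms) >= min_length & !(norm %in% stop_norm)
  unique(terms[keep])
}

#' Default common-word stoplist
#'
#' Reads the stoplist shipped with the package: standard English stopwords
#' plus a curated list of geographic and common words known to collide
#' with taxon or disease names. Users can pass their own file instead;
#' the list is configuration, not a fixed part of the method.
#'
#' @param path Path to a stoplist file (one word per line, `#` comments
#'   allowed). Defaults to the packaged list.
#' @return Character vector of stop words.
#' @export
default_stoplist <- function(path = system.file("extdata", "stoplist.txt",
                                                package = "padminer")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Build a refined term dictionary from an ontology branch
#'
#' For every non-obsolete class in `branch`, each label and synonym that
#' survives refinement is entered as a surface form mapping to that class
#' id. A surface form shared by several classes maps to all of them;
#' the ambiguity is preserved here and resolved downstream by counting
#' per class.
#'
#' @param o An `ontology`.
#' @param branch Character vector of class ids (e.g. from
#'   [extract_branch()]) restricting the dictionary.
#' @param category `"pathogen"` or `"disease"`.
#' @param min_length Minimum surviving term length in characters.
#' @param stoplist Character vector of excluded words.
#' @return A `term_dictionary`: list with `category`, `entries` (named
#'   list: normalized surface form -> character vector of class ids) and
#'   `case_sensitive_forms` (forms matched with exact case).
#' @export
build_dictionary <- function(o, branch, category = c("pathogen", "disease"),
                             min_length = 3L,
                             stoplist = default_stoplist()) {
  category <- match.arg(category)
  if (!length(branch)) stop("empty branch: no classes to index")
  assert_class_exists(o, branch)
  entries <- list()
  for (id in branch) {
    cls <- o$classes[[id]]
    if (cls$obsolete) next
    terms <- refine_terms(labels_of(o, id), min_length = min_length,
                          stoplist = stoplist)
    for (tm in terms) {
      key <- normalize_term(tm)
      entries[[key]] <- union(entries[[key]], id)
    }
  }
  if (!length(entries)) {
    stop("refinement removed every term; check branch roots and stoplist")
  }
  structure(list(category = category, entries = entries,
                 case_sensitive_forms =
                   names(entries)[is_case_sensitive_form(names(entries))]),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary> category=", x$category, ", ",
      length(x$entries), " surface forms, ",
      length(unique(unlist(x$entries))), " classes\n", sep = "")
  invisible(x)
}

#' Write a term dictionary as two-column TSV
#'
#' One row per (surface form, class id) pair; columns `surface_form`,
#' `class_id`. Rows are sorted for byte-stable output.
#'
#' @param dict A `term_dictionary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary_tsv <- function(dict, path) {
  stopifnot(inherits(dict, "term_dictionary"))
  forms <- rep(names(dict$entries), lengths(dict$entries))
  ids <- unlist(dict$entries, use.names = FALSE)
  ord <- order(forms, ids, method = "radix")
  df <- data.frame(surface_form = forms[ord], class_id = ids[ord],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term dictionary from two-column TSV
#'
#' @param path TSV file with columns `surface_form`, `class_id`.
#' @param category `"pathogen"` or `"disease"`.
#' @return A `term_dictionary`.
#' @export
read_dictionary_tsv <- function(path, category = c("pathogen", "disease")) {
  category <- match.arg(category)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  entries <- lapply(split(df$class_id, df$surface_form), unique)
  structure(list(category = category, entries = entries,
                 case_sensitive_forms =
                   names(entries)[is_case_sensitive_form(names(entries))]),
            class = "term_dictionary")
}
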