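#' Abbreviations that never end a sentence
#'
#' Tokens after which a period is not treated as a sentence boundary by
#' [split_sentences()]. Single capital initials ("E. coli") need no
#' entry: a break additionally requires the next word to open with an
#' upper-case letter or digit, which a species epithet never does.
#'
#' @return Character vector of abbreviation tokens (without the period).
#' @export
sentence_abbreviations <- function() {
  c("sp", "spp", "subsp", "str", "cf", "var", "al", "et",
    "fig", "figs", "eq", "ref", "refs", "no", "vs", "ca", "approx",
    "dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr",
    "e.g", "i.e", "etc")
}

is_alnum_char <- function(ch) grepl("^[[:alnum:]]$", ch)

#' Split a document into sentences
#'
#' Rule-based segmentation: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter, digit or opening quote — unless
#' the token preceding the period is a known non-terminal abbreviation
#' (so "E. coli" or "et al." never break). Offsets index into the original
#' document text, so mention spans can be mapped back.
#'
#' @param doc A list with `doc_id` and `text`, or a single string.
#' @param abbreviations Abbreviation exception list (without periods).
#' @return A data.frame with columns `doc_id`, `index` (0-based),
#'   `text`, `char_offset` (0-based start offset in the document).
#' @export
split_sentences <- function(doc, abbreviations = sentence_abbreviations()) {
  if (is.character(doc)) doc <- list(doc_id = "doc", text = doc)
  text <- doc$text
  empty <- data.frame(doc_id = character(0), index = integer(0),
                      text = character(0), char_offset = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(trimws(text))) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  abbrev <- tolower(abbreviations)
  breaks <- integer(0)  # positions (1-based) of sentence-final punctuation

  punct_pos <- which(chars %in% c(".", "!", "?"))
  for (i in punct_pos) {
    if (i == n) next
    # require whitespace then an upper-case/digit/quote sentence opener
    j <- i + 1L
    if (!grepl("^[[:space:]]$", chars[j])) next
    while (j <= n && grepl("^[[:space:]]$", chars[j])) j <- j + 1L
    if (j > n) next
    if (!grepl('^["\'(\\[A-Z0-9]$', chars[j])) next
    if (chars[i] == ".") {
      # token before the period; skip breaks after known abbreviations
      k <- i - 1L
      while (k >= 1L && grepl("^[[:alnum:].]$", chars[k])) k <- k - 1L
      token <- if (k + 1L <= i - 1L) {
        paste(chars[(k + 1L):(i - 1L)], collapse = "")
      } else ""
      token <- tolower(sub("\\.$", "", token))
      if (token %in% abbrev) next
    }
    breaks <- c(breaks, i)
  }

  bounds <- c(0L, breaks, n)
  out <- empty
  idx <- 0L
  for (s in seq_len(length(bounds) - 1L)) {
    from <- bounds[s] + 1L
    to <- bounds[s + 1L]
    seg <- substr(text, from, to)
    lead_ws <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    seg_trim <- trimws(seg)
    if (!nzchar(seg_trim)) next
    out <- rbind(out, data.frame(
      doc_id = doc$doc_id, index = idx, text = seg_trim,
      char_offset = from - 1L + lead_ws, stringsAsFactors = FALSE))
    idx <- idx + 1L
  }
  out
}

word_boundary_ok <- function(text_chars, start, end) {
  # start/end are 1-based inclusive positions of the match
  before_ok <- start == 1L || !is_alnum_char(text_chars[start - 1L])
  after_ok <- end == length(text_chars) || !is_alnum_char(text_chars[end + 1L])
  before_ok && after_ok
}

locate_fixed <- function(haystack, needle) {
  # all 1-based start positions of fixed-string matches
  m <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Tag class mentions in one sentence
#'
#' Dictionary matching with word-boundary alignment on both edges (a
#' boundary is a transition between alphanumeric and non-alphanumeric, so
#' "rat" never matches inside "strategy"). Matching is case-insensitive
#' except for the dictionary's case-sensitive forms (short all-caps
#' abbreviations). Overlapping candidate matches resolve to the longest
#' match, ties to the leftmost; each surviving match yields one mention
#' carrying every class id mapped to that surface form.
#'
#' @param sentence A one-row data.frame from [split_sentences()], or a
#'   list/string with a `text` field.
#' @param dict A `term_dictionary`.
#' @return A list of mentions; each is a list with `class_ids`
#'   (character), `category`, `start`, `end` (0-based half-open character
#'   interval within the sentence) and `surface` (matched text).
#' @export
tag_sentence <- function(sentence, dict) {
  stopifnot(inherits(dict, "term_dictionary"))
  if (!length(dict$entries)) stop("empty dictionary")
  text <- if (is.character(sentence)) sentence else sentence$text
  if (is.null(text) || !nzchar(text)) return(list())
  lower <- tolower(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]

  cand <- list()
  for (form in names(dict$entries)) {
    cs <- form %in% dict$case_sensitive_forms
    hay <- if (cs) text else lower
    needle <- if (cs) form else tolower(form)
    for (pos in locate_fixed(hay, needle)) {
      end <- pos + nchar(needle) - 1L
      if (!word_boundary_ok(chars, pos, end)) next
      cand[[length(cand) + 1L]] <- list(start = pos, end = end, form = form)
    }
  }
  if (!length(cand)) return(list())

  # longest match wins; ties to the leftmost
  lens <- vapply(cand, function(c) c$end - c$start + 1L, integer(1))
  starts <- vapply(cand, `[[`, integer(1), "start")
  ord <- order(-lens, starts)
  taken <- rep(FALSE, nchar(text))
  mentions <- list()
  for (i in ord) {
    c <- cand[[i]]
    span <- c$start:c$end
    if (any(taken[span])) next
    taken[span] <- TRUE
    mentions[[length(mentions) + 1L]] <- list(
      class_ids = sort(dict$entries[[c$form]]),
      category = dict$category,
      start = c$start - 1L,
      end = c$end,
      surface = substr(text, c$start, c$end))
  }
  ord2 <- order(vapply(mentions, `[[`, integer(1), "start"))
  mentions[ord2]
}

#' Detect abbreviations and their long forms in a document
#'
#' Finds parenthetical short-form definitions "LONG FORM (SF)" using the
#' letter-alignment convention: SF must be 2-10 characters with at least
#' half of them upper-case letters or digits, and every alphanumeric
#' character of SF must appear, in order, inside the candidate long form
#' (matched scanning right-to-left from the parenthesis; the first SF
#' character must start a word). The candidate long form is capped at
#' `min(|SF| + 5, 2 * |SF|)` words before the parenthesis.
#'
#' @param doc A list with `doc_id` and `text`, or a single string.
#' @return An `abbreviation_map`: named list short form -> character
#'   vector of long forms found in the document.
#' @export
detect_abbreviations <- function(doc) {
  text <- if (is.character(doc)) doc else doc$text
  pairs <- list()
  if (is.null(text) || !nzchar(text)) {
    return(structure(pairs, class = "abbreviation_map"))
  }
  m <- gregexpr("\\(([^()]{2,10})\\)", text)[[1]]
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      open <- as.integer(m[k])
      len <- attr(m, "match.length")[k]
      sf <- substr(text, open + 1L, open + len - 2L)
      if (!is_valid_short_form(sf)) next
      before <- substr(text, 1L, open - 1L)
      lf <- find_long_form(sf, before)
      if (!is.null(lf)) {
        pairs[[sf]] <- union(pairs[[sf]], lf)
      }
    }
  }
  structure(pairs, class = "abbreviation_map")
}

is_valid_short_form <- function(sf) {
  n <- nchar(sf)
  if (n < 2L || n > 10L) return(FALSE)
  chars <- strsplit(sf, "", fixed = TRUE)[[1]]
  if (!any(grepl("[[:alpha:]]", chars))) return(FALSE)
  mean(grepl("[A-Z0-9]", chars)) >= 0.5
}

find_long_form <- function(sf, before) {
  # candidate window: last min(|sf|+5, 2*|sf|) words before the parenthesis
  before <- sub("[[:space:]]+$", "", before)
  if (!nzchar(before)) return(NULL)
  max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
  word_starts <- gregexpr("[^[:space:]]+", before)[[1]]
  if (word_starts[1] == -1L) return(NULL)
  n_words <- length(word_starts)
  first <- word_starts[max(1L, n_words - max_words + 1L)]
  cand <- substr(before, first, nchar(before))

  sf_chars <- strsplit(tolower(sf), "", fixed = TRUE)[[1]]
  sf_chars <- sf_chars[grepl("[[:alnum:]]", sf_chars)]
  if (!length(sf_chars)) return(NULL)
  lf_chars <- strsplit(tolower(cand), "", fixed = TRUE)[[1]]

  s <- length(sf_chars)
  l <- length(lf_chars)
  while (s >= 1L) {
    cur <- sf_chars[s]
    repeat {
      if (l < 1L) return(NULL)
      ok <- lf_chars[l] == cur
      if (ok && s == 1L && l > 1L && grepl("[[:alnum:]]", lf_chars[l - 1L])) {
        ok <- FALSE  # first short-form char must start a word
      }
      if (ok) break
      l <- l - 1L
    }
    s <- s - 1L
    l <- l - 1L
  }
  long <- trimws(substr(cand, l + 1L, nchar(cand)))
  if (nzchar(long)) long else NULL
}

abbrev_surface_pattern <- "^[A-Z0-9]{2,10}$"

#' Filter ambiguous disease-abbreviation mentions
#'
#' A disease mention whose surface form looks like an abbreviation
#' (all-caps/digits, 2-10 characters, at least one letter) is kept only if
#' (a) some dictionary surface form mapped to any of its class ids occurs
#' elsewhere in the document — evidence that the disease long form is
#' really present — or (b) a detected long form of the abbreviation
#' contains a disease-indicating keyword ("syndrome", "disease", ...).
#' All other mentions, including every pathogen mention, pass through
#' unchanged. This screens out collisions like "ALS" meaning "Advanced
#' Life Support" rather than "Amyotrophic Lateral Sclerosis".
#'
#' @param mentions List of mentions (from [tag_sentence()]).
#' @param abbrevs An `abbreviation_map` for the document.
#' @param disease_dict The disease `term_dictionary`.
#' @param doc The document (list with `text`) the mentions came from.
#' @param keywords Disease-indicating keywords, matched case-insensitively
#'   on word boundaries inside long forms.
#' @return The filtered mention list (a subset of the input).
#' @export
filter_disease_abbreviations <- function(mentions, abbrevs, disease_dict, doc,
                                         keywords = default_disease_keywords()) {
  text <- if (is.character(doc)) doc else doc$text
  lower <- tolower(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  kw <- tolower(keywords)

  keep <- vapply(mentions, function(m) {
    if (m$category != "disease") return(TRUE)
    if (!grepl(abbrev_surface_pattern, m$surface) ||
        !grepl("[A-Z]", m$surface)) {
      return(TRUE)
    }
    # (a) long-form evidence: a non-abbreviation dictionary form for any of
    # the mention's classes occurs in the document
    for (form in names(disease_dict$entries)) {
      if (identical(form, m$surface)) next
      if (grepl(abbrev_surface_pattern, form)) next
      if (!length(intersect(disease_dict$entries[[form]], m$class_ids))) next
      for (pos in locate_fixed(lower, tolower(form))) {
        if (word_boundary_ok(chars, pos, pos + nchar(form) - 1L)) return(TRUE)
      }
    }
    # (b) keyword evidence in a detected long form
    long_forms <- abbrevs[[m$surface]]
    for (lf in long_forms) {
      lf_words <- strsplit(tolower(lf), "[^[:alnum:]]+")[[1]]
      if (any(kw %in% lf_words)) return(TRUE)
    }
    FALSE
  }, logical(1))
  mentions[keep]
}

#' Default disease-indicating keywords
#'
#' Words whose presence in an abbreviation's long form marks it as a
#' disease name. Configurable because the canonical list is open-ended.
#'
#' @return Character vector of keywords.
#' @export
default_disease_keywords <- function() {
  c("disease", "disorder", "syndrome", "defect", "infection", "fever")
}

#' Read a corpus from JSONL or a directory of text files
#'
#' @param path A `.jsonl` file (one JSON object per line with fields `id`
#'   and `text`) or a directory of `.txt` files (filename stem = doc id).
#' @return A data.frame with columns `doc_id`, `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files in ", path)
    return(data.frame(
      doc_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, warn = FALSE), collapse = "\n"), character(1)),
      stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$doc_id)) {
    stop("duplicate doc_id in corpus: ", df$doc_id[duplicated(df$doc_id)][1])
  }
  df
}

#' Tag a whole corpus
#'
#' Splits each document into sentences, tags pathogen and disease
#' mentions, and (optionally) applies the disease-abbreviation filter per
#' document. A surface form present in both dictionaries at the same span
#' yields two mentions, one per category.
#'
#' @param corpus Data.frame with `doc_id`, `text` (see [read_corpus()]).
#' @param pathogen_dict,disease_dict `term_dictionary` objects.
#' @param abbrev_filter Apply [filter_disease_abbreviations()]?
#' @param keywords Keywords for the abbreviation filter.
#' @return A list of tagged sentences; each element has `doc_id`, `index`,
#'   `text`, `char_offset` and `mentions` (list as from [tag_sentence()]).
#' @export
tag_corpus <- function(corpus, pathogen_dict, disease_dict,
                       abbrev_filter = TRUE,
                       keywords = default_disease_keywords()) {
  out <- list()
  for (r in seq_len(nrow(corpus))) {
    doc <- list(doc_id = corpus$doc_id[r], text = corpus$text[r])
    sents <- split_sentences(doc)
    if (!nrow(sents)) next
    abbrevs <- if (abbrev_filter) detect_abbreviations(doc) else NULL
    for (s in seq_len(nrow(sents))) {
      sent <- sents[s, ]
      mentions <- c(tag_sentence(sent, pathogen_dict),
                    tag_sentence(sent, disease_dict))
      if (abbrev_filter && length(mentions)) {
        mentions <- filter_disease_abbreviations(
          mentions, abbrevs, disease_dict, doc, keywords = keywords)
      }
      out[[length(out) + 1L]] <- list(
        doc_id = sent$doc_id, index = sent$index, text = sent$text,
        char_offset = sent$char_offset, mentions = mentions)
    }
  }
  out
}

#' Write tagged sentences as JSONL
#'
#' One JSON object per sentence: `doc_id`, `sent_index`, `text`,
#' `char_offset`, and `mentions` (array of objects with `start`, `end`
#' 0-based half-open, `class_ids`, `category`, `surface`).
#'
#' @param tagged List from [tag_corpus()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tagged_jsonl <- function(tagged, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ts in tagged) {
    rec <- list(doc_id = ts$doc_id, sent_index = ts$index, text = ts$text,
                char_offset = ts$char_offset,
                mentions = lapply(ts$mentions, function(m) {
                  list(start = m$start, end = m$end,
                       class_ids = as.list(m$class_ids),
                       category = m$category, surface = m$surface)
                }))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read tagged sentences from JSONL
#'
#' @param path File written by [write_tagged_jsonl()].
#' @return List of tagged sentences (see [tag_corpus()]).
#' @export
read_tagged_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    list(doc_id = r$doc_id, index = r$sent_index, text = r$text,
         char_offset = r$char_offset,
         mentions = lapply(r$mentions, function(m) {
           list(class_ids = unlist(m$class_ids), category = m$category,
                start = m$start, end = m$end, surface = m$surface)
         }))
  })
}
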