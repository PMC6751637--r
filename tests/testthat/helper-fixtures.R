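# In-code fixtures and independent brute-force oracles.

# Assemble OBO flat-file lines from parallel vectors/lists.
make_obo <- function(ids, labels = ids, parents = NULL, synonyms = NULL,
                     obsolete = character(0)) {
  lines <- "format-version: 1.2"
  for (i in seq_along(ids)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", ids[i]),
               paste0("name: ", labels[i]))
    for (s in synonyms[[ids[i]]]) {
      lines <- c(lines, paste0("synonym: \"", s, "\" EXACT []"))
    }
    for (p in parents[[ids[i]]]) {
      lines <- c(lines, paste0("is_a: ", p))
    }
    if (ids[i] %in% obsolete) lines <- c(lines, "is_obsolete: true")
  }
  lines
}

# Random DAG as OBO: node i draws 0-2 parents among nodes 1..i-1.
random_dag_obo <- function(n, prefix = "X") {
  ids <- sprintf("%s:%03d", prefix, seq_len(n))
  parents <- list()
  for (i in seq_len(n)) {
    k <- if (i == 1L) 0L else sample(0:min(2L, i - 1L), 1L)
    parents[[ids[i]]] <- if (k) sample(ids[seq_len(i - 1L)], k) else character(0)
  }
  make_obo(ids, parents = parents)
}

# Reachability by repeated edge expansion (independent of descendants()).
oracle_descendants <- function(o, id) {
  ids <- names(o$classes)
  reach <- id
  repeat {
    grew <- FALSE
    for (x in ids) {
      if (x %in% reach) next
      if (any(o$classes[[x]]$parents %in% reach)) {
        reach <- c(reach, x)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  sort(reach[!vapply(reach, function(x) o$classes[[x]]$obsolete, logical(1))])
}

# Upward reachability by repeated parent expansion.
oracle_ancestors <- function(o, id) {
  reach <- id
  repeat {
    more <- unique(unlist(lapply(reach, function(x) o$classes[[x]]$parents)))
    more <- setdiff(more, reach)
    if (!length(more)) break
    reach <- c(reach, more)
  }
  sort(reach[!vapply(reach, function(x) o$classes[[x]]$obsolete, logical(1))])
}

# Quadratic all-substring dictionary matcher with independent
# longest-leftmost resolution; mirrors the stated matching semantics.
oracle_tag <- function(text, dict) {
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_alnum <- grepl("[[:alnum:]]", chars)
  cand <- list()
  for (start in seq_len(n)) {
    for (end in start:n) {
      if (start > 1L && is_alnum[start - 1L]) next
      if (end < n && is_alnum[end + 1L]) next
      sub <- substr(text, start, end)
      hit <- NULL
      if (sub %in% dict$case_sensitive_forms) {
        hit <- sub
      } else {
        low <- tolower(sub)
        if (low %in% setdiff(names(dict$entries), dict$case_sensitive_forms)) {
          hit <- low
        }
      }
      if (!is.null(hit)) {
        cand[[length(cand) + 1L]] <- list(start = start, end = end, form = hit)
      }
    }
  }
  accepted <- list()
  while (length(cand)) {
    lens <- vapply(cand, function(c) c$end - c$start + 1L, integer(1))
    starts <- vapply(cand, function(c) c$start, integer(1))
    best <- which(lens == max(lens))
    best <- best[which.min(starts[best])]
    b <- cand[[best]]
    accepted[[length(accepted) + 1L]] <- b
    cand <- Filter(function(c) c$end < b$start || c$start > b$end, cand)
  }
  accepted <- accepted[order(vapply(accepted, function(c) c$start, integer(1)))]
  lapply(accepted, function(c) {
    list(class_ids = sort(dict$entries[[c$form]]), start = c$start - 1L,
         end = c$end, surface = substr(text, c$start, c$end))
  })
}

# Triple-enumeration co-occurrence counter: for every sentence with both
# categories, enumerate every (ancestor-pathogen, ancestor-disease)
# combination directly. Independent of count_cooccurrences().
oracle_counts <- function(tagged, po, do_) {
  n_tot <- 0L
  n_C <- integer(0); n_D <- integer(0); n_CD <- integer(0)
  add <- function(tab, keys) {
    for (k in keys) tab[k] <- if (is.na(tab[k])) 1L else tab[k] + 1L
    tab
  }
  for (ts in tagged) {
    p_raw <- unique(unlist(lapply(
      Filter(function(m) m$category == "pathogen", ts$mentions),
      `[[`, "class_ids")))
    d_raw <- unique(unlist(lapply(
      Filter(function(m) m$category == "disease", ts$mentions),
      `[[`, "class_ids")))
    if (!length(p_raw) || !length(d_raw)) next
    n_tot <- n_tot + 1L
    P <- unique(unlist(lapply(p_raw, oracle_ancestors, o = po)))
    D <- unique(unlist(lapply(d_raw, oracle_ancestors, o = do_)))
    n_C <- add(n_C, P)
    n_D <- add(n_D, D)
    n_CD <- add(n_CD, as.vector(outer(P, D, paste, sep = "\t")))
  }
  sort_tab <- function(tab) tab[order(names(tab))]
  list(n_tot = n_tot, n_C = sort_tab(n_C), n_D = sort_tab(n_D),
       n_CD = sort_tab(n_CD))
}

# Build a tagged-sentence stream straight from synthetic ground truth
# (bypasses the tagger; mention spans are not needed for counting).
tagged_from_truth <- function(truth) {
  ann <- truth$sentences
  out <- list()
  for (i in seq_len(nrow(ann))) {
    mentions <- list()
    if (!is.na(ann$pathogen_id[i])) {
      mentions[[length(mentions) + 1L]] <- list(
        class_ids = ann$pathogen_id[i], category = "pathogen",
        start = 0L, end = 1L, surface = "x")
    }
    if (!is.na(ann$disease_id[i])) {
      mentions[[length(mentions) + 1L]] <- list(
        class_ids = ann$disease_id[i], category = "disease",
        start = 0L, end = 1L, surface = "x")
    }
    out[[i]] <- list(doc_id = ann$doc_id[i], index = ann$index[i],
                     text = "", char_offset = 0L, mentions = mentions)
  }
  out
}

# Construct a cooccurrence_counts object from explicit count tables
# (for threshold-semantics tests where exact counts are prescribed).
counts_from_tables <- function(n_tot, n_C, n_D, n_CD) {
  structure(list(n_tot = n_tot, n_C = n_C, n_D = n_D, n_CD = n_CD,
                 evidence = stats::setNames(
                   lapply(seq_along(n_CD), function(i) integer(0)),
                   names(n_CD)),
                 sentences = list(), whole_corpus_marginals = FALSE),
            class = "cooccurrence_counts")
}

pair_keys <- function(p, d) paste(p, d, sep = "\t")

# A small two-category fixture shared by tagger/association tests.
tiny_mining_fixture <- function() {
  po <- parse_obo(make_obo(
    ids = c("P:1", "P:2", "P:3"),
    labels = c("pathogenia", "dengue virus", "dengue virus type 2"),
    parents = list("P:1" = character(0), "P:2" = "P:1", "P:3" = "P:2")))
  do_ <- parse_obo(make_obo(
    ids = c("D:1", "D:2", "D:3"),
    labels = c("dengue disease", "dengue hemorrhagic fever",
               "dengue shock syndrome"),
    parents = list("D:1" = character(0), "D:2" = "D:1", "D:3" = "D:1"),
    synonyms = list("D:1" = "breakbone fever")))
  list(
    po = po, do_ = do_,
    p_dict = build_dictionary(po, names(po$classes), "pathogen",
                              stoplist = character(0)),
    d_dict = build_dictionary(do_, names(do_$classes), "disease",
                              stoplist = character(0)))
}
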