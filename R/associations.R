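pair_key <- function(C, D) paste(C, D, sep = "\t")

#' Count ontology-propagated sentence-level co-occurrences
#'
#' A sentence enters the counting space iff it carries at least one
#' pathogen and at least one disease mention; `n_tot` is the size of that
#' space. Within it, every pathogen class that is an ancestor-or-self of
#' any mentioned pathogen class counts once toward `n_C` (set semantics:
#' multiplicity within a sentence is ignored), symmetrically for diseases,
#' and every such (pathogen, disease) combination counts once toward
#' `n_CD`. Counting a subclass mention toward all its ancestors is
#' equivalent to matching the full term set of each ancestor class, but
#' costs O(mentions x depth) instead of O(|terms|).
#'
#' Propagation can be capped below the branch roots via `cap_roots`
#' (associations at "root of all life" / "disease" level are vacuous).
#' By default the marginals `n_C`, `n_D` are counted in the same
#' restricted space as `n_tot`, which keeps every count ratio a valid
#' probability and the NPMI inside \[-1, 1\];
#' `whole_corpus_marginals = TRUE` counts them over all sentences instead.
#'
#' @param tagged List of tagged sentences (see [tag_corpus()]).
#' @param patho_onto,dis_onto The pathogen and disease `ontology` objects;
#'   a mention class id absent from its ontology is an error.
#' @param cap_roots Optional character vector of class ids at which upward
#'   propagation stops (these ids are excluded from counting).
#' @param whole_corpus_marginals Count `n_C`/`n_D` over every sentence
#'   rather than only co-occurrence sentences.
#' @return A `cooccurrence_counts` object: list with `n_tot`, `n_C`,
#'   `n_D`, `n_CD` (named integer vectors; pair names are
#'   tab-separated id pairs), `evidence` (pair -> integer indices into
#'   `sentences`), and `sentences` (per co-occurrence sentence: `doc_id`,
#'   `index`, and the raw, un-propagated mention class ids per category).
#' @export
count_cooccurrences <- function(tagged, patho_onto, dis_onto,
                                cap_roots = NULL,
                                whole_corpus_marginals = FALSE) {
  shared <- intersect(names(patho_onto$classes), names(dis_onto$classes))
  if (length(shared)) {
    stop("pathogen and disease ontologies share class id(s): ",
         paste(utils::head(shared, 3), collapse = ", "))
  }
  anc_cache <- new.env(parent = emptyenv())
  anc_of <- function(o, id, tag) {
    key <- paste0(tag, id)
    got <- anc_cache[[key]]
    if (is.null(got)) {
      got <- ancestors(o, id, stop_at = cap_roots)
      anc_cache[[key]] <- got
    }
    got
  }

  n_C <- new.env(parent = emptyenv())
  n_D <- new.env(parent = emptyenv())
  n_CD <- new.env(parent = emptyenv())
  evidence <- new.env(parent = emptyenv())
  bump <- function(env, keys) {
    for (k in keys) {
      cur <- env[[k]]
      env[[k]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  sentences <- list()
  n_tot <- 0L

  for (ts in tagged) {
    p_raw <- character(0)
    d_raw <- character(0)
    for (m in ts$mentions) {
      if (m$category == "pathogen") {
        assert_class_exists(patho_onto, m$class_ids)
        p_raw <- union(p_raw, m$class_ids)
      } else {
        assert_class_exists(dis_onto, m$class_ids)
        d_raw <- union(d_raw, m$class_ids)
      }
    }
    cooc <- length(p_raw) > 0L && length(d_raw) > 0L
    if (!cooc && !whole_corpus_marginals) next

    p_anc <- unique(unlist(lapply(p_raw, anc_of, o = patho_onto, tag = "P"),
                           use.names = FALSE))
    d_anc <- unique(unlist(lapply(d_raw, anc_of, o = dis_onto, tag = "D"),
                           use.names = FALSE))
    if (whole_corpus_marginals) {
      bump(n_C, p_anc)
      bump(n_D, d_anc)
    }
    if (!cooc) next

    n_tot <- n_tot + 1L
    if (!whole_corpus_marginals) {
      bump(n_C, p_anc)
      bump(n_D, d_anc)
    }
    sentences[[length(sentences) + 1L]] <- list(
      doc_id = ts$doc_id, index = ts$index,
      pathogen_ids = p_raw, disease_ids = d_raw)
    sent_i <- length(sentences)
    for (C in p_anc) {
      for (D in d_anc) {
        k <- pair_key(C, D)
        bump(n_CD, k)
        evidence[[k]] <- c(evidence[[k]], sent_i)
      }
    }
  }

  env_to_vec <- function(env) {
    keys <- sort(ls(env))
    stats::setNames(vapply(keys, function(k) env[[k]], integer(1)), keys)
  }
  structure(list(
    n_tot = n_tot,
    n_C = env_to_vec(n_C),
    n_D = env_to_vec(n_D),
    n_CD = env_to_vec(n_CD),
    evidence = stats::setNames(
      lapply(sort(ls(evidence)), function(k) evidence[[k]]),
      sort(ls(evidence))),
    sentences = sentences,
    whole_corpus_marginals = whole_corpus_marginals
  ), class = "cooccurrence_counts")
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat("<cooccurrence_counts> n_tot=", x$n_tot, ", ",
      length(x$n_C), " pathogen classes, ", length(x$n_D),
      " disease classes, ", length(x$n_CD), " pairs\n", sep = "")
  invisible(x)
}

#' Normalized pointwise mutual information from raw counts
#'
#' `log(n_cd * n_tot / (n_c * n_d)) / (-log(n_cd / n_tot))`, the
#' collocation measure scaled to \[-1, 1\]: 1 means the two classes only
#' ever occur together, 0 exact independence, -1 never together. The two
#' degenerate cases are mapped to the continuous limits of the formula:
#' `n_cd = 0` gives -1 and `n_cd = n_tot` gives +1. The logarithm base
#' cancels in the ratio.
#'
#' @param n_cd Sentences where both classes occur.
#' @param n_c,n_d Marginal sentence counts for each class.
#' @param n_tot Size of the co-occurrence sentence space (> 0).
#' @return A number in \[-1, 1\].
#' @export
npmi_value <- function(n_cd, n_c, n_d, n_tot) {
  if (n_tot <= 0) stop("n_tot must be positive (empty counting space)")
  stopifnot(n_cd >= 0, n_c >= n_cd, n_d >= n_cd, n_tot >= n_cd)
  n_cd <- as.numeric(n_cd); n_c <- as.numeric(n_c)
  n_d <- as.numeric(n_d); n_tot <- as.numeric(n_tot)
  if (n_cd == 0) return(-1)
  if (n_cd == n_tot) return(1)
  log(n_cd * n_tot / (n_c * n_d)) / (-log(n_cd / n_tot))
}

#' Class-level NPMI for one pathogen-disease pair
#'
#' @param counts A `cooccurrence_counts` object.
#' @param C Pathogen class id (must have `n_C >= 1`).
#' @param D Disease class id (must have `n_D >= 1`).
#' @return A number in \[-1, 1\].
#' @export
npmi <- function(counts, C, D) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  if (!C %in% names(counts$n_C)) stop("no marginal count for ", C)
  if (!D %in% names(counts$n_D)) stop("no marginal count for ", D)
  key <- pair_key(C, D)
  n_cd <- if (key %in% names(counts$n_CD)) counts$n_CD[[key]] else 0L
  npmi_value(n_cd, counts$n_C[[C]], counts$n_D[[D]], counts$n_tot)
}

#' Is a pair supported by a direct mention of both classes?
#'
#' An association is direct when at least one evidence sentence mentions,
#' for each side, a surface form of the class itself (not only of a
#' proper subclass); otherwise the pair is reached only through ontology
#' propagation and is flagged indirect/inferred.
#'
#' @param counts A `cooccurrence_counts` object.
#' @param C Pathogen class id.
#' @param D Disease class id.
#' @return `TRUE`/`FALSE`.
#' @export
classify_direct <- function(counts, C, D) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  idx <- counts$evidence[[pair_key(C, D)]]
  if (is.null(idx)) return(FALSE)
  for (i in idx) {
    s <- counts$sentences[[i]]
    if (C %in% s$pathogen_ids && D %in% s$disease_ids) return(TRUE)
  }
  FALSE
}

#' Extract thresholded pathogen-disease associations
#'
#' Returns exactly the pairs with `n_CD >= count_threshold` and NPMI
#' strictly greater than `npmi_threshold` (the score cut is strict, the
#' count cut inclusive), each with its score, counts, direct/indirect
#' flag and evidence pointers. Output order is NPMI descending, then
#' pathogen id, then disease id, so runs are byte-reproducible.
#'
#' @param counts A `cooccurrence_counts` object.
#' @param npmi_threshold Minimum (exclusive) NPMI; default 0.2.
#' @param count_threshold Minimum (inclusive) co-occurrence count;
#'   default 10.
#' @return A data.frame with columns `pathogen_id`, `disease_id`, `npmi`,
#'   `count`, `n_C`, `n_D`, `direct` (logical) and `evidence`
#'   (semicolon-joined `doc:sent` tokens).
#' @export
extract_associations <- function(counts, npmi_threshold = 0.2,
                                 count_threshold = 10L) {
  stopifnot(inherits(counts, "cooccurrence_counts"),
            is.finite(npmi_threshold), count_threshold >= 1L)
  keys <- names(counts$n_CD)
  rows <- list()
  for (k in keys) {
    n_cd <- counts$n_CD[[k]]
    if (n_cd < count_threshold) next
    ids <- strsplit(k, "\t", fixed = TRUE)[[1]]
    C <- ids[1]; D <- ids[2]
    score <- npmi(counts, C, D)
    if (!(score > npmi_threshold)) next
    ev <- counts$evidence[[k]]
    ev_str <- paste(vapply(ev, function(i) {
      s <- counts$sentences[[i]]
      paste0(s$doc_id, ":", s$index)
    }, character(1)), collapse = ";")
    rows[[length(rows) + 1L]] <- data.frame(
      pathogen_id = C, disease_id = D, npmi = score, count = n_cd,
      n_C = counts$n_C[[C]], n_D = counts$n_D[[D]],
      direct = classify_direct(counts, C, D),
      evidence = ev_str, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pathogen_id = character(0), disease_id = character(0),
                      npmi = numeric(0), count = integer(0),
                      n_C = integer(0), n_D = integer(0),
                      direct = logical(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$npmi, df$pathogen_id, df$disease_id, method = "radix"), ]
  rownames(df) <- NULL
  df
}

#' Write associations as TSV
#'
#' Columns: pathogen_id, pathogen_label, disease_id, disease_label, npmi
#' (6 decimal places), n_CD, n_C, n_D, direct (true/false), evidence.
#' Labels are looked up in the ontologies when supplied, else left empty.
#'
#' @param assoc Data.frame from [extract_associations()].
#' @param path Output file.
#' @param patho_onto,dis_onto Optional `ontology` objects for labels.
#' @return `path`, invisibly.
#' @export
write_associations_tsv <- function(assoc, path, patho_onto = NULL,
                                   dis_onto = NULL) {
  label_for <- function(o, id) {
    if (is.null(o) || is.null(o$classes[[id]])) "" else o$classes[[id]]$label
  }
  out <- data.frame(
    pathogen_id = assoc$pathogen_id,
    pathogen_label = vapply(assoc$pathogen_id, label_for, character(1),
                            o = patho_onto),
    disease_id = assoc$disease_id,
    disease_label = vapply(assoc$disease_id, label_for, character(1),
                           o = dis_onto),
    npmi = sprintf("%.6f", assoc$npmi),
    n_CD = assoc$count, n_C = assoc$n_C, n_D = assoc$n_D,
    direct = ifelse(assoc$direct, "true", "false"),
    evidence = assoc$evidence,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an associations TSV back into a data.frame
#'
#' @param path File written by [write_associations_tsv()].
#' @return Data.frame with the same columns as [extract_associations()],
#'   plus the label columns.
#' @export
read_associations_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  df$npmi <- as.numeric(df$npmi)
  df$n_CD <- as.integer(df$n_CD)
  df$n_C <- as.integer(df$n_C)
  df$n_D <- as.integer(df$n_D)
  df$direct <- df$direct == "true"
  df
}

#' Export associations as RDF N-Triples
#'
#' Writes one association node per pair with score, count and direct-flag
#' literals, linking the pathogen and disease class IRIs (CURIEs are
#' expanded against the OBO PURL namespace). Mirrors a triple-store
#' distribution of the extraction output.
#'
#' @param assoc Data.frame from [extract_associations()].
#' @param path Output `.nt` file.
#' @param base Base IRI for association nodes.
#' @return `path`, invisibly.
#' @export
write_associations_nt <- function(assoc, path,
                                  base = "http://example.org/padminer/") {
  curie_iri <- function(id) {
    paste0("http://purl.obolibrary.org/obo/", gsub(":", "_", id, fixed = TRUE))
  }
  xsd <- "http://www.w3.org/2001/XMLSchema#"
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(assoc))) {
    node <- paste0("<", base, "association/", i, ">")
    writeLines(c(
      paste0(node, " <", base, "vocab#pathogen> <",
             curie_iri(assoc$pathogen_id[i]), "> ."),
      paste0(node, " <", base, "vocab#disease> <",
             curie_iri(assoc$disease_id[i]), "> ."),
      paste0(node, " <", base, "vocab#npmi> \"",
             sprintf("%.6f", assoc$npmi[i]), "\"^^<", xsd, "double> ."),
      paste0(node, " <", base, "vocab#cooccurrences> \"",
             assoc$count[i], "\"^^<", xsd, "integer> ."),
      paste0(node, " <", base, "vocab#direct> \"",
             ifelse(assoc$direct[i], "true", "false"),
             "\"^^<", xsd, "boolean> .")), con)
  }
  invisible(path)
}
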