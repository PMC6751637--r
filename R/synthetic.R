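#' Specification for a synthetic mining fixture
#'
#' Bundles the parameters of the seeded generator that emits miniature
#' pathogen/disease ontologies and a corpus with planted associations.
#' Defaults describe a desk-scale study: two ontologies of 20 and 15
#' classes (depth 3), a 2000-sentence corpus, three planted pairs at
#' joint probabilities 0.10/0.07/0.05 (one planted only through
#' subclasses, to exercise indirect inference) against independent
#' background mentions at rate 0.1 per category.
#'
#' @param n_pathogen_classes,n_disease_classes Ontology sizes (>= 2).
#' @param max_depth Maximum is_a depth of the generated trees.
#' @param n_sentences Corpus size in sentences.
#' @param planted_pairs `NULL` for automatic selection, or a data.frame
#'   with columns `pathogen_id`, `disease_id`, `joint_probability` and
#'   `mode` (`"mixed"`, `"direct_only"` or `"subclass_only"`).
#' @param background_rate Probability that a background sentence mentions
#'   a uniformly random pathogen (and, independently, a random disease).
#' @param abbreviation_rate Probability that a planted multi-word disease
#'   surface is introduced with a parenthetical short form.
#' @param ambiguity_rate Probability that a planted pathogen surface is
#'   emitted as an ambiguous stoplist word instead of its proper label.
#' @param subclass_rate For `"mixed"` pairs: probability that a side is
#'   emitted through a proper subclass's surface form.
#' @param sentences_per_doc Sentences packed into each document.
#' @param seed Integer seed; the whole fixture is a pure function of the
#'   spec including the seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pathogen_classes = 20L, n_disease_classes = 15L,
                           max_depth = 3L, n_sentences = 2000L,
                           planted_pairs = NULL, background_rate = 0.1,
                           abbreviation_rate = 0.05, ambiguity_rate = 0,
                           subclass_rate = 0.5, sentences_per_doc = 10L,
                           seed = 1L) {
  stopifnot(n_pathogen_classes >= 2L, n_disease_classes >= 2L,
            max_depth >= 1L, n_sentences >= 0L,
            background_rate >= 0, background_rate <= 1,
            abbreviation_rate >= 0, abbreviation_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            subclass_rate >= 0, subclass_rate <= 1)
  structure(list(
    n_pathogen_classes = as.integer(n_pathogen_classes),
    n_disease_classes = as.integer(n_disease_classes),
    max_depth = as.integer(max_depth),
    n_sentences = as.integer(n_sentences),
    planted_pairs = planted_pairs,
    background_rate = background_rate,
    abbreviation_rate = abbreviation_rate,
    ambiguity_rate = ambiguity_rate,
    subclass_rate = subclass_rate,
    sentences_per_doc = as.integer(sentences_per_doc),
    seed = as.integer(seed)), class = "synthetic_spec")
}

syllable_word <- function(n_syllables) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syllables, replace = TRUE),
                sample(vow, n_syllables, replace = TRUE)), collapse = "")
}

make_word_pool <- function(n, taken = character(0)) {
  pool <- character(0)
  avoid <- c(taken, default_stoplist())
  while (length(pool) < n) {
    w <- syllable_word(sample(2:3, 1))
    if (nchar(w) >= 4 && !(w %in% pool) && !(w %in% avoid)) {
      pool <- c(pool, w)
    }
  }
  pool
}

generate_tree <- function(n, prefix, label_pool, syn_pool, max_depth,
                          disease_style = FALSE) {
  ids <- sprintf("%s:%04d", prefix, seq_len(n))
  depth <- integer(n)
  depth[1] <- 1L
  parents <- rep(NA_character_, n)
  for (i in seq_len(n)[-1]) {
    eligible <- which(depth[seq_len(i - 1L)] < max_depth)
    if (!length(eligible)) eligible <- 1L
    p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    parents[i] <- ids[p]
    depth[i] <- depth[p] + 1L
  }
  suffixes <- c("fever", "syndrome", "sickness")
  labels <- character(n)
  syn_i <- 0L
  synonyms <- vector("list", n)
  for (i in seq_len(n)) {
    base <- label_pool[i]
    labels[i] <- if (disease_style && i > 1L && stats::runif(1) < 0.4) {
      paste(base, sample(suffixes, 1L))
    } else {
      base
    }
    k <- sample(0:2, 1L)
    if (k > 0L) {
      synonyms[[i]] <- syn_pool[(syn_i + 1L):(syn_i + k)]
      syn_i <- syn_i + k
    } else {
      synonyms[[i]] <- character(0)
    }
  }
  list(ids = ids, labels = labels, synonyms = synonyms, parents = parents,
       depth = depth)
}

tree_to_obo <- function(tree, seed, ontology_name) {
  lines <- c("format-version: 1.2",
             paste0("remark: synthetic ", ontology_name,
                    " fixture, seed=", seed))
  for (i in seq_along(tree$ids)) {
    lines <- c(lines, "", "[Term]",
               paste0("id: ", tree$ids[i]),
               paste0("name: ", tree$labels[i]))
    for (s in tree$synonyms[[i]]) {
      lines <- c(lines, paste0("synonym: \"", s, "\" EXACT []"))
    }
    if (!is.na(tree$parents[i])) {
      lines <- c(lines, paste0("is_a: ", tree$parents[i]))
    }
  }
  lines
}

#' Generate a pair of miniature ontologies
#'
#' Emits a pathogen and a disease ontology as OBO flat-file text: random
#' is_a trees with unique pronounceable labels (4+ characters, never on
#' the default stoplist) and 0-2 synonyms per class. Disease classes may
#' carry two-word labels ("... fever") so the abbreviation machinery is
#' exercised. Byte-identical output under the same spec and seed; the
#' seed is recorded in the OBO header remark.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `pathogen` and `disease`, each a character vector of
#'   OBO lines (parse with [parse_obo()]).
#' @export
generate_ontologies <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_p <- spec$n_pathogen_classes
  n_d <- spec$n_disease_classes
  pool <- make_word_pool(3L * (n_p + n_d))
  p_labels <- pool[seq_len(n_p)]
  d_labels <- pool[n_p + seq_len(n_d)]
  syn_pool <- pool[(n_p + n_d + 1L):length(pool)]
  p_tree <- generate_tree(n_p, "PATH", p_labels,
                          syn_pool[seq_len(2L * n_p)], spec$max_depth)
  d_tree <- generate_tree(n_d, "DIS", d_labels,
                          syn_pool[2L * n_p + seq_len(2L * n_d)],
                          spec$max_depth, disease_style = TRUE)
  list(pathogen = tree_to_obo(p_tree, spec$seed, "pathogen taxonomy"),
       disease = tree_to_obo(d_tree, spec$seed, "disease ontology"))
}

# Planted signals must sit on disjoint subtrees: if one planted class
# subsumed another planted pair's class, their marginal counts would
# absorb each other's sentences and the ground truth would be ill-posed.
# The subclass-only pair is chosen first (it needs an internal class with
# children); the two leaf-level pairs are then drawn outside its subtree.
auto_planted_pairs <- function(po, do_) {
  non_root_with_children <- function(o) {
    ids <- setdiff(names(o$classes), o$roots)
    ids[vapply(ids, function(i) length(o$children[[i]]) > 0L, logical(1))]
  }
  leaves <- function(o) {
    ids <- setdiff(names(o$classes), o$roots)
    ids[vapply(ids, function(i) length(o$children[[i]]) == 0L, logical(1))]
  }
  pick <- function(x, avoid = character(0)) {
    x <- setdiff(x, avoid)
    if (!length(x)) stop("ontology too small to plant disjoint pairs")
    x[sample.int(length(x), 1L)]
  }
  pick_side <- function(o) {
    int <- non_root_with_children(o)
    if (!length(int)) stop("ontology too shallow for a subclass-only pair")
    c3 <- pick(int)
    avoid <- descendants(o, c3)
    c1 <- pick(leaves(o), avoid)
    c2 <- pick(leaves(o), c(avoid, c1, descendants(o, c1)))
    c(c1, c2, c3)
  }
  p <- pick_side(po)
  d <- pick_side(do_)
  data.frame(
    pathogen_id = p, disease_id = d,
    joint_probability = c(0.10, 0.07, 0.05),
    mode = c("mixed", "mixed", "subclass_only"),
    stringsAsFactors = FALSE)
}

templates_both <- c(
  "%P was isolated from patients with %D.",
  "Infection with %P is a recognized cause of %D.",
  "Patients diagnosed with %D tested positive for %P.",
  "Cases of %D were attributed to %P in this cohort.")
templates_pathogen <- c(
  "%P was cultured from the environmental samples.",
  "The genome of %P was sequenced in this study.",
  "Surveillance detected %P in three districts.")
templates_disease <- c(
  "Several cases of %D were reported during the study period.",
  "The incidence of %D declined after the intervention.",
  "Clinical records mentioned %D in the admission notes.")
templates_filler <- c(
  "The study enrolled 120 participants across four sites.",
  "Samples were stored frozen until processing.",
  "Ethical approval was obtained before enrollment.",
  "Statistical analyses used standard software.")

capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

initials_of <- function(x) {
  words <- strsplit(x, "[^[:alnum:]]+")[[1]]
  toupper(paste0(substr(words[nzchar(words)], 1L, 1L), collapse = ""))
}

surface_for <- function(o, id) {
  ls_ <- labels_of(o, id)
  ls_[sample.int(length(ls_), 1L)]
}

#' Generate a corpus with planted pathogen-disease associations
#'
#' Draws `n_sentences` one at a time: with probability equal to its joint
#' probability a planted pair emits a carrier sentence containing one
#' surface form for each side (through a proper subclass for
#' `"subclass_only"` pairs, or with probability `subclass_rate` for
#' `"mixed"` pairs); otherwise a background sentence independently
#' mentions a uniformly random pathogen and/or disease at
#' `background_rate`, or is pure filler. Multi-word planted disease
#' surfaces are introduced with a parenthetical short form at
#' `abbreviation_rate`. Sentences are packed into documents and the full
#' ground truth is recorded.
#'
#' @param spec A `synthetic_spec`.
#' @param ontologies Output of [generate_ontologies()] (or a list with
#'   parsed `pathogen`/`disease` `ontology` objects).
#' @return List with `corpus` (data.frame `doc_id`, `text`), `truth`
#'   (list: `planted` data.frame with `expected_direct`; `expected_pairs`
#'   — the ancestor-closure of the planted pairs, i.e. every pair the
#'   propagated counts should surface; `sentences` — per-sentence
#'   annotations; `seed`) and the parsed `pathogen`/`disease` ontologies.
#' @export
generate_corpus <- function(spec, ontologies) {
  stopifnot(inherits(spec, "synthetic_spec"))
  po <- if (inherits(ontologies$pathogen, "ontology")) ontologies$pathogen
        else parse_obo(ontologies$pathogen)
  do_ <- if (inherits(ontologies$disease, "ontology")) ontologies$disease
         else parse_obo(ontologies$disease)
  set.seed(spec$seed + 1L)

  planted <- spec$planted_pairs
  if (is.null(planted)) planted <- auto_planted_pairs(po, do_)
  bad_p <- setdiff(planted$pathogen_id, names(po$classes))
  bad_d <- setdiff(planted$disease_id, names(do_$classes))
  if (length(bad_p) || length(bad_d)) {
    stop("planted pair references unknown class: ",
         paste(c(bad_p, bad_d), collapse = ", "))
  }
  jp <- planted$joint_probability
  if (sum(jp) > 1) stop("planted joint probabilities sum to more than 1")

  geo_words <- c("arabia", "katanga", "congo", "victoria")
  proper_desc <- function(o, id) setdiff(descendants(o, id), id)

  side_class <- function(o, id, mode) {
    sub <- proper_desc(o, id)
    if (mode == "subclass_only") {
      if (!length(sub)) stop("subclass_only pair needs a class with ",
                             "subclasses: ", id)
      return(sub[sample.int(length(sub), 1L)])
    }
    if (mode == "mixed" && length(sub) && stats::runif(1) < spec$subclass_rate) {
      return(sub[sample.int(length(sub), 1L)])
    }
    id
  }

  n <- spec$n_sentences
  sent_text <- character(n)
  ann <- data.frame(sent_id = seq_len(n) - 1L,
                    kind = character(n), pair = NA_integer_,
                    pathogen_id = NA_character_, disease_id = NA_character_,
                    stringsAsFactors = FALSE)
  cum <- cumsum(jp)
  for (i in seq_len(n)) {
    u <- stats::runif(1)
    k <- if (length(cum) && u < cum[length(cum)]) which(u < cum)[1] else 0L
    if (k > 0L) {
      mode <- planted$mode[k]
      pc <- side_class(po, planted$pathogen_id[k], mode)
      dc <- side_class(do_, planted$disease_id[k], mode)
      ps <- surface_for(po, pc)
      if (spec$ambiguity_rate > 0 && stats::runif(1) < spec$ambiguity_rate) {
        ps <- geo_words[sample.int(length(geo_words), 1L)]
        pc <- NA_character_  # emitted form is not a dictionary term
      }
      ds <- surface_for(do_, dc)
      if (spec$abbreviation_rate > 0 && grepl(" ", ds) &&
          stats::runif(1) < spec$abbreviation_rate) {
        ds <- paste0(ds, " (", initials_of(ds), ")")
      }
      tmpl <- templates_both[sample.int(length(templates_both), 1L)]
      txt <- sub("%P", ps, sub("%D", ds, tmpl), fixed = TRUE)
      ann$kind[i] <- "planted"; ann$pair[i] <- k
      ann$pathogen_id[i] <- pc; ann$disease_id[i] <- dc
    } else {
      has_p <- stats::runif(1) < spec$background_rate
      has_d <- stats::runif(1) < spec$background_rate
      if (has_p) {
        pc <- names(po$classes)[sample.int(length(po$classes), 1L)]
        ps <- surface_for(po, pc)
      }
      if (has_d) {
        dc <- names(do_$classes)[sample.int(length(do_$classes), 1L)]
        ds <- surface_for(do_, dc)
      }
      if (has_p && has_d) {
        tmpl <- templates_both[sample.int(length(templates_both), 1L)]
        txt <- sub("%P", ps, sub("%D", ds, tmpl), fixed = TRUE)
        ann$kind[i] <- "background_both"
        ann$pathogen_id[i] <- pc; ann$disease_id[i] <- dc
      } else if (has_p) {
        tmpl <- templates_pathogen[sample.int(length(templates_pathogen), 1L)]
        txt <- sub("%P", ps, tmpl, fixed = TRUE)
        ann$kind[i] <- "background_pathogen"; ann$pathogen_id[i] <- pc
      } else if (has_d) {
        tmpl <- templates_disease[sample.int(length(templates_disease), 1L)]
        txt <- sub("%D", ds, tmpl, fixed = TRUE)
        ann$kind[i] <- "background_disease"; ann$disease_id[i] <- dc
      } else {
        txt <- templates_filler[sample.int(length(templates_filler), 1L)]
        ann$kind[i] <- "filler"
      }
    }
    sent_text[i] <- capitalize(txt)
  }

  per_doc <- spec$sentences_per_doc
  doc_of <- (seq_len(n) - 1L) %/% per_doc + 1L
  doc_ids <- sprintf("doc%04d", unique(doc_of))
  corpus <- data.frame(
    doc_id = doc_ids,
    text = vapply(unique(doc_of), function(d)
      paste(sent_text[doc_of == d], collapse = " "), character(1)),
    stringsAsFactors = FALSE)
  ann$doc_id <- sprintf("doc%04d", doc_of)
  ann$index <- unlist(lapply(split(seq_len(n), doc_of),
                             function(ix) seq_along(ix) - 1L),
                      use.names = FALSE)

  # direct/indirect expectation from the realized emissions: a pair is
  # expected direct iff some sentence (planted carrier or background)
  # actually mentioned both classes themselves. A subclass-only planting
  # can still become direct through a chance background co-mention.
  planted$expected_direct <- vapply(seq_len(nrow(planted)), function(k) {
    any(!is.na(ann$pathogen_id) & !is.na(ann$disease_id) &
          ann$pathogen_id == planted$pathogen_id[k] &
          ann$disease_id == planted$disease_id[k])
  }, logical(1))
  # Every (pathogen, disease) class combination actually co-emitted by a
  # planted carrier sentence is a genuine association of the corpus, and
  # so is everything it propagates to: the expected pair set is the
  # ancestor closure of the realized emissions. Pairs outside it are
  # decoys that the thresholds should reject.
  emitted <- unique(ann[ann$kind == "planted" & !is.na(ann$pathogen_id),
                        c("pathogen_id", "disease_id")])
  expected_pairs <- if (nrow(emitted)) {
    unique(do.call(rbind, lapply(seq_len(nrow(emitted)), function(k) {
      expand.grid(pathogen_id = ancestors(po, emitted$pathogen_id[k]),
                  disease_id = ancestors(do_, emitted$disease_id[k]),
                  stringsAsFactors = FALSE)
    })))
  } else {
    data.frame(pathogen_id = character(0), disease_id = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(expected_pairs) <- NULL

  list(corpus = corpus,
       truth = list(planted = planted, expected_pairs = expected_pairs,
                    sentences = ann, seed = spec$seed),
       pathogen = po, disease = do_)
}

#' Write a corpus as JSONL
#'
#' One JSON object per document with fields `id` and `text`.
#'
#' @param corpus Data.frame with `doc_id`, `text`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(id = corpus$doc_id[i],
                                     text = corpus$text[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Materialize a complete synthetic fixture on disk
#'
#' Writes `pathogen.obo`, `disease.obo`, `corpus.jsonl` and `truth.json`
#' into a directory.
#'
#' @param spec A `synthetic_spec`.
#' @param out_dir Output directory (created if missing).
#' @return Invisible list of the paths written.
#' @export
write_fixture <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obo <- generate_ontologies(spec)
  gen <- generate_corpus(spec, obo)
  paths <- list(
    pathogen = file.path(out_dir, "pathogen.obo"),
    disease = file.path(out_dir, "disease.obo"),
    corpus = file.path(out_dir, "corpus.jsonl"),
    truth = file.path(out_dir, "truth.json"))
  writeLines(obo$pathogen, paths$pathogen)
  writeLines(obo$disease, paths$disease)
  write_corpus_jsonl(gen$corpus, paths$corpus)
  jsonlite::write_json(gen$truth, paths$truth, auto_unbox = TRUE,
                       dataframe = "rows", na = "null")
  invisible(paths)
}
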