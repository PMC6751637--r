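#' Parse an OBO flat file into an ontology
#'
#' Reads OBO 1.2/1.4 flat-file text and builds an `ontology` object holding
#' one class per `[Term]` stanza. Only `is_a` edges are retained as
#' subsumption; `relationship:` lines (e.g. `part_of`) are ignored because
#' downstream term propagation uses subclass semantics only. Synonyms are
#' ingested regardless of scope tag (EXACT/RELATED/NARROW/BROAD). Obsolete
#' classes are kept in the class map but excluded from closures, term sets
#' and dictionary construction.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `ontology`: a list with elements
#'   `classes` (named list of class records with fields `id`, `label`,
#'   `synonyms`, `parents`, `obsolete`), `roots` (ids with no parents) and
#'   `children` (named list: id -> character vector of direct subclasses).
#' @details Parent references pointing outside the file are dropped with a
#'   warning (real OBO exports contain them). A cyclic `is_a` graph is an
#'   error naming one cycle. A `[Term]` stanza without an `id:` line is a
#'   parse error naming the offending line.
#' @examples
#' obo <- c("[Term]", "id: A:1", "name: alpha",
#'          "[Term]", "id: A:2", "name: beta", "is_a: A:1 ! alpha")
#' o <- parse_obo(obo)
#' descendants(o, "A:1")
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }

  stanza_starts <- which(trimws(lines) == "[Term]")
  classes <- vector("list", length(stanza_starts))
  other_headers <- which(grepl("^\\[[^]]+\\]$", trimws(lines)))
  n_lines <- length(lines)

  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k] + 1L
    nexts <- other_headers[other_headers > stanza_starts[k]]
    to <- if (length(nexts)) nexts[1] - 1L else n_lines
    if (from > to) {
      stop("malformed [Term] stanza with no id at line ", stanza_starts[k])
    }
    body <- lines[from:to]
    cls <- list(id = NA_character_, label = NA_character_,
                synonyms = character(0), parents = character(0),
                obsolete = FALSE)
    for (j in seq_along(body)) {
      ln <- body[j]
      if (!grepl(":", ln, fixed = TRUE)) next
      key <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]+:", "", ln))
      if (key == "id") {
        cls$id <- val
      } else if (key == "name") {
        cls$label <- val
      } else if (key == "synonym") {
        m <- regmatches(val, regexpr('"[^"]*"', val))
        if (length(m)) {
          syn <- substr(m, 2L, nchar(m) - 1L)
          if (nzchar(syn)) cls$synonyms <- union(cls$synonyms, syn)
        }
      } else if (key == "is_a") {
        target <- trimws(sub("!.*$", "", val))
        if (nzchar(target)) cls$parents <- union(cls$parents, target)
      } else if (key == "is_obsolete") {
        cls$obsolete <- identical(tolower(val), "true")
      }
    }
    if (is.na(cls$id) || !nzchar(cls$id)) {
      stop("malformed [Term] stanza with no id at line ", stanza_starts[k])
    }
    if (is.na(cls$label)) cls$label <- cls$id
    classes[[k]] <- cls
  }

  ids <- vapply(classes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate class id: ", ids[duplicated(ids)][1])
  }
  names(classes) <- ids

  # drop dangling parent references
  for (id in ids) {
    p <- classes[[id]]$parents
    missing <- setdiff(p, ids)
    if (length(missing)) {
      warning("dropping dangling parent reference(s) of ", id, ": ",
              paste(missing, collapse = ", "), call. = FALSE)
      classes[[id]]$parents <- setdiff(p, missing)
    }
  }

  o <- new_ontology(classes)
  check_acyclic(o)
  o
}

new_ontology <- function(classes) {
  ids <- names(classes)
  children <- lapply(stats::setNames(ids, ids), function(i) character(0))
  for (id in ids) {
    for (p in classes[[id]]$parents) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  roots <- ids[vapply(classes, function(c) length(c$parents) == 0L, logical(1))]
  structure(list(classes = classes, roots = roots, children = children),
            class = "ontology")
}

check_acyclic <- function(o) {
  ids <- names(o$classes)
  indeg <- vapply(o$classes, function(c) length(c$parents), integer(1))
  queue <- ids[indeg == 0L]
  seen <- 0L
  indeg_env <- indeg
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in o$children[[id]]) {
      indeg_env[ch] <- indeg_env[ch] - 1L
      if (indeg_env[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    start <- ids[indeg_env > 0L][1]
    path <- start
    cur <- start
    repeat {
      cur <- o$classes[[cur]]$parents[1]
      if (cur %in% path) {
        cyc <- c(path[which(path == cur):length(path)], cur)
        stop("cyclic is_a hierarchy: ", paste(cyc, collapse = " -> "))
      }
      path <- c(path, cur)
    }
  }
  invisible(o)
}

#' @export
print.ontology <- function(x, ...) {
  n_edges <- sum(vapply(x$classes, function(c) length(c$parents), integer(1)))
  n_obs <- sum(vapply(x$classes, `[[`, logical(1), "obsolete"))
  cat("<ontology> ", length(x$classes), " classes, ", n_edges,
      " is_a edges, ", length(x$roots), " roots",
      if (n_obs) paste0(", ", n_obs, " obsolete") else "", "\n", sep = "")
  invisible(x)
}

assert_class_exists <- function(o, id) {
  missing <- setdiff(id, names(o$classes))
  if (length(missing)) {
    stop("unknown class id: ", paste(missing, collapse = ", "))
  }
}

#' Reflexive transitive subclass closure
#'
#' All non-obsolete classes subsumed by `id`, including `id` itself
#' (unless obsolete). This realizes the subsumption relation used to
#' propagate term sets and mention counts up the hierarchy.
#'
#' @param o An `ontology`.
#' @param id A class identifier present in `o`.
#' @return Character vector of class ids.
#' @export
descendants <- function(o, id) {
  assert_class_exists(o, id)
  out <- character(0)
  queue <- id
  visited <- new.env(parent = emptyenv())
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (!is.null(visited[[cur]])) next
    visited[[cur]] <- TRUE
    if (!o$classes[[cur]]$obsolete) out <- c(out, cur)
    queue <- c(queue, o$children[[cur]])
  }
  out
}

#' Reflexive transitive superclass closure
#'
#' All ancestors of `id` including `id` itself, following `is_a` edges
#' upward. Traversal stops at (and excludes) any id in `stop_at`, which is
#' how propagation is capped at branch roots.
#'
#' @param o An `ontology`.
#' @param id A class identifier present in `o`.
#' @param stop_at Optional character vector of ids at which to stop;
#'   these ids and anything above them are excluded.
#' @return Character vector of class ids.
#' @export
ancestors <- function(o, id, stop_at = NULL) {
  assert_class_exists(o, id)
  out <- character(0)
  queue <- id
  visited <- new.env(parent = emptyenv())
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (!is.null(visited[[cur]])) next
    visited[[cur]] <- TRUE
    if (!is.null(stop_at) && cur %in% stop_at) next
    if (!o$classes[[cur]]$obsolete) out <- c(out, cur)
    queue <- c(queue, o$classes[[cur]]$parents)
  }
  out
}

#' Labels and synonyms attached directly to a class
#'
#' @param o An `ontology`.
#' @param id A class identifier.
#' @return Character vector: the class label plus all synonyms.
#' @export
labels_of <- function(o, id) {
  assert_class_exists(o, id)
  cls <- o$classes[[id]]
  union(cls$label, cls$synonyms)
}

#' All terms that can refer to a class
#'
#' The union of labels and synonyms over the subclass closure of `id`:
#' every string that, under subsumption semantics, denotes an instance of
#' the class. This is the term set that class-level co-occurrence
#' statistics are defined over.
#'
#' @param o An `ontology`.
#' @param id A class identifier.
#' @return Character vector of surface strings.
#' @export
terms_of <- function(o, id) {
  ds <- descendants(o, id)
  unique(unlist(lapply(ds, function(d) labels_of(o, d)), use.names = FALSE))
}

#' Extract an ontology branch
#'
#' Union of the subclass closures below one or more roots. Used to restrict
#' dictionaries to, e.g., the pathogen groups of a taxonomy or the
#' infectious-disease branch of a disease ontology; classes outside the
#' selected branch are never tagged.
#'
#' @param o An `ontology`.
#' @param root_ids Character vector of class ids, all present in `o`.
#' @return Character vector of non-obsolete class ids (no duplicates).
#' @export
extract_branch <- function(o, root_ids) {
  assert_class_exists(o, root_ids)
  unique(unlist(lapply(root_ids, function(r) descendants(o, r)),
                use.names = FALSE))
}

#' Summary statistics for an ontology
#'
#' @param o An `ontology`.
#' @return Named list: `n_classes`, `n_edges`, `n_roots`, `n_obsolete`,
#'   `n_terms` (total labels + synonyms on non-obsolete classes).
#' @export
ontology_stats <- function(o) {
  stopifnot(inherits(o, "ontology"))
  live <- Filter(function(c) !c$obsolete, o$classes)
  list(
    n_classes = length(o$classes),
    n_edges = sum(vapply(o$classes, function(c) length(c$parents), integer(1))),
    n_roots = length(o$roots),
    n_obsolete = length(o$classes) - length(live),
    n_terms = sum(vapply(live, function(c) 1L + length(c$synonyms), integer(1)))
  )
}
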