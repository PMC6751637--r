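#' Read a pipeline run configuration
#'
#' One flat JSON (or YAML, if the yaml package is installed) file whose
#' keys mirror the CLI flags; see [run_pipeline()] for the fields.
#'
#' @param path Config file (`.json`, `.yaml` or `.yml`).
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

default_run_config <- function() {
  list(min_length = 3L, npmi_threshold = 0.2, count_threshold = 10L,
       abbrev_filter = TRUE, whole_corpus_marginals = FALSE,
       write_nt = FALSE)
}

#' Run the full association-mining pipeline
#'
#' Executes build-dict, tag, extract and (optionally) evaluate as one
#' reproducible run: parses both ontologies, builds refined dictionaries
#' over the configured branches, tags the corpus, counts propagated
#' co-occurrences, applies the NPMI/count thresholds and writes every
#' intermediate artifact plus a machine-readable JSON report (input
#' checksums, parameters, stage timings, output row counts). Identical
#' configuration and inputs produce a byte-identical association TSV.
#'
#' @param config A named list or a path readable by [read_run_config()].
#'   Required fields: `pathogen_obo`, `disease_obo`, `corpus`, `out_dir`.
#'   Optional: `pathogen_roots`, `disease_roots` (character vectors;
#'   default = ontology roots), `stoplist` (file path), `min_length` (3),
#'   `npmi_threshold` (0.2), `count_threshold` (10), `abbrev_filter`
#'   (TRUE), `whole_corpus_marginals` (FALSE), `cap_roots` (ids excluded
#'   from upward propagation; defaults to the branch roots, an empty
#'   vector disables the cap), `reference` (TSV of reference pairs),
#'   `write_nt` (also export N-Triples).
#' @return The run report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)

  required <- c("pathogen_obo", "disease_obo", "corpus", "out_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("validation error: missing config field(s): ",
         paste(missing, collapse = ", "))
  }
  for (f in c("pathogen_obo", "disease_obo", "corpus", "stoplist",
              "reference")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p) && !dir.exists(p)) {
      stop("validation error: ", f, " path does not exist: ", p)
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  stoplist <- if (is.null(cfg$stoplist)) default_stoplist()
              else default_stoplist(cfg$stoplist)

  po <- stage("parse_pathogen_ontology", parse_obo(cfg$pathogen_obo))
  do_ <- stage("parse_disease_ontology", parse_obo(cfg$disease_obo))
  p_roots <- if (is.null(cfg$pathogen_roots)) po$roots else cfg$pathogen_roots
  d_roots <- if (is.null(cfg$disease_roots)) do_$roots else cfg$disease_roots

  p_branch <- extract_branch(po, p_roots)
  d_branch <- extract_branch(do_, d_roots)
  p_dict <- stage("build_pathogen_dictionary",
                  build_dictionary(po, p_branch, "pathogen",
                                   min_length = cfg$min_length,
                                   stoplist = stoplist))
  d_dict <- stage("build_disease_dictionary",
                  build_dictionary(do_, d_branch, "disease",
                                   min_length = cfg$min_length,
                                   stoplist = stoplist))
  write_dictionary_tsv(p_dict, file.path(cfg$out_dir, "pathogen_dict.tsv"))
  write_dictionary_tsv(d_dict, file.path(cfg$out_dir, "disease_dict.tsv"))

  corpus <- stage("read_corpus", read_corpus(cfg$corpus))
  tagged <- stage("tag", tag_corpus(corpus, p_dict, d_dict,
                                    abbrev_filter = isTRUE(cfg$abbrev_filter)))
  write_tagged_jsonl(tagged, file.path(cfg$out_dir, "tagged.jsonl"))

  # propagation stops below the branch roots by default: associations at
  # the level of "pathogen" or "disease" as such are vacuous
  cap_roots <- if ("cap_roots" %in% names(cfg)) cfg$cap_roots
               else c(p_roots, d_roots)
  if (!length(cap_roots)) cap_roots <- NULL
  counts <- stage("count", count_cooccurrences(
    tagged, po, do_, cap_roots = cap_roots,
    whole_corpus_marginals = isTRUE(cfg$whole_corpus_marginals)))
  assoc <- stage("extract", extract_associations(
    counts, npmi_threshold = cfg$npmi_threshold,
    count_threshold = cfg$count_threshold))
  assoc_path <- file.path(cfg$out_dir, "associations.tsv")
  write_associations_tsv(assoc, assoc_path, po, do_)
  if (isTRUE(cfg$write_nt)) {
    write_associations_nt(assoc, file.path(cfg$out_dir, "associations.nt"))
  }

  evaluation <- NULL
  if (!is.null(cfg$reference)) {
    ref <- read_reference_tsv(cfg$reference)
    res <- stage("evaluate", recall_against(assoc, ref))
    evaluation <- list(reference = ref$name,
                       n_reference_pairs = length(ref$pairs),
                       recall = res$recall,
                       n_found = length(res$found),
                       n_missed = length(res$missed))
  }

  input_files <- Filter(function(p) !is.null(p) && file.exists(p) &&
                          !dir.exists(p),
                        cfg[c("pathogen_obo", "disease_obo", "corpus",
                              "stoplist", "reference")])
  report <- list(
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = as.list(tools::md5sum(unlist(input_files))),
    stage_timings_s = timings,
    n_documents = nrow(corpus),
    n_sentences = length(tagged),
    n_cooccurrence_sentences = counts$n_tot,
    n_pairs_counted = length(counts$n_CD),
    n_associations = nrow(assoc),
    evaluation = evaluation,
    outputs = list(associations = assoc_path))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(report)
}
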