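test_that("split_sentences segments prose and keeps offsets", {
  doc <- list(doc_id = "d1", text = "A causes B. C causes D.")
  s <- split_sentences(doc)
  expect_equal(nrow(s), 2L)
  expect_equal(s$index, 0:1)
  # offsets map each sentence back into the document verbatim
  for (i in seq_len(nrow(s))) {
    expect_equal(substr(doc$text, s$char_offset[i] + 1L,
                        s$char_offset[i] + nchar(s$text[i])), s$text[i])
  }
})

test_that("split_sentences does not break at known abbreviations", {
  s <- split_sentences("Infection by E. coli is common.")
  expect_equal(nrow(s), 1L)
  s2 <- split_sentences(
    "Samples were analyzed by Smith et al. and processed further.")
  expect_equal(nrow(s2), 1L)
  s3 <- split_sentences("See Fig. 2 for details. The end came later.")
  expect_equal(nrow(s3), 2L)
  expect_match(s3$text[1], "^See Fig")
})

test_that("split_sentences handles empty and whitespace documents", {
  expect_equal(nrow(split_sentences(list(doc_id = "d", text = "   "))), 0L)
  expect_equal(nrow(split_sentences(list(doc_id = "d", text = ""))), 0L)
})

test_that("split_sentences loses no non-whitespace characters", {
  txt <- paste("Dr. Smith reported three cases.",
               "Patients with q fever recovered!",
               "Was E. coli involved? Yes.")
  s <- split_sentences(txt)
  strip <- function(x) gsub("[[:space:]]", "", paste(x, collapse = ""))
  expect_equal(strip(s$text), strip(txt))
})

test_that("tag_sentence prefers the longest match, ties to the leftmost", {
  fx <- tiny_mining_fixture()
  m <- tag_sentence("dengue hemorrhagic fever was confirmed", fx$d_dict)
  expect_length(m, 1L)
  expect_equal(m[[1]]$surface, "dengue hemorrhagic fever")
  expect_equal(m[[1]]$class_ids, "D:2")
  expect_equal(m[[1]]$category, "disease")
})

test_that("tagged spans index the sentence text and align on word boundaries", {
  fx <- tiny_mining_fixture()
  sent <- "Cases of dengue disease and dengue shock syndrome rose."
  m <- tag_sentence(sent, fx$d_dict)
  expect_length(m, 2L)
  for (x in m) {
    expect_equal(substr(sent, x$start + 1L, x$end), x$surface)
  }
  # no match inside a longer word: "rat" must not fire inside "strategy"
  o <- parse_obo(make_obo(c("Z:1", "Z:2"), labels = c("animals", "rat"),
                          parents = list("Z:1" = character(0), "Z:2" = "Z:1")))
  d <- build_dictionary(o, names(o$classes), "pathogen",
                        stoplist = character(0))
  expect_length(tag_sentence("The strategy worked on rats.", d), 0L)
  expect_length(tag_sentence("One rat was caught.", d), 1L)
})

test_that("an unrefined dictionary tags geographic names; the stoplist stops it", {
  o <- parse_obo(make_obo(
    c("N:1", "N:2"), labels = c("bacteria", "Katanga"),
    parents = list("N:1" = character(0), "N:2" = "N:1")))
  unrefined <- build_dictionary(o, names(o$classes), "pathogen",
                                stoplist = character(0))
  m <- tag_sentence("Katanga province reported cases.", unrefined)
  expect_length(m, 1L)
  expect_equal(m[[1]]$class_ids, "N:2")
  # the documented false-positive mode is prevented upstream by refinement
  refined <- build_dictionary(o, names(o$classes), "pathogen",
                              stoplist = default_stoplist())
  expect_length(tag_sentence("Katanga province reported cases.", refined), 0L)
})

test_that("matching is case-insensitive except for short all-caps forms", {
  o <- parse_obo(make_obo(
    c("D:1", "D:2"), labels = c("diseases", "amyotrophic lateral sclerosis"),
    parents = list("D:1" = character(0), "D:2" = "D:1"),
    synonyms = list("D:2" = "ALS")))
  d <- build_dictionary(o, names(o$classes), "disease",
                        stoplist = character(0))
  expect_length(tag_sentence("Amyotrophic Lateral Sclerosis progressed.", d),
                1L)
  expect_length(tag_sentence("Patients with ALS declined.", d), 1L)
  # lower-case "als" must not trigger the case-sensitive abbreviation
  expect_length(tag_sentence("als is a common german word.", d), 0L)
})

test_that("a sentence without dictionary terms yields no mentions", {
  fx <- tiny_mining_fixture()
  expect_length(tag_sentence("Nothing relevant happened here.", fx$d_dict), 0L)
})

test_that("tagging matches a brute-force substring matcher and is deterministic", {
  fx <- tiny_mining_fixture()
  set.seed(99)
  frags <- c("dengue disease", "dengue hemorrhagic fever", "breakbone fever",
             "dengue virus", "dengue virus type 2", "pathogenia",
             "was found in", "patients with", "no match here", "and")
  for (rep in 1:20) {
    sent <- paste(sample(frags, sample(2:6, 1), replace = TRUE),
                  collapse = " ")
    for (dict in list(fx$p_dict, fx$d_dict)) {
      got <- tag_sentence(sent, dict)
      want <- oracle_tag(sent, dict)
      expect_equal(lapply(got, function(m) m[c("class_ids", "start", "end",
                                               "surface")]),
                   want, info = sent)
      expect_identical(got, tag_sentence(sent, dict))
    }
  }
})

test_that("abbreviation detection follows the long-form letter alignment", {
  ab <- detect_abbreviations("Amyotrophic Lateral Sclerosis (ALS) progresses.")
  expect_equal(ab[["ALS"]], "Amyotrophic Lateral Sclerosis")
  # short forms failing the character-class test are rejected
  expect_length(detect_abbreviations("the control group (n = 12)"), 0L)
  # one short form can map to several long forms within a document
  ab2 <- detect_abbreviations(paste(
    "Teams trained in advanced life support (ALS) responded.",
    "A diagnosis of Amyotrophic Lateral Sclerosis (ALS) followed."))
  expect_setequal(ab2[["ALS"]],
                  c("advanced life support", "Amyotrophic Lateral Sclerosis"))
})

test_that("abbreviation long forms are capped and must align in order", {
  # long form window respects min(|SF|+5, 2|SF|) words
  ab <- detect_abbreviations(
    "word word word severe acute respiratory syndrome (SARS) spread.")
  expect_equal(ab[["SARS"]], "severe acute respiratory syndrome")
  # characters out of order: no pair recorded
  expect_length(detect_abbreviations("sclerosis lateral (ALS)"), 0L)
})

test_that("the disease-abbreviation filter implements both keep rules", {
  o <- parse_obo(make_obo(
    c("D:1", "D:2", "D:3"),
    labels = c("diseases", "amyotrophic lateral sclerosis",
               "severe acute respiratory syndrome"),
    parents = list("D:1" = character(0), "D:2" = "D:1", "D:3" = "D:1"),
    synonyms = list("D:2" = "ALS", "D:3" = "SARS")))
  dict <- build_dictionary(o, names(o$classes), "disease",
                           stoplist = character(0))

  # only a non-disease expansion in the document: the mention is removed
  doc1 <- list(doc_id = "d1",
               text = "Advanced Life Support (ALS) units responded. ALS was given.")
  s1 <- split_sentences(doc1)
  m1 <- tag_sentence(s1[2, ], dict)
  expect_length(m1, 1L)
  kept1 <- filter_disease_abbreviations(m1, detect_abbreviations(doc1),
                                        dict, doc1)
  expect_length(kept1, 0L)

  # the ontology long form occurs in the document: kept via rule (a)
  doc2 <- list(doc_id = "d2",
               text = "Patients had amyotrophic lateral sclerosis. ALS progressed.")
  s2 <- split_sentences(doc2)
  m2 <- tag_sentence(s2[2, ], dict)
  kept2 <- filter_disease_abbreviations(m2, detect_abbreviations(doc2),
                                        dict, doc2)
  expect_length(kept2, 1L)

  # a detected long form contains "syndrome": kept via rule (b)
  doc3 <- list(doc_id = "d3",
               text = paste("An outbreak of severe acute respiratory syndrome",
                            "(SARS) began. SARS spread fast."))
  s3 <- split_sentences(doc3)
  m3 <- tag_sentence(s3[2, ], dict)
  kept3 <- filter_disease_abbreviations(m3, detect_abbreviations(doc3),
                                        dict, doc3)
  expect_length(kept3, 1L)
})

test_that("the filter returns a subset and never touches pathogen mentions", {
  fx <- tiny_mining_fixture()
  doc <- list(doc_id = "d", text = "ALS and dengue virus were discussed.")
  s <- split_sentences(doc)
  path_m <- tag_sentence(s[1, ], fx$p_dict)
  expect_length(path_m, 1L)
  fake_disease <- list(list(class_ids = "D:9", category = "disease",
                            start = 0L, end = 3L, surface = "ALS"))
  all_m <- c(path_m, fake_disease)
  kept <- filter_disease_abbreviations(all_m, detect_abbreviations(doc),
                                       fx$d_dict, doc)
  expect_length(Filter(function(m) m$category == "disease", kept), 0L)
  expect_length(Filter(function(m) m$category == "pathogen", kept), 1L)
  expect_true(length(kept) <= length(all_m))
})

test_that("corpora round-trip through JSONL and directories of text files", {
  corpus <- data.frame(doc_id = c("a", "b"),
                       text = c("One sentence. Two sentences.",
                                "Only one here."),
                       stringsAsFactors = FALSE)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, jl)
  expect_equal(read_corpus(jl), corpus)

  dir <- withr::local_tempdir()
  writeLines("Text of alpha.", file.path(dir, "alpha.txt"))
  writeLines("Text of beta.", file.path(dir, "beta.txt"))
  got <- read_corpus(dir)
  expect_setequal(got$doc_id, c("alpha", "beta"))
})

test_that("tagged sentences round-trip through JSONL", {
  fx <- tiny_mining_fixture()
  corpus <- data.frame(
    doc_id = "d1",
    text = "Dengue virus was isolated from patients with dengue disease.",
    stringsAsFactors = FALSE)
  tagged <- tag_corpus(corpus, fx$p_dict, fx$d_dict)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tagged_jsonl(tagged, path)
  back <- read_tagged_jsonl(path)
  expect_equal(length(back), length(tagged))
  expect_equal(back[[1]]$mentions, tagged[[1]]$mentions)
  expect_equal(back[[1]]$doc_id, tagged[[1]]$doc_id)
})

test_that("planted surface forms are fully recovered on a clean corpus", {
  # recall of the tagger itself is 1 when every sentence embeds a known form
  fx <- tiny_mining_fixture()
  forms <- names(fx$d_dict$entries)
  corpus <- data.frame(
    doc_id = sprintf("c%d", seq_along(forms)),
    text = sprintf("Several cases of %s were confirmed today.", forms),
    stringsAsFactors = FALSE)
  tagged <- tag_corpus(corpus, fx$p_dict, fx$d_dict)
  hits <- vapply(tagged, function(ts) length(ts$mentions) >= 1L, logical(1))
  expect_true(all(hits))
})
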