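Package: padminer
Title: Ontology-Based Mining of Pathogen-Disease Associations from Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts pathogen-disease associations from a document corpus by
    dictionary-based recognition of ontology classes in sentences, a rule-based
    disease-abbreviation filter, subsumption-propagated co-occurrence counting,
    and a class-level normalized pointwise mutual information (NPMI) score with
    fixed acceptance thresholds. Includes an OBO flat-file parser, refined
    term-dictionary construction from ontology branches, evaluation against
    reference association lists, and a seeded generator of miniature ontologies
    and corpora with planted associations for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
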