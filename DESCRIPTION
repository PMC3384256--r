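Package: standoffeval
Title: Evaluation Tools for Biomedical Event Extraction and Protein
    Coreference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parse, validate, and serialize standoff-annotated corpora
    (text-bound, event, modification, and coreference relation records)
    and score predicted annotations against gold annotations.  Implements
    the family of event matching modes used in community evaluations of
    bio-molecular event extraction -- strict matching, approximate span
    matching with one-word extension, approximate recursive matching, and
    event decomposition -- together with task-level scoring of core
    events, secondary arguments, and negation/speculation modifications.
    Also implements surface and protein-mode coreference scoring with
    antecedent chain tracing, descriptive corpus statistics, and a seeded
    synthetic corpus generator with controlled error injection for
    validating evaluators against known-by-construction scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
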