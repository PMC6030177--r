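Package: floratrait
Title: Rule-Based Extraction of Morphological Characters from Spanish
    Plant Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts telegraphic Spanish plant morphological descriptions
    into structured records of botanical structures, characters (states,
    measurement ranges, constraints) and structure-structure relations,
    emitted as XML. Implements a rule-based semantic annotator operating on
    comma-delimited chunks: lexicon part-of-speech tagging with an
    unsupervised bootstrapping knowledge base, heuristic dependency trees,
    glossary-driven character-name resolution, measurement range parsing
    with atypical extremes, and character-to-structure association by
    gender and number agreement. Includes a synthetic description generator
    with gold annotations and precision/recall/F-1 scoring of the four
    annotation aspects (structures, characters, association, conjunctions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
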