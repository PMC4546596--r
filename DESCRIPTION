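Package: cnemr
Title: Structured Triple Extraction from Chinese Clinical Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts free-text Chinese clinical narratives (electronic
    medical record History of Present Illness sections) into structured
    (time, event, description) triples. Provides categorized medical
    lexicon management, weakly-supervised lexicon enrichment by iterative
    character-context pattern induction, compound-term assembly from
    body-part prefixes and directional modifiers, dictionary-driven
    longest-match term tagging with negation and future-mention filtering,
    rule-based temporal expression extraction with statement-level
    scoping, and event-description linking with a linear support vector
    machine over local-context and Normalized Google Distance features.
    Ships a seeded synthetic corpus generator with complete gold
    annotations and exact/inexact span-level evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stringi,
    tibble,
    jsonlite,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
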