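Package: citancer
Title: Citation Contexts and Sentence Annotations from JATS XML Articles
Version: 0.1.0
Authors@R:
    person("citancer", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Extracts bibliographies, inline citations (explicit xref-tagged
    and implicitly-mentioned range citations), and their citation contexts
    (citing sentences) from JATS-standard XML articles such as those in the
    PubMed Central open access subset. Every sentence is labelled with its
    article component, a rule-based IMRaD category, and text progression, and
    written as a 14-column tab-separated record. Cited-work identifiers tagged
    in the XML are reconciled against external citation-matcher candidate
    tables and Entrez-style cited-PMID lists. A deterministic synthetic
    article generator with ground-truth manifests makes the full pipeline
    testable without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    xml2 (>= 1.3)
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
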