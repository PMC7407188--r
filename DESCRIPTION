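Package: ddiscreen
Title: Domain-Mediated Interactor Screening of Virtual Metaproteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens genus-resolved virtual metaproteomes for proteins that
    can interact with a query protein through known Pfam domain-domain
    interactions. The query protein's domain architecture (hmmscan domtblout)
    is expanded into its set of potentially interacting domains via an
    iPfam-style partner table; per-group virtual proteomes are built by
    genus filtering of an annotated protein table, screened for proteins
    carrying at least one partner domain, and partitioned across groups.
    Per-domain occurrence is compared between groups with a chi-squared
    observed/expected model, and gene-ontology enrichment of the screened
    sets uses one-sided Fisher tests on true-path-propagated annotations
    with Benjamini-Hochberg adjustment. A seeded synthetic-data generator
    emulating healthy and inflammatory-bowel-disease gut communities
    supports end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
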