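Package: fieldcollect
Title: Hierarchical Field Data Collection with Skip Logic, Validation and
    Client-Server Synchronisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Define multi-form data-collection projects as a declarative XML
    (or JSON) document, link forms in a linear one-to-many hierarchy with
    optional branch forms, execute interview sessions with jump (skip) logic
    and field validation (required, integer/decimal ranges, date and time
    formats, regular expressions, double entry), store completed entries in a
    hierarchical repository that enforces parent-key integrity and key
    uniqueness, synchronise entries top-down from clients to a server store
    with idempotent retry and deferred media transfer, and export collected
    data as CSV/TSV tables or nested XML. Includes deterministic fixture
    generators (a schools demonstration project and seeded random projects and
    collection runs) so every component is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
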