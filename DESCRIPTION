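Package: iprsummary
Title: Summary Statistics and Reports for InterProScan Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses InterProScan raw-XML result files into a seven-table
    SQLite database, computes per-member-database signature count statistics
    with Gene Ontology annotations, and exports pie/bar charts, browsable
    HTML reports, CSV/XLSX tables and reloadable session archives. Includes
    a seeded synthetic-data generator that emits dialect-conformant XML
    together with a ground-truth manifest, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    DBI,
    RSQLite,
    jsonlite,
    zip,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
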