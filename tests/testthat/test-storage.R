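test_that("a fresh database gets exactly the seven application tables", {
  con <- local_db()
  info <- init_schema(con)
  expect_length(info$table_names, 7L)
  expect_setequal(DBI::dbListTables(con), info$table_names)
  # idempotent re-run, no data loss
  load_run(con, parse_interproscan_xml(local_toy_xml()))
  info2 <- init_schema(con)
  expect_identical(info2, info)
  expect_identical(
    DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM protein")$n, 3L)
})

test_that("a database stamped at another version refuses to load", {
  con <- open_db()
  withr::defer(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA user_version = 99")
  expect_error(init_schema(con), "migration")
})

test_that("loading the toy run fills the tables with the expected counts", {
  con <- local_db()
  run <- parse_interproscan_xml(local_toy_xml())
  stats <- load_run(con, run)
  expect_identical(stats, list(proteins_loaded = 3L, matches_loaded = 3L,
                               locations_loaded = 3L, go_links_loaded = 1L))
  # re-loading merges by primary key: protein count unchanged
  load_run(con, run)
  expect_identical(
    DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM protein")$n, 3L)
  expect_identical(
    DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM go_annotation")$n, 1L)
})

test_that("an empty run loads as a no-op", {
  con <- local_db()
  stats <- load_run(con, ipr_run())
  expect_true(all(unlist(stats) == 0L))
  expect_identical(
    DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM protein")$n, 0L)
})

test_that("signature counts match hand enumeration on the toy fixture", {
  con <- local_toy_db()
  counts <- query_signature_counts(con, "PFAM")
  expect_identical(counts$signature_accession, c("PF00001", "PF00002"))
  expect_identical(counts$count, c(2L, 1L))
  expect_identical(nrow(query_signature_counts(con, "SMART")), 0L)
})

test_that("equal counts are ordered by accession ascending", {
  run <- make_run(list(one_match_protein("A", "PF00009"),
                       one_match_protein("B", "PF00001")))
  con <- local_db()
  load_run(con, run)
  counts <- query_signature_counts(con, "PFAM")
  expect_identical(counts$signature_accession, c("PF00001", "PF00009"))
})

test_that("protein counting never exceeds match counting", {
  # one protein hit twice by the same signature (two match records)
  p <- ipr_protein("multi", length = 500L, entries = list(
    ipr_entry("noIPR", matches = list(
      ipr_match("PF00010", member_db = "PFAM",
                locations = list(ipr_location(1, 50))),
      ipr_match("PF00010", member_db = "PFAM",
                locations = list(ipr_location(100, 150)))))))
  con <- local_db()
  stats <- load_run(con, make_run(list(p)))
  expect_identical(stats$matches_loaded, 2L)
  by_p <- query_signature_counts(con, "PFAM", counting = "proteins")
  by_m <- query_signature_counts(con, "PFAM", counting = "matches")
  expect_identical(by_p$count, 1L)
  expect_identical(by_m$count, 2L)
})

test_that("member databases list alphabetically", {
  expect_identical(query_member_dbs(local_toy_db()), "PFAM")
  expect_identical(query_member_dbs(local_db()), character(0))
  g <- local_generated(n_proteins = 50L, seed = 5L)
  con <- local_db()
  load_run(con, parse_interproscan_xml(g$xml))
  expect_identical(query_member_dbs(con),
                   sort(c("PFAM", "SMART", "PROSITE", "GENE3D")))
})

test_that("the signature table carries de-duplicated, sorted GO annotations", {
  con <- local_toy_db()
  tab <- query_signature_table(con, "PFAM")
  expect_identical(tab$signature_accession, c("PF00001", "PF00002"))
  expect_identical(tab$count, c(2L, 1L))
  expect_identical(tab$go[[1L]]$go_id, "GO:0005524")
  expect_identical(tab$go[[1L]]$description, "ATP binding")
  # signature under noIPR: no GO annotations
  expect_identical(nrow(tab$go[[2L]]), 0L)
})

test_that("duplicate GO classifications collapse to one row", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<interpro_matches>",
    '  <protein id="P" length="200">',
    '    <interpro id="IPR000123" name="x" type="Domain">',
    '      <classification id="GO:0008150" class_type="GO">',
    "        <category>Biological Process</category>",
    "        <description>biological_process</description></classification>",
    '      <classification id="8150" class_type="GO">',
    "        <category>Biological Process</category>",
    "        <description>biological_process</description></classification>",
    '      <match id="PF00077" name="y" dbname="PFAM">',
    '        <location start="1" end="99" score="1e-3"/>',
    "      </match></interpro></protein>",
    "</interpro_matches>"), path)
  con <- local_db()
  stats <- load_run(con, parse_interproscan_xml(path))
  expect_identical(stats$go_links_loaded, 1L)
  tab <- query_signature_table(con, "PFAM")
  expect_identical(tab$go[[1L]]$go_id, "GO:0008150")
})

test_that("queries are stable across repeated calls", {
  g <- local_generated(n_proteins = 60L, seed = 9L)
  con <- local_db()
  load_run(con, parse_interproscan_xml(g$xml))
  for (d in query_member_dbs(con)) {
    expect_identical(query_signature_counts(con, d),
                     query_signature_counts(con, d))
  }
})
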