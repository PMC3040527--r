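read_bytes <- function(path) readBin(path, "raw", file.size(path))

test_that("the HTML report reproduces the signature table on the toy fixture", {
  con <- local_toy_db()
  out <- withr::local_tempfile()
  idx <- export_html(con, out, deterministic = TRUE)
  expect_true(file.exists(idx))
  page <- paste(readLines(file.path(out, "db_PFAM.html")), collapse = "\n")
  tab <- query_signature_table(con, "PFAM")
  for (r in seq_len(nrow(tab))) {
    expect_match(page, sprintf("<td>%s</td><td>%s</td><td>%d</td>",
                               tab$signature_accession[r],
                               tab$signature_name[r], tab$count[r]),
                 fixed = TRUE)
  }
  expect_match(page, "https://www.ebi.ac.uk/QuickGO/term/GO:0005524",
               fixed = TRUE)
  expect_match(page, "<svg", fixed = TRUE)
  index <- paste(readLines(idx), collapse = "\n")
  expect_match(index, "db_PFAM.html", fixed = TRUE)
})

test_that("report charts only show that database's signatures plus 'other'", {
  g <- local_generated(n_proteins = 100L, seed = 21L)
  con <- local_db()
  load_run(con, parse_interproscan_xml(g$xml))
  out <- withr::local_tempfile()
  export_html(con, out, top_n = 5L, deterministic = TRUE)
  dbs <- query_member_dbs(con)
  expect_length(dbs, 4L)
  for (d in dbs) {
    page <- paste(readLines(file.path(out, paste0("db_", d, ".html"))),
                  collapse = "\n")
    counts <- query_signature_counts(con, d)
    cd <- make_chart_data(counts, top_n = 5L)
    for (lab in cd$labels) expect_match(page, lab, fixed = TRUE)
    if (cd$other_count > 0L) expect_match(page, "other", fixed = TRUE)
    # every signature is in the table even when bucketed out of the chart
    for (acc in counts$signature_accession) {
      expect_match(page, sprintf("<td>%s</td>", acc), fixed = TRUE)
    }
  }
})

test_that("an empty database yields a zero-count index and no db pages", {
  out <- withr::local_tempfile()
  export_html(local_db(), out, deterministic = TRUE)
  expect_identical(list.files(out), "index.html")
  expect_match(paste(readLines(file.path(out, "index.html")),
                     collapse = "\n"),
               "<tr><th>proteins</th><td>0</td></tr>", fixed = TRUE)
})

test_that("the url backend embeds an image-chart link instead of SVG", {
  out <- withr::local_tempfile()
  export_html(local_toy_db(), out, chart_backend = "url",
              deterministic = TRUE)
  page <- paste(readLines(file.path(out, "db_PFAM.html")), collapse = "\n")
  expect_match(page, "<img", fixed = TRUE)
  expect_match(page, "chart?cht=p", fixed = TRUE)
  expect_no_match(page, "<svg", fixed = TRUE)
})

test_that("CSV export round-trips through a CSV reader", {
  con <- local_toy_db()
  out <- withr::local_tempfile()
  export_tables(con, out, "csv")
  df <- utils::read.csv(file.path(out, "PFAM.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(go_ids = "character",
                                       go_names = "character"))
  tab <- query_signature_table(con, "PFAM")
  expect_identical(df$signature_accession, tab$signature_accession)
  expect_identical(df$count, tab$count)
  expect_identical(df$go_ids, c("GO:0005524", ""))
  expect_identical(df$go_names, c("ATP binding", ""))
})

test_that("empty databases export a header-only CSV", {
  out <- withr::local_tempfile()
  export_tables(local_db(), out, "csv")
  files <- list.files(out, full.names = TRUE)
  expect_length(files, 1L)
  lines <- readLines(files[[1L]])
  expect_length(lines, 1L)
  expect_match(lines, "signature_accession", fixed = TRUE)
})

test_that("fields containing the CSV separator are quoted, not split", {
  run <- make_run(list(one_match_protein(
    "P1", "PF00042", sig_name = "name, with comma")))
  con <- local_db()
  load_run(con, run)
  out <- withr::local_tempfile()
  export_tables(con, out, "csv")
  df <- utils::read.csv(file.path(out, "PFAM.csv"), stringsAsFactors = FALSE)
  expect_identical(nrow(df), 1L)
  expect_identical(df$signature_name, "name, with comma")
})

test_that("unknown export formats are rejected", {
  expect_error(export_tables(local_toy_db(), tempfile(), "pdf"), "pdf")
})

test_that("XLSX export opens in an independent spreadsheet reader", {
  con <- local_toy_db()
  out <- withr::local_tempfile(fileext = ".xlsx")
  export_tables(con, out, "xlsx")
  got <- system2("python", c("-c", shQuote(paste0(
    "import openpyxl, sys\n",
    "wb = openpyxl.load_workbook(sys.argv[1])\n",
    "ws = wb['PFAM']\n",
    "for row in ws.iter_rows(values_only=True):\n",
    "    print('|'.join('' if v is None else str(v) for v in row))")),
    shQuote(out)), stdout = TRUE)
  expect_identical(got[1L],
                   "signature_accession|signature_name|count|go_ids|go_names")
  expect_identical(got[2L], "PF00001|ABC_membrane|2|GO:0005524|ATP binding")
  expect_identical(got[3L], "PF00002|7tm_2|1||")
})

test_that("sessions round-trip every query result", {
  for (src in c("toy", "generated")) {
    con <- if (src == "toy") local_toy_db() else {
      g <- local_generated(n_proteins = 50L, seed = 31L)
      con2 <- local_db()
      load_run(con2, parse_interproscan_xml(g$xml))
      con2
    }
    archive <- withr::local_tempfile(fileext = ".zip")
    save_session(con, list(source = src, top_n = 10L), archive)
    ses <- load_session(archive)
    expect_identical(ses$config$source, src)
    expect_identical(query_member_dbs(ses$db), query_member_dbs(con))
    for (d in query_member_dbs(con)) {
      expect_identical(query_signature_counts(ses$db, d),
                       query_signature_counts(con, d))
    }
    expect_identical(compute_overview(ses$db), compute_overview(con))
    DBI::dbDisconnect(ses$db)
  }
})

test_that("truncated archives and version mismatches refuse to load", {
  con <- local_toy_db()
  archive <- withr::local_tempfile(fileext = ".zip")
  save_session(con, list(), archive)
  truncated <- withr::local_tempfile(fileext = ".zip")
  writeBin(readBin(archive, "raw", 120), truncated)
  expect_error(load_session(truncated), "corrupt|archive")

  # rebuild the archive with a doctored manifest version
  exdir <- withr::local_tempfile()
  zip::unzip(archive, exdir = exdir)
  mf <- jsonlite::read_json(file.path(exdir, "manifest.json"))
  mf$version <- 999L
  jsonlite::write_json(mf, file.path(exdir, "manifest.json"),
                       auto_unbox = TRUE)
  bad <- withr::local_tempfile(fileext = ".zip")
  zip::zip(normalizePath(bad, mustWork = FALSE),
           files = c("manifest.json", "session.db"),
           root = exdir, mode = "mirror")
  expect_error(load_session(bad), "version")
})

test_that("regenerated deterministic reports are byte-identical", {
  con <- local_toy_db()
  d1 <- withr::local_tempfile()
  d2 <- withr::local_tempfile()
  export_html(con, d1, deterministic = TRUE)
  export_html(con, d2, deterministic = TRUE)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    expect_identical(read_bytes(file.path(d1, f)),
                     read_bytes(file.path(d2, f)))
  }
})
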