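# HTML report, CSV/XLSX table export, and reloadable session archives.

html_escape <- xml_escape

sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

# One exportable table per member database: counts plus semicolon-joined
# GO ids/names in go_id order.
export_frame <- function(db, member_db) {
  tab <- query_signature_table(db, member_db)
  data.frame(
    signature_accession = tab$signature_accession,
    signature_name = tab$signature_name,
    count = tab$count,
    go_ids = vapply(tab$go, function(g) paste(g$go_id, collapse = ";"), ""),
    go_names = vapply(tab$go, function(g) {
      paste(g$description, collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
}

#' Export a browsable HTML report
#'
#' Writes an index page with the run overview and one page per member
#' database holding that database's chart (inline SVG for the local
#' backend, an image-chart URL for the url backend) and the full signature
#' table with counts and QuickGO term links. Every signature appears in
#' the table even when the chart buckets it into "other".
#'
#' @param db Initialized connection.
#' @param out_dir Output directory (created if missing).
#' @param top_n Chart bucket size passed to [make_chart_data()].
#' @param chart_kind `"pie"` or `"bar"`.
#' @param chart_backend `"local"` or `"url"`.
#' @param counting Counting unit for the charts and tables
#'   (see [query_signature_counts()]).
#' @param deterministic Suppress timestamps so regenerated reports are
#'   byte-identical.
#' @return Path of the written `index.html`.
#' @export
export_html <- function(db, out_dir, top_n = 10L,
                        chart_kind = c("pie", "bar"),
                        chart_backend = c("local", "url"),
                        counting = "proteins", deterministic = FALSE) {
  chart_kind <- match.arg(chart_kind)
  chart_backend <- match.arg(chart_backend)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create report directory: ", out_dir, call. = FALSE)
  }
  ov <- compute_overview(db)
  dbs <- query_member_dbs(db)
  footer <- if (deterministic) "" else {
    sprintf("<footer><small>generated %s</small></footer>",
            format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  }
  style <- paste0(
    "<style>body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:4px 8px}</style>")

  pages <- character(length(dbs))
  for (i in seq_along(dbs)) {
    d <- dbs[i]
    fname <- paste0("db_", sanitize_name(d), ".html")
    pages[i] <- fname
    counts <- query_signature_counts(db, d, counting = counting)
    cd <- make_chart_data(counts, top_n = top_n,
                          title = paste0(d, " signature counts"))
    chart_html <- if (chart_backend == "local") {
      paste(chart_svg(cd, chart_spec(chart_kind, backend = "local"),
                      standalone = FALSE), collapse = "\n")
    } else {
      sprintf('<img alt="%s chart" src="%s"/>', html_escape(d),
              html_escape(build_chart_url(
                cd, chart_spec(chart_kind, backend = "url"))))
    }
    tab <- query_signature_table(db, d)
    rows <- vapply(seq_len(nrow(tab)), function(r) {
      gos <- tab$go[[r]]
      links <- if (nrow(gos) == 0L) "" else {
        paste(sprintf('<a href="%s">%s</a>%s', go_link(gos$go_id),
                      gos$go_id,
                      ifelse(nzchar(gos$description),
                             paste0(" (", html_escape(gos$description), ")"),
                             "")),
              collapse = "; ")
      }
      sprintf("<tr><td>%s</td><td>%s</td><td>%d</td><td>%s</td></tr>",
              html_escape(tab$signature_accession[r]),
              html_escape(tab$signature_name[r]),
              tab$count[r], links)
    }, "")
    page <- c(
      "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
      sprintf("<title>%s</title>", html_escape(d)), style, "</head><body>",
      sprintf("<p><a href=\"index.html\">overview</a></p><h1>%s</h1>",
              html_escape(d)),
      chart_html,
      "<table><tr><th>signature</th><th>name</th><th>count</th>",
      "<th>GO annotations</th></tr>",
      rows, "</table>", footer, "</body></html>")
    writeLines(page, file.path(out_dir, fname), useBytes = TRUE)
  }

  index <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
    "<title>InterProScan run summary</title>", style, "</head><body>",
    "<h1>InterProScan run summary</h1>",
    "<table>",
    sprintf("<tr><th>proteins</th><td>%d</td></tr>", ov$n_proteins),
    sprintf("<tr><th>proteins with a match</th><td>%d</td></tr>",
            ov$n_proteins_with_match),
    sprintf("<tr><th>member databases</th><td>%d</td></tr>",
            ov$n_member_dbs),
    sprintf("<tr><th>distinct signatures</th><td>%d</td></tr>",
            ov$n_distinct_signatures),
    sprintf("<tr><th>distinct GO terms</th><td>%d</td></tr>", ov$n_go_terms),
    "</table>",
    if (length(dbs)) c("<h2>Member databases</h2>", "<ul>",
      sprintf('<li><a href="%s">%s</a></li>', pages, html_escape(dbs)),
      "</ul>"),
    footer, "</body></html>")
  index_path <- file.path(out_dir, "index.html")
  writeLines(index, index_path, useBytes = TRUE)
  index_path
}

#' Export signature tables as CSV or XLSX
#'
#' CSV writes one file per member database into the directory `out_path`
#' (comma separator, `"` quoting, `\n` line ends, UTF-8); XLSX writes one
#' workbook at `out_path` with one sheet per member database. Both carry
#' the header `signature_accession, signature_name, count, go_ids,
#' go_names`, GO ids semicolon-joined in id order.
#'
#' @param db Initialized connection.
#' @param out_path Directory (csv) or file path (xlsx).
#' @param format `"csv"` or `"xlsx"`.
#' @return `out_path`.
#' @export
export_tables <- function(db, out_path, format = c("csv", "xlsx")) {
  if (length(format) == 1L && !format %in% c("csv", "xlsx")) {
    stop("unknown export format: ", format, call. = FALSE)
  }
  format <- match.arg(format)
  dbs <- query_member_dbs(db)
  frames <- lapply(dbs, function(d) export_frame(db, d))
  names(frames) <- dbs
  if (length(frames) == 0L) {
    frames <- list(signatures = export_frame(db, ""))
  }
  if (format == "csv") {
    dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
    for (d in names(frames)) {
      f <- file.path(out_path, paste0(sanitize_name(d), ".csv"))
      con <- file(f, open = "wb")  # binary: fixed "\n" line ends everywhere
      utils::write.csv(frames[[d]], con, row.names = FALSE, eol = "\n")
      close(con)
    }
  } else {
    write_minimal_xlsx(frames, out_path)
  }
  out_path
}

# --- minimal OOXML (xlsx) writer -------------------------------------------
# A workbook is a zip of XML parts; cells are written as inline strings or
# plain numbers. Enough of the format for spreadsheet tools to open the
# tables; no styling, no shared strings.

col_letter <- function(i) {
  s <- ""
  while (i > 0L) {
    s <- paste0(LETTERS[(i - 1L) %% 26L + 1L], s)
    i <- (i - 1L) %/% 26L
  }
  s
}

sheet_xml <- function(df) {
  header <- names(df)
  cell <- function(ref, value) {
    if (is.numeric(value) && !is.na(value)) {
      sprintf('<c r="%s"><v>%s</v></c>', ref, format(value, scientific = FALSE))
    } else {
      sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              ref, xml_escape(as.character(value)))
    }
  }
  rows <- character(nrow(df) + 1L)
  rows[1L] <- paste0('<row r="1">', paste(
    vapply(seq_along(header), function(j) {
      cell(paste0(col_letter(j), 1L), header[j])
    }, ""), collapse = ""), "</row>")
  for (r in seq_len(nrow(df))) {
    rows[r + 1L] <- paste0(sprintf('<row r="%d">', r + 1L), paste(
      vapply(seq_along(header), function(j) {
        cell(paste0(col_letter(j), r + 1L), df[[j]][r])
      }, ""), collapse = ""), "</row>")
  }
  c('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    paste0('<worksheet xmlns="http://schemas.openxmlformats.org/',
           'spreadsheetml/2006/main">'),
    "<sheetData>", rows, "</sheetData>", "</worksheet>")
}

write_minimal_xlsx <- function(frames, path) {
  root <- tempfile("xlsx")
  dir.create(file.path(root, "_rels"), recursive = TRUE)
  dir.create(file.path(root, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(root, "xl", "worksheets"), recursive = TRUE)
  n <- length(frames)
  overrides <- sprintf(
    paste0('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType=',
           '"application/vnd.openxmlformats-officedocument.spreadsheetml.',
           'worksheet+xml"/>'), seq_len(n))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    paste0('<Types xmlns="http://schemas.openxmlformats.org/package/2006/',
           'content-types">'),
    paste0('<Default Extension="rels" ContentType="application/',
           'vnd.openxmlformats-package.relationships+xml"/>'),
    '<Default Extension="xml" ContentType="application/xml"/>',
    paste0('<Override PartName="/xl/workbook.xml" ContentType="application/',
           'vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>'),
    overrides, "</Types>"),
    file.path(root, "[Content_Types].xml"), useBytes = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    paste0('<Relationships xmlns="http://schemas.openxmlformats.org/package/',
           '2006/relationships">'),
    paste0('<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
           'officeDocument/2006/relationships/officeDocument" ',
           'Target="xl/workbook.xml"/>'),
    "</Relationships>"),
    file.path(root, "_rels", ".rels"), useBytes = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    paste0('<Relationships xmlns="http://schemas.openxmlformats.org/package/',
           '2006/relationships">'),
    sprintf(paste0('<Relationship Id="rId%d" Type="http://schemas.',
                   'openxmlformats.org/officeDocument/2006/relationships/',
                   'worksheet" Target="worksheets/sheet%d.xml"/>'),
            seq_len(n), seq_len(n)),
    "</Relationships>"),
    file.path(root, "xl", "_rels", "workbook.xml.rels"), useBytes = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    paste0('<workbook xmlns="http://schemas.openxmlformats.org/',
           'spreadsheetml/2006/main" xmlns:r="http://schemas.',
           'openxmlformats.org/officeDocument/2006/relationships">'),
    "<sheets>",
    sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
            xml_escape(substr(names(frames), 1L, 31L)), seq_len(n),
            seq_len(n)),
    "</sheets>", "</workbook>"),
    file.path(root, "xl", "workbook.xml"), useBytes = TRUE)
  for (i in seq_len(n)) {
    writeLines(sheet_xml(frames[[i]]),
               file.path(root, "xl", "worksheets",
                         sprintf("sheet%d.xml", i)), useBytes = TRUE)
  }
  out <- normalizePath(path, mustWork = FALSE)
  zip::zip(out,
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels",
                     sprintf("xl/worksheets/sheet%d.xml", seq_len(n))),
           root = root, mode = "mirror")
  unlink(root, recursive = TRUE)
  invisible(out)
}

# --- session archives ------------------------------------------------------

#' Save / load a work session
#'
#' A session is a zip archive holding the SQLite database payload
#' (`session.db`) and a JSON manifest (`manifest.json` with keys `version`,
#' `created`, `source`, `config`), so a finished analysis can be reopened
#' later or on another machine. `load_session` verifies that the manifest
#' version matches the schema version of the embedded database before
#' returning.
#'
#' @param db Initialized connection (file-backed or in-memory).
#' @param config Named list of configuration values to snapshot.
#' @param out_path Path for the `.zip` archive.
#' @return `save_session` returns `out_path`; `load_session` returns
#'   `list(db = <connection>, config = <list>)`.
#' @export
save_session <- function(db, config = list(), out_path) {
  root <- tempfile("session")
  dir.create(root)
  RSQLite::sqliteCopyDatabase(db, file.path(root, "session.db"))
  manifest <- list(
    version = db_version(db),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    source = config$source %||% "",
    config = config)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out <- normalizePath(out_path, mustWork = FALSE)
  zip::zip(out, files = c("manifest.json", "session.db"), root = root,
           mode = "mirror")
  unlink(root, recursive = TRUE)
  out_path
}

#' @rdname save_session
#' @param path Path of a session archive written by `save_session`.
#' @export
load_session <- function(path) {
  exdir <- tempfile("session")
  dir.create(exdir)
  ok <- tryCatch({
    zip::unzip(path, exdir = exdir)
    TRUE
  }, error = function(e) FALSE)
  mf_path <- file.path(exdir, "manifest.json")
  db_path <- file.path(exdir, "session.db")
  if (!ok || !file.exists(mf_path) || !file.exists(db_path)) {
    stop("not a readable session archive (corrupt or truncated): ", path,
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  con <- open_db(db_path)
  if (!identical(as.integer(manifest$version), db_version(con))) {
    DBI::dbDisconnect(con)
    stop("session manifest version ", manifest$version,
         " does not match database schema version; refusing to load",
         call. = FALSE)
  }
  list(db = con, config = as.list(manifest$config))
}
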