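# Seven-table SQLite store for parsed runs. The schema follows the element
# hierarchy of the InterProScan XML: protein, member_db, signature,
# interpro_entry, protein_match, match_location, go_annotation. The database
# file is ordinary SQLite and persists for queries by other software.

SCHEMA_VERSION <- 1L

IPR_TABLES <- c("protein", "member_db", "signature", "interpro_entry",
                "protein_match", "match_location", "go_annotation")

#' Open (or create) a results database
#'
#' @param path Path to an SQLite database file, or `":memory:"`.
#' @return A DBI connection. Close with [DBI::dbDisconnect()].
#' @export
open_db <- function(path = ":memory:") {
  DBI::dbConnect(RSQLite::SQLite(), path)
}

db_version <- function(db) {
  as.integer(DBI::dbGetQuery(db, "PRAGMA user_version")[[1L]])
}

#' Initialize the seven-table schema
#'
#' Creates the application tables on a fresh database and stamps the schema
#' version. Idempotent when called again at the same version; a database
#' stamped with a different version raises a migration-required error.
#'
#' @param db DBI connection from [open_db()].
#' @return A list with `table_names` (the 7 application tables, in creation
#'   order) and `version`.
#' @export
init_schema <- function(db) {
  ver <- db_version(db)
  have <- DBI::dbListTables(db)
  if (length(have) > 0L || ver != 0L) {
    if (ver != SCHEMA_VERSION) {
      stop("database schema version ", ver, " differs from supported ",
           SCHEMA_VERSION, "; migration required", call. = FALSE)
    }
    return(list(table_names = IPR_TABLES, version = ver))
  }
  stmts <- c(
    "CREATE TABLE protein (
       protein_id TEXT PRIMARY KEY,
       length     INTEGER NOT NULL,
       crc64      TEXT NOT NULL DEFAULT '')",
    "CREATE TABLE member_db (
       db_id INTEGER PRIMARY KEY,
       name  TEXT NOT NULL UNIQUE)",
    "CREATE TABLE signature (
       accession TEXT PRIMARY KEY,
       name      TEXT NOT NULL DEFAULT '',
       db_id     INTEGER NOT NULL REFERENCES member_db(db_id))",
    "CREATE TABLE interpro_entry (
       accession  TEXT PRIMARY KEY,
       name       TEXT NOT NULL DEFAULT '',
       entry_type TEXT NOT NULL DEFAULT '')",
    "CREATE TABLE protein_match (
       match_id            INTEGER PRIMARY KEY,
       protein_id          TEXT NOT NULL REFERENCES protein(protein_id),
       signature_accession TEXT NOT NULL REFERENCES signature(accession),
       interpro_accession  TEXT NOT NULL REFERENCES interpro_entry(accession),
       status              TEXT NOT NULL DEFAULT 'T',
       evidence            TEXT NOT NULL DEFAULT '')",
    "CREATE TABLE match_location (
       location_id INTEGER PRIMARY KEY,
       match_id    INTEGER NOT NULL REFERENCES protein_match(match_id),
       start       INTEGER NOT NULL,
       end         INTEGER NOT NULL,
       score       REAL)",
    "CREATE TABLE go_annotation (
       interpro_accession TEXT NOT NULL REFERENCES interpro_entry(accession),
       go_id       TEXT NOT NULL,
       category    TEXT NOT NULL DEFAULT '',
       description TEXT NOT NULL DEFAULT '',
       PRIMARY KEY (interpro_accession, go_id))"
  )
  DBI::dbBegin(db)
  ok <- FALSE
  tryCatch({
    for (s in stmts) DBI::dbExecute(db, s)
    DBI::dbExecute(db, paste0("PRAGMA user_version = ", SCHEMA_VERSION))
    DBI::dbCommit(db)
    ok <- TRUE
  }, finally = if (!ok) DBI::dbRollback(db))
  list(table_names = IPR_TABLES, version = SCHEMA_VERSION)
}

#' Load a parsed run into the database
#'
#' Inserts all entities of the run in one transaction (all-or-nothing).
#' Dimension rows shared between proteins — signatures, InterPro entries,
#' member databases, GO links — are merged by primary key, so loading the
#' same run twice does not duplicate them.
#'
#' @param db Initialized connection (see [init_schema()]).
#' @param run An [ipr_run()] object.
#' @return Load statistics: `proteins_loaded`, `matches_loaded`,
#'   `locations_loaded`, and `go_links_loaded` (distinct
#'   entry–GO-term pairs in the run).
#' @export
load_run <- function(db, run) {
  stopifnot(inherits(run, "ipr_run"))
  init_schema(db)
  tb <- run_tables(run)
  DBI::dbBegin(db)
  ok <- FALSE
  tryCatch({
    insert <- function(sql, df) {
      if (nrow(df) > 0L) DBI::dbExecute(db, sql, params = unname(as.list(df)))
    }
    insert("INSERT OR IGNORE INTO protein (protein_id, length, crc64)
            VALUES (?,?,?)", tb$protein)
    dbs <- sort(unique(tb$match$member_db))
    for (d in dbs) {
      DBI::dbExecute(db, "INSERT OR IGNORE INTO member_db (name) VALUES (?)",
                     params = list(d))
    }
    if (nrow(tb$match) > 0L) {
      sig <- unique(tb$match[, c("signature_accession", "signature_name",
                                 "member_db")])
      DBI::dbExecute(db,
        "INSERT OR IGNORE INTO signature (accession, name, db_id)
         SELECT ?, ?, db_id FROM member_db WHERE name = ?",
        params = unname(as.list(sig)))
    }
    entry <- unique(tb$entry)
    insert("INSERT OR IGNORE INTO interpro_entry (accession, name, entry_type)
            VALUES (?,?,?)", entry)
    go <- unique(tb$go[, c("interpro_accession", "go_id", "category",
                           "description")])
    insert("INSERT OR IGNORE INTO go_annotation
              (interpro_accession, go_id, category, description)
            VALUES (?,?,?,?)", go)
    if (nrow(tb$match) > 0L) {
      base <- as.integer(DBI::dbGetQuery(db,
        "SELECT COALESCE(MAX(match_id), 0) FROM protein_match")[[1L]])
      tb$match$db_key <- base + tb$match$match_id
      tb$location$db_key <- base + tb$location$match_id
      insert("INSERT INTO protein_match
                (match_id, protein_id, signature_accession,
                 interpro_accession, status, evidence)
              VALUES (?,?,?,?,?,?)",
             tb$match[, c("db_key", "protein_id", "signature_accession",
                          "interpro_accession", "status", "evidence")])
      insert("INSERT INTO match_location (match_id, start, end, score)
              VALUES (?,?,?,?)",
             tb$location[, c("db_key", "start", "end", "score")])
    }
    DBI::dbCommit(db)
    ok <- TRUE
  }, error = function(e) {
    stop("load failed, rolled back: ", conditionMessage(e), call. = FALSE)
  }, finally = if (!ok) try(DBI::dbRollback(db), silent = TRUE))
  list(proteins_loaded = nrow(tb$protein),
       matches_loaded = nrow(tb$match),
       locations_loaded = nrow(tb$location),
       go_links_loaded = nrow(unique(tb$go[, c("interpro_accession",
                                               "go_id")])))
}

#' Signature counts for one member database
#'
#' The headline statistic: how often each signature of a member database
#' occurs in the analyzed sequence population. With `counting = "proteins"`
#' (default) a signature is counted once per distinct protein it matches;
#' with `counting = "matches"` every match record counts, which can exceed
#' the protein count for fragmented multi-hit signatures.
#'
#' @param db Initialized connection.
#' @param member_db Member database name (e.g. `"PFAM"`); an absent name
#'   yields a zero-row result.
#' @param counting `"proteins"` or `"matches"`.
#' @param status Optional status filter (e.g. `"T"`); `NULL` (default)
#'   keeps all matches.
#' @return Data frame with `signature_accession`, `signature_name`,
#'   `member_db`, `count`, sorted by count descending then accession
#'   ascending.
#' @export
query_signature_counts <- function(db, member_db,
                                   counting = c("proteins", "matches"),
                                   status = NULL) {
  counting <- match.arg(counting)
  agg <- if (counting == "proteins") {
    "COUNT(DISTINCT pm.protein_id)"
  } else {
    "COUNT(pm.match_id)"
  }
  filt <- if (is.null(status)) "" else "AND pm.status = ?"
  sql <- sprintf(
    "SELECT s.accession AS signature_accession, s.name AS signature_name,
            m.name AS member_db, %s AS count
     FROM protein_match pm
     JOIN signature s ON s.accession = pm.signature_accession
     JOIN member_db m ON m.db_id = s.db_id
     WHERE m.name = ? %s
     GROUP BY s.accession, s.name, m.name
     ORDER BY count DESC, s.accession ASC", agg, filt)
  params <- if (is.null(status)) list(member_db) else list(member_db, status)
  out <- DBI::dbGetQuery(db, sql, params = params)
  out$count <- as.integer(out$count)
  out
}

#' List member databases present in a run
#'
#' @param db Initialized connection.
#' @return Character vector of member database names, alphabetical.
#' @export
query_member_dbs <- function(db) {
  DBI::dbGetQuery(db,
    "SELECT name FROM member_db ORDER BY name ASC")$name
}

#' Signature table with GO annotations
#'
#' Same signatures and order as [query_signature_counts()] with
#' distinct-protein counting; each row additionally carries the GO
#' annotations of the InterPro entries the signature's matches belong to,
#' de-duplicated by GO id and sorted by GO id. Signatures filed under the
#' synthetic `noIPR` entry have no GO annotations.
#'
#' @param db Initialized connection.
#' @param member_db Member database name.
#' @return Data frame with `signature_accession`, `signature_name`, `count`
#'   and a list-column `go` of per-signature GO data frames
#'   (`go_id`, `category`, `description`).
#' @export
query_signature_table <- function(db, member_db) {
  counts <- query_signature_counts(db, member_db, counting = "proteins")
  go <- DBI::dbGetQuery(db,
    "SELECT DISTINCT pm.signature_accession, g.go_id, g.category,
            g.description
     FROM protein_match pm
     JOIN signature s ON s.accession = pm.signature_accession
     JOIN member_db m ON m.db_id = s.db_id
     JOIN go_annotation g ON g.interpro_accession = pm.interpro_accession
     WHERE m.name = ?
     ORDER BY pm.signature_accession, g.go_id", params = list(member_db))
  counts$go <- lapply(counts$signature_accession, function(acc) {
    rows <- go[go$signature_accession == acc,
               c("go_id", "category", "description"), drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
  counts
}
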