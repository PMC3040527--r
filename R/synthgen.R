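# Seeded generator of dialect-conformant InterProScan XML plus a
# ground-truth manifest. The manifest is tallied *while emitting* the XML,
# never re-derived, so it is a true oracle for the parser and the store.

DB_SIG_PREFIX <- c(PFAM = "PF", SMART = "SM", PROSITE = "PS",
                   GENE3D = "G3", PRINTS = "PR", TIGRFAMs = "TI",
                   PANTHER = "PT", SUPERFAMILY = "SF")

DB_EVIDENCE <- c(PFAM = "HMMPfam", SMART = "HMMSmart",
                 PROSITE = "ProfileScan", GENE3D = "Gene3D",
                 PRINTS = "FPrintScan", TIGRFAMs = "HMMTigr",
                 PANTHER = "HMMPanther", SUPERFAMILY = "superfamily")

#' Parameters for the XML fixture generator
#'
#' Defaults emulate a small whole-genome InterProScan run: four member
#' databases, a few dozen signatures each with rank-skewed popularity
#' (so a handful of families dominate, as in real annotation profiles),
#' about three matches per protein, and a shared GO term pool.
#'
#' @param n_proteins Number of query proteins (positive).
#' @param member_dbs Member database names.
#' @param signatures_per_db Size of each database's signature pool.
#' @param mean_matches_per_protein Mean of the Poisson match-count draw.
#' @param go_terms_pool Number of distinct GO ids available to entries.
#' @param seed Integer seed; same parameters + seed give identical bytes.
#' @return A `gen_params` list.
#' @export
gen_params <- function(n_proteins = 100L,
                       member_dbs = c("PFAM", "SMART", "PROSITE", "GENE3D"),
                       signatures_per_db = 25L,
                       mean_matches_per_protein = 3,
                       go_terms_pool = 40L,
                       seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  signatures_per_db <- as.integer(signatures_per_db)
  go_terms_pool <- as.integer(go_terms_pool)
  if (is.na(n_proteins) || n_proteins < 1L) {
    stop("n_proteins must be a positive integer", call. = FALSE)
  }
  if (signatures_per_db < 1L || go_terms_pool < 1L ||
      mean_matches_per_protein < 0) {
    stop("generator counts must be positive and the match mean non-negative",
         call. = FALSE)
  }
  structure(list(n_proteins = n_proteins, member_dbs = member_dbs,
                 signatures_per_db = signatures_per_db,
                 mean_matches_per_protein = mean_matches_per_protein,
                 go_terms_pool = go_terms_pool, seed = as.integer(seed)),
            class = "gen_params")
}

attr_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

# Fixed per-db signature pools with rank-skewed sampling weights (~1/rank),
# a 1:1 signature->entry map with ~20% unintegrated (noIPR) signatures,
# and 0-3 GO terms per integrated entry. All drawn from the seeded RNG.
build_catalog <- function(params) {
  dbs <- params$member_dbs
  k <- params$signatures_per_db
  ipr_counter <- 0L
  catalog <- list()
  for (db in dbs) {
    prefix <- DB_SIG_PREFIX[[db]] %||% toupper(substr(db, 1, 2))
    sigs <- vector("list", k)
    for (i in seq_len(k)) {
      acc <- sprintf("%s%05d", prefix, i)
      unintegrated <- stats::runif(1) < 0.2
      if (unintegrated) {
        entry <- list(accession = "noIPR", name = "unintegrated",
                      type = "unintegrated", go = list())
      } else {
        ipr_counter <- ipr_counter + 1L
        n_go <- sample(0:3, 1L)
        go_ids <- if (n_go > 0L) {
          sort(sample.int(params$go_terms_pool, n_go))
        } else integer()
        entry <- list(
          accession = sprintf("IPR%06d", ipr_counter),
          name = sprintf("Synthetic entry %d", ipr_counter),
          type = sample(c("Domain", "Family", "Repeat"), 1L),
          go = lapply(go_ids, function(g) list(
            id = sprintf("GO:%07d", g),
            category = c("Molecular Function", "Biological Process",
                         "Cellular Component")[(g %% 3L) + 1L],
            description = sprintf("synthetic term %d", g))))
      }
      sigs[[i]] <- list(accession = acc,
                        name = sprintf("%s family %d", db, i),
                        entry = entry)
    }
    catalog[[db]] <- list(signatures = sigs,
                          weights = 1 / seq_len(k))
  }
  catalog
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic InterProScan XML file with known ground truth
#'
#' Emits a dialect-conformant `interpro_matches` document: protein lengths
#' uniform in 50..2000, per-protein match counts Poisson with the requested
#' mean, signatures drawn rank-weighted from per-database pools so a few
#' signatures dominate, and 0-3 GO classifications per integrated InterPro
#' entry (emitted at the entry's first occurrence in the file). Repeated
#' draws of one signature for one protein become extra locations of a
#' single match. Deterministic per seed; the caller's RNG state is left
#' untouched.
#'
#' @param params A [gen_params()] object.
#' @param xml_out Path for the XML file.
#' @param manifest_out Optional path for the flat key=value manifest.
#' @return The ground-truth manifest: `n_proteins`,
#'   `per_db_match_counts` (named), `per_signature_protein_counts`
#'   (named `DB.ACCESSION`), `n_go_links`.
#' @export
generate_ipr_xml <- function(params, xml_out, manifest_out = NULL) {
  stopifnot(inherits(params, "gen_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(params$seed)

  catalog <- build_catalog(params)
  dbs <- params$member_dbs
  db_match <- stats::setNames(integer(length(dbs)), dbs)
  sig_prot <- new.env(parent = emptyenv())
  emitted_entries <- new.env(parent = emptyenv())
  n_go_links <- 0L

  chunks <- vector("list", params$n_proteins + 2L)
  chunks[[1L]] <- c('<?xml version="1.0" encoding="UTF-8"?>',
                    "<interpro_matches>")
  for (pi in seq_len(params$n_proteins)) {
    lines <- character()
    pid <- sprintf("SYNP%05d", pi)
    plen <- sample(50:2000, 1L)
    crc <- paste(sprintf("%02X", sample(0:255, 8L, replace = TRUE)),
                 collapse = "")
    n_draw <- stats::rpois(1L, params$mean_matches_per_protein)
    draws <- if (n_draw > 0L) {
      data.frame(
        db = sample(dbs, n_draw, replace = TRUE),
        idx = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(db = character(), idx = integer(),
                 stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(draws))) {
      pool <- catalog[[draws$db[j]]]
      draws$idx[j] <- sample.int(params$signatures_per_db, 1L,
                                 prob = pool$weights)
    }
    lines <- c(lines, sprintf(
      '  <protein id="%s" length="%d" crc64="%s">', pid, plen, crc))
    if (nrow(draws) > 0L) {
      key <- paste(draws$db, draws$idx)
      # group distinct signatures under their entries; noIPR collects all
      # unintegrated matches of the protein
      uniq <- draws[!duplicated(key), , drop = FALSE]
      n_loc <- as.integer(table(key)[paste(uniq$db, uniq$idx)])
      entry_of <- character(nrow(uniq))
      for (j in seq_len(nrow(uniq))) {
        entry_of[j] <- catalog[[uniq$db[j]]]$signatures[[uniq$idx[j]]]$entry$accession
      }
      for (eacc in unique(entry_of)) {
        in_entry <- which(entry_of == eacc)
        entry <- catalog[[uniq$db[in_entry[1L]]]]$signatures[[uniq$idx[in_entry[1L]]]]$entry
        lines <- c(lines, sprintf(
          '    <interpro id="%s" name="%s" type="%s">',
          entry$accession, attr_escape(entry$name), entry$type))
        if (eacc != "noIPR" &&
            !exists(eacc, envir = emitted_entries, inherits = FALSE)) {
          assign(eacc, TRUE, envir = emitted_entries)
          for (g in entry$go) {
            n_go_links <- n_go_links + 1L
            lines <- c(lines, sprintf(
              paste0('      <classification id="%s" class_type="GO">',
                     "<category>%s</category>",
                     "<description>%s</description></classification>"),
              g$id, g$category, attr_escape(g$description)))
          }
        }
        for (j in in_entry) {
          sig <- catalog[[uniq$db[j]]]$signatures[[uniq$idx[j]]]
          db <- uniq$db[j]
          db_match[[db]] <- db_match[[db]] + 1L
          skey <- paste0(db, ".", sig$accession)
          assign(skey,
                 (if (exists(skey, envir = sig_prot, inherits = FALSE)) {
                    get(skey, envir = sig_prot, inherits = FALSE)
                  } else 0L) + 1L,
                 envir = sig_prot)
          lines <- c(lines, sprintf(
            '      <match id="%s" name="%s" dbname="%s">',
            sig$accession, attr_escape(sig$name), db))
          for (li in seq_len(n_loc[j])) {
            span <- sample(20:min(300L, plen - 1L), 1L)
            start <- sample.int(plen - span, 1L)
            score_raw <- stats::runif(1)
            score <- if (score_raw < 0.1) "NA" else {
              sprintf("%.1e", 10^(-stats::runif(1, 2, 40)))
            }
            lines <- c(lines, sprintf(
              paste0('        <location start="%d" end="%d" score="%s" ',
                     'status="T" evidence="%s"/>'),
              start, start + span - 1L, score,
              DB_EVIDENCE[[db]] %||% "HMM"))
          }
          lines <- c(lines, "      </match>")
        }
        lines <- c(lines, "    </interpro>")
      }
    }
    chunks[[pi + 1L]] <- c(lines, "  </protein>")
  }
  chunks[[params$n_proteins + 2L]] <- "</interpro_matches>"
  writeLines(unlist(chunks), xml_out, useBytes = TRUE)

  sig_keys <- sort(ls(sig_prot))
  manifest <- list(
    n_proteins = params$n_proteins,
    per_db_match_counts = db_match[sort(names(db_match))],
    per_signature_protein_counts = stats::setNames(
      vapply(sig_keys, get, 0L, envir = sig_prot), sig_keys),
    n_go_links = n_go_links)
  if (!is.null(manifest_out)) write_manifest(manifest, manifest_out)
  manifest
}

#' Write / read a ground-truth manifest as flat key=value text
#'
#' @param manifest Manifest list as returned by [generate_ipr_xml()].
#' @param path File path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  lines <- c(
    sprintf("n_proteins=%d", manifest$n_proteins),
    sprintf("n_go_links=%d", manifest$n_go_links),
    sprintf("db_match_count.%s=%d", names(manifest$per_db_match_counts),
            manifest$per_db_match_counts),
    sprintf("sig_protein_count.%s=%d",
            names(manifest$per_signature_protein_counts),
            manifest$per_signature_protein_counts))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- as.integer(vapply(kv, `[[`, "", 2L))
  pick <- function(prefix) {
    sel <- startsWith(keys, prefix)
    stats::setNames(vals[sel], substring(keys[sel], nchar(prefix) + 1L))
  }
  list(n_proteins = vals[keys == "n_proteins"],
       per_db_match_counts = pick("db_match_count."),
       per_signature_protein_counts = pick("sig_protein_count."),
       n_go_links = vals[keys == "n_go_links"])
}

#' Write the fixed three-protein toy fixture
#'
#' Proteins A and B match PFAM signature PF00001 under the InterPro entry
#' IPR000001, which carries GO:0005524 (ATP binding); protein C matches
#' PF00002, unintegrated (`noIPR`). Used as the fully hand-enumerable
#' example throughout the test suite.
#'
#' @param out Path for the XML file.
#' @return The toy's ground-truth manifest (same shape as
#'   [generate_ipr_xml()]).
#' @export
write_toy_fixture <- function(out) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<interpro_matches>",
    '  <protein id="A" length="100" crc64="0011223344556677">',
    '    <interpro id="IPR000001" name="ATP-binding cassette domain" type="Domain">',
    paste0('      <classification id="GO:0005524" class_type="GO">',
           "<category>Molecular Function</category>",
           "<description>ATP binding</description></classification>"),
    '      <match id="PF00001" name="ABC_membrane" dbname="PFAM">',
    '        <location start="10" end="60" score="1.0e-10" status="T" evidence="HMMPfam"/>',
    "      </match>",
    "    </interpro>",
    "  </protein>",
    '  <protein id="B" length="120" crc64="8899AABBCCDDEEFF">',
    '    <interpro id="IPR000001" name="ATP-binding cassette domain" type="Domain">',
    '      <match id="PF00001" name="ABC_membrane" dbname="PFAM">',
    '        <location start="5" end="100" score="2.5e-08" status="T" evidence="HMMPfam"/>',
    "      </match>",
    "    </interpro>",
    "  </protein>",
    '  <protein id="C" length="80" crc64="FFEEDDCCBBAA9988">',
    '    <interpro id="noIPR" name="unintegrated" type="unintegrated">',
    '      <match id="PF00002" name="7tm_2" dbname="PFAM">',
    '        <location start="1" end="70" score="NA" status="T" evidence="HMMPfam"/>',
    "      </match>",
    "    </interpro>",
    "  </protein>",
    "</interpro_matches>")
  writeLines(lines, out, useBytes = TRUE)
  list(n_proteins = 3L,
       per_db_match_counts = c(PFAM = 3L),
       per_signature_protein_counts = c(PFAM.PF00001 = 2L,
                                        PFAM.PF00002 = 1L),
       n_go_links = 1L)
}
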