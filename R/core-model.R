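# Canonical in-memory representation of a parsed InterProScan run.
# All coordinates are 1-based inclusive; an absent score is NA_real_, never 0.

#' Construct a match location
#'
#' A location is the span on the query protein where a signature matched.
#' Coordinates are 1-based and inclusive, as emitted by InterProScan.
#'
#' @param start,end Integer coordinates, `1 <= start <= end`.
#' @param score Numeric score/E-value, or `NA` when the scanning method
#'   reports none. `NA` is the absent sentinel; 0 is a legal score.
#' @param status Single-character status flag (`"T"` marks a true match).
#' @param evidence Name of the scanning method that produced the match.
#' @return An object of class `ipr_location`.
#' @export
ipr_location <- function(start, end, score = NA_real_, status = "T",
                         evidence = "") {
  start <- suppressWarnings(as.integer(start))
  end <- suppressWarnings(as.integer(end))
  if (is.na(start) || is.na(end)) {
    stop("location start/end must be integers", call. = FALSE)
  }
  structure(
    list(start = start, end = end, score = as.numeric(score),
         status = as.character(status), evidence = as.character(evidence)),
    class = "ipr_location"
  )
}

#' Construct a signature match
#'
#' @param signature_accession Member-database accession (e.g. `"PF00005"`).
#' @param signature_name Human-readable signature name.
#' @param member_db Member database the signature belongs to
#'   (e.g. `"PFAM"`, `"SMART"`, `"PROSITE"`).
#' @param locations List of [ipr_location()] objects; at least one.
#' @return An object of class `ipr_match`.
#' @export
ipr_match <- function(signature_accession, signature_name = "",
                      member_db, locations) {
  structure(
    list(signature_accession = as.character(signature_accession),
         signature_name = as.character(signature_name),
         member_db = as.character(member_db),
         locations = locations),
    class = "ipr_match"
  )
}

#' Construct a GO annotation
#'
#' @param go_id GO identifier; normalized with [normalize_go_id()].
#' @param category GO aspect: `"Molecular Function"`, `"Biological Process"`
#'   or `"Cellular Component"`.
#' @param description Term name; may be empty until resolved against a
#'   mapping (see [resolve_names()]).
#' @return An object of class `ipr_go`.
#' @export
ipr_go <- function(go_id, category = "", description = "") {
  structure(
    list(go_id = normalize_go_id(go_id), category = as.character(category),
         description = as.character(description)),
    class = "ipr_go"
  )
}

#' Construct an InterPro entry
#'
#' An InterPro entry groups equivalent signatures across member databases.
#' Matches whose signature is not integrated into InterPro are attached to a
#' synthetic entry with accession `"noIPR"`, so every match has exactly one
#' parent entry.
#'
#' @param accession `IPR` + 6 digits, or the literal `"noIPR"`.
#' @param name Entry name.
#' @param entry_type Entry type (e.g. `"Domain"`, `"Family"`).
#' @param go_annotations List of [ipr_go()] objects.
#' @param matches List of [ipr_match()] objects.
#' @return An object of class `ipr_entry`.
#' @export
ipr_entry <- function(accession, name = "", entry_type = "",
                      go_annotations = list(), matches = list()) {
  accession <- as.character(accession)
  if (!grepl("^(IPR[0-9]{6}|noIPR)$", accession)) {
    stop("invalid InterPro accession: ", accession, call. = FALSE)
  }
  structure(
    list(accession = accession, name = as.character(name),
         entry_type = as.character(entry_type),
         go_annotations = go_annotations, matches = matches),
    class = "ipr_entry"
  )
}

#' Construct a protein result
#'
#' @param protein_id Query protein identifier, unique within a run.
#' @param length Protein length in residues (sequence itself is never kept).
#' @param crc64 CRC64 checksum string; may be empty.
#' @param entries List of [ipr_entry()] objects.
#' @return An object of class `ipr_protein`.
#' @export
ipr_protein <- function(protein_id, length = 0L, crc64 = "",
                        entries = list()) {
  length <- suppressWarnings(as.integer(length))
  if (is.na(length) || length < 0L) {
    stop("protein length must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(protein_id = as.character(protein_id), length = length,
         crc64 = as.character(crc64), entries = entries),
    class = "ipr_protein"
  )
}

#' Construct a parsed run
#'
#' @param proteins List of [ipr_protein()] objects, in input-file order.
#' @param source_path Path of the XML file the run came from.
#' @param parsed_at Timestamp of parsing (POSIXct).
#' @return An object of class `ipr_run`.
#' @export
ipr_run <- function(proteins = list(), source_path = "",
                    parsed_at = Sys.time()) {
  structure(
    list(proteins = proteins, source_path = as.character(source_path),
         parsed_at = parsed_at),
    class = "ipr_run"
  )
}

#' @export
print.ipr_run <- function(x, ...) {
  n_entries <- sum(vapply(x$proteins, function(p) length(p$entries), 0L))
  n_matches <- sum(vapply(x$proteins, function(p) {
    sum(vapply(p$entries, function(e) length(e$matches), 0L))
  }, 0L))
  cat("InterProScan run:", length(x$proteins), "proteins,",
      n_entries, "entry records,", n_matches, "matches\n")
  if (nzchar(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Normalize a GO identifier
#'
#' Coerces any digit-bearing GO identifier spelling to the canonical
#' `GO:` + 7-digit zero-padded form. Idempotent.
#'
#' @param raw Character vector of raw GO identifiers (e.g. `"8150"`,
#'   `"GO:5524"`, `"GO:0008150"`).
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_go_id(c("GO:0008150", "8150", "GO:5524"))
#' @export
normalize_go_id <- function(raw) {
  raw <- as.character(raw)
  payload <- sub("^GO:", "", raw)
  bad <- !grepl("^[0-9]+$", payload) | nchar(payload) > 7L
  if (any(bad)) {
    stop("not a numeric GO identifier: ", paste(raw[bad], collapse = ", "),
         call. = FALSE)
  }
  sprintf("GO:%07d", as.integer(payload))
}

#' Validate a parsed run
#'
#' Checks the run's structural invariants and reports violations instead of
#' throwing: duplicate protein identifiers, locations with `start > end` or
#' ends beyond the protein length, matches with no location or an empty
#' member database, and malformed accessions.
#'
#' @param run An [ipr_run()] object.
#' @return A data frame with columns `protein_id`, `where`, `problem`;
#'   zero rows for a valid run.
#' @export
validate_run <- function(run) {
  stopifnot(inherits(run, "ipr_run"))
  v <- list()
  note <- function(protein_id, where, problem) {
    v[[length(v) + 1L]] <<- data.frame(
      protein_id = protein_id, where = where, problem = problem,
      stringsAsFactors = FALSE)
  }
  ids <- vapply(run$proteins, `[[`, "", "protein_id")
  for (d in unique(ids[duplicated(ids)])) {
    note(d, "protein", "duplicate protein identifier")
  }
  for (p in run$proteins) {
    if (p$length < 0L) note(p$protein_id, "protein", "negative length")
    for (e in p$entries) {
      if (!grepl("^(IPR[0-9]{6}|noIPR)$", e$accession)) {
        note(p$protein_id, e$accession, "malformed InterPro accession")
      }
      for (g in e$go_annotations) {
        if (!grepl("^GO:[0-9]{7}$", g$go_id)) {
          note(p$protein_id, e$accession,
               paste0("unnormalized GO id ", g$go_id))
        }
      }
      for (m in e$matches) {
        tag <- paste0(e$accession, "/", m$signature_accession)
        if (!nzchar(m$member_db)) note(p$protein_id, tag, "empty member_db")
        if (length(m$locations) == 0L) note(p$protein_id, tag, "no locations")
        for (l in m$locations) {
          if (l$start < 1L || l$start > l$end) {
            note(p$protein_id, tag,
                 sprintf("bad location %d..%d", l$start, l$end))
          } else if (p$length > 0L && l$end > p$length) {
            note(p$protein_id, tag,
                 sprintf("location end %d beyond protein length %d",
                         l$end, p$length))
          }
        }
      }
    }
  }
  if (length(v) == 0L) {
    return(data.frame(protein_id = character(), where = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

# Flat tabular views of a run; used by the loader and tests.
run_tables <- function(run) {
  prot <- list(); entr <- list(); mat <- list(); loc <- list(); go <- list()
  mi <- 0L
  for (p in run$proteins) {
    prot[[length(prot) + 1L]] <- data.frame(
      protein_id = p$protein_id, length = p$length, crc64 = p$crc64,
      stringsAsFactors = FALSE)
    for (e in p$entries) {
      entr[[length(entr) + 1L]] <- data.frame(
        accession = e$accession, name = e$name, entry_type = e$entry_type,
        stringsAsFactors = FALSE)
      for (g in e$go_annotations) {
        go[[length(go) + 1L]] <- data.frame(
          interpro_accession = e$accession, go_id = g$go_id,
          category = g$category, description = g$description,
          stringsAsFactors = FALSE)
      }
      for (m in e$matches) {
        mi <- mi + 1L
        mat[[length(mat) + 1L]] <- data.frame(
          match_id = mi, protein_id = p$protein_id,
          signature_accession = m$signature_accession,
          signature_name = m$signature_name, member_db = m$member_db,
          interpro_accession = e$accession,
          status = m$locations[[1L]]$status,
          evidence = m$locations[[1L]]$evidence,
          stringsAsFactors = FALSE)
        for (l in m$locations) {
          loc[[length(loc) + 1L]] <- data.frame(
            match_id = mi, start = l$start, end = l$end, score = l$score,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  list(
    protein = bind(prot, data.frame(protein_id = character(),
      length = integer(), crc64 = character(), stringsAsFactors = FALSE)),
    entry = bind(entr, data.frame(accession = character(), name = character(),
      entry_type = character(), stringsAsFactors = FALSE)),
    match = bind(mat, data.frame(match_id = integer(),
      protein_id = character(), signature_accession = character(),
      signature_name = character(), member_db = character(),
      interpro_accession = character(), status = character(),
      evidence = character(), stringsAsFactors = FALSE)),
    location = bind(loc, data.frame(match_id = integer(), start = integer(),
      end = integer(), score = numeric(), stringsAsFactors = FALSE)),
    go = bind(go, data.frame(interpro_accession = character(),
      go_id = character(), category = character(), description = character(),
      stringsAsFactors = FALSE))
  )
}
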