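# Reader for InterProScan raw-XML result files (`interpro_matches` dialect).
#
# Dialect: root <interpro_matches>; <protein id length crc64>; under protein,
# <interpro id name type>; under interpro, zero or more
# <classification id class_type> with <category> and <description> children,
# and one or more <match id name dbname>; under match, one or more
# <location start end score status evidence>. Unknown attributes and elements
# are ignored for forward compatibility.

#' Identify the XML dialect of a result file
#'
#' @param path Path to an XML file.
#' @return A list with `root_tag`, `dialect_name` and `protein_count`.
#'   Raises an error for unreadable files, non-XML content, or a root tag
#'   other than `interpro_matches` (e.g. the undocumented EBIXML dialect).
#' @export
sniff_dialect <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read file: ", path, call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(xml2::xml_root(doc))
  if (!identical(root, "interpro_matches")) {
    stop("unsupported XML dialect: root tag <", root,
         "> (expected <interpro_matches>)", call. = FALSE)
  }
  list(root_tag = root, dialect_name = "interpro_matches",
       protein_count = length(xml2::xml_find_all(doc, "./protein")))
}

# attrs is the named character vector from xml2::xml_attrs(); indexing by
# an absent name yields NA rather than an error
req_attr <- function(attrs, name, path) {
  v <- unname(attrs[name])
  if (length(v) != 1L || is.na(v)) {
    stop("missing required attribute '", name, "' at ", path, call. = FALSE)
  }
  v
}

num_attr <- function(attrs, name, path, required = TRUE) {
  v <- unname(attrs[name])
  if (length(v) != 1L || is.na(v)) {
    if (required) {
      stop("missing required attribute '", name, "' at ", path,
           call. = FALSE)
    }
    return(NA_integer_)
  }
  n <- suppressWarnings(as.integer(v))
  if (is.na(n)) {
    stop("malformed numeric attribute ", name, "='", v, "' at ", path,
         call. = FALSE)
  }
  n
}

opt_attr <- function(attrs, name, default = "") {
  v <- unname(attrs[name])
  if (length(v) != 1L || is.na(v)) default else v
}

parse_score <- function(v) {
  if (is.na(v) || identical(v, "NA") || !nzchar(v)) return(NA_real_)
  s <- suppressWarnings(as.numeric(v))
  if (is.na(s)) stop("malformed score attribute: '", v, "'", call. = FALSE)
  s
}

# Children of `node` whose element name is `what` (no XPath: per-node
# XPath evaluation dominates parse time on large files).
kids <- function(node, what) {
  ch <- xml2::xml_children(node)
  ch[xml2::xml_name(ch) == what]
}

parse_protein_node <- function(pnode, idx) {
  ppath <- sprintf("protein[%d]", idx)
  pa <- xml2::xml_attrs(pnode)
  pid <- req_attr(pa, "id", ppath)
  plen <- num_attr(pa, "length", ppath, required = FALSE)
  if (is.na(plen)) plen <- 0L
  enodes <- kids(pnode, "interpro")
  entries <- vector("list", length(enodes))
  for (ei in seq_along(enodes)) {
    enode <- enodes[[ei]]
    epath <- paste0(ppath, "/interpro")
    ea <- xml2::xml_attrs(enode)
    acc <- req_attr(ea, "id", epath)
    ech <- xml2::xml_children(enode)
    enames <- xml2::xml_name(ech)
    gos <- list()
    for (cnode in ech[enames == "classification"]) {
      ca <- xml2::xml_attrs(cnode)
      if (!identical(opt_attr(ca, "class_type"), "GO")) next
      cch <- xml2::xml_children(cnode)
      cnames <- xml2::xml_name(cch)
      gos[[length(gos) + 1L]] <- ipr_go(
        go_id = req_attr(ca, "id", paste0(epath, "/classification")),
        category = if (any(cnames == "category")) {
          xml2::xml_text(cch[[which(cnames == "category")[1L]]])
        } else "",
        description = if (any(cnames == "description")) {
          xml2::xml_text(cch[[which(cnames == "description")[1L]]])
        } else "")
    }
    mnodes <- ech[enames == "match"]
    matches <- vector("list", length(mnodes))
    for (mi in seq_along(mnodes)) {
      mnode <- mnodes[[mi]]
      mpath <- paste0(epath, "/match")
      ma <- xml2::xml_attrs(mnode)
      macc <- req_attr(ma, "id", mpath)
      lnodes <- kids(mnode, "location")
      locs <- vector("list", length(lnodes))
      for (li in seq_along(lnodes)) {
        la <- xml2::xml_attrs(lnodes[[li]])
        lpath <- paste0(mpath, "[", macc, "]/location")
        locs[[li]] <- ipr_location(
          start = num_attr(la, "start", lpath),
          end = num_attr(la, "end", lpath),
          score = parse_score(opt_attr(la, "score", NA_character_)),
          status = opt_attr(la, "status", "T"),
          evidence = opt_attr(la, "evidence"))
      }
      matches[[mi]] <- ipr_match(
        signature_accession = macc,
        signature_name = opt_attr(ma, "name"),
        member_db = opt_attr(ma, "dbname"),
        locations = locs)
    }
    entries[[ei]] <- ipr_entry(
      accession = acc,
      name = opt_attr(ea, "name"),
      entry_type = opt_attr(ea, "type"),
      go_annotations = gos, matches = matches)
  }
  ipr_protein(protein_id = pid, length = plen,
              crc64 = opt_attr(pa, "crc64"), entries = entries)
}

#' Parse an InterProScan raw-XML result file
#'
#' Reads the document once and converts protein elements one at a time, so
#' the R-side working set is bounded per protein; element order is
#' preserved. `classification` elements with `class_type="GO"` become GO
#' annotations after [normalize_go_id()]; other classification types are
#' ignored. A `score` of `NA` (the literal string) becomes the absent
#' sentinel `NA_real_`.
#'
#' @param path Path to an `interpro_matches` XML file
#'   (checked with [sniff_dialect()]).
#' @return An [ipr_run()] object.
#' @export
parse_interproscan_xml <- function(path) {
  sniff_dialect(path)
  doc <- xml2::read_xml(path)
  pnodes <- kids(xml2::xml_root(doc), "protein")
  proteins <- vector("list", length(pnodes))
  for (i in seq_along(pnodes)) {
    proteins[[i]] <- parse_protein_node(pnodes[[i]], i)
  }
  ipr_run(proteins = proteins, source_path = path, parsed_at = Sys.time())
}
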