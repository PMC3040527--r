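# Offline GO id -> name resolution and EBI term-page links.
#
# The mapping is a 3-column tab-separated file (go_id, name, category);
# lines starting with '!' or '#' are comments. Such a file is trivially
# produced from any GO release, so no live database connection is needed.

#' Load an offline GO id-to-name mapping
#'
#' @param path Tab-separated file with columns `go_id`, `name`, `category`
#'   (no header); `!` or `#` start comment lines. Later duplicate ids
#'   override earlier ones.
#' @return A `go_name_map`: environment keyed by normalized GO id holding
#'   `list(name, category)`, plus the `source_path` attribute.
#' @export
load_go_mapping <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  map <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || grepl("^[!#]", line)) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("GO mapping line ", i, " has ", length(parts),
           " column(s); expected 3 (go_id, name, category)", call. = FALSE)
    }
    id <- normalize_go_id(parts[[1L]])
    assign(id, list(name = parts[[2L]], category = parts[[3L]]), envir = map)
  }
  structure(map, source_path = path, class = c("go_name_map", "environment"))
}

#' @export
print.go_name_map <- function(x, ...) {
  cat("GO name map:", length(ls(x)), "terms from",
      attr(x, "source_path"), "\n")
  invisible(x)
}

#' Fill GO term descriptions from a mapping
#'
#' Pure enrichment: every annotation comes back, in input order, with its
#' `description` filled from the map when the id is present and untouched
#' otherwise; `go_id` and `category` are never modified. Idempotent.
#'
#' @param annotations List of [ipr_go()] objects.
#' @param map A `go_name_map` from [load_go_mapping()].
#' @return The annotation list with descriptions resolved.
#' @export
resolve_names <- function(annotations, map) {
  lapply(annotations, function(a) {
    hit <- if (exists(a$go_id, envir = map, inherits = FALSE)) {
      get(a$go_id, envir = map, inherits = FALSE)
    }
    if (!is.null(hit)) a$description <- hit$name
    a
  })
}

#' Link a GO term to its EBI QuickGO page
#'
#' @param go_id Normalized GO id (`GO:` + 7 digits).
#' @return The QuickGO term-page URL.
#' @examples
#' go_link("GO:0008150")
#' @export
go_link <- function(go_id) {
  bad <- !grepl("^GO:[0-9]{7}$", go_id)
  if (any(bad)) {
    stop("not a normalized GO id: ", paste(go_id[bad], collapse = ", "),
         " (use normalize_go_id first)", call. = FALSE)
  }
  paste0("https://www.ebi.ac.uk/QuickGO/term/", go_id)
}
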