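# Chart-ready summaries and run-level overview numbers.

#' Bucket signature counts for charting
#'
#' Keeps the first `top_n` summaries verbatim (they arrive sorted from
#' [query_signature_counts()]) and folds the remainder into a single
#' "other" bucket, so long signature lists stay plottable. Counts are
#' conserved: `sum(values) + other_count` equals the total input count.
#'
#' @param summaries Data frame from [query_signature_counts()].
#' @param top_n Maximum number of individual slices/bars (default 10).
#' @param title Chart title.
#' @return A `chart_data` list: `title`, `labels`, `values`, `other_count`.
#' @export
make_chart_data <- function(summaries, top_n = 10L, title = "") {
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L) {
    stop("top_n must be a positive integer", call. = FALSE)
  }
  n <- nrow(summaries)
  keep <- seq_len(min(top_n, n))
  structure(
    list(title = as.character(title),
         labels = as.character(summaries$signature_accession[keep]),
         values = as.integer(summaries$count[keep]),
         other_count = if (n > top_n) {
           as.integer(sum(summaries$count[(top_n + 1L):n]))
         } else 0L),
    class = "chart_data")
}

#' @export
print.chart_data <- function(x, ...) {
  cat("chart data:", length(x$labels), "labels, other_count =",
      x$other_count, "\n")
  invisible(x)
}

#' Run-level overview numbers
#'
#' @param db Initialized connection.
#' @return A list with `n_proteins`, `n_proteins_with_match`,
#'   `n_member_dbs`, `n_distinct_signatures` and `n_go_terms`
#'   (distinct GO ids linked anywhere in the run).
#' @export
compute_overview <- function(db) {
  one <- function(sql) as.integer(DBI::dbGetQuery(db, sql)[[1L]])
  list(
    n_proteins = one("SELECT COUNT(*) FROM protein"),
    n_proteins_with_match =
      one("SELECT COUNT(DISTINCT protein_id) FROM protein_match"),
    n_member_dbs = one("SELECT COUNT(*) FROM member_db"),
    n_distinct_signatures =
      one("SELECT COUNT(DISTINCT signature_accession) FROM protein_match"),
    n_go_terms = one("SELECT COUNT(DISTINCT go_id) FROM go_annotation")
  )
}

# Percentage of the grand total (incl. "other"), one decimal, half-up.
# Half-up (not R's half-even) so regenerated reports are byte-stable across
# platforms and obviously reproducible by hand.
format_pct <- function(value, total) {
  if (total <= 0) return("0.0")
  sprintf("%.1f", floor(value / total * 1000 + 0.5) / 10)
}
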