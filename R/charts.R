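# Chart rendering: a pure URL-string builder for the legacy image-chart web
# API, and a local SVG backend. SVG is written directly as text so output is
# byte-deterministic and tests can assert on label strings.

SIMPLE_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Simple-encode a numeric series
#'
#' The 62-character "simple encoding" used by legacy URL-based chart
#' services: a value `v` maps to alphabet index `round(v * 61 / v_max)`
#' in `A..Z a..z 0..9`, so 0 encodes as `A` and `v_max` as `9`. Missing
#' values encode as `_`.
#'
#' @param values Non-negative numeric vector, all `<= v_max`; `NA` allowed.
#' @param v_max Positive scale maximum.
#' @return A single string, one character per value.
#' @examples
#' encode_simple(c(0, 30, 61), 61)  # "Ae9"
#' @export
encode_simple <- function(values, v_max) {
  v_max <- as.numeric(v_max)
  if (length(v_max) != 1L || is.na(v_max) || v_max < 1) {
    stop("v_max must be a positive number", call. = FALSE)
  }
  if (length(values) == 0L) return("")
  values <- as.numeric(values)
  if (any(values > v_max, na.rm = TRUE)) {
    stop("values exceed v_max = ", v_max, call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("values must be non-negative", call. = FALSE)
  }
  idx <- round(values * 61 / v_max)
  chars <- ifelse(is.na(values), "_", SIMPLE_ALPHABET[idx + 1L])
  paste(chars, collapse = "")
}

#' Chart rendering specification
#'
#' @param kind `"pie"` or `"bar"`.
#' @param width,height Pixels. The url backend is limited to 1..1000 per
#'   side (the legacy service limit); the local backend only requires
#'   positive sizes.
#' @param backend `"local"` (SVG file) or `"url"` (image-chart URL string).
#' @return A `chart_spec` list.
#' @export
chart_spec <- function(kind = c("pie", "bar"), width = 500L, height = 300L,
                       backend = c("local", "url")) {
  kind <- match.arg(kind)
  backend <- match.arg(backend)
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L) {
    stop("chart width/height must be positive", call. = FALSE)
  }
  if (backend == "url" && (width > 1000L || height > 1000L)) {
    stop("url backend limits width/height to 1..1000 pixels", call. = FALSE)
  }
  structure(list(kind = kind, width = width, height = height,
                 backend = backend), class = "chart_spec")
}

# Chart series = named values plus the "other" bucket when present.
chart_series <- function(data) {
  labels <- data$labels
  values <- as.numeric(data$values)
  if (data$other_count > 0L) {
    labels <- c(labels, "other")
    values <- c(values, as.numeric(data$other_count))
  }
  list(labels = labels, values = values)
}

#' Build a legacy image-chart URL
#'
#' Serializes chart data into the URL-string scheme of the legacy
#' Google-style image-chart API (`cht` chart type, `chs` size, `chd=s:`
#' simple-encoded data, `chl` pipe-separated labels). The string is never
#' fetched by this package; it is generated for embedding in reports.
#'
#' @param data `chart_data` from [make_chart_data()].
#' @param spec `chart_spec` with `backend = "url"`.
#' @return The URL string; identical inputs give identical strings.
#' @export
build_chart_url <- function(data, spec) {
  stopifnot(inherits(spec, "chart_spec"))
  if (spec$backend != "url") {
    stop("build_chart_url requires a spec with backend = 'url'",
         call. = FALSE)
  }
  ser <- chart_series(data)
  v_max <- max(ser$values, 1)
  enc <- encode_simple(ser$values, v_max)
  labels <- vapply(ser$labels, utils::URLencode, "", reserved = TRUE,
                   USE.NAMES = FALSE)
  cht <- if (spec$kind == "pie") "p" else "bvs"
  paste0("https://chart.apis.google.com/chart",
         "?cht=", cht,
         "&chs=", spec$width, "x", spec$height,
         "&chd=s:", enc,
         "&chl=", paste(labels, collapse = "|"))
}

CHART_PALETTE <- c("#4e79a7", "#f28e2b", "#e15759", "#76b7b2", "#59a14f",
                   "#edc948", "#b07aa1", "#ff9da7", "#9c755f", "#bab0ac",
                   "#86bcb6", "#d37295")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

num <- function(x) sprintf("%.2f", x)

svg_pie <- function(ser, w, h, title) {
  total <- sum(ser$values)
  cx <- h / 2
  cy <- h / 2 + 10
  r <- max(min(w / 4, h / 2 - 20), 10)
  parts <- character()
  if (total > 0) {
    frac <- ser$values / total
    ang <- cumsum(c(0, frac)) * 2 * pi - pi / 2
    for (i in seq_along(ser$values)) {
      if (ser$values[i] <= 0) next
      col <- CHART_PALETTE[(i - 1L) %% length(CHART_PALETTE) + 1L]
      if (frac[i] >= 1 - 1e-9) {
        parts <- c(parts, sprintf(
          '<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
          num(cx), num(cy), num(r), col))
        next
      }
      a0 <- ang[i]; a1 <- ang[i + 1L]
      large <- if ((a1 - a0) > pi) 1L else 0L
      parts <- c(parts, sprintf(
        '<path d="M %s %s L %s %s A %s %s 0 %d 1 %s %s Z" fill="%s"/>',
        num(cx), num(cy),
        num(cx + r * cos(a0)), num(cy + r * sin(a0)),
        num(r), num(r), large,
        num(cx + r * cos(a1)), num(cy + r * sin(a1)), col))
    }
  }
  lx <- cx + r + 20
  for (i in seq_along(ser$labels)) {
    col <- CHART_PALETTE[(i - 1L) %% length(CHART_PALETTE) + 1L]
    ly <- 30 + (i - 1L) * 16
    parts <- c(parts,
      sprintf('<rect x="%s" y="%s" width="10" height="10" fill="%s"/>',
              num(lx), num(ly - 9), col),
      sprintf('<text x="%s" y="%s" font-size="12">%s: %s (%s%%)</text>',
              num(lx + 14), num(ly), xml_escape(ser$labels[i]),
              ser$values[i], format_pct(ser$values[i], total)))
  }
  parts
}

svg_bar <- function(ser, w, h, title) {
  pad_l <- 40; pad_b <- 70; pad_t <- 30; pad_r <- 10
  plot_w <- max(w - pad_l - pad_r, 10)
  plot_h <- max(h - pad_t - pad_b, 10)
  v_max <- max(ser$values, 1)
  n <- length(ser$values)
  parts <- c(
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333"/>',
            num(pad_l), num(pad_t), num(pad_l), num(pad_t + plot_h)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333"/>',
            num(pad_l), num(pad_t + plot_h), num(pad_l + plot_w),
            num(pad_t + plot_h)))
  if (n > 0) {
    slot <- plot_w / n
    bw <- slot * 0.7
    for (i in seq_len(n)) {
      col <- CHART_PALETTE[(i - 1L) %% length(CHART_PALETTE) + 1L]
      bh <- ser$values[i] / v_max * plot_h
      x0 <- pad_l + (i - 1L) * slot + slot * 0.15
      y0 <- pad_t + plot_h - bh
      parts <- c(parts,
        sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                num(x0), num(y0), num(bw), num(bh), col),
        sprintf('<text x="%s" y="%s" font-size="11" text-anchor="middle">%s</text>',
                num(x0 + bw / 2), num(y0 - 3), ser$values[i]),
        sprintf(paste0('<text x="%s" y="%s" font-size="11" ',
                       'text-anchor="end" transform="rotate(-45 %s %s)">',
                       "%s</text>"),
                num(x0 + bw / 2), num(pad_t + plot_h + 12),
                num(x0 + bw / 2), num(pad_t + plot_h + 12),
                xml_escape(ser$labels[i])))
    }
  }
  parts
}

#' Render chart data to an SVG file
#'
#' Draws a labeled pie or bar chart, including the "other" bucket when
#' `other_count > 0`. Output is plain-text SVG and is byte-identical for
#' identical inputs. An empty series yields a valid empty-axes image.
#'
#' @param data `chart_data` from [make_chart_data()].
#' @param spec `chart_spec` with `backend = "local"`.
#' @param out_path Output file path (conventionally `.svg`).
#' @return `out_path`, invisibly checked to exist and be non-empty.
#' @export
render_chart <- function(data, spec, out_path) {
  stopifnot(inherits(spec, "chart_spec"))
  if (spec$backend != "local") {
    stop("render_chart requires a spec with backend = 'local'",
         call. = FALSE)
  }
  writeLines(chart_svg(data, spec), out_path, sep = "\n")
  if (!file.exists(out_path) || file.size(out_path) == 0) {
    stop("failed to write chart to ", out_path, call. = FALSE)
  }
  out_path
}

# SVG document as a character vector of lines (also embedded in HTML
# reports without the XML prolog).
chart_svg <- function(data, spec, standalone = TRUE) {
  ser <- chart_series(data)
  w <- spec$width; h <- spec$height
  body <- if (spec$kind == "pie") {
    svg_pie(ser, w, h, data$title)
  } else {
    svg_bar(ser, w, h, data$title)
  }
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'), w, h, w, h),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>', w, h),
    if (nzchar(data$title)) {
      sprintf('<text x="%s" y="16" font-size="14" font-weight="bold">%s</text>',
              num(w / 2 - nchar(data$title) * 3.5), xml_escape(data$title))
    },
    body,
    "</svg>")
  if (standalone) {
    lines <- c('<?xml version="1.0" encoding="UTF-8"?>', lines)
  }
  lines
}
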