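test_that("simple encoding maps the documented examples", {
  expect_identical(encode_simple(c(0, 10), 10), "A9")
  expect_identical(encode_simple(30, 61), "e")
  expect_identical(encode_simple(numeric(), 5), "")
  expect_identical(encode_simple(c(2, NA, 0), 2), "9_A")
  expect_error(encode_simple(5, 4), "exceed")
  expect_error(encode_simple(-1, 4), "non-negative")
})

test_that("simple encoding hits its endpoints and preserves order", {
  for (v_max in c(1, 2, 10, 61, 1000)) {
    expect_identical(encode_simple(0, v_max), "A")
    expect_identical(encode_simple(v_max, v_max), "9")
  }
  # brute force order preservation over the full 0..61 range
  idx <- match(strsplit(encode_simple(0:61, 61), "")[[1L]],
               iprsummary:::SIMPLE_ALPHABET)
  expect_identical(idx, 1:62)
  expect_false(is.unsorted(idx))
})

test_that("chart URLs carry type, size, encoded data and labels", {
  cd <- structure(list(title = "", labels = c("PF00001", "PF00002"),
                       values = c(2L, 1L), other_count = 0L),
                  class = "chart_data")
  url <- build_chart_url(cd, chart_spec("pie", 400, 200, backend = "url"))
  expect_match(url, "cht=p", fixed = TRUE)
  expect_match(url, "chs=400x200", fixed = TRUE)
  expect_match(url, "chd=s:9e", fixed = TRUE)
  expect_match(url, "chl=PF00001|PF00002", fixed = TRUE)
  # determinism
  expect_identical(
    url, build_chart_url(cd, chart_spec("pie", 400, 200, backend = "url")))

  empty <- structure(list(title = "", labels = character(),
                          values = integer(), other_count = 0L),
                     class = "chart_data")
  expect_match(build_chart_url(empty,
                               chart_spec("bar", 100, 100, backend = "url")),
               "chd=s:&", fixed = TRUE)
})

test_that("chart URLs are syntactically valid and labels round-trip", {
  cd <- structure(list(title = "", labels = c("has space", "a&b|c"),
                       values = c(5L, 3L), other_count = 0L),
                  class = "chart_data")
  url <- build_chart_url(cd, chart_spec("bar", 300, 150, backend = "url"))
  expect_match(url, "^https://[^ ]+\\?[A-Za-z0-9=&:%._|-]+$")
  query <- sub("^[^?]*\\?", "", url)
  parts <- strsplit(strsplit(query, "&", fixed = TRUE)[[1L]], "=")
  keys <- vapply(parts, `[[`, "", 1L)
  expect_setequal(keys, c("cht", "chs", "chd", "chl"))
  chl <- sub("^chl=", "", grep("^chl=", strsplit(query, "&")[[1L]],
                               value = TRUE))
  decoded <- vapply(strsplit(chl, "|", fixed = TRUE)[[1L]],
                    utils::URLdecode, "", USE.NAMES = FALSE)
  expect_identical(decoded, cd$labels)
})

test_that("the url backend enforces the legacy size limit", {
  expect_error(chart_spec("pie", 1200, 200, backend = "url"), "1000")
  expect_no_error(chart_spec("pie", 1200, 200, backend = "local"))
})

test_that("rendered SVG contains every label including the other bucket", {
  cd <- structure(list(title = "PFAM signature counts",
                       labels = c("PF00001", "PF00002", "long name & co"),
                       values = c(5L, 3L, 2L), other_count = 4L),
                  class = "chart_data")
  for (kind in c("pie", "bar")) {
    out <- withr::local_tempfile(fileext = ".svg")
    render_chart(cd, chart_spec(kind, backend = "local"), out)
    svg <- paste(readLines(out), collapse = "\n")
    expect_match(svg, "<svg", fixed = TRUE)
    expect_match(svg, "PF00001", fixed = TRUE)
    expect_match(svg, "long name &amp; co", fixed = TRUE)
    expect_match(svg, "other", fixed = TRUE)
  }
})

test_that("an empty series renders a valid image without crashing", {
  empty <- structure(list(title = "", labels = character(),
                          values = integer(), other_count = 0L),
                     class = "chart_data")
  out <- withr::local_tempfile(fileext = ".svg")
  render_chart(empty, chart_spec("bar", backend = "local"), out)
  expect_gt(file.size(out), 0)
  expect_no_error(xml2::read_xml(out))
})

test_that("a single dominant slice renders as a full circle", {
  cd <- structure(list(title = "", labels = "PF00001", values = 7L,
                       other_count = 0L), class = "chart_data")
  out <- withr::local_tempfile(fileext = ".svg")
  render_chart(cd, chart_spec("pie", backend = "local"), out)
  expect_match(paste(readLines(out), collapse = ""), "<circle")
})
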