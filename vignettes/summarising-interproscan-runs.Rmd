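---
title: "Summarising InterProScan runs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summarising InterProScan runs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iprsummary)
```

## The pipeline

`iprsummary` turns an InterProScan raw-XML result file into summary
statistics of the functional potential of the scanned protein set. The
pipeline has four stages, each usable on its own:

1. **Parse** (`parse_interproscan_xml`): the `interpro_matches` XML dialect
   is read into an in-memory run object — proteins, their InterPro entries,
   signature matches, match locations, and GO classifications.
2. **Store** (`init_schema`, `load_run`): the run is written to a
   seven-table SQLite database that mirrors the XML element hierarchy and
   persists for queries by other tools.
3. **Summarise** (`query_signature_counts`, `make_chart_data`,
   `compute_overview`): per-member-database signature counts, ranked and
   bucketed for charting.
4. **Report** (`export_html`, `export_tables`, `render_chart`,
   `build_chart_url`, `save_session`): HTML pages with embedded charts and
   QuickGO links, CSV/XLSX tables, and a reloadable session archive.

## Model of the data and its assumptions

A *signature* is a member-database entry (a Pfam domain, a PROSITE pattern,
...) that a scanning method can match against a sequence; InterPro groups
equivalent signatures into entries with `IPR` accessions and attaches GO
terms to entries, not to individual matches. The package models this
faithfully:

* every match belongs to exactly one InterPro entry of its protein;
  unintegrated matches are attached to a synthetic `noIPR` entry, so the
  object graph never has optional parentage, and `noIPR` carries no GO
  terms by construction;
* GO terms are properties of entries, so a signature's GO annotations are
  the de-duplicated union over the entries its matches belong to;
* coordinates are 1-based inclusive, exactly as InterProScan emits them;
  no half-open conversion happens anywhere;
* an absent score (the literal `NA` in the XML) becomes `NA_real_`, never
  `0`, because 0 is a legal score;
* match `status` is recorded but not filtered on: nothing in the upstream
  semantics makes non-`T` matches safe to drop silently, so filtering is a
  query-time option (`status =` argument) defaulting to "keep everything".

### Counting units

"How often does this signature occur in the population" has two defensible
readings: distinct proteins hit, or match records. The default is
**distinct proteins** because it is robust to a single domain shattering
into several partial hits on one protein; match-record counting is kept as
an explicit option and obeys a conservation law (totals across all member
databases equal the number of matches loaded) that the tests verify.
A *GO link* is a distinct (entry, GO id) pair; repeated emission of the
same classification in a file, or loading a run twice, does not inflate
the count.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `top_n` | 10 | chart slices/bars kept before folding into `other`; real signature lists are far too long to plot unbucketed |
| `counting` | `"proteins"` | counting unit (see above) |
| `chart kind` | `"pie"` | or `"bar"`; pure presentation |
| chart size | 500×300 px | the legacy URL backend caps sides at 1000 px |
| `deterministic` | off | suppresses timestamps so regenerated reports are byte-identical |

Chart label percentages are computed over the grand total including
`other` and rounded half-up to one decimal; half-up (rather than the
IEC half-even used by R's `round`) keeps report regeneration reproducible
by hand arithmetic.

## The chart backends

Charts render through two backends. The **local** backend writes SVG
directly as text: plain-text output makes chart content assertable in
tests without image diffing and makes report trees byte-deterministic,
which an R graphics device does not guarantee. The **url** backend builds
(but never fetches) an image-chart URL string in the legacy Google-style
scheme, including the 62-character *simple encoding*: a value $v$ on a
scale with maximum $v_{max}$ maps to alphabet index
$\mathrm{round}(61\,v/v_{max})$ in `A..Z a..z 0..9`, so 0 is always `A`
and $v_{max}$ always `9`. Rounding is R's `round` (half-to-even), which
reproduces the scheme's reference examples. The URL is a
presentation-layer serialization kept for compatibility with existing
tooling; the backing web service is long deprecated, so nothing in the
package dereferences it.

## The GO mapping

Translating numeric GO ids to readable names needs an ontology release.
Rather than querying a live GO database (slow, online-only), the package
reads a three-column tab-separated mapping (`go_id`, `name`, `category`,
comments `!`/`#`), which is trivially produced from any GO release.
`resolve_names` is a pure enrichment: it never drops, reorders, or
modifies ids — it only fills empty descriptions. Term links point at the
current EBI QuickGO term pages.

## The synthetic-data generator

`generate_ipr_xml` emits dialect-conformant XML with a known ground truth
so every stage is testable without external data, and the manifest is
tallied *while emitting*, never re-derived — the generator is therefore a
true oracle for the parser and the store. Its defaults emulate a small
whole-genome run:

* 100 proteins with lengths uniform in 50–2000 residues;
* 4 member databases (PFAM, SMART, PROSITE, GENE3D), 25 signatures each;
* per-protein match counts Poisson with mean 3 (so a few percent of
  proteins have no match, as in real annotation runs);
* signature popularity rank-weighted $\propto 1/\mathrm{rank}$ — real
  signature frequency profiles are heavy-tailed, and a skewed profile is
  what makes top-$N$ bucketing non-trivial to get right;
* roughly one signature in five unintegrated (`noIPR`); integrated
  entries carry 0–3 GO terms from a pool of 40.

Repeated draws of one signature for one protein become extra locations of
a single match, mirroring how InterProScan reports fragmented hits. GO
classifications are emitted at an entry's first occurrence in the file;
loading de-duplicates in any case, so files that repeat them parse
identically.

What the generator does **not** emulate: realistic E-value distributions
(scores are log-uniform decorations), inter-database correlation of hits
on the same protein, real accession vocabularies, or any specific
proteome. Green tests therefore demonstrate the pipeline's bookkeeping —
parsing, storage, counting, conservation, export fidelity — not
biological plausibility of any particular summary.

## Numerical and degenerate-input choices

* Ties in signature counts break by accession ascending, making every
  query result a total order and repeated queries byte-identical.
* An empty run, an empty database, and an empty chart series are all
  legal: loads are no-ops, overviews are zero, charts render valid
  empty-axes images, CSV exports write a header-only file.
* Validation (`validate_run`) reports violations as data instead of
  throwing, so a damaged file can be triaged in one pass.
* Loads are transactional: a failure rolls back the whole run.
* A schema-version stamp (`PRAGMA user_version`) distinguishes "fresh
  database" from "incompatible database"; re-initialising at the same
  version is a no-op, any other version is an explicit migration error.

## Design decisions on genuinely open points

* **Single embedded backend.** SQLite has the same relational semantics
  as a server backend with zero deployment burden; the schema is stable
  and documented so other tools can query the file directly.
* **XML reading strategy.** The file is parsed into a DOM once (xml2) and
  protein elements are converted one at a time, keeping the R-side
  working set bounded per protein. Files with thousands of proteins parse
  in seconds; the test suite exercises a 2,000-protein file.
* **Only `interpro_matches` is normative.** The historical EBIXML flavour
  has no published structure to implement against; `sniff_dialect` is the
  extension point (keyed by root tag) if one is added later.
* **Sessions are inspectable zips** (database + JSON manifest with
  `version`, `created`, `source`, `config`) rather than opaque R
  serialisations: they survive package-version changes and can be opened
  by anything that reads zip and SQLite.
* **XLSX is written directly** as the minimal OOXML part set (workbook,
  relationships, one inline-string worksheet per member database). The
  format is a documented zip-of-XML; the test suite verifies the output
  by reading it back with an independent spreadsheet library.
* **The CLI is a thin dispatcher** (`ipr_cli`) over exported functions,
  so everything scriptable from the shell is equally callable from R.

## Problem sizes used by the test suite

Unit and property tests run on the 3-protein toy fixture and generated
runs of 30–200 proteins; the parser determinism/scale test uses 2,000
proteins; the end-to-end ground-truth checks use ten 100-protein runs
with distinct seeds. These sizes give full code-path coverage (multi-db,
skew, bucketing, noIPR, absent scores) while the whole suite stays fast
enough to run on every change.

## Known limitations

* InterProScan 5 JSON/TSV/XML outputs are not parsed; input is the raw
  `interpro_matches` XML dialect only.
* GO names resolve only as far as the supplied mapping file; there is no
  OBO parsing, graph traversal, or enrichment testing.
* No cross-run comparisons: the unit of analysis is a single run.
* The spreadsheet export contains tables only, no embedded charts.
* Concurrent writers to one database file are not supported.
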