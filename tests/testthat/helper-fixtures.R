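# Shared fixtures: everything is generated in code at test time.

local_toy_xml <- function(env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".xml", .local_envir = env)
  manifest <- write_toy_fixture(path)
  attr(path, "manifest") <- manifest
  path
}

local_db <- function(env = parent.frame()) {
  con <- open_db()
  withr::defer(DBI::dbDisconnect(con), envir = env)
  init_schema(con)
  con
}

local_toy_db <- function(env = parent.frame()) {
  con <- local_db(env)
  load_run(con, parse_interproscan_xml(local_toy_xml(env)))
  con
}

local_generated <- function(env = parent.frame(), n_proteins = 100L,
                            seed = 42L, ...) {
  path <- withr::local_tempfile(fileext = ".xml", .local_envir = env)
  manifest <- generate_ipr_xml(
    gen_params(n_proteins = n_proteins, seed = seed, ...), path)
  list(xml = path, manifest = manifest)
}

# A small run built directly from constructors, for targeted cases.
make_run <- function(proteins) ipr_run(proteins = proteins)

one_match_protein <- function(id, sig, db = "PFAM", entry = "noIPR",
                              sig_name = "", len = 200L,
                              go = list()) {
  ipr_protein(id, length = len, entries = list(
    ipr_entry(entry, go_annotations = go, matches = list(
      ipr_match(sig, signature_name = sig_name, member_db = db,
                locations = list(ipr_location(1L, 50L)))))))
}

# check that every manifest number is recovered by parse -> load -> query
expect_manifest_recovered <- function(xml, manifest) {
  run <- parse_interproscan_xml(xml)
  con <- open_db()
  on.exit(DBI::dbDisconnect(con))
  stats <- load_run(con, run)
  expect_identical(stats$proteins_loaded, manifest$n_proteins)
  expect_identical(stats$matches_loaded,
                   as.integer(sum(manifest$per_db_match_counts)))
  expect_identical(stats$go_links_loaded, manifest$n_go_links)
  dbs <- query_member_dbs(con)
  expect_identical(dbs, sort(names(manifest$per_db_match_counts)))
  for (d in dbs) {
    by_match <- query_signature_counts(con, d, counting = "matches")
    expect_identical(sum(by_match$count),
                     as.integer(manifest$per_db_match_counts[[d]]))
    by_prot <- query_signature_counts(con, d, counting = "proteins")
    key <- paste0(d, ".", by_prot$signature_accession)
    expect_identical(
      as.integer(by_prot$count),
      unname(as.integer(manifest$per_signature_protein_counts[key])))
    expect_true(all(by_prot$count <= by_match$count[
      match(by_prot$signature_accession, by_match$signature_accession)]))
  }
  invisible(con)
}
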