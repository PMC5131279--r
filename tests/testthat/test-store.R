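make_store <- function(n = 30, seed = 5) generate_records(n, seed = seed, anchors = TRUE)

test_that("record loading validates schema, duplicates and invariants", {
  recs <- make_store(3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  save_records(recs, tf)
  expect_equal(nrow(load_records(tf)), 3)

  dup <- rbind(recs, recs[1, ])
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  save_records(dup, tf2)
  expect_error(load_records(tf2), "duplicate interaction_id.*G4DIP1")

  bad <- recs
  bad$kd[2] <- -1e-9
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  save_records(bad, tf3)
  expect_error(load_records(tf3), "kd")

  tf4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("interaction_id\tcategory", tf4)
  expect_error(load_records(tf4), "missing column")
})

test_that("load/save round-trips record content in both formats", {
  recs <- make_store(40)
  for (ext in c(".tsv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    save_records(recs, f)
    back <- load_records(f)
    for (col in names(recs))
      expect_equal(back[[col]], recs[[col]], tolerance = 0, info = paste(ext, col))
  }
})

test_that("record validation names each violated invariant", {
  good <- interaction_record("X1", "DNA", "ProtA", pmid = "12345", kd = 1e-8)
  expect_length(validate_record(good), 0)
  expect_equal(validate_record(interaction_record("X1", "DNA", "P", pmid = "25-679")),
               "pmid: non-digit characters")
  expect_equal(validate_record(
    interaction_record("X1", "RNA", "P", target_sequence = "ACGT")),
    "target_sequence: alphabet/category mismatch")
  expect_match(validate_record(interaction_record("", "DNA", "P")),
               "interaction_id", all = FALSE)
  expect_match(validate_record(interaction_record("X1", "protein", "P")),
               "category", all = FALSE)
  expect_match(validate_record(interaction_record("X1", "DNA", "P", ka = 0)),
               "ka", all = FALSE)
})

test_that("category browsing partitions the store", {
  recs <- make_store(50)
  dna <- browse_by_category(recs, "DNA")
  rna <- browse_by_category(recs, "RNA")
  expect_equal(nrow(dna) + nrow(rna), nrow(recs))
  expect_setequal(c(dna$interaction_id, rna$interaction_id), recs$interaction_id)
  expect_false(is.unsorted(dna$interaction_id))
  expect_equal(nrow(browse_by_category(recs[0, ], "DNA")), 0)
})

test_that("quick search matches any text field, case-insensitively", {
  recs <- make_store(50)
  expect_equal(quick_search(recs, "FMRP")$interaction_id, "G4RIP1")
  expect_equal(quick_search(recs, "fmrp")$interaction_id, "G4RIP1")
  expect_equal(quick_search(recs, "G4DIP1")$interaction_id, "G4DIP1")
  expect_equal(nrow(quick_search(recs, "zzqx")), 0)
  expect_error(quick_search(recs, ""), "empty query")
})

test_that("advanced search is a conjunction over the ten criteria fields", {
  recs <- make_store(50)
  expect_equal(advanced_search(recs, c(pmid = "25679041"))$protein_name,
               "Nucleoside diphosphate kinase 1")
  # single-criterion advanced search is a subset of quick search
  for (q in c("Nucleolin", "FMR1", "GENE0")) {
    adv <- advanced_search(recs, c(protein_name = q))$interaction_id
    expect_true(all(adv %in% quick_search(recs, q)$interaction_id))
  }
  # AND semantics: individually matching, jointly disjoint criteria
  expect_equal(nrow(advanced_search(recs, c(protein_name = "Nucleolin",
                                            pmid = "25679041"))), 0)
  expect_error(advanced_search(recs, c(bogus = "x")), "valid fields")
  expect_error(advanced_search(recs, list()), "at least one")
  # the author criterion searches the authors list
  a <- advanced_search(recs, c(author = "Silva"))
  expect_true("G4PIBD28" %in% a$interaction_id)
})

test_that("search results equal a naive per-record filter oracle", {
  recs <- make_store(60, seed = 13)
  for (q in c("FMRP", "Nucleolin", "G4", "EMSA", "sapiens", "gge", "25679041")) {
    expect_equal(quick_search(recs, q)$interaction_id,
                 naive_quick_search_ids(recs, q), info = q)
  }
  crits <- list(c(protein_name = "protein"),
                c(gene_name = "GENE0", pmid = "0"),
                c(uniprot_id = "P"),
                c(author = "a", target_name = "RNA"))
  for (cr in crits) {
    expect_equal(advanced_search(recs, cr)$interaction_id,
                 naive_advanced_search_ids(recs, cr),
                 info = paste(names(cr), cr, collapse = ","))
  }
})
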