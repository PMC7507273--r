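pubtator_fixture <- function(path) {
  writeLines(c(
    "101|t|Aspirin and pain",
    "101|a|Aspirin relieves headache pain quickly.",
    "101\t0\t7\tAspirin\tChemical\tD001241",
    "101\t17\t24\tAspirin\tChemical\tD001241",
    "101\t34\t42\theadache\tDisease\tD006261",
    "",
    "102|t|An empty one",
    "102|a|Nothing is annotated here.",
    "",
    "103|t|Mixture",
    "103|a|Benzene toluene xylene and more benzene here.",
    "103\t8\t15\tBenzene\tChemical\tD001554",
    "103\t16\t23\ttoluene\tChemical\tD014050",
    "103\t24\t30\txylene\tChemical\tD014982",
    "103\t40\t47\tbenzene\tChemical\tD001554",
    "103\tCID\tD001554\tD006261"
  ), path)
  path
}

test_that("read_pubtator parses blocks, mentions and offsets", {
  docs <- read_pubtator(pubtator_fixture(withr::local_tempfile(fileext = ".txt")))
  expect_equal(docs$doc_id, c("101", "102", "103"))
  expect_equal(vapply(docs$mentions, nrow, integer(1)), c(3L, 0L, 4L))
  m <- docs$mentions[[1]]
  expect_equal(m$surface[1], "Aspirin")
  expect_equal(m$gold_id, c("MESH:D001241", "MESH:D001241", "MESH:D006261"))
  # every surface equals its [start, end) slice of title + " " + abstract
  for (i in seq_len(nrow(docs))) {
    text <- paste(docs$title[i], docs$abstract[i], sep = " ")
    mm <- docs$mentions[[i]]
    expect_equal(substr(rep(text, nrow(mm)), mm$start + 1, mm$end), mm$surface)
  }
})

test_that("read_pubtator fails loudly on offset mismatches and odd lines", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "7|t|Title here",
    "7|a|Abstract here.",
    "7\t0\t5\tWRONG\tChemical\tD000001"
  ), bad)
  expect_error(read_pubtator(bad), "does not match")
  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("7|t|Title here", "7\tjust\tthree"), bad2)
  expect_error(read_pubtator(bad2), "unrecognised")
})

test_that("composite annotations become two mentions sharing a span", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "9|t|Carcinoma study",
    "9|a|hepatocellular carcinoma observed.",
    "9\t16\t40\thepatocellular carcinoma\tDisease\tD008113|D006528"
  ), path)
  docs <- read_pubtator(path)
  m <- docs$mentions[[1]]
  expect_equal(nrow(m), 2)
  expect_equal(unique(m$start), 16L)
  expect_setequal(m$gold_id, c("MESH:D008113", "MESH:D006528"))
})

test_that("pubtator writer round-trips document structure", {
  cfg <- synth_config(
    n_concepts = 30, n_synonyms = 1, ambiguity = 1,
    n_docs = 4, mentions_per_doc = 3, seed = 11
  )
  corp <- make_corpus(make_ontology(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pubtator(corp$documents, path)
  back <- read_pubtator(path)
  expect_equal(
    back[, c("doc_id", "title", "abstract", "mentions")],
    corp$documents[, c("doc_id", "title", "abstract", "mentions")]
  )
  # reading a file concatenated with itself adds nothing new per block id
  expect_identical(read_pubtator(path)$mentions, back$mentions)
})

test_that("read_gold_relations pools unique unordered CID pairs with roles", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "1|t|t", "1|a|a",
    "1\tCID\tD001554\tD006261",
    "1\tCID\tD001554\tD006261",
    "",
    "2|t|t", "2|a|a",
    "2\tCID\tD014050\tD006261",
    "2\tCID\tD001554\tD003643",
    "2\tCID\tD099999\tD003643",
    "",
    "3|t|t", "3|a|a",
    "3\tCID\tD088888\tD003643"
  ), path)
  rs <- read_gold_relations(path)
  expect_equal(nrow(rs), 5)
  expect_true(all(rs$provenance == "gold_cid"))
  expect_true(all(rs$c1 <= rs$c2))
  types <- attr(rs, "entity_types")
  expect_equal(unname(types["MESH:D001554"]), "chemical")
  expect_equal(unname(types["MESH:D006261"]), "disease")
  # no CID lines at all -> empty set
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1|t|t", "1|a|a"), empty)
  expect_equal(nrow(read_gold_relations(empty)), 0)
})

test_that("read_re_output keeps only effect pairs, unordered and pooled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "d1\tCHEBI:1\tCHEBI:2\teffect",
    "d1\tCHEBI:1\tCHEBI:3\tnoeffect",
    "d2\tCHEBI:2\tCHEBI:1\teffect",
    "d2\tCHEBI:4\tCHEBI:5\teffect",
    "d3\tCHEBI:4\tCHEBI:5\tnoeffect",
    "d3\tCHEBI:6\tCHEBI:7\teffect",
    "d3\tCHEBI:6\tCHEBI:8\teffect",
    "d4\tCHEBI:8\tCHEBI:6\teffect",
    "d4\tCHEBI:9\tCHEBI:2\tnoeffect",
    "d4\tCHEBI:2\tCHEBI:9\tnoeffect"
  ), path)
  rs <- read_re_output(path)
  expect_equal(nrow(rs), 4) # 6 effect rows over 4 distinct unordered pairs
  expect_true(all(rs$provenance == "re_tool"))
  # duplicated file content changes nothing
  double <- withr::local_tempfile(fileext = ".tsv")
  writeLines(rep(readLines(path), 2), double)
  expect_equal(read_re_output(double), rs, ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("d1\tCHEBI:1\tCHEBI:2\tmaybe", bad)
  expect_error(read_re_output(bad), "unknown relation label")
})

test_that("candidate files round-trip losslessly, edge hints included", {
  cfg <- synth_config(
    n_concepts = 40, n_synonyms = 1, ambiguity = 1,
    n_docs = 3, mentions_per_doc = 3, seed = 5
  )
  kb <- make_ontology(cfg)
  corp <- make_corpus(kb, cfg)
  cands <- generate_candidate_table(corp$documents, kb, k = 4)
  edge_hints <- dplyr::bind_rows(lapply(corp$documents$doc_id, function(d) {
    g <- build_graph(cands[cands$doc_id == d, ], kb, corp$relations, "corpus")
    if (nrow(g$edges) == 0) {
      return(NULL)
    }
    tibble::tibble(doc_id = d, link_mode = "corpus", from = g$edges$from, to = g$edges$to)
  }))
  dir <- withr::local_tempdir()
  write_candidate_files(cands, dir, edges = edge_hints)
  expect_length(list.files(dir, pattern = "\\.json$"), 3)
  back <- read_candidate_files(dir)
  expect_equal(back$candidates, dplyr::arrange(cands, doc_id, mention_index, rank))
  expect_equal(
    dplyr::arrange(back$edges, doc_id, from, to),
    dplyr::arrange(edge_hints, doc_id, from, to)
  )
})

test_that("candidate file reader rejects dangling edge hints and missing dirs", {
  expect_error(read_candidate_files(file.path(tempdir(), "no-such-dir-xyz")), "no such")
  dir <- withr::local_tempdir()
  writeLines('{
    "doc_id": "d1",
    "records": [{
      "mention_index": 1, "surface": "x", "entity_type": "Chemical",
      "gold_id": null,
      "candidates": [{"concept_id": "T:1", "matched_name": "x",
                      "lexical_score": 0.5, "is_exact": false, "rank": 1}]
    }],
    "edges": {"corpus": [[1, 7]]}
  }', file.path(dir, "d1.json"))
  expect_error(read_candidate_files(dir), "dangling")
})

test_that("an empty corpus writes an empty directory without error", {
  dir <- withr::local_tempdir()
  cands <- generate_candidate_table(
    tibble::tibble(
      doc_id = character(), title = character(), abstract = character(),
      mentions = list()
    ),
    make_ontology(synth_config(n_concepts = 5, ambiguity = 0, seed = 1))
  )
  write_candidate_files(cands, dir)
  expect_length(list.files(dir), 0)
})
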