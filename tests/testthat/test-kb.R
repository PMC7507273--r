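obo_fixture <- function(path) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: CHEBI:0001",
    "name: alpha acid",
    "",
    "[Term]",
    "id: CHEBI:0002",
    "name: beta acid",
    'synonym: "b acid" EXACT []',
    'synonym: "second acid" RELATED []',
    'synonym: "acid two" EXACT []',
    "alt_id: CHEBI:0099",
    "is_a: CHEBI:0001 ! alpha acid",
    "",
    "[Term]",
    "id: CHEBI:0003",
    "name: gone acid",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: has_role",
    "name: has role"
  ), path)
  path
}

test_that("load_obo reads terms, is_a relations, synonyms and obsolete flags", {
  kb <- load_obo(obo_fixture(withr::local_tempfile(fileext = ".obo")))
  expect_equal(nrow(kb$concepts), 3)
  expect_equal(kb$relations, tibble::tibble(child = "CHEBI:0002", parent = "CHEBI:0001"))
  # name index: 1 (alpha) + 4 (beta + 3 synonyms); obsolete term unsearchable
  expect_equal(sum(kb$names$concept_id == "CHEBI:0002"), 4)
  expect_false("CHEBI:0003" %in% kb$names$concept_id)
  expect_true("CHEBI:0003" %in% kb$concepts$id)
  # alt_id resolves to the canonical concept
  expect_equal(resolve_concept(kb, "CHEBI:0099"), "CHEBI:0002")
  # loading twice gives identical structures
  kb2 <- load_obo(obo_fixture(withr::local_tempfile(fileext = ".obo")))
  expect_identical(kb$concepts, kb2$concepts)
  expect_identical(kb$names, kb2$names)
})

test_that("load_obo reports a missing id with its byte offset and honours prefix filters", {
  bad <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "name: nameless"), bad)
  expect_error(load_obo(bad), "byte offset 0")
  expect_error(load_obo(file.path(tempdir(), "nope-missing.obo")), "cannot read")

  mixed <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: CHEBI:1", "name: one", "",
    "[Term]", "id: GO:2", "name: two", "is_a: CHEBI:1"
  ), mixed)
  kb <- suppressWarnings(load_obo(mixed, prefix_filter = "CHEBI"))
  expect_equal(kb$concepts$id, "CHEBI:1")
  expect_equal(nrow(kb$relations), 0)
})

test_that("load_ctd_chemicals_tsv parses the CTD dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "# CTD chemicals test",
    paste("#", paste(c(
      "ChemicalName", "ChemicalID", "CasRN", "Definition",
      "ParentIDs", "TreeNumbers", "ParentTreeNumbers", "Synonyms"
    ), collapse = "\t")),
    paste("acids", "MESH:D000143", "", "", "", "", "", "", sep = "\t"),
    paste("acetic acid", "MESH:D000428", "", "", "MESH:D000143", "", "",
      "ethanoic acid|vinegar acid|AcOH",
      sep = "\t"
    ),
    paste("benzene", "MESH:D001554", "", "", "MESH:D000143", "", "",
      "benzol|cyclohexatriene|phene",
      sep = "\t"
    ),
    paste("toluene", "MESH:D014050", "", "", "MESH:D001554", "", "",
      "methylbenzene|toluol|phenylmethane",
      sep = "\t"
    ),
    paste("xylene", "MESH:D014982", "", "", "MESH:D014050", "", "",
      "dimethylbenzene|xylol|mixed xylenes",
      sep = "\t"
    )
  )
  writeLines(rows, path)
  kb <- load_ctd_chemicals_tsv(path)
  expect_equal(nrow(kb$concepts), 5)
  expect_true(all(grepl("^MESH:D", kb$concepts$id)))
  expect_true(all(c("MESH:D000428", "MESH:D001554") %in%
    kb$relations$child[kb$relations$parent == "MESH:D000143"]))
  # row with empty Synonyms keeps an empty synonym list
  expect_length(kb$concepts$synonyms[[1]], 0)
  # 5 primary names + 4 rows x 3 synonyms
  expect_equal(nrow(kb$names), 5 + 12)
})

test_that("load_ctd_chemicals_tsv fails on a missing mandatory column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("#", paste(c("ChemicalName", "ChemicalID"), collapse = "\t")),
    paste("acids", "MESH:D000143", sep = "\t")
  ), path)
  expect_error(load_ctd_chemicals_tsv(path), "ParentIDs")
})

chain_kb <- function() {
  new_knowledge_base(
    tibble::tibble(
      id = c("T:A", "T:B", "T:C"),
      primary_name = c("a", "b", "c")
    ),
    tibble::tibble(child = c("T:B", "T:C"), parent = c("T:A", "T:B"))
  )
}

test_that("directly_linked is path-length-1 adjacency, undirected and irreflexive", {
  kb <- chain_kb()
  expect_true(directly_linked(kb, "T:B", "T:A"))
  expect_true(directly_linked(kb, "T:A", "T:B")) # symmetric
  expect_false(directly_linked(kb, "T:A", "T:C")) # grandparent: path length 2
  expect_false(directly_linked(kb, "T:B", "T:B"))
  expect_error(directly_linked(kb, "T:A", "T:Z"), "unknown concept")
})

test_that("compute_ic matches hand evaluation of cumulative smoothed frequencies", {
  kb <- new_knowledge_base(
    tibble::tibble(id = c("T:A", "T:B"), primary_name = c("a", "b")),
    tibble::tibble(child = "T:B", parent = "T:A")
  )
  ic <- compute_ic(kb, c("T:B" = 9))
  # n(A) = n(B) = 9, N = 9, |C| = 2 -> p = 10/11 for both
  expect_equal(ic$ic, rep(-log(10 / 11), 2), tolerance = 1e-12)

  # an unobserved leaf takes the maximum IC forced by smoothing
  kb3 <- chain_kb()
  ic3 <- compute_ic(kb3, c("T:C" = 5))
  expect_equal(
    ic3$ic[ic3$concept_id == "T:A"],
    ic3$ic[ic3$concept_id == "T:C"]
  )
  kb4 <- new_knowledge_base(
    tibble::tibble(id = c("T:A", "T:B", "T:Z"), primary_name = c("a", "b", "z")),
    tibble::tibble(child = "T:B", parent = "T:A")
  )
  ic4 <- compute_ic(kb4, c("T:B" = 7))
  expect_equal(max(ic4$ic), ic4$ic[ic4$concept_id == "T:Z"])
  expect_equal(ic4$ic[ic4$concept_id == "T:Z"], -log(1 / (7 + 3)), tolerance = 1e-12)
})

test_that("IC is monotone along is-a edges and strictly positive", {
  cfg <- synth_config(n_concepts = 40, branching = 3, n_synonyms = 0, ambiguity = 0, seed = 3)
  kb <- make_ontology(cfg)
  freq <- make_frequency_table(kb, seed = 4)
  ic <- compute_ic(kb, freq)
  v <- setNames(ic$ic, ic$concept_id)
  expect_true(all(v > 0), info = "smoothing keeps IC finite and positive")
  expect_true(all(v[kb$relations$parent] <= v[kb$relations$child] + 1e-12))
})

test_that("a star ontology with uniform leaf counts gives all leaves equal IC", {
  n_leaves <- 6
  ids <- c("T:root", sprintf("T:leaf%02d", seq_len(n_leaves)))
  kb <- new_knowledge_base(
    tibble::tibble(id = ids, primary_name = ids),
    tibble::tibble(child = ids[-1], parent = "T:root")
  )
  ic <- compute_ic(kb, setNames(rep(3, n_leaves), ids[-1]))
  leaf_ic <- ic$ic[ic$concept_id != "T:root"]
  expect_true(all(leaf_ic == leaf_ic[1]))
  expect_lt(ic$ic[ic$concept_id == "T:root"], leaf_ic[1])
})

test_that("compute_ic rejects negative counts and cyclic relations", {
  kb <- chain_kb()
  expect_error(compute_ic(kb, c("T:A" = -1)), "negative")
  cyc <- new_knowledge_base(
    tibble::tibble(id = c("T:A", "T:B"), primary_name = c("a", "b")),
    tibble::tibble(child = c("T:A", "T:B"), parent = c("T:B", "T:A"))
  )
  expect_error(compute_ic(cyc, c("T:A" = 1)), "cycle")
})

test_that("knowledge base invariants are enforced at construction", {
  expect_error(
    new_knowledge_base(
      tibble::tibble(id = "T:A", primary_name = "a"),
      tibble::tibble(child = "T:A", parent = "T:A")
    ),
    "self"
  )
  expect_error(
    new_knowledge_base(
      tibble::tibble(id = "T:A", primary_name = "a"),
      tibble::tibble(child = "T:A", parent = "T:B")
    ),
    "absent"
  )
  expect_error(
    new_knowledge_base(tibble::tibble(id = "notacurie", primary_name = "x")),
    "CURIE"
  )
  # a synonym that folds onto the primary name is dropped from the index
  kb <- new_knowledge_base(tibble::tibble(
    id = "T:A", primary_name = "Alcohol", synonyms = list(c("ALCOHOL", "ethanol"))
  ))
  expect_equal(sort(kb$names$folded), c("alcohol", "ethanol"))
})
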