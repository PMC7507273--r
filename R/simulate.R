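#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the structure the linking pipeline consumes in the
#' wild: an is-a tree vocabulary with synonyms standing in for a large
#' curated ontology, documents whose mention surfaces are lexically ambiguous
#' (each gold concept has near-miss decoy concepts within edit distance 1),
#' and a relation set that preferentially connects the gold concepts
#' co-occurring in a document — the signal a relation-extraction tool would
#' supply.
#'
#' @param n_concepts Number of concepts in the is-a tree (default 5000; large
#'   relative to the candidate depth, as real vocabularies are).
#' @param branching Children per internal node (default 3).
#' @param n_synonyms Synonyms per concept (default 2).
#' @param n_docs Number of documents (default 20).
#' @param mentions_per_doc Mentions per document (default 4).
#' @param ambiguity Decoy concepts per gold concept, each within edit
#'   distance 1 of the gold name and deliberately not is-a linked to it
#'   (default 2).
#' @param relation_coverage Probability that a same-document gold pair enters
#'   the relation set (default 1).
#' @param seed Integer seed; everything downstream is byte-reproducible.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_concepts = 5000, branching = 3, n_synonyms = 2,
                         n_docs = 20, mentions_per_doc = 4, ambiguity = 2,
                         relation_coverage = 1, seed = 1L) {
  stopifnot(
    n_concepts >= 1, branching >= 1, n_synonyms >= 0, n_docs >= 1,
    mentions_per_doc >= 1, ambiguity >= 0,
    relation_coverage >= 0, relation_coverage <= 1
  )
  structure(
    list(
      n_concepts = as.integer(n_concepts), branching = as.integer(branching),
      n_synonyms = as.integer(n_synonyms), n_docs = as.integer(n_docs),
      mentions_per_doc = as.integer(mentions_per_doc),
      ambiguity = as.integer(ambiguity),
      relation_coverage = as.numeric(relation_coverage), seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# pronounceable unique random names, 5-7 consonant-vowel syllables
synth_names <- function(n, taken = character()) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    batch <- vapply(seq_len(need * 2L), function(i) {
      k <- sample(5:7, 1)
      paste0(sample(cons, k, replace = TRUE), sample(vowels, k, replace = TRUE),
        collapse = ""
      )
    }, character(1))
    batch <- setdiff(unique(batch), c(taken, out))
    out <- c(out, batch)
  }
  out[seq_len(n)]
}

#' Generate a synthetic knowledge base with decoy ambiguity
#'
#' Builds a complete `branching`-ary is-a tree of `n_concepts` concepts with
#' synthetic names and synonyms. Every leaf is a designated *gold* concept
#' and receives `ambiguity` decoy concepts whose names are single-character
#' deletions of the gold name (edit distance 1) and which are attached
#' nowhere in the tree — lexically confusable but structurally isolated, so
#' only graph coherence can tell them from the real concept.
#'
#' @param config A [synth_config()].
#' @return A [new_knowledge_base()] object with attributes `gold_ids`
#'   (character vector of leaf concept ids) and `decoy_map` (tibble
#'   `decoy_id`, `gold_id`, `position` of the deleted character).
#' @export
make_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    n <- config$n_concepts
    ids <- sprintf("TOY:%06d", seq_len(n))
    names_tree <- synth_names(n)
    parent_idx <- if (n >= 2) ((2:n) - 2L) %/% config$branching + 1L else integer()
    relations <- tibble::tibble(
      child = ids[if (n >= 2) 2:n else integer()],
      parent = ids[parent_idx]
    )
    has_child <- seq_len(n) %in% parent_idx
    gold_idx <- which(!has_child)

    taken <- new.env(parent = emptyenv())
    for (nmv in names_tree) assign(nmv, TRUE, envir = taken)
    decoy_rows <- vector("list", length(gold_idx) * config$ambiguity)
    decoy_names <- character(0)
    di <- 0L
    if (config$ambiguity > 0) {
      for (gi in gold_idx) {
        g <- names_tree[[gi]]
        pos_order <- sample(nchar(g))
        made <- 0L
        for (p in pos_order) {
          if (made >= config$ambiguity) break
          cand <- paste0(substr(g, 1, p - 1L), substr(g, p + 1L, nchar(g)))
          if (exists(cand, envir = taken, inherits = FALSE)) next
          assign(cand, TRUE, envir = taken)
          di <- di + 1L
          made <- made + 1L
          decoy_rows[[di]] <- list(gold_id = ids[[gi]], position = p)
          decoy_names <- c(decoy_names, cand)
        }
      }
    }
    decoy_rows <- decoy_rows[seq_len(di)]
    decoy_ids <- sprintf("TOY:9%05d", seq_len(di))
    decoy_map <- tibble::tibble(
      decoy_id = decoy_ids,
      gold_id = vapply(decoy_rows, `[[`, "", "gold_id"),
      position = vapply(decoy_rows, function(r) as.integer(r$position), integer(1))
    )

    all_ids <- c(ids, decoy_ids)
    all_names <- c(names_tree, decoy_names)
    synonyms <- if (config$n_synonyms > 0) {
      extras <- synth_names(length(all_ids) * config$n_synonyms, taken = all_names)
      lapply(seq_along(all_ids), function(i) {
        paste(
          all_names[[i]],
          extras[seq((i - 1L) * config$n_synonyms + 1L, length.out = config$n_synonyms)]
        )
      })
    } else {
      rep(list(character()), length(all_ids))
    }

    concepts <- tibble::tibble(
      id = all_ids, primary_name = all_names,
      synonyms = synonyms,
      alt_ids = rep(list(character()), length(all_ids)),
      obsolete = rep(FALSE, length(all_ids))
    )
    kb <- new_knowledge_base(concepts, relations)
    attr(kb, "gold_ids") <- ids[gold_idx]
    attr(kb, "decoy_map") <- decoy_map
    kb
  })
}

#' Generate a synthetic annotated corpus and relation set
#'
#' Each document mentions `mentions_per_doc` distinct gold (leaf) concepts.
#' Half the surfaces (in expectation) are verbatim gold names — these resolve
#' by exact match and anchor the graph — and the rest carry one substituted
#' character at a position where a decoy of that concept dropped a character,
#' which makes the decoy tie the gold concept on lexical similarity and win
#' the shorter-name tie-break. Pure string matching therefore errs on the
#' perturbed mentions while graph coherence can recover them. A perturbed
#' surface never exactly matches any knowledge-base name. Same-document gold
#' pairs enter the relation set independently with probability
#' `relation_coverage`, pooled corpus-wide with provenance `"re_tool"`.
#'
#' @param kb A [make_ontology()] knowledge base (its `gold_ids` and
#'   `decoy_map` attributes are required).
#' @param config The same [synth_config()] used for the ontology.
#' @return A list with `documents` (PubTator-layout tibble with gold
#'   annotations) and `relations` (a [relation_set()]).
#' @export
make_corpus <- function(kb, config) {
  stopifnot(inherits(config, "synth_config"))
  gold_ids <- attr(kb, "gold_ids")
  decoy_map <- attr(kb, "decoy_map")
  if (is.null(gold_ids) || is.null(decoy_map)) {
    rlang::abort("make_corpus needs a knowledge base produced by make_ontology()")
  }
  if (length(gold_ids) < config$mentions_per_doc) {
    rlang::abort("not enough gold concepts for mentions_per_doc")
  }
  name_of <- stats::setNames(kb$concepts$primary_name, kb$concepts$id)
  folded_names <- new.env(parent = emptyenv())
  for (f in kb$names$folded) assign(f, TRUE, envir = folded_names)
  alphabet <- letters

  withr::with_seed(config$seed + 1L, {
    docs <- vector("list", config$n_docs)
    rel_c1 <- character(0)
    rel_c2 <- character(0)
    for (d in seq_len(config$n_docs)) {
      doc_id <- sprintf("SIM%05d", d)
      golds <- sample(gold_ids, config$mentions_per_doc)
      surfaces <- vapply(golds, function(g) {
        nm <- unname(name_of[[g]])
        if (stats::runif(1) < 0.5) return(nm)
        rows <- decoy_map[decoy_map$gold_id == g, ]
        if (nrow(rows) == 0) return(nm)
        p <- rows$position[[sample.int(nrow(rows), 1)]]
        orig <- substr(nm, p, p)
        for (ch in sample(setdiff(alphabet, orig))) {
          cand <- paste0(substr(nm, 1, p - 1L), ch, substr(nm, p + 1L, nchar(nm)))
          if (!exists(fold_string(cand), envir = folded_names, inherits = FALSE)) {
            return(cand)
          }
        }
        nm
      }, character(1))
      surfaces <- unname(surfaces)

      title <- paste("Synthetic abstract", doc_id)
      abstract <- paste(surfaces, collapse = " and ")
      starts <- nchar(title) + 1L +
        cumsum(c(0L, utils::head(nchar(surfaces) + nchar(" and "), -1L)))
      mentions <- tibble::tibble(
        mention_index = seq_along(golds),
        start = starts,
        end = starts + nchar(surfaces),
        surface = surfaces,
        entity_type = "Chemical",
        gold_id = unname(golds)
      )
      docs[[d]] <- tibble::tibble(
        doc_id = doc_id, title = title, abstract = abstract,
        mentions = list(mentions)
      )

      if (config$mentions_per_doc >= 2) {
        cmb <- utils::combn(sort(golds), 2)
        hit <- stats::runif(ncol(cmb)) < config$relation_coverage
        rel_c1 <- c(rel_c1, cmb[1, hit])
        rel_c2 <- c(rel_c2, cmb[2, hit])
      }
    }
    list(
      documents = dplyr::bind_rows(docs),
      relations = relation_set(rel_c1, rel_c2,
        provenance = rep("re_tool", length(rel_c1))
      )
    )
  })
}

#' Synthetic concept-frequency table
#'
#' Draws a positive count for every concept (1 plus a Poisson draw), giving a
#' non-degenerate extrinsic IC table for the synthetic benchmark.
#'
#' @param kb A [new_knowledge_base()] object.
#' @param seed Integer seed.
#' @param lambda Poisson mean of the count excess (default 2).
#' @return A tibble with columns `concept_id`, `count`.
#' @export
make_frequency_table <- function(kb, seed = 1L, lambda = 2) {
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      concept_id = kb$concepts$id,
      count = 1 + stats::rpois(nrow(kb$concepts), lambda)
    )
  })
}
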