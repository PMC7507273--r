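#' Expand relations by shared chemical or disease partners
#'
#' Given chemical-disease interaction pairs, infers that two diseases are
#' related when the same chemical is involved with both, and that two
#' chemicals are related when they are involved with the same disease. The
#' original pairs are retained; derived pairs carry provenance
#' `"derived_shared_entity"`.
#'
#' @param relations A [relation_set()] of chemical-disease pairs.
#' @param type_map Named character vector mapping concept ids to
#'   `"chemical"` or `"disease"`. Defaults to the `entity_types` attribute of
#'   `relations`; ids with a `CHEBI:` prefix default to `"chemical"`.
#' @return A [relation_set()] containing the original and derived pairs.
#' @export
expand_shared_entity_relations <- function(relations,
                                           type_map = attr(relations, "entity_types")) {
  ids <- unique(c(relations$c1, relations$c2))
  type_of <- function(id) {
    t <- if (is.null(type_map)) {
      rep(NA_character_, length(id))
    } else {
      unname(type_map[id])
    }
    t[is.na(t) & startsWith(id, "CHEBI:")] <- "chemical"
    t
  }
  t1 <- type_of(relations$c1)
  t2 <- type_of(relations$c2)
  if (anyNA(c(t1, t2))) {
    bad <- unique(c(relations$c1[is.na(t1)], relations$c2[is.na(t2)]))
    rlang::abort(paste0(
      "cannot resolve chemical/disease type for: ", paste(bad, collapse = ", ")
    ))
  }
  chem <- ifelse(t1 == "chemical", relations$c1, relations$c2)
  dis <- ifelse(t1 == "disease", relations$c1, relations$c2)

  derive <- function(keys, values) {
    groups <- split(values, keys)
    pairs <- purrr::map(groups, function(v) {
      v <- sort(unique(v))
      if (length(v) < 2) return(NULL)
      cmb <- utils::combn(v, 2)
      tibble::tibble(c1 = cmb[1, ], c2 = cmb[2, ])
    })
    dplyr::bind_rows(pairs)
  }
  new_pairs <- dplyr::bind_rows(
    derive(chem, dis), # diseases sharing a chemical
    derive(dis, chem) # chemicals sharing a disease
  )
  if (nrow(new_pairs) == 0) {
    return(relations)
  }
  relation_set(
    c(relations$c1, new_pairs$c1),
    c(relations$c2, new_pairs$c2),
    provenance = c(
      relations$provenance,
      rep("derived_shared_entity", nrow(new_pairs))
    ),
    entity_types = type_map
  )
}

#' Build the per-document disambiguation graph
#'
#' Nodes are mention/candidate pairs: one node per distinct candidate concept
#' of each mention, plus a single *fixed* node for every exact-matched
#' mention (the anchor keeps its concept regardless of ranking but still
#' participates in the walk). Edges never join two candidates of the same
#' mention; across mentions an edge is added when
#'
#' * `link_mode = "kb"`: the two concepts are directly connected in the
#'   ontology ([directly_linked()]),
#' * `link_mode = "corpus"`: the unordered concept pair occurs in
#'   `relations`,
#' * `link_mode = "kb_corpus"`: either of the above.
#'
#' Node order is lexicographic in `(mention_index, concept_id)` and edges are
#' stored with `from < to`, so identical inputs give identical graphs.
#'
#' @param candidates Candidate rows for a single document, as produced by
#'   [generate_candidate_table()].
#' @param kb A [new_knowledge_base()] object covering every candidate.
#' @param relations A [relation_set()] (may be `NULL` or empty; required
#'   content only for the corpus-informed modes).
#' @param link_mode One of `"kb"`, `"corpus"`, `"kb_corpus"`.
#' @return An object of class `disambiguation_graph`: list with `doc_id`,
#'   `nodes` (tibble `node`, `mention_index`, `concept_id`, `fixed`,
#'   `lexical_score`), `edges` (tibble `from`, `to`), `link_mode`.
#' @export
build_graph <- function(candidates, kb, relations = NULL,
                        link_mode = c("kb", "corpus", "kb_corpus")) {
  link_mode <- rlang::arg_match(link_mode)
  doc_id <- unique(candidates$doc_id)
  if (length(doc_id) > 1) {
    rlang::abort("build_graph expects the candidates of a single document")
  }
  if (length(doc_id) == 0) doc_id <- NA_character_

  unknown <- unique(candidates$concept_id[is.na(resolve_concept(kb, candidates$concept_id))])
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "candidate concept(s) absent from the knowledge base: ",
      paste(unknown, collapse = ", ")
    ))
  }

  nodes <- candidates |>
    dplyr::group_by(.data$mention_index, .data$concept_id) |>
    dplyr::summarise(
      fixed = any(.data$is_exact),
      lexical_score = max(.data$lexical_score),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mention_index, .data$concept_id) |>
    dplyr::mutate(node = dplyr::row_number(), .before = 1L)

  n <- nrow(nodes)
  edges <- tibble::tibble(from = integer(), to = integer())
  if (n >= 2) {
    cmb <- utils::combn(n, 2L)
    from <- cmb[1, ]
    to <- cmb[2, ]
    cross <- nodes$mention_index[from] != nodes$mention_index[to]
    from <- from[cross]
    to <- to[cross]
    keys <- pair_key(nodes$concept_id[from], nodes$concept_id[to])
    not_self <- nodes$concept_id[from] != nodes$concept_id[to]
    in_kb <- not_self & (keys %in% kb$pair_keys)
    rel_keys <- if (is.null(relations) || nrow(relations) == 0) {
      character()
    } else {
      pair_key(relations$c1, relations$c2)
    }
    in_corpus <- not_self & (keys %in% rel_keys)
    hit <- switch(link_mode,
      kb = in_kb,
      corpus = in_corpus,
      kb_corpus = in_kb | in_corpus
    )
    edges <- tibble::tibble(from = from[hit], to = to[hit])
  }

  structure(
    list(doc_id = doc_id, nodes = nodes, edges = edges, link_mode = link_mode),
    class = "disambiguation_graph"
  )
}

#' @export
print.disambiguation_graph <- function(x, ...) {
  cat(
    "<disambiguation_graph> doc ", x$doc_id, ": ", nrow(x$nodes), " nodes (",
    length(unique(x$nodes$mention_index)), " mentions), ", nrow(x$edges),
    " edges, link mode '", x$link_mode, "'\n",
    sep = ""
  )
  invisible(x)
}
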