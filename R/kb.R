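#' Construct a knowledge base from concept and relation tables
#'
#' A knowledge base is the pair of a concept set and its is-a relations,
#' together with a searchable name index. Obsolete concepts are retained in
#' the concept table (so deprecated gold identifiers still resolve during
#' evaluation) but are excluded from the name index and can never be proposed
#' as candidates.
#'
#' @param concepts A data frame with columns `id` (CURIE, e.g. `"CHEBI:17996"`),
#'   `primary_name`, and optionally `synonyms` (list column of character
#'   vectors), `alt_ids` (list column) and `obsolete` (logical).
#' @param relations A data frame with columns `child`, `parent` holding
#'   directed is-a edges, or `NULL` for none.
#' @return An object of class `knowledge_base` with elements `concepts`,
#'   `relations`, `names` (the flat name index: one row per searchable
#'   name/synonym of a non-obsolete concept) and `alt_ids`.
#' @export
new_knowledge_base <- function(concepts, relations = NULL) {
  concepts <- tibble::as_tibble(concepts)
  stopifnot(all(c("id", "primary_name") %in% names(concepts)))
  n <- nrow(concepts)
  if (!"synonyms" %in% names(concepts)) concepts$synonyms <- rep(list(character()), n)
  if (!"alt_ids" %in% names(concepts)) concepts$alt_ids <- rep(list(character()), n)
  if (!"obsolete" %in% names(concepts)) concepts$obsolete <- rep(FALSE, n)
  if (anyDuplicated(concepts$id)) {
    rlang::abort("duplicate concept ids in knowledge base")
  }
  bad <- !is_curie(concepts$id)
  if (any(bad)) {
    rlang::abort(paste0(
      "concept ids must be CURIEs (<PREFIX>:<local>); offending: ",
      paste(utils::head(concepts$id[bad], 3), collapse = ", ")
    ))
  }
  noname <- !concepts$obsolete & (is.na(concepts$primary_name) | concepts$primary_name == "")
  if (any(noname)) {
    rlang::abort("non-obsolete concepts must have a non-empty primary name")
  }
  # a synonym that case-folds to the primary name is redundant; drop it
  concepts$synonyms <- purrr::map2(
    concepts$synonyms, concepts$primary_name,
    function(s, p) unique(s[fold_string(s) != fold_string(p)])
  )

  if (is.null(relations) || nrow(as.data.frame(relations)) == 0) {
    relations <- tibble::tibble(child = character(), parent = character())
  } else {
    relations <- tibble::as_tibble(relations)[, c("child", "parent")]
    relations <- dplyr::distinct(relations)
    missing <- setdiff(c(relations$child, relations$parent), concepts$id)
    if (length(missing) > 0) {
      rlang::abort(paste0(
        "is-a relation endpoint(s) absent from concept set: ",
        paste(utils::head(missing, 3), collapse = ", ")
      ))
    }
    if (any(relations$child == relations$parent)) {
      rlang::abort("self is-a relation (c, c) is not allowed")
    }
  }

  searchable <- concepts[!concepts$obsolete, ]
  name_rows <- tibble::tibble(
    concept_id = rep(searchable$id, lengths(searchable$synonyms) + 1L),
    name = unlist(purrr::map2(
      searchable$primary_name, searchable$synonyms, function(p, s) c(p, s)
    ), use.names = FALSE) %||% character(),
    is_primary = unlist(purrr::map(
      lengths(searchable$synonyms),
      function(k) c(TRUE, rep(FALSE, k))
    ), use.names = FALSE) %||% logical()
  )
  name_rows$folded <- fold_string(name_rows$name)
  name_rows <- name_rows[!duplicated(name_rows[, c("concept_id", "folded")]), ]
  name_rows$n_fold <- nchar(name_rows$folded)

  alt <- tibble::tibble(
    alt_id = unlist(concepts$alt_ids, use.names = FALSE) %||% character(),
    canonical = rep(concepts$id, lengths(concepts$alt_ids))
  )
  alt <- alt[!duplicated(alt$alt_id), ]
  alt_map <- stats::setNames(alt$canonical, alt$alt_id)

  structure(
    list(
      concepts = concepts,
      relations = relations,
      names = name_rows,
      alt_ids = alt_map,
      pair_keys = pair_key(relations$child, relations$parent)
    ),
    class = "knowledge_base"
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(
    "<knowledge_base> ", nrow(x$concepts), " concepts (",
    sum(x$concepts$obsolete), " obsolete), ",
    nrow(x$relations), " is-a relations, ",
    nrow(x$names), " searchable names\n",
    sep = ""
  )
  invisible(x)
}

#' Resolve a concept identifier to its canonical form
#'
#' Alternative identifiers (e.g. OBO `alt_id` tags) resolve to the canonical
#' concept id; canonical ids resolve to themselves; unknown ids give `NA`.
#'
#' @param kb A [new_knowledge_base()] object.
#' @param id Character vector of CURIEs.
#' @return Character vector of canonical ids (`NA` where unknown).
#' @export
resolve_concept <- function(kb, id) {
  out <- ifelse(id %in% kb$concepts$id, id, unname(kb$alt_ids[id]))
  as.character(out)
}

#' Test whether two concepts are directly connected in the ontology
#'
#' Two concepts are directly linked when the shortest path between them along
#' is-a edges, treated as undirected, has length exactly 1. A concept is never
#' directly linked to itself.
#'
#' @param kb A [new_knowledge_base()] object.
#' @param c1,c2 Concept CURIEs (alternative ids are resolved first).
#' @return Logical scalar (vectorised over `c1`/`c2`).
#' @export
directly_linked <- function(kb, c1, c2) {
  a <- resolve_concept(kb, c1)
  b <- resolve_concept(kb, c2)
  if (anyNA(a) || anyNA(b)) {
    bad <- unique(c(c1[is.na(a)], c2[is.na(b)]))
    rlang::abort(paste0("unknown concept id(s): ", paste(bad, collapse = ", ")))
  }
  (a != b) & (pair_key(a, b) %in% kb$pair_keys)
}

#' Compute extrinsic information content for every concept
#'
#' Information content follows the extrinsic (corpus-frequency) definition:
#' the cumulative count of a concept is its own observed frequency plus the
#' frequencies of all of its is-a descendants, counted once each. With add-one
#' smoothing over the concept set,
#' `IC(c) = -ln((n(c) + 1) / (N + |C|))` where `N` is the total observed
#' frequency and `|C|` the number of concepts. Rare concepts receive high IC;
#' ancestors never exceed the IC of their descendants.
#'
#' @param kb A [new_knowledge_base()] object.
#' @param freq Observed concept frequencies: a data frame with columns
#'   `concept_id`, `count`, a named numeric vector, or `NULL` (all zero).
#'   Missing concepts count 0. Counts must be nonnegative.
#' @return A tibble with columns `concept_id`, `ic` (natural-log units,
#'   strictly positive).
#' @seealso [uniform_ic()] for the unweighted (IC = 1) table,
#'   [read_ic_frequencies()] for the TSV frequency format.
#' @export
compute_ic <- function(kb, freq = NULL) {
  ids <- kb$concepts$id
  counts <- stats::setNames(numeric(length(ids)), ids)
  if (!is.null(freq)) {
    if (is.data.frame(freq)) {
      freq <- stats::setNames(freq$count, freq$concept_id)
    }
    if (any(freq < 0)) rlang::abort("negative frequency count")
    keys <- resolve_concept(kb, names(freq))
    if (anyNA(keys)) {
      rlang::abort(paste0(
        "frequency table names unknown concept(s): ",
        paste(names(freq)[is.na(keys)], collapse = ", ")
      ))
    }
    for (i in seq_along(freq)) {
      counts[keys[i]] <- counts[keys[i]] + freq[[i]]
    }
  }

  rel <- kb$relations
  if (nrow(rel) > 0) {
    g <- igraph::graph_from_data_frame(rel, directed = TRUE, vertices = ids)
    if (!igraph::is_dag(g)) rlang::abort("cycle detected in is-a relations")
  }
  parents_of <- split(rel$parent, rel$child)

  # propagate each observed count to all ancestors, visiting each once
  cum <- counts
  for (id in names(counts)[counts > 0]) {
    seen <- character()
    frontier <- parents_of[[id]] %||% character()
    while (length(frontier) > 0) {
      frontier <- setdiff(unique(frontier), seen)
      if (length(frontier) == 0) break
      cum[frontier] <- cum[frontier] + counts[[id]]
      seen <- c(seen, frontier)
      frontier <- unlist(parents_of[frontier], use.names = FALSE)
    }
  }

  n_total <- sum(counts)
  p <- (cum + 1) / (n_total + length(ids))
  tibble::tibble(concept_id = ids, ic = -log(unname(p)))
}

#' Unit information-content table
#'
#' Assigns IC = 1 to every concept, turning IC-weighted coherence into plain
#' (unweighted) graph coherence. Used as the default when no external
#' frequency data are available.
#'
#' @param kb A [new_knowledge_base()] object.
#' @return A tibble with columns `concept_id`, `ic`.
#' @export
uniform_ic <- function(kb) {
  tibble::tibble(concept_id = kb$concepts$id, ic = 1)
}

#' Read a concept-frequency table
#'
#' Two-column tab-separated file: `concept_id<TAB>count`, no header.
#'
#' @param path File path.
#' @return A tibble with columns `concept_id`, `count`.
#' @export
read_ic_frequencies <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read frequency table: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    rlang::abort("frequency table rows must be 'concept_id<TAB>count'")
  }
  tibble::tibble(
    concept_id = vapply(parts, `[[`, "", 1L),
    count = as.numeric(vapply(parts, `[[`, "", 2L))
  )
}

#' @rdname new_knowledge_base
#' @param x Object.
#' @export
is_knowledge_base <- function(x) inherits(x, "knowledge_base")
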