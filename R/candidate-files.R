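#' Write per-document candidate files
#'
#' Materialises everything needed to rebuild a document's disambiguation
#' graph — mentions, ranked candidate entries and optional precomputed edge
#' hints per link mode — as one JSON file per document with a fixed,
#' deterministic field order. [read_candidate_files()] restores the exact
#' structures.
#'
#' @param candidates A [generate_candidate_table()] tibble (any number of
#'   documents).
#' @param out_dir Output directory (created if needed).
#' @param edges Optional edge hints: a tibble with columns `doc_id`,
#'   `link_mode`, `from`, `to`, where the indices refer to the
#'   `(mention_index, concept_id)`-ordered node list of [build_graph()].
#' @return Character vector of the files written, invisibly.
#' @export
write_candidate_files <- function(candidates, out_dir, edges = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    rlang::abort(paste0("cannot write to directory: ", out_dir))
  }
  doc_ids <- unique(candidates$doc_id)
  paths <- character(0)
  for (doc in doc_ids) {
    dc <- candidates[candidates$doc_id == doc, ]
    n_nodes <- nrow(unique(dc[, c("mention_index", "concept_id")]))
    records <- lapply(split(dc, dc$mention_index), function(m) {
      list(
        mention_index = m$mention_index[[1]],
        surface = m$surface[[1]],
        entity_type = m$entity_type[[1]],
        gold_id = m$gold_id[[1]],
        candidates = purrr::pmap(
          m[, c("concept_id", "matched_name", "lexical_score", "is_exact", "rank")],
          function(concept_id, matched_name, lexical_score, is_exact, rank) {
            list(
              concept_id = concept_id, matched_name = matched_name,
              lexical_score = lexical_score, is_exact = is_exact, rank = rank
            )
          }
        )
      )
    })
    names(records) <- NULL
    edge_hints <- NULL
    if (!is.null(edges)) {
      de <- edges[edges$doc_id == doc, ]
      if (nrow(de) > 0 && max(c(de$from, de$to)) > n_nodes) {
        rlang::abort(paste0("edge hint references a node beyond the ", n_nodes,
          " candidate nodes of document ", doc
        ))
      }
      edge_hints <- lapply(split(de, de$link_mode), function(e) {
        purrr::map2(e$from, e$to, c)
      })
    }
    payload <- list(doc_id = doc, records = records, edges = edge_hints)
    path <- file.path(out_dir, paste0(doc, ".json"))
    jsonlite::write_json(payload, path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
    )
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-document candidate files
#'
#' Inverse of [write_candidate_files()]: restores the flat candidate table
#' and any edge hints, validating that hint indices stay within each
#' document's candidate node set.
#'
#' @param dir Directory containing `*.json` candidate files.
#' @return A list with `candidates` (tibble in [generate_candidate_table()]
#'   layout) and `edges` (tibble `doc_id`, `link_mode`, `from`, `to`, or
#'   `NULL` when no file carries hints).
#' @export
read_candidate_files <- function(dir) {
  if (!dir.exists(dir)) rlang::abort(paste0("no such directory: ", dir))
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  cand_rows <- list()
  edge_rows <- list()
  for (path in files) {
    payload <- jsonlite::read_json(path)
    doc <- payload$doc_id
    for (rec in payload$records) {
      for (cd in rec$candidates) {
        cand_rows[[length(cand_rows) + 1L]] <- tibble::tibble(
          doc_id = doc,
          mention_index = as.integer(rec$mention_index),
          surface = rec$surface,
          entity_type = rec$entity_type,
          gold_id = if (is.null(rec$gold_id)) NA_character_ else rec$gold_id,
          concept_id = cd$concept_id,
          matched_name = cd$matched_name,
          lexical_score = as.numeric(cd$lexical_score),
          is_exact = isTRUE(cd$is_exact),
          rank = as.integer(cd$rank)
        )
      }
    }
    if (!is.null(payload$edges)) {
      dc_nodes <- length(unique(vapply(
        unlist(lapply(payload$records, function(r) {
          lapply(r$candidates, function(cd) {
            paste(r$mention_index, cd$concept_id)
          })
        }), recursive = FALSE),
        identity, ""
      )))
      for (mode in names(payload$edges)) {
        for (e in payload$edges[[mode]]) {
          from <- as.integer(e[[1]])
          to <- as.integer(e[[2]])
          if (from > dc_nodes || to > dc_nodes || from < 1 || to < 1) {
            rlang::abort(paste0(
              "dangling edge-hint index in ", basename(path), " (", mode, ")"
            ))
          }
          edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
            doc_id = doc, link_mode = mode, from = from, to = to
          )
        }
      }
    }
  }
  candidates <- dplyr::bind_rows(cand_rows)
  if (nrow(candidates) > 0) {
    candidates <- dplyr::arrange(candidates, .data$doc_id, .data$mention_index, .data$rank)
  }
  edges <- if (length(edge_rows) > 0) dplyr::bind_rows(edge_rows) else NULL
  list(candidates = candidates, edges = edges)
}
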