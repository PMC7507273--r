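#' Normalised lexical similarity between strings
#'
#' Similarity is one minus the Levenshtein edit distance divided by the
#' length of the longer string, computed after case folding and whitespace
#' collapsing; it lies in `[0, 1]` with 1 for strings identical after
#' folding. Two empty strings have similarity 1.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
#' @examples
#' lexical_similarity("kitten", "sitting") # 1 - 3/7
lexical_similarity <- function(a, b) {
  fa <- fold_string(a)
  fb <- fold_string(b)
  n <- max(length(fa), length(fb))
  fa <- rep_len(fa, n)
  fb <- rep_len(fb, n)
  d <- if (length(fa) == 1L) {
    as.numeric(utils::adist(fa, fb))
  } else {
    utils::adist(fa, fb)[cbind(seq_len(n), seq_len(n))]
  }
  maxlen <- pmax(nchar(fa), nchar(fb))
  ifelse(maxlen == 0, 1, 1 - d / maxlen)
}

#' Generate the ranked candidate list for a mention surface
#'
#' If the folded surface hits the knowledge-base name index exactly, the
#' mention is resolved immediately: the list contains a single exact
#' candidate and no further ranking happens (should several concepts share
#' the exact name, the lexicographically smallest id wins, with a warning).
#' Otherwise every searchable name and synonym is scored by
#' [lexical_similarity()]; the `k` distinct concepts with the best scores
#' enter the list, and every other name/synonym of those concepts is appended
#' as an additional entry pointing at the same concept. Obsolete concepts are
#' never searchable and therefore never proposed.
#'
#' Ordering is deterministic: entries sort by descending score, then shorter
#' matched name, then concept id.
#'
#' @param surface Mention surface form (non-empty).
#' @param kb A [new_knowledge_base()] object.
#' @param k Number of distinct concepts retained by the primary ranking
#'   (default 10).
#' @param min_score Optional similarity floor; entries scoring below it are
#'   discarded before ranking. Default 0 (no floor).
#' @return A tibble with columns `concept_id`, `matched_name`,
#'   `lexical_score`, `is_exact`, ordered by rank.
#' @export
generate_candidates <- function(surface, kb, k = 10, min_score = 0) {
  stopifnot(k >= 1)
  fs <- fold_string(surface)
  if (!nzchar(fs)) rlang::abort("cannot generate candidates for an empty surface")
  nm <- kb$names
  if (nrow(nm) == 0) {
    return(tibble::tibble(
      concept_id = character(), matched_name = character(),
      lexical_score = numeric(), is_exact = logical()
    ))
  }

  exact <- which(nm$folded == fs)
  if (length(exact) > 0) {
    ids <- sort(unique(nm$concept_id[exact]))
    if (length(ids) > 1) {
      rlang::warn(paste0(
        'surface "', surface, '" exactly matches several concepts (',
        paste(ids, collapse = ", "), "); keeping ", ids[[1]]
      ))
    }
    hit <- exact[nm$concept_id[exact] == ids[[1]]][[1]]
    return(tibble::tibble(
      concept_id = ids[[1]], matched_name = nm$name[[hit]],
      lexical_score = 1, is_exact = TRUE
    ))
  }

  d <- as.numeric(utils::adist(fs, nm$folded))
  sim <- 1 - d / pmax(nchar(fs), nm$n_fold)
  keep <- sim >= min_score
  nm <- nm[keep, ]
  sim <- sim[keep]
  if (nrow(nm) == 0) {
    return(tibble::tibble(
      concept_id = character(), matched_name = character(),
      lexical_score = numeric(), is_exact = logical()
    ))
  }

  # one pass: rows sorted by (score desc, shorter name, concept id); the first
  # occurrence of each concept is both its best entry and its rank position
  o <- ord(-sim, nm$n_fold, nm$concept_id, nm$folded)
  first <- o[!duplicated(nm$concept_id[o])]
  chosen <- nm$concept_id[utils::head(first, k)]

  sel <- nm$concept_id %in% chosen
  nm <- nm[sel, ]
  sim <- sim[sel]
  o2 <- ord(-sim, nm$n_fold, nm$concept_id, nm$folded)
  tibble::tibble(
    concept_id = nm$concept_id[o2],
    matched_name = nm$name[o2],
    lexical_score = sim[o2],
    is_exact = FALSE
  )
}

#' Generate candidate lists for every mention of a corpus
#'
#' Applies [generate_candidates()] to each mention of each document (caching
#' repeated surfaces) and returns one flat table, the tabular equivalent of a
#' per-document candidates file.
#'
#' @param documents A document tibble as returned by [read_pubtator()].
#' @param kb A [new_knowledge_base()] object.
#' @inheritParams generate_candidates
#' @return A tibble with columns `doc_id`, `mention_index`, `surface`,
#'   `entity_type`, `gold_id`, `concept_id`, `matched_name`, `lexical_score`,
#'   `is_exact`, `rank` (entry order within the mention). Mentions with no
#'   valid candidate contribute no rows.
#' @export
generate_candidate_table <- function(documents, kb, k = 10, min_score = 0) {
  mentions <- tidyr::unnest(
    documents[, c("doc_id", "mentions")],
    "mentions"
  )
  if (nrow(mentions) == 0) {
    return(tibble::tibble(
      doc_id = character(), mention_index = integer(), surface = character(),
      entity_type = character(), gold_id = character(), concept_id = character(),
      matched_name = character(), lexical_score = numeric(),
      is_exact = logical(), rank = integer()
    ))
  }
  surfaces <- unique(mentions$surface)
  lists <- lapply(surfaces, function(s) {
    cl <- generate_candidates(s, kb, k = k, min_score = min_score)
    cl$rank <- seq_len(nrow(cl))
    cl
  })
  names(lists) <- surfaces
  per_mention <- purrr::pmap(
    mentions[, c("doc_id", "mention_index", "surface", "entity_type", "gold_id")],
    function(doc_id, mention_index, surface, entity_type, gold_id) {
      cl <- lists[[surface]]
      if (nrow(cl) == 0) return(NULL)
      tibble::tibble(
        doc_id = doc_id, mention_index = mention_index, surface = surface,
        entity_type = entity_type, gold_id = gold_id, cl
      )
    }
  )
  dplyr::bind_rows(per_mention)
}
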