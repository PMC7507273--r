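#' Read a PubTator-format corpus
#'
#' Parses blank-line-separated document blocks: a `PMID|t|title` line, an
#' optional `PMID|a|abstract` line, then tab-separated annotation lines
#' `PMID<TAB>start<TAB>end<TAB>surface<TAB>type<TAB>conceptID`. Character
#' offsets are 0-based half-open over the concatenation `title + " " +
#' abstract` and are validated against the annotated surface. Relation
#' (`CID`) lines are skipped here; see [read_gold_relations()].
#'
#' Composite annotations carrying two gold identifiers separated by `|`
#' become two mention rows sharing the same span. Bare MeSH identifiers are
#' normalised to `MESH:` CURIEs; the unnormalised marker `-1` becomes `NA`.
#'
#' @param path Path to a PubTator text file.
#' @return A tibble with one row per document: columns `doc_id`, `title`,
#'   `abstract` and `mentions`, a list column of tibbles with columns
#'   `mention_index`, `start`, `end`, `surface`, `entity_type`, `gold_id`.
#' @export
read_pubtator <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read PubTator file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  breaks <- !nzchar(lines)
  block_id <- cumsum(c(TRUE, breaks[-length(breaks)])) # blank line opens a new block
  blocks <- split(lines[!breaks], block_id[!breaks])
  line_no <- split(seq_along(lines)[!breaks], block_id[!breaks])

  docs <- purrr::map2(blocks, line_no, parse_pubtator_block)
  docs <- docs[!vapply(docs, is.null, logical(1))]
  dplyr::bind_rows(docs)
}

parse_pubtator_block <- function(block, line_no) {
  if (length(block) == 0) return(NULL)
  title <- abstract <- NULL
  doc_id <- NULL
  ann <- list()
  for (j in seq_along(block)) {
    line <- block[[j]]
    tm <- regmatches(line, regexec("^([^|\t]+)\\|t\\|(.*)$", line))[[1]]
    am <- regmatches(line, regexec("^([^|\t]+)\\|a\\|(.*)$", line))[[1]]
    if (length(tm) == 3) {
      doc_id <- tm[[2]]; title <- tm[[3]]
      next
    }
    if (length(am) == 3) {
      abstract <- am[[3]]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) == 4 && fields[[2]] == "CID") next
    if (length(fields) < 6) {
      rlang::abort(paste0(
        "unrecognised PubTator line shape at line ", line_no[[j]], ": ", line
      ))
    }
    ann[[length(ann) + 1L]] <- list(fields = fields, line = line_no[[j]])
  }
  if (is.null(title)) {
    rlang::abort(paste0(
      "PubTator block starting at line ", line_no[[1]], " has no title line"
    ))
  }
  abstract <- abstract %||% ""
  text <- paste(title, abstract, sep = " ")

  mentions <- purrr::map(ann, function(a) {
    f <- a$fields
    start <- suppressWarnings(as.integer(f[[2]]))
    end <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end) {
      rlang::abort(paste0("invalid offsets in document ", doc_id, " at line ", a$line))
    }
    slice <- substr(text, start + 1L, end)
    if (slice != f[[4]]) {
      rlang::abort(paste0(
        "annotation text does not match the [", start, ",", end,
        ") slice in document ", doc_id, " at line ", a$line,
        ': got "', slice, '", annotated "', f[[4]], '"'
      ))
    }
    ids <- normalize_curie(strsplit(f[[6]], "|", fixed = TRUE)[[1]])
    if (length(ids) == 0) ids <- NA_character_
    tibble::tibble(
      start = start, end = end, surface = f[[4]],
      entity_type = f[[5]], gold_id = ids
    )
  })
  mentions <- dplyr::bind_rows(mentions)
  if (nrow(mentions) == 0) {
    mentions <- tibble::tibble(
      start = integer(), end = integer(), surface = character(),
      entity_type = character(), gold_id = character()
    )
  }
  mentions <- dplyr::mutate(mentions, mention_index = dplyr::row_number(),
    .before = 1L
  )
  tibble::tibble(
    doc_id = doc_id, title = title, abstract = abstract,
    mentions = list(mentions)
  )
}

#' Write documents in PubTator format
#'
#' Inverse of [read_pubtator()] on the `(doc_id, title, abstract, mentions)`
#' structure; composite mentions are written as one annotation line per gold
#' identifier, matching how the reader splits them.
#'
#' @param documents A document tibble as returned by [read_pubtator()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(documents, path) {
  blocks <- purrr::pmap_chr(
    documents[, c("doc_id", "title", "abstract", "mentions")],
    function(doc_id, title, abstract, mentions) {
      ann <- if (nrow(mentions)) {
        paste(doc_id, mentions$start, mentions$end, mentions$surface,
          mentions$entity_type,
          ifelse(is.na(mentions$gold_id), "-1", mentions$gold_id),
          sep = "\t"
        )
      }
      paste(
        c(
          paste0(doc_id, "|t|", title),
          paste0(doc_id, "|a|", abstract),
          ann
        ),
        collapse = "\n"
      )
    }
  )
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Build a relation set from concept-id pairs
#'
#' A relation set is a set of unordered concept pairs; `{a, b}` and `{b, a}`
#' are the same pair and self-pairs are rejected. Each pair carries a
#' provenance tag saying where it came from.
#'
#' @param c1,c2 Character vectors of concept CURIEs.
#' @param provenance Provenance tag per pair: one of `"gold_cid"`,
#'   `"re_tool"`, `"derived_shared_entity"`.
#' @param entity_types Optional named character vector mapping concept ids to
#'   `"chemical"`/`"disease"`, kept as an attribute for shared-entity
#'   expansion.
#' @return A tibble with columns `c1`, `c2` (canonically ordered so
#'   `c1 <= c2`), `provenance`; duplicated pairs are collapsed, keeping the
#'   first provenance seen.
#' @export
relation_set <- function(c1 = character(), c2 = character(),
                         provenance = character(), entity_types = NULL) {
  if (any(c1 == c2)) rlang::abort("relation set cannot contain a self-pair {c, c}")
  lo <- pmin(c1, c2)
  hi <- pmax(c1, c2)
  if (length(lo) > 0 && length(provenance) == 0) {
    rlang::abort("a provenance tag is required for every relation pair")
  }
  out <- tibble::tibble(
    c1 = lo, c2 = hi,
    provenance = rep_len(provenance %||% character(), length(lo))
  )
  out <- out[!duplicated(pair_key(out$c1, out$c2)), ]
  out <- out[ord(out$c1, out$c2), ]
  attr(out, "entity_types") <- entity_types
  out
}

#' Read gold chemical-disease interactions from a PubTator file
#'
#' Collects 4-field `PMID<TAB>CID<TAB>chemID<TAB>diseaseID` lines and pools
#' them corpus-wide into a relation set with provenance `"gold_cid"`. The
#' chemical/disease role of each identifier is preserved in the
#' `entity_types` attribute.
#'
#' @param path Path to a PubTator text file.
#' @return A [relation_set()] tibble.
#' @export
read_gold_relations <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read PubTator file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  cid <- grep("\tCID\t", lines, fixed = TRUE, value = TRUE)
  fields <- strsplit(cid, "\t", fixed = TRUE)
  bad <- lengths(fields) != 4
  if (any(bad)) {
    rlang::abort(paste0("malformed CID line: ", cid[bad][[1]]))
  }
  chem <- normalize_curie(vapply(fields, `[[`, "", 3L))
  dis <- normalize_curie(vapply(fields, `[[`, "", 4L))
  keep <- !is.na(chem) & !is.na(dis)
  chem <- chem[keep]; dis <- dis[keep]
  types <- stats::setNames(
    c(rep("chemical", length(chem)), rep("disease", length(dis))),
    c(chem, dis)
  )
  types <- types[!duplicated(names(types))]
  relation_set(chem, dis,
    provenance = rep("gold_cid", length(chem)),
    entity_types = types
  )
}

#' Read relation-extraction tool output
#'
#' Consumes the 4-column TSV emitted by sentence-level relation classifiers:
#' `doc_id<TAB>concept_id_1<TAB>concept_id_2<TAB>label` with label `effect`
#' (a relation holds) or `noeffect`. Only `effect` rows yield pairs, pooled
#' corpus-wide with provenance `"re_tool"`.
#'
#' @param path Path to the TSV file (no header).
#' @return A [relation_set()] tibble.
#' @export
read_re_output <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read relation TSV: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4)) {
    rlang::abort("relation TSV rows must be 'doc_id<TAB>c1<TAB>c2<TAB>label'")
  }
  label <- vapply(fields, `[[`, "", 4L)
  unknown <- setdiff(unique(label), c("effect", "noeffect"))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown relation label(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- label == "effect"
  relation_set(
    vapply(fields, `[[`, "", 2L)[keep],
    vapply(fields, `[[`, "", 3L)[keep],
    provenance = rep("re_tool", sum(keep))
  )
}

#' Write a relation set as a 4-column TSV
#'
#' Emits rows in the dialect read by [read_re_output()], with label `effect`
#' and a constant document column (pooled relations are document-agnostic).
#'
#' @param relations A [relation_set()] tibble.
#' @param path Output path.
#' @param doc_id Document column value for every row.
#' @return `path`, invisibly.
#' @export
write_relations_tsv <- function(relations, path, doc_id = "corpus") {
  writeLines(
    paste(doc_id, relations$c1, relations$c2, "effect", sep = "\t"),
    path, useBytes = TRUE
  )
  invisible(path)
}
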