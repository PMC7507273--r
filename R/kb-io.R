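#' Load an OBO ontology into a knowledge base
#'
#' Parses the OBO 1.2/1.4 flat-file tags relevant to entity linking:
#' `[Term]` stanzas with `id`, `name`, `synonym`, `alt_id`, `is_a` and
#' `is_obsolete`. Only `is_a` lines become relations; cross-products and other
#' relationship types are ignored. Obsolete terms are kept in the concept
#' table but excluded from the searchable name index.
#'
#' @param path Path to an OBO file.
#' @param prefix_filter Optional CURIE prefix (e.g. `"CHEBI"`); terms with a
#'   different prefix are dropped, as are relations pointing outside the kept
#'   set (with a warning).
#' @return A [new_knowledge_base()] object.
#' @export
load_obo <- function(path, prefix_filter = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read OBO file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # byte offset of the start of each line, for format diagnostics
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))

  terms <- list()
  cur <- NULL
  cur_offset <- 0L
  flush <- function(stanza, offset) {
    if (is.null(stanza)) return(invisible(NULL))
    if (is.null(stanza$id)) {
      rlang::abort(paste0("[Term] stanza without an id tag at byte offset ", offset))
    }
    terms[[length(terms) + 1L]] <<- stanza
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\[", line)) {
      flush(cur, cur_offset)
      cur <- if (line == "[Term]") {
        cur_offset <- offsets[[i]]
        list(
          id = NULL, name = "", synonyms = character(),
          alt_ids = character(), is_a = character(), obsolete = FALSE
        )
      } else {
        NULL
      }
      next
    }
    if (is.null(cur) || !nzchar(line)) next
    if (grepl("^id:", line)) {
      cur$id <- trimws(sub("^id:", "", line))
    } else if (grepl("^name:", line)) {
      cur$name <- trimws(sub("^name:", "", line))
    } else if (grepl("^synonym:", line)) {
      m <- regmatches(line, regexec('^synonym:\\s*"([^"]*)"', line))[[1]]
      if (length(m) == 2) cur$synonyms <- c(cur$synonyms, m[[2]])
    } else if (grepl("^alt_id:", line)) {
      cur$alt_ids <- c(cur$alt_ids, trimws(sub("^alt_id:", "", line)))
    } else if (grepl("^is_a:", line)) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      target <- trimws(sub("\\{.*\\}", "", target))
      if (nzchar(target)) cur$is_a <- c(cur$is_a, target)
    } else if (grepl("^is_obsolete:", line)) {
      cur$obsolete <- grepl("true", line, fixed = TRUE)
    }
  }
  flush(cur, cur_offset)

  if (!is.null(prefix_filter)) {
    keep <- vapply(
      terms, function(t) startsWith(t$id, paste0(prefix_filter, ":")), logical(1)
    )
    terms <- terms[keep]
  }
  concepts <- tibble::tibble(
    id = vapply(terms, `[[`, "", "id"),
    primary_name = vapply(terms, `[[`, "", "name"),
    synonyms = purrr::map(terms, "synonyms"),
    alt_ids = purrr::map(terms, "alt_ids"),
    obsolete = vapply(terms, `[[`, logical(1), "obsolete")
  )
  rel <- tibble::tibble(
    child = rep(concepts$id, lengths(purrr::map(terms, "is_a"))),
    parent = unlist(purrr::map(terms, "is_a"), use.names = FALSE) %||% character()
  )
  dangling <- !(rel$parent %in% concepts$id)
  if (any(dangling)) {
    rlang::warn(paste0(
      "dropping ", sum(dangling), " is_a relation(s) whose parent is not in the file"
    ))
    rel <- rel[!dangling, ]
  }
  new_knowledge_base(concepts, rel)
}

#' Load a CTD chemicals vocabulary into a knowledge base
#'
#' Reads the Comparative Toxicogenomics Database TSV dialect: '#'-prefixed
#' header lines (one of which carries the column names), tab-separated rows,
#' pipe-separated multi-value cells. Identifiers are normalised to prefixed
#' CURIEs (`MESH:Dxxxxxx`).
#'
#' @param path Path to a CTD-Chemicals TSV file.
#' @return A [new_knowledge_base()] object.
#' @export
load_ctd_chemicals_tsv <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read CTD TSV: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  comment <- startsWith(lines, "#")
  header_line <- rev(lines[comment & grepl("ChemicalName", lines)])[1]
  if (is.na(header_line)) {
    rlang::abort("CTD TSV: no '#' header line naming the columns (ChemicalName ...)")
  }
  cols <- strsplit(sub("^#\\s*", "", header_line), "\t", fixed = TRUE)[[1]]
  cols <- trimws(cols)
  required <- c("ChemicalName", "ChemicalID", "ParentIDs", "Synonyms")
  if (!all(required %in% cols)) {
    rlang::abort(paste0(
      "CTD TSV missing mandatory column(s): ",
      paste(setdiff(required, cols), collapse = ", ")
    ))
  }
  body <- lines[!comment & nzchar(lines)]
  split_cell <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
  }
  rows <- strsplit(body, "\t", fixed = TRUE)
  field <- function(r, name) {
    i <- match(name, cols)
    if (i > length(r)) "" else r[[i]]
  }
  ids <- normalize_curie(vapply(rows, field, "", "ChemicalID"))
  concepts <- tibble::tibble(
    id = ids,
    primary_name = vapply(rows, field, "", "ChemicalName"),
    synonyms = purrr::map(rows, function(r) split_cell(field(r, "Synonyms"))),
    alt_ids = rep(list(character()), length(rows)),
    obsolete = rep(FALSE, length(rows))
  )
  parents <- purrr::map(rows, function(r) normalize_curie(split_cell(field(r, "ParentIDs"))))
  rel <- tibble::tibble(
    child = rep(ids, lengths(parents)),
    parent = unlist(parents, use.names = FALSE) %||% character()
  )
  dangling <- !(rel$parent %in% ids)
  if (any(dangling)) {
    rlang::warn(paste0(
      "dropping ", sum(dangling), " ParentIDs relation(s) not present in the file"
    ))
    rel <- rel[!dangling, ]
  }
  new_knowledge_base(concepts, rel)
}

#' Write a knowledge base as an OBO file
#'
#' Emits the tag subset understood by [load_obo()]; `load_obo(write_obo(kb))`
#' reproduces concepts, relations and the name index. Mainly used to
#' materialise synthetic ontologies for command-line runs.
#'
#' @param kb A [new_knowledge_base()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(kb, path) {
  parents_of <- split(kb$relations$parent, kb$relations$child)
  blocks <- purrr::pmap_chr(
    kb$concepts,
    function(id, primary_name, synonyms, alt_ids, obsolete) {
      paste(c(
        "[Term]",
        paste0("id: ", id),
        paste0("name: ", primary_name),
        if (length(alt_ids)) paste0("alt_id: ", alt_ids),
        if (length(synonyms)) paste0('synonym: "', synonyms, '" EXACT []'),
        if (obsolete) "is_obsolete: true",
        if (!is.null(parents_of[[id]])) paste0("is_a: ", sort(parents_of[[id]]))
      ), collapse = "\n")
    }
  )
  writeLines(
    c("format-version: 1.2", "", paste(blocks, collapse = "\n\n")),
    path, useBytes = TRUE
  )
  invisible(path)
}
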