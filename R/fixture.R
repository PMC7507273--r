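#' Compact worked example: an exact-match anchor rescuing two ambiguous mentions
#'
#' Builds a single synthetic document with three chemical mentions — `"Cl"`,
#' `"sodium vanate"` and `"sodium deoxycholate"` — over a small knowledge
#' base in which the third mention matches its concept (`CHEBI:9177`)
#' exactly, while the other two are lexically ambiguous: each has a decoy
#' concept that outranks the correct one (`CHEBI:17996` chloride,
#' `CHEBI:35607` sodium vanadate) on pure string similarity. The relation set
#' links both correct concepts to the anchored `CHEBI:9177`, so a
#' corpus-informed disambiguation graph gains exactly two edges while the
#' ontology structure alone yields none — the situation where text-derived
#' relations, and only they, drive the disambiguation.
#'
#' The knowledge base is a stand-in for a full chemical ontology, so the
#' returned `k = 2` candidate depth plays the role that the default depth of
#' 10 plays against a vocabulary of tens of thousands of names; use it when
#' generating candidates for this fixture. Identifiers follow the ChEBI
#' scheme for realism; the decoy entry is invented.
#'
#' @return A list with `document` (one-row tibble), `kb`, `relations` and
#'   `k` (the candidate depth matching the compact knowledge base).
#' @export
#' @examples
#' fx <- make_anchor_fixture()
#' cands <- generate_candidate_table(fx$document, fx$kb, k = fx$k)
#' nrow(build_graph(cands, fx$kb, fx$relations, "kb")$edges) # 0
#' nrow(build_graph(cands, fx$kb, fx$relations, "corpus")$edges) # 2
make_anchor_fixture <- function() {
  concepts <- tibble::tibble(
    id = c(
      "CHEBI:24431", "CHEBI:9177", "CHEBI:17996",
      "CHEBI:35607", "CHEBI:30514", "CHEBI:12093"
    ),
    primary_name = c(
      "chemical entity", "sodium deoxycholate", "chloride",
      "sodium vanadate", "caesium", "sodium vanite"
    ),
    synonyms = list(
      character(), character(), character(),
      character(), "Cs", character()
    ),
    alt_ids = rep(list(character()), 6),
    obsolete = rep(FALSE, 6)
  )
  relations <- tibble::tibble(
    child = concepts$id[-1],
    parent = "CHEBI:24431"
  )
  kb <- new_knowledge_base(concepts, relations)

  title <- "Sodium salts"
  abstract <- "Cl and sodium vanate were applied with sodium deoxycholate ."
  text <- paste(title, abstract, sep = " ")
  surfaces <- c("Cl", "sodium vanate", "sodium deoxycholate")
  starts <- vapply(surfaces, function(s) {
    as.integer(regexpr(s, text, fixed = TRUE)) - 1L
  }, integer(1))
  mentions <- tibble::tibble(
    mention_index = 1:3,
    start = unname(starts),
    end = unname(starts) + nchar(surfaces),
    surface = surfaces,
    entity_type = "Chemical",
    gold_id = c("CHEBI:17996", "CHEBI:35607", "CHEBI:9177")
  )
  document <- tibble::tibble(
    doc_id = "ANCHOR01", title = title, abstract = abstract,
    mentions = list(mentions)
  )
  rels <- relation_set(
    c("CHEBI:17996", "CHEBI:35607"),
    c("CHEBI:9177", "CHEBI:9177"),
    provenance = c("re_tool", "re_tool")
  )
  list(document = document, kb = kb, relations = rels, k = 2L)
}
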