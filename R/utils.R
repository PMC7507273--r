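#' Canonicalise a string for lexical comparison
#'
#' Case-folds, trims, and collapses internal whitespace runs to single spaces.
#' All name-index lookups and similarity computations operate on folded strings.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' fold_string("  Sodium   Deoxycholate ")
fold_string <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

# Canonical unordered key for a concept pair. Used for both ontology adjacency
# and text-derived relation membership tests.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stable radix order wrapper; ties among remaining keys resolved by earlier keys
ord <- function(...) order(..., method = "radix")

is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9_.-]*:\\S+$", x)
}

# Prefix bare MeSH-style identifiers (e.g. "D003072") as used in BC5CDR
# annotation lines; "-1" marks an unnormalised mention and becomes NA.
normalize_curie <- function(x, default_prefix = "MESH") {
  out <- ifelse(x == "-1" | x == "", NA_character_,
    ifelse(grepl(":", x, fixed = TRUE), x, paste0(default_prefix, ":", x))
  )
  out
}
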