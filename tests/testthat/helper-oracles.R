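# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: a textbook dynamic-programming edit distance, a
# plain-loop confusion counter, and direct construction of graph objects.

lev_dp <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1L,
        d[i + 1, j] + 1L,
        d[i, j] + (a[i] != b[j])
      )
    }
  }
  d[n + 1, m + 1]
}

# a bare disambiguation graph where every node is its own mention
toy_graph <- function(n, edges) {
  structure(
    list(
      doc_id = "toy",
      nodes = tibble::tibble(
        node = seq_len(n),
        mention_index = seq_len(n),
        concept_id = sprintf("T:%03d", seq_len(n)),
        fixed = FALSE,
        lexical_score = 1
      ),
      edges = edges,
      link_mode = "corpus"
    ),
    class = "disambiguation_graph"
  )
}

random_toy_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    cmb <- utils::combn(n, 2)
    keep <- stats::runif(ncol(cmb)) < p
    toy_graph(n, tibble::tibble(from = cmb[1, keep], to = cmb[2, keep]))
  })
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# plain-loop micro counter over (gold, predicted) unit pairs
count_confusion <- function(gold, predicted) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(gold)) {
    if (is.na(predicted[i])) {
      fn <- fn + 1L
    } else if (predicted[i] == gold[i]) {
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# minimal single-mention candidate row builder
cand_row <- function(doc_id, mention, concept, score = 0.9, rank = 1L,
                     exact = FALSE, surface = paste0("m", mention),
                     gold = NA_character_) {
  tibble::tibble(
    doc_id = doc_id, mention_index = as.integer(mention), surface = surface,
    entity_type = "Chemical", gold_id = gold, concept_id = concept,
    matched_name = concept, lexical_score = score, is_exact = exact,
    rank = as.integer(rank)
  )
}

# one-document corpus wrapper around a mentions tibble
as_document <- function(doc_id, mentions, title = "t", abstract = "a") {
  tibble::tibble(
    doc_id = doc_id, title = title, abstract = abstract,
    mentions = list(mentions)
  )
}
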