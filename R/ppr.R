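#' Personalized PageRank configuration
#'
#' Parameters of the truncated personalized random walk used to score the
#' disambiguation graph: the walk runs for exactly `n_steps` steps from a
#' source node; at each step the walker teleports back to the source with
#' probability `teleport`, otherwise moves to a uniformly random neighbour
#' (a node with no neighbours sends the walker back to the source). The
#' Monte-Carlo engine launches `n_walks` independent walks per source and
#' estimates the end-point distribution; the exact engine computes the same
#' distribution by power iteration.
#'
#' @param n_walks Walks per source node for the Monte-Carlo engine
#'   (default 2000).
#' @param n_steps Walk length (default 5).
#' @param teleport Probability of jumping back to the source at each step
#'   (default 0.2).
#' @param seed Integer seed driving the Monte-Carlo engine.
#' @return An object of class `ppr_config`.
#' @export
ppr_config <- function(n_walks = 2000, n_steps = 5, teleport = 0.2, seed = 1L) {
  stopifnot(
    n_walks >= 1, n_steps >= 1,
    teleport > 0, teleport < 1,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      n_walks = as.integer(n_walks), n_steps = as.integer(n_steps),
      teleport = as.numeric(teleport), seed = as.integer(seed)
    ),
    class = "ppr_config"
  )
}

# flat adjacency (neighbor list) of an undirected graph
graph_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  e <- graph$edges
  ends <- c(e$to, e$from)
  at <- c(e$from, e$to)
  o <- ord(at, ends)
  deg <- tabulate(at, nbins = n)
  list(
    deg = deg,
    flat = ends[o],
    start = cumsum(c(1L, deg))[seq_len(n)] # start[i]: first neighbor of i in flat
  )
}

#' Exact truncated personalized PageRank from one source
#'
#' Computes the end-point distribution of the `n_steps`-step teleporting walk
#' by power iteration:
#' `p_0 = e_s`, `p_{t+1} = teleport * e_s + (1 - teleport) * p_t W`, where
#' `W` is the row-stochastic transition matrix over the undirected edges and
#' a neighbourless node transitions to the source with probability 1. This is
#' exactly the quantity the Monte-Carlo engine estimates, so it serves as its
#' reference oracle.
#'
#' @param graph A [build_graph()] object.
#' @param source Node index (row of `graph$nodes`).
#' @param config A [ppr_config()].
#' @return A tibble with columns `node`, `prob` summing to 1, with the
#'   source index in attribute `"source"`.
#' @export
ppr_exact <- function(graph, source, config = ppr_config()) {
  n <- nrow(graph$nodes)
  if (!(is.numeric(source) && length(source) == 1 && source >= 1 && source <= n)) {
    rlang::abort("source is not a node of the graph")
  }
  source <- as.integer(source)
  P <- ppr_matrix(graph, config, engine = "exact", sources = source)
  tibble::tibble(node = seq_len(n), prob = as.numeric(P)) |>
    structure(source = source)
}

#' Monte-Carlo truncated personalized PageRank from one source
#'
#' Simulates `n_walks` independent `n_steps`-step walks from the source
#' (teleport with probability `teleport`, otherwise a uniform neighbour; no
#' neighbour means a jump back to the source) and returns end-point
#' frequencies. The estimator is unbiased for [ppr_exact()] and converges to
#' it as `n_walks` grows; the global RNG state is left untouched, so the same
#' seed always gives the identical distribution.
#'
#' @inheritParams ppr_exact
#' @return A tibble with columns `node`, `prob` (multiples of `1/n_walks`
#'   summing to 1), with the source index in attribute `"source"`.
#' @export
ppr_monte_carlo <- function(graph, source, config = ppr_config()) {
  n <- nrow(graph$nodes)
  if (!(is.numeric(source) && length(source) == 1 && source >= 1 && source <= n)) {
    rlang::abort("source is not a node of the graph")
  }
  source <- as.integer(source)
  P <- ppr_matrix(graph, config, engine = "monte_carlo", sources = source)
  tibble::tibble(node = seq_len(n), prob = as.numeric(P)) |>
    structure(source = source)
}

#' Personalized PageRank from every source node
#'
#' Convenience wrapper computing the full source-by-node PPR matrix needed
#' for coherence scoring, with either engine.
#'
#' @inheritParams ppr_exact
#' @param engine `"exact"` (power iteration) or `"monte_carlo"` (end-point
#'   sampling).
#' @param sources Integer vector of source nodes (default: all nodes).
#' @return A numeric matrix with one row per source (in `sources` order) and
#'   one column per node; each row sums to 1.
#' @export
ppr_matrix <- function(graph, config = ppr_config(),
                       engine = c("exact", "monte_carlo"), sources = NULL) {
  engine <- rlang::arg_match(engine)
  n <- nrow(graph$nodes)
  sources <- as.integer(sources %||% seq_len(n))
  if (n == 0) {
    return(matrix(numeric(), nrow = 0, ncol = 0))
  }
  eps <- config$teleport
  adj <- graph_adjacency(graph)

  if (engine == "exact") {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (adj$deg[i] > 0) {
        nb <- adj$flat[seq(adj$start[i], length.out = adj$deg[i])]
        W[i, nb] <- 1 / adj$deg[i]
      }
    }
    dangling <- adj$deg == 0
    m <- length(sources)
    P <- matrix(0, m, n)
    P[cbind(seq_len(m), sources)] <- 1
    for (t in seq_len(config$n_steps)) {
      M <- P %*% W
      if (any(dangling)) {
        dm <- rowSums(P[, dangling, drop = FALSE])
        M[cbind(seq_len(m), sources)] <- M[cbind(seq_len(m), sources)] + dm
      }
      P <- (1 - eps) * M
      P[cbind(seq_len(m), sources)] <- P[cbind(seq_len(m), sources)] + eps
    }
    return(P)
  }

  withr::with_seed(config$seed, {
    nw <- config$n_walks
    src <- rep(sources, each = nw)
    cur <- src
    for (t in seq_len(config$n_steps)) {
      tele <- stats::runif(length(cur)) < eps
      u <- stats::runif(length(cur))
      nd <- adj$deg[cur]
      nxt <- src # teleport / dangling default
      move <- !tele & nd > 0
      if (any(move)) {
        pick <- 1L + as.integer(floor(u[move] * nd[move]))
        # guard the measure-zero u == 1 case
        pick <- pmin(pick, nd[move])
        nxt[move] <- adj$flat[adj$start[cur[move]] + pick - 1L]
      }
      cur <- nxt
    }
    counts <- tabulate(
      (rep(seq_along(sources), each = nw) - 1L) * n + cur,
      nbins = length(sources) * n
    )
    matrix(counts, nrow = length(sources), byrow = TRUE) / nw
  })
}

#' Coherence scores for every node of a disambiguation graph
#'
#' The coherence of node `n` sums the PPR mass it receives from every source
#' node belonging to a *different* mention, weighted by the information
#' content of `n`'s concept:
#' `Coherence(n) = IC(concept(n)) * sum_{s : mention(s) != mention(n)} PPR(s -> n)`.
#' Competing candidates of the same mention (including `n` itself) never
#' contribute, so a node reachable only from its own rivals scores 0.
#'
#' @param graph A [build_graph()] object.
#' @param ppr PPR matrix from [ppr_matrix()] covering every node as source
#'   (rows = sources in node order), or a list of per-source distributions
#'   from [ppr_exact()]/[ppr_monte_carlo()].
#' @param ic IC table (`concept_id`, `ic`) from [compute_ic()] or
#'   [uniform_ic()]; `NULL` means unit weights. Every node concept must be
#'   covered.
#' @return A tibble with columns `node`, `score` (nonnegative).
#' @export
coherence_scores <- function(graph, ppr, ic = NULL) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  if (is.list(ppr) && !is.matrix(ppr)) {
    stopifnot(length(ppr) == n)
    ppr <- do.call(rbind, lapply(ppr, function(d) d$prob))
  }
  if (!is.matrix(ppr) || nrow(ppr) != n || ncol(ppr) != n) {
    rlang::abort("ppr must cover every node as source (n-by-n matrix)")
  }
  icv <- if (is.null(ic)) {
    rep(1, n)
  } else {
    v <- ic$ic[match(nodes$concept_id, ic$concept_id)]
    if (anyNA(v)) {
      rlang::abort(paste0(
        "no information-content value for concept(s): ",
        paste(unique(nodes$concept_id[is.na(v)]), collapse = ", ")
      ))
    }
    v
  }
  other_mention <- outer(nodes$mention_index, nodes$mention_index, `!=`)
  score <- colSums(ppr * other_mention) * icv
  tibble::tibble(node = seq_len(n), score = as.numeric(score))
}

#' Choose one candidate per mention from coherence scores
#'
#' Per mention: an exact-matched mention keeps its fixed concept; otherwise
#' the candidate node with the strictly highest positive coherence wins
#' (ties broken by higher lexical score, then concept id). When every
#' candidate of a mention scores 0 — an edgeless or disconnected graph — the
#' decision falls back to lexical order, reproducing the string-matching
#' baseline. Mentions with an empty candidate list are absent from the
#' result and count as unlinked (NIL) downstream.
#'
#' @param graph A [build_graph()] object.
#' @param coherence Tibble from [coherence_scores()].
#' @param candidates Candidate rows of this document (for the lexical
#'   fallback order).
#' @return A tibble with columns `mention_index`, `concept_id`.
#' @export
disambiguate_document <- function(graph, coherence, candidates) {
  nodes <- dplyr::left_join(graph$nodes, coherence, by = "node")
  first_by_rank <- candidates |>
    dplyr::arrange(.data$mention_index, .data$rank) |>
    dplyr::distinct(.data$mention_index, .keep_all = TRUE)

  picks <- nodes |>
    dplyr::group_by(.data$mention_index) |>
    dplyr::group_modify(function(d, key) {
      if (any(d$fixed)) {
        return(tibble::tibble(concept_id = d$concept_id[d$fixed][[1]]))
      }
      if (max(d$score) > 0) {
        o <- ord(-d$score, -d$lexical_score, d$concept_id)
        return(tibble::tibble(concept_id = d$concept_id[o[[1]]]))
      }
      fallback <- first_by_rank$concept_id[
        match(key$mention_index, first_by_rank$mention_index)
      ]
      tibble::tibble(concept_id = fallback)
    }) |>
    dplyr::ungroup()
  picks[, c("mention_index", "concept_id")]
}

#' Run a full entity-linking model over a corpus
#'
#' The four model variants differ in how the disambiguation graph is built
#' and whether graph coherence is used at all:
#'
#' * `"string_matching"`: baseline; every mention takes its top lexical
#'   candidate, no graph.
#' * `"ppr_ic"`: IC-weighted PPR coherence over a graph whose edges come from
#'   the ontology structure only (`link_mode = "kb"`).
#' * `"reel_corpus"`: same scoring, edges only from text-derived relations
#'   (`link_mode = "corpus"`).
#' * `"reel_kb_corpus"`: union of both edge sources
#'   (`link_mode = "kb_corpus"`).
#'
#' @param documents Document tibble ([read_pubtator()] layout).
#' @param kb A [new_knowledge_base()] object.
#' @param relations A [relation_set()]; required substance only for the
#'   corpus-informed modes (may be `NULL`/empty).
#' @param ic IC table, or `NULL` for unit weights.
#' @param model One of `"string_matching"`, `"ppr_ic"`, `"reel_corpus"`,
#'   `"reel_kb_corpus"`.
#' @param config A [ppr_config()]; per-document seeds are derived from
#'   `config$seed` so corpora of any size stay reproducible.
#' @param k Candidate-list depth passed to [generate_candidate_table()].
#' @param engine PPR engine, `"exact"` (default) or `"monte_carlo"`.
#' @param candidates Optional precomputed [generate_candidate_table()]
#'   output, to avoid re-scoring when several models run on one corpus.
#' @return A tibble with one row per mention: `doc_id`, `mention_index`,
#'   `surface`, `entity_type`, `gold_id`, `predicted_id` (`NA` = NIL),
#'   `model`.
#' @export
run_model <- function(documents, kb, relations = NULL, ic = NULL,
                      model = c(
                        "string_matching", "ppr_ic",
                        "reel_corpus", "reel_kb_corpus"
                      ),
                      config = ppr_config(), k = 10,
                      engine = c("exact", "monte_carlo"),
                      candidates = NULL) {
  model <- rlang::arg_match(model)
  engine <- rlang::arg_match(engine)
  cands <- candidates %||% generate_candidate_table(documents, kb, k = k)

  mentions <- tidyr::unnest(documents[, c("doc_id", "mentions")], "mentions")

  if (model == "string_matching") {
    pred <- cands |>
      dplyr::filter(.data$rank == 1L) |>
      dplyr::select("doc_id", "mention_index", predicted_id = "concept_id")
  } else {
    mode <- switch(model,
      ppr_ic = "kb",
      reel_corpus = "corpus",
      reel_kb_corpus = "kb_corpus"
    )
    doc_ids <- documents$doc_id
    per_doc <- lapply(seq_along(doc_ids), function(i) {
      dc <- cands[cands$doc_id == doc_ids[[i]], ]
      if (nrow(dc) == 0) return(NULL)
      g <- build_graph(dc, kb, relations, link_mode = mode)
      cfg <- config
      cfg$seed <- as.integer((config$seed + i * 7919L) %% .Machine$integer.max)
      P <- ppr_matrix(g, cfg, engine = engine)
      coh <- coherence_scores(g, P, ic = ic)
      asg <- disambiguate_document(g, coh, dc)
      asg$doc_id <- doc_ids[[i]]
      asg
    })
    pred <- dplyr::bind_rows(per_doc)
    if (nrow(pred) == 0) {
      pred <- tibble::tibble(
        doc_id = character(), mention_index = integer(),
        predicted_id = character()
      )
    } else {
      pred <- dplyr::select(pred, "doc_id", "mention_index",
        predicted_id = "concept_id"
      )
    }
  }

  mentions |>
    dplyr::left_join(pred, by = c("doc_id", "mention_index")) |>
    dplyr::select(
      "doc_id", "mention_index", "surface", "entity_type",
      "gold_id", "predicted_id"
    ) |>
    dplyr::mutate(model = model)
}
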