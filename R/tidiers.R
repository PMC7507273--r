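#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a knowledge base into its concept table
#'
#' @param x A [new_knowledge_base()] object.
#' @param ... Unused.
#' @return The concept tibble with synonym and alternative-id counts.
#' @export
tidy.knowledge_base <- function(x, ...) {
  dplyr::mutate(
    x$concepts,
    n_synonyms = lengths(.data$synonyms),
    n_alt_ids = lengths(.data$alt_ids)
  )
}

#' One-row summary of a knowledge base
#'
#' @param x A [new_knowledge_base()] object.
#' @param ... Unused.
#' @return A one-row tibble: concept, relation and name-index counts.
#' @export
glance.knowledge_base <- function(x, ...) {
  tibble::tibble(
    n_concepts = nrow(x$concepts),
    n_obsolete = sum(x$concepts$obsolete),
    n_relations = nrow(x$relations),
    n_names = nrow(x$names)
  )
}

#' Tidy a disambiguation graph into an edge table
#'
#' @param x A [build_graph()] object.
#' @param ... Unused.
#' @return A tibble with one row per edge, annotated with both endpoints'
#'   mention index and concept.
#' @export
tidy.disambiguation_graph <- function(x, ...) {
  e <- x$edges
  tibble::tibble(
    doc_id = x$doc_id,
    link_mode = x$link_mode,
    from = e$from, to = e$to,
    from_mention = x$nodes$mention_index[e$from],
    from_concept = x$nodes$concept_id[e$from],
    to_mention = x$nodes$mention_index[e$to],
    to_concept = x$nodes$concept_id[e$to]
  )
}

#' One-row summary of a disambiguation graph
#'
#' @param x A [build_graph()] object.
#' @param ... Unused.
#' @return A one-row tibble: node/edge/mention counts and link mode.
#' @export
glance.disambiguation_graph <- function(x, ...) {
  tibble::tibble(
    doc_id = x$doc_id,
    link_mode = x$link_mode,
    n_mentions = length(unique(x$nodes$mention_index)),
    n_nodes = nrow(x$nodes),
    n_fixed = sum(x$nodes$fixed),
    n_edges = nrow(x$edges)
  )
}

#' Plot a disambiguation graph
#'
#' Lays the mention/candidate nodes out on a mention-by-candidate grid and
#' draws the link-mode edges; fixed (exact-match) nodes are highlighted.
#'
#' @param object A [build_graph()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disambiguation_graph <- function(object, ...) {
  nodes <- object$nodes |>
    dplyr::group_by(.data$mention_index) |>
    dplyr::mutate(slot = dplyr::row_number()) |>
    dplyr::ungroup()
  edges <- object$edges
  seg <- tibble::tibble(
    x = nodes$mention_index[edges$from], y = nodes$slot[edges$from],
    xend = nodes$mention_index[edges$to], yend = nodes$slot[edges$to]
  )
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$mention_index, y = .data$slot)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      inherit.aes = FALSE, colour = "grey55"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$fixed), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$concept_id),
      vjust = -1, size = 2.8
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(
      x = "mention", y = "candidate slot",
      title = paste0(
        "Disambiguation graph (", object$link_mode, "), doc ", object$doc_id
      ),
      shape = "exact match"
    ) +
    ggplot2::theme_minimal()
}

#' Plot micro-averaged metrics per model
#'
#' @param object An [evaluate_linking()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of precision, recall and F1 per model.
#' @export
autoplot.nel_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("model", "precision", "recall", "f1")],
    c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "score (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.nel_metrics <- function(x, ...) {
  cat("Micro-averaged entity-linking metrics (per unique surface form):\n")
  df <- tibble::as_tibble(x)
  df$precision <- round(df$precision, 1)
  df$recall <- round(df$recall, 1)
  df$f1 <- round(df$f1, 1)
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}
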