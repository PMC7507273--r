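#' Collapse repeated surface forms into unique evaluation units
#'
#' Within one document, repeated instances of a mention with the same
#' case-folded surface form count as a single unit; distinct surfaces stay
#' distinct, and a composite mention annotated with two gold identifiers
#' yields two units (one per gold id).
#'
#' @param mentions A mention tibble (columns `surface`, `gold_id`, and
#'   optionally `mention_index`), or one row of a document tibble.
#' @return A tibble with columns `surface`, `gold_id`, `mention_index` (the
#'   first instance), one row per unique unit.
#' @export
dedup_unique_mentions <- function(mentions) {
  if ("mentions" %in% names(mentions)) {
    mentions <- tidyr::unnest(mentions[, "mentions", drop = FALSE], "mentions")
  }
  if (!"mention_index" %in% names(mentions)) {
    mentions$mention_index <- seq_len(nrow(mentions))
  }
  mentions |>
    dplyr::filter(!is.na(.data$gold_id)) |>
    dplyr::mutate(.folded = fold_string(.data$surface)) |>
    dplyr::arrange(.data$mention_index) |>
    dplyr::distinct(.data$.folded, .data$gold_id, .keep_all = TRUE) |>
    dplyr::select("surface", "gold_id", "mention_index")
}

#' Micro-averaged precision, recall and F1 for a linking run
#'
#' Counts are taken over unique evaluation units (see
#' [dedup_unique_mentions()]), pooled across all documents: a unit whose
#' predicted identifier equals the gold identifier is a true positive, a
#' differing prediction is a false positive, and an unlinked unit (NIL) is a
#' false negative. Then, on a 0-100 scale,
#' `precision = 100 tp / (tp + fp)`, `recall = 100 tp / (tp + fn)` and
#' `f1 = 2 P R / (P + R)` (0 where a denominator vanishes).
#'
#' @param predictions A [run_model()] result (may stack several models; one
#'   metric row is returned per model).
#' @param documents The gold document tibble the predictions refer to.
#' @return A tibble of class `nel_metrics` with columns `model`, `tp`, `fp`,
#'   `fn`, `n_units`, `precision`, `recall`, `f1`.
#' @export
evaluate_linking <- function(predictions, documents) {
  stray <- setdiff(unique(predictions$doc_id), documents$doc_id)
  if (length(stray) > 0) {
    rlang::abort(paste0(
      "predictions refer to unknown document(s): ", paste(stray, collapse = ", ")
    ))
  }
  units <- documents[, c("doc_id", "mentions")] |>
    dplyr::mutate(mentions = purrr::map(.data$mentions, dedup_unique_mentions)) |>
    tidyr::unnest("mentions")

  if (!"model" %in% names(predictions)) predictions$model <- "model"
  preds <- predictions |>
    dplyr::distinct(.data$model, .data$doc_id, .data$mention_index, .data$gold_id,
      .keep_all = TRUE
    ) |>
    dplyr::select("model", "doc_id", "mention_index", "gold_id", "predicted_id")
  out <- tidyr::crossing(model = unique(preds$model), units) |>
    dplyr::left_join(
      preds,
      by = c("model", "doc_id", "mention_index", "gold_id")
    ) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      tp = sum(!is.na(.data$predicted_id) & .data$predicted_id == .data$gold_id),
      fp = sum(!is.na(.data$predicted_id) & .data$predicted_id != .data$gold_id),
      fn = sum(is.na(.data$predicted_id)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_units = .data$tp + .data$fp + .data$fn,
      precision = ifelse(.data$tp + .data$fp > 0, 100 * .data$tp / (.data$tp + .data$fp), 0),
      recall = ifelse(.data$tp + .data$fn > 0, 100 * .data$tp / (.data$tp + .data$fn), 0),
      f1 = ifelse(.data$precision + .data$recall > 0,
        2 * .data$precision * .data$recall / (.data$precision + .data$recall), 0
      )
    )
  class(out) <- c("nel_metrics", class(out))
  out
}
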