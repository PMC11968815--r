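# Scoring predictions against a reference annotation, and ranking tool
# combinations. A deliberately minimal perfect/partial/missed/spurious
# scheme matched on the (strand, stop) terminus -- the quantity the
# consensus merge keys on -- sufficient to rank tools and combinations.

.stop_key <- function(x) {
  stop_pos <- ifelse(x$strand == "+", x$end, x$start)
  paste(x$contig_id, x$strand, stop_pos)
}

.coord_key <- function(x) {
  paste(x$contig_id, x$strand, x$start, x$end)
}

#' Score predictions against a reference annotation
#'
#' Reference genes are classified: perfect (a prediction matches strand,
#' stop and start exactly), partial (a prediction shares the stop but not
#' the start), missed (no prediction shares the stop). Predictions whose
#' stop matches no reference gene are spurious. perfect + partial +
#' missed = n_reference, and every prediction is classified exactly once.
#'
#' @param predictions data.frame: contig_id, start, end, strand.
#' @param reference data.frame of reference genes (same columns).
#' @return Object of class \code{evaluation_report}: list with
#'   n_reference, n_predicted, perfect, partial, missed, spurious.
#' @export
evaluate_predictions <- function(predictions, reference) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("reference annotation is empty")
  }
  if (is.null(predictions)) predictions <- .empty_predictions()
  ref_stop <- .stop_key(reference)
  ref_coord <- .coord_key(reference)
  if (nrow(predictions) > 0L) {
    pred_stop <- .stop_key(predictions)
    pred_coord <- .coord_key(predictions)
  } else {
    pred_stop <- pred_coord <- character()
  }
  perfect <- sum(ref_coord %in% pred_coord)
  stop_hit <- ref_stop %in% pred_stop
  partial <- sum(stop_hit & !(ref_coord %in% pred_coord))
  missed <- sum(!stop_hit)
  spurious <- sum(!(pred_stop %in% ref_stop))
  structure(list(n_reference = nrow(reference),
                 n_predicted = nrow(predictions),
                 perfect = perfect, partial = partial, missed = missed,
                 spurious = spurious),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation: %d reference genes, %d predictions\n  perfect %d | partial %d | missed %d | spurious %d\n",
    x$n_reference, x$n_predicted, x$perfect, x$partial, x$missed,
    x$spurious))
  invisible(x)
}

#' Evaluate all k-tool combinations after consensus merging
#'
#' For every k-subset of tools, the pooled predictions are consensus
#' merged per contig and scored against the reference; combinations are
#' ranked by perfect matches, then partial matches, then fewest spurious
#' predictions.
#'
#' @param per_tool_predictions Named list: tool -> prediction data.frame.
#' @param reference Reference annotation data.frame.
#' @param contigs Named character vector of contig sequences (needed by
#'   the merge for edge filtering and translation).
#' @param table_id Genetic code used for translation during merging.
#' @param k Combination size (1, 2 or 3).
#' @param min_len_nt Minimum gene length passed to the merge.
#' @return data.frame, one row per combination, ranked best first:
#'   combination, n_predicted, perfect, partial, missed, spurious.
#' @export
evaluate_combinations <- function(per_tool_predictions, reference, contigs,
                                  table_id, k = 3L, min_len_nt = 21L) {
  tools <- names(per_tool_predictions)
  if (length(tools) < k) stop("k exceeds the number of tools")
  combos <- utils::combn(tools, k, simplify = FALSE)
  rows <- lapply(combos, function(cmb) {
    preds <- do.call(rbind, per_tool_predictions[cmb])
    merged <- list()
    for (cid in names(contigs)) {
      p <- preds[preds$contig_id == cid, , drop = FALSE]
      if (nrow(p) == 0L) next
      m <- suppressWarnings(
        merge_predictions(contigs[[cid]], p, table_id,
                          min_len_nt = min_len_nt))
      if (nrow(m) > 0L) merged[[length(merged) + 1L]] <- m
    }
    merged <- if (length(merged) > 0L) do.call(rbind, merged) else
      .empty_predictions()
    rep <- evaluate_predictions(merged, reference)
    data.frame(combination = paste(sort(cmb), collapse = "+"),
               n_predicted = rep$n_predicted, perfect = rep$perfect,
               partial = rep$partial, missed = rep$missed,
               spurious = rep$spurious, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$perfect, -out$partial, out$spurious,
                   out$combination), ]
  rownames(out) <- NULL
  out
}
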