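#' Precision and recall of a classification run
#'
#' A prediction is correct iff the predicted taxid equals the truth taxid
#' projected to the evaluation rank.  Precision is correct assignments
#' over attempted assignments (`n_correct / n_classified`, 0 when nothing
#' was classified); recall is correct assignments over all queries
#' (`n_correct / n_queries`), so unclassified queries lower recall but not
#' precision.
#'
#' @param results Data.frame from [classify_set()].
#' @param truth Named integer vector mapping every query accession to its
#'   true taxid (at any rank at or below `rank`).
#' @param tree A [load_taxonomy()] tree.
#' @param rank Evaluation rank.
#' @return An object of class `eval_report` with fields `rank`,
#'   `n_queries`, `n_classified`, `n_correct`, `precision`, `recall`.
#' @export
evaluate_results <- function(results, truth, tree, rank) {
  missing_q <- setdiff(results$query_accession, names(truth))
  if (length(missing_q))
    stop("query accession(s) missing from truth: ",
         paste(utils::head(missing_q, 10), collapse = ", "))
  n_queries <- nrow(results)
  classified <- results$status == "classified"
  truth_taxa <- truth[results$query_accession]
  utax <- unique(truth_taxa)
  proj <- setNames(taxa_at_rank(tree, utax, rank), as.character(utax))
  truth_at_rank <- proj[as.character(truth_taxa)]
  correct <- classified & !is.na(truth_at_rank) &
    results$predicted_taxid == truth_at_rank
  correct[is.na(correct)] <- FALSE
  n_classified <- sum(classified)
  n_correct <- sum(correct)
  structure(list(rank = rank,
                 n_queries = n_queries,
                 n_classified = n_classified,
                 n_correct = n_correct,
                 precision = if (n_classified > 0)
                   n_correct / n_classified else 0,
                 recall = if (n_queries > 0) n_correct / n_queries else 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> rank %s: %d queries, %d classified, ",
                     "%d correct\n  precision %.3f  recall %.3f\n"),
              x$rank, x$n_queries, x$n_classified, x$n_correct,
              x$precision, x$recall))
  invisible(x)
}
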