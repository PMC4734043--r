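# ---- measure kernels -------------------------------------------------------
# Each kernel computes one measure's raw values for one query against a set
# of references.  The leave-one-out machinery reuses exactly these kernels,
# so cross-validated and deployed classifications are bit-identical.

raw_euclidean_vec <- function(qv, P) {
  sqrt(rowSums(sweep(P, 2, qv, "-")^2))
}

raw_jsd_vec <- function(qv, P) {
  jsd_to_rows(qv, P)
}

raw_alignment_vec <- function(qseq, db, refs) {
  out <- setNames(numeric(length(refs)), refs)
  w <- db$align$word_size
  if (nchar(qseq) < w) return(out)
  qcodes <- unique(word_codes_cpp(qseq, w)$code)
  if (!length(qcodes)) return(out)
  qrc <- revcomp(qseq)
  for (r in refs) {
    if (!any(qcodes %in% db$seed_index[[r]]$codes)) next
    rs <- db$sequences$sequence[match(r, db$sequences$accession)]
    raw <- max(align_raw(qseq, rs, db$align), align_raw(qrc, rs, db$align))
    if (raw > 0) out[[r]] <- bit_from_raw(raw, db$align)
  }
  out
}

raw_ncd_vec <- function(qseq, db, refs, cq = NULL) {
  if (is.null(cq)) cq <- compressed_size(qseq, db$compressor)
  vapply(refs, function(r) {
    rs <- db$sequences$sequence[match(r, db$sequences$accession)]
    ncd(qseq, rs, db$compressor, cx = cq, cy = db$comp_sizes[[r]])
  }, numeric(1))
}

# Raw vectors for the selected measures of one query.
query_raw_vectors <- function(qseq, db, refs, measures, k) {
  raws <- list()
  if (any(measures %in% K_DEPENDENT)) {
    qv <- profile_vector(qseq, k)  # errors if query shorter than k
    P <- db_profile_matrix(db, k)[refs, , drop = FALSE]
    if ("euclidean" %in% measures)
      raws$euclidean <- setNames(raw_euclidean_vec(qv, P), refs)
    if ("jsd" %in% measures)
      raws$jsd <- setNames(raw_jsd_vec(qv, P), refs)
  }
  if ("alignment" %in% measures)
    raws$alignment <- raw_alignment_vec(qseq, db, refs)
  if ("compression" %in% measures)
    raws$compression <- raw_ncd_vec(qseq, db, refs)
  raws[intersect(measures, names(raws))]
}

# ---- eligibility and assignment -------------------------------------------

# References whose lineage contains the requested rank, with their
# rank-projected taxon.
eligible_refs <- function(db, rank) {
  taxa <- db$taxmap[db$sequences$accession]
  utax <- unique(taxa)
  proj <- setNames(taxa_at_rank(db$tree, utax, rank), as.character(utax))
  ref_taxon <- proj[as.character(taxa)]
  keep <- !is.na(ref_taxon)
  if (!any(keep))
    stop("rank '", rank, "' absent from every reference lineage")
  excluded <- db$sequences$accession[!keep]
  out <- data.frame(accession = db$sequences$accession[keep],
                    taxon = as.integer(ref_taxon[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

# Normalize, combine and pick the nearest reference.  Ties at equal CSSS
# resolve to the majority rank-projected taxon among tied references, then
# to the smallest taxid; the reported reference is the first tied one (in
# reference order) carrying the winning taxon.
classify_core <- function(raws, orientations, ref_taxon, min_score = NULL) {
  norms <- lapply(names(raws), function(m)
    normalize_similarity(raws[[m]], orientations[[m]]))
  names(norms) <- names(raws)
  degenerate <- vapply(norms, attr, TRUE, "degenerate")
  if (all(degenerate))
    return(list(status = "unclassified",
                reason = "no measure distinguishes any reference"))
  comb <- combine_scores(norms)
  best <- max(comb)
  if (!is.null(min_score) && best < min_score)
    return(list(status = "unclassified",
                reason = sprintf("best CSSS %.4f below min score", best)))
  tied <- names(comb)[comb == best]
  taxa <- ref_taxon[tied]
  tab <- table(taxa)
  winners <- as.integer(names(tab)[tab == max(tab)])
  taxon <- min(winners)
  ref <- tied[taxa == taxon][1]
  list(status = "classified", taxon = taxon, ref = ref,
       csss = unname(comb[ref]),
       per_measure = vapply(norms, function(v) unname(v[ref]), numeric(1)))
}

result_row <- function(acc, rank, res, tree = NULL, reason = NA_character_) {
  sims <- setNames(rep(NA_real_, length(MEASURES)), MEASURES)
  if (identical(res$status, "classified")) {
    sims[names(res$per_measure)] <- res$per_measure
    data.frame(query_accession = acc, rank = rank,
               predicted_taxid = res$taxon,
               predicted_name = if (is.null(tree)) NA_character_ else
                 unname(tree$name[as.character(res$taxon)]),
               best_reference = res$ref, csss = res$csss,
               status = "classified", reason = NA_character_,
               sim_alignment = sims[["alignment"]],
               sim_euclidean = sims[["euclidean"]],
               sim_jsd = sims[["jsd"]],
               sim_compression = sims[["compression"]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(query_accession = acc, rank = rank,
               predicted_taxid = NA_integer_,
               predicted_name = NA_character_,
               best_reference = NA_character_, csss = NA_real_,
               status = "unclassified",
               reason = if (is.na(reason)) res$reason else reason,
               sim_alignment = NA_real_, sim_euclidean = NA_real_,
               sim_jsd = NA_real_, sim_compression = NA_real_,
               stringsAsFactors = FALSE)
  }
}

as_query <- function(query) {
  if (inherits(query, "seq_set")) {
    stopifnot(length(query) == 1)
    return(list(accession = query$accession, sequence = query$sequence))
  }
  if (is.character(query) && length(query) == 1 && !is.null(names(query)))
    return(list(accession = names(query), sequence = unname(query)))
  if (is.list(query) && !is.null(query$accession) && !is.null(query$sequence))
    return(query[c("accession", "sequence")])
  stop("query must be a 1-record seq_set, a named character scalar, ",
       "or a list(accession=, sequence=)")
}

#' Classify one query sequence by nearest neighbour on the CSSS
#'
#' Computes every selected measure between the query and each eligible
#' reference (references whose lineage contains the requested rank),
#' min-max normalizes each measure across the reference set, averages the
#' normalized similarities into the combined sequence similarity score,
#' and assigns the rank-projected taxon of the best-scoring reference.
#' The query is reported unclassified when every selected measure is
#' degenerate (no measure distinguishes any reference), when its best CSSS
#' falls below `min_score`, or when it is shorter than `k`.
#'
#' @param query A 1-record [seq_set()], a named character scalar, or a
#'   `list(accession=, sequence=)`.
#' @param db A [build_db()] reference database.
#' @param rank Target rank (one of species, genus, family, order, class,
#'   phylum).
#' @param measures Character subset of
#'   `c("alignment", "euclidean", "jsd", "compression")`.
#' @param k k-mer size; must belong to the database `k_grid`.
#' @param exclude Accessions to drop from the reference pool (used by the
#'   leave-one-out machinery).
#' @param min_score Optional CSSS floor below which the query is reported
#'   unclassified.
#' @return A one-row data.frame with the predicted taxid and name, the
#'   best reference, the CSSS, a status, and the normalized similarity of
#'   each selected measure at the winning reference.
#' @export
classify_query <- function(query, db, rank, measures = MEASURES,
                           k = db$k_grid[1], exclude = character(0),
                           min_score = NULL) {
  stopifnot(inherits(db, "reference_db"))
  q <- as_query(query)
  measures <- resolve_measures(measures)
  if (!k %in% db$k_grid)
    stop("k=", k, " not in database k_grid {",
         paste(db$k_grid, collapse = ","), "}")
  elig <- eligible_refs(db, rank)
  keep <- !elig$accession %in% c(exclude)
  elig <- elig[keep, , drop = FALSE]
  if (!nrow(elig)) stop("no eligible references after exclusion")
  ref_taxon <- setNames(elig$taxon, elig$accession)

  if (any(measures %in% K_DEPENDENT) && nchar(q$sequence) < k)
    return(result_row(q$accession, rank, list(status = "unclassified"),
                      reason = sprintf("query shorter than k=%d", k)))
  raws <- query_raw_vectors(q$sequence, db, elig$accession, measures, k)
  orientations <- setNames(lapply(names(raws), measure_orientation),
                           names(raws))
  res <- classify_core(raws, orientations, ref_taxon, min_score)
  result_row(q$accession, rank, res, db$tree)
}

resolve_measures <- function(measures) {
  if (identical(measures, "all")) return(MEASURES)
  measures <- unique(as.character(measures))
  bad <- setdiff(measures, MEASURES)
  if (length(bad))
    stop("unknown measure(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(MEASURES, collapse = ", "))
  if (!length(measures)) stop("no measures selected")
  measures
}

#' Classify a set of queries
#'
#' Applies [classify_query()] to every record; queries are independent, so
#' results are identical for any thread count and are returned in input
#' order.  Per-query errors become unclassified rows with a reason; the
#' batch never aborts.  When `measures` or `k` is `NULL`, tuned parameters
#' stored in the database (see [tune()]) are used.
#'
#' @param queries A [seq_set()].
#' @param db A [build_db()] reference database.
#' @param rank Target rank.
#' @param measures Measure subset, or `NULL` to use tuned parameters.
#' @param k k-mer size, or `NULL` to use tuned parameters.
#' @param threads Number of worker processes (forked; 1 = serial).
#' @param min_score Optional CSSS floor.
#' @return A data.frame with one row per query, in input order.
#' @export
classify_set <- function(queries, db, rank, measures = NULL, k = NULL,
                         threads = 1, min_score = NULL) {
  stopifnot(inherits(queries, "seq_set"))
  if (is.null(measures) || is.null(k)) {
    if (is.null(db$params))
      stop("measures/k not given and the database has no tuned parameters; ",
           "run tune() first")
    if (is.null(measures)) measures <- db$params$selected_measures
    if (is.null(k)) k <- db$params$k_opt
  }
  measures <- resolve_measures(measures)
  if (length(queries) == 0) {
    return(result_row("x", rank, list(status = "unclassified"),
                      reason = "")[0, ])
  }
  one <- function(i) {
    tryCatch(
      classify_query(list(accession = queries$accession[i],
                          sequence = queries$sequence[i]),
                     db, rank, measures, k, min_score = min_score),
      error = function(e)
        result_row(queries$accession[i], rank,
                   list(status = "unclassified"),
                   reason = conditionMessage(e)))
  }
  idx <- seq_len(length(queries))
  rows <- if (threads > 1) {
    parallel::mclapply(idx, one, mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(idx, one)
  }
  do.call(rbind, rows)
}
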