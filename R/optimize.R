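# ---- pairwise raw-score matrices ------------------------------------------
# Full query-by-reference matrices over the training set, built from the
# same kernels classification uses, and cached so the optimizer never
# recomputes a measure while scanning k values or measure subsets.

measure_matrix <- function(db, measure, k, cache = new.env()) {
  key <- if (measure %in% K_DEPENDENT) paste0(measure, "_k", k) else measure
  if (!is.null(cache[[key]])) return(cache[[key]])
  acc <- db$sequences$accession
  m <- switch(measure,
    euclidean = {
      P <- db_profile_matrix(db, k)[acc, , drop = FALSE]
      t(vapply(acc, function(a) raw_euclidean_vec(P[a, ], P),
               numeric(length(acc))))
    },
    jsd = {
      P <- db_profile_matrix(db, k)[acc, , drop = FALSE]
      t(vapply(acc, function(a) raw_jsd_vec(P[a, ], P),
               numeric(length(acc))))
    },
    alignment = {
      t(vapply(acc, function(a)
        raw_alignment_vec(db$sequences$sequence[match(a, acc)], db, acc),
        numeric(length(acc))))
    },
    compression = {
      t(vapply(acc, function(a)
        raw_ncd_vec(db$sequences$sequence[match(a, acc)], db, acc,
                    cq = db$comp_sizes[[a]]),
        numeric(length(acc))))
    },
    stop("unknown measure: ", measure))
  dimnames(m) <- list(acc, acc)
  cache[[key]] <- m
  m
}

# Stratified subsample of query accessions, one stratum per label.
stratified_sample <- function(acc, labels, cap, seed) {
  if (length(acc) <= cap) return(acc)
  with_seed(seed, {
    split_acc <- split(acc, labels)
    per <- ceiling(cap * lengths(split_acc) / length(acc))
    out <- unlist(mapply(function(a, n) sample(a, min(n, length(a))),
                         split_acc, per, SIMPLIFY = FALSE))
    acc[acc %in% out]
  })
}

# Leave-one-out engine shared by all optimizer operations.  `measures` are
# built-in measure names; `extra_measures` is an optional named list of
# raw query-by-reference matrices (with an `orientation` attribute) that
# take part exactly like built-in measures.
loocv_engine <- function(db, rank, measures, k, cap = 500, seed = 1234,
                         cache = new.env(), extra_measures = NULL) {
  elig <- eligible_refs(db, rank)
  if (nrow(elig) < 2) stop("degenerate training set: fewer than 2 eligible sequences")
  if (length(unique(elig$taxon)) < 2)
    stop("degenerate training set: fewer than 2 distinct labels at rank ", rank)
  ref_taxon <- setNames(elig$taxon, elig$accession)

  mats <- lapply(measures, measure_matrix, db = db, k = k, cache = cache)
  names(mats) <- measures
  orientations <- setNames(lapply(measures, measure_orientation), measures)
  for (m in names(extra_measures)) {
    mats[[m]] <- extra_measures[[m]]
    ori <- attr(extra_measures[[m]], "orientation")
    orientations[[m]] <- if (is.null(ori)) "similarity" else ori
  }

  queries <- stratified_sample(elig$accession, elig$taxon, cap, seed)
  correct <- vapply(queries, function(q) {
    refs <- setdiff(elig$accession, q)
    raws <- lapply(mats, function(M) M[q, refs])
    res <- classify_core(raws, orientations, ref_taxon)
    identical(res$status, "classified") && res$taxon == ref_taxon[[q]]
  }, logical(1))
  mean(correct)
}

#' Leave-one-out cross-validated accuracy on the training set
#'
#' Each eligible training sequence is classified against the database with
#' itself removed from the reference pool; accuracy is the fraction whose
#' predicted rank-level taxon equals their true rank-level taxon, with
#' unclassified sequences counting as incorrect.  Training sets larger
#' than `cap` are subsampled on the query side (stratified by label,
#' seeded); the reference pool always remains the full eligible set minus
#' the left-out sequence.
#'
#' @param db A [build_db()] reference database (>= 2 eligible sequences
#'   and >= 2 distinct labels at `rank` required).
#' @param rank Target rank.
#' @param measures Measure subset (see [classify_query()]).
#' @param k k-mer size from the database grid.
#' @param cap Maximum number of left-out queries (default 500).
#' @param seed Seed for the subsample draw (the only randomness).
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(db, rank, measures = MEASURES, k = db$k_grid[1],
                           cap = 500, seed = 1234) {
  measures <- resolve_measures(measures)
  if (!k %in% db$k_grid)
    stop("k=", k, " not in database k_grid {",
         paste(db$k_grid, collapse = ","), "}")
  loocv_engine(db, rank, measures, k, cap, seed)
}

#' Select the k-mer size by leave-one-out accuracy
#'
#' Scans the database k-grid and returns the k maximizing joint LOOCV
#' accuracy of the permitted measures; ties resolve to the smallest k.
#' When no permitted measure depends on k the smallest grid k is returned
#' by convention.
#'
#' @inheritParams loocv_accuracy
#' @param cache Internal matrix cache (shared by [tune()]).
#' @return The selected k, with attribute `accuracy` holding the per-k
#'   accuracies.
#' @export
select_k <- function(db, rank, measures = MEASURES, cap = 500, seed = 1234,
                     cache = new.env()) {
  measures <- resolve_measures(measures)
  grid <- sort(db$k_grid)
  if (!any(measures %in% K_DEPENDENT)) {
    return(structure(grid[1], accuracy = NULL))
  }
  accs <- vapply(grid, function(k)
    loocv_engine(db, rank, measures, k, cap, seed, cache), numeric(1))
  structure(grid[which.max(accs)], accuracy = setNames(accs, grid))
}

#' Drop measures with low predictive power
#'
#' Computes the standalone LOOCV accuracy of every candidate measure and
#' drops any whose accuracy is no better than the majority-class baseline
#' (the frequency of the most common rank-level label).  If every
#' candidate would be dropped, the single best one is kept.
#'
#' @inheritParams select_k
#' @param candidates Non-empty character vector of built-in measure names.
#' @param extra_measures Optional named list of raw query-by-reference
#'   matrices (rows and columns named by training accession, with an
#'   `orientation` attribute of `"similarity"` or `"distance"`) screened
#'   alongside the built-in candidates.
#' @return Character vector of surviving measures with attributes
#'   `accuracy` (per-candidate standalone accuracy) and `baseline`.
#' @export
eliminate_measures <- function(db, rank, candidates = MEASURES,
                               k = db$k_grid[1], extra_measures = NULL,
                               cap = 500, seed = 1234, cache = new.env()) {
  builtin <- resolve_measures(candidates)
  all_names <- c(builtin, names(extra_measures))
  accs <- vapply(all_names, function(m) {
    if (m %in% builtin)
      loocv_engine(db, rank, m, k, cap, seed, cache)
    else
      loocv_engine(db, rank, character(0), k, cap, seed, cache,
                   extra_measures = extra_measures[m])
  }, numeric(1))
  elig <- eligible_refs(db, rank)
  baseline <- max(table(elig$taxon)) / nrow(elig)
  kept <- all_names[accs > baseline]
  if (!length(kept)) kept <- all_names[which.max(accs)]
  structure(kept, accuracy = accs, baseline = unname(baseline))
}

#' Tune the classifier on the training set
#'
#' The optimization pipeline: (1) select the k-mer size over the permitted
#' measures with [select_k()]; (2) drop low-predictive-power measures at
#' that k with [eliminate_measures()]; (3) estimate the expected overall
#' accuracy of the surviving set with [loocv_accuracy()].  The result is
#' stored in the database (and persisted to its manifest when the database
#' lives on disk) so that [classify_set()] can pick it up.
#'
#' @inheritParams loocv_accuracy
#' @param measures Measures the user permits, or `"all"` (the default).
#' @return The database with its `params` field set to the tuned
#'   parameters (`k_opt`, `selected_measures`, `loocv_accuracy`,
#'   `per_measure_accuracy`, `rank`).
#' @export
tune <- function(db, rank = "genus", measures = "all", cap = 500,
                 seed = 1234) {
  stopifnot(inherits(db, "reference_db"))
  measures <- resolve_measures(measures)
  cache <- new.env()
  k_opt <- select_k(db, rank, measures, cap, seed, cache)
  kept <- eliminate_measures(db, rank, measures, k = as.integer(k_opt),
                             cap = cap, seed = seed, cache = cache)
  per_acc <- attr(kept, "accuracy")
  dropped <- setdiff(measures, kept)
  for (m in dropped)
    message(sprintf("tune: dropping measure '%s' (standalone accuracy %.3f <= baseline %.3f)",
                    m, per_acc[[m]], attr(kept, "baseline")))
  final <- loocv_engine(db, rank, as.character(kept), as.integer(k_opt),
                        cap, seed, cache)
  db$params <- list(k_opt = as.integer(k_opt),
                    selected_measures = as.character(kept),
                    loocv_accuracy = final,
                    per_measure_accuracy = per_acc,
                    rank = rank, cap = cap, seed = seed)
  message(sprintf("tune: k=%d, measures {%s}, LOOCV accuracy %.3f",
                  db$params$k_opt,
                  paste(db$params$selected_measures, collapse = ","),
                  final))
  save_manifest(db)
  db
}
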