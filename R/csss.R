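#' Min-max normalization of a raw similarity vector
#'
#' Rescales the raw values of one measure across the reference set of a
#' single query to `[0, 1]` in similarity orientation (larger = more
#' similar).  Similarity-oriented measures (alignment bit scores) keep
#' their orientation, `(s - min) / (max - min)`; distance-oriented
#' measures are flipped, `(max - d) / (max - min)`.  When all raw values
#' are equal the measure carries no information for this query and every
#' normalized value is set to 0.
#'
#' @param raw Named numeric vector of raw values (one per reference).
#' @param orientation `"similarity"` or `"distance"`.
#' @return Named numeric vector in `[0, 1]` with attribute `degenerate`
#'   set to `TRUE` when `max == min`.
#' @export
normalize_similarity <- function(raw,
                                 orientation = c("similarity", "distance")) {
  orientation <- match.arg(orientation)
  if (!length(raw)) stop("empty similarity vector")
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) {
    out <- setNames(rep(0, length(raw)), names(raw))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- if (orientation == "similarity") (raw - lo) / (hi - lo)
         else (hi - raw) / (hi - lo)
  attr(out, "degenerate") <- FALSE
  out
}

measure_orientation <- function(measure) {
  if (measure == "alignment") "similarity" else "distance"
}

#' Combine normalized similarity vectors into the CSSS
#'
#' The combined sequence similarity score of a reference is the unweighted
#' arithmetic mean, over the selected measures, of its normalized
#' similarities.  All vectors must cover the same references.
#'
#' @param normalized Named list of normalized vectors (one per measure),
#'   as produced by [normalize_similarity()].
#' @param selected Non-empty character vector of measure names to average
#'   (must all be present in `normalized`).
#' @return Named numeric vector of CSSS values in `[0, 1]` with attribute
#'   `measures_used`.
#' @export
combine_scores <- function(normalized, selected = names(normalized)) {
  if (!length(selected)) stop("no measures selected")
  missing_m <- setdiff(selected, names(normalized))
  if (length(missing_m))
    stop("measure(s) not present: ", paste(missing_m, collapse = ", "))
  accs <- names(normalized[[selected[1]]])
  for (m in selected[-1]) {
    if (!identical(names(normalized[[m]]), accs))
      stop("accession sets differ between measures")
  }
  out <- Reduce(`+`, lapply(normalized[selected], as.numeric)) /
    length(selected)
  out <- setNames(out, accs)
  attr(out, "measures_used") <- selected
  out
}
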