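#' Canonical k-mers
#'
#' All length-`k` strings over `{A,C,G,T}` that are the lexicographic
#' minimum of themselves and their reverse complement, in sorted order.
#' This is the fixed coordinate system of every k-mer profile at size `k`.
#'
#' @param k k-mer size (1-10).
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmers <- function(k) {
  canon_table(k)$kmer
}

# Cached table of canonical k-mers and their 2-bit codes (A=0,C=1,G=2,T=3).
canon_table <- function(k) {
  stopifnot(k >= 1, k <= 10)
  key <- paste0("canon", k)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
  km <- sort(do.call(paste0, grid))
  chars <- lapply(seq_len(k), function(i) substring(km, i, i))
  rc <- do.call(paste0, lapply(rev(chars), function(v)
    chartr("ACGT", "TGCA", v)))
  keep <- km <= rc
  km <- km[keep]
  code <- integer(length(km))
  for (i in seq_len(k)) {
    code <- code * 4L + (match(substring(km, i, i), bases) - 1L)
  }
  res <- list(kmer = km, code = code)
  .pkg_cache[[key]] <- res
  res
}

# Relative-abundance vector over the full canonical k-mer space (unnamed,
# ordered as canonical_kmers(k)); shared kernel of the profile store and of
# per-query classification.
profile_vector <- function(sequence, k) {
  if (k < 1) stop("k must be >= 1")
  if (nchar(sequence) < k) stop("sequence shorter than k")
  res <- kmer_counts_cpp(sequence, as.integer(k))
  if (res$total == 0) stop("no informative k-mers")
  ct <- canon_table(k)
  res$counts[ct$code + 1L] / res$total
}

#' Canonical k-mer relative-abundance profile of a sequence
#'
#' Slides a window of size `k` along the sequence; windows containing `N`
#' are skipped; each counted window contributes one count to its canonical
#' form (the lexicographic minimum of the k-mer and its reverse
#' complement).  Abundances are counts divided by the number of counted
#' windows, so they sum to one.
#'
#' @param sequence A DNA sequence (character scalar).
#' @param k k-mer size (`nchar(sequence) >= k` required).
#' @return A named numeric vector of relative abundances over the observed
#'   canonical k-mers, of class `kmer_profile`, with attributes `k` and
#'   `total_counted`.
#' @examples
#' kmer_profile("ACGT", 2)  # AC: 2/3, CG: 1/3 (GT canonicalizes to AC)
#' @export
kmer_profile <- function(sequence, k) {
  if (inherits(sequence, "seq_set")) {
    stopifnot(length(sequence) == 1)
    sequence <- sequence$sequence
  }
  v <- profile_vector(sequence, k)
  res <- kmer_counts_cpp(sequence, as.integer(k))
  keep <- v > 0
  structure(setNames(v[keep], canonical_kmers(k)[keep]),
            k = as.integer(k), total_counted = as.integer(res$total),
            class = "kmer_profile")
}

# Expand a (possibly sparse, named) profile to the full canonical space.
full_profile <- function(p) {
  k <- attr(p, "k")
  ct <- canon_table(k)
  v <- numeric(length(ct$kmer))
  v[match(names(p), ct$kmer)] <- unclass(p)
  v
}

check_same_k <- function(p, q) {
  if (!identical(attr(p, "k"), attr(q, "k")))
    stop("profiles have different k (", attr(p, "k"), " vs ", attr(q, "k"), ")")
  attr(p, "k")
}

#' Euclidean distance between two k-mer profiles
#'
#' Square root of the sum of squared abundance differences over the union
#' of observed k-mers (absent k-mers count as zero).
#'
#' @param p,q [kmer_profile()] objects with the same `k`.
#' @return Non-negative numeric scalar (at most `sqrt(2)` for probability
#'   profiles).
#' @export
euclidean_distance <- function(p, q) {
  check_same_k(p, q)
  keys <- union(names(p), names(q))
  pv <- unclass(p)[keys]; pv[is.na(pv)] <- 0
  qv <- unclass(q)[keys]; qv[is.na(qv)] <- 0
  sqrt(sum((pv - qv)^2))
}

shannon_bits <- function(v) {
  v <- v[v > 0]
  -sum(v * log2(v))
}

#' Jensen-Shannon divergence between two k-mer profiles
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m` the pointwise average
#' and `H` the Shannon entropy in bits, so the value is bounded in
#' `[0, 1]`; `0 * log 0` is taken as 0.
#'
#' @param p,q [kmer_profile()] objects with the same `k`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
jsd <- function(p, q) {
  check_same_k(p, q)
  keys <- union(names(p), names(q))
  pv <- unclass(p)[keys]; pv[is.na(pv)] <- 0
  qv <- unclass(q)[keys]; qv[is.na(qv)] <- 0
  val <- shannon_bits((pv + qv) / 2) - (shannon_bits(pv) + shannon_bits(qv)) / 2
  min(max(val, 0), 1)
}

# JSD of one full-space profile against the rows of a full-space profile
# matrix; vectorized kernel used at classification time.
jsd_to_rows <- function(qv, P) {
  hq <- shannon_bits(qv)
  hrows <- apply(P, 1, shannon_bits)
  M <- sweep(P, 2, qv, "+") / 2
  hm <- apply(M, 1, shannon_bits)
  pmin(pmax(hm - (hrows + hq) / 2, 0), 1)
}

#' Compressor contracts
#'
#' A compressor contract is a deterministic function from a raw byte
#' string to its compressed size in bytes; the normalized compression
#' distance depends on the compressor only through these sizes.  The
#' default is the xz (LZMA) compressor of [memCompress()], compressing in
#' a single block so that sizes are comparable across sequence lengths.
#'
#' @param name One of `"xz"`, `"gzip"`, `"bzip2"`, or an arbitrary label
#'   when `compress_size` is supplied.
#' @param compress_size Optional function `raw bytes -> integer size`
#'   overriding the built-in backends.
#' @return An object of class `compressor_contract` with fields `name` and
#'   `compress_size`.
#' @export
make_compressor <- function(name = c("xz", "gzip", "bzip2"),
                            compress_size = NULL) {
  if (is.null(compress_size)) {
    name <- match.arg(name)
    type <- name
    compress_size <- function(bytes) length(memCompress(bytes, type = type))
  } else {
    name <- as.character(name)[1]
    stopifnot(is.function(compress_size))
  }
  structure(list(name = name, compress_size = compress_size),
            class = "compressor_contract")
}

#' @rdname make_compressor
#' @export
default_compressor <- function() make_compressor("xz")

compressed_size <- function(sequence, compressor) {
  as.integer(compressor$compress_size(charToRaw(sequence)))
}

#' Normalized compression distance between two sequences
#'
#' `NCD(x, y) = (C(xy) - min(C(x), C(y))) / max(C(x), C(y))` where `C` is
#' the compressed size in bytes and `xy` the concatenation in the caller's
#' argument order.  Values are near 0 for near-identical compressible
#' sequences and near 1 for unrelated ones; real compressors can overshoot
#' 1 slightly.
#'
#' @param x,y Non-empty DNA sequences (character scalars).
#' @param compressor A [make_compressor()] contract.
#' @param cx,cy Optional precomputed `C(x)`, `C(y)` (bytes).
#' @return Non-negative numeric scalar.
#' @export
ncd <- function(x, y, compressor = default_compressor(),
                cx = NULL, cy = NULL) {
  if (!nzchar(x) || !nzchar(y)) stop("empty sequence")
  if (is.null(cx)) cx <- compressed_size(x, compressor)
  if (is.null(cy)) cy <- compressed_size(y, compressor)
  cxy <- compressed_size(paste0(x, y), compressor)
  (cxy - min(cx, cy)) / max(cx, cy)
}

#' Local alignment scoring parameters
#'
#' Match/mismatch and affine gap scores for the seed-and-extend local
#' aligner, together with the Karlin-Altschul-style statistical parameters
#' `lambda` (nats per score unit) and `K_stat` used to rescale raw scores
#' into bit scores.  Defaults follow classic megablast-style scoring
#' (match +1, mismatch -2, gap open -5, gap extend -2, word size 11,
#' lambda 1.28, K 0.46); the bit-score transform is monotone in the raw
#' score, which is all the rank-based classifier requires.  `band` is the
#' half-width of the banded gapped extension around each seed diagonal.
#'
#' @param match Positive match reward.
#' @param mismatch Negative mismatch penalty.
#' @param gap_open,gap_extend Negative affine gap penalties; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param word_size Exact-match seed length (>= 4).
#' @param lambda,K_stat Positive statistical parameters of the bit-score
#'   transform `S' = (lambda * S - ln K_stat) / ln 2`.
#' @param band Half-width of the banded extension (bases).
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -2, gap_open = -5,
                             gap_extend = -2, word_size = 11,
                             lambda = 1.28, K_stat = 0.46, band = 25) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            word_size >= 4, lambda > 0, K_stat > 0, band >= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = as.integer(word_size),
                 lambda = lambda, K_stat = K_stat, band = as.integer(band)),
            class = "alignment_params")
}

# Bit-score transform of a positive raw local-alignment score.
bit_from_raw <- function(S, params) {
  pmax(0, (params$lambda * S - log(params$K_stat)) / log(2))
}

align_raw <- function(query, subject, params) {
  align_raw_score_cpp(query, subject, params$match, params$mismatch,
                      params$gap_open, params$gap_extend,
                      params$word_size, params$band)
}

#' Seed-and-extend local alignment bit score
#'
#' Exact `word_size` matches between the two sequences seed a banded
#' affine-gap local extension around each candidate diagonal; the best raw
#' local score `S` is rescaled to a bit score
#' `S' = (lambda * S - ln K_stat) / ln 2`, floored at 0.  When the
#' sequences share no seed word the score is 0 (absence of alignment is
#' not an error).  The forward strands are compared; callers handle
#' strandness by also scoring the reverse complement of the query.
#'
#' @param query,subject Non-empty DNA sequences (character scalars).
#' @param params An [alignment_params()] object.
#' @return Non-negative bit score.
#' @export
alignment_bitscore <- function(query, subject, params = alignment_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  raw <- align_raw(query, subject, params)
  if (raw <= 0) return(0)
  bit_from_raw(raw, params)
}
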