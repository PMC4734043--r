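# Independent oracles: deliberately naive re-implementations used only to
# check the package; they share no code with the implementation paths.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Full canonical k-mer space by brute enumeration.
oracle_canon_space <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  km <- sort(apply(grid, 1, paste0, collapse = ""))
  km[km <= vapply(km, oracle_revcomp, "")]
}

# Sliding-window canonical profile over the full canonical space.
oracle_profile <- function(seq, k) {
  n <- nchar(seq)
  wins <- substring(seq, 1:(n - k + 1), k:n)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  canon <- pmin(wins, vapply(wins, oracle_revcomp, ""))
  space <- oracle_canon_space(k)
  cnt <- table(factor(canon, levels = space))
  setNames(as.numeric(cnt) / length(canon), space)
}

oracle_entropy_bits <- function(v) {
  v <- v[v > 0]
  -sum(v * log2(v))
}

oracle_euclid <- function(pfull, qfull) sqrt(sum((pfull - qfull)^2))

oracle_jsd <- function(pfull, qfull) {
  oracle_entropy_bits((pfull + qfull) / 2) -
    (oracle_entropy_bits(pfull) + oracle_entropy_bits(qfull)) / 2
}

oracle_xz_size <- function(x) length(memCompress(charToRaw(x), type = "xz"))

oracle_ncd <- function(x, y) {
  cx <- oracle_xz_size(x); cy <- oracle_xz_size(y)
  (oracle_xz_size(paste0(x, y)) - min(cx, cy)) / max(cx, cy)
}

oracle_bit <- function(S, par) (par$lambda * S - log(par$K_stat)) / log(2)

oracle_words <- function(x, w) {
  n <- nchar(x)
  if (n < w) return(list(word = character(0), pos = integer(0)))
  ww <- substring(x, 1:(n - w + 1), w:n)
  ok <- !grepl("N", ww, fixed = TRUE)
  list(word = ww[ok], pos = which(ok) - 1L)
}

# Longest exact shared substring (length), via rolling run-length DP.
oracle_lcs_substring <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- numeric(length(bv)); best <- 0
  for (i in seq_along(av)) {
    cur <- ifelse(av[i] == bv, c(0, prev[-length(bv)]) + 1, 0)
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# Full affine-gap local alignment score through Biostrings (the quadratic
# Smith-Waterman upper bound of the seeded banded heuristic).
oracle_sw_score <- function(a, b, par) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = par$match,
                                                 mismatch = par$mismatch,
                                                 baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = abs(par$gap_open),
    gapExtension = abs(par$gap_extend)))
}

# Independent re-implementation of the seeded banded local aligner:
# candidate diagonals from shared words, then a row-vectorized banded
# affine-gap DP (gap of length L costs gap_open + L * gap_extend).
oracle_seed_band_raw <- function(q, s, par) {
  n <- nchar(q); m <- nchar(s)
  w <- par$word_size; B <- par$band
  if (n < w || m < w) return(0)
  qw <- oracle_words(q, w); sw <- oracle_words(s, w)
  shared <- intersect(qw$word, sw$word)
  if (!length(shared)) return(0)
  diags <- sort(unique(unlist(lapply(shared, function(word)
    outer(sw$pos[sw$word == word], qw$pos[qw$word == word], "-")))))
  code <- function(x) {
    v <- match(strsplit(x, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
    v[is.na(v)] <- -1L
    v
  }
  qv <- code(q); sv <- code(s)
  NEG <- -1e18
  W <- 2L * B + 1L; off <- (-B):B
  go <- par$gap_open; ge <- par$gap_extend
  best <- 0
  for (d in diags) {
    Hprev <- rep(NEG, W); Fprev <- rep(NEG, W)
    for (i in 0:(n - 1)) {
      j <- i + d + off
      validj <- j >= 0 & j < m
      if (!any(validj)) { Hprev <- rep(NEG, W); Fprev <- rep(NEG, W); next }
      Fv <- if (i == 0) rep(NEG, W) else
        pmax(c(Hprev[-1], NEG) + go, c(Fprev[-1], NEG)) + ge
      diagbase <- if (i == 0) rep(0, W) else ifelse(j == 0, 0, Hprev)
      jj <- pmin(pmax(j, 0L), m - 1L)
      subv <- ifelse(qv[i + 1] >= 0 & qv[i + 1] == sv[jj + 1],
                     par$match, par$mismatch)
      Hpre <- pmax(0, diagbase + subv, Fv)
      Hpre[!validj] <- NEG
      # single gap along the row beats multiple; closed form via cummax
      A <- Hpre - off * ge
      Ev <- c(NEG, cummax(A)[-W]) + go + off * ge
      H <- pmax(Hpre, Ev)
      H[!validj] <- NEG
      best <- max(best, H[validj])
      Fv[!validj] <- NEG
      Hprev <- H; Fprev <- Fv
    }
  }
  max(best, 0)
}

oracle_align_bit <- function(q, s, par) {
  raw <- max(oracle_seed_band_raw(q, s, par),
             oracle_seed_band_raw(oracle_revcomp(q), s, par))
  if (raw <= 0) 0 else max(0, oracle_bit(raw, par))
}

# From-scratch nearest-neighbour classifier: recomputes every measure with
# the oracles above, min-max normalizes, averages, and applies the
# majority-then-smallest-taxid tie rule.
oracle_classify <- function(qseq, refs_acc, refs_seq, ref_taxon,
                            measures, k, par) {
  raw <- list()
  if (any(c("euclidean", "jsd") %in% measures)) {
    qp <- oracle_profile(qseq, k)
    rp <- lapply(refs_seq, oracle_profile, k = k)
    if ("euclidean" %in% measures)
      raw$euclidean <- vapply(rp, oracle_euclid, numeric(1), qfull = qp)
    if ("jsd" %in% measures)
      raw$jsd <- vapply(rp, oracle_jsd, numeric(1), qfull = qp)
  }
  if ("alignment" %in% measures)
    raw$alignment <- vapply(refs_seq, function(s)
      oracle_align_bit(qseq, s, par), numeric(1))
  if ("compression" %in% measures) {
    cq <- oracle_xz_size(qseq)
    raw$compression <- vapply(refs_seq, function(s) {
      cs <- oracle_xz_size(s)
      (oracle_xz_size(paste0(qseq, s)) - min(cq, cs)) / max(cq, cs)
    }, numeric(1))
  }
  raw <- raw[intersect(measures, names(raw))]
  norm <- lapply(names(raw), function(m) {
    v <- raw[[m]]; lo <- min(v); hi <- max(v)
    if (hi == lo) rep(0, length(v))
    else if (m == "alignment") (v - lo) / (hi - lo)
    else (hi - v) / (hi - lo)
  })
  if (all(vapply(norm, function(v) all(v == 0), TRUE)))
    return(list(status = "unclassified"))
  comb <- Reduce(`+`, norm) / length(norm)
  names(comb) <- refs_acc
  best <- max(comb)
  tied <- refs_acc[comb == best]
  taxa <- ref_taxon[tied]
  tab <- table(taxa)
  taxon <- min(as.integer(names(tab)[tab == max(tab)]))
  list(status = "classified", taxon = taxon,
       ref = tied[taxa == taxon][1], csss = unname(comb[tied[taxa == taxon][1]]))
}
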