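#' Sequence sets
#'
#' A `seq_set` is an ordered collection of DNA sequence records, each an
#' accession paired with a sequence over the alphabet `{A,C,G,T,N}`.
#' Accessions must be non-empty and unique within a set.
#'
#' @param accession Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of DNA sequences (same length as
#'   `accession`).  Sequences are uppercased and characters outside
#'   `{A,C,G,T,N}` are replaced by `N`.
#' @param role Either `"training"` or `"query"`.
#' @return An object of class `seq_set` with fields `accession`, `sequence`
#'   and `role`.
#' @examples
#' s <- seq_set(c("a", "b"), c("ACGT", "acgtn"))
#' s$sequence
#' @export
seq_set <- function(accession, sequence, role = c("query", "training")) {
  role <- match.arg(role)
  accession <- as.character(accession)
  sequence <- as.character(sequence)
  if (length(accession) != length(sequence))
    stop("accession and sequence must have the same length")
  if (any(is.na(accession)) || any(!nzchar(accession)))
    stop("accessions must be non-empty")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup))
    stop("duplicate accession: ", paste(utils::head(dup, 10), collapse = ", "))
  norm <- normalize_dna(sequence)
  if (any(!nzchar(norm$sequence)))
    stop("empty sequence for accession: ",
         accession[!nzchar(norm$sequence)][1])
  structure(list(accession = accession, sequence = norm$sequence, role = role),
            class = "seq_set")
}

# Uppercase and map everything outside {A,C,G,T,N} to N; returns the
# normalized sequences and the number of replaced characters.
normalize_dna <- function(sequence) {
  x <- toupper(sequence)
  n_bad <- sum(nchar(gsub("[ACGTN]", "", x)))
  if (n_bad > 0) x <- gsub("[^ACGTN]", "N", x)
  list(sequence = x, replaced = n_bad)
}

#' @export
length.seq_set <- function(x) length(x$accession)

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s sequence(s), lengths %s\n",
              length(x), x$role,
              if (length(x)) paste0(min(nchar(x$sequence)), "-",
                                    max(nchar(x$sequence))) else "-"))
  invisible(x)
}

#' Subset a sequence set
#' @param x A `seq_set`.
#' @param i Index vector (positions, logicals, or accession names).
#' @param ... Unused.
#' @export
`[.seq_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$accession)
  seq_set(x$accession[i], x$sequence[i], role = x$role)
}

#' Read a FASTA file into a sequence set
#'
#' The token before the first whitespace of each header becomes the
#' accession; the remainder of the header is discarded.  Lowercase bases are
#' uppercased and characters outside `{A,C,G,T,N}` (including IUPAC
#' ambiguity codes) are replaced by `N`, with the number of replacements
#' reported via [message()].
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @param role Role given to the resulting set (`"query"` or `"training"`).
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, role = c("query", "training")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path)
  acc <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  norm <- normalize_dna(seqs)
  if (norm$replaced > 0)
    message("read_fasta: replaced ", norm$replaced,
            " non-ACGTN character(s) with N")
  seq_set(acc, norm$sequence, role = role)
}

#' Write a sequence set to a FASTA file
#'
#' Round-trip property: `read_fasta(write_fasta(s, path))` reproduces
#' accessions and sequences exactly.
#'
#' @param set A non-empty [seq_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "seq_set"))
  if (length(set) == 0) stop("cannot write an empty sequence set")
  x <- Biostrings::BStringSet(setNames(set$sequence, set$accession))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param x A single DNA sequence (character scalar over `{A,C,G,T,N}`).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
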