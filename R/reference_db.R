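#' Build the reference database
#'
#' Precomputes everything classification needs from a training sequence
#' set: canonical k-mer profiles for every k in `k_grid`, compressed sizes
#' for the compression measure, a word index over both strands of every
#' reference for alignment seeding, and the taxonomy/taxon-map needed for
#' rank projection.  The operation is deterministic given its inputs, and
#' permuting the training records changes nothing per accession.
#'
#' @param training A [seq_set()] of reference sequences.
#' @param taxmap Named integer vector mapping every training accession to
#'   a taxid (see [read_taxmap()]).
#' @param tree A [load_taxonomy()] tree containing every taxid of `taxmap`.
#' @param k_grid Integer vector of k-mer sizes to precompute (each >= 2).
#' @param align An [alignment_params()] object.
#' @param compressor A [make_compressor()] contract.
#' @param out Optional directory; when given the database is persisted
#'   there as a self-contained set of flat files.
#' @return An object of class `reference_db`.
#' @export
build_db <- function(training, taxmap, tree, k_grid = 2:6,
                     align = alignment_params(),
                     compressor = default_compressor(), out = NULL) {
  stopifnot(inherits(training, "seq_set"), length(training) > 0)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (!length(k_grid) || any(k_grid < 2)) stop("k_grid must contain k >= 2")
  validate_taxmap(taxmap, tree)
  missing_acc <- setdiff(training$accession, names(taxmap))
  if (length(missing_acc))
    stop("training accession(s) missing from taxmap: ",
         paste(utils::head(missing_acc, 10), collapse = ", "))

  kmax <- max(k_grid)
  short <- nchar(training$sequence) < kmax
  if (any(short)) {
    warning("excluding ", sum(short), " sequence(s) shorter than max k (",
            kmax, "): ", paste(utils::head(training$accession[short], 10),
                               collapse = ", "))
    training <- training[!short]
    if (!length(training)) stop("no training sequences left after exclusion")
  }

  acc <- training$accession
  profiles <- lapply(k_grid, function(k) {
    m <- t(vapply(training$sequence, profile_vector,
                  numeric(length(canonical_kmers(k))), k = k))
    dimnames(m) <- list(acc, canonical_kmers(k))
    m
  })
  names(profiles) <- paste0("k", k_grid)

  comp_sizes <- setNames(vapply(training$sequence, compressed_size,
                                integer(1), compressor = compressor), acc)

  db <- structure(list(
    sequences = training,
    taxmap = taxmap[acc],
    tree = tree,
    k_grid = k_grid,
    profiles = profiles,
    comp_sizes = comp_sizes,
    seed_index = build_seed_index(training, align$word_size),
    align = align,
    compressor = compressor,
    params = NULL,
    path = NULL,
    build_meta = list(format_version = DB_FORMAT_VERSION,
                      k_grid = k_grid,
                      compressor = compressor$name,
                      word_size = align$word_size)
  ), class = "reference_db")

  if (!is.null(out)) {
    save_db(db, out)
    db$path <- out
  }
  db
}

# Word-code index over both strands of each reference (forward codes and
# codes of the reverse-complement strand, offsets 0-based on the indexed
# strand).  `codes` is the sorted union used to shortlist references that
# can possibly seed an alignment.
build_seed_index <- function(training, word_size) {
  idx <- lapply(training$sequence, function(s) {
    if (nchar(s) < word_size)
      return(list(fwd = list(code = integer(0), offset = integer(0)),
                  rc = list(code = integer(0), offset = integer(0)),
                  codes = integer(0)))
    fwd <- word_codes_cpp(s, word_size)
    rc <- word_codes_cpp(revcomp(s), word_size)
    list(fwd = fwd, rc = rc,
         codes = sort(unique(c(fwd$code, rc$code))))
  })
  names(idx) <- training$accession
  idx
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d references, k_grid {%s}, compressor %s%s\n",
              length(x$sequences), paste(x$k_grid, collapse = ","),
              x$compressor$name,
              if (is.null(x$params)) ", untuned" else
                sprintf(", tuned (k=%d, measures %s)", x$params$k_opt,
                        paste(x$params$selected_measures, collapse = "+"))))
  invisible(x)
}

# Profile matrix accessor; errors when the DB was not built for this k.
db_profile_matrix <- function(db, k) {
  key <- paste0("k", k)
  if (!k %in% db$k_grid || is.null(db$profiles[[key]]))
    stop("no profiles for k=", k, "; database built with k_grid {",
         paste(db$k_grid, collapse = ","), "}")
  db$profiles[[key]]
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Persist a reference database to a directory of flat files
#'
#' @param db A [build_db()] database.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_fasta(db$sequences, file.path(path, "sequences.fasta"))
  write_taxmap(db$taxmap, file.path(path, "taxmap.tsv"))
  tax <- data.frame(taxid = names(db$tree$parent),
                    parent = unname(db$tree$parent),
                    rank = unname(db$tree$rank[names(db$tree$parent)]),
                    name = unname(db$tree$name[names(db$tree$parent)]))
  write.table(tax, file.path(path, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(accession = names(db$comp_sizes),
                         bytes = unname(db$comp_sizes)),
              file.path(path, "comp_sizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (k in db$k_grid) {
    m <- db$profiles[[paste0("k", k)]]
    fm <- matrix(fmt_full(m), nrow = nrow(m), dimnames = dimnames(m))
    write.table(fm, file.path(path, sprintf("profiles_k%d.tsv", k)),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  manifest <- list(format_version = db$build_meta$format_version,
                   k_grid = db$k_grid,
                   compressor = db$compressor$name,
                   align = unclass(db$align),
                   params = db$params)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Rewrite only the manifest (used after tuning).
save_manifest <- function(db) {
  if (is.null(db$path)) return(invisible(NULL))
  manifest <- list(format_version = db$build_meta$format_version,
                   k_grid = db$k_grid,
                   compressor = db$compressor$name,
                   align = unclass(db$align),
                   params = db$params)
  jsonlite::write_json(manifest, file.path(db$path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(db$path)
}

#' Load a persisted reference database
#'
#' Reads back a [save_db()] directory, rebuilds the in-memory seed index
#' deterministically from the persisted sequences, and checks all database
#' invariants.  Profiles and compressed sizes round-trip exactly.
#'
#' @param path Directory written by [build_db()]/[save_db()].
#' @return A `reference_db`.
#' @export
load_db <- function(path) {
  need <- c("manifest.json", "sequences.fasta", "taxmap.tsv",
            "taxonomy.tsv", "comp_sizes.tsv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("database component missing: ", f)
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), DB_FORMAT_VERSION))
    stop("database format version mismatch: found ",
         manifest$format_version, ", expected ", DB_FORMAT_VERSION)
  k_grid <- sort(as.integer(manifest$k_grid))
  for (k in k_grid) {
    if (!file.exists(file.path(path, sprintf("profiles_k%d.tsv", k))))
      stop("database component missing: ", sprintf("profiles_k%d.tsv", k))
  }

  sequences <- read_fasta(file.path(path, "sequences.fasta"),
                          role = "training")
  tax <- read.table(file.path(path, "taxonomy.tsv"), sep = "\t",
                    header = TRUE, colClasses = "character", quote = "")
  tree <- structure(list(parent = setNames(tax$parent, tax$taxid),
                         rank = setNames(tax$rank, tax$taxid),
                         name = setNames(tax$name, tax$taxid),
                         root = tax$taxid[tax$parent == tax$taxid]),
                    class = "taxonomy_tree")
  taxmap <- read_taxmap(file.path(path, "taxmap.tsv"), tree)
  cs <- read.table(file.path(path, "comp_sizes.tsv"), sep = "\t",
                   header = TRUE, quote = "",
                   colClasses = c("character", "integer"))
  comp_sizes <- setNames(cs$bytes, cs$accession)
  if (is.null(comp_sizes) || !length(comp_sizes))
    stop("comp_sizes missing or empty")

  profiles <- lapply(k_grid, function(k) {
    m <- as.matrix(read.table(file.path(path, sprintf("profiles_k%d.tsv", k)),
                              sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE, quote = ""))
    storage.mode(m) <- "double"
    m
  })
  names(profiles) <- paste0("k", k_grid)

  al <- manifest$align
  align <- alignment_params(match = al$match, mismatch = al$mismatch,
                            gap_open = al$gap_open,
                            gap_extend = al$gap_extend,
                            word_size = al$word_size, lambda = al$lambda,
                            K_stat = al$K_stat, band = al$band)
  params <- manifest$params
  if (!is.null(params)) {
    params$k_opt <- as.integer(params$k_opt)
    params$selected_measures <- as.character(params$selected_measures)
    params$per_measure_accuracy <- unlist(params$per_measure_accuracy)
  }

  db <- structure(list(
    sequences = sequences,
    taxmap = taxmap[sequences$accession],
    tree = tree,
    k_grid = k_grid,
    profiles = profiles,
    comp_sizes = comp_sizes,
    seed_index = build_seed_index(sequences, align$word_size),
    align = align,
    compressor = make_compressor(manifest$compressor),
    params = params,
    path = path,
    build_meta = list(format_version = as.character(manifest$format_version),
                      k_grid = k_grid,
                      compressor = manifest$compressor,
                      word_size = align$word_size)
  ), class = "reference_db")
  validate_db(db)
  db
}

#' Check the structural invariants of a reference database
#'
#' Every accession must be present in the taxon map, the size cache and
#' every profile matrix; profile rows must sum to one; seed-index offsets
#' must lie within their sequence.
#'
#' @param db A `reference_db`.
#' @return `db` invisibly; errors on any violation.
#' @export
validate_db <- function(db) {
  acc <- db$sequences$accession
  if (!all(acc %in% names(db$taxmap))) stop("taxmap incomplete")
  if (!all(acc %in% names(db$comp_sizes))) stop("comp_sizes incomplete")
  for (k in db$k_grid) {
    m <- db$profiles[[paste0("k", k)]]
    if (is.null(m) || !all(acc %in% rownames(m)))
      stop("profiles incomplete for k=", k)
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stop("profile rows do not sum to 1 for k=", k)
  }
  w <- db$align$word_size
  lens <- setNames(nchar(db$sequences$sequence), acc)
  for (a in acc) {
    si <- db$seed_index[[a]]
    if (is.null(si)) stop("seed index missing for ", a)
    offs <- c(si$fwd$offset, si$rc$offset)
    if (length(offs) && (min(offs) < 0 || max(offs) + w > lens[[a]]))
      stop("invalid seed offset for ", a)
  }
  validate_taxmap(db$taxmap, db$tree)
  invisible(db)
}
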