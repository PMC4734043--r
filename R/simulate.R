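#' Configuration for the hierarchical sequence simulator
#'
#' The simulator emulates a taxonomically structured reference collection:
#' a root genome drawn uniformly over `{A,C,G,T}` accumulates substitutions
#' down a three-level hierarchy (genus ancestors, species ancestors,
#' individual strain sequences), so that sequence divergence mirrors
#' taxonomic distance.  Divergences must satisfy
#' `strain < species < genus` (the signal hierarchy).
#'
#' @param n_genera Number of genera (>= 2).
#' @param species_per_genus Species per genus (>= 1).
#' @param seqs_per_species Strain sequences per species (>= 1).
#' @param genome_length Genome length in bases.
#' @param genus_divergence Per-base substitution probability from the root
#'   to each genus ancestor.
#' @param species_divergence Genus ancestor to species ancestor.
#' @param strain_divergence Species ancestor to each strain sequence.
#' @param read_length When set, each test sequence is replaced by a
#'   uniformly placed substring of this length drawn from a uniformly
#'   chosen strand (emulating unassembled reads); `NULL` keeps full
#'   genomes.
#' @param seed Integer seed; identical configurations produce identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genera = 5, species_per_genus = 4,
                       seqs_per_species = 3, genome_length = 5000,
                       genus_divergence = 0.30, species_divergence = 0.10,
                       strain_divergence = 0.01, read_length = NULL,
                       seed = 1) {
  stopifnot(n_genera >= 2, species_per_genus >= 1, seqs_per_species >= 1,
            genome_length >= 1)
  div <- c(strain_divergence, species_divergence, genus_divergence)
  if (any(div < 0) || any(div > 0.75))
    stop("divergences must lie in [0, 0.75]")
  if (!(strain_divergence < species_divergence &&
        species_divergence < genus_divergence))
    stop("divergences must satisfy strain < species < genus")
  if (!is.null(read_length))
    stopifnot(read_length >= 1, read_length <= genome_length)
  structure(list(n_genera = n_genera, species_per_genus = species_per_genus,
                 seqs_per_species = seqs_per_species,
                 genome_length = genome_length,
                 genus_divergence = genus_divergence,
                 species_divergence = species_divergence,
                 strain_divergence = strain_divergence,
                 read_length = read_length, seed = seed),
            class = "sim_config")
}

#' Random DNA sequence
#' @param n Length in bases.
#' @return Character scalar drawn uniformly over `{A,C,G,T}`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Substitute bases at a fixed per-base rate
#'
#' Each base is independently replaced, with probability `p`, by one of
#' the three other bases chosen uniformly; length is preserved and no
#' indels are introduced.
#'
#' @param sequence DNA sequence (character scalar).
#' @param p Substitution probability per base, in `[0, 0.75]`.
#' @param seed Optional seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(sequence, p, seed = NULL) {
  if (p < 0 || p > 0.75) stop("substitution probability must be in [0, 0.75]")
  run <- function() {
    if (p == 0) return(sequence)
    bases <- c("A", "C", "G", "T")
    x <- strsplit(sequence, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(x)) < p)
    if (length(hit)) {
      cur <- match(x[hit], bases)
      step <- sample.int(3, length(hit), replace = TRUE)
      repl <- ifelse(is.na(cur), bases[step],       # N mutates to a base
                     bases[((cur - 1 + step) %% 4) + 1])
      x[hit] <- repl
      sequence <- paste(x, collapse = "")
    }
    sequence
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Toy taxonomy ids: one shared phylum/class/order/family chain, genera and
# species below it.
sim_taxids <- function(config) {
  g <- seq_len(config$n_genera)
  list(root = 1L, phylum = 10L, class = 11L, order = 12L, family = 13L,
       genus = 100L + g,
       species = function(gi, si) 1000L + 100L * gi + si)
}

write_sim_taxdump <- function(config, dir) {
  ids <- sim_taxids(config)
  nodes <- c(
    sprintf("%d\t|\t%d\t|\t%s\t|", ids$root, ids$root, "no rank"),
    sprintf("%d\t|\t%d\t|\t%s\t|", ids$phylum, ids$root, "phylum"),
    sprintf("%d\t|\t%d\t|\t%s\t|", ids$class, ids$phylum, "class"),
    sprintf("%d\t|\t%d\t|\t%s\t|", ids$order, ids$class, "order"),
    sprintf("%d\t|\t%d\t|\t%s\t|", ids$family, ids$order, "family"))
  names_l <- c(
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids$root, "root"),
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids$phylum, "Simphyla"),
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids$class, "Simclassia"),
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids$order, "Simordales"),
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids$family, "Simfamiliaceae"))
  for (gi in seq_len(config$n_genera)) {
    nodes <- c(nodes, sprintf("%d\t|\t%d\t|\tgenus\t|",
                              ids$genus[gi], ids$family))
    names_l <- c(names_l, sprintf("%d\t|\tSimgenus%02d\t|\t\t|\tscientific name\t|",
                                  ids$genus[gi], gi))
    for (si in seq_len(config$species_per_genus)) {
      sid <- ids$species(gi, si)
      nodes <- c(nodes, sprintf("%d\t|\t%d\t|\tspecies\t|",
                                sid, ids$genus[gi]))
      names_l <- c(names_l,
                   sprintf("%d\t|\tSimgenus%02d species%02d\t|\t\t|\tscientific name\t|",
                           sid, gi, si))
    }
  }
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(nodes, nodes_path)
  writeLines(names_l, names_path)
  list(nodes = nodes_path, names = names_path)
}

#' Simulate a taxonomically structured training/test collection
#'
#' Generates strain sequences under the hierarchical substitution model of
#' [sim_config()], splits each species' strains into training and test
#' (at least one of each when a species has two or more strains, in a
#' 2/3-1/3 proportion otherwise), optionally reduces test sequences to
#' fixed-length substrings from a random strand, and emits a matching toy
#' NCBI-style taxonomy dump (species, genus, family, order, class, phylum
#' all present in every lineage).
#'
#' @param config A [sim_config()].
#' @param dir Directory for the taxonomy dump files (created if needed).
#' @return A list with `training` and `test` [seq_set()]s, `taxmap` and
#'   `truth` (named taxid vectors at species level for training and test
#'   accessions), `tree` (the parsed taxonomy), and `nodes`/`names` dump
#'   paths.
#' @export
simulate_community <- function(config, dir = tempfile("simtax")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- write_sim_taxdump(config, dir)
  ids <- sim_taxids(config)

  with_seed(config$seed, {
    root <- random_dna(config$genome_length)
    train_acc <- character(0); train_seq <- character(0)
    train_tax <- integer(0)
    test_acc <- character(0); test_seq <- character(0)
    test_tax <- integer(0)
    for (gi in seq_len(config$n_genera)) {
      genus_anc <- mutate_sequence(root, config$genus_divergence)
      for (si in seq_len(config$species_per_genus)) {
        sp_anc <- mutate_sequence(genus_anc, config$species_divergence)
        s <- config$seqs_per_species
        n_train <- if (s == 1) 1L else max(1L, min(s - 1L, round(2 * s / 3)))
        for (ti in seq_len(s)) {
          sq <- mutate_sequence(sp_anc, config$strain_divergence)
          acc <- sprintf("G%02d_S%02d_T%02d", gi, si, ti)
          sid <- ids$species(gi, si)
          if (ti <= n_train) {
            train_acc <- c(train_acc, acc)
            train_seq <- c(train_seq, sq)
            train_tax <- c(train_tax, sid)
          } else {
            if (!is.null(config$read_length)) {
              start <- sample.int(nchar(sq) - config$read_length + 1L, 1)
              sq <- substr(sq, start, start + config$read_length - 1L)
              if (sample(c(TRUE, FALSE), 1)) sq <- revcomp(sq)
              acc <- paste0(acc, "_read")
            }
            test_acc <- c(test_acc, acc)
            test_seq <- c(test_seq, sq)
            test_tax <- c(test_tax, sid)
          }
        }
      }
    }
    list(training = seq_set(train_acc, train_seq, role = "training"),
         test = if (length(test_acc))
           seq_set(test_acc, test_seq, role = "query")
         else NULL,
         taxmap = setNames(train_tax, train_acc),
         truth = setNames(test_tax, test_acc),
         tree = load_taxonomy(dump$nodes, dump$names),
         nodes = dump$nodes, names = dump$names, dir = dir)
  })
}
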