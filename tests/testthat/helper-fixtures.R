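# Fixture builders: everything is generated in code at test time.

# Toy taxonomy dump with two genera under a complete six-rank chain.
# species 1101,1102 under genus 101; species 1201 under genus 102.
write_toy_dump <- function(dir = tempfile("toytax")) {
  dir.create(dir, showWarnings = FALSE)
  nodes <- c("1\t|\t1\t|\tno rank\t|",
             "10\t|\t1\t|\tphylum\t|",
             "11\t|\t10\t|\tclass\t|",
             "12\t|\t11\t|\torder\t|",
             "13\t|\t12\t|\tfamily\t|",
             "101\t|\t13\t|\tgenus\t|",
             "102\t|\t13\t|\tgenus\t|",
             "1101\t|\t101\t|\tspecies\t|",
             "1102\t|\t101\t|\tspecies\t|",
             "1201\t|\t102\t|\tspecies\t|")
  names_l <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "10\t|\tToyphyla\t|\t\t|\tscientific name\t|",
               "11\t|\tToyclassia\t|\t\t|\tscientific name\t|",
               "12\t|\tToyordales\t|\t\t|\tscientific name\t|",
               "13\t|\tToyfamily\t|\t\t|\tscientific name\t|",
               "101\t|\tToygenus one\t|\t\t|\tscientific name\t|",
               "102\t|\tToygenus two\t|\t\t|\tscientific name\t|",
               "1101\t|\tToygenus one sp a\t|\t\t|\tscientific name\t|",
               "1102\t|\tToygenus one sp b\t|\t\t|\tscientific name\t|",
               "1201\t|\tToygenus two sp a\t|\t\t|\tscientific name\t|")
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(nodes, nodes_path)
  writeLines(names_l, names_path)
  list(nodes = nodes_path, names = names_path, dir = dir)
}

toy_tree <- function() {
  d <- write_toy_dump()
  load_taxonomy(d$nodes, d$names)
}

# Two well-separated genera, `per` near-identical strains of one species
# each; returns a training seq_set plus its taxmap and tree.
two_genus_training <- function(per = 3, len = 1000, seed = 5,
                               strain_p = 0.01) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g1 <- random_dna(len); g2 <- random_dna(len)
  acc <- c(paste0("a", seq_len(per)), paste0("b", seq_len(per)))
  seqs <- c(vapply(seq_len(per), function(i) mutate_sequence(g1, strain_p),
                   ""),
            vapply(seq_len(per), function(i) mutate_sequence(g2, strain_p),
                   ""))
  taxmap <- setNames(c(rep(1101L, per), rep(1201L, per)), acc)
  list(training = seq_set(acc, seqs, role = "training"),
       taxmap = taxmap, tree = toy_tree())
}

# Random profile pair at a given k (from independent random sequences).
random_profile_pair <- function(k, len = 600) {
  list(p = kmer_profile(random_dna(len), k),
       q = kmer_profile(random_dna(len), k))
}
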