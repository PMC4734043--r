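make_small_db <- function(per = 3, len = 600, seed = 5) {
  fx <- two_genus_training(per = per, len = len, seed = seed)
  list(db = build_db(fx$training, fx$taxmap, fx$tree, k_grid = c(2, 4)),
       fx = fx)
}

test_that("a query identical to a training sequence recovers its genus", {
  s <- make_small_db()
  q <- list(accession = "q1",
            sequence = s$fx$training$sequence[1])  # identical to a1
  for (m in list("alignment", c("euclidean", "jsd"), "all")) {
    res <- classify_query(q, s$db, "genus", measures = m, k = 4)
    expect_equal(res$status, "classified")
    expect_equal(res$predicted_taxid, 101L)
  }
  res <- classify_query(q, s$db, "genus", k = 4)
  expect_equal(res$best_reference, "a1")
  expect_equal(res$predicted_name, "Toygenus one")
  expect_true(res$csss >= 0 && res$csss <= 1)
})

test_that("queries sharing no seed word with any reference go unclassified", {
  s <- make_small_db()
  set.seed(99)
  res <- classify_query(list(accession = "q", sequence = random_dna(50)),
                        s$db, "genus", measures = "alignment", k = 4)
  expect_equal(res$status, "unclassified")
  expect_true(is.na(res$predicted_taxid))
  expect_match(res$reason, "no measure")
})

test_that("queries shorter than k are unclassified with a reason", {
  s <- make_small_db()
  res <- classify_query(list(accession = "q", sequence = "ACG"),
                        s$db, "genus", measures = "euclidean", k = 4)
  expect_equal(res$status, "unclassified")
  expect_match(res$reason, "shorter than k")
})

test_that("invalid ranks, measures and k are rejected", {
  s <- make_small_db()
  q <- list(accession = "q", sequence = s$fx$training$sequence[1])
  expect_error(classify_query(q, s$db, "genus", k = 7), "k_grid")
  expect_error(classify_query(q, s$db, "genus", measures = "blast", k = 4),
               "unknown measure")
  expect_error(classify_query(q, s$db, "tribe", k = 4), "unknown rank")
})

test_that("classification agrees with the from-scratch oracle classifier", {
  set.seed(17)
  cfg <- sim_config(n_genera = 3, species_per_genus = 2,
                    seqs_per_species = 3, genome_length = 400,
                    species_divergence = 0.12, seed = 17)
  sim <- simulate_community(cfg)
  db <- build_db(sim$training, sim$taxmap, sim$tree, k_grid = 4)
  elig <- cssstax:::eligible_refs(db, "genus")
  ref_taxon <- setNames(elig$taxon, elig$accession)
  refs_seq <- db$sequences$sequence[match(elig$accession,
                                          db$sequences$accession)]
  for (i in seq_len(length(sim$test))) {
    got <- classify_query(list(accession = sim$test$accession[i],
                               sequence = sim$test$sequence[i]),
                          db, "genus", k = 4)
    want <- oracle_classify(sim$test$sequence[i], elig$accession, refs_seq,
                            ref_taxon,
                            c("alignment", "euclidean", "jsd", "compression"),
                            4, db$align)
    expect_equal(got$status, want$status)
    if (got$status == "classified") {
      expect_equal(got$predicted_taxid, want$taxon)
      expect_equal(got$csss, want$csss, tolerance = 1e-12)
    }
  }
})

test_that("batch classification preserves order, length and thread-invariance", {
  s <- make_small_db()
  set.seed(4)
  qs <- seq_set(sprintf("q%02d", 1:10),
                vapply(1:10, function(i)
                  mutate_sequence(s$fx$training$sequence[(i %% 6) + 1], 0.05),
                  ""))
  r1 <- classify_set(qs, s$db, "genus", measures = "all", k = 4)
  expect_equal(nrow(r1), 10)
  expect_equal(r1$query_accession, qs$accession)
  r2 <- classify_set(qs, s$db, "genus", measures = "all", k = 4, threads = 2)
  expect_identical(r1, r2)
  # empty set -> empty frame with the same columns
  r0 <- classify_set(qs[0], s$db, "genus", measures = "all", k = 4)
  expect_equal(nrow(r0), 0)
  expect_identical(names(r0), names(r1))
})

test_that("per-query failures never abort a batch", {
  s <- make_small_db()
  qs <- seq_set(c("good", "short"),
                c(s$fx$training$sequence[1], "ACT"))
  res <- classify_set(qs, s$db, "genus", measures = "euclidean", k = 4)
  expect_equal(res$status, c("classified", "unclassified"))
  expect_match(res$reason[2], "shorter")
})

test_that("training sequences classify to their own taxon (self-consistency)", {
  s <- make_small_db()
  for (i in seq_len(length(s$fx$training))) {
    res <- classify_query(list(accession = "self",
                               sequence = s$fx$training$sequence[i]),
                          s$db, "genus", measures = "alignment", k = 4)
    want <- ancestor_at_rank(s$fx$tree,
                             s$fx$taxmap[[s$fx$training$accession[i]]],
                             "genus")
    expect_equal(res$predicted_taxid, want)
  }
})

test_that("a min-score floor turns weak assignments into unclassified", {
  s <- make_small_db()
  q <- list(accession = "q", sequence = s$fx$training$sequence[1])
  res <- classify_query(q, s$db, "genus", k = 4, min_score = 1.01)
  expect_equal(res$status, "unclassified")
  expect_match(res$reason, "below min score")
})
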