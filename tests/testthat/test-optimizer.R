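test_that("leave-one-out with singleton labels scores zero", {
  # every species has exactly one training sequence; removing it removes
  # the only same-label neighbour, so genus-level LOO at species rank = 0
  fx <- two_genus_training(per = 1, len = 500)
  # add a third singleton species so >= 2 labels remain after leave-one-out
  set.seed(12)
  tr <- seq_set(c(fx$training$accession, "c1"),
                c(fx$training$sequence, random_dna(500)), role = "training")
  tm <- c(fx$taxmap, c1 = 1102L)
  db <- build_db(tr, tm, fx$tree, k_grid = 4)
  expect_equal(loocv_accuracy(db, "species", "euclidean", k = 4), 0)
})

test_that("well-separated genera with sibling strains reach accuracy 1", {
  fx <- two_genus_training(per = 3, len = 800)
  db <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = 4)
  expect_equal(loocv_accuracy(db, "genus", "alignment", k = 4), 1.0)
})

test_that("degenerate training sets are rejected", {
  fx <- two_genus_training(per = 2, len = 300)
  one_genus <- fx$training[1:2]
  db <- build_db(one_genus, fx$taxmap[1:2], fx$tree, k_grid = 2)
  expect_error(loocv_accuracy(db, "genus", "euclidean", k = 2),
               "degenerate training set")
})

test_that("LOO accuracy equals an explicit classify_query loop", {
  cfg <- sim_config(n_genera = 3, species_per_genus = 2,
                    seqs_per_species = 3, genome_length = 500, seed = 23)
  sim <- simulate_community(cfg)
  db <- build_db(sim$training, sim$taxmap, sim$tree, k_grid = c(2, 4))
  for (ms in list("euclidean", c("jsd", "compression"), "all")) {
    got <- loocv_accuracy(db, "genus", ms, k = 4)
    elig <- cssstax:::eligible_refs(db, "genus")
    truth <- setNames(elig$taxon, elig$accession)
    correct <- vapply(elig$accession, function(a) {
      r <- classify_query(
        list(accession = a,
             sequence = db$sequences$sequence[match(a, db$sequences$accession)]),
        db, "genus", measures = ms, k = 4, exclude = a)
      identical(r$status, "classified") && r$predicted_taxid == truth[[a]]
    }, logical(1))
    expect_equal(got, mean(correct))
  }
})

test_that("the reference pool in LOO excludes exactly the left-out sequence", {
  fx <- two_genus_training(per = 2, len = 400)
  db <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = 2)
  r <- classify_query(list(accession = "a1",
                           sequence = fx$training$sequence[1]),
                      db, "genus", measures = "alignment", k = 2,
                      exclude = "a1")
  expect_false(identical(r$best_reference, "a1"))
})

test_that("select_k degenerates to the smallest k without k-dependent measures", {
  fx <- two_genus_training(per = 2, len = 400)
  db <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = c(3, 5))
  expect_equal(as.integer(select_k(db, "genus", "alignment")), 3L)
  db1 <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = 3)
  expect_equal(as.integer(select_k(db1, "genus", c("euclidean", "jsd"))), 3L)
})

test_that("select_k breaks accuracy ties toward the smallest k", {
  fx <- two_genus_training(per = 3, len = 800)
  db <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = c(2, 4, 6))
  kk <- select_k(db, "genus", c("euclidean", "jsd"))
  accs <- attr(kk, "accuracy")
  expect_equal(as.integer(kk),
               as.integer(names(accs)[which.max(accs)]))
  if (all(accs == accs[1])) expect_equal(as.integer(kk), 2L)
})

test_that("select_k is invariant to reference ordering", {
  cfg <- sim_config(n_genera = 3, species_per_genus = 2,
                    seqs_per_species = 2, genome_length = 500, seed = 31)
  sim <- simulate_community(cfg)
  db <- build_db(sim$training, sim$taxmap, sim$tree, k_grid = c(2, 4))
  perm <- rev(seq_len(length(sim$training)))
  tr2 <- seq_set(sim$training$accession[perm], sim$training$sequence[perm],
                 role = "training")
  db2 <- build_db(tr2, sim$taxmap, sim$tree, k_grid = c(2, 4))
  expect_equal(as.integer(select_k(db, "genus", c("euclidean", "jsd"))),
               as.integer(select_k(db2, "genus", c("euclidean", "jsd"))))
})

test_that("a single candidate measure is always retained", {
  fx <- two_genus_training(per = 2, len = 400)
  db <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = 2)
  kept <- eliminate_measures(db, "genus", "euclidean", k = 2)
  expect_equal(as.character(kept), "euclidean")
})

test_that("perfect measures on separable data are all retained", {
  fx <- two_genus_training(per = 3, len = 800)
  db <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = 4)
  kept <- eliminate_measures(db, "genus", k = 4)
  expect_setequal(as.character(kept),
                  c("alignment", "euclidean", "jsd", "compression"))
  expect_true(all(attr(kept, "accuracy") > attr(kept, "baseline")))
})

test_that("a planted random-similarity measure is eliminated", {
  cfg <- sim_config(n_genera = 5, species_per_genus = 1,
                    seqs_per_species = 3, genome_length = 2000, seed = 61)
  sim <- simulate_community(cfg)
  db <- build_db(sim$training, sim$taxmap, sim$tree, k_grid = 4)
  acc <- db$sequences$accession
  set.seed(61)
  noise <- matrix(runif(length(acc)^2), length(acc),
                  dimnames = list(acc, acc))
  attr(noise, "orientation") <- "similarity"
  kept <- eliminate_measures(db, "genus", c("alignment", "euclidean"),
                             k = 4, extra_measures = list(noise = noise))
  expect_true(all(c("alignment", "euclidean") %in% kept))
  expect_false("noise" %in% kept)
})

test_that("tune runs the full pipeline deterministically", {
  fx <- two_genus_training(per = 3, len = 800)
  out <- tempfile("db")
  db <- build_db(fx$training, fx$taxmap, fx$tree, k_grid = c(2, 4),
                 out = out)
  suppressMessages(t1 <- tune(db, "genus"))
  suppressMessages(t2 <- tune(db, "genus"))
  expect_identical(t1$params, t2$params)
  expect_true(t1$params$k_opt %in% db$k_grid)
  expect_true(length(t1$params$selected_measures) >= 1)
  expect_true(t1$params$loocv_accuracy >= 0 && t1$params$loocv_accuracy <= 1)
  # tuned parameters are persisted in the manifest and restored on load
  suppressMessages(db2 <- load_db(out))
  expect_equal(db2$params$k_opt, t1$params$k_opt)
  expect_setequal(db2$params$selected_measures, t1$params$selected_measures)
  # alignment-only tuning skips k selection (smallest grid k by convention)
  suppressMessages(ta <- tune(db, "genus", measures = "alignment"))
  expect_equal(ta$params$k_opt, 2L)
  expect_equal(ta$params$selected_measures, "alignment")
})

test_that("LOO subsampling caps the query side but stays stratified", {
  cfg <- sim_config(n_genera = 3, species_per_genus = 2,
                    seqs_per_species = 4, genome_length = 400, seed = 41)
  sim <- simulate_community(cfg)
  db <- build_db(sim$training, sim$taxmap, sim$tree, k_grid = 2)
  a1 <- loocv_accuracy(db, "genus", "euclidean", k = 2, cap = 6, seed = 1)
  a2 <- loocv_accuracy(db, "genus", "euclidean", k = 2, cap = 6, seed = 1)
  expect_identical(a1, a2)  # seeded subsample is reproducible
  expect_true(a1 >= 0 && a1 <= 1)
})
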