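test_that("k-mer profiles canonicalize, skip N windows and sum to one", {
  p <- kmer_profile("ACGT", 2)  # windows AC,CG,GT; GT canonicalizes to AC
  expect_equal(unclass(p)[c("AC", "CG")], c(AC = 2 / 3, CG = 1 / 3))
  expect_equal(attr(p, "total_counted"), 3L)

  p <- kmer_profile("AAAA", 2)
  expect_equal(unclass(p), c(AA = 1), ignore_attr = TRUE)
  expect_equal(attr(p, "total_counted"), 3L)

  p <- kmer_profile("ACNGT", 2)  # CN and NG skipped
  expect_equal(unclass(p), c(AC = 1), ignore_attr = TRUE)
  expect_equal(attr(p, "total_counted"), 2L)

  expect_error(kmer_profile("ACG", 4), "shorter than k")
  expect_error(kmer_profile("ANNNA", 3), "no informative")
})

test_that("profiles match the brute-force sliding-window oracle", {
  set.seed(21)
  for (k in c(2, 4, 6)) {
    s <- random_dna(400)
    got <- unclass(kmer_profile(s, k))
    want <- oracle_profile(s, k)
    want <- want[want > 0]
    expect_equal(got[order(names(got))], want[order(names(want))],
                 tolerance = 1e-12)
  }
})

test_that("Euclidean and JSD match full-keyspace oracles and their bounds", {
  expect_error(euclidean_distance(kmer_profile("ACGTAC", 2),
                                  kmer_profile("ACGTAC", 3)), "different k")
  p <- kmer_profile("ACGTACGT", 3)
  expect_equal(euclidean_distance(p, p), 0)
  expect_equal(jsd(p, p), 0)
  # disjoint unit supports
  p1 <- structure(c(AA = 1), k = 2L, class = "kmer_profile")
  q1 <- structure(c(AC = 1), k = 2L, class = "kmer_profile")
  expect_equal(euclidean_distance(p1, q1), sqrt(2))
  expect_equal(jsd(p1, q1), 1)

  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    pr <- random_profile_pair(k)
    a <- euclidean_distance(pr$p, pr$q)
    b <- jsd(pr$p, pr$q)
    pfull <- setNames(numeric(length(oracle_canon_space(k))),
                      oracle_canon_space(k))
    qfull <- pfull
    pfull[names(pr$p)] <- unclass(pr$p)
    qfull[names(pr$q)] <- unclass(pr$q)
    expect_equal(a, oracle_euclid(pfull, qfull), tolerance = 1e-12)
    expect_equal(b, oracle_jsd(pfull, qfull), tolerance = 1e-12)
    expect_lte(a, sqrt(2)); expect_gte(a, 0)
    expect_lte(b, 1); expect_gte(b, 0)
  }
})

test_that("NCD behaves like a normalized compression distance", {
  set.seed(13)
  motif <- random_dna(200)
  compressible <- paste(rep(motif, 50), collapse = "")  # 10 kb of repeats
  expect_lte(ncd(compressible, compressible), 0.15)
  x <- random_dna(10000); y <- random_dna(10000)
  expect_gte(ncd(x, y), 0.8)
  expect_lte(abs(ncd(x, y) - ncd(y, x)), 0.05)
  expect_lte(ncd(x, y), 1.1)
  expect_equal(ncd(x, y), oracle_ncd(x, y))
  expect_error(ncd("", "ACGT"), "empty")
})

test_that("pluggable compressors honour the size contract", {
  c2 <- make_compressor("gzip")
  expect_identical(c2$compress_size(charToRaw("AAAA")),
                   c2$compress_size(charToRaw("AAAA")))  # deterministic
  expect_gte(c2$compress_size(charToRaw("A")), 1)
  custom <- make_compressor("len", compress_size = function(b) length(b))
  expect_equal(ncd("AAAA", "AAAA", custom), (8 - 4) / 4)
})

test_that("alignment bit score follows the stated transform on identities", {
  par <- alignment_params()
  set.seed(3)
  x <- random_dna(100)
  expect_equal(alignment_bitscore(x, x, par),
               (par$lambda * 100 - log(par$K_stat)) / log(2),
               tolerance = 1e-9)
  expect_equal(alignment_bitscore(x, x, par), 185.785, tolerance = 1e-3)
  # exact 50-bp substring forces a perfect local alignment of score 50
  long <- random_dna(400)
  sub <- substr(long, 101, 150)
  expect_equal(alignment_bitscore(sub, long, par),
               (par$lambda * 50 * par$match - log(par$K_stat)) / log(2),
               tolerance = 1e-9)
})

test_that("sequences sharing no seed word score zero", {
  par <- alignment_params()
  expect_equal(alignment_bitscore(strrep("A", 50), strrep("C", 50), par), 0)
  set.seed(8)
  expect_equal(alignment_bitscore(random_dna(20), random_dna(20), par), 0)
})

test_that("the aligner agrees exactly with its independent reimplementation", {
  par <- alignment_params()
  set.seed(42)
  for (t in 1:15) {
    x <- random_dna(sample(80:300, 1))
    y <- switch(t %% 3 + 1,
                mutate_sequence(x, runif(1, 0.02, 0.2)),
                random_dna(sample(80:300, 1)),
                paste0(substr(x, 1, 40), random_dna(5), substr(x, 44, nchar(x))))
    got <- cssstax:::align_raw_score_cpp(x, y, par$match, par$mismatch,
                                         par$gap_open, par$gap_extend,
                                         par$word_size, par$band)
    expect_identical(got, oracle_seed_band_raw(x, y, par))
  }
})

test_that("all four measures are deterministic", {
  set.seed(55)
  x <- random_dna(500); y <- mutate_sequence(x, 0.1)
  px <- kmer_profile(x, 4); py <- kmer_profile(y, 4)
  expect_identical(euclidean_distance(px, py), euclidean_distance(px, py))
  expect_identical(jsd(px, py), jsd(px, py))
  expect_identical(ncd(x, y), ncd(x, y))
  expect_identical(alignment_bitscore(x, y), alignment_bitscore(x, y))
})
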