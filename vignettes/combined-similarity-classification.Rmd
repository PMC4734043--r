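---
title: "Combined sequence similarity scores for taxonomic classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined sequence similarity scores for taxonomic classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Given a collection of reference DNA sequences with known taxonomic labels
and a query of unknown origin — anything from a 150-bp read to a complete
genome — we want the taxon of the query at a chosen rank (species, genus,
family, order, class or phylum).  `cssstax` solves this with a
nearest-neighbour classifier over a *combined sequence similarity score*
(CSSS): four heterogeneous measures of query-reference similarity are
rescaled to a common `[0, 1]` range and averaged, and the query receives
the rank-projected taxon of the reference with the highest combined
score.

The four measures capture complementary signal:

* **Alignment bit score.**  A seed-and-extend local aligner: exact
  `word_size` matches (default 11) between query and reference nominate
  diagonals, each diagonal is explored with a banded affine-gap
  Smith–Waterman (half-width 25), and the best raw score $S$ is rescaled
  to a bit score $S' = (\lambda S - \ln K)/\ln 2$ with $\lambda = 1.28$,
  $K = 0.46$ (classic megablast-style ungapped statistics).  The
  transform is monotone in $S$, which is all a rank-based classifier
  needs; recomputing exact Karlin–Altschul parameters per scoring scheme
  would change no decision.  Both strands of the query are scored and the
  better one kept.  When no seed word is shared the score is 0.
* **Euclidean distance** between canonical k-mer relative-abundance
  profiles.  A profile counts sliding windows of size $k$ (windows
  containing `N` are skipped) under canonical identification of a k-mer
  with its reverse complement, normalized to sum to one.
* **Jensen–Shannon divergence** between the same profiles,
  $\mathrm{JSD}(p,q) = H(m) - \tfrac{1}{2}(H(p)+H(q))$ with $m$ the
  pointwise average.  Entropies are in bits so the divergence is bounded
  by 1; the base is a convention we pin so that all measures live on
  comparable bounded scales.
* **Normalized compression distance**,
  $\mathrm{NCD}(x,y) = (C(xy) - \min(C(x),C(y)))/\max(C(x),C(y))$, the
  standard Li–Vitányi form, where $C$ is the size in bytes produced by a
  deterministic general-purpose compressor.  The default backend is xz
  (LZMA), chosen for its large dictionary: sequences are compressed in a
  single block so self-similarity is visible at any length we target,
  and concatenation order is fixed as (query, reference).  Any
  deterministic compressor can be substituted through
  `make_compressor()`.

## Normalization and combination

Raw measures are incommensurable (bit scores are unbounded similarities,
the rest are bounded or unbounded distances).  For each query we min-max
normalize each measure *across the reference set*: similarities keep
their orientation, distances are flipped, so 1 always marks the most
similar reference.  When a measure assigns every reference the same raw
value it carries no information for that query; its normalized vector is
set identically to 0, which leaves the ranking to the remaining measures
without biasing any reference.  The CSSS is the unweighted arithmetic
mean of the normalized similarities of the selected measures.  We chose
the unweighted mean deliberately: it is scale-free, order-preserving in
each component, and introduces no tunable weights that a small training
set could not support.

A query is reported *unclassified* only when every selected measure is
degenerate — no measure distinguishes any reference (for example a short
read sharing no seed word with any reference, scored by alignment
alone).  No CSSS floor is applied by default; `min_score` adds one when a
rejection threshold is wanted.  Ties at equal CSSS resolve to the
majority rank-projected taxon among the tied references, then to the
smallest taxid — an arbitrary but deterministic convention.

## Self-tuning by leave-one-out cross-validation

Before classification the package estimates its own operating point on
the training references:

1. **k-mer size.**  `select_k()` scans the database k-grid (default 2–6)
   and keeps the k maximizing joint LOOCV accuracy of the permitted
   measures, ties resolving to the smallest k (cheapest profiles).  With
   no k-dependent measure permitted the smallest grid k is returned by
   convention.
2. **Measure elimination.**  `eliminate_measures()` computes each
   candidate's standalone LOOCV accuracy and drops those at or below the
   majority-class baseline (the frequency of the most common label) —
   chance-level performance is the least arbitrary operationalization of
   "low predictive power", and it is directly testable by planting a
   random-similarity measure.  If everything would be dropped the single
   best measure is kept.
3. **Accuracy estimate.**  A final LOOCV pass with the surviving set
   yields the expected overall accuracy, stored with `k_opt` and the
   selected measures in the database manifest.

Every left-out sequence is scored against the full eligible pool minus
itself; unclassified counts as incorrect.  On large collections the
query side of LOOCV is subsampled to a cap (default 500, stratified by
label, seeded — the only randomness in the whole pipeline); the
reference pool is never subsampled.  Internally all LOOCV passes share
cached pairwise raw-score matrices built from the same kernels the
classifier uses, so the cross-validated decisions are bit-identical to
deployed classifications.

## The simulator: what it emulates and what it does not

`simulate_community()` generates the study conditions every test runs
under: a uniform random root genome accumulates substitutions down a
genus → species → strain hierarchy, each species' strains are split
2/3–1/3 into training and test (always at least one of each when a
species has two or more strains), and a matching six-rank taxonomy dump
is emitted.  Defaults — 5 genera × 4 species × 3 strains, 5-kb genomes,
divergences 0.30 (genus), 0.10 (species), 0.01 (strain) — are the
package's standard benchmark: genome length at the scale of typical
viral genomes, a strong but not saturating genus signal, and
within-species strains close enough that a training sibling is almost
always the true nearest neighbour.  `read_length` replaces each test
sequence by a uniformly placed substring from a uniformly chosen strand,
emulating unassembled single-end reads.

The model is substitution-only: no indels, no rearrangement, no
horizontal transfer, no sequencer error profiles, and genome length is
constant within a simulation.  Passing tests therefore demonstrate
correctness of the machinery and sane behaviour under hierarchical
composition signal; they do not demonstrate robustness to structural
variation or real error processes, and accuracies near 1.0 on these
fixtures should not be read as field performance.

One structural property of the generator is worth stating because it
shapes what parameter recovery can show.  When every species contributes
two or more strains to training, each left-out sequence has a
near-identical sibling (~2% divergence) in the pool, and that sibling is
the nearest neighbour under *every* measure at *every* k: LOOCV accuracy
saturates at 1.0 across the whole k-grid and `select_k()`'s tie rule
then returns the smallest k.  Discrimination between k values only
surfaces when species have a single training representative, forcing
classification to lean on the weaker genus-level composition signal —
there small k (2–3) genuinely degrades while k ≥ 4 stays accurate.

## Numerical and design choices

* Alignment scoring: match +1, mismatch −2, gap open −5, gap extend −2
  (a gap of length L costs `gap_open + L*gap_extend`); word size 11;
  band half-width 25.  The banded score is bounded above by the exact
  Smith–Waterman optimum and below by the longest shared substring times
  the match reward (when that substring is at least one word long) —
  both bounds are enforced in the test suite via independent oracles.
* Profiles use canonical (strand-insensitive) k-mers, so queries from
  either strand project onto the same coordinates; the aligner handles
  strand explicitly instead.
* Degenerate inputs: sequences shorter than k are accepted at ingest but
  rejected at profile time; queries shorter than k are reported
  unclassified with a reason rather than erroring a batch; all-`N`
  windows make a profile impossible and are an error.
* The reference database persists as a directory of flat text files
  (FASTA, TSV tables with `%.17g` numerics, a JSON manifest) — builds
  are deterministic and byte-identical, and profiles and compressed
  sizes round-trip exactly.  The alignment seed index (word codes and
  offsets over both strands of each reference) is rebuilt
  deterministically from the persisted sequences at load time rather
  than serialized.
* Reverse-complement hits are found by indexing both strands of each
  reference once at build time; classification shortlists references
  sharing at least one word code with the query before running any
  extension, so unrelated references cost one set intersection.

## Worked example

```{r}
library(cssstax)

sim <- simulate_community(sim_config(seed = 101))
db <- build_db(sim$training, sim$taxmap, sim$tree, k_grid = 2:6)
db <- tune(db, rank = "genus")       # LOOCV: picks k and the measure set
res <- classify_set(sim$test, db, "genus")
evaluate_results(res, sim$truth, sim$tree, "genus")
```

Problem sizes throughout the test suite follow the standard benchmark
above (30–45 training sequences, 0.5–10 kb genomes); they are chosen as
the smallest scales at which every property of interest — oracle
equivalence, measure elimination, generalization, short-read recall —
is already expressed.

## Known limitations

* The alignment measure is a heuristic: a true optimal alignment lying
  far from every seeded diagonal (possible only with long indels) can be
  missed; the simulator produces none, and for real data the band
  half-width is configurable.
* Min-max normalization makes each measure's contribution depend on the
  composition of the reference set, so CSSS values are comparable within
  a query, not across queries.
* The LOOCV accuracy estimate inherits the usual optimism when training
  sets contain near-duplicates (see the sibling saturation note above).
* Taxonomy handling covers the standard nodes/names dump dialect only;
  merged and deleted node files are not consulted.
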