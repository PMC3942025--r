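# Composition, overlaps, codon usage and start-codon statistics of annotated
# genomes, validated on hand-built records and against generator ground truth.

test_that("composition of a uniform-AT genome with one CDS is exact", {
  g <- genome_record("toy", "ATATATATAT", circular = FALSE,
                     features = list(feature("cds1", "CDS", "+", 1, 5)))
  s <- summarize_composition(g)
  expect_identical(s$genome_length, 10L)
  expect_equal(s$at_overall, 1.0)
  expect_equal(s$coding_fraction, 0.5)
  expect_equal(s$at_coding, 1.0)
  expect_equal(s$coding_bases + s$noncoding_bases, s$genome_length)
})

test_that("composition rejects degenerate input", {
  expect_error(genome_record("x", ""), "empty")
  expect_error(genome_record("x", "ACGT", circular = FALSE,
                             features = list(feature("f", "CDS", "+", 3, 2))),
               "origin-wrapping")
  expect_error(genome_record("x", "ACGT", circular = FALSE,
                             features = list(feature("f", "CDS", "+", 2, 9))),
               "outside")
})

test_that("pseudogenes count as noncoding", {
  g <- genome_record("toy", paste(rep("ACGT", 25), collapse = ""),
                     circular = FALSE,
                     features = list(feature("cds1", "CDS", "+", 1, 60),
                                     feature("psi1", "pseudogene", "+", 70, 90)))
  s <- summarize_composition(g)
  expect_equal(s$coding_bases, 60)
})

test_that("overlap detection handles plain, nested and origin-wrapping pairs", {
  seq100 <- paste(rep("ACGT", 50), collapse = "")
  g <- genome_record("lin", seq100, circular = FALSE,
                     features = list(feature("a", "CDS", "+", 1, 100),
                                     feature("b", "CDS", "-", 90, 150)))
  ov <- find_overlapping_pairs(g)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlap_bp, 11L)

  gc <- genome_record("circ", paste(rep("ACGT", 25), collapse = ""),
                      circular = TRUE,
                      features = list(feature("w", "CDS", "+", 95, 10),
                                      feature("b", "CDS", "+", 5, 20)))
  ovc <- find_overlapping_pairs(gc)
  expect_equal(ovc$overlap_bp, 6L)
  expect_equal(ovc, overlap_oracle(gc))
})

test_that("overlap detection matches the per-base oracle on random toy genomes", {
  set.seed(101)
  for (i in 1:20) {
    tg <- make_toy_genome(length = sample(300:500, 1), coding_fraction = 0.8,
                          n_cds = 4, n_rrna = 0, n_trna = 1,
                          n_overlap_pairs = sample(0:1, 1),
                          initiator_cau = FALSE, seed = i)
    got <- find_overlapping_pairs(tg$genome, kinds = c("CDS", "rRNA", "tRNA"))
    ora <- overlap_oracle(tg$genome, kinds = c("CDS", "rRNA", "tRNA"))
    o1 <- got[order(got$id1, got$id2), ]
    o2 <- ora[order(ora$id1, ora$id2), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2)
  }
})

test_that("codon usage counts the annotated frame on either strand", {
  g <- genome_record("p", "ATGAAATAA", circular = FALSE,
                     features = list(feature("c1", "CDS", "+", 1, 9)))
  u <- codon_usage(g)
  expect_equal(unname(u$counts[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(u$counts), 3L)
  expect_equal(unname(u$frequencies[c("ATG", "AAA", "TAA")]), rep(1 / 3, 3))
  expect_equal(sum(u$frequencies), 1)
  expect_equal(unname(u$stop_counts["TAA"]), 1L)

  gm <- genome_record("m", mtevo:::revcomp("ATGAAATAA"), circular = FALSE,
                      features = list(feature("c1", "CDS", "-", 1, 9)))
  expect_identical(codon_usage(gm)$counts, u$counts)
})

test_that("codon usage skips out-of-frame CDS with a warning and drops ambiguous codons", {
  g <- genome_record("p", "ATGAAATAAC", circular = FALSE,
                     features = list(feature("bad", "CDS", "+", 1, 10)))
  expect_warning(u <- codon_usage(g), "not divisible by 3")
  expect_equal(sum(u$counts), 0L)

  gn <- genome_record("n", "ATGANATAA", circular = FALSE,
                      features = list(feature("c1", "CDS", "+", 1, 9)))
  un <- codon_usage(gn)
  expect_equal(sum(un$counts), 2L)  # middle codon ANA excluded
})

test_that("excluding URFs changes only URF-derived counts", {
  g <- genome_record("p", "ATGAAATAAATGCCCTAA", circular = FALSE,
                     features = list(feature("cox1", "CDS", "+", 1, 9),
                                     feature("URF77", "CDS", "+", 10, 18)))
  all_u <- codon_usage(g, include_urfs = TRUE)
  no_u <- codon_usage(g, include_urfs = FALSE)
  expect_equal(unname(all_u$counts["CCC"]), 1L)
  expect_equal(unname(no_u$counts["CCC"]), 0L)
  shared <- setdiff(names(all_u$counts), c("ATG", "CCC", "TAA"))
  expect_identical(all_u$counts[shared], no_u$counts[shared])
  expect_equal(unname(all_u$counts["ATG"] - no_u$counts["ATG"]), 1L)
})

test_that("nonstandard start codons are listed and ATG starts are not", {
  g <- genome_record("p", "ATGAAATAAGTGCCCTAA", circular = FALSE,
                     features = list(feature("c1", "CDS", "+", 1, 9),
                                     feature("c2", "CDS", "+", 10, 18)))
  ns <- nonstandard_starts(g)
  expect_equal(ns$feature_id, "c2")
  expect_equal(ns$start_codon, "GTG")
})

test_that("composition identities hold on random toy genomes", {
  set.seed(202)
  for (i in 1:25) {
    tg <- make_toy_genome(length = sample(900:1500, 1),
                          coding_fraction = runif(1, 0.65, 0.95),
                          n_cds = sample(3:6, 1), n_trna = sample(1:2, 1),
                          n_overlap_pairs = 1, seed = i)
    s <- summarize_composition(tg$genome)
    expect_equal(s$coding_bases + s$noncoding_bases, s$genome_length)
    expect_equal(s$at_overall,
                 (s$at_coding * s$coding_bases +
                    s$at_noncoding * s$noncoding_bases) / s$genome_length,
                 tolerance = 1e-12)
    expect_equal(s$coding_fraction, tg$truth$coding_fraction)
    expect_equal(s$at_overall, tg$truth$at_overall)
  }
})
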