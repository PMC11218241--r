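test_that("toy aligner scores identity, rejects empty input, degrades with mismatches", {
  h <- toy_align("ACGTACGT", "ACGTACGT")
  expect_equal(h$pct_identity, 100)
  expect_equal(h$aln_length, 8L)
  expect_gt(h$bitscore, 0)

  # no positive-scoring local alignment
  h0 <- toy_align("AAAA", "CCCC", match = 1, mismatch = -1)
  expect_equal(h0$bitscore, 0)
  expect_equal(h0$aln_length, 0L)

  h1 <- toy_align("ACGTACGT", "ACGTTCGT")
  expect_gte(h$bitscore, h1$bitscore)

  expect_error(toy_align("", "ACGT"), "empty")

  p <- toy_align("MKVLAT", "MKVLAT", type = "protein")
  expect_equal(p$pct_identity, 100)
})

test_that("weight normalization follows the max-self-score rule", {
  gmap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  hit <- function(q, t, bits) data.frame(
    query_id = q, target_id = t, pct_identity = 90, aln_length = 100L,
    mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 100L,
    tstart = 1L, tend = 100L, evalue = 1e-30, bitscore = bits)
  hits <- rbind(hit("a1", "a1", 100), hit("b1", "b1", 80),
                hit("a1", "b1", 90))
  w <- normalize_weights(hits, gmap)
  expect_equal(w$weight, 0.90)

  # below-threshold edges are dropped
  hits2 <- rbind(hit("a1", "a1", 100), hit("b1", "b1", 100),
                 hit("a1", "b1", 55))
  expect_equal(nrow(normalize_weights(hits2, gmap, edge_threshold = 0.6)), 0L)
  expect_equal(nrow(normalize_weights(hits2, gmap, edge_threshold = 0.5)), 1L)

  # same-genome pairs never become edges
  hits3 <- rbind(hit("a1", "a1", 100), hit("a2", "a2", 100),
                 hit("a1", "a2", 95))
  expect_equal(nrow(normalize_weights(hits3, gmap)), 0L)

  # reciprocal hits collapse to the larger bitscore
  hits4 <- rbind(hit("a1", "a1", 100), hit("b1", "b1", 100),
                 hit("a1", "b1", 70), hit("b1", "a1", 90))
  expect_equal(normalize_weights(hits4, gmap)$weight, 0.90)

  # missing self-score is an error naming the gene
  expect_error(normalize_weights(rbind(hit("a1", "a1", 100),
                                       hit("a1", "b1", 90)), gmap), "b1")
})

test_that("normalized weights are invariant under bitscore rescaling", {
  gmap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  set.seed(5)
  base <- data.frame(
    query_id = c("a1", "a2", "b1", "b2", "a1", "a2", "a1"),
    target_id = c("a1", "a2", "b1", "b2", "b1", "b2", "b2"),
    pct_identity = 90, aln_length = 100L, mismatches = 0L, gap_opens = 0L,
    qstart = 1L, qend = 100L, tstart = 1L, tend = 100L, evalue = 0,
    bitscore = c(100, 120, 90, 110, 85, 100, 70))
  w1 <- normalize_weights(base, gmap)
  scaled <- base
  scaled$bitscore <- scaled$bitscore * 7.3
  w2 <- normalize_weights(scaled, gmap)
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("POCP formula, symmetry and filter monotonicity hold", {
  qlen <- c(a1 = 100, a2 = 100, a3 = 100, a4 = 100,
            b1 = 100, b2 = 100, b3 = 100, b4 = 100, b5 = 100, b6 = 100)
  hit <- function(q, t, id = 80, len = 80L, ev = 1e-30) data.frame(
    query_id = q, target_id = t, pct_identity = id, aln_length = len,
    mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 100L,
    tstart = 1L, tend = 100L, evalue = ev, bitscore = 200)
  # 3 of 4 conserved one way, 3 of 6 the other: POCP = 100*6/10 = 60
  ab <- rbind(hit("a1", "b1"), hit("a2", "b2"), hit("a3", "b3"))
  ba <- rbind(hit("b1", "a1"), hit("b2", "a2"), hit("b3", "a3"))
  p <- compute_pocp(ab, ba, 4, 6, qlen)
  expect_equal(p$pocp, 60.0)

  # symmetric under swapping the genomes
  p2 <- compute_pocp(ba, ab, 6, 4, qlen)
  expect_equal(p2$pocp, p$pocp)

  # identical proteomes, all reciprocally conserved
  ab5 <- do.call(rbind, lapply(1:4, function(i)
    hit(paste0("a", i), paste0("b", i))))
  ba5 <- do.call(rbind, lapply(1:4, function(i)
    hit(paste0("b", i), paste0("a", i))))
  expect_equal(compute_pocp(ab5, ba5, 4, 4, qlen)$pocp, 100.0)

  # no passing hits
  none <- ab[0, ]
  expect_equal(compute_pocp(none, none, 4, 6, qlen)$pocp, 0.0)

  # strict thresholds: identity exactly 40 fails, just above passes
  at40 <- rbind(hit("a1", "b1", id = 40))
  expect_equal(compute_pocp(at40, none, 4, 6, qlen)$conserved_a, 0L)
  just <- rbind(hit("a1", "b1", id = 40.01))
  expect_equal(compute_pocp(just, none, 4, 6, qlen)$conserved_a, 1L)

  # relaxing any filter never decreases POCP
  mixed <- rbind(hit("a1", "b1", id = 35), hit("a2", "b2", ev = 1e-3),
                 hit("a3", "b3", len = 45L))
  base <- compute_pocp(mixed, none, 4, 6, qlen)$pocp
  expect_gte(compute_pocp(mixed, none, 4, 6, qlen,
                          identity_min = 30)$pocp, base)
  expect_gte(compute_pocp(mixed, none, 4, 6, qlen,
                          evalue_max = 1e-2)$pocp, base)
  expect_gte(compute_pocp(mixed, none, 4, 6, qlen,
                          aln_frac_min = 0.4)$pocp, base)

  expect_error(compute_pocp(ab, ba, 0, 6, qlen), "zero")
})

test_that("POCP matrix is symmetric with unit diagonal and records the mean", {
  cfg <- sim_config(n_genomes = 3, genes_per_genome = 6, inversions = 0,
                    seed = 9)
  sim <- simulate_pangenome(cfg)
  m <- pocp_matrix(sim$hits, sim$genomes)
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(attr(m, "mean"), mean(m[upper.tri(m)]))
})
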