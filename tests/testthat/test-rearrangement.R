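test_that("similarity graph keeps isolated vertices and deduplicates edges", {
  A <- mk_genome("A", c("a1", "a2", "a3"))
  B <- mk_genome("B", c("b1", "b2", "b3"))
  gs <- build_gs_graph(A, B, identity_edges(c("a1", "a2", "a3"),
                                            c("b1", "b2", "b3"), 0.9))
  expect_equal(nrow(gs$edges), 3L)

  # duplicate edge collapses to max weight
  dup <- rbind(identity_edges("a1", "b1", 0.7), identity_edges("a1", "b1", 0.9))
  gs2 <- build_gs_graph(A, B, dup)
  expect_equal(nrow(gs2$edges), 1L)
  expect_equal(gs2$edges$weight, 0.9)

  # isolated genes remain as singleton components
  comps <- gs_components(gs2)
  expect_equal(length(comps), 5L)

  expect_error(build_gs_graph(A, B, identity_edges("a1", "zz", 1)),
               "unknown gene")
})

test_that("component decomposition and the trivial-case rule", {
  A <- mk_genome("A", c("a1", "a2"))
  B <- mk_genome("B", c("b1", "b2", "b3"))
  ed <- data.frame(gene_a = c("a1", "a1", "a2"),
                   gene_b = c("b1", "b2", "b3"),
                   weight = c(0.8, 0.7, 0.9))
  comps <- gs_components(build_gs_graph(A, B, ed))
  expect_equal(length(comps), 2L)
  triv <- vapply(comps, is_trivial_component, logical(1L))
  expect_equal(sum(triv), 1L)
  # the a1-{b1,b2} component is ambiguous, not trivial
  amb <- comps[[which(!triv)]]
  expect_setequal(amb$genes_b, c("b1", "b2"))

  # an isolated gene is a forced singleton, not a trivial mapping
  C <- mk_genome("C", "c1")
  D <- mk_genome("D", "d1")
  iso <- gs_components(build_gs_graph(C, D, identity_edges(character(),
                                                           character())[0, ]))
  expect_false(any(vapply(iso, is_trivial_component, logical(1L))))
})

test_that("genome reduction removes singletons and preserves circular order", {
  A <- mk_genome("A", c("a1", "a2", "a3"))
  B <- mk_genome("B", c("b1", "b3"))
  m <- data.frame(gene_a = c("a1", "a3"), gene_b = c("b1", "b3"))
  red <- reduce_genomes(A, B, m)
  expect_equal(red$a$c1$genes, c("a1", "a3"))
  expect_equal(red$b$c1$genes, c("b1", "b3"))

  # no singletons: identity
  m2 <- data.frame(gene_a = c("a1", "a2", "a3"), gene_b = c("x", "y", "z"))
  expect_equal(reduce_genomes(A, A, m2)$a$c1$genes, c("a1", "a2", "a3"))

  # everything unmatched: empty reduced genome
  m0 <- data.frame(gene_a = character(), gene_b = character())
  expect_equal(length(reduce_genomes(A, B, m0)$a), 0L)
})

test_that("adjacency graph cycle structure on hand-built cases", {
  A <- mk_genome("A", c("a1", "a2", "a3"))
  B <- mk_genome("B", c("b1", "b2", "b3"))
  m <- data.frame(gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3"))

  # identical circular genomes: three 2-cycles, all fixed
  red <- reduce_genomes(A, B, m)
  ag <- build_adjacency_graph(red$a, red$b, m)
  expect_equal(ag$cycles, 3L)
  expect_equal(ag$fixed_components, 3L)

  # middle gene inverted: one 2-cycle + one 4-cycle
  Binv <- mk_genome("B", c("b1", "b2", "b3"), c("+", "-", "+"))
  red2 <- reduce_genomes(A, Binv, m)
  ag2 <- build_adjacency_graph(red2$a, red2$b, m)
  expect_equal(ag2$cycles, 2L)
  expect_setequal(ag2$cycle_lengths, c(2L, 4L))

  # empty reduced genomes
  m0 <- data.frame(gene_a = character(), gene_b = character())
  expect_equal(build_adjacency_graph(list(), list(), m0)$cycles, 0L)
})

test_that("adjacency graphs decompose into cycles covering every adjacency", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    gs <- build_gs_graph(inst$A, inst$B, inst$edges)
    # take a maximal greedy matching
    m <- pangraft:::greedy_matching(gs$edges)
    if (nrow(m) == 0L) next
    red <- reduce_genomes(inst$A, inst$B, m)
    ag <- build_adjacency_graph(red$a, red$b, m)
    # total cycle length equals the number of adjacencies on both sides
    expect_equal(sum(ag$cycle_lengths),
                 length(ag$a_adjacencies) + length(ag$b_adjacencies))
    # cycle count never exceeds the matching size
    expect_lte(ag$cycles, nrow(m))
  }
})

test_that("brute-force oracle reproduces the closed-form cases", {
  A <- mk_genome("A", c("a1", "a2", "a3"))
  B <- mk_genome("B", c("b1", "b2", "b3"))
  ed <- identity_edges(c("a1", "a2", "a3"), c("b1", "b2", "b3"))

  for (al in c(0, 0.25, 0.5, 1)) {
    expect_equal(brute_force_ffdcj_indel(A, B, ed, alpha = al)$distance, 0)
  }

  # one inversion, unit weights, alpha = 1: distance |M| - c = 3 - 2 = 1
  Binv <- mk_genome("B", c("b1", "b2", "b3"), c("+", "-", "+"))
  o <- brute_force_ffdcj_indel(A, Binv, ed, alpha = 1)
  expect_equal(o$distance, 1)
  expect_equal(o$cycles, 2L)

  # deletion: S = 1, I = 1, c = |M| = 2 -> d = alpha * 2 = 1 at alpha 0.5
  B2 <- mk_genome("B", c("b1", "b3"))
  ed2 <- identity_edges(c("a1", "a3"), c("b1", "b3"))
  o2 <- brute_force_ffdcj_indel(A, B2, ed2, alpha = 0.5)
  expect_equal(o2$distance, 1.0)
  expect_equal(o2$singletons, 1L)
  expect_equal(o2$blocks, 1L)

  # guard against oversized enumeration
  big <- mk_genome("A", sprintf("a%d", 1:9))
  expect_error(brute_force_ffdcj_indel(big, B, ed), "ILP")
})

test_that("oracle distance is non-negative and bounded by applied operations", {
  for (seed in 1:10) {
    inst <- random_instance(seed + 100)
    for (al in c(0, 0.5, 1)) {
      expect_gte(brute_force_ffdcj_indel(inst$A, inst$B, inst$edges,
                                         alpha = al)$distance, -1e-12)
    }
  }
  # k inversions: unit-weight alpha-1 distance <= k
  for (seed in 1:8) {
    k <- sample(1:3, 1)
    cfg <- sim_config(genes_per_genome = 6, inversions = k, tier = c(1, 1),
                      seed = seed)
    sim <- simulate_genome_pair(cfg)
    d <- brute_force_ffdcj_indel(sim$genome_a, sim$genome_b, sim$edges,
                                 alpha = 1)$distance
    expect_lte(d, k)
    expect_gte(d, 0)
  }
})

test_that("independent circular DCJ cross-check agrees with the oracle at alpha 1", {
  # hand-built inversion and transposition cases on shared gene labels
  X <- mk_genome("X", c("g1", "g2", "g3", "g4"))
  Yinv <- mk_genome("Y", c("g1", "g2", "g3", "g4"), c("+", "-", "-", "+"))
  # same case expressed as a bipartite instance with distinct IDs
  A <- mk_genome("A", c("a1", "a2", "a3", "a4"))
  Binv <- mk_genome("B", c("b1", "b2", "b3", "b4"), c("+", "-", "-", "+"))
  ed <- identity_edges(paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(brute_force_ffdcj_indel(A, Binv, ed, alpha = 1)$distance,
               dcj_distance_circular(X, Yinv))

  # transposition: (1,2,3,4) -> (1,3,4,2)
  Ytrans <- genome("Y", data.frame(
    gene_id = c("g1", "g3", "g4", "g2"), contig_id = "c1",
    start = c(1, 101, 201, 301), end = c(80, 180, 280, 380), strand = "+"))
  Btrans <- genome("B", data.frame(
    gene_id = c("b1", "b3", "b4", "b2"), contig_id = "c1",
    start = c(1, 101, 201, 301), end = c(80, 180, 280, 380), strand = "+"))
  expect_equal(brute_force_ffdcj_indel(A, Btrans, ed, alpha = 1)$distance,
               dcj_distance_circular(X, Ytrans))
  expect_equal(dcj_distance_circular(X, Ytrans), 2)
})
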