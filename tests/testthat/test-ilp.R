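test_that("formulation encodes the objective and trivial substitutions", {
  A <- mk_genome("A", "a1")
  B <- mk_genome("B", "b1")
  gs <- build_gs_graph(A, B, identity_edges("a1", "b1", 0.8))
  comp <- gs_components(gs)[[1]]
  alpha <- 0.5
  inst <- formulate(comp, alpha = alpha)
  expect_s3_class(inst, "ffdcj_ilp")
  expect_equal(inst$max_matching_size, 1L)
  # single-edge component at x = 1: d = alpha*(1-1) + (1-alpha)*(1-w)
  sol <- solve_ilp(inst)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$distance, (1 - alpha) * (1 - 0.8))

  # identical 3-gene circular component: optimum 0
  A3 <- mk_genome("A", c("a1", "a2", "a3"))
  B3 <- mk_genome("B", c("b1", "b2", "b3"))
  ed3 <- identity_edges(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  full <- ffdcj_indel_distance(A3, B3, ed3, alpha = 0.5)
  expect_equal(full$distance, 0)
  expect_equal(full$cycles, full$matching |> nrow())

  # a fully isolated gene costs the double indel penalty 2*alpha
  for (alpha in c(0.25, 0.5, 1)) {
    iso <- ffdcj_indel_distance(mk_genome("A", "a1"), mk_genome("B", "b1"),
                                identity_edges(character(), character())[0, ],
                                alpha = alpha)
    expect_equal(iso$distance, 2 * alpha * 2)  # two genomes, one singleton each
  }

  expect_error(formulate(structure(list(genes_a = character(),
                                        genes_b = character()),
                                   class = "gs_component")), "empty")
})

test_that("ILP optimum equals brute-force enumeration on random instances", {
  alphas <- c(0, 0.5, 1)
  for (seed in 1:30) {
    inst <- random_instance(seed + 500)
    al <- alphas[(seed %% 3) + 1]
    o <- brute_force_ffdcj_indel(inst$A, inst$B, inst$edges, alpha = al)
    s <- ffdcj_indel_distance(inst$A, inst$B, inst$edges, alpha = al)
    expect_equal(s$distance, o$distance, tolerance = 1e-6,
                 label = sprintf("seed %d alpha %g ilp", seed, al),
                 expected.label = "oracle")
    # the solver's internal checks also recompute the distance on the
    # adjacency graph and against the constraint matrix
    expect_equal(s$status, "optimal")
  }
})

test_that("alpha 1 with unit weights reduces to classical circular DCJ", {
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    cfg <- sim_config(genes_per_genome = n, inversions = sample(0:2, 1),
                      transpositions = sample(0:1, 1), tier = c(1, 1),
                      seed = 1000 + rep)
    sim <- simulate_genome_pair(cfg)
    s <- ffdcj_indel_distance(sim$genome_a, sim$genome_b, sim$edges, alpha = 1)
    # relabel genome B with A's gene IDs to apply the one-to-one DCJ check
    pair <- sim$truth$pairs
    bt <- sim$genome_b$genes
    bt$gene_id <- pair$gene_a[match(bt$gene_id, pair$gene_b)]
    expect_equal(s$distance,
                 dcj_distance_circular(sim$genome_a, genome("Br", bt)))
  }
})

test_that("alpha 0 maximizes matching weight among maximum matchings", {
  for (seed in 1:8) {
    inst <- random_instance(seed + 900, max_genes = 4L)
    s <- ffdcj_indel_distance(inst$A, inst$B, inst$edges, alpha = 0)
    # independent combinatorial check: enumerate matchings of maximum
    # cardinality directly from the edge list
    ed <- inst$edges
    K <- nrow(s$matching)
    best_w <- 0
    enum <- function(i, used_a, used_b, w, size) {
      if (i > nrow(ed)) {
        if (size == K) best_w <<- max(best_w, w)
        return(invisible())
      }
      if (!(ed$gene_a[i] %in% used_a) && !(ed$gene_b[i] %in% used_b)) {
        enum(i + 1L, c(used_a, ed$gene_a[i]), c(used_b, ed$gene_b[i]),
             w + ed$weight[i], size + 1L)
      }
      enum(i + 1L, used_a, used_b, w, size)
    }
    enum(1L, character(), character(), 0, 0L)
    expect_equal(s$omega, best_w, tolerance = 1e-9)
    expect_equal(s$distance, K - best_w, tolerance = 1e-9)
  }
})

test_that("matching cardinality always equals the bipartite maximum", {
  for (seed in 1:10) {
    inst <- random_instance(seed + 300)
    gs <- build_gs_graph(inst$A, inst$B, inst$edges)
    K <- pangraft:::max_matching_size(pangraft:::make_instance(gs))
    s <- ffdcj_indel_distance(inst$A, inst$B, inst$edges,
                              alpha = c(0, 0.5, 1)[(seed %% 3) + 1])
    expect_equal(nrow(s$matching), K)
  }
})

test_that("a longer time limit never worsens the reported distance", {
  set.seed(321)
  n <- 6L
  A <- mk_genome("A", sprintf("a%d", 1:n), sample(c("+", "-"), n, TRUE))
  B <- mk_genome("B", sprintf("b%d", 1:n), sample(c("+", "-"), n, TRUE))
  ed <- expand.grid(gene_a = sprintf("a%d", 1:n),
                    gene_b = sprintf("b%d", 1:n), stringsAsFactors = FALSE)
  ed$weight <- round(stats::runif(nrow(ed), 0.6, 1), 3)
  short <- ffdcj_indel_distance(A, B, ed, alpha = 0.5, time_limit_s = 0.05)
  long <- ffdcj_indel_distance(A, B, ed, alpha = 0.5, time_limit_s = 60)
  expect_equal(short$status, "feasible_timeout")
  expect_equal(long$status, "optimal")
  expect_lte(long$distance, short$distance + 1e-9)
})

test_that("pairwise refinement shortcuts trivial components and stays deterministic", {
  A <- mk_genome("A", c("a1", "a2", "a3"))
  B <- mk_genome("B", c("b1", "b2", "b3"))
  ed <- identity_edges(c("a1", "a2", "a3"), c("b1", "b2", "b3"), 0.95)
  hp <- pairwise_refine(A, B, ed)
  expect_equal(nrow(hp$pairs), 3L)
  expect_true(all(hp$pairs$source == "trivial"))
  expect_equal(hp$stats$n_ilp, 0L)

  # empty edge set: no pairs, all genes singleton
  hp0 <- pairwise_refine(A, B, ed[0, ])
  expect_equal(nrow(hp0$pairs), 0L)
  expect_equal(length(hp0$singletons), 6L)

  hp2 <- pairwise_refine(A, B, ed)
  expect_identical(hp$pairs, hp2$pairs)
})

test_that("gene order overrides a small similarity advantage (synteny rescue)", {
  # a2 and a4 each have two candidates; the higher-weight assignment
  # permutes gene order, the lower-weight one is syntenic
  A <- mk_genome("A", c("a1", "a2", "a3", "a4"))
  B <- mk_genome("B", c("b1", "b2", "b3", "b4"))
  ed <- rbind(identity_edges(c("a1", "a3"), c("b1", "b3"), 1),
              data.frame(gene_a = c("a2", "a2", "a4", "a4"),
                         gene_b = c("b2", "b4", "b4", "b2"),
                         weight = c(0.61, 0.62, 0.61, 0.62)))
  o <- brute_force_ffdcj_indel(A, B, ed, alpha = 0.5)
  expect_true(all(c("a2|b2", "a4|b4") %in%
                    paste(o$matching$gene_a, o$matching$gene_b, sep = "|")))
  s <- ffdcj_indel_distance(A, B, ed, alpha = 0.5)
  expect_equal(s$distance, o$distance, tolerance = 1e-9)
  expect_setequal(paste(s$matching$gene_a, s$matching$gene_b),
                  paste(o$matching$gene_a, o$matching$gene_b))
  # at alpha 0 the similarity advantage wins instead
  s0 <- ffdcj_indel_distance(A, B, ed, alpha = 0)
  expect_true("a2" %in% s0$matching$gene_a &&
                s0$matching$gene_b[s0$matching$gene_a == "a2"] == "b4")
})

test_that("LP-format dumps are written when requested", {
  A <- mk_genome("A", c("a1", "a2"))
  B <- mk_genome("B", c("b1", "b2"))
  ed <- data.frame(gene_a = c("a1", "a1", "a2"),
                   gene_b = c("b1", "b2", "b2"),
                   weight = c(0.9, 0.8, 0.85))
  dir <- withr::local_tempdir()
  hp <- pairwise_refine(A, B, ed, keep_ilps = dir)
  lp_files <- list.files(dir, pattern = "\\.lp$")
  expect_gte(length(lp_files), 1L)
  txt <- readLines(file.path(dir, lp_files[1]))
  expect_true(any(grepl("^Minimize$", txt)))
  expect_true(any(grepl("Subject To", txt)))
})
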