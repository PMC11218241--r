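# three genomes with one gene each per family is the recurring fixture here
three_genomes <- function() {
  list(mk_genome("gA", c("a1", "a2")), mk_genome("gB", c("b1", "b2")),
       mk_genome("gC", c("c1", "c2")))
}

test_that("cluster merging reproduces the three canonical scenarios", {
  gmap <- c(a1 = "gA", b1 = "gB", c1 = "gC", d1 = "gD", e1 = "gE",
            a2 = "gA")
  # trivial: one cluster, no cross-cluster pairs -> one group unchanged
  sc <- scaffold_clusters(list(cl1 = c("a1", "b1", "c1", "d1", "e1")))
  pairs0 <- data.frame(gene_a = character(), gene_b = character())
  pre <- merge_clusters(sc, pairs0, all_genes = names(gmap)[1:5])
  expect_equal(length(pre), 1L)
  expect_setequal(pre[[1]]$members, c("a1", "b1", "c1", "d1", "e1"))

  # merge-of-two: clusters of 3 and 2 linked by one homology pair
  sc2 <- scaffold_clusters(list(cl1 = c("a1", "b1", "c1"),
                                cl2 = c("d1", "e1")))
  pairs1 <- data.frame(gene_a = "c1", gene_b = "d1")
  pre2 <- merge_clusters(sc2, pairs1, all_genes = names(gmap)[1:5])
  expect_equal(length(pre2), 1L)
  expect_equal(length(pre2[[1]]$members), 5L)
  expect_setequal(pre2[[1]]$provenance, c("cl1", "cl2"))

  # unclustered genes join via pairs or become singleton groups
  sc3 <- scaffold_clusters(list(cl1 = c("a1", "b1")))
  pre3 <- merge_clusters(sc3, data.frame(gene_a = "b1", gene_b = "c1"),
                         all_genes = c("a1", "b1", "c1", "d1"))
  expect_equal(length(pre3), 2L)
  expect_setequal(pre3[[1]]$members, c("a1", "b1", "c1"))
  expect_equal(pre3[[2]]$members, "d1")
})

test_that("paralog resolution follows the tie-breaking ladder", {
  gmap <- c(a1 = "gA", a2 = "gA", b1 = "gB", c1 = "gC", d1 = "gD",
            e1 = "gE")
  members <- c("a1", "a2", "b1", "c1", "d1", "e1")

  # rule 1: connection counts decide (a1: 4 links, a2: 1)
  pairs <- data.frame(
    gene_a = c("a1", "a1", "a1", "a1", "a2"),
    gene_b = c("b1", "c1", "d1", "e1", "b1"))
  res <- resolve_paralogs(members, "group7", pairs, gmap)
  ids <- vapply(res, `[[`, character(1L), "group_id")
  expect_setequal(ids, c("group7", "group7.1"))
  top <- res[[which(ids == "group7")]]
  expect_true("a1" %in% top$members)
  sub <- res[[which(ids == "group7.1")]]
  expect_true("a2" %in% sub$members)

  # rule 2: tie on connections, larger scaffold cluster wins
  pairs2 <- data.frame(gene_a = c("a1", "a1", "a2", "a2"),
                       gene_b = c("b1", "c1", "d1", "e1"))
  cs <- c(a1 = 2, a2 = 5, b1 = 2, c1 = 2, d1 = 5, e1 = 5)
  res2 <- resolve_paralogs(members, "g", pairs2, gmap, cluster_size = cs)
  top2 <- res2[[which(vapply(res2, `[[`, character(1L), "group_id") == "g")]]
  expect_true("a2" %in% top2$members)

  # rule 3: persistent tie resolved by majority gene name, ignoring
  # hypothetical-protein placeholders
  nm <- c(a1 = "hypothetical protein", a2 = "ompA", b1 = "ompA",
          c1 = "ompA", d1 = "hypothetical protein", e1 = "ompA")
  res3 <- resolve_paralogs(members, "g", pairs2, gmap,
                           cluster_size = c(a1 = 3, a2 = 3),
                           gene_names = nm)
  top3 <- res3[[which(vapply(res3, `[[`, character(1L), "group_id") == "g")]]
  expect_true("a2" %in% top3$members)

  # rule 4: lexicographic fallback
  res4 <- resolve_paralogs(c("a1", "a2", "b1"), "g",
                           pairs2[0, ], gmap)
  top4 <- res4[[which(vapply(res4, `[[`, character(1L), "group_id") == "g")]]
  expect_true("a1" %in% top4$members)
})

test_that("paralogous merge yields a subgroup with the .1 suffix", {
  gmap <- c(a1 = "gA", a2 = "gA", b1 = "gB", c1 = "gC")
  genomes <- list(mk_genome("gA", c("a1", "a2")), mk_genome("gB", "b1"),
                  mk_genome("gC", "c1"))
  sc <- scaffold_clusters(list(cl1 = c("a1", "b1", "c1"), cl2 = "a2"))
  pairs <- data.frame(gene_a = c("a1", "a1", "a2"),
                      gene_b = c("b1", "c1", "c1"))
  pre <- merge_clusters(sc, pairs, all_genes = names(gmap))
  expect_equal(length(pre), 1L)
  gt <- build_group_table(pre, pairs, sc, genomes)
  expect_setequal(rownames(gt$presence), c("group1", "group1.1"))
  # each gene in exactly one group; at most one member per genome
  all_members <- unlist(lapply(gt$groups, function(g)
    unlist(g$members, use.names = FALSE)))
  expect_setequal(all_members, names(gmap))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("every gene lands in exactly one group (partition invariant)", {
  for (seed in c(2, 5, 8)) {
    cfg <- sim_config(n_genomes = 4, genes_per_genome = 7,
                      core_fraction = 0.7, duplications = 1,
                      inversions = 1, seed = seed)
    sim <- simulate_pangenome(cfg)
    res <- run_pipeline(sim$genomes, edges = sim$edges, compute_pocp = FALSE,
                        seed = seed)
    gt <- res$group_table
    all_members <- unlist(lapply(gt$groups, function(g)
      unlist(g$members, use.names = FALSE)))
    all_genes <- unlist(lapply(sim$genomes, function(g) g$genes$gene_id))
    expect_setequal(all_members, all_genes)
    expect_equal(anyDuplicated(all_members), 0L)
    expect_equal(sum(gt$presence), length(all_genes))
  }
})

test_that("group IDs are invariant to genome input order", {
  cfg <- sim_config(n_genomes = 4, genes_per_genome = 6, inversions = 1,
                    seed = 13)
  sim <- simulate_pangenome(cfg)
  r1 <- run_pipeline(sim$genomes, edges = sim$edges, compute_pocp = FALSE,
                     seed = 1)
  r2 <- run_pipeline(rev(sim$genomes), edges = sim$edges[rev(seq_len(nrow(sim$edges))), ],
                     compute_pocp = FALSE, seed = 1)
  expect_identical(r1$group_table$presence, r2$group_table$presence)
  expect_identical(group_ids <- vapply(r1$group_table$groups, `[[`,
                                       character(1L), "group_id"),
                   vapply(r2$group_table$groups, `[[`, character(1L),
                          "group_id"))
})

test_that("adding homology pairs never increases the number of top-level groups", {
  sc <- scaffold_clusters(list(cl1 = c("a1", "b1"), cl2 = c("c1", "d1"),
                               cl3 = "e1"))
  genes <- c("a1", "b1", "c1", "d1", "e1")
  n_top <- function(pairs) {
    length(merge_clusters(sc, pairs, all_genes = genes))
  }
  p0 <- data.frame(gene_a = character(), gene_b = character())
  p1 <- data.frame(gene_a = "b1", gene_b = "c1")
  p2 <- rbind(p1, data.frame(gene_a = "d1", gene_b = "e1"))
  expect_gte(n_top(p0), n_top(p1))
  expect_gte(n_top(p1), n_top(p2))
  expect_equal(n_top(p2), 1L)
})

test_that("core extraction uses the ceiling rule and subgroups stay independent", {
  genomes <- three_genomes()
  sc <- scaffold_clusters(list(cl1 = c("a1", "b1", "c1"),
                               cl2 = c("a2", "b2")))
  pairs <- data.frame(gene_a = character(), gene_b = character())
  gt <- build_group_table(merge_clusters(sc, pairs,
                                         all_genes = c("a1", "b1", "c1",
                                                       "a2", "b2", "c2")),
                          pairs, sc, genomes)
  # full-coverage group is core at 100; 2-of-3 group is not
  expect_true("group1" %in% gt$core_ids)
  cov <- rowSums(gt$presence)
  expect_false(any(cov == 2 & rownames(gt$presence) %in% gt$core_ids))
  # at 66% the 2-of-3 group qualifies: ceiling(0.66 * 3) = 2
  core66 <- extract_core(gt, 66)
  expect_true(all(rownames(gt$presence)[cov >= 2] %in% core66))
  expect_error(extract_core(gt, 0), "core_perc")
  expect_error(extract_core(gt, 101), "core_perc")
})

test_that("summaries annotate groups with per-threshold cluster counts", {
  genes <- sprintf("omp%d", 1:4)
  gmaps <- list(mk_genome("g1", "omp1"), mk_genome("g2", "omp2"),
                mk_genome("g3", "omp3"), mk_genome("g4", "omp4"))
  ed <- data.frame(gene_a = c("omp1", "omp2", "omp3", "omp1", "omp1"),
                   gene_b = c("omp2", "omp3", "omp4", "omp3", "omp4"),
                   weight = c(0.96, 0.65, 0.96, 0.65, 0.65))
  sc <- cluster_genes(ed, 0.95, all_genes = genes)
  expect_equal(length(sc$clusters), 2L)  # split at high stringency
  pairs <- data.frame(gene_a = "omp2", gene_b = "omp3")
  gt <- build_group_table(merge_clusters(sc, pairs, all_genes = genes),
                          pairs, sc, gmaps)
  tc <- multi_threshold_annotation(ed, all_genes = genes)
  out <- withr::local_tempdir()
  summarize_run(gt, out, genomes = gmaps, threshold_clusterings = tc,
                params = list(alpha = 0.5, time_limit_s = 240))
  tab <- utils::read.table(file.path(out, "groups.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE)
  expect_equal(tab$n_clusters_0.95[tab$group_id == "group1"], 2L)
  expect_equal(tab$n_clusters_0.60[tab$group_id == "group1"], 1L)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$alpha, 0.5)
  expect_equal(manifest$time_limit_s, 240)
})
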