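#' Run the full pangenome-refinement pipeline
#'
#' Orchestrates every stage: annotation parsing, bitscore normalization,
#' high-stringency scaffold clustering, pairwise gene-order-aware
#' refinement over all genome pairs, cluster merging, paralog resolution,
#' core-genome extraction and output summarization.
#'
#' @param genomes List of [genome()] objects, or a character vector of
#'   GFF3 paths (read with [read_annotated_genome()]).
#' @param hits All-vs-all hit table (`data.frame` from [read_hit_table()]
#'   or a path to an m8 file), including self-hits. Alternatively supply
#'   pre-normalized `edges`.
#' @param edges Optional normalized weighted edges (`gene_a`, `gene_b`,
#'   `weight`); overrides `hits`-based normalization.
#' @param scaffold_file Optional Roary-style `clustered_proteins` file;
#'   when given it overrides the internal scaffold clustering verbatim.
#' @param alpha Gene-order/similarity trade-off in `[0, 1]` (default 0.5).
#' @param edge_threshold Minimum normalized weight for gene-order evidence
#'   (default 0.6).
#' @param scaffold_threshold Internal scaffold stringency (default 0.95).
#' @param core_perc Core-genome threshold in percent of genomes
#'   (default 100).
#' @param time_limit_s Per-component ILP time limit in seconds
#'   (default 240).
#' @param indel_model Include singleton/block penalties (default `TRUE`).
#' @param keep_ilps Optional directory for LP-format dumps of every
#'   formulated instance.
#' @param compute_pocp Also compute the pairwise POCP matrix from `hits`
#'   (default `TRUE` when hits are available).
#' @param pocp_use_evalue Apply the e-value filter in POCP (disable for
#'   internally aligned hits whose e-value is a sentinel).
#' @param seed Integer seed recorded in the manifest and applied before
#'   any randomized step (default 1).
#' @param out_dir Optional output directory; when given, the TSV/JSON/
#'   FASTA bundle is written via [summarize_run()].
#' @return Object of class `"pangraft"`: list with `group_table`,
#'   `scaffold`, `threshold_clusterings`, `pairwise` (per-pair
#'   [pairwise_refine()] results), `pocp`, `edges`, `stats`, `params`.
#' @export
run_pipeline <- function(genomes, hits = NULL, edges = NULL,
                         scaffold_file = NULL, alpha = 0.5,
                         edge_threshold = 0.6, scaffold_threshold = 0.95,
                         core_perc = 100, time_limit_s = 240,
                         indel_model = TRUE, keep_ilps = NULL,
                         compute_pocp = !is.null(hits),
                         pocp_use_evalue = TRUE,
                         seed = 1L, out_dir = NULL) {
  if (is.character(genomes)) {
    genomes <- lapply(genomes, read_annotated_genome)
  }
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (edge_threshold <= 0 || edge_threshold > 1) stop("edge_threshold must be in (0, 1]")
  if (scaffold_threshold <= 0 || scaffold_threshold > 1) {
    stop("scaffold_threshold must be in (0, 1]")
  }
  if (core_perc <= 0 || core_perc > 100) stop("core_perc must be in (0, 100]")
  set.seed(as.integer(seed))

  ids <- vapply(genomes, function(g) g$genome_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate genome IDs")
  genomes <- genomes[order(ids, method = "radix")]
  ids <- sort(ids)
  names(genomes) <- ids
  gmap <- genome_of_map(genomes)
  all_genes <- names(gmap)

  if (is.character(hits) && length(hits) == 1L) hits <- read_hit_table(hits)
  if (is.null(edges)) {
    if (is.null(hits)) stop("supply either hits or edges")
    edges <- normalize_weights(hits, gmap, edge_threshold = edge_threshold)
  }

  scaffold <- if (!is.null(scaffold_file)) {
    read_scaffold_clusters(scaffold_file)
  } else {
    cluster_genes(edges, threshold = scaffold_threshold,
                  all_genes = all_genes)
  }
  thresholds <- multi_threshold_annotation(edges, all_genes = all_genes)

  pairwise <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      key <- paste(ids[i], ids[j], sep = "~")
      pairwise[[key]] <- pairwise_refine(
        genomes[[i]], genomes[[j]], edges, alpha = alpha,
        time_limit_s = time_limit_s, indel_model = indel_model,
        keep_ilps = if (is.null(keep_ilps)) NULL else
          file.path(keep_ilps, key))
    }
  }
  pairs <- combine_pairs(pairwise)

  prelim <- merge_clusters(scaffold, pairs, all_genes)
  group_table <- build_group_table(prelim, pairs, scaffold, genomes,
                                   core_perc = core_perc)

  pocp <- NULL
  if (isTRUE(compute_pocp) && !is.null(hits)) {
    pocp <- pocp_matrix(hits, genomes, use_evalue = pocp_use_evalue)
  }

  stats <- list(
    n_genomes = length(ids),
    n_genes = length(all_genes),
    n_edges = nrow(edges),
    n_scaffold_clusters = length(scaffold$clusters),
    n_groups = nrow(group_table$presence),
    n_core = length(group_table$core_ids),
    n_trivial = sum(vapply(pairwise, function(p) p$stats$n_trivial, integer(1L))),
    n_ilp = sum(vapply(pairwise, function(p) p$stats$n_ilp, integer(1L))),
    n_timeout = sum(vapply(pairwise, function(p) p$stats$n_timeout, integer(1L)))
  )
  params <- list(alpha = alpha, edge_threshold = edge_threshold,
                 scaffold_threshold = scaffold_threshold,
                 core_perc = core_perc, time_limit_s = time_limit_s,
                 indel_model = indel_model, seed = as.integer(seed))

  result <- structure(list(group_table = group_table, scaffold = scaffold,
                           threshold_clusterings = thresholds,
                           pairwise = pairwise, pocp = pocp, edges = edges,
                           genomes = genomes, stats = stats, params = params),
                      class = "pangraft")
  if (!is.null(out_dir)) {
    summarize_run(group_table, out_dir, genomes = genomes,
                  threshold_clusterings = thresholds, pocp = pocp,
                  params = params)
  }
  result
}

#' @rdname run_pipeline
#' @param ... Passed to [run_pipeline()].
#' @export
pangraft <- function(...) run_pipeline(...)

#' @export
print.pangraft <- function(x, ...) {
  s <- x$stats
  cat("Gene-order-aware pangenome refinement\n")
  cat(sprintf("  genomes: %d  genes: %d  similarity edges: %d\n",
              s$n_genomes, s$n_genes, s$n_edges))
  cat(sprintf("  scaffold clusters (%.2f): %d -> refined groups: %d (core: %d at %g%%)\n",
              x$params$scaffold_threshold, s$n_scaffold_clusters,
              s$n_groups, s$n_core, x$params$core_perc))
  cat(sprintf("  pairwise components: %d trivial, %d solved, %d timeouts\n",
              s$n_trivial, s$n_ilp, s$n_timeout))
  if (!is.null(x$pocp)) {
    cat(sprintf("  mean pairwise POCP: %.2f%%\n", attr(x$pocp, "mean")))
  }
  invisible(x)
}

#' @export
summary.pangraft <- function(object, ...) {
  print(object)
  cov <- rowSums(object$group_table$presence)
  cat("  group coverage distribution:\n")
  print(table(cov))
  invisible(object)
}
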