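#' High-stringency scaffold clustering of genes
#'
#' Single-linkage clustering: connected components over similarity edges
#' at or above `threshold`. This provides the high-stringency scaffold
#' partition that gene-order-aware refinement later merges; 0.95 is the
#' default stringency for the scaffold actually used downstream. Every
#' gene appears — isolated genes become singleton clusters. Cluster IDs
#' are deterministic, derived from the smallest member gene ID.
#'
#' @param weighted_edges `data.frame` with `gene_a`, `gene_b`, `weight`.
#' @param threshold Similarity threshold in `(0, 1]`.
#' @param all_genes Optional character vector of every gene ID that must
#'   appear (isolated genes as singleton clusters); defaults to the genes
#'   seen in `weighted_edges`.
#' @return A [scaffold_clusters()] object with `provenance = "internal"`.
#' @export
cluster_genes <- function(weighted_edges, threshold = 0.95,
                          all_genes = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  e <- weighted_edges[weighted_edges$weight >= threshold, , drop = FALSE]
  genes <- sort(unique(c(all_genes, weighted_edges$gene_a,
                         weighted_edges$gene_b)))
  if (length(genes) == 0L) {
    return(scaffold_clusters(list(), provenance = "internal",
                             threshold = threshold))
  }
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g)$name <- genes
  if (nrow(e) > 0L) g <- igraph::add_edges(g, rbind(e$gene_a, e$gene_b))
  comp <- igraph::components(g)
  clusters <- split(genes, comp$membership)
  names(clusters) <- paste0("cluster_", vapply(clusters, min, character(1L)))
  clusters <- clusters[order(names(clusters), method = "radix")]
  clusters <- lapply(clusters, sort)
  scaffold_clusters(clusters, provenance = "internal", threshold = threshold)
}

#' Scaffold clusterings across the standard threshold ladder
#'
#' Produces clusterings at 0.60/0.70/0.80/0.90/0.95. Only the 0.95
#' clustering feeds downstream group computation; the lower-threshold
#' clusterings annotate the output tables for visual comparison of how
#' families split as stringency rises. Single linkage makes the ladder
#' nested: lowering the threshold never splits a cluster.
#'
#' @inheritParams cluster_genes
#' @param thresholds Numeric vector of thresholds (default the standard
#'   ladder).
#' @return Object of class `"threshold_clusterings"`: list with
#'   `clusterings` (named by threshold, e.g. `"0.95"`).
#' @export
multi_threshold_annotation <- function(weighted_edges, all_genes = NULL,
                                       thresholds = c(0.60, 0.70, 0.80,
                                                      0.90, 0.95)) {
  cls <- lapply(thresholds, function(t)
    cluster_genes(weighted_edges, threshold = t, all_genes = all_genes))
  names(cls) <- format(thresholds, nsmall = 2)
  structure(list(clusterings = cls), class = "threshold_clusterings")
}

#' @export
print.threshold_clusterings <- function(x, ...) {
  for (nm in names(x$clusterings)) {
    cat(sprintf("  %s: %d clusters\n", nm,
                length(x$clusterings[[nm]]$clusters)))
  }
  invisible(x)
}

#' Write per-threshold cluster memberships as TSV
#' @param tc A [multi_threshold_annotation()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_threshold_clusters <- function(tc, path) {
  genes <- sort(unique(unlist(lapply(tc$clusterings, function(cl)
    unlist(cl$clusters, use.names = FALSE)))))
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (nm in names(tc$clusterings)) {
    memb <- cluster_membership(tc$clusterings[[nm]])
    tab[[paste0("cluster_", nm)]] <- memb[genes]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
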