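# small builders used across the suite

# circular single-contig genome from gene IDs and strands
mk_genome <- function(id, genes, strands = rep("+", length(genes)),
                      contig = "c1", names = NULL) {
  n <- length(genes)
  genome(id, data.frame(
    gene_id = genes, contig_id = contig,
    start = (seq_len(n) - 1L) * 100L + 1L,
    end = (seq_len(n) - 1L) * 100L + 80L,
    strand = strands,
    gene_name = if (is.null(names)) NA_character_ else names,
    stringsAsFactors = FALSE))
}

# one-to-one identity edge set a_i -- b_i with given weights
identity_edges <- function(genes_a, genes_b, weight = 1) {
  data.frame(gene_a = genes_a, gene_b = genes_b,
             weight = rep_len(weight, length(genes_a)),
             stringsAsFactors = FALSE)
}

# random bipartite instance with weights in [0.6, 1]
random_instance <- function(seed, max_genes = 5L) {
  set.seed(seed)
  na <- sample(2:max_genes, 1L)
  nb <- sample(2:max_genes, 1L)
  A <- mk_genome("A", sprintf("a%02d", seq_len(na)),
                 sample(c("+", "-"), na, replace = TRUE))
  B <- mk_genome("B", sprintf("b%02d", seq_len(nb)),
                 sample(c("+", "-"), nb, replace = TRUE))
  ne <- sample.int(na * nb, 1L)
  idx <- sample.int(na * nb, ne)
  ed <- data.frame(
    gene_a = sprintf("a%02d", ((idx - 1L) %% na) + 1L),
    gene_b = sprintf("b%02d", ((idx - 1L) %/% na) + 1L),
    weight = round(stats::runif(ne, 0.6, 1), 3),
    stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$gene_a, ed$gene_b)), , drop = FALSE]
  list(A = A, B = B, edges = ed)
}
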