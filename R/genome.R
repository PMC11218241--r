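#' Construct a genome object from a gene feature table
#'
#' A genome is an ordered, oriented collection of gene features grouped by
#' contig. Every contig is treated as an independent circular replicon (the
#' usual situation for bacterial chromosomes and plasmids). Within a contig,
#' genes are ordered by `(start, end, gene_id)`; the resulting order is the
#' gene order used by all downstream rearrangement machinery.
#'
#' @param genome_id Single string naming the genome.
#' @param genes `data.frame` with at least columns `gene_id`, `contig_id`,
#'   `start`, `end`, `strand` (`"+"` or `"-"`); optional columns
#'   `feature_type`, `gene_name`, `product`, `sequence` are carried along.
#' @param circular Logical, recycled per contig: is the replicon circular?
#'   Default `TRUE`.
#'
#' @return Object of class `"genome"`: a list with elements `genome_id`,
#'   `genes` (the validated, ordered feature table) and `circular`
#'   (named logical per contig).
#' @export
genome <- function(genome_id, genes, circular = TRUE) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  required <- c("gene_id", "contig_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("genes table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  for (col in c("feature_type", "gene_name", "product", "sequence")) {
    if (is.null(genes[[col]])) genes[[col]] <- NA_character_
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig_id <- as.character(genes$contig_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)

  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end]
    stop("start > end for gene(s): ", paste(bad, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }

  ord <- order(genes$contig_id, genes$start, genes$end, genes$gene_id,
               method = "radix")
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL

  contigs <- unique(genes$contig_id)
  circ <- rep_len(as.logical(circular), length(contigs))
  names(circ) <- contigs

  structure(
    list(genome_id = genome_id, genes = genes, circular = circ),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d genes on %d contig(s)\n",
              x$genome_id, nrow(x$genes), length(x$circular)))
  invisible(x)
}

#' Per-contig oriented gene orders of a genome
#'
#' @param g A [genome()] object.
#' @param subset Optional character vector of gene IDs; the order is then
#'   restricted to these genes (non-subset genes are contracted away while
#'   the circular order of the remainder is preserved).
#' @return Named list (one element per contig that retains at least one
#'   gene): each element is a list with `genes` (character vector of gene
#'   IDs in genomic order) and `strand` (matching `"+"`/`"-"` vector).
#' @export
gene_orders <- function(g, subset = NULL) {
  stopifnot(inherits(g, "genome"))
  tab <- g$genes
  if (!is.null(subset)) tab <- tab[tab$gene_id %in% subset, , drop = FALSE]
  out <- list()
  for (ctg in unique(tab$contig_id)) {
    sub <- tab[tab$contig_id == ctg, , drop = FALSE]
    out[[ctg]] <- list(genes = sub$gene_id, strand = sub$strand)
  }
  out
}

#' Number of genes in a genome
#' @param g A [genome()] object.
#' @return Integer gene count.
#' @export
n_genes <- function(g) nrow(g$genes)

# genome_id lookup for a set of genomes: named vector gene_id -> genome_id
genome_of_map <- function(genomes) {
  ids <- unlist(lapply(genomes, function(g) g$genes$gene_id), use.names = FALSE)
  gms <- unlist(lapply(genomes, function(g) rep(g$genome_id, n_genes(g))),
                use.names = FALSE)
  stats::setNames(gms, ids)
}
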