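#' Read an annotated genome from GFF3 (+ optional FASTA)
#'
#' Reads Prokka-style annotations: gene features (CDS, tRNA, rRNA by
#' default) with their coordinates, strand, name and product. If the GFF3
#' file carries a trailing `##FASTA` section (as Prokka writes), contig
#' sequences are taken from there; otherwise from `fasta_path` when given.
#' Gene sequences are extracted from the contig sequence (reverse
#' complemented for minus-strand genes) when resolvable.
#'
#' Coordinates are kept 1-based inclusive as in GFF3. Features with strand
#' `"."` are accepted as `"+"` with a warning (unoriented features are rare
#' annotation artifacts; the rearrangement model needs oriented genes).
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Optional path to a (nucleotide) FASTA with the contig
#'   sequences.
#' @param feature_types Feature types to keep (GFF3 column 3).
#' @param genome_id Genome identifier; defaults to the GFF3 basename.
#' @param circular Are contigs circular replicons? Default `TRUE`.
#' @return A [genome()] object.
#' @export
read_annotated_genome <- function(gff3_path, fasta_path = NULL,
                                  feature_types = c("CDS", "tRNA", "rRNA"),
                                  genome_id = NULL, circular = TRUE) {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(gff3_path))
  }

  raw <- readLines(gff3_path, warn = FALSE)
  fasta_block <- NULL
  fasta_at <- which(raw == "##FASTA")
  if (length(fasta_at) > 0L) {
    fasta_block <- raw[(fasta_at[1L] + 1L):length(raw)]
    raw <- raw[seq_len(fasta_at[1L] - 1L)]
  }

  body <- !(startsWith(raw, "#") | raw == "")
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad_line <- which(body)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, found %d",
                 bad_line, gff3_path, nfield[nfield != 9L][1L]))
  }

  gff <- ape::read.gff(gff3_path, GFF3 = TRUE)
  gff <- gff[gff$type %in% feature_types, , drop = FALSE]

  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) utils::URLdecode(x[2L]) else NA_character_,
           character(1L))
  }

  strand <- as.character(gff$strand)
  unoriented <- is.na(strand) | strand == "." | strand == "?"
  if (any(unoriented)) {
    warning(sprintf("%d feature(s) with strand '.' treated as '+'",
                    sum(unoriented)))
    strand[unoriented] <- "+"
  }

  ids <- attr_field(gff$attributes, "ID")
  if (anyNA(ids)) {
    ids[is.na(ids)] <- sprintf("%s_feat%04d", genome_id, which(is.na(ids)))
  }

  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(gff$seqid),
    start = gff$start,
    end = gff$end,
    strand = strand,
    feature_type = as.character(gff$type),
    gene_name = attr_field(gff$attributes, "Name"),
    product = attr_field(gff$attributes, "product"),
    sequence = NA_character_,
    stringsAsFactors = FALSE
  )
  miss_name <- is.na(genes$gene_name)
  genes$gene_name[miss_name] <- attr_field(gff$attributes[miss_name], "gene")

  contig_seqs <- NULL
  if (!is.null(fasta_path)) {
    contig_seqs <- Biostrings::readDNAStringSet(fasta_path)
  } else if (!is.null(fasta_block)) {
    tmp <- tempfile(fileext = ".fasta")
    writeLines(fasta_block, tmp)
    contig_seqs <- Biostrings::readDNAStringSet(tmp)
    unlink(tmp)
  }
  if (!is.null(contig_seqs)) {
    names(contig_seqs) <- sub("\\s.*$", "", names(contig_seqs))
    ok <- genes$contig_id %in% names(contig_seqs)
    if (any(ok)) {
      sub <- Biostrings::subseq(contig_seqs[genes$contig_id[ok]],
                                start = genes$start[ok], end = genes$end[ok])
      neg <- genes$strand[ok] == "-"
      if (any(neg)) sub[neg] <- Biostrings::reverseComplement(sub[neg])
      genes$sequence[ok] <- as.character(sub)
    }
  }

  genome(genome_id, genes, circular = circular)
}

#' Read a 12-column tabular similarity hit file (BLAST outfmt 6 / m8)
#'
#' @param path Path to a tab- or whitespace-separated hit table with at
#'   least the 12 standard columns: query, target, percent identity,
#'   alignment length, mismatches, gap opens, qstart, qend, tstart, tend,
#'   e-value, bitscore. Extra columns are retained verbatim.
#' @return `data.frame` of hits with the standard column names
#'   (`query_id`, `target_id`, `pct_identity`, `aln_length`, `mismatches`,
#'   `gap_opens`, `qstart`, `qend`, `tstart`, `tend`, `evalue`,
#'   `bitscore`, ...). Self-hits are retained (they are needed for
#'   bitscore normalization).
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop(sprintf("malformed hit line %d in %s: %d column(s), expected >= 12",
                 bad, path, nf[bad]))
  }
  k <- min(nf)
  mat <- t(vapply(fields, function(x) x[seq_len(k)], character(k)))
  hits <- data.frame(
    query_id = mat[, 1L], target_id = mat[, 2L],
    pct_identity = as.numeric(mat[, 3L]), aln_length = as.integer(mat[, 4L]),
    mismatches = as.integer(mat[, 5L]), gap_opens = as.integer(mat[, 6L]),
    qstart = as.integer(mat[, 7L]), qend = as.integer(mat[, 8L]),
    tstart = as.integer(mat[, 9L]), tend = as.integer(mat[, 10L]),
    evalue = as.numeric(mat[, 11L]), bitscore = as.numeric(mat[, 12L]),
    stringsAsFactors = FALSE
  )
  if (k > 12L) for (j in 13L:k) hits[[paste0("extra", j - 12L)]] <- mat[, j]
  hits
}

empty_hit_table <- function() {
  data.frame(
    query_id = character(), target_id = character(),
    pct_identity = numeric(), aln_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    qstart = integer(), qend = integer(), tstart = integer(),
    tend = integer(), evalue = numeric(), bitscore = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Write a hit table in m8 (BLAST outfmt 6) layout
#' @param hits Hit `data.frame` as returned by [read_hit_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  core <- c("query_id", "target_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "qstart", "qend", "tstart", "tend",
            "evalue", "bitscore")
  utils::write.table(hits[, core, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read scaffold clusters in the Roary "clustered_proteins" dialect
#'
#' Each line has the form `clusterName: geneID<TAB>geneID...`.
#'
#' @param path Path to the cluster file.
#' @return Object of class `"scaffold_clusters"`: list with `clusters`
#'   (named list of character gene-ID vectors), `provenance`
#'   (`"external-file"`) and `threshold` (`NA`, unknown for external files).
#' @export
read_scaffold_clusters <- function(path) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  clusters <- list()
  seen <- character()
  seen_cluster <- character()
  for (i in seq_along(lines)) {
    pos <- regexpr(":", lines[i], fixed = TRUE)
    if (pos < 0L) stop(sprintf("malformed cluster line %d: no ':' separator", i))
    nm <- trimws(substr(lines[i], 1L, pos - 1L))
    members <- strsplit(trimws(substr(lines[i], pos + 1L, nchar(lines[i]))),
                        "[ \t]+")[[1L]]
    members <- members[nzchar(members)]
    dup <- members[members %in% seen]
    if (length(dup) > 0L) {
      other <- seen_cluster[match(dup[1L], seen)]
      stop(sprintf("gene '%s' appears in clusters '%s' and '%s'",
                   dup[1L], other, nm))
    }
    seen <- c(seen, members)
    seen_cluster <- c(seen_cluster, rep(nm, length(members)))
    clusters[[nm]] <- members
  }
  scaffold_clusters(clusters, provenance = "external-file", threshold = NA_real_)
}

#' Construct a scaffold_clusters object
#' @param clusters Named list of character gene-ID vectors (disjoint).
#' @param provenance `"internal"` or `"external-file"`.
#' @param threshold Similarity threshold used to build the clustering
#'   (fraction in `(0, 1]`), or `NA` when unknown.
#' @return Object of class `"scaffold_clusters"`.
#' @export
scaffold_clusters <- function(clusters, provenance = "internal",
                              threshold = NA_real_) {
  all_members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("clusters are not disjoint: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  structure(list(clusters = clusters, provenance = provenance,
                 threshold = threshold),
            class = "scaffold_clusters")
}

#' @export
print.scaffold_clusters <- function(x, ...) {
  cat(sprintf("<scaffold_clusters> %d clusters, %d genes (%s%s)\n",
              length(x$clusters), length(unlist(x$clusters, use.names = FALSE)),
              x$provenance,
              if (is.na(x$threshold)) "" else sprintf(", threshold %.2f", x$threshold)))
  invisible(x)
}

#' Write group outputs: group table, presence/absence matrix, per-group FASTA
#'
#' Writes three artifact sets under `out_dir`:
#' * `groups.tsv` — one row per group/subgroup: ID, representative
#'   name/product, per-genome member gene ID (or `NA`), genome coverage,
#'   core flag, and per-threshold scaffold-cluster membership columns.
#' * `presence_absence.tsv` — binary groups x genomes matrix.
#' * `group_fastas/<group_id>.fasta` — member sequences, where available.
#'
#' @param group_table A `group_table` object (see [build_group_table()]).
#' @param out_dir Output directory (created if needed).
#' @param genomes Optional list of [genome()] objects supplying sequences
#'   for per-group FASTA output; skipped when absent.
#' @param threshold_clusterings Optional [multi_threshold_annotation()]
#'   result used to annotate each group with the number of scaffold
#'   clusters its members occupy at each threshold.
#' @return Invisibly, character vector of the files written.
#' @export
write_group_outputs <- function(group_table, out_dir, genomes = NULL,
                                threshold_clusterings = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  written <- character()

  tab <- group_table_df(group_table)
  if (!is.null(threshold_clusterings)) {
    for (thr in names(threshold_clusterings$clusterings)) {
      cl <- threshold_clusterings$clusterings[[thr]]
      gene2cl <- cluster_membership(cl)
      tab[[paste0("n_clusters_", thr)]] <- vapply(group_table$groups, function(g) {
        members <- unlist(g$members, use.names = FALSE)
        length(unique(stats::na.omit(gene2cl[members])))
      }, integer(1L))
    }
  }
  groups_path <- file.path(out_dir, "groups.tsv")
  utils::write.table(tab, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(written, groups_path)

  pa <- group_table$presence
  pa_path <- file.path(out_dir, "presence_absence.tsv")
  utils::write.table(data.frame(group_id = rownames(pa), pa,
                                check.names = FALSE),
                     pa_path, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, pa_path)

  if (!is.null(genomes)) {
    seq_map <- do.call(rbind, lapply(genomes, function(g)
      g$genes[, c("gene_id", "sequence")]))
    seqs <- stats::setNames(seq_map$sequence, seq_map$gene_id)
    fasta_dir <- file.path(out_dir, "group_fastas")
    dir.create(fasta_dir, showWarnings = FALSE)
    for (g in group_table$groups) {
      members <- unlist(g$members, use.names = FALSE)
      s <- seqs[members]
      keep <- !is.na(s)
      if (!any(keep)) next
      fp <- file.path(fasta_dir, paste0(g$group_id, ".fasta"))
      writeLines(paste0(">", members[keep], "\n", s[keep]), fp)
      written <- c(written, fp)
    }
  }
  invisible(written)
}

#' Read back a presence/absence TSV written by [write_group_outputs()]
#' @param path Path to `presence_absence.tsv`.
#' @return Integer matrix (groups x genomes) with dimnames.
#' @export
read_presence_absence <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "integer"
  m
}

# map gene_id -> cluster name for a scaffold_clusters object
cluster_membership <- function(sc) {
  ids <- unlist(sc$clusters, use.names = FALSE)
  nms <- rep(names(sc$clusters), lengths(sc$clusters))
  stats::setNames(nms, ids)
}
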