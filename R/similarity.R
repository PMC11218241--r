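#' Toy local aligner producing m8-style hit records
#'
#' A small Smith-Waterman wrapper (via [Biostrings::pairwiseAlignment()])
#' so the whole pipeline can run without an external search tool. DNA
#' sequences are scored match/mismatch (+2/-3 by default, affine gaps);
#' protein sequences with BLOSUM62. The returned score is the raw local
#' alignment score (bitscore-like, >= 0); the e-value field is set to the
#' sentinel `0.0` because no e-value statistics are estimated — POCP on
#' internally aligned data should disable its e-value filter.
#'
#' @param seq_a,seq_b Non-empty residue strings.
#' @param type `"dna"` or `"protein"`.
#' @param match,mismatch DNA scoring (ignored for proteins).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @param query_id,target_id IDs written into the hit record.
#' @return One-row hit `data.frame` in the layout of [read_hit_table()].
#'   When no positive-scoring local alignment exists, the hit has
#'   `aln_length = 0` and `bitscore = 0`.
#' @export
toy_align <- function(seq_a, seq_b, type = c("dna", "protein"),
                      match = 2, mismatch = -3,
                      gap_open = 5, gap_extend = 2,
                      query_id = "query", target_id = "target") {
  type <- match.arg(type)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (type == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend)
  }
  score <- Biostrings::score(pa)
  if (score <= 0) {
    hit <- empty_hit_table()[NA_integer_, ]
    hit$query_id <- query_id; hit$target_id <- target_id
    hit$pct_identity <- 0; hit$aln_length <- 0L
    hit$mismatches <- 0L; hit$gap_opens <- 0L
    hit$qstart <- 0L; hit$qend <- 0L; hit$tstart <- 0L; hit$tend <- 0L
    hit$evalue <- 0; hit$bitscore <- 0
    rownames(hit) <- NULL
    return(hit)
  }
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  data.frame(
    query_id = query_id, target_id = target_id,
    pct_identity = Biostrings::pid(pa),
    aln_length = aln_len,
    mismatches = Biostrings::nmismatch(pa),
    gap_opens = 0L,
    qstart = pa@pattern@range@start,
    qend = pa@pattern@range@start + pa@pattern@range@width - 1L,
    tstart = pa@subject@range@start,
    tend = pa@subject@range@start + pa@subject@range@width - 1L,
    evalue = 0, bitscore = score,
    stringsAsFactors = FALSE
  )
}

#' All-vs-all toy alignment of two gene sets
#'
#' Convenience driver running [toy_align()] for every cross pair plus the
#' self-hits needed by [normalize_weights()]. Zero-score pairs are dropped.
#'
#' @param seqs_a,seqs_b Named character vectors of sequences (names are
#'   gene IDs).
#' @param ... Passed to [toy_align()].
#' @return Hit `data.frame` (cross hits in both directions plus self-hits).
#' @export
toy_align_all <- function(seqs_a, seqs_b, ...) {
  out <- list()
  selfs <- c(seqs_a, seqs_b)
  selfs <- selfs[!duplicated(names(selfs))]
  for (id in names(selfs)) {
    out[[length(out) + 1L]] <- toy_align(selfs[[id]], selfs[[id]],
                                         query_id = id, target_id = id, ...)
  }
  for (ia in names(seqs_a)) {
    for (ib in names(seqs_b)) {
      h <- toy_align(seqs_a[[ia]], seqs_b[[ib]],
                     query_id = ia, target_id = ib, ...)
      if (h$bitscore > 0) out[[length(out) + 1L]] <- h
    }
  }
  do.call(rbind, out)
}

#' Normalize raw bitscores into inter-gene edge weights
#'
#' The raw bitscore of a cross-genome hit is normalized by the larger of
#' the two self-alignment bitscores, `weight(a,b) =
#' bits(a,b) / max(bits(a,a), bits(b,b))`, clipped to `[0, 1]`. Normalizing
#' by the larger self-score guarantees weights never exceed 1 even for
#' asymmetric local alignments. Reciprocal hits (a vs b and b vs a) are
#' collapsed to one undirected edge using the larger raw bitscore before
#' normalization, because the downstream matching model needs one edge per
#' gene pair. Edges below `edge_threshold` are dropped — by default 0.6,
#' the similarity floor at which gene-order evidence is still trusted to
#' assert homology.
#'
#' @param hits Hit `data.frame` including self-hits for every gene that
#'   participates in a cross-genome hit.
#' @param genome_of Named character vector mapping gene IDs to genome IDs
#'   (e.g. from a list of genomes via their feature tables); used to drop
#'   intra-genome pairs.
#' @param edge_threshold Minimum normalized weight kept (default 0.6).
#' @return `data.frame` with columns `gene_a`, `gene_b`, `weight`
#'   (one row per undirected cross-genome edge, `gene_a < gene_b`).
#' @export
normalize_weights <- function(hits, genome_of, edge_threshold = 0.6) {
  if (nrow(hits) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  self <- hits$query_id == hits$target_id
  self_scores <- tapply(hits$bitscore[self], hits$query_id[self], max)

  cross <- hits[!self, , drop = FALSE]
  ga <- genome_of[cross$query_id]
  gb <- genome_of[cross$target_id]
  known <- !is.na(ga) & !is.na(gb)
  cross <- cross[known & ga[known] != gb[known], , drop = FALSE]
  if (nrow(cross) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }

  a <- pmin(cross$query_id, cross$target_id)
  b <- pmax(cross$query_id, cross$target_id)
  key <- paste(a, b, sep = "\r")
  bits <- tapply(cross$bitscore, key, max)
  parts <- strsplit(names(bits), "\r", fixed = TRUE)
  gene_a <- vapply(parts, `[`, character(1L), 1L)
  gene_b <- vapply(parts, `[`, character(1L), 2L)

  need_self <- unique(c(gene_a, gene_b))
  missing_self <- need_self[!(need_self %in% names(self_scores))]
  if (length(missing_self) > 0L) {
    stop("missing self-hit bitscore for gene(s): ",
         paste(missing_self, collapse = ", "))
  }
  denom <- pmax(self_scores[gene_a], self_scores[gene_b])
  w <- pmin(pmax(as.numeric(bits) / as.numeric(denom), 0), 1)

  out <- data.frame(gene_a = gene_a, gene_b = gene_b, weight = w,
                    stringsAsFactors = FALSE)
  out <- out[out$weight >= edge_threshold, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of conserved proteins (POCP) between two genomes
#'
#' A protein of genome A is conserved if it has at least one hit into
#' genome B with e-value below `evalue_max`, identity above `identity_min`
#' percent, and alignable region (alignment length / query length) above
#' `aln_frac_min` (all strict inequalities). POCP is then
#' `100 * (conserved_a + conserved_b) / (total_a + total_b)`; around 50%
#' has been proposed as a genus boundary.
#'
#' @param hits_ab Hits with genome-A proteins as queries, B as targets.
#' @param hits_ba Hits with genome-B proteins as queries, A as targets.
#' @param total_a,total_b Total protein counts of the two genomes.
#' @param query_lengths Named numeric vector of protein lengths (residues)
#'   for all query IDs appearing in the hit tables.
#' @param evalue_max,identity_min,aln_frac_min Conservation filters.
#' @param use_evalue Set `FALSE` for internally aligned hits, whose e-value
#'   field is a sentinel rather than an estimate.
#' @return Object of class `"pocp_result"`: list with `conserved_a`,
#'   `conserved_b`, `total_a`, `total_b`, `pocp` (percent).
#' @export
compute_pocp <- function(hits_ab, hits_ba, total_a, total_b, query_lengths,
                         evalue_max = 1e-5, identity_min = 40.0,
                         aln_frac_min = 0.5, use_evalue = TRUE) {
  if (total_a == 0L || total_b == 0L) {
    stop("POCP undefined: a genome with zero proteins")
  }
  conserved <- function(hits) {
    if (nrow(hits) == 0L) return(0L)
    qlen <- query_lengths[hits$query_id]
    if (anyNA(qlen)) {
      stop("missing query length for: ",
           paste(unique(hits$query_id[is.na(qlen)]), collapse = ", "))
    }
    pass <- hits$pct_identity > identity_min &
      (hits$aln_length / qlen) > aln_frac_min
    if (use_evalue) pass <- pass & hits$evalue < evalue_max
    length(unique(hits$query_id[pass]))
  }
  ca <- conserved(hits_ab)
  cb <- conserved(hits_ba)
  structure(list(conserved_a = ca, conserved_b = cb,
                 total_a = total_a, total_b = total_b,
                 pocp = 100 * (ca + cb) / (total_a + total_b)),
            class = "pocp_result")
}

#' @export
print.pocp_result <- function(x, ...) {
  cat(sprintf("POCP = %.2f%% (%d/%d + %d/%d conserved)\n",
              x$pocp, x$conserved_a, x$total_a, x$conserved_b, x$total_b))
  invisible(x)
}

#' Pairwise POCP matrix over a set of genomes
#'
#' @param hits Combined all-vs-all hit table (all directed pairs).
#' @param genomes List of [genome()] objects (protein/gene counts and, via
#'   sequences, query lengths).
#' @param query_lengths Optional named lengths; defaults to sequence
#'   lengths from the genomes.
#' @param ... Filters passed to [compute_pocp()].
#' @return Symmetric numeric matrix of POCP percentages (diagonal 100),
#'   with attribute `"mean"` holding the dataset-average pairwise POCP.
#' @export
pocp_matrix <- function(hits, genomes, query_lengths = NULL, ...) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1L))
  gmap <- genome_of_map(genomes)
  if (is.null(query_lengths)) {
    all_genes <- do.call(rbind, lapply(genomes, function(g)
      g$genes[, c("gene_id", "sequence")]))
    query_lengths <- stats::setNames(nchar(all_genes$sequence),
                                     all_genes$gene_id)
    # genomes without attached sequences: fall back to the self-hit
    # alignment end as the query length
    self <- hits$query_id == hits$target_id
    if (any(self) && anyNA(query_lengths)) {
      self_len <- tapply(hits$qend[self], hits$query_id[self], max)
      miss <- names(query_lengths)[is.na(query_lengths)]
      query_lengths[miss] <- as.numeric(self_len[miss])
    }
  }
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  qg <- gmap[hits$query_id]
  tg <- gmap[hits$target_id]
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ab <- hits[qg == ids[i] & tg == ids[j], , drop = FALSE]
      ba <- hits[qg == ids[j] & tg == ids[i], , drop = FALSE]
      p <- compute_pocp(ab, ba, n_genes(genomes[[i]]), n_genes(genomes[[j]]),
                        query_lengths, ...)
      m[i, j] <- m[j, i] <- p$pocp
    }
  }
  vals <- m[upper.tri(m)]
  attr(m, "mean") <- if (length(vals) > 0L) mean(vals) else NA_real_
  m
}

#' Write a POCP matrix as a square symmetric TSV (2 decimals)
#' @param m Matrix from [pocp_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pocp_matrix <- function(m, path) {
  fm <- format(round(m, 2), nsmall = 2, trim = TRUE)
  utils::write.table(data.frame(genome = rownames(m), fm, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
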