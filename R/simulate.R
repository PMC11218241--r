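#' Configuration for the synthetic genome/pangenome generator
#'
#' The generator emulates the evolutionary scenarios that the
#' rearrangement model reasons about: circular bacterial replicons,
#' oriented genes, inversions/transpositions rearranging gene order,
#' deletions/insertions creating singletons, duplications creating
#' paralogs, and per-family divergence tiers controlling where sequence
#' similarity lands relative to the clustering thresholds.
#'
#' @param n_genomes Number of genomes (pangenome mode).
#' @param genes_per_genome Genes on the (single, circular) ancestral
#'   replicon.
#' @param core_fraction Fraction of ancestral families present in every
#'   genome; the rest are accessory, each present per genome with
#'   probability `accessory_prob`.
#' @param accessory_prob Presence probability of an accessory family.
#' @param inversions,transpositions,deletions,insertions,duplications
#'   Operation counts applied per derived genome.
#' @param tier Default similarity range (normalized weight) for true
#'   ortholog pairs, e.g. `c(0.96, 1)` for a tight species-level family.
#' @param family_tiers Optional named list overriding `tier` per family
#'   index (as character), e.g. `list("1" = c(0.60, 0.895))` for one
#'   family whose similarity falls below scaffold stringency but above
#'   the gene-order evidence floor.
#' @param decoy_rate Probability of emitting a sub-threshold decoy edge
#'   between unrelated genes.
#' @param decoy_range Weight range for decoys (below 0.6).
#' @param seed Integer seed; the generator is deterministic under
#'   `(config, seed)`.
#' @return Object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_genomes = 5L, genes_per_genome = 8L,
                       core_fraction = 1.0, accessory_prob = 0.5,
                       inversions = 1L, transpositions = 0L,
                       deletions = 0L, insertions = 0L, duplications = 0L,
                       tier = c(0.96, 1.0), family_tiers = list(),
                       decoy_rate = 0.0, decoy_range = c(0.2, 0.55),
                       seed = 1L) {
  cfg <- list(n_genomes = as.integer(n_genomes),
              genes_per_genome = as.integer(genes_per_genome),
              core_fraction = core_fraction, accessory_prob = accessory_prob,
              inversions = as.integer(inversions),
              transpositions = as.integer(transpositions),
              deletions = as.integer(deletions),
              insertions = as.integer(insertions),
              duplications = as.integer(duplications),
              tier = tier, family_tiers = family_tiers,
              decoy_rate = decoy_rate, decoy_range = decoy_range,
              seed = as.integer(seed))
  stopifnot(cfg$n_genomes >= 1L, cfg$genes_per_genome >= 1L,
            cfg$core_fraction >= 0, cfg$core_fraction <= 1,
            all(cfg$tier >= 0), all(cfg$tier <= 1),
            cfg$inversions >= 0L, cfg$transpositions >= 0L,
            cfg$deletions >= 0L, cfg$insertions >= 0L,
            cfg$duplications >= 0L)
  if (cfg$deletions >= cfg$genes_per_genome) {
    stop("more deletions than genes")
  }
  structure(cfg, class = "sim_config")
}

# apply rearrangement/indel operations to a signed order (data.frame with
# gene_id, strand, family); returns the new order plus an operation log
apply_operations <- function(ord, cfg, new_gene_prefix) {
  log <- list()
  k_new <- 0L
  for (op in seq_len(cfg$inversions)) {
    n <- nrow(ord)
    if (n < 2L) break
    i <- sample.int(n, 1L)
    len <- sample.int(max(1L, n - 1L), 1L)
    j <- min(i + len - 1L, n)
    seg <- ord[i:j, , drop = FALSE]
    seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    ord <- rbind(if (i > 1L) ord[1:(i - 1L), ], seg,
                 if (j < n) ord[(j + 1L):n, ])
    log[[length(log) + 1L]] <- list(op = "inversion", from = i, to = j)
  }
  for (op in seq_len(cfg$transpositions)) {
    n <- nrow(ord)
    if (n < 3L) break
    i <- sample.int(n - 1L, 1L)
    len <- sample.int(max(1L, min(3L, n - i)), 1L)
    j <- i + len - 1L
    seg <- ord[i:j, , drop = FALSE]
    rest <- ord[-(i:j), , drop = FALSE]
    at <- sample.int(nrow(rest) + 1L, 1L)
    ord <- rbind(if (at > 1L) rest[1:(at - 1L), ], seg,
                 if (at <= nrow(rest)) rest[at:nrow(rest), ])
    log[[length(log) + 1L]] <- list(op = "transposition", from = i, to = j,
                                    at = at)
  }
  for (op in seq_len(cfg$deletions)) {
    if (nrow(ord) < 2L) break
    i <- sample.int(nrow(ord), 1L)
    log[[length(log) + 1L]] <- list(op = "deletion",
                                    gene = ord$gene_id[i])
    ord <- ord[-i, , drop = FALSE]
  }
  for (op in seq_len(cfg$insertions)) {
    k_new <- k_new + 1L
    gid <- sprintf("%s_ins%02d", new_gene_prefix, k_new)
    at <- sample.int(nrow(ord) + 1L, 1L)
    row <- data.frame(gene_id = gid, strand = sample(c("+", "-"), 1L),
                      family = NA_integer_, stringsAsFactors = FALSE)
    ord <- rbind(if (at > 1L) ord[1:(at - 1L), ], row,
                 if (at <= nrow(ord)) ord[at:nrow(ord), ])
    log[[length(log) + 1L]] <- list(op = "insertion", gene = gid)
  }
  for (op in seq_len(cfg$duplications)) {
    i <- sample.int(nrow(ord), 1L)
    k_new <- k_new + 1L
    row <- ord[i, , drop = FALSE]
    row$gene_id <- sprintf("%s_dup%02d", new_gene_prefix, k_new)
    ord <- rbind(ord[1:i, ], row,
                 if (i < nrow(ord)) ord[(i + 1L):nrow(ord), ])
    log[[length(log) + 1L]] <- list(op = "duplication",
                                    template = ord$gene_id[i],
                                    gene = row$gene_id)
  }
  rownames(ord) <- NULL
  list(order = ord, log = log)
}

order_to_genome <- function(genome_id, ord, families = NULL) {
  n <- nrow(ord)
  genes <- data.frame(
    gene_id = ord$gene_id,
    contig_id = paste0(genome_id, "_chr"),
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 800L,
    strand = ord$strand,
    feature_type = "CDS",
    gene_name = if (is.null(families)) NA_character_ else families,
    product = NA_character_,
    sequence = if (is.null(ord$sequence)) NA_character_ else ord$sequence,
    stringsAsFactors = FALSE
  )
  genome(genome_id, genes, circular = TRUE)
}

tier_of <- function(cfg, fam) {
  t <- cfg$family_tiers[[as.character(fam)]]
  if (is.null(t)) cfg$tier else t
}

#' Simulate a genome pair with known rearrangements and truth orthology
#'
#' Genome B is derived from genome A by the configured numbers of
#' inversions, transpositions, deletions, insertions and duplications,
#' applied uniformly at random under the seed. Similarity weights for true
#' ortholog pairs are drawn from the family's divergence tier; optional
#' decoy edges fall below the 0.6 evidence floor. Deterministic under
#' `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @return List with `genome_a`, `genome_b` ([genome()] objects), `edges`
#'   (`gene_a`, `gene_b`, `weight`), and `truth` (list: `pairs`
#'   `data.frame`, `operations` log).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$genes_per_genome
  fams <- seq_len(n)
  ord_a <- data.frame(gene_id = sprintf("A_g%03d", fams),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      family = fams, stringsAsFactors = FALSE)
  ord_b <- data.frame(gene_id = sprintf("B_g%03d", fams),
                      strand = ord_a$strand, family = fams,
                      stringsAsFactors = FALSE)
  res <- apply_operations(ord_b, config, "B")
  ord_b <- res$order

  truth <- merge(
    data.frame(gene_a = ord_a$gene_id, family = ord_a$family),
    data.frame(gene_b = ord_b$gene_id, family = ord_b$family),
    by = "family"
  )
  # duplications create several B genes per family; every copy is a true
  # homolog of the A gene
  edges <- data.frame(gene_a = truth$gene_a, gene_b = truth$gene_b,
                      weight = vapply(truth$family, function(f) {
                        t <- tier_of(config, f)
                        stats::runif(1L, t[1L], t[2L])
                      }, numeric(1L)),
                      stringsAsFactors = FALSE)
  if (config$decoy_rate > 0) {
    for (ga in ord_a$gene_id) {
      for (gb in ord_b$gene_id) {
        if (any(edges$gene_a == ga & edges$gene_b == gb)) next
        if (stats::runif(1L) < config$decoy_rate) {
          edges <- rbind(edges, data.frame(
            gene_a = ga, gene_b = gb,
            weight = stats::runif(1L, config$decoy_range[1L],
                                  config$decoy_range[2L]),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(genome_a = order_to_genome("A", ord_a),
       genome_b = order_to_genome("B", ord_b),
       edges = edges,
       truth = list(pairs = truth[, c("gene_a", "gene_b", "family")],
                    operations = res$log))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# mutate a sequence so that the toy aligner's normalized score lands near
# the target weight: with match 2 / mismatch -3 scoring, identity q gives
# normalized score ~ (5q - 3) / 2, hence q = (2w + 3) / 5
mutate_to_weight <- function(seq, w) {
  q <- (2 * w + 3) / 5
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  flip <- stats::runif(length(chars)) > q
  if (any(flip)) {
    chars[flip] <- vapply(chars[flip], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1L), character(1L))
  }
  paste(chars, collapse = "")
}

#' Simulate a multi-genome pangenome dataset with truth
#'
#' Draws an ancestral pool of gene families (core families present in all
#' genomes, accessory families present per genome with probability
#' `accessory_prob`), derives each genome by seeded rearrangement
#' operations, and emits similarity edges per family divergence tier
#' (`realize = "weights"`), or mutated gene sequences whose toy-aligner
#' scores land in the tier (`realize = "sequences"`). Optionally writes
#' GFF3 + FASTA + m8 + truth JSON to `out_dir`.
#'
#' @param config A [sim_config()].
#' @param realize `"weights"` (fast; emit normalized edges directly) or
#'   `"sequences"` (emit DNA so the internal aligner can reproduce them).
#' @param out_dir Optional directory to write GFF3/FASTA/m8/truth files.
#' @return List with `genomes` (list of [genome()]), `edges`, `hits`
#'   (m8-style table, `realize = "weights"` only emits synthetic scores),
#'   `truth` (family -> gene map and per-genome operation logs), and
#'   `files` when written.
#' @export
simulate_pangenome <- function(config, realize = c("weights", "sequences"),
                               out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  realize <- match.arg(realize)
  set.seed(config$seed)
  nf <- config$genes_per_genome
  fams <- seq_len(nf)
  n_core <- max(1L, round(config$core_fraction * nf))
  core <- fams <= n_core

  fam_seq <- NULL
  if (realize == "sequences") {
    fam_seq <- vapply(fams, function(f) random_dna(240L), character(1L))
  }

  genomes <- list()
  logs <- list()
  fam_genes <- list()  # family -> data.frame(genome, gene_id)
  for (gi in seq_len(config$n_genomes)) {
    gid <- sprintf("g%d", gi)
    present <- core | stats::runif(nf) < config$accessory_prob
    fams_g <- fams[present]
    ord <- data.frame(gene_id = sprintf("%s_f%03d", gid, fams_g),
                      strand = "+", family = fams_g,
                      stringsAsFactors = FALSE)
    res <- apply_operations(ord, config, gid)
    ord <- res$order
    logs[[gid]] <- res$log
    if (realize == "sequences") {
      ord$sequence <- NA_character_
      for (i in seq_len(nrow(ord))) {
        f <- ord$family[i]
        if (is.na(f)) {
          ord$sequence[i] <- random_dna(240L)
        } else {
          t <- tier_of(config, f)
          # each genome diverges from the ancestor by half the tier gap so
          # pairwise similarity lands inside the tier
          w_target <- 1 - (1 - mean(t)) / 2
          ord$sequence[i] <- mutate_to_weight(fam_seq[f], w_target)
        }
      }
    }
    genomes[[gid]] <- order_to_genome(gid, ord,
                                      families = sprintf("fam%03d", ord$family))
    for (i in seq_len(nrow(ord))) {
      f <- ord$family[i]
      if (is.na(f)) next
      fam_genes[[as.character(f)]] <-
        rbind(fam_genes[[as.character(f)]],
              data.frame(genome = gid, gene_id = ord$gene_id[i],
                         stringsAsFactors = FALSE))
    }
  }

  edges <- list()
  for (f in names(fam_genes)) {
    tab <- fam_genes[[f]]
    if (nrow(tab) < 2L) next
    t <- tier_of(config, as.integer(f))
    for (i in seq_len(nrow(tab) - 1L)) {
      for (j in (i + 1L):nrow(tab)) {
        if (tab$genome[i] == tab$genome[j]) next
        edges[[length(edges) + 1L]] <- data.frame(
          gene_a = tab$gene_id[i], gene_b = tab$gene_id[j],
          weight = stats::runif(1L, t[1L], t[2L]),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(gene_a = character(), gene_b = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  # m8-style hit table realizing the weights: self-hits give the
  # normalization denominator, cross bitscores reproduce the weights
  self_bits <- 480
  gene_len <- 240L
  all_ids <- unlist(lapply(genomes, function(g) g$genes$gene_id),
                    use.names = FALSE)
  hits <- data.frame(
    query_id = c(all_ids, edges$gene_a, edges$gene_b),
    target_id = c(all_ids, edges$gene_b, edges$gene_a),
    pct_identity = c(rep(100, length(all_ids)),
                     rep(round(30 + 70 * edges$weight, 1), 2L)),
    aln_length = gene_len,
    mismatches = 0L, gap_opens = 0L,
    qstart = 1L, qend = gene_len, tstart = 1L, tend = gene_len,
    evalue = c(rep(0, length(all_ids)),
               rep(10^(-30 - 120 * edges$weight), 2L)),
    bitscore = c(rep(self_bits, length(all_ids)),
                 rep(round(edges$weight * self_bits, 1), 2L)),
    stringsAsFactors = FALSE
  )

  truth <- list(families = fam_genes, operations = logs,
                core_families = sprintf("fam%03d", fams[core]))

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (gid in names(genomes)) {
      files <- c(files,
                 write_genome_gff3(genomes[[gid]],
                                   file.path(out_dir, paste0(gid, ".gff"))))
      if (realize == "sequences") {
        fp <- file.path(out_dir, paste0(gid, ".fasta"))
        gtab <- genomes[[gid]]$genes
        writeLines(paste0(">", gtab$gene_id, "\n", gtab$sequence), fp)
        files <- c(files, fp)
      }
    }
    files <- c(files, write_hit_table(hits, file.path(out_dir, "hits.m8")))
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, tp)
  }

  list(genomes = genomes, edges = edges, hits = hits, truth = truth,
       files = files)
}

#' Write a genome's features as GFF3
#' @param g A [genome()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_gff3 <- function(g, path) {
  tab <- g$genes
  attrs <- paste0("ID=", tab$gene_id,
                  ifelse(is.na(tab$gene_name), "",
                         paste0(";Name=", tab$gene_name)),
                  ifelse(is.na(tab$product), "",
                         paste0(";product=", tab$product)))
  lines <- c("##gff-version 3",
             paste(tab$contig_id, "pangraft",
                   ifelse(is.na(tab$feature_type), "CDS", tab$feature_type),
                   tab$start, tab$end, ".", tab$strand, "0", attrs,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
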