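#' Merge scaffold clusters with pairwise homology pairs into preliminary groups
#'
#' Union-find over the scaffold clusters: whenever a homology pair links
#' genes sitting in two different clusters, the clusters are merged into
#' one preliminary group. Genes absent from every cluster join through
#' their pairs, or become singleton groups. Preliminary groups may still
#' contain several genes of one genome (paralogs); see
#' [resolve_paralogs()].
#'
#' @param scaffold A [scaffold_clusters()] object (the high-stringency
#'   scaffold, or an external cluster file read with
#'   [read_scaffold_clusters()]).
#' @param homology_pairs A `data.frame` with columns `gene_a`, `gene_b`
#'   (e.g. `rbind` of the `$pairs` of all pairwise [pairwise_refine()]
#'   results), or a list of `"homology_pairs"` objects.
#' @param all_genes Character vector of every gene ID in the dataset.
#' @return List of preliminary groups: each a list with `members`
#'   (character vector) and `provenance` (originating cluster IDs),
#'   ordered by smallest member gene ID.
#' @export
merge_clusters <- function(scaffold, homology_pairs, all_genes) {
  pairs <- combine_pairs(homology_pairs)
  memb <- cluster_membership(scaffold)
  unit_of <- function(g) {
    cl <- memb[g]
    ifelse(is.na(cl), paste0("gene\r", g), paste0("cl\r", cl))
  }
  units <- unique(c(unit_of(all_genes),
                    if (nrow(pairs) > 0L) unit_of(c(pairs$gene_a, pairs$gene_b))))
  parent <- stats::setNames(seq_along(units), units)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  if (nrow(pairs) > 0L) {
    ua <- match(unit_of(pairs$gene_a), units)
    ub <- match(unit_of(pairs$gene_b), units)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(ua[i]); rb <- find(ub[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots_units <- vapply(seq_along(units), find, integer(1L))
  gene_pool <- sort(unique(c(all_genes, pairs$gene_a, pairs$gene_b)))
  gene_root <- roots_units[match(unit_of(gene_pool), units)]
  groups <- split(gene_pool, gene_root)
  out <- lapply(groups, function(members) {
    prov <- sort(unique(stats::na.omit(memb[members])))
    list(members = sort(members), provenance = as.character(prov))
  })
  names(out) <- NULL
  smallest <- vapply(out, function(g) g$members[1L], character(1L))
  out[order(smallest, method = "radix")]
}

combine_pairs <- function(homology_pairs) {
  if (is.data.frame(homology_pairs)) return(homology_pairs)
  if (length(homology_pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(homology_pairs, function(hp)
    hp$pairs[, c("gene_a", "gene_b"), drop = FALSE]))
}

#' Resolve paralogs in a merged group into subgroups
#'
#' When a genome contributes two or more genes to a group, one gene is
#' kept as the representative homolog and the remaining `n - 1` genes each
#' seed a subgroup (IDs suffixed `.1`, `.2`, ...). The representative is
#' chosen by a tie-breaking ladder: (1) the gene connected to the rest of
#' the group by the most homology pairs; (2) the gene from the largest
#' originating scaffold cluster; (3) the gene whose annotated name matches
#' the majority gene name of the group ("hypothetical protein"
#' placeholders are ignored when counting the majority); (4) the
#' lexicographically smallest gene ID. Other group members follow the
#' paralog they are directly paired with; the procedure recurses while any
#' genome still has paralogs.
#'
#' @param members Character vector of the group's gene IDs.
#' @param group_id Base group ID (e.g. `"group7"`).
#' @param pairs Homology pair `data.frame` (`gene_a`, `gene_b`).
#' @param genome_of Named vector gene ID -> genome ID.
#' @param cluster_size Named numeric vector gene ID -> size of its
#'   originating scaffold cluster (0 when unclustered).
#' @param gene_names Named character vector gene ID -> annotated gene name
#'   (may be `NA`).
#' @return List of resolved groups: each a list with `group_id`, `members`
#'   and `parent` (`NA` for the top-level group).
#' @export
resolve_paralogs <- function(members, group_id, pairs, genome_of,
                             cluster_size = NULL, gene_names = NULL) {
  if (is.null(cluster_size)) {
    cluster_size <- stats::setNames(rep(0, length(members)), members)
  }
  if (is.null(gene_names)) {
    gene_names <- stats::setNames(rep(NA_character_, length(members)), members)
  }
  n_links <- function(g, within) {
    sum((pairs$gene_a == g & pairs$gene_b %in% within) |
          (pairs$gene_b == g & pairs$gene_a %in% within))
  }
  resolve <- function(members, id, parent) {
    genomes <- genome_of[members]
    counts <- table(genomes)
    dup_genomes <- sort(names(counts)[counts > 1L])
    if (length(dup_genomes) == 0L) {
      return(list(list(group_id = id, members = sort(members),
                       parent = parent)))
    }
    g_dup <- sort(members[genomes == dup_genomes[1L]])
    others <- setdiff(members, g_dup)

    # ladder rule 1: homology connections into the rest of the group
    conn <- vapply(g_dup, n_links, numeric(1L), within = others)
    cand <- g_dup[conn == max(conn)]
    if (length(cand) > 1L) {
      # rule 2: largest originating scaffold cluster
      cs <- cluster_size[cand]
      cs[is.na(cs)] <- 0
      cand <- cand[cs == max(cs)]
    }
    if (length(cand) > 1L) {
      # rule 3: name matching the group's majority gene name
      nm <- gene_names[others]
      nm <- nm[!is.na(nm) & !grepl("hypothetical", nm, ignore.case = TRUE)]
      if (length(nm) > 0L) {
        tb <- table(nm)
        majority <- names(tb)[tb == max(tb)]
        hit <- cand[gene_names[cand] %in% majority]
        if (length(hit) > 0L) cand <- hit
      }
    }
    representative <- min(cand)  # rule 4: lexicographic fallback
    seeds <- setdiff(g_dup, representative)

    # remaining members follow the paralog they are directly paired with;
    # ties or links to the representative keep them in the parent group
    assign_to <- stats::setNames(rep(id, length(others)), others)
    candidates <- c(representative, seeds)
    for (m in others) {
      link_counts <- vapply(candidates, function(cd)
        n_links(m, cd), numeric(1L))
      if (max(link_counts) == 0) next
      topc <- candidates[link_counts == max(link_counts)]
      if (length(topc) == 1L && topc != representative) {
        assign_to[[m]] <- topc
      }
    }
    out <- list()
    parent_members <- c(representative, others[assign_to[others] == id])
    out <- c(out, resolve(parent_members, id, parent))
    for (k in seq_along(seeds)) {
      sub_id <- paste0(id, ".", k)
      sub_members <- c(seeds[k], others[assign_to[others] == seeds[k]])
      out <- c(out, resolve(sub_members, sub_id, id))
    }
    out
  }
  resolve(members, group_id, NA_character_)
}

#' Build the final group table
#'
#' Assigns deterministic group IDs (by sorted smallest member gene ID),
#' resolves paralogs into subgroups and assembles the presence/absence
#' matrix. Every input gene ends up in exactly one group or subgroup.
#'
#' @param preliminary_groups Result of [merge_clusters()].
#' @param pairs Combined homology pair `data.frame`.
#' @param scaffold The [scaffold_clusters()] used for merging (cluster
#'   sizes feed the paralog ladder).
#' @param genomes List of [genome()] objects (genome order fixes the
#'   presence-matrix columns).
#' @param core_perc Core threshold in percent of genomes, in `(0, 100]`
#'   (default 100: a core gene is present in all input genomes).
#' @return Object of class `"group_table"`: list with `groups` (each:
#'   `group_id`, `members` named genome -> gene, `parent`, `provenance`),
#'   `genomes`, `presence` (binary matrix), `core_perc`, `core_ids`.
#' @export
build_group_table <- function(preliminary_groups, pairs, scaffold, genomes,
                              core_perc = 100) {
  genome_ids <- sort(vapply(genomes, function(g) g$genome_id, character(1L)))
  gmap <- genome_of_map(genomes)
  name_map <- stats::setNames(
    unlist(lapply(genomes, function(g) g$genes$gene_name), use.names = FALSE),
    unlist(lapply(genomes, function(g) g$genes$gene_id), use.names = FALSE))
  memb <- cluster_membership(scaffold)
  sizes <- lengths(scaffold$clusters)
  csize <- stats::setNames(as.numeric(sizes[memb]), names(memb))

  resolved <- list()
  for (i in seq_along(preliminary_groups)) {
    pg <- preliminary_groups[[i]]
    res <- resolve_paralogs(pg$members, paste0("group", i), pairs,
                            genome_of = gmap, cluster_size = csize,
                            gene_names = name_map)
    res <- lapply(res, function(r) { r$provenance <- pg$provenance; r })
    resolved <- c(resolved, res)
  }

  groups <- lapply(resolved, function(r) {
    gm <- gmap[r$members]
    stopifnot(!anyDuplicated(gm))
    list(group_id = r$group_id,
         members = stats::setNames(as.list(r$members), gm),
         parent = r$parent, provenance = r$provenance)
  })

  presence <- matrix(0L, nrow = length(groups), ncol = length(genome_ids),
                     dimnames = list(vapply(groups, `[[`, character(1L),
                                            "group_id"),
                                     genome_ids))
  for (i in seq_along(groups)) {
    presence[i, names(groups[[i]]$members)] <- 1L
  }
  gt <- structure(list(groups = groups, genomes = genome_ids,
                       presence = presence, core_perc = core_perc),
                  class = "group_table")
  gt$core_ids <- extract_core(gt, core_perc)
  gt
}

#' @export
print.group_table <- function(x, ...) {
  n_sub <- sum(grepl("\\.", rownames(x$presence)))
  cat(sprintf("<group_table> %d groups (%d subgroups) x %d genomes; %d core at %g%%\n",
              nrow(x$presence), n_sub, length(x$genomes),
              length(x$core_ids), x$core_perc))
  invisible(x)
}

#' Extract core groups
#'
#' A group is core when it covers at least `ceiling(core_perc/100 *
#' n_genomes)` genomes; the default 100 requires presence in all input
#' genomes. Subgroups count as independent groups.
#'
#' @param group_table A `"group_table"`.
#' @param core_perc Percent of genomes required, in `(0, 100]`.
#' @return Character vector of core group IDs.
#' @export
extract_core <- function(group_table, core_perc = 100) {
  if (!is.numeric(core_perc) || core_perc <= 0 || core_perc > 100) {
    stop("core_perc must be in (0, 100]")
  }
  need <- ceiling(core_perc / 100 * length(group_table$genomes))
  cov <- rowSums(group_table$presence)
  rownames(group_table$presence)[cov >= need]
}

# flat data.frame view of a group table (groups.tsv layout)
group_table_df <- function(group_table) {
  gt <- group_table
  rep_field <- function(g, field) {
    vals <- field[unlist(g$members, use.names = FALSE)]
    vals <- vals[!is.na(vals) & !grepl("hypothetical", vals, ignore.case = TRUE)]
    if (length(vals) == 0L) return(NA_character_)
    tb <- sort(table(vals), decreasing = TRUE)
    names(tb)[1L]
  }
  tab <- data.frame(
    group_id = vapply(gt$groups, `[[`, character(1L), "group_id"),
    stringsAsFactors = FALSE
  )
  tab$parent <- vapply(gt$groups, function(g)
    if (is.na(g$parent)) "" else g$parent, character(1L))
  for (gm in gt$genomes) {
    tab[[gm]] <- vapply(gt$groups, function(g)
      if (!is.null(g$members[[gm]])) g$members[[gm]] else NA_character_,
      character(1L))
  }
  tab$n_genomes_covered <- rowSums(gt$presence)
  tab$core <- tab$group_id %in% gt$core_ids
  tab$scaffold_clusters <- vapply(gt$groups, function(g)
    paste(g$provenance, collapse = ","), character(1L))
  tab
}

#' Summarize a refinement run into its output bundle
#'
#' Writes the group table (with per-threshold scaffold-cluster annotation
#' columns), the presence/absence matrix, the core-group list, per-group
#' FASTA files, the POCP matrix and a JSON run manifest.
#'
#' @param group_table A `"group_table"`.
#' @param out_dir Output directory.
#' @param genomes List of [genome()] objects (sequences for FASTA output).
#' @param threshold_clusterings Optional [multi_threshold_annotation()]
#'   result.
#' @param pocp Optional POCP matrix from [pocp_matrix()].
#' @param params Named list recorded in the manifest (alpha, thresholds,
#'   time limit, seed, ...).
#' @return Invisibly, character vector of files written.
#' @export
summarize_run <- function(group_table, out_dir, genomes = NULL,
                          threshold_clusterings = NULL, pocp = NULL,
                          params = list()) {
  written <- write_group_outputs(group_table, out_dir, genomes = genomes,
                                 threshold_clusterings = threshold_clusterings)
  core_path <- file.path(out_dir, "core_groups.tsv")
  utils::write.table(data.frame(group_id = group_table$core_ids),
                     core_path, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, core_path)
  if (!is.null(threshold_clusterings)) {
    p <- file.path(out_dir, "threshold_clusters.tsv")
    write_threshold_clusters(threshold_clusterings, p)
    written <- c(written, p)
  }
  if (!is.null(pocp)) {
    p <- file.path(out_dir, "pocp_matrix.tsv")
    write_pocp_matrix(pocp, p)
    written <- c(written, p)
  }
  manifest <- c(list(package = "pangraft",
                     version = as.character(utils::packageVersion("pangraft")),
                     n_genomes = length(group_table$genomes),
                     n_groups = nrow(group_table$presence),
                     n_core = length(group_table$core_ids),
                     core_perc = group_table$core_perc),
                params)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, mp)
  invisible(written)
}
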