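#' Build the gene similarity graph of two genomes
#'
#' Bipartite graph with the genes of genome A on one side, genes of genome
#' B on the other, and edges weighted by normalized sequence similarity in
#' `(0, 1]`. Genes without any incident edge are kept as isolated vertices
#' (they are candidates for indel events). Duplicate edges are collapsed to
#' the maximum weight.
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param weighted_edges `data.frame` with columns `gene_a`, `gene_b`,
#'   `weight` (orientation of the columns does not matter; each edge must
#'   connect one gene of each genome).
#' @return Object of class `"gs_graph"`.
#' @export
build_gs_graph <- function(genome_a, genome_b, weighted_edges) {
  stopifnot(inherits(genome_a, "genome"), inherits(genome_b, "genome"))
  ga <- genome_a$genes$gene_id
  gb <- genome_b$genes$gene_id
  shared <- intersect(ga, gb)
  if (length(shared) > 0L) {
    stop("gene IDs must be unique across genomes; shared: ",
         paste(utils::head(shared, 3L), collapse = ", "))
  }
  e <- as.data.frame(weighted_edges, stringsAsFactors = FALSE)
  if (nrow(e) > 0L) {
    in_a <- e$gene_a %in% ga
    in_b <- e$gene_b %in% gb
    swapped <- !in_a & (e$gene_a %in% gb) & (e$gene_b %in% ga)
    tmp <- e$gene_a[swapped]
    e$gene_a[swapped] <- e$gene_b[swapped]
    e$gene_b[swapped] <- tmp
    bad <- !(e$gene_a %in% ga & e$gene_b %in% gb)
    if (any(bad)) {
      stop("edge references unknown gene(s): ",
           paste(unique(c(e$gene_a[bad], e$gene_b[bad])), collapse = ", "))
    }
    key <- paste(e$gene_a, e$gene_b, sep = "\r")
    w <- tapply(e$weight, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    e <- data.frame(gene_a = vapply(parts, `[`, character(1L), 1L),
                    gene_b = vapply(parts, `[`, character(1L), 2L),
                    weight = as.numeric(w), stringsAsFactors = FALSE)
    e <- e[order(e$gene_a, e$gene_b, method = "radix"), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(gene_a = character(), gene_b = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(genome_a = genome_a, genome_b = genome_b, edges = e),
            class = "gs_graph")
}

#' @export
print.gs_graph <- function(x, ...) {
  cat(sprintf("<gs_graph> %s (%d genes) vs %s (%d genes), %d edges\n",
              x$genome_a$genome_id, n_genes(x$genome_a),
              x$genome_b$genome_id, n_genes(x$genome_b), nrow(x$edges)))
  invisible(x)
}

# A sub-instance of the pairwise problem: a set of genes from both genomes,
# their similarity edges, and the component-restricted circular gene orders
# (genes outside the set are contracted away, freezing the matched context).
make_instance <- function(gs, genes_a = NULL, genes_b = NULL) {
  if (is.null(genes_a)) genes_a <- gs$genome_a$genes$gene_id
  if (is.null(genes_b)) genes_b <- gs$genome_b$genes$gene_id
  e <- gs$edges
  e <- e[e$gene_a %in% genes_a & e$gene_b %in% genes_b, , drop = FALSE]
  structure(list(
    genome_a_id = gs$genome_a$genome_id,
    genome_b_id = gs$genome_b$genome_id,
    genes_a = sort(genes_a), genes_b = sort(genes_b),
    edges = e,
    orders_a = gene_orders(gs$genome_a, subset = genes_a),
    orders_b = gene_orders(gs$genome_b, subset = genes_b)
  ), class = "gs_component")
}

#' Connected components of a gene similarity graph
#'
#' The pairwise problem decomposes into independent sub-instances along the
#' connected components of the similarity graph; each component carries its
#' genes, edges, and the component-restricted circular gene orders that
#' freeze the surrounding matched context. Isolated genes come back as
#' singleton components (forced indels).
#'
#' @param gs A [build_gs_graph()] object.
#' @return List of `"gs_component"` objects, ordered by smallest member
#'   gene ID.
#' @export
gs_components <- function(gs) {
  ga <- gs$genome_a$genes$gene_id
  gb <- gs$genome_b$genes$gene_id
  verts <- c(paste0("A\r", ga), paste0("B\r", gb))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  if (nrow(gs$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(paste0("A\r", gs$edges$gene_a),
                                    paste0("B\r", gs$edges$gene_b)))
  }
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    members <- verts[comp$membership == k]
    side <- substr(members, 1L, 1L)
    ids <- substring(members, 3L)
    out[[k]] <- make_instance(gs, genes_a = ids[side == "A"],
                              genes_b = ids[side == "B"])
  }
  smallest <- vapply(out, function(cmp) min(c(cmp$genes_a, cmp$genes_b)),
                     character(1L))
  out[order(smallest, method = "radix")]
}

#' Is a component a trivial one-to-one mapping?
#'
#' Trivial components — a single similarity edge joining one gene of each
#' genome, each of degree one — are accepted directly as homolog pairs and
#' never formulated as optimization problems. An isolated gene is *not*
#' trivial in this sense: it is a forced singleton, not a mapping.
#'
#' @param component A `"gs_component"` from [gs_components()].
#' @return `TRUE` for single-edge components.
#' @export
is_trivial_component <- function(component) {
  nrow(component$edges) == 1L &&
    length(component$genes_a) == 1L && length(component$genes_b) == 1L
}

#' Reduce genomes under a matching
#'
#' Removes unmatched (singleton) genes from the circular gene orders and
#' joins their neighbors, producing the reduced genomes on which the
#' adjacency graph is built.
#'
#' @param orders_a,orders_b Gene orders (from [gene_orders()]) or
#'   [genome()] objects.
#' @param matching `data.frame` with columns `gene_a`, `gene_b`.
#' @return List with `a` and `b`: reduced orders in the [gene_orders()]
#'   layout (contigs that lose all genes are dropped).
#' @export
reduce_genomes <- function(orders_a, orders_b, matching) {
  as_orders <- function(x) if (inherits(x, "genome")) gene_orders(x) else x
  keep <- function(orders, kept) {
    out <- list()
    for (ctg in names(orders)) {
      sel <- orders[[ctg]]$genes %in% kept
      if (!any(sel)) next
      out[[ctg]] <- list(genes = orders[[ctg]]$genes[sel],
                         strand = orders[[ctg]]$strand[sel])
    }
    out
  }
  list(a = keep(as_orders(orders_a), matching$gene_a),
       b = keep(as_orders(orders_b), matching$gene_b))
}

# extremity keys -------------------------------------------------------------
# A gene's two ends: tail (t) and head (h). In genome coordinates a "+" gene
# exposes its tail on the left and head on the right; a "-" gene the reverse.
ext_left <- function(gene, strand) {
  paste0(gene, ifelse(strand == "+", ".t", ".h"))
}
ext_right <- function(gene, strand) {
  paste0(gene, ifelse(strand == "+", ".h", ".t"))
}

# adjacencies of a circular gene order: one per consecutive pair (with
# wrap-around); a single-gene contig yields the self-adjacency of that gene.
contig_adjacencies <- function(genes, strand) {
  k <- length(genes)
  if (k == 0L) return(list())
  nxt <- c(seq_len(k)[-1L], 1L)
  lapply(seq_len(k), function(i) {
    c(ext_right(genes[i], strand[i]), ext_left(genes[nxt[i]], strand[nxt[i]]))
  })
}

orders_adjacencies <- function(orders) {
  out <- list()
  for (ctg in names(orders)) {
    out <- c(out, contig_adjacencies(orders[[ctg]]$genes, orders[[ctg]]$strand))
  }
  out
}

#' Build the adjacency graph of two reduced genomes under a matching
#'
#' Every consecutive gene pair on a circular contig contributes one
#' adjacency (an unordered pair of gene extremities); cross edges connect
#' an A-adjacency and a B-adjacency that share a matched extremity (the
#' matching identifies head with head and tail with tail of paired genes).
#' In fully circular reduced genomes every vertex has degree two, so the
#' graph decomposes into cycles; 2-cycles are "fixed components" where the
#' local gene context is identical and no rearrangement is needed.
#'
#' @param reduced_a,reduced_b Reduced gene orders (see [reduce_genomes()]).
#' @param matching `data.frame` with columns `gene_a`, `gene_b`; must cover
#'   every gene of the reduced genomes.
#' @return Object of class `"adjacency_graph"`: list with
#'   `a_adjacencies`, `b_adjacencies` (lists of extremity pairs),
#'   `cycles` (count `c`), `cycle_lengths` (vertices per cycle) and
#'   `fixed_components` (number of 2-cycles).
#' @export
build_adjacency_graph <- function(reduced_a, reduced_b, matching) {
  adj_a <- orders_adjacencies(reduced_a)
  adj_b <- orders_adjacencies(reduced_b)

  res <- structure(list(a_adjacencies = adj_a, b_adjacencies = adj_b,
                        cycles = 0L, cycle_lengths = integer(),
                        fixed_components = 0L),
                   class = "adjacency_graph")
  if (length(adj_a) == 0L || length(adj_b) == 0L) return(res)

  # matched-extremity correspondence (t<->t, h<->h of paired genes)
  a2b <- c(stats::setNames(paste0(matching$gene_b, ".t"),
                           paste0(matching$gene_a, ".t")),
           stats::setNames(paste0(matching$gene_b, ".h"),
                           paste0(matching$gene_a, ".h")))
  b2a <- stats::setNames(names(a2b), a2b)

  partner_in <- function(adjs) {
    exts <- unlist(adjs, use.names = FALSE)
    if (anyDuplicated(exts)) stop("extremity appears in two adjacencies")
    other <- unlist(lapply(adjs, rev), use.names = FALSE)
    stats::setNames(other, exts)
  }
  other_a <- partner_in(adj_a)
  other_b <- partner_in(adj_b)
  if (!all(names(other_a) %in% names(a2b)) ||
      !all(names(other_b) %in% names(b2a))) {
    stop("reduced genomes contain unmatched genes")
  }

  # walk the alternating cycles: the step map visits one entry extremity
  # per A-adjacency along a cycle; the complementary extremities (exit
  # side) trace the same cycle in the opposite direction and are marked
  # off together so each cycle is counted once
  visited <- stats::setNames(logical(length(other_a)), names(other_a))
  cycles <- 0L
  cycle_lengths <- integer()
  for (start in names(other_a)) {
    if (visited[[start]]) next
    cycles <- cycles + 1L
    orbit <- character()
    e <- start
    repeat {
      visited[[e]] <- TRUE
      orbit <- c(orbit, e)
      e <- other_a[[b2a[[other_b[[a2b[[e]]]]]]]]
      if (e == start) break
    }
    partners <- unname(other_a[orbit])
    if (all(partners %in% orbit)) {
      # self-paired orbit: the walk already covered both directions
      cycle_lengths <- c(cycle_lengths, length(orbit))
    } else {
      visited[partners] <- TRUE
      # cycle vertices = A-adjacencies + B-adjacencies = 2 * orbit length
      cycle_lengths <- c(cycle_lengths, 2L * length(orbit))
    }
  }
  res$cycles <- cycles
  res$cycle_lengths <- cycle_lengths
  res$fixed_components <- sum(cycle_lengths == 2L)
  res
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d + %d adjacencies, %d cycle(s) (%d fixed)\n",
              length(x$a_adjacencies), length(x$b_adjacencies),
              x$cycles, x$fixed_components))
  invisible(x)
}

# number of indel blocks: maximal runs of consecutive singleton genes on
# each circular contig; a contig whose genes are all singletons is 1 block.
count_singleton_blocks <- function(orders, singletons) {
  total <- 0L
  for (ctg in names(orders)) {
    s <- orders[[ctg]]$genes %in% singletons
    k <- length(s)
    if (k == 0L || !any(s)) next
    if (all(s)) {
      total <- total + 1L
    } else {
      nxt <- c(seq_len(k)[-1L], 1L)
      total <- total + sum(s & !s[nxt])
    }
  }
  total
}

# Evaluate the family-free DCJ-indel distance of a fixed matching on an
# instance: d = alpha*(|M| - c + I + S) + (1-alpha)*(|M| - omega(M)).
evaluate_matching <- function(instance, matching, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  M <- nrow(matching)
  singles <- c(setdiff(instance$genes_a, matching$gene_a),
               setdiff(instance$genes_b, matching$gene_b))
  S <- length(singles)
  I <- count_singleton_blocks(instance$orders_a, singles) +
    count_singleton_blocks(instance$orders_b, singles)
  red <- reduce_genomes(instance$orders_a, instance$orders_b, matching)
  ag <- build_adjacency_graph(red$a, red$b, matching)
  omega <- 0
  if (M > 0L) {
    wkey <- paste(instance$edges$gene_a, instance$edges$gene_b, sep = "\r")
    w <- stats::setNames(instance$edges$weight, wkey)
    omega <- sum(w[paste(matching$gene_a, matching$gene_b, sep = "\r")])
  }
  list(distance = alpha * (M - ag$cycles + I + S) + (1 - alpha) * (M - omega),
       M = M, cycles = ag$cycles, blocks = I, singletons = S, omega = omega,
       fixed_components = ag$fixed_components)
}

# maximum bipartite matching cardinality of an instance's similarity edges
max_matching_size <- function(instance) {
  if (nrow(instance$edges) == 0L) return(0L)
  verts <- c(paste0("A\r", instance$genes_a), paste0("B\r", instance$genes_b))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  igraph::V(g)$type <- c(rep(FALSE, length(instance$genes_a)),
                         rep(TRUE, length(instance$genes_b)))
  g <- igraph::add_edges(g, rbind(paste0("A\r", instance$edges$gene_a),
                                  paste0("B\r", instance$edges$gene_b)))
  igraph::max_bipartite_match(g)$matching_size
}

#' Brute-force family-free DCJ-indel distance oracle
#'
#' Enumerates every maximum-cardinality matching of the similarity graph
#' and evaluates `d = alpha*(|M| - c + I + S) + (1-alpha)*(|M| - omega(M))`
#' for each, returning the minimum. `c` is the adjacency-graph cycle
#' count, `S` the number of singleton genes and `I` the number of blocks
#' of consecutive singletons (indels are deliberately penalized twice:
#' once per singleton, once per block). Ties are broken by larger matching
#' weight, then by the lexicographically smallest pair set. Intended as a
#' small-instance reference; guarded to at most `guard` genes per genome.
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param weighted_edges Similarity edges (`gene_a`, `gene_b`, `weight`).
#' @param alpha Trade-off between gene order and gene similarity in
#'   `[0, 1]`; 1 ignores similarities, 0 ignores genome order.
#' @param guard Maximum genes per genome before refusing (default 8).
#' @return List with `distance`, `matching` (`data.frame`), `singletons`,
#'   `blocks`, `cycles`, `omega`, `n_enumerated`.
#' @export
brute_force_ffdcj_indel <- function(genome_a, genome_b, weighted_edges,
                                    alpha = 0.5, guard = 8L) {
  if (n_genes(genome_a) > guard || n_genes(genome_b) > guard) {
    stop("instance too large for enumeration (", guard,
         " genes per genome max); use the ILP solver")
  }
  gs <- build_gs_graph(genome_a, genome_b, weighted_edges)
  inst <- make_instance(gs)
  K <- max_matching_size(inst)

  edges <- inst$edges
  a_genes <- inst$genes_a
  n_a <- length(a_genes)
  inc <- lapply(a_genes, function(g) which(edges$gene_a == g))

  best <- NULL
  best_key <- NULL
  n_enum <- 0L

  consider <- function(pairs_idx) {
    matching <- edges[pairs_idx, c("gene_a", "gene_b"), drop = FALSE]
    ev <- evaluate_matching(inst, matching, alpha)
    n_enum <<- n_enum + 1L
    key <- paste(sort(paste(matching$gene_a, matching$gene_b, sep = "|")),
                 collapse = ";")
    better <- is.null(best) ||
      ev$distance < best$distance - 1e-12 ||
      (abs(ev$distance - best$distance) <= 1e-12 &&
         (ev$omega > best$omega + 1e-12 ||
            (abs(ev$omega - best$omega) <= 1e-12 && key < best_key)))
    if (better) {
      best <<- c(ev, list(matching = matching))
      best_key <<- key
    }
  }

  used_b <- character()
  pairs_idx <- integer()
  recurse <- function(i) {
    if (i > n_a) {
      if (length(pairs_idx) == K) consider(pairs_idx)
      return(invisible())
    }
    if (length(pairs_idx) + (n_a - i + 1L) >= K) {
      for (ei in inc[[i]]) {
        b <- edges$gene_b[ei]
        if (b %in% used_b) next
        used_b <<- c(used_b, b)
        pairs_idx <<- c(pairs_idx, ei)
        recurse(i + 1L)
        used_b <<- used_b[-length(used_b)]
        pairs_idx <<- pairs_idx[-length(pairs_idx)]
      }
    }
    # leave gene i unmatched only if cardinality K is still attainable
    if (length(pairs_idx) + (n_a - i) >= K) recurse(i + 1L)
    invisible()
  }
  recurse(1L)

  if (is.null(best)) stop("no maximum matching found (internal error)")
  list(distance = best$distance, matching = best$matching,
       singletons = best$singletons, blocks = best$blocks,
       cycles = best$cycles, omega = best$omega, n_enumerated = n_enum)
}

#' Classical circular DCJ distance of two duplicate-free genomes
#'
#' Independent cycle-counting implementation for one-to-one instances
#' (same gene set, each gene exactly once per genome, circular contigs):
#' `d = n - c`, with cycles counted by union-find over gene extremities
#' where the adjacency sets of both genomes are the edges.
#'
#' @param genome_a,genome_b [genome()] objects over the same gene set
#'   (gene IDs identify homologs).
#' @return Integer DCJ distance.
#' @export
dcj_distance_circular <- function(genome_a, genome_b) {
  ga <- sort(genome_a$genes$gene_id)
  gb <- sort(genome_b$genes$gene_id)
  if (!identical(ga, gb)) stop("genomes must share the same gene set")
  exts <- c(paste0(ga, ".t"), paste0(ga, ".h"))
  parent <- stats::setNames(seq_along(exts), exts)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  union_ <- function(a, b) {
    ra <- find(match(a, exts)); rb <- find(match(b, exts))
    if (ra != rb) parent[[ra]] <<- rb
    invisible()
  }
  for (orders in list(gene_orders(genome_a), gene_orders(genome_b))) {
    for (adj in orders_adjacencies(orders)) union_(adj[1L], adj[2L])
  }
  roots <- vapply(seq_along(exts), find, integer(1L))
  length(ga) - length(unique(roots))
}
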