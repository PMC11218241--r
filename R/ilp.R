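#' Formulate the family-free DCJ-indel optimization as an integer linear program
#'
#' Encodes, for one similarity-graph component (or a full pairwise
#' instance), the minimization of
#' `d = alpha*(|M| - c + I + S) + (1-alpha)*(|M| - omega(M))`
#' over all maximum-cardinality matchings `M` of the component's
#' similarity edges:
#'
#' * binary matching indicators `x_e` per similarity edge, with
#'   `sum(x_e) = |M|` fixed to the maximum bipartite matching cardinality
#'   (an indel event is only considered if a gene cannot be matched);
#' * a self-edge (singleton) indicator `s_g = 1 - sum(incident x_e)` per
#'   gene, costing `alpha` each (the number of singletons `S`);
#' * block-end indicators `b_g >= s_g - s_next(g)` over each circular gene
#'   order, costing `alpha` each (the number of indel blocks `I`); an
#'   auxiliary per-contig indicator forces one block when an entire contig
#'   is singleton (a circular run has no end otherwise). Together with the
#'   self-edges this penalizes indels twice — once per singleton gene and
#'   once per block of consecutive singletons;
#' * adjacency indicators `y_(p,q)` marking extremity pairs that become
#'   adjacent in the reduced genomes (all genes between them singleton);
#' * cycle counting after the label scheme of Shao et al.: every gene
#'   extremity `v` carries a bounded integer label equalized along active
#'   matching/adjacency edges, and a binary representative indicator that
#'   can be 1 only when `v` attains its own index — exactly one vertex per
#'   cycle — so the representative sum is the cycle count `c`, rewarded
#'   with `-alpha` each.
#'
#' @param component A `"gs_component"` (from [gs_components()] or a full
#'   instance via [gs_components()] of a connected graph).
#' @param alpha Weight between genome order and gene similarity, in
#'   `[0, 1]` (default 0.5).
#' @param indel_model If `FALSE`, singleton and block costs are dropped
#'   from the objective (the plain family-free DCJ objective).
#' @return Object of class `"ffdcj_ilp"`: list with `variables`
#'   (`data.frame`: name, label, type, lb, ub, obj), `constraints` (list of
#'   rows `list(ind, val, sense, rhs)`), `alpha`, `indel_model`,
#'   `max_matching_size`, and the originating `component`.
#' @export
formulate <- function(component, alpha = 0.5, indel_model = TRUE) {
  stopifnot(inherits(component, "gs_component"), alpha >= 0, alpha <= 1)
  genes_a <- component$genes_a
  genes_b <- component$genes_b
  if (length(genes_a) + length(genes_b) == 0L) stop("empty component")
  edges <- component$edges
  K <- max_matching_size(component)

  vars <- data.frame(name = character(), label = character(),
                     type = character(), lb = numeric(), ub = numeric(),
                     obj = numeric(), stringsAsFactors = FALSE)
  add_var <- function(label, type, lb, ub, obj) {
    vars <<- rbind(vars, data.frame(
      name = paste0("v", nrow(vars) + 1L), label = label, type = type,
      lb = lb, ub = ub, obj = obj, stringsAsFactors = FALSE))
    nrow(vars)
  }
  cons <- list()
  add_con <- function(ind, val, sense, rhs) {
    keep <- val != 0
    cons[[length(cons) + 1L]] <<- list(ind = ind[keep], val = val[keep],
                                       sense = sense, rhs = rhs)
  }

  indel_cost <- if (indel_model) alpha else 0

  # matching indicators
  x_idx <- integer(nrow(edges))
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      x_idx[i] <- add_var(sprintf("x(%s,%s)", edges$gene_a[i], edges$gene_b[i]),
                          "B", 0, 1,
                          1 - (1 - alpha) * edges$weight[i])
    }
  }

  # self-edge (singleton) indicators, one per gene
  all_genes <- c(genes_a, genes_b)
  s_idx <- stats::setNames(integer(length(all_genes)), all_genes)
  for (g in all_genes) {
    s_idx[[g]] <- add_var(sprintf("s(%s)", g), "B", 0, 1, indel_cost)
  }

  # block-end indicators, one per gene
  b_idx <- stats::setNames(integer(length(all_genes)), all_genes)
  for (g in all_genes) {
    b_idx[[g]] <- add_var(sprintf("b(%s)", g), "B", 0, 1, indel_cost)
  }

  # degree / self-edge linkage: sum(x incident to g) + s_g = 1
  for (g in genes_a) {
    inc <- x_idx[edges$gene_a == g]
    add_con(c(inc, s_idx[[g]]), rep(1, length(inc) + 1L), "=", 1)
  }
  for (g in genes_b) {
    inc <- x_idx[edges$gene_b == g]
    add_con(c(inc, s_idx[[g]]), rep(1, length(inc) + 1L), "=", 1)
  }

  # maximum-cardinality equality
  if (nrow(edges) > 0L) {
    add_con(x_idx, rep(1, length(x_idx)), "=", K)
  }

  # blocks on each circular contig: b_g >= s_g - s_next(g);
  # an all-singleton contig has no block end, so force sum(b) >= z with
  # z = 1 iff every gene of the contig is singleton
  orders_all <- list(A = component$orders_a, B = component$orders_b)
  for (side in names(orders_all)) {
    orders <- orders_all[[side]]
    for (ctg in names(orders)) {
      gs_ctg <- orders[[ctg]]$genes
      k <- length(gs_ctg)
      nxt <- c(seq_len(k)[-1L], 1L)
      for (i in seq_len(k)) {
        if (nxt[i] == i) next
        add_con(c(b_idx[[gs_ctg[i]]], s_idx[[gs_ctg[i]]], s_idx[[gs_ctg[nxt[i]]]]),
                c(1, -1, 1), ">=", 0)
      }
      z <- add_var(sprintf("z(%s:%s)", side, ctg), "B", 0, 1, 0)
      for (g in gs_ctg) add_con(c(z, s_idx[[g]]), c(1, -1), "<=", 0)
      add_con(c(z, s_idx[gs_ctg]), c(1, rep(-1, k)), ">=", 1 - k)
      add_con(c(b_idx[gs_ctg], z), c(rep(1, k), -1), ">=", 0)
    }
  }

  # extremity index (stable): tails and heads of all genes, A then B
  ext_of <- function(genes) c(rbind(paste0(genes, ".t"), paste0(genes, ".h")))
  exts <- c(ext_of(genes_a), ext_of(genes_b))
  ext_pos <- stats::setNames(seq_along(exts), exts)
  V <- length(exts)
  gene_of_ext <- sub("\\.[th]$", "", exts)

  l_idx <- integer(V)
  r_idx <- integer(V)
  for (v in seq_len(V)) {
    l_idx[v] <- add_var(sprintf("l(%s)", exts[v]), "I", 0, v, 0)
  }
  for (v in seq_len(V)) {
    r_idx[v] <- add_var(sprintf("r(%s)", exts[v]), "B", 0, 1,
                        -alpha)
    # representative only when the label attains the vertex' own index
    add_con(c(r_idx[v], l_idx[v]), c(v, -1), "<=", 0)
    # singleton extremities never represent a cycle
    add_con(c(r_idx[v], s_idx[[gene_of_ext[v]]]), c(1, 1), "<=", 1)
  }

  # label equalization along an edge active under indicator t:
  # |l_u - l_v| <= V * (1 - t)
  equalize <- function(u, v, t_idx) {
    add_con(c(l_idx[u], l_idx[v], t_idx), c(1, -1, V), "<=", V)
    add_con(c(l_idx[v], l_idx[u], t_idx), c(1, -1, V), "<=", V)
  }

  # matching edges identify tail with tail and head with head
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      equalize(ext_pos[[paste0(edges$gene_a[i], ".t")]],
               ext_pos[[paste0(edges$gene_b[i], ".t")]], x_idx[i])
      equalize(ext_pos[[paste0(edges$gene_a[i], ".h")]],
               ext_pos[[paste0(edges$gene_b[i], ".h")]], x_idx[i])
    }
  }

  # adjacency indicators y(p,q): right extremity of gene i adjacent to left
  # extremity of gene j in the reduced genome iff i and j are matched and
  # every gene circularly between them is singleton
  y_labels <- character()
  for (orders in orders_all) {
    for (ctg in names(orders)) {
      gs_ctg <- orders[[ctg]]$genes
      st_ctg <- orders[[ctg]]$strand
      k <- length(gs_ctg)
      for (i in seq_len(k)) {
        for (d in seq_len(k) - 1L) {
          # j is d+1 steps ahead cyclically, with d genes strictly between;
          # d = k-1 wraps to j = i, the self-adjacency of a fully-contracted
          # contig
          j <- ((i - 1L + d + 1L) %% k) + 1L
          between <- if (d == 0L) integer() else ((i + seq_len(d) - 1L) %% k) + 1L
          p <- ext_right(gs_ctg[i], st_ctg[i])
          q <- ext_left(gs_ctg[j], st_ctg[j])
          y <- add_var(sprintf("y(%s,%s)", p, q), "B", 0, 1, 0)
          y_labels <- c(y_labels, sprintf("y(%s,%s)", p, q))
          ends <- unique(c(gs_ctg[i], gs_ctg[j]))
          for (g in ends) add_con(c(y, s_idx[[g]]), c(1, 1), "<=", 1)
          for (bidx in between) {
            add_con(c(y, s_idx[[gs_ctg[bidx]]]), c(1, -1), "<=", 0)
          }
          # force y = 1 when all conditions hold
          nb <- length(between)
          t_terms <- length(ends) + nb
          add_con(c(y, s_idx[ends], if (nb) s_idx[gs_ctg[between]]),
                  c(1, rep(1, length(ends)), if (nb) rep(-1, nb)),
                  ">=", length(ends) - (t_terms - 1L))
          equalize(ext_pos[[p]], ext_pos[[q]], y)
        }
      }
    }
  }

  structure(list(variables = vars, constraints = cons, alpha = alpha,
                 indel_model = indel_model, max_matching_size = K,
                 component = component,
                 x_idx = x_idx, s_idx = s_idx, b_idx = b_idx,
                 l_idx = l_idx, r_idx = r_idx,
                 extremities = exts, ext_pos = ext_pos),
            class = "ffdcj_ilp")
}

#' @export
print.ffdcj_ilp <- function(x, ...) {
  cat(sprintf("<ffdcj_ilp> %d variables, %d constraints, |M| = %d, alpha = %g\n",
              nrow(x$variables), length(x$constraints),
              x$max_matching_size, x$alpha))
  invisible(x)
}

#' Write an ILP instance in CPLEX LP format
#' @param instance A `"ffdcj_ilp"` from [formulate()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lp <- function(instance, path) {
  v <- instance$variables
  term <- function(ind, val) {
    paste(sprintf("%+g %s", val, v$name[ind]), collapse = " ")
  }
  lines <- c("\\ family-free DCJ-indel instance",
             sprintf("\\ %s = %s", v$name, v$label),
             "Minimize",
             paste(" obj:", term(seq_len(nrow(v)), v$obj)),
             "Subject To")
  for (i in seq_along(instance$constraints)) {
    cn <- instance$constraints[[i]]
    sense <- c("<=" = "<=", ">=" = ">=", "=" = "=")[[cn$sense]]
    lines <- c(lines, sprintf(" c%d: %s %s %g", i, term(cn$ind, cn$val),
                              sense, cn$rhs))
  }
  lines <- c(lines, "Bounds",
             sprintf(" %g <= %s <= %g", v$lb, v$name, v$ub),
             "Binary", paste("", paste(v$name[v$type == "B"], collapse = " ")),
             "General", paste("", paste(v$name[v$type == "I"], collapse = " ")),
             "End")
  writeLines(lines, path)
  invisible(path)
}

# cycle count of a fixed matching by union-find over gene extremities:
# active edges = matching identifications (t-t, h-h) plus the dynamic
# adjacencies of the reduced genomes. Independent of build_adjacency_graph.
cycles_by_union <- function(component, matched_a, matched_b, pair_of_a) {
  matched <- c(matched_a, matched_b)
  if (length(matched_a) == 0L) return(0L)
  exts <- c(paste0(matched, ".t"), paste0(matched, ".h"))
  parent <- seq_along(exts)
  pos <- stats::setNames(seq_along(exts), exts)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(p, q) {
    rp <- find(pos[[p]]); rq <- find(pos[[q]])
    if (rp != rq) parent[rp] <<- rq
    invisible()
  }
  for (a in matched_a) {
    b <- pair_of_a[[a]]
    link(paste0(a, ".t"), paste0(b, ".t"))
    link(paste0(a, ".h"), paste0(b, ".h"))
  }
  for (orders in list(component$orders_a, component$orders_b)) {
    for (ctg in names(orders)) {
      keep <- orders[[ctg]]$genes %in% matched
      gs_ctg <- orders[[ctg]]$genes[keep]
      st_ctg <- orders[[ctg]]$strand[keep]
      k <- length(gs_ctg)
      if (k == 0L) next
      nxt <- c(seq_len(k)[-1L], 1L)
      for (i in seq_len(k)) {
        link(ext_right(gs_ctg[i], st_ctg[i]),
             ext_left(gs_ctg[nxt[i]], st_ctg[nxt[i]]))
      }
    }
  }
  roots <- vapply(seq_along(exts), find, integer(1L))
  length(unique(roots))
}

# assemble a full feasible assignment from a matching and check every
# formulated constraint plus the objective row; returns the objective value
assignment_objective <- function(instance, matching) {
  comp <- instance$component
  v <- instance$variables
  val <- numeric(nrow(v))

  edges <- comp$edges
  in_m <- paste(edges$gene_a, edges$gene_b) %in%
    paste(matching$gene_a, matching$gene_b)
  val[instance$x_idx] <- as.numeric(in_m)

  matched <- c(matching$gene_a, matching$gene_b)
  all_genes <- c(comp$genes_a, comp$genes_b)
  singles <- setdiff(all_genes, matched)
  val[instance$s_idx] <- as.numeric(names(instance$s_idx) %in% singles)

  # minimal feasible block-ends: ends of singleton runs; one marker on
  # all-singleton contigs (the z variables force it)
  sided <- list(A = comp$orders_a, B = comp$orders_b)
  for (side in names(sided)) {
    orders <- sided[[side]]
    for (ctg in names(orders)) {
      gs_ctg <- orders[[ctg]]$genes
      k <- length(gs_ctg)
      s <- gs_ctg %in% singles
      if (all(s) && k > 0L) {
        val[instance$b_idx[[gs_ctg[1L]]]] <- 1
        zi <- which(v$label == sprintf("z(%s:%s)", side, ctg))
        val[zi] <- 1
      } else {
        nxt <- c(seq_len(k)[-1L], 1L)
        for (i in seq_len(k)) {
          if (s[i] && !s[nxt[i]]) val[instance$b_idx[[gs_ctg[i]]]] <- 1
        }
      }
    }
  }

  # adjacency indicators: consecutive matched genes after contraction
  for (orders in list(comp$orders_a, comp$orders_b)) {
    for (ctg in names(orders)) {
      keep <- orders[[ctg]]$genes %in% matched
      gs_ctg <- orders[[ctg]]$genes[keep]
      st_ctg <- orders[[ctg]]$strand[keep]
      k <- length(gs_ctg)
      if (k == 0L) next
      nxt <- c(seq_len(k)[-1L], 1L)
      for (i in seq_len(k)) {
        lbl <- sprintf("y(%s,%s)", ext_right(gs_ctg[i], st_ctg[i]),
                       ext_left(gs_ctg[nxt[i]], st_ctg[nxt[i]]))
        val[which(v$label == lbl)] <- 1
      }
    }
  }

  # labels: minimal extremity index per cycle; representative at that vertex
  pair_of_a <- stats::setNames(matching$gene_b, matching$gene_a)
  exts <- instance$extremities
  gene_of_ext <- sub("\\.[th]$", "", exts)
  comp_id <- rep(NA_integer_, length(exts))
  if (nrow(matching) > 0L) {
    parent <- seq_along(exts)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    link <- function(p, q) {
      rp <- find(instance$ext_pos[[p]]); rq <- find(instance$ext_pos[[q]])
      if (rp != rq) parent[rp] <<- rq
      invisible()
    }
    for (a in matching$gene_a) {
      b <- pair_of_a[[a]]
      link(paste0(a, ".t"), paste0(b, ".t"))
      link(paste0(a, ".h"), paste0(b, ".h"))
    }
    for (orders in list(comp$orders_a, comp$orders_b)) {
      for (ctg in names(orders)) {
        keep <- orders[[ctg]]$genes %in% matched
        gs_ctg <- orders[[ctg]]$genes[keep]
        st_ctg <- orders[[ctg]]$strand[keep]
        k <- length(gs_ctg)
        if (k == 0L) next
        nxt <- c(seq_len(k)[-1L], 1L)
        for (i in seq_len(k)) {
          link(ext_right(gs_ctg[i], st_ctg[i]),
               ext_left(gs_ctg[nxt[i]], st_ctg[nxt[i]]))
        }
      }
    }
    comp_id <- vapply(seq_along(exts), find, integer(1L))
  }
  for (vtx in seq_along(exts)) {
    if (gene_of_ext[vtx] %in% matched) {
      members <- which(comp_id == comp_id[vtx])
      lab <- min(members)
      val[instance$l_idx[vtx]] <- lab
      if (vtx == lab) val[instance$r_idx[vtx]] <- 1
    } else {
      val[instance$l_idx[vtx]] <- vtx
    }
  }

  for (i in seq_along(instance$constraints)) {
    cn <- instance$constraints[[i]]
    lhs <- sum(cn$val * val[cn$ind])
    ok <- switch(cn$sense,
                 "<=" = lhs <= cn$rhs + 1e-9,
                 ">=" = lhs >= cn$rhs - 1e-9,
                 "=" = abs(lhs - cn$rhs) <= 1e-9)
    if (!ok) {
      stop(sprintf("assignment violates constraint %d (%s %s %g, lhs %g)",
                   i, cn$sense, "rhs", cn$rhs, lhs))
    }
  }
  sum(v$obj * val)
}

#' Solve a family-free DCJ-indel ILP instance
#'
#' Exact branch-and-bound specialized to the block structure of the
#' formulation: the search branches on the matching indicators in stable
#' (sorted-edge) order; once a maximum-cardinality matching is fixed, the
#' induced subproblem is solved exactly — self-edge and block variables
#' take their minimal feasible values and the label/representative
#' subproblem attains the cycle count, computed by merging the label
#' equalization classes. Admissible bounds (remaining matchable weight,
#' fixed singleton count) prune the search. The best incumbent is
#' returned if the time limit expires. The decoded solution is verified
#' two ways: its distance is recomputed on the adjacency graph
#' ([build_adjacency_graph()]) and a full variable assignment is checked
#' against every formulated constraint and the objective row (1e-6).
#'
#' @param instance A `"ffdcj_ilp"` from [formulate()].
#' @param time_limit_s Time limit in seconds (default 240).
#' @param verify Check the decoded solution against the constraint matrix
#'   and the adjacency-graph recomputation (default `TRUE`).
#' @return Object of class `"ilp_solution"`: list with `status`
#'   (`"optimal"` or `"feasible_timeout"`), `distance`, `matching`
#'   (`data.frame` with `gene_a`, `gene_b`), `singletons` (gene IDs),
#'   `blocks`, `cycles`, `omega`, `solve_seconds`, `nodes`.
#' @export
solve_ilp <- function(instance, time_limit_s = 240, verify = TRUE) {
  stopifnot(inherits(instance, "ffdcj_ilp"))
  comp <- instance$component
  edges <- comp$edges
  nE <- nrow(edges)
  K <- instance$max_matching_size
  alpha <- instance$alpha
  indel_on <- instance$indel_model
  nA <- length(comp$genes_a)
  nB <- length(comp$genes_b)
  S_fixed <- nA + nB - 2L * K
  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE

  wkey <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  weights <- edges$weight

  best <- NULL
  best_key <- NULL
  nodes <- 0L

  eval_leaf <- function(sel) {
    matching <- edges[sel, c("gene_a", "gene_b"), drop = FALSE]
    pair_of_a <- stats::setNames(matching$gene_b, matching$gene_a)
    singles <- c(setdiff(comp$genes_a, matching$gene_a),
                 setdiff(comp$genes_b, matching$gene_b))
    cyc <- cycles_by_union(comp, matching$gene_a, matching$gene_b, pair_of_a)
    blocks <- count_singleton_blocks(comp$orders_a, singles) +
      count_singleton_blocks(comp$orders_b, singles)
    omega <- sum(weights[sel])
    M <- nrow(matching)
    d <- alpha * (M - cyc + if (indel_on) blocks + length(singles) else 0) +
      (1 - alpha) * (M - omega)
    key <- paste(sort(paste(matching$gene_a, matching$gene_b, sep = "|")),
                 collapse = ";")
    better <- is.null(best) ||
      d < best$distance - 1e-12 ||
      (abs(d - best$distance) <= 1e-12 &&
         (omega > best$omega + 1e-12 ||
            (abs(omega - best$omega) <= 1e-12 && key < best_key)))
    if (better) {
      best <<- list(distance = d, matching = matching, singletons = singles,
                    blocks = blocks, cycles = cyc, omega = omega)
      best_key <<- key
    }
  }

  used_a <- character()
  used_b <- character()
  sel <- integer()

  search <- function(i) {
    if (timed_out) return(invisible())
    nodes <<- nodes + 1L
    if (nodes %% 512L == 0L &&
        proc.time()[["elapsed"]] - t0 > time_limit_s) {
      timed_out <<- TRUE
      return(invisible())
    }
    if (i > nE) {
      if (length(sel) == K) eval_leaf(sel)
      return(invisible())
    }
    # cardinality feasibility: can the undecided edges still complete K?
    undecided <- i:nE
    free <- !(edges$gene_a[undecided] %in% used_a) &
      !(edges$gene_b[undecided] %in% used_b)
    cap <- min(length(unique(edges$gene_a[undecided][free])),
               length(unique(edges$gene_b[undecided][free])))
    if (length(sel) + cap < K) return(invisible())
    # objective bound: cycles at most K, singleton count fixed, best-case
    # remaining matching weight
    if (!is.null(best)) {
      w_free <- sort(weights[undecided][free], decreasing = TRUE)
      need <- K - length(sel)
      omega_ub <- sum(weights[sel]) + sum(w_free[seq_len(min(need, length(w_free)))])
      i_lb <- if (indel_on && S_fixed > 0L) 1L else 0L
      lb <- alpha * (if (indel_on) i_lb + S_fixed else 0) +
        (1 - alpha) * (K - omega_ub)
      if (lb > best$distance + 1e-9) return(invisible())
    }
    ea <- edges$gene_a[i]
    eb <- edges$gene_b[i]
    if (!(ea %in% used_a) && !(eb %in% used_b) && length(sel) < K) {
      used_a <<- c(used_a, ea); used_b <<- c(used_b, eb)
      sel <<- c(sel, i)
      search(i + 1L)
      used_a <<- used_a[-length(used_a)]
      used_b <<- used_b[-length(used_b)]
      sel <<- sel[-length(sel)]
    }
    search(i + 1L)
    invisible()
  }

  if (nE == 0L) {
    eval_leaf(integer())
  } else {
    search(1L)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  if (is.null(best)) {
    return(structure(list(status = "feasible_timeout", distance = NA_real_,
                          matching = NULL, singletons = character(),
                          blocks = NA_integer_, cycles = NA_integer_,
                          omega = NA_real_, solve_seconds = elapsed,
                          nodes = nodes),
                     class = "ilp_solution"))
  }

  if (verify) {
    check <- evaluate_matching(comp, best$matching, alpha)
    ref <- if (indel_on) check$distance else {
      alpha * (check$M - check$cycles) + (1 - alpha) * (check$M - check$omega)
    }
    if (abs(ref - best$distance) > 1e-6) {
      stop(sprintf("solver/adjacency-graph distance mismatch: %g vs %g",
                   best$distance, ref))
    }
    obj <- assignment_objective(instance, best$matching)
    if (abs(obj - best$distance) > 1e-6) {
      stop(sprintf("objective row (%g) disagrees with decoded distance (%g)",
                   obj, best$distance))
    }
  }

  structure(list(status = if (timed_out) "feasible_timeout" else "optimal",
                 distance = best$distance, matching = best$matching,
                 singletons = best$singletons, blocks = best$blocks,
                 cycles = best$cycles, omega = best$omega,
                 solve_seconds = elapsed, nodes = nodes),
            class = "ilp_solution")
}

#' @export
print.ilp_solution <- function(x, ...) {
  cat(sprintf("<ilp_solution> %s: distance %.4f (|M|=%d, c=%s, I=%s, S=%d) in %.2fs\n",
              x$status, x$distance,
              if (is.null(x$matching)) 0L else nrow(x$matching),
              x$cycles, x$blocks, length(x$singletons), x$solve_seconds))
  invisible(x)
}

#' Family-free DCJ-indel distance of a genome pair
#'
#' Convenience wrapper: builds the similarity graph, formulates the full
#' pairwise instance (no component decomposition, so cycle counting is
#' exact across the whole genomes) and solves it.
#'
#' @inheritParams brute_force_ffdcj_indel
#' @param time_limit_s Solver time limit in seconds.
#' @param indel_model Include singleton/block penalties (default `TRUE`).
#' @return An `"ilp_solution"`.
#' @export
ffdcj_indel_distance <- function(genome_a, genome_b, weighted_edges,
                                 alpha = 0.5, time_limit_s = 240,
                                 indel_model = TRUE) {
  ga <- genome_a$genes$gene_id
  gb <- genome_b$genes$gene_id
  keep <- (weighted_edges$gene_a %in% ga & weighted_edges$gene_b %in% gb) |
    (weighted_edges$gene_a %in% gb & weighted_edges$gene_b %in% ga)
  weighted_edges <- weighted_edges[keep, , drop = FALSE]
  gs <- build_gs_graph(genome_a, genome_b, weighted_edges)
  inst <- formulate(make_instance(gs), alpha = alpha,
                    indel_model = indel_model)
  solve_ilp(inst, time_limit_s = time_limit_s)
}

# greedy maximum-weight matching (timeout fallback, flagged by caller)
greedy_matching <- function(edges) {
  ord <- order(-edges$weight, edges$gene_a, edges$gene_b, method = "radix")
  used_a <- character(); used_b <- character(); keep <- integer()
  for (i in ord) {
    if (edges$gene_a[i] %in% used_a || edges$gene_b[i] %in% used_b) next
    keep <- c(keep, i)
    used_a <- c(used_a, edges$gene_a[i])
    used_b <- c(used_b, edges$gene_b[i])
  }
  edges[sort(keep), c("gene_a", "gene_b"), drop = FALSE]
}

#' Pairwise homology refinement of two genomes
#'
#' Runs the whole pairwise stage: similarity-graph construction, component
#' decomposition, the trivial-case shortcut (single-edge components are
#' accepted directly as homolog pairs without optimization), and one ILP
#' per nontrivial component. Isolated genes are forced singletons. If a
#' component's solve times out without an incumbent, a greedy
#' maximum-weight matching is used and flagged.
#'
#' @inheritParams brute_force_ffdcj_indel
#' @param alpha Order/similarity trade-off (default 0.5).
#' @param time_limit_s Per-component ILP time limit in seconds
#'   (default 240).
#' @param decompose Solve per similarity component (default) or as one
#'   full instance (exact cycle accounting; feasible for small inputs).
#' @param indel_model Include singleton/block penalties (default `TRUE`).
#' @param keep_ilps Optional directory; when given, every formulated
#'   instance is dumped there in LP format.
#' @return Object of class `"homology_pairs"`: list with `genome_a_id`,
#'   `genome_b_id`, `pairs` (`data.frame`: `gene_a`, `gene_b`, `source`
#'   in trivial/ilp/timeout-fallback), `singletons`, `stats` (component
#'   and solver counts) and `distance` (summed component distances).
#' @export
pairwise_refine <- function(genome_a, genome_b, weighted_edges,
                            alpha = 0.5, time_limit_s = 240,
                            decompose = TRUE, indel_model = TRUE,
                            keep_ilps = NULL) {
  # a dataset-wide edge table may be passed: keep only this pair's edges
  ga <- genome_a$genes$gene_id
  gb <- genome_b$genes$gene_id
  keep <- (weighted_edges$gene_a %in% ga & weighted_edges$gene_b %in% gb) |
    (weighted_edges$gene_a %in% gb & weighted_edges$gene_b %in% ga)
  gs <- build_gs_graph(genome_a, genome_b,
                       weighted_edges[keep, , drop = FALSE])
  comps <- if (decompose) gs_components(gs) else list(make_instance(gs))
  pairs <- list()
  singles <- character()
  n_trivial <- 0L; n_ilp <- 0L; n_timeout <- 0L
  total_distance <- 0
  if (!is.null(keep_ilps) && !dir.exists(keep_ilps)) {
    dir.create(keep_ilps, recursive = TRUE)
  }
  for (ci in seq_along(comps)) {
    cmp <- comps[[ci]]
    if (nrow(cmp$edges) == 0L) {
      singles <- c(singles, cmp$genes_a, cmp$genes_b)
      total_distance <- total_distance +
        (if (indel_model) 2 * alpha * (length(cmp$genes_a) + length(cmp$genes_b)) else 0)
      next
    }
    if (is_trivial_component(cmp)) {
      n_trivial <- n_trivial + 1L
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = cmp$edges$gene_a, gene_b = cmp$edges$gene_b,
        source = "trivial", stringsAsFactors = FALSE)
      total_distance <- total_distance +
        (1 - alpha) * (1 - cmp$edges$weight)
      next
    }
    inst <- formulate(cmp, alpha = alpha, indel_model = indel_model)
    if (!is.null(keep_ilps)) {
      write_lp(inst, file.path(keep_ilps, sprintf("component_%03d.lp", ci)))
    }
    sol <- solve_ilp(inst, time_limit_s = time_limit_s)
    if (is.null(sol$matching)) {
      n_timeout <- n_timeout + 1L
      m <- greedy_matching(cmp$edges)
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = m$gene_a, gene_b = m$gene_b,
        source = "timeout-fallback", stringsAsFactors = FALSE)
      next
    }
    if (sol$status == "feasible_timeout") n_timeout <- n_timeout + 1L
    n_ilp <- n_ilp + 1L
    if (nrow(sol$matching) > 0L) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = sol$matching$gene_a, gene_b = sol$matching$gene_b,
        source = "ilp", stringsAsFactors = FALSE)
    }
    singles <- c(singles, sol$singletons)
    total_distance <- total_distance + sol$distance
  }
  pairs <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(gene_a = character(), gene_b = character(),
               source = character(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b, method = "radix"), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(genome_a_id = genome_a$genome_id,
                 genome_b_id = genome_b$genome_id,
                 pairs = pairs, singletons = sort(singles),
                 stats = list(n_components = length(comps),
                              n_trivial = n_trivial, n_ilp = n_ilp,
                              n_timeout = n_timeout),
                 distance = total_distance),
            class = "homology_pairs")
}

#' @export
print.homology_pairs <- function(x, ...) {
  cat(sprintf("<homology_pairs> %s vs %s: %d pairs (%d trivial, %d via ILP), %d singletons\n",
              x$genome_a_id, x$genome_b_id, nrow(x$pairs),
              sum(x$pairs$source == "trivial"),
              sum(x$pairs$source != "trivial"), length(x$singletons)))
  invisible(x)
}
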