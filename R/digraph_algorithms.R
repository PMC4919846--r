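#' Accessibility (transitive closure) matrix
#'
#' Entry `(u, v)` is 1 iff a directed path of length >= 1 leads from `u` to
#' `v`. A diagonal entry is 1 only when the gene lies on a directed cycle
#' through itself; self-edges are never materialised as graph edges. The
#' accessibility relation is what steady-state knock-out data can resolve at
#' best: knocking out `u` perturbs exactly the genes accessible from `u`.
#'
#' @param g a [signed_digraph()]
#' @return a square 0/1 integer matrix over the node ordering
#' @export
accessibility_matrix <- function(g) {
  A <- adjacency_matrix(g)
  n <- nrow(A)
  if (n == 0L) return(A)
  # Warshall's algorithm; n is at most a few hundred genes here
  R <- A > 0L
  for (k in seq_len(n)) {
    R <- R | outer(R[, k], R[k, ], "&")
  }
  storage.mode(R) <- "integer"
  R
}

#' Transitive closure as a graph
#'
#' Returns the signed digraph whose edges are all ordered pairs `(u, v)` with
#' `v` accessible from `u` (`u != v`). Signs are taken from
#' [signed_closure()] semantics when `signed = TRUE` (direct edges keep their
#' sign; purely indirect pairs get the cumulative sign product along a
#' shortest directed path), otherwise all edges are `+1`.
#'
#' @param g a [signed_digraph()]
#' @param signed propagate signs along paths?
#' @return a [signed_digraph()]
#' @export
transitive_closure <- function(g, signed = TRUE) {
  if (signed) return(signed_closure(g))
  Acc <- accessibility_matrix(g)
  diag(Acc) <- 0L
  idx <- which(Acc == 1L, arr.ind = TRUE)
  signed_digraph(data.frame(from = g$nodes[idx[, 1L]],
                            to = g$nodes[idx[, 2L]],
                            sign = 1L, stringsAsFactors = FALSE),
                 nodes = g$nodes)
}

#' Signed transitive closure
#'
#' The idealised upper bound reachable from noise-free knock-out data: every
#' accessible ordered pair becomes an edge. The sign of a direct edge is the
#' edge's own sign (the direct regulation dominates the observed response);
#' a purely indirect pair carries the product of edge signs along a shortest
#' directed path (shortest-path tie-breaks are immaterial when all paths
#' agree, which holds for coherent cascades).
#'
#' @param g a [signed_digraph()]
#' @return a [signed_digraph()] over the same node set
#' @export
signed_closure <- function(g) {
  stopifnot(is_signed_digraph(g))
  Acc <- accessibility_matrix(g)
  diag(Acc) <- 0L
  S <- sign_matrix(g)
  A <- adjacency_matrix(g)
  n <- n_nodes(g)
  idx <- which(Acc == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(signed_digraph(NULL, nodes = g$nodes))
  sgn <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    u <- idx[r, 1L]; v <- idx[r, 2L]
    if (A[u, v] == 1L) {
      sgn[r] <- S[u, v]
    } else {
      sgn[r] <- path_sign_bfs(A, S, u, v)
    }
  }
  signed_digraph(data.frame(from = g$nodes[idx[, 1L]],
                            to = g$nodes[idx[, 2L]],
                            sign = sgn, stringsAsFactors = FALSE),
                 nodes = g$nodes)
}

# cumulative sign along one shortest directed path u -> v (BFS)
path_sign_bfs <- function(A, S, u, v) {
  n <- nrow(A)
  dist <- rep(NA_integer_, n)
  psign <- rep(NA_integer_, n)
  queue <- u
  dist[u] <- 0L
  psign[u] <- 1L
  while (length(queue) > 0L) {
    w <- queue[1L]
    queue <- queue[-1L]
    for (x in which(A[w, ] == 1L)) {
      if (is.na(dist[x])) {
        dist[x] <- dist[w] + 1L
        psign[x] <- psign[w] * S[w, x]
        if (x == v) return(psign[x])
        queue <- c(queue, x)
      }
    }
  }
  stop("no path found; accessibility matrix inconsistent")
}

#' Condense a digraph into its DAG of strongly connected components
#'
#' Genes on common directed cycles are lumped into one strongly connected
#' component; the quotient graph over components is acyclic, with
#' inter-component edges deduplicated.
#'
#' @param g a [signed_digraph()]
#' @return a list with `quotient` (a [signed_digraph()] over component
#'   labels, quotient edge signs carried from an arbitrary member edge for
#'   bookkeeping only), `membership` (named integer vector node ->
#'   component id) and `components` (list of character vectors)
#' @export
condense <- function(g) {
  stopifnot(is_signed_digraph(g))
  ig <- as_igraph(g)
  comp <- igraph::components(ig, mode = "strong")
  membership <- comp$membership
  comp_label <- function(id) paste0("scc", id)
  comps <- split(g$nodes, membership[g$nodes])
  names(comps) <- comp_label(names(comps))
  e <- g$edges
  cf <- membership[e$from]
  ct <- membership[e$to]
  keep <- which(cf != ct)
  if (length(keep) > 0L) {
    qe <- data.frame(from = comp_label(cf[keep]), to = comp_label(ct[keep]),
                     sign = e$sign[keep], stringsAsFactors = FALSE)
    qe <- qe[!duplicated(paste(qe$from, qe$to)), , drop = FALSE]
  } else {
    qe <- NULL
  }
  quotient <- signed_digraph(qe, nodes = comp_label(sort(unique(membership))))
  list(quotient = quotient, membership = membership, components = comps)
}

#' Transitive reduction of a directed acyclic graph
#'
#' Removes every edge `(i, j)` for which a directed path from `i` to `j`
#' exists that does not use the edge itself. For a DAG the result is the
#' unique minimum graph with the same accessibility matrix.
#'
#' @param g an acyclic [signed_digraph()]
#' @return a [signed_digraph()] with the reduced edge set (signs and weights
#'   carried over)
#' @export
transitive_reduction_dag <- function(g) {
  stopifnot(is_signed_digraph(g))
  if (has_cycle(g)) stop("input must be acyclic")
  e <- g$edges
  if (nrow(e) == 0L) return(g)
  A <- adjacency_matrix(g)
  # edge (i,j) is redundant iff some child k != j of i reaches j
  Acc <- accessibility_matrix(g)
  redundant <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    i <- e$from[r]; j <- e$to[r]
    ks <- g$nodes[A[i, ] == 1L]
    ks <- setdiff(ks, j)
    redundant[r] <- any(Acc[ks, j] == 1L)
  }
  signed_digraph(e[!redundant, , drop = FALSE], nodes = g$nodes)
}

#' Does the graph contain a directed cycle?
#' @param g a [signed_digraph()]
#' @return logical
#' @export
has_cycle <- function(g) {
  Acc <- accessibility_matrix(g)
  any(diag(Acc) == 1L)
}

#' Is there an indirect path between two genes avoiding a node set?
#'
#' Tests for a directed path from `i` to `j` of length >= 2 that avoids all
#' nodes in `excluded`. The direct edge `(i, j)`, if present, is ignored.
#' This is the defining property of a separatoid: a node set is a separator
#' for the edge `(i, j)` exactly when this function returns `FALSE`.
#'
#' @param g a [signed_digraph()]
#' @param i,j distinct gene identifiers
#' @param excluded character vector of genes removed from the graph (must not
#'   contain `i` or `j`)
#' @return logical
#' @export
has_indirect_path <- function(g, i, j, excluded = character()) {
  stopifnot(is_signed_digraph(g))
  if (i == j) stop("'i' and 'j' must differ")
  if (!i %in% g$nodes) stop("unknown node '", i, "'")
  if (!j %in% g$nodes) stop("unknown node '", j, "'")
  if (i %in% excluded || j %in% excluded) {
    stop("'excluded' must not contain 'i' or 'j'")
  }
  keep <- setdiff(g$nodes, excluded)
  e <- g$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  # drop the direct edge, then ask for plain reachability i -> j
  e <- e[!(e$from == i & e$to == j), , drop = FALSE]
  sub <- signed_digraph(e, nodes = keep)
  Acc <- accessibility_matrix(sub)
  Acc[i, j] == 1L
}
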