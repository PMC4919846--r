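# Independent brute-force oracles used to validate the graph algorithms.
# These deliberately avoid the package's matrix-based implementations:
# reachability is recursive DFS over the raw edge list, path existence is
# exhaustive simple-path enumeration, and transitive reduction is a search
# over all edge subsets.

# adjacency list from an edge data frame
oracle_adjlist <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    adj[[edges$from[r]]] <- c(adj[[edges$from[r]]], edges$to[r])
  }
  adj
}

# all nodes reachable from `start` by a path of length >= 1 (DFS)
oracle_reachable <- function(g, start) {
  adj <- oracle_adjlist(g$edges, g$nodes)
  seen <- character()
  stack <- adj[[start]]
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, adj[[v]])
  }
  sort(seen)
}

# does a simple directed path i -> ... -> j of length >= 2 exist avoiding
# `excluded` (exhaustive enumeration)?
oracle_indirect_path <- function(g, i, j, excluded = character()) {
  adj <- oracle_adjlist(g$edges, setdiff(g$nodes, excluded))
  adj <- lapply(adj, setdiff, y = excluded)
  found <- FALSE
  walk <- function(v, visited, len) {
    if (found) return()
    for (w in adj[[v]]) {
      if (w == j && len + 1L >= 2L) found <<- TRUE
      else if (w != j && !w %in% visited) walk(w, c(visited, w), len + 1L)
    }
  }
  if (!i %in% names(adj)) return(FALSE)
  walk(i, i, 0L)
  found
}

# closure as a sorted "from>to" key set, via the DFS oracle
oracle_closure_keys <- function(g) {
  keys <- character()
  for (u in g$nodes) {
    for (v in oracle_reachable(g, u)) keys <- c(keys, paste(u, v, sep = ">"))
  }
  sort(keys)
}

# minimum subgraph with the same closure, by exhaustive subset search
# (feasible for m <= ~12 edges)
oracle_min_closure_subgraph <- function(g) {
  target <- oracle_closure_keys(g)
  m <- nrow(g$edges)
  best <- g$edges
  for (size in 0:(m - 1L)) {
    hit <- NULL
    for (drop in utils::combn(m, m - size, simplify = FALSE)) {
      sub <- signed_digraph(g$edges[-drop, , drop = FALSE], nodes = g$nodes)
      if (identical(oracle_closure_keys(sub), target)) {
        hit <- sub$edges
        break
      }
    }
    if (!is.null(hit)) return(hit)
  }
  best
}

edge_key_set <- function(g, signed = TRUE) {
  e <- g$edges
  if (signed) sort(paste(e$from, e$to, e$sign)) else sort(paste(e$from, e$to))
}

graphs_identical <- function(a, b, signed = TRUE) {
  identical(edge_key_set(a, signed), edge_key_set(b, signed))
}

# small random digraph over letters, unrestricted sources (used by the
# algorithm oracles; edge probability p)
rand_digraph <- function(n, p = 0.3, negfrac = 0.4) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairs <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  sgn <- ifelse(stats::runif(nrow(pairs)) < negfrac, -1L, 1L)
  signed_digraph(data.frame(pairs, sign = sgn, stringsAsFactors = FALSE),
                 nodes = nodes)
}

# noise-free constructed dataset: values[gene, experiment, replicate]
make_dataset <- function(values, ko_sets, genes = rownames(values)) {
  ids <- vapply(ko_sets, function(k) if (length(k) == 0L) "WT" else
    paste(sort(k), collapse = ","), "")
  dimnames(values) <- list(genes, ids, NULL)
  names(ko_sets) <- ids
  structure(list(genes = genes,
                 ko_sets = lapply(ko_sets, function(k) sort(as.character(k))),
                 values = values),
            class = "expression_dataset")
}
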