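#' Construct a signed directed graph
#'
#' A signed digraph is the network model used throughout the package: nodes
#' are genes and a directed edge `(i, j)` with sign `+1` (activation) or `-1`
#' (repression) states that the product of gene `i` regulates the
#' transcription of gene `j`. Self-loops are disallowed and each ordered node
#' pair carries at most one edge (one sign per pair). Edges may optionally
#' carry a weight in `[0, 1]` quantifying regulatory strength.
#'
#' @param edges a data frame with columns `from`, `to`, `sign` and optionally
#'   `weight`. `sign` must be `+1` or `-1`; `weight`, when present, must lie in
#'   `[0, 1]`. A zero-row data frame (or `NULL`) gives an edgeless graph.
#' @param nodes character vector of gene identifiers. Defaults to the sorted
#'   union of edge endpoints. Supply explicitly to fix a node ordering or to
#'   include isolated genes.
#' @return an object of class `signed_digraph`: a list with components
#'   `nodes` (character) and `edges` (data frame `from`, `to`, `sign`
#'   and optionally `weight`, sorted by `(from, to)`).
#' @examples
#' g <- signed_digraph(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                sign = c(1, -1)))
#' g
#' @export
signed_digraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("from", "to", "sign")
  if (!all(required %in% names(edges))) {
    stop("'edges' must have columns 'from', 'to' and 'sign'")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) {
      bad <- edges$from[edges$from == edges$to][1L]
      stop("self-loops are not allowed (node '", bad, "')")
    }
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge signs must be +1 or -1")
    }
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("duplicate edge for ordered pair ",
           gsub("\r", " -> ", dup, fixed = TRUE))
    }
    if ("weight" %in% names(edges)) {
      w <- as.numeric(edges$weight)
      if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
        stop("edge weights must be finite and lie in [0, 1]")
      }
      edges$weight <- w
    }
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers")
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(missing) > 0L) {
      stop("edge endpoint(s) not in node set: ",
           paste(missing, collapse = ", "))
    }
  }
  keep <- intersect(c("from", "to", "sign", "weight"), names(edges))
  edges <- edges[order(edges$from, edges$to), keep, drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_digraph")
}

#' Test for the signed-digraph class
#' @param x an object
#' @return `TRUE` for `signed_digraph` objects
#' @export
is_signed_digraph <- function(x) inherits(x, "signed_digraph")

#' Number of nodes and edges
#'
#' Order (number of genes) and size (number of regulatory edges) of a signed
#' digraph.
#' @param g a [signed_digraph()]
#' @return an integer
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
print.signed_digraph <- function(x, ...) {
  cat("Signed digraph: ", n_nodes(x), " genes, ", n_edges(x), " edges (",
      sum(x$edges$sign > 0), " activating, ", sum(x$edges$sign < 0),
      " repressing)\n", sep = "")
  if (n_edges(x) > 0L) {
    show <- utils::head(x$edges, 10L)
    lab <- paste0("  ", show$from, ifelse(show$sign > 0, " -> ", " -| "),
                  show$to)
    if ("weight" %in% names(show)) {
      lab <- paste0(lab, sprintf("  (w=%.2f)", show$weight))
    }
    cat(lab, sep = "\n")
    if (n_edges(x) > 10L) cat("  ... and", n_edges(x) - 10L, "more edges\n")
  }
  invisible(x)
}

#' @export
plot.signed_digraph <- function(x, ...) {
  ig <- as_igraph(x)
  cols <- ifelse(igraph::E(ig)$sign > 0, "black", "red3")
  igraph::plot.igraph(ig, edge.color = cols, ...)
  invisible(x)
}

#' Convert to an igraph object
#'
#' @param g a [signed_digraph()]
#' @return an [igraph::graph] with a `sign` edge attribute
#' @export
as_igraph <- function(g) {
  stopifnot(is_signed_digraph(g))
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = g$nodes)
}

# canonical "from\rto" keys used for set operations on edges
edge_keys <- function(g) paste(g$edges$from, g$edges$to, sep = "\r")

#' Adjacency and sign matrices
#'
#' The adjacency matrix has entry `(u, v) = 1` iff the edge `(u, v)` exists;
#' the companion sign matrix holds the edge sign at exactly those entries and
#' 0 elsewhere. The diagonal is always 0 (no self-loops). Rows and columns
#' follow the graph's node ordering.
#'
#' @param g a [signed_digraph()]
#' @return a square integer matrix with dimnames equal to the node set
#' @export
adjacency_matrix <- function(g) {
  stopifnot(is_signed_digraph(g))
  n <- n_nodes(g)
  A <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  if (n_edges(g) > 0L) A[cbind(g$edges$from, g$edges$to)] <- 1L
  A
}

#' @rdname adjacency_matrix
#' @export
sign_matrix <- function(g) {
  stopifnot(is_signed_digraph(g))
  n <- n_nodes(g)
  S <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  if (n_edges(g) > 0L) S[cbind(g$edges$from, g$edges$to)] <- g$edges$sign
  S
}

#' Weight matrix of a signed digraph
#'
#' Edge weights arranged as a square matrix; entries without an edge are
#' `NA`. If the graph carries no weights, all edge entries default to 1.
#'
#' @param g a [signed_digraph()]
#' @return a square numeric matrix
#' @export
weight_matrix <- function(g) {
  stopifnot(is_signed_digraph(g))
  n <- n_nodes(g)
  W <- matrix(NA_real_, n, n, dimnames = list(g$nodes, g$nodes))
  if (n_edges(g) > 0L) {
    w <- if ("weight" %in% names(g$edges)) g$edges$weight else 1
    W[cbind(g$edges$from, g$edges$to)] <- w
  }
  W
}

#' One-step and transitive neighbourhoods of a gene
#'
#' `parents`/`children` are the direct regulators/targets of `node`;
#' `ancestors`/`descendants` are their transitive counterparts (all genes
#' from/to which a directed path exists). A gene is its own ancestor or
#' descendant if and only if it lies on a directed cycle through itself.
#'
#' @param g a [signed_digraph()]
#' @param node a gene identifier present in `g`
#' @param relation one of `"parents"`, `"children"`, `"ancestors"`,
#'   `"descendants"`
#' @return a character vector of gene identifiers (possibly empty)
#' @export
node_relatives <- function(g, node,
                           relation = c("parents", "children",
                                        "ancestors", "descendants")) {
  stopifnot(is_signed_digraph(g))
  relation <- match.arg(relation)
  if (!node %in% g$nodes) stop("unknown node '", node, "'")
  switch(relation,
    parents  = sort(unique(g$edges$from[g$edges$to == node])),
    children = sort(unique(g$edges$to[g$edges$from == node])),
    ancestors = {
      Acc <- accessibility_matrix(g)
      g$nodes[Acc[, node] == 1L]
    },
    descendants = {
      Acc <- accessibility_matrix(g)
      g$nodes[Acc[node, ] == 1L]
    })
}

#' Delete genes from a network
#'
#' Removes the given nodes together with every edge incident to them,
#' emulating a gene knock-out at the graph level.
#'
#' @param g a [signed_digraph()]
#' @param nodes genes to delete
#' @return a [signed_digraph()] over the remaining genes
#' @export
delete_nodes <- function(g, nodes) {
  stopifnot(is_signed_digraph(g))
  unknown <- setdiff(nodes, g$nodes)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  keep <- !(g$edges$from %in% nodes | g$edges$to %in% nodes)
  signed_digraph(g$edges[keep, , drop = FALSE], setdiff(g$nodes, nodes))
}
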