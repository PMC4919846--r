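#' Sign-consistent local transitive reduction
#'
#' Builds the ensemble lower bound from a signed upper bound: an edge
#' `(i, j)` is removed when some length-2 directed path `i -> k -> j` in the
#' upper bound explains it, i.e. when
#' `S(i, j) = S(i, k) * S(k, j)` (sign consistency) and
#' `w_cut * W(i, j) < W(i, k) * W(k, j)` (the indirect route is strong
#' enough; strict inequality). All conditions are evaluated against the
#' original upper bound, never against a partially reduced graph, so the
#' result does not depend on edge-processing order. Restricting to length-2
#' paths sidesteps the sign ambiguity of negative cycles: traversing a cycle
#' more than once always yields a longer path.
#'
#' @param upper a signed [signed_digraph()]; per-edge weights are used when
#'   present, otherwise every weight defaults to 1
#' @param w_cut weight cutoff ratio in `[0, 1]`; `w_cut = 0` disables the
#'   weight condition (for strictly positive weights)
#' @param W optional weight matrix overriding the graph's edge weights
#' @return the lower-bound [signed_digraph()]
#' @export
signed_ltr <- function(upper, w_cut = 0.3, W = NULL) {
  stopifnot(is_signed_digraph(upper))
  if (w_cut < 0 || w_cut > 1) stop("'w_cut' must lie in [0, 1]")
  e <- upper$edges
  if (nrow(e) == 0L) return(upper)
  A <- adjacency_matrix(upper)
  S <- sign_matrix(upper)
  if (is.null(W)) {
    W <- weight_matrix(upper)
  } else {
    stopifnot(is.matrix(W))
    W <- W[upper$nodes, upper$nodes]
  }
  W[is.na(W)] <- 1
  removed <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    i <- e$from[r]; j <- e$to[r]
    ks <- upper$nodes[A[i, ] == 1L & A[, j] == 1L]
    ks <- setdiff(ks, c(i, j))
    if (length(ks) == 0L) next
    consistent <- S[i, j] == S[i, ks] * S[ks, j]
    strong <- w_cut * W[i, j] < W[i, ks] * W[ks, j]
    removed[r] <- any(consistent & strong)
  }
  signed_digraph(e[!removed, , drop = FALSE], nodes = upper$nodes)
}

#' Unsigned condensation-reduction-expansion lower bound
#'
#' The sign-agnostic baseline lower bound: (1) condense strongly connected
#' components into a DAG, (2) transitively reduce the DAG, (3) expand the
#' components back, removing every edge incident to a component of two or
#' more genes except the two edges inside each two-gene cycle. Signs are
#' carried over from the upper bound for bookkeeping only; the procedure
#' itself ignores them.
#'
#' @param upper a [signed_digraph()]
#' @return the lower-bound [signed_digraph()]
#' @export
contrex_reduction <- function(upper) {
  stopifnot(is_signed_digraph(upper))
  e <- upper$edges
  if (nrow(e) == 0L) return(upper)
  con <- condense(upper)
  red <- transitive_reduction_dag(con$quotient)
  qkeys <- edge_keys(red)
  memb <- con$membership
  csize <- table(memb)
  keep <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    ci <- memb[e$from[r]]
    cj <- memb[e$to[r]]
    if (ci == cj) {
      # intra-component edge: kept only inside a two-gene cycle
      keep[r] <- csize[as.character(ci)] == 2L
    } else {
      # inter-component edge: kept iff both endpoints are singleton
      # components and the quotient edge survived the reduction
      keep[r] <- csize[as.character(ci)] == 1L &&
        csize[as.character(cj)] == 1L &&
        paste(paste0("scc", ci), paste0("scc", cj), sep = "\r") %in% qkeys
    }
  }
  signed_digraph(e[keep, , drop = FALSE], nodes = upper$nodes)
}

new_grn_ensemble <- function(upper, lower, initial_upper, params, call) {
  obj <- structure(list(upper = upper, lower = lower,
                        initial_upper = initial_upper,
                        params = params, call = call),
                   class = "grn_ensemble")
  validate_bounds(obj)
  obj
}

validate_bounds <- function(x) {
  lk <- edge_keys(x$lower)
  uk <- edge_keys(x$upper)
  if (!all(lk %in% uk)) {
    stop("lower-bound edges must be a subset of the upper bound")
  }
  su <- x$upper$edges$sign[match(lk, uk)]
  if (length(lk) > 0L && any(su != x$lower$edges$sign)) {
    stop("lower-bound edge signs must match the upper bound")
  }
  invisible(x)
}

#' Uncertain edges of an ensemble
#'
#' Edges present in the upper bound but absent from the lower bound; their
#' existence cannot be decided from the data seen so far.
#'
#' @param x a [grn_ensemble()]
#' @return a data frame `from`, `to`, `sign`
#' @export
uncertain_edges <- function(x) {
  stopifnot(inherits(x, "grn_ensemble"))
  uk <- edge_keys(x$upper)
  lk <- edge_keys(x$lower)
  x$upper$edges[!(uk %in% lk), c("from", "to", "sign"), drop = FALSE]
}

#' Infer ensemble network bounds from a knock-out compendium
#'
#' The central fitting function. From a complete single-gene knock-out
#' compendium it computes (1) the z-score matrix of differential expression,
#' (2) the signed accessibility graph, which is the ensemble upper bound
#' (every network consistent with the data is a subgraph of it), and (3) the
#' ensemble lower bound (edges every consistent network must contain). With
#' `method = "signed"` the lower bound is the sign-consistent local
#' transitive reduction with correlation edge weights; with
#' `method = "unsigned"` it is the condensation-reduction-expansion
#' baseline that ignores signs.
#'
#' @param data an `expression_dataset` covering the complete single-KO
#'   design (a wild-type experiment, when present, enters the per-gene
#'   statistics)
#' @param method `"signed"` or `"unsigned"` lower-bound construction
#' @param z_cutoff outlier-exclusion threshold for [corrected_stats()]
#' @param z_threshold accessibility threshold on averaged z-scores
#' @param w_cut weight cutoff ratio for [signed_ltr()]
#' @return an object of class `grn_ensemble` with components `upper`,
#'   `lower`, `initial_upper` (frozen copy of the first upper bound),
#'   `params` and `call`. Use [uncertain_edges()], [update.grn_ensemble()],
#'   [evaluate_bounds()] on it.
#' @examples
#' net <- random_grn(8, seed = 1)
#' mod <- kinetic_model(net, seed = 2)
#' dat <- generate_compendium(mod, config = sim_config(replicates = 4),
#'                            seed = 3)
#' fit <- grn_ensemble(dat, w_cut = 0.3)
#' fit
#' @export
grn_ensemble <- function(data, method = c("signed", "unsigned"),
                         z_cutoff = 3, z_threshold = 2, w_cut = 0.3) {
  method <- match.arg(method)
  Z <- zscore_matrix(data, z_cutoff)
  acc <- accessibility_from_z(Z, z_threshold)
  upper <- acc$graph
  if (method == "signed") {
    W <- edge_weights(data)
    upper$edges$weight <- W[cbind(upper$edges$from, upper$edges$to)]
    lower <- signed_ltr(upper, w_cut = w_cut, W = W)
  } else {
    lower <- contrex_reduction(upper)
  }
  new_grn_ensemble(upper, lower, initial_upper = upper,
                   params = list(method = method, z_cutoff = z_cutoff,
                                 z_threshold = z_threshold, w_cut = w_cut),
                   call = match.call())
}

#' Build ensemble bounds from a given upper bound
#'
#' Variant of [grn_ensemble()] for workflows where the upper bound is
#' already known (e.g. an idealised signed closure): only the lower-bound
#' reduction is applied.
#'
#' @inheritParams grn_ensemble
#' @param upper a [signed_digraph()] used as upper bound (and frozen as the
#'   initial upper bound)
#' @param W optional weight matrix for the signed reduction
#' @return a `grn_ensemble`
#' @export
ensemble_from_upper <- function(upper, method = c("signed", "unsigned"),
                                w_cut = 0.3, W = NULL) {
  method <- match.arg(method)
  lower <- if (method == "signed") signed_ltr(upper, w_cut = w_cut, W = W)
           else contrex_reduction(upper)
  new_grn_ensemble(upper, lower, initial_upper = upper,
                   params = list(method = method, z_cutoff = NA,
                                 z_threshold = NA, w_cut = w_cut),
                   call = match.call())
}

#' @export
print.grn_ensemble <- function(x, ...) {
  cat("Ensemble network bounds (", x$params$method, " reduction)\n",
      sep = "")
  cat("  upper bound: ", n_edges(x$upper), " edges\n", sep = "")
  cat("  lower bound: ", n_edges(x$lower), " edges\n", sep = "")
  cat("  uncertain:   ", nrow(uncertain_edges(x)), " edges\n", sep = "")
  invisible(x)
}

#' @export
summary.grn_ensemble <- function(object, ...) {
  un <- uncertain_edges(object)
  out <- list(
    n_genes = n_nodes(object$upper),
    n_upper = n_edges(object$upper),
    n_lower = n_edges(object$lower),
    n_uncertain = nrow(un),
    uncertain = un,
    converged = nrow(un) == 0L,
    params = object$params)
  class(out) <- "summary.grn_ensemble"
  out
}

#' @export
print.summary.grn_ensemble <- function(x, ...) {
  cat("Ensemble network bounds over", x$n_genes, "genes\n")
  cat(sprintf("  upper %d edges | lower %d edges | uncertain %d\n",
              x$n_upper, x$n_lower, x$n_uncertain))
  if (x$converged) {
    cat("  bounds have converged: the network is uniquely determined\n")
  } else if (x$n_uncertain <= 15L) {
    cat("  uncertain edges:\n")
    lab <- paste0("    ", x$uncertain$from,
                  ifelse(x$uncertain$sign > 0, " -> ", " -| "),
                  x$uncertain$to)
    cat(lab, sep = "\n")
  }
  invisible(x)
}

#' @export
plot.grn_ensemble <- function(x, ...) {
  un <- uncertain_edges(x)
  ig <- as_igraph(x$upper)
  ek <- paste(x$upper$edges$from, x$upper$edges$to)
  uk <- paste(un$from, un$to)
  col <- ifelse(ek %in% uk, "grey60",
                ifelse(x$upper$edges$sign > 0, "black", "red3"))
  lty <- ifelse(ek %in% uk, 2L, 1L)
  igraph::plot.igraph(ig, edge.color = col, edge.lty = lty, ...)
  invisible(x)
}

#' Extract inferred edges
#'
#' `coef` method: returns the lower-bound (confirmed) edge list of the
#' ensemble, the point summary of the fit.
#'
#' @param object a `grn_ensemble`
#' @param ... unused
#' @return a data frame `from`, `to`, `sign`
#' @export
coef.grn_ensemble <- function(object, ...) {
  object$lower$edges[, c("from", "to", "sign"), drop = FALSE]
}
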