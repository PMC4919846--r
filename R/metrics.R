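#' Edge-set intersection of two networks
#'
#' In signed mode an ordered pair counts as shared only when both graphs
#' carry it with the same sign; in unsigned mode the pair alone decides.
#'
#' @param a,b [signed_digraph()] objects
#' @param signed respect edge signs?
#' @return a data frame of the shared edges (with `a`'s signs)
#' @export
edge_intersection <- function(a, b, signed = TRUE) {
  stopifnot(is_signed_digraph(a), is_signed_digraph(b))
  ka <- edge_keys(a); kb <- edge_keys(b)
  shared <- ka %in% kb
  if (signed && any(shared)) {
    sb <- b$edges$sign[match(ka[shared], kb)]
    shared[shared] <- a$edges$sign[shared] == sb
  }
  a$edges[shared, c("from", "to", "sign"), drop = FALSE]
}

edge_count_union <- function(graphs, signed) {
  keys <- unlist(lapply(graphs, function(g) {
    if (signed) paste(edge_keys(g), g$edges$sign) else edge_keys(g)
  }))
  length(unique(keys))
}

edge_count_intersection <- function(graphs, signed) {
  keysets <- lapply(graphs, function(g) {
    if (signed) paste(edge_keys(g), g$edges$sign) else edge_keys(g)
  })
  length(Reduce(intersect, keysets))
}

#' True positive rate of the lower bound
#'
#' Fraction of the reference network's edges recovered in the lower bound
#' (sign-respecting in signed mode).
#'
#' @param lower the lower-bound [signed_digraph()]
#' @param reference the reference [signed_digraph()] (non-empty)
#' @param signed respect edge signs?
#' @return a scalar in `[0, 1]`
#' @export
true_positive_rate <- function(lower, reference, signed = TRUE) {
  if (n_edges(reference) == 0L) {
    stop("true positive rate undefined for an empty reference network")
  }
  nrow(edge_intersection(reference, lower, signed)) / n_edges(reference)
}

#' Total distance between ensemble bounds and a reference network
#'
#' `TD = [N(U(up, low, ref)) - N(I(up, low, ref))] / N(ref)` over edge sets:
#' the three-way union minus the three-way intersection, scaled by the
#' reference size. Zero iff both bounds equal the reference; larger values
#' indicate more inference uncertainty.
#'
#' @param upper,lower the ensemble bound [signed_digraph()]s
#' @inheritParams true_positive_rate
#' @return a non-negative scalar
#' @export
total_distance <- function(upper, lower, reference, signed = TRUE) {
  if (n_edges(reference) == 0L) {
    stop("total distance undefined for an empty reference network")
  }
  gs <- list(upper, lower, reference)
  (edge_count_union(gs, signed) - edge_count_intersection(gs, signed)) /
    n_edges(reference)
}

#' Jaccard distance between two networks
#'
#' `JD = [N(union) - N(intersection)] / N(union)` over edge sets. 0 for
#' identical edge sets, 1 for disjoint ones. Both graphs empty is defined
#' as 0 with a warning.
#'
#' @param a,b [signed_digraph()] objects
#' @param signed respect edge signs?
#' @return a scalar in `[0, 1]`
#' @export
jaccard_distance <- function(a, b, signed = TRUE) {
  gs <- list(a, b)
  u <- edge_count_union(gs, signed)
  if (u == 0L) {
    warning("both edge sets empty; Jaccard distance defined as 0")
    return(0)
  }
  (u - edge_count_intersection(gs, signed)) / u
}

#' Tally inference errors against a reference network
#'
#' Three error classes: false negatives (`fn`) are reference edges missing
#' from the upper bound (sign ignored); false positives (`fp`) are
#' lower-bound edges absent from the reference (sign ignored); incorrect
#' signs (`is_count`) are reference edges present in the upper bound with
#' the opposite sign.
#'
#' @param x a `grn_ensemble` (or a list with `upper` and `lower` graphs)
#' @param reference the reference [signed_digraph()]
#' @return a list with integer `fn`, `fp` and `is_count`
#' @export
error_tally <- function(x, reference) {
  upper <- x$upper; lower <- x$lower
  ku <- edge_keys(upper); kl <- edge_keys(lower); kr <- edge_keys(reference)
  fn <- sum(!kr %in% ku)
  fp <- sum(!kl %in% kr)
  at <- match(kr, ku)
  hit <- !is.na(at)
  is_count <- sum(reference$edges$sign[hit] != upper$edges$sign[at[hit]])
  list(fn = fn, fp = fp, is_count = as.integer(is_count))
}

#' Score ensemble bounds against a reference network
#'
#' Convenience wrapper computing the true positive rate, total distance,
#' the Jaccard distances of both bounds from the reference, and the error
#' tallies.
#'
#' @param x a `grn_ensemble`
#' @param reference the reference [signed_digraph()]
#' @param signed respect edge signs in TPR/TD/JD?
#' @return a list of class `bounds_evaluation` with fields `tpr`, `td`,
#'   `jd_upper`, `jd_lower`, `fn`, `fp`, `is_count`, `mode`
#' @export
evaluate_bounds <- function(x, reference, signed = TRUE) {
  stopifnot(inherits(x, "grn_ensemble"))
  err <- error_tally(x, reference)
  structure(list(
    tpr = true_positive_rate(x$lower, reference, signed),
    td = total_distance(x$upper, x$lower, reference, signed),
    jd_upper = jaccard_distance(x$upper, reference, signed),
    jd_lower = jaccard_distance(x$lower, reference, signed),
    fn = err$fn, fp = err$fp, is_count = err$is_count,
    mode = if (signed) "signed" else "unsigned"),
    class = "bounds_evaluation")
}

#' @export
print.bounds_evaluation <- function(x, ...) {
  cat(sprintf("Bounds evaluation (%s mode)\n", x$mode))
  cat(sprintf("  TPR %.3f | TD %.3f | JD(upper) %.3f | JD(lower) %.3f\n",
              x$tpr, x$td, x$jd_upper, x$jd_lower))
  cat(sprintf("  errors: FN %d, FP %d, IS %d\n", x$fn, x$fp, x$is_count))
  invisible(x)
}
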