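#' Candidate separatoids of the uncertain edges
#'
#' For every uncertain edge `(i, j)` three easily computed candidate
#' separator node sets are derived from the current upper bound `G^U` and
#' the frozen initial upper bound `G^U0`:
#' \itemize{
#'   \item `Sep1 = children(i, G^U)  intersect ancestors(j, G^U0)`
#'   \item `Sep2 = descendants(i, G^U0) intersect parents(j, G^U)`
#'   \item `Sep3 = descendants(i, G^U0) intersect ancestors(j, G^U0)`
#' }
#' with `i` and `j` removed from every set. Knocking out all genes of a
#' separatoid eliminates every directed path of length >= 2 from `i` to `j`,
#' so that a differential response of `j` to deleting `i` in that background
#' can only flow through the direct edge. These three are not the only
#' separatoids (enumerating all of them amounts to a longest-path search,
#' which is NP-hard) but they are cheap and always valid whenever the upper
#' bound contains the true network's accessibility relation.
#'
#' @param x a `grn_ensemble`
#' @return a named list (one entry per uncertain edge, name `"i→j"`) of
#'   lists with elements `i`, `j` and `seps` (list of the three character
#'   vectors)
#' @export
compute_separatoids <- function(x) {
  stopifnot(inherits(x, "grn_ensemble"))
  un <- uncertain_edges(x)
  if (nrow(un) == 0L) return(structure(list(), names = character()))
  gu <- x$upper
  gu0 <- x$initial_upper
  acc_u <- accessibility_matrix(gu)
  acc_0 <- accessibility_matrix(gu0)
  A_u <- adjacency_matrix(gu)
  nodes <- gu$nodes
  out <- vector("list", nrow(un))
  for (r in seq_len(nrow(un))) {
    i <- un$from[r]; j <- un$to[r]
    children_i_u <- nodes[A_u[i, ] == 1L]
    parents_j_u <- nodes[A_u[, j] == 1L]
    desc_i_0 <- nodes[acc_0[i, ] == 1L]
    anc_j_0 <- nodes[acc_0[, j] == 1L]
    anc_j_u0 <- anc_j_0
    trim <- function(s) sort(setdiff(s, c(i, j)))
    out[[r]] <- list(
      i = i, j = j,
      seps = list(sep1 = trim(intersect(children_i_u, anc_j_u0)),
                  sep2 = trim(intersect(desc_i_0, parents_j_u)),
                  sep3 = trim(intersect(desc_i_0, anc_j_0))))
  }
  names(out) <- paste(un$from, un$to, sep = "\r")
  out
}

#' Find verifying knock-out experiment pairs for an uncertain edge
#'
#' Searches the performed KO sets for pairs `(V_k, V_k + {i})` such that
#' `i, j` are not in `V_k` and at least one candidate separatoid of the edge
#' is contained in `V_k` (subset, not proper subset: the background may
#' equal the separatoid). Comparing gene `j`'s expression between the two
#' experiments of such a pair isolates the direct regulation `i -> j`.
#'
#' @param edge list with elements `i`, `j` and `seps` (as produced by
#'   [compute_separatoids()])
#' @param ko_sets list of performed KO sets (character vectors)
#' @return a data frame with columns `background`, `test` (list columns of
#'   KO sets) and `sep` (index of the licensing separatoid), deduplicated by
#'   background and ordered by background size then lexicographically
#' @export
find_verification_pairs <- function(edge, ko_sets) {
  i <- edge$i; j <- edge$j
  ids <- vapply(ko_sets, ko_id, "")
  bg_idx <- integer()
  sep_idx <- integer()
  for (k in seq_along(ko_sets)) {
    vk <- ko_sets[[k]]
    if (i %in% vk || j %in% vk) next
    lic <- 0L
    for (l in seq_along(edge$seps)) {
      if (all(edge$seps[[l]] %in% vk)) { lic <- l; break }
    }
    if (lic == 0L) next
    if (!ko_id(sort(c(vk, i))) %in% ids) next
    bg_idx <- c(bg_idx, k)
    sep_idx <- c(sep_idx, lic)
  }
  if (length(bg_idx) == 0L) {
    return(data.frame(background = I(list()), test = I(list()),
                      sep = integer()))
  }
  keep <- !duplicated(ids[bg_idx])
  bg_idx <- bg_idx[keep]
  sep_idx <- sep_idx[keep]
  ord <- order(lengths(ko_sets[bg_idx]), ids[bg_idx])
  bg_idx <- bg_idx[ord]
  sep_idx <- sep_idx[ord]
  data.frame(
    background = I(lapply(ko_sets[bg_idx], sort)),
    test = I(lapply(ko_sets[bg_idx], function(v) sort(c(v, i)))),
    sep = sep_idx)
}

#' Two-sample t-test on one gene between two knock-out experiments
#'
#' Pooled-variance two-tailed two-sample t-test on the replicate expression
#' values of `gene` between the `background` and `test` experiments.
#' When both samples are exactly constant the test degenerates: the null is
#' rejected iff the two means differ beyond a tiny relative tolerance
#' (noise-free simulated data land here), and never rejected when the means
#' coincide.
#'
#' @param data an `expression_dataset` containing both experiments
#' @param gene the measured gene
#' @param background,test KO sets (character vectors) identifying the two
#'   experiments
#' @param alpha significance level (default 0.01); the null is rejected for
#'   p-values strictly below it
#' @param var_equal pooled (`TRUE`, default) or Welch (`FALSE`) variance
#' @return a list with `reject` (logical), `direction` (`"below"` iff the
#'   test-experiment mean is lower than the background mean), `p_value` and
#'   `statistic`
#' @export
edge_ttest <- function(data, gene, background, test, alpha = 0.01,
                       var_equal = TRUE) {
  stopifnot(inherits(data, "expression_dataset"))
  bi <- ko_index(data, background)
  ti <- ko_index(data, test)
  if (is.na(bi) || is.na(ti)) stop("experiment not present in data")
  if (!gene %in% data$genes) stop("unknown gene '", gene, "'")
  xb <- data$values[gene, bi, ]
  xt <- data$values[gene, ti, ]
  if (length(xb) < 2L || length(xt) < 2L) {
    stop("at least 2 replicates required")
  }
  mb <- mean(xb); mt <- mean(xt)
  direction <- if (mt < mb) "below" else "above"
  tol <- 1e-8 * max(1, abs(mb), abs(mt))
  if (stats::sd(xb) == 0 && stats::sd(xt) == 0) {
    reject <- abs(mt - mb) > tol
    return(list(reject = reject, direction = direction,
                p_value = if (reject) 0 else 1,
                statistic = if (reject) Inf else 0))
  }
  tt <- stats::t.test(xt, xb, var.equal = var_equal)
  list(reject = tt$p.value < alpha, direction = direction,
       p_value = tt$p.value, statistic = unname(tt$statistic))
}

# apply one edge verdict to the bounds; votes is a list of
# list(reject=, direction=) results, one per verification pair
edge_verdict <- function(votes, upper_sign) {
  nfor <- sum(vapply(votes, `[[`, TRUE, "reject"))
  nagainst <- length(votes) - nfor
  if (nfor > nagainst) {
    dirs <- vapply(votes[vapply(votes, `[[`, TRUE, "reject")],
                   `[[`, "", "direction")
    nb <- sum(dirs == "below")
    na_ <- sum(dirs == "above")
    sign <- if (nb > na_) 1L else if (na_ > nb) -1L else upper_sign
    list(decision = "confirm", sign = sign,
         votes_for = nfor, votes_against = nagainst)
  } else if (nagainst > nfor) {
    list(decision = "remove", sign = NA_integer_,
         votes_for = nfor, votes_against = nagainst)
  } else {
    list(decision = "undecided", sign = NA_integer_,
         votes_for = nfor, votes_against = nagainst)
  }
}

#' Update ensemble bounds with multi-gene knock-out data
#'
#' Iteratively refines the ensemble using all experiments present in
#' `data`. Each round: (1) recompute the candidate separatoids of the
#' uncertain edges from the round-start bounds, (2) collect the verifying
#' experiment pairs of every uncertain edge, (3) run the per-pair t-tests
#' and vote. A majority of rejections confirms the edge (it moves into the
#' lower bound, its sign set by the majority response direction among the
#' confirming pairs — a drop in the target upon deleting the regulator votes
#' for activation; sign ties keep the upper bound's sign, and a changed
#' confirmed sign overwrites the upper bound's); a majority of
#' non-rejections removes the edge from the upper bound; a tie leaves the
#' edge uncertain. All verdicts in a round are computed against the
#' round-start bounds and applied together, so the result does not depend on
#' edge order. Rounds repeat until no uncertain edge has a verification pair
#' or a full round changes nothing.
#'
#' @param object a `grn_ensemble`
#' @param data an `expression_dataset` holding all performed experiments,
#'   single-gene KOs included
#' @param alpha t-test significance level
#' @param var_equal pooled (default) or Welch t-test
#' @param ... unused
#' @return the updated `grn_ensemble`; the element `last_update` records
#'   per-round vote tallies
#' @export
update.grn_ensemble <- function(object, data, alpha = 0.01,
                                var_equal = TRUE, ...) {
  stopifnot(inherits(object, "grn_ensemble"),
            inherits(data, "expression_dataset"))
  ko_sets <- unname(data$ko_sets)
  log <- list()
  repeat {
    seps <- compute_separatoids(object)
    if (length(seps) == 0L) break
    verdicts <- list()
    for (ed in seps) {
      pairs <- find_verification_pairs(ed, ko_sets)
      if (nrow(pairs) == 0L) next
      votes <- lapply(seq_len(nrow(pairs)), function(p) {
        edge_ttest(data, ed$j, pairs$background[[p]], pairs$test[[p]],
                   alpha = alpha, var_equal = var_equal)
      })
      usign <- object$upper$edges$sign[
        object$upper$edges$from == ed$i & object$upper$edges$to == ed$j]
      v <- edge_verdict(votes, usign)
      v$i <- ed$i; v$j <- ed$j; v$n_pairs <- nrow(pairs)
      verdicts[[length(verdicts) + 1L]] <- v
    }
    if (length(verdicts) == 0L) break
    changed <- FALSE
    upper <- object$upper
    lower <- object$lower
    for (v in verdicts) {
      ui <- which(upper$edges$from == v$i & upper$edges$to == v$j)
      if (v$decision == "remove") {
        upper$edges <- upper$edges[-ui, , drop = FALSE]
        changed <- TRUE
      } else if (v$decision == "confirm") {
        if (upper$edges$sign[ui] != v$sign) upper$edges$sign[ui] <- v$sign
        cols <- intersect(names(lower$edges), names(upper$edges))
        lower$edges <- rbind(lower$edges[, cols, drop = FALSE],
                             upper$edges[ui, cols, drop = FALSE])
        changed <- TRUE
      }
    }
    log[[length(log) + 1L]] <- verdicts
    if (!changed) break
    object$upper <- signed_digraph(upper$edges, nodes = upper$nodes)
    object$lower <- signed_digraph(lower$edges, nodes = lower$nodes)
    validate_bounds(object)
  }
  object$last_update <- log
  object
}
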