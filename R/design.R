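#' Candidate background knock-outs under a size constraint
#'
#' For each uncertain edge and each of its candidate separatoids, proposes
#' the separatoid itself as the background KO set `V_k`, provided the paired
#' test experiment `V_k + {i}` respects the maximum KO size. Backgrounds of
#' size `> max_size - 1` are infeasible because their test set would exceed
#' the constraint.
#'
#' @param seps separatoid table from [compute_separatoids()]
#' @param max_size maximum number of genes per KO experiment (>= 1)
#' @return a named list (per uncertain edge) of lists with `i`, `j` and
#'   `backgrounds` (deduplicated list of feasible background KO sets)
#' @export
candidate_backgrounds <- function(seps, max_size) {
  if (max_size < 1L) stop("'max_size' must be >= 1")
  lapply(seps, function(ed) {
    bgs <- list()
    for (s in ed$seps) {
      if (length(s) > max_size - 1L) next
      if (ed$i %in% s || ed$j %in% s) next
      bgs[[length(bgs) + 1L]] <- s
    }
    if (length(bgs) > 0L) {
      bgs <- bgs[!duplicated(vapply(bgs, ko_id, ""))]
    }
    list(i = ed$i, j = ed$j, backgrounds = bgs)
  })
}

#' Greedy proposal of the next knock-out experiments
#'
#' Greedy surrogate of an optimal KO design: repeatedly selects the
#' (background, test) experiment pair that completes verification for the
#' largest number of not-yet-covered uncertain edges, given the experiments
#' already performed and those already chosen. An edge `(i, j)` is covered
#' by the pair `(V_k, V_k + {i})` when some candidate separatoid of the edge
#' is contained in `V_k` and `i, j` are not in `V_k`. Ties are broken by
#' smaller background, then lexicographically. The search stops at `budget`
#' proposed pairs or when no addition covers a new edge.
#'
#' @param seps separatoid table from [compute_separatoids()]
#' @param performed list of already-performed KO sets
#' @param max_size maximum KO experiment size
#' @param budget maximum number of experiment pairs to propose (>= 1)
#' @return a list of class `design_proposal` with `experiments` (KO sets to
#'   run, in order, already-performed ones omitted), `covers` (map from
#'   proposed pair label to the uncertain edges it verifies) and `max_size`
#' @export
greedy_design <- function(seps, performed, max_size, budget = 1L) {
  if (budget < 1L) stop("'budget' must be >= 1")
  cand <- candidate_backgrounds(seps, max_size)
  # enumerate candidate pairs with the edges each one covers
  pair_key <- character(); pair_bg <- list(); pair_test <- list()
  pair_edges <- list()
  for (ed in cand) {
    for (bg in ed$backgrounds) {
      test <- sort(c(bg, ed$i))
      key <- paste(ko_id(bg), ko_id(test), sep = "|")
      at <- match(key, pair_key)
      if (is.na(at)) {
        pair_key <- c(pair_key, key)
        pair_bg <- c(pair_bg, list(bg))
        pair_test <- c(pair_test, list(test))
        pair_edges <- c(pair_edges, list(character()))
        at <- length(pair_key)
      }
      pair_edges[[at]] <- union(pair_edges[[at]],
                                paste(ed$i, ed$j, sep = "\r"))
    }
  }
  # a pair also covers edges (i', j') sharing the same background whose
  # test set i' happens to be already performed: handled implicitly since
  # such edges list their own pair
  done <- vapply(performed, ko_id, "")
  covered <- character()
  chosen <- list()
  covers <- list()
  performed_ids <- done
  while (length(chosen) < budget && length(pair_key) > 0L) {
    gains <- vapply(pair_edges, function(e) length(setdiff(e, covered)), 0L)
    if (all(gains == 0L)) break
    sizes <- lengths(pair_bg)
    ord <- order(-gains, sizes, vapply(pair_bg, ko_id, ""))
    best <- ord[1L]
    newexp <- list()
    for (ko in list(pair_bg[[best]], pair_test[[best]])) {
      if (!ko_id(ko) %in% performed_ids) {
        newexp[[length(newexp) + 1L]] <- ko
        performed_ids <- c(performed_ids, ko_id(ko))
      }
    }
    chosen <- c(chosen, newexp)
    covers[[pair_key[best]]] <- setdiff(pair_edges[[best]], covered)
    covered <- union(covered, pair_edges[[best]])
  }
  structure(list(experiments = chosen, covers = covers,
                 max_size = max_size),
            class = "design_proposal")
}

#' @export
print.design_proposal <- function(x, ...) {
  cat("Design proposal:", length(x$experiments),
      "new KO experiment(s), max KO size", x$max_size, "\n")
  for (e in x$experiments) cat("  KO {", paste(e, collapse = ", "), "}\n")
  invisible(x)
}

#' Relax the knock-out size constraint
#'
#' Returns `max_size + 1`. Invoked by the iterative driver exactly when the
#' design step cannot propose any feasible experiment while uncertain edges
#' remain.
#'
#' @param max_size current maximum KO size
#' @return `max_size + 1L`
#' @export
escalate_constraint <- function(max_size) as.integer(max_size) + 1L

#' Multiplexed experiment design
#'
#' Runs [greedy_design()] repeatedly, removing the edges covered by each run
#' from the objective of subsequent runs, until no remaining uncertain edge
#' is coverable at the given size constraint. Proposals are concatenated in
#' generation order (earlier runs cover more edges), matching how a
#' multiplexed assay would consume a ranked experiment list.
#'
#' @inheritParams greedy_design
#' @return a `design_proposal`
#' @export
multiplexed_design <- function(seps, performed, max_size) {
  remaining <- seps
  all_exps <- list()
  all_covers <- list()
  performed <- c(performed, list())
  repeat {
    if (length(remaining) == 0L) break
    prop <- greedy_design(remaining, performed, max_size, budget = 1L)
    if (length(prop$covers) == 0L) break
    all_exps <- c(all_exps, prop$experiments)
    all_covers <- c(all_covers, prop$covers)
    performed <- c(performed, prop$experiments)
    covered <- unique(unlist(prop$covers))
    remaining <- remaining[setdiff(names(remaining), covered)]
  }
  structure(list(experiments = all_exps, covers = all_covers,
                 max_size = max_size),
            class = "design_proposal")
}

#' Iterative network inference with designed knock-out experiments
#'
#' Runs the full closed loop against the simulator: (1) simulate the
#' complete single-gene KO compendium and fit the initial ensemble bounds;
#' (2) propose the next KO experiments ([greedy_design()] or
#' [multiplexed_design()]); (3) simulate the proposed experiments and
#' [update.grn_ensemble()] the bounds; repeat. The maximum KO size starts at
#' 2 and is incremented by one whenever no feasible experiment exists while
#' uncertain edges remain. The loop stops when no uncertain edge is left
#' (the bounds have converged to a unique network), when escalation exceeds
#' `n - 1` genes, or after `max_iters` iterations. All simulated
#' experiments are cached and reused.
#'
#' @param model a [kinetic_model()]
#' @param config a [sim_config()]
#' @param w_cut weight cutoff for the initial signed reduction
#' @param method `"signed"` or `"unsigned"` bound construction
#' @param multiplex propose many experiments per iteration?
#' @param budget experiment pairs per iteration in non-multiplexed mode
#' @param alpha t-test significance level
#' @param max_iters iteration cap
#' @param seed integer seed driving all simulation randomness
#' @return a list with `ensemble` (final `grn_ensemble`), `data` (the
#'   accumulated `expression_dataset`) and `log` (per-iteration data frame:
#'   proposed and cumulative experiment counts, uncertain-edge count, KO
#'   size constraint)
#' @export
iterative_inference <- function(model, config = sim_config(), w_cut = 0.3,
                                method = c("signed", "unsigned"),
                                multiplex = FALSE, budget = 1L,
                                alpha = 0.01, max_iters = 50L, seed = 1L) {
  method <- match.arg(method)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, max_iters + 1L)
  data <- generate_compendium(model, config = config, seed = seeds[1L])
  ens <- grn_ensemble(data, method = method, w_cut = w_cut)
  ens <- update(ens, data, alpha = alpha)
  n <- length(model$genes$gene)
  max_size <- 2L
  log <- data.frame(iteration = 0L, proposed = 0L,
                    cumulative_experiments = length(data$ko_sets),
                    uncertain = nrow(uncertain_edges(ens)),
                    max_ko_size = NA_integer_)
  iter <- 0L
  while (nrow(uncertain_edges(ens)) > 0L && iter < max_iters) {
    iter <- iter + 1L
    seps <- compute_separatoids(ens)
    prop <- if (multiplex) {
      multiplexed_design(seps, unname(data$ko_sets), max_size)
    } else {
      greedy_design(seps, unname(data$ko_sets), max_size, budget = budget)
    }
    if (length(prop$experiments) == 0L) {
      if (max_size >= n - 1L) break     # no constraint can help any further
      max_size <- escalate_constraint(max_size)
      next
    }
    newdata <- generate_compendium(model, ko_sets = prop$experiments,
                                   config = config, seed = seeds[iter + 1L])
    data <- bind_experiments(data, newdata)
    ens <- update(ens, data, alpha = alpha)
    log <- rbind(log, data.frame(
      iteration = iter, proposed = length(prop$experiments),
      cumulative_experiments = length(data$ko_sets),
      uncertain = nrow(uncertain_edges(ens)),
      max_ko_size = max_size))
  }
  list(ensemble = ens, data = data, log = log)
}
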