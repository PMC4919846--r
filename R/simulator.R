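#' Generate a random signed gene regulatory network
#'
#' Samples a random signed digraph as a stand-in reference network. A
#' designated regulator subset (the "transcription factors",
#' `ceiling(regulator_fraction * n)` genes) are the only possible edge
#' sources, mirroring the hub structure of real transcriptional networks
#' and of the DREAM gold standards, where most genes are terminal targets.
#' Each admissible ordered pair (regulator source, distinct target)
#' receives an edge independently with a probability chosen so that the
#' expected number of edges is `n * mean_out_degree`; each edge is negative
#' (repression) with probability `negative_fraction`. When
#' `allow_cycles = FALSE`, edges follow a random gene ordering (regulators
#' first), guaranteeing a DAG.
#'
#' @param n number of genes (>= 2)
#' @param mean_out_degree expected number of targets per gene (network-wide
#'   average, i.e. expected edge count is `n * mean_out_degree`)
#' @param negative_fraction probability that an edge is repressing, in `[0,1]`
#' @param allow_cycles permit directed cycles?
#' @param regulator_fraction fraction of genes allowed to regulate others;
#'   1 gives an unrestricted random digraph
#' @param seed optional integer seed (local to this call)
#' @return a [signed_digraph()] with genes `G001`, `G002`, ...
#' @export
random_grn <- function(n, mean_out_degree = 1.5, negative_fraction = 0.3,
                       allow_cycles = FALSE, regulator_fraction = 0.25,
                       seed = NULL) {
  if (n < 2L) stop("'n' must be at least 2")
  if (negative_fraction < 0 || negative_fraction > 1) {
    stop("'negative_fraction' must lie in [0, 1]")
  }
  if (regulator_fraction <= 0 || regulator_fraction > 1) {
    stop("'regulator_fraction' must lie in (0, 1]")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  genes <- sprintf("G%03d", seq_len(n))
  ntf <- max(1L, ceiling(regulator_fraction * n))
  ord <- sample(genes)                 # regulators are ord[1..ntf]
  tfs <- ord[seq_len(ntf)]
  if (allow_cycles) {
    pairs <- expand.grid(from = tfs, to = genes, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  } else {
    rank <- stats::setNames(seq_len(n), ord)
    pairs <- expand.grid(from = tfs, to = ord, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[rank[pairs$from] < rank[pairs$to], , drop = FALSE]
  }
  if (n * mean_out_degree >= nrow(pairs)) {
    stop("'mean_out_degree' infeasible for ", n, " genes with ",
         ntf, " regulators")
  }
  p <- n * mean_out_degree / nrow(pairs)
  draw <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[draw, , drop = FALSE]
  sgn <- ifelse(stats::runif(nrow(pairs)) < negative_fraction, -1L, 1L)
  signed_digraph(data.frame(pairs, sign = sgn, stringsAsFactors = FALSE),
                 nodes = genes)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Parameterise a kinetic transcription/translation model
#'
#' Attaches chemical-Langevin kinetics to a signed regulatory network. For
#' gene i the mRNA level x_i and protein level y_i evolve as
#' \deqn{dx_i = [m_i f_i(y) - \lambda^{RNA}_i x_i]\,dt + \sigma_{int}\,dW}
#' \deqn{dy_i = [r_i x_i - \lambda^{Prot}_i y_i]\,dt + \sigma_{int}\,dW}
#' where `m_i` is the maximal transcription rate, `r_i` the translation rate
#' constant, and the lambdas first-order degradation constants. The
#' regulation input `f_i(y)` multiplies independent Hill terms, one per
#' regulator (see [regulation_input()]).
#'
#' Unspecified parameters are drawn uniformly: `m, r ~ U(0.5, 2)`,
#' `lambda ~ U(0.5, 1.5)`, Hill exponent `h in {1, 2}`; each half-saturation
#' constant `K` is set to one quarter of the regulator's unregulated
#' steady-state protein level `(m r) / (lambda_RNA lambda_Prot)`, so that a
#' present regulator operates near saturation and its deletion produces a
#' strong, propagating response.
#'
#' @param network a [signed_digraph()]; edge signs set activation/repression
#' @param basal basal transcription fraction `b in [0, 1]` reached when all
#'   activators are absent and all repressors saturated
#' @param sigma_int intrinsic (Langevin) noise scale, >= 0
#' @param sigma_meas log-normal measurement noise scale (sd of `log` values)
#' @param seed optional integer seed for the parameter draws
#' @return an object of class `kinetic_model` with components `network`,
#'   `genes` (per-gene parameter data frame), `regulation` (per-edge
#'   parameter data frame) and `noise`
#' @export
kinetic_model <- function(network, basal = 0.01, sigma_int = 0.05,
                          sigma_meas = 0.05, seed = NULL) {
  stopifnot(is_signed_digraph(network))
  if (n_nodes(network) == 0L) stop("empty gene list")
  if (sigma_int < 0 || sigma_meas < 0) stop("noise scales must be >= 0")
  if (basal < 0 || basal > 1) stop("'basal' must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  genes <- network$nodes
  n <- length(genes)
  gp <- data.frame(
    gene = genes,
    m = stats::runif(n, 0.5, 2),
    r = stats::runif(n, 0.5, 2),
    lambda_rna = stats::runif(n, 0.5, 1.5),
    lambda_prot = stats::runif(n, 0.5, 1.5),
    basal = basal,
    stringsAsFactors = FALSE)
  e <- network$edges
  y_free <- gp$m * gp$r / (gp$lambda_rna * gp$lambda_prot)
  names(y_free) <- genes
  # K at a quarter of the regulator's wild-type operating protein level
  # keeps every present regulation active (near saturation), so knock-out
  # effects stay strong along cascades instead of attenuating
  # multiplicatively. The operating point depends on K, so the calibration
  # is iterated on the deterministic fixed point until self-consistent.
  reg <- data.frame(
    from = e$from, to = e$to, sign = e$sign,
    K = 0.25 * unname(y_free[e$from]),
    h = sample(c(1, 2), nrow(e), replace = TRUE),
    stringsAsFactors = FALSE)
  model <- structure(list(network = network, genes = gp, regulation = reg,
                          noise = list(sigma_int = sigma_int,
                                       sigma_meas = sigma_meas)),
                     class = "kinetic_model")
  if (nrow(reg) > 0L) {
    # every regulator operates at its half-saturation point in the wild
    # type, so each individual gain or loss of a regulator produces a
    # strong response; the operating point depends on K, hence the
    # fixed-point iteration
    for (it in 1:8) {
      y_wt <- deterministic_fixed_point(model)$y
      model$regulation$K <- pmax(unname(y_wt[reg$from]),
                                 1e-6 * unname(y_free[reg$from]))
    }
  }
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic GRN model: ", nrow(x$genes), " genes, ",
      nrow(x$regulation), " regulatory edges\n", sep = "")
  cat(sprintf("  sigma_int = %g, sigma_meas = %g\n",
              x$noise$sigma_int, x$noise$sigma_meas))
  invisible(x)
}

#' Transcriptional regulation input of one gene
#'
#' Evaluates `f_i(y)`, the fraction of the maximal transcription rate of
#' gene `i` realised at protein levels `y`. Each regulator contributes a
#' Hill term `t = y^h / (K^h + y^h)`; activators act as independent inputs
#' and combine as a noisy-OR, `A = 1 - prod_a (1 - t_a)` (1 when there are
#' no activators), while repressors attenuate all transcription — basal
#' included — multiplicatively, `R = prod_r (1 - t_r)`:
#' \deqn{f_i(y) = (b_i + (1 - b_i)\, A) \, R}
#' Genes without regulators return 1; a gene with one activator at its
#' half-saturation point and no basal offset transcribes at half the
#' maximal rate. The value is monotone increasing in each activator level,
#' decreasing in each repressor level, and lies in `[0, 1]`. The
#' independent (OR) integration of activators mirrors how alternative
#' transcription-factor inputs act on promoters and keeps each regulation
#' individually perturbable: a deleted activator changes the target even
#' when co-activators remain, and a repressor remains measurable (through
#' the basal term) even in knock-out backgrounds that silence the
#' activators.
#'
#' @param model a [kinetic_model()]
#' @param gene a gene identifier
#' @param y named (or model-ordered) non-negative protein level vector
#' @return a scalar in `[0, 1]`
#' @export
regulation_input <- function(model, gene, y) {
  stopifnot(inherits(model, "kinetic_model"))
  genes <- model$genes$gene
  if (!gene %in% genes) stop("unknown gene '", gene, "'")
  if (is.null(names(y))) names(y) <- genes
  reg <- model$regulation[model$regulation$to == gene, , drop = FALSE]
  if (nrow(reg) == 0L) return(1)
  b <- model$genes$basal[match(gene, genes)]
  ya <- y[reg$from]
  num <- ya^reg$h
  term <- num / (reg$K^reg$h + num)
  act <- reg$sign > 0
  A <- if (any(act)) 1 - prod(1 - term[act]) else 1
  R <- prod(1 - term[!act])
  (b + (1 - b) * A) * R
}

#' Simulation settings
#'
#' @param step Euler-Maruyama integration step (time units)
#' @param horizon total integrated time; must exceed `step`
#' @param avg_window trailing fraction of the horizon averaged to extract
#'   the steady state
#' @param replicates technical replicates per experiment
#' @return a list of class `sim_config`
#' @export
sim_config <- function(step = 0.05, horizon = 30, avg_window = 0.2,
                       replicates = 10L) {
  if (step >= horizon) stop("'step' must be smaller than 'horizon'")
  if (avg_window <= 0 || avg_window > 1) stop("'avg_window' must be in (0, 1]")
  if (replicates < 1L) stop("'replicates' must be >= 1")
  structure(list(step = step, horizon = horizon, avg_window = avg_window,
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

#' Read simulation settings from a YAML file
#' @param path a YAML file with any of the [sim_config()] fields
#' @return a `sim_config`
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configuration")
  }
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals[intersect(names(vals),
                                     names(formals(sim_config)))])
}

# deterministic steady state (noise-free fixed point) by damped iteration
# of x = m f(y) / lambda_RNA, y = r x / lambda_Prot; exact after one sweep
# per cascade level on a DAG, converges geometrically otherwise
deterministic_fixed_point <- function(model, ko_set = character(),
                                      iters = 200L, damp = 0.5) {
  gp <- model$genes
  genes <- gp$gene
  m <- gp$m
  m[genes %in% ko_set] <- 0
  x <- m / gp$lambda_rna
  y <- gp$r * x / gp$lambda_prot
  names(y) <- genes
  for (it in seq_len(iters)) {
    f <- vapply(genes, function(g) regulation_input(model, g, y), 0)
    x_new <- m * f / gp$lambda_rna
    y_new <- gp$r * x_new / gp$lambda_prot
    delta <- max(abs(y_new - y))
    x <- (1 - damp) * x + damp * x_new
    y <- (1 - damp) * y + damp * y_new
    names(y) <- genes
    if (delta < 1e-10) break
  }
  names(x) <- genes
  list(x = x, y = y)
}

# core integrator: R replicates of one KO experiment, states batched as
# n x R matrices. Returns the time-averaged tail mRNA matrix.
simulate_ss_matrix <- function(model, ko_set, config, R, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  gp <- model$genes
  genes <- gp$gene
  n <- length(genes)
  unknown <- setdiff(ko_set, genes)
  if (length(unknown) > 0L) {
    stop("KO gene(s) not in model: ", paste(unknown, collapse = ", "))
  }
  m <- gp$m
  m[genes %in% ko_set] <- 0           # knock-out: zero maximal transcription
  lr <- gp$lambda_rna
  lp <- gp$lambda_prot
  rr <- gp$r
  b <- gp$basal
  reg <- model$regulation
  src <- match(reg$from, genes)
  Kh <- reg$K^reg$h
  h <- reg$h
  act <- reg$sign > 0
  tgt_of <- match(reg$to, genes)
  tgt_groups <- split(seq_len(nrow(reg)), tgt_of)
  tgt_idx <- as.integer(names(tgt_groups))
  act_rows <- lapply(tgt_groups, function(rows) rows[act[rows]])
  rep_rows <- lapply(tgt_groups, function(rows) rows[!act[rows]])
  sig <- model$noise$sigma_int
  dt <- config$step
  nstep <- max(2L, ceiling(config$horizon / dt))
  ntail <- max(1L, ceiling(config$avg_window * nstep))
  sqdt <- sqrt(dt)

  # initialise at the unregulated deterministic fixed point
  x <- matrix(m / lr, n, R)
  y <- (rr * x) / lp                   # per-gene rates recycle down columns
  f <- matrix(1, n, R)
  xsum <- matrix(0, n, R)
  for (s in seq_len(nstep)) {
    if (nrow(reg) > 0L) {
      ys <- y[src, , drop = FALSE]^h    # h recycles down rows (column-major)
      off <- 1 - ys / (Kh + ys)         # 1 - Hill occupancy, per edge
      for (k in seq_along(tgt_groups)) {
        g <- tgt_idx[k]
        arow <- act_rows[[k]]; rrow <- rep_rows[[k]]
        A <- if (length(arow) == 0L) 1 else if (length(arow) == 1L)
          1 - off[arow, ] else
          1 - exp(colSums(log(pmax(off[arow, , drop = FALSE], 1e-300))))
        Rp <- if (length(rrow) == 0L) 1 else if (length(rrow) == 1L)
          off[rrow, ] else
          exp(colSums(log(pmax(off[rrow, , drop = FALSE], 1e-300))))
        f[g, ] <- (b[g] + (1 - b[g]) * A) * Rp
      }
    }
    dx <- (m * f - lr * x) * dt
    dy <- (rr * x - lp * y) * dt
    if (sig > 0) {
      dx <- dx + sig * sqdt * matrix(stats::rnorm(n * R), n, R)
      dy <- dy + sig * sqdt * matrix(stats::rnorm(n * R), n, R)
    }
    x <- pmax(x + dx, 0)
    y <- pmax(y + dy, 0)
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("divergent trajectory at step ", s)
    }
    if (s > nstep - ntail) xsum <- xsum + x
  }
  out <- xsum / ntail
  out[genes %in% ko_set, ] <- 0        # deleted genes express exactly zero
  dimnames(out) <- list(genes, NULL)
  out
}

#' Simulate steady-state mRNA levels of one knock-out experiment
#'
#' Integrates the chemical-Langevin model by the Euler-Maruyama scheme with
#' non-negativity clipping, starting from the unregulated deterministic fixed
#' point, and returns the time average of the mRNA levels over the trailing
#' `avg_window` fraction of the horizon. Knocked-out genes have their maximal
#' transcription rate set to zero and report exactly zero expression.
#'
#' @param model a [kinetic_model()]
#' @param ko_set character vector of knocked-out genes (empty = wild type)
#' @param config a [sim_config()]
#' @param seed optional integer seed (local to this call)
#' @return named numeric vector of steady-state mRNA levels
#' @export
simulate_steady_state <- function(model, ko_set = character(),
                                  config = sim_config(), seed = NULL) {
  drop(simulate_ss_matrix(model, ko_set, config, R = 1L, seed = seed)[, 1L])
}
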