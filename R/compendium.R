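#' Knock-out experiment designs
#'
#' `single_ko_design` returns the complete single-gene knock-out design:
#' the wild type (empty KO set) followed by one experiment per gene.
#' `double_ko_design` enumerates every unordered gene pair, i.e.
#' `choose(n, 2)` experiments.
#'
#' @param genes character vector of gene identifiers
#' @return a list of character vectors (KO sets); `character(0)` is the wild
#'   type
#' @export
single_ko_design <- function(genes) {
  c(list(character(0)), lapply(genes, function(g) g))
}

#' @rdname single_ko_design
#' @export
double_ko_design <- function(genes) {
  idx <- utils::combn(length(genes), 2L)
  lapply(seq_len(ncol(idx)), function(k) genes[idx[, k]])
}

ko_id <- function(ko) {
  if (length(ko) == 0L) "WT" else paste(sort(ko), collapse = ",")
}

#' Generate a steady-state knock-out expression compendium
#'
#' Runs [simulate_steady_state()] for every requested KO experiment and
#' technical replicate (each experiment drawing an independent sub-seed),
#' then multiplies every measured value by `exp(eps)` with
#' `eps ~ N(0, sigma_meas^2)` — the log-normal measurement noise model.
#' Knocked-out genes are exactly zero before measurement noise.
#'
#' @param model a [kinetic_model()]
#' @param ko_sets list of character vectors of knocked-out genes; defaults to
#'   the complete single-KO design over the model's genes
#' @param config a [sim_config()]; its `replicates` field sets R
#' @param seed integer seed; fully determines the output
#' @return an object of class `expression_dataset`: list with `genes`,
#'   `ko_sets` (named list, names are experiment ids), and `values`, a
#'   non-negative numeric array `gene x experiment x replicate`
#' @export
generate_compendium <- function(model, ko_sets = NULL,
                                config = sim_config(), seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"))
  genes <- model$genes$gene
  if (length(genes) == 0L) stop("empty gene list")
  if (is.null(ko_sets)) ko_sets <- single_ko_design(genes)
  if (config$replicates < 2L) stop("at least 2 replicates are required")
  ids <- vapply(ko_sets, ko_id, "")
  if (anyDuplicated(ids)) {
    warning("duplicate KO sets in design; keeping all")
    ids <- make.unique(ids)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  nexp <- length(ko_sets)
  R <- config$replicates
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nexp)
  vals <- array(NA_real_, dim = c(length(genes), nexp, R),
                dimnames = list(genes, ids, NULL))
  sm <- model$noise$sigma_meas
  for (e in seq_len(nexp)) {
    ss <- simulate_ss_matrix(model, ko_sets[[e]], config, R,
                             seed = sub_seeds[e])
    if (sm > 0) {
      ss <- ss * exp(matrix(stats::rnorm(length(ss), 0, sm), nrow(ss)))
    }
    vals[, e, ] <- ss
  }
  names(ko_sets) <- ids
  structure(list(genes = genes,
                 ko_sets = lapply(ko_sets, function(k) sort(as.character(k))),
                 values = vals),
            class = "expression_dataset")
}

#' Simulate a compendium from a kinetic model
#'
#' `simulate` method wrapper around [generate_compendium()]; `nsim` sets the
#' number of technical replicates.
#'
#' @param object a [kinetic_model()]
#' @param nsim technical replicates per experiment
#' @param seed integer seed
#' @param ko_sets list of KO sets; defaults to the complete single-KO design
#' @param config a [sim_config()] (its `replicates` field is overridden by
#'   `nsim`)
#' @param ... unused
#' @return an `expression_dataset`
#' @export
simulate.kinetic_model <- function(object, nsim = 10L, seed = 1L,
                                   ko_sets = NULL, config = sim_config(),
                                   ...) {
  config$replicates <- as.integer(nsim)
  generate_compendium(object, ko_sets = ko_sets, config = config, seed = seed)
}

#' @export
print.expression_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat("Expression dataset: ", d[1L], " genes x ", d[2L], " experiments x ",
      d[3L], " replicates\n", sep = "")
  sizes <- lengths(x$ko_sets)
  cat("  KO set sizes: ",
      paste(names(table(sizes)), table(sizes), sep = ":", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of technical replicates in a dataset
#' @param data an `expression_dataset`
#' @return an integer
#' @export
n_replicates <- function(data) dim(data$values)[3L]

#' Locate an experiment by its KO set
#' @param data an `expression_dataset`
#' @param ko_set character vector of knocked-out genes
#' @return the experiment index, or `NA` when absent
#' @export
ko_index <- function(data, ko_set) {
  match(ko_id(ko_set), names(data$ko_sets))
}

#' Combine two expression datasets over the same genes
#'
#' Appends the experiments of `b` to those of `a`; experiments of `b` whose
#' KO set already exists in `a` are dropped. Replicate counts must match.
#'
#' @param a,b `expression_dataset` objects over identical gene lists
#' @return an `expression_dataset`
#' @export
bind_experiments <- function(a, b) {
  stopifnot(inherits(a, "expression_dataset"),
            inherits(b, "expression_dataset"))
  if (!identical(a$genes, b$genes)) stop("gene lists differ")
  if (dim(a$values)[3L] != dim(b$values)[3L]) {
    stop("replicate counts differ")
  }
  new <- setdiff(names(b$ko_sets), names(a$ko_sets))
  if (length(new) == 0L) return(a)
  vals <- array(NA_real_,
                dim = c(length(a$genes),
                        dim(a$values)[2L] + length(new),
                        dim(a$values)[3L]),
                dimnames = list(a$genes,
                                c(names(a$ko_sets), new), NULL))
  vals[, seq_len(dim(a$values)[2L]), ] <- a$values
  vals[, dim(a$values)[2L] + seq_along(new), ] <-
    b$values[, new, , drop = FALSE]
  structure(list(genes = a$genes,
                 ko_sets = c(a$ko_sets, b$ko_sets[new]),
                 values = vals),
            class = "expression_dataset")
}

#' Read and write expression compendia
#'
#' Long tab-separated format with header
#' `experiment_id  ko_genes  replicate  gene  value`, where `ko_genes` is a
#' comma-joined sorted gene list (empty string for the wild type).
#'
#' @param data an `expression_dataset`
#' @param path file path
#' @return `read_compendium` returns an `expression_dataset`;
#'   `write_compendium` returns `path` invisibly.
#' @export
write_compendium <- function(data, path) {
  stopifnot(inherits(data, "expression_dataset"))
  d <- dim(data$values)
  grid <- expand.grid(gene = seq_len(d[1L]), exp = seq_len(d[2L]),
                      rep = seq_len(d[3L]))
  ko_str <- vapply(data$ko_sets, paste, "", collapse = ",")
  df <- data.frame(
    experiment_id = names(data$ko_sets)[grid$exp],
    ko_genes = unname(ko_str[grid$exp]),
    replicate = grid$rep,
    gene = data$genes[grid$gene],
    value = as.vector(data$values),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer",
                                         "character", "numeric"))
  genes <- sort(unique(df$gene))
  ids <- unique(df$experiment_id)
  reps <- sort(unique(df$replicate))
  vals <- array(NA_real_, dim = c(length(genes), length(ids), length(reps)),
                dimnames = list(genes, ids, NULL))
  vals[cbind(match(df$gene, genes), match(df$experiment_id, ids),
             match(df$replicate, reps))] <- df$value
  if (anyNA(vals)) stop("incomplete compendium: missing gene/replicate cells")
  ko_sets <- lapply(ids, function(id) {
    s <- df$ko_genes[match(id, df$experiment_id)]
    if (!nzchar(s)) character(0) else sort(strsplit(s, ",")[[1L]])
  })
  names(ko_sets) <- ids
  structure(list(genes = genes, ko_sets = ko_sets, values = vals),
            class = "expression_dataset")
}
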