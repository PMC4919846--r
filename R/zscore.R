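#' Outlier-corrected mean and standard deviation
#'
#' Estimates the unperturbed distribution of one gene across knock-out
#' experiments: values deviating from an initial location estimate by more
#' than `z_cutoff` initial scale units are excluded in a single pass, and
#' the mean and standard deviation of the retained values are returned.
#' The initial location/scale estimates are the median and (scaled) median
#' absolute deviation: with only a handful of experiments, the strong
#' responses that must be excluded would inflate a plain standard deviation
#' enough to mask themselves, whereas the median/MAD pair stays anchored to
#' the unperturbed majority.
#'
#' @param values numeric vector (one gene's expression across experiments,
#'   one replicate); at least 3 values
#' @param z_cutoff exclusion threshold in initial-scale units (default 3)
#' @return a list with `mean` and `sd`
#' @export
corrected_stats <- function(values, z_cutoff = 3) {
  if (length(values) < 3L) stop("at least 3 values required")
  mu0 <- stats::median(values)
  s0 <- stats::mad(values)
  keep <- abs(values - mu0) <= z_cutoff * s0
  if (!any(keep)) {
    warning("all values excluded; falling back to uncorrected statistics")
    keep <- rep(TRUE, length(values))
  }
  v <- values[keep]
  s <- if (length(v) >= 2L) stats::sd(v) else 0
  list(mean = mean(v), sd = s)
}

# floor applied to corrected SDs so that noise-free (exactly repeated)
# baseline values still yield finite, very large z-scores for genuine
# responses, while a truly constant gene keeps z = 0 (zero numerator).
sd_floor <- function(s, mu) pmax(s, 1e-8 * pmax(1, abs(mu)))

single_ko_view <- function(data) {
  sizes <- lengths(data$ko_sets)
  single <- which(sizes == 1L)
  ko_genes <- vapply(data$ko_sets[single], `[[`, "", 1L)
  if (!setequal(ko_genes, data$genes)) {
    stop("data must contain the complete single-KO design ",
         "(one experiment per gene)")
  }
  list(single = single[match(data$genes, ko_genes)],
       stats_exps = which(sizes <= 1L))   # single KOs plus wild type if present
}

#' Knock-out z-score matrix
#'
#' For each technical replicate and each gene `j`, computes the
#' outlier-corrected mean and SD of gene `j` across the single-KO
#' experiments (plus the wild type when present), then the z-score
#' `z(i, j) = (g_ij - mu_j) / s_j` of gene `j`'s expression in the KO of
#' gene `i`. Entry `Z(i, j)` is the average of `z(i, j)` over replicates;
#' the diagonal (gene `i` under its own KO) is `NA`.
#'
#' @param data an `expression_dataset` containing the complete single-KO
#'   design (extra experiments are ignored) with at least 2 replicates
#' @param z_cutoff outlier-exclusion threshold passed to [corrected_stats()]
#' @return a square numeric matrix (KO gene x measured gene)
#' @export
zscore_matrix <- function(data, z_cutoff = 3) {
  stopifnot(inherits(data, "expression_dataset"))
  R <- n_replicates(data)
  if (R < 2L) stop("at least 2 replicates required")
  view <- single_ko_view(data)
  genes <- data$genes
  n <- length(genes)
  Z <- matrix(0, n, n, dimnames = list(genes, genes))
  for (r in seq_len(R)) {
    X <- data$values[, view$stats_exps, r, drop = TRUE]   # gene x experiment
    Xko <- data$values[, view$single, r, drop = TRUE]     # gene x KO(=gene)
    for (j in seq_len(n)) {
      st <- corrected_stats(X[j, ], z_cutoff)
      s <- sd_floor(st$sd, st$mean)
      Z[, j] <- Z[, j] + (Xko[j, ] - st$mean) / s
    }
  }
  Z <- Z / R
  diag(Z) <- NA_real_
  Z
}

#' Signed accessibility from a z-score matrix
#'
#' Thresholds the averaged z-score matrix into the ensemble upper bound:
#' edge `(i, j)` exists iff `|Z(i, j)| > z_threshold` (strict). The edge sign
#' is `+1` when `Z(i, j) <= 0` (expression drops when the regulator is
#' deleted, hence activation) and `-1` otherwise. The diagonal is forced to
#' zero.
#'
#' @param Z square z-score matrix from [zscore_matrix()]
#' @param z_threshold accessibility threshold (default 2)
#' @return a list with `graph` (a [signed_digraph()]), `acc` (0/1 matrix)
#'   and `sign` (sign matrix, nonzero exactly where `acc` is 1)
#' @export
accessibility_from_z <- function(Z, z_threshold = 2) {
  stopifnot(is.matrix(Z), nrow(Z) == ncol(Z))
  genes <- rownames(Z)
  A <- ifelse(!is.na(Z) & abs(Z) > z_threshold, 1L, 0L)
  diag(A) <- 0L
  S <- ifelse(A == 1L, ifelse(Z <= 0, 1L, -1L), 0L)
  S[is.na(S)] <- 0L
  idx <- which(A == 1L, arr.ind = TRUE)
  g <- signed_digraph(
    data.frame(from = genes[idx[, 1L]], to = genes[idx[, 2L]],
               sign = S[idx], stringsAsFactors = FALSE),
    nodes = genes)
  list(graph = g, acc = A, sign = S)
}

#' Regulatory-strength weight matrix
#'
#' `W(i, j)` is the magnitude of the Pearson correlation between the
#' expression of genes `i` and `j` across the single-KO experiments,
#' excluding the KO-of-`j` experiment (whose differential expression of `j`
#' does not reflect regulation by `i`), averaged over technical replicates.
#' The matrix is asymmetric because the excluded experiment differs between
#' `W(i, j)` and `W(j, i)`. A replicate in which either gene has zero
#' variance contributes 0 with a warning. The diagonal is `NA`.
#'
#' @param data an `expression_dataset` containing the complete single-KO
#'   design
#' @return a square numeric matrix with entries in `[0, 1]`
#' @export
edge_weights <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  R <- n_replicates(data)
  view <- single_ko_view(data)
  genes <- data$genes
  n <- length(genes)
  if (n < 4L) stop("at least 3 experiments must remain after exclusion")
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  warned <- FALSE
  for (r in seq_len(R)) {
    X <- data$values[, view$single, r, drop = TRUE]  # gene x KO experiment
    for (j in seq_len(n)) {
      Xj <- X[, -j, drop = FALSE]                    # exclude KO of gene j
      sds <- apply(Xj, 1L, stats::sd)
      ok <- sds > 0
      col <- numeric(n)
      if (ok[j] && any(ok)) {
        col[ok] <- abs(suppressWarnings(
          stats::cor(t(Xj[ok, , drop = FALSE]), Xj[j, ])))
      }
      if (!all(ok[-j]) || !ok[j]) warned <- TRUE
      W[, j] <- W[, j] + col
    }
  }
  if (warned) {
    warning("zero-variance gene(s) contributed weight 0 in some replicates")
  }
  W <- W / R
  diag(W) <- NA_real_
  W
}
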