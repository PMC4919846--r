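# brute-force separator check: a candidate set is a separator for (i, j)
# iff no simple indirect path survives its removal (oracle enumeration)
oracle_is_separator <- function(g, i, j, sep) {
  !oracle_indirect_path(g, i, j, excluded = sep)
}

test_that("separatoid formulas produce valid separators on the demonstration bounds", {
  ens <- example_bounds()
  seps <- compute_separatoids(ens)
  expect_length(seps, 3L)
  keys <- vapply(seps, function(e) paste0(e$i, e$j), "")
  expect_setequal(unname(keys), c("AD", "AE", "CE"))
  gu <- ens$upper
  for (ed in seps) {
    for (s in ed$seps) {
      expect_false(ed$i %in% s)
      expect_false(ed$j %in% s)
      expect_true(oracle_is_separator(gu, ed$i, ed$j, s))
      expect_false(has_indirect_path(gu, ed$i, ed$j, excluded = s))
    }
  }
  # the (C,E) edge is separated by gene D alone
  ce <- seps[[which(keys == "CE")]]
  expect_identical(ce$seps$sep1, "D")
})

test_that("separatoids are valid separators on random ensembles (exhaustive oracle)", {
  set.seed(61)
  checked <- 0L
  for (rep in 1:200) {
    g <- rand_digraph(sample(4:8, 1L), p = 0.35)
    if (n_edges(g) < 3L) next
    upper <- signed_closure(g)
    if (n_edges(upper) == 0L) next
    ens <- ensemble_from_upper(upper, w_cut = 0)
    seps <- compute_separatoids(ens)
    for (ed in seps) {
      for (s in ed$seps) {
        checked <- checked + 1L
        expect_true(oracle_is_separator(upper, ed$i, ed$j, s))
      }
    }
  }
  expect_gt(checked, 100L)
})

test_that("an edge with no indirect route has three empty separatoids", {
  g <- signed_digraph(data.frame(from = "A", to = "B", sign = 1L),
                      nodes = c("A", "B", "C"))
  ens <- structure(list(upper = g, lower = signed_digraph(NULL, g$nodes),
                        initial_upper = g,
                        params = list(), call = NULL),
                   class = "grn_ensemble")
  seps <- compute_separatoids(ens)
  expect_length(seps, 1L)
  expect_true(all(lengths(seps[[1L]]$seps) == 0L))
})

test_that("verification pairs require both experiments and the separatoid subset", {
  ed <- list(i = "A", j = "D", seps = list(sep1 = "C", sep2 = "C",
                                           sep3 = character(0)))
  kos <- list(character(0), "A", "C", c("A", "C"), "D")
  pairs <- find_verification_pairs(ed, kos)
  # empty separatoid licenses (WT, {A}); sep {C} licenses ({C}, {A, C})
  expect_identical(nrow(pairs), 2L)
  expect_identical(pairs$background[[1L]], character(0))  # sorted by size
  expect_identical(pairs$test[[1L]], "A")
  expect_identical(pairs$background[[2L]], "C")
  expect_identical(pairs$test[[2L]], c("A", "C"))
  # backgrounds containing i or j are rejected
  expect_false(any(vapply(pairs$background,
                          function(b) any(c("A", "D") %in% b), TRUE)))
  # missing test experiment: no pair even though the background exists
  ed2 <- list(i = "B", j = "D", seps = list(sep1 = "C", sep2 = "C",
                                            sep3 = "C"))
  expect_identical(nrow(find_verification_pairs(ed2, kos)), 0L)
})

test_that("the two-sample t-test votes with direction and alpha semantics", {
  genes <- c("G1", "G2")
  kos <- list(character(0), "G1")
  vals <- array(0, dim = c(2L, 2L, 10L))
  set.seed(71)
  vals[1L, 1L, ] <- stats::rnorm(10, 1, 0.1)
  vals[2L, 1L, ] <- stats::rnorm(10, 2, 0.1)
  vals[2L, 2L, ] <- stats::rnorm(10, 1, 0.1)
  dat <- make_dataset(vals, kos, genes)
  tt <- edge_ttest(dat, "G2", background = character(0), test = "G1")
  expect_true(tt$reject)
  expect_identical(tt$direction, "below")
  # identical samples never reject
  dat2 <- dat
  dat2$values[2L, 2L, ] <- dat2$values[2L, 1L, ]
  tt2 <- edge_ttest(dat2, "G2", character(0), "G1")
  expect_false(tt2$reject)
  # zero-variance degenerate branch: equal constants fail to reject,
  # different constants reject deterministically
  dat3 <- dat
  dat3$values[2L, 1L, ] <- 1
  dat3$values[2L, 2L, ] <- 1
  expect_false(edge_ttest(dat3, "G2", character(0), "G1")$reject)
  dat3$values[2L, 2L, ] <- 2
  tt3 <- edge_ttest(dat3, "G2", character(0), "G1")
  expect_true(tt3$reject)
  expect_identical(tt3$direction, "above")
  # the alpha boundary is strict: p just above 0.01 fails to reject
  set.seed(72)
  found <- FALSE
  for (k in 1:200) {
    a <- stats::rnorm(5); b <- stats::rnorm(5)
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    if (p > 0.01 && p < 0.02) {
      v <- array(0, dim = c(1L, 2L, 5L))
      v[1L, 1L, ] <- a - min(a, b) + 1
      v[1L, 2L, ] <- b - min(a, b) + 1
      d <- make_dataset(v, list(character(0), "X"), genes = "G1")
      expect_false(edge_ttest(d, "G1", character(0), "X")$reject)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("vote aggregation follows majority rule with sign voting", {
  vt <- function(...) lapply(list(...), function(x)
    list(reject = x[[1L]], direction = x[[2L]]))
  # single confirming pair, expression lower in test: positive sign
  v <- grnbounds:::edge_verdict(vt(list(TRUE, "below")), upper_sign = -1L)
  expect_identical(v$decision, "confirm")
  expect_identical(v$sign, 1L)
  # 2 for / 3 against: removed
  v <- grnbounds:::edge_verdict(vt(list(TRUE, "below"), list(TRUE, "below"),
                                   list(FALSE, "below"), list(FALSE, "above"),
                                   list(FALSE, "below")), 1L)
  expect_identical(v$decision, "remove")
  # 2 / 2 tie: undecided, bounds unchanged
  v <- grnbounds:::edge_verdict(vt(list(TRUE, "below"), list(TRUE, "above"),
                                   list(FALSE, "below"), list(FALSE, "below")),
                                1L)
  expect_identical(v$decision, "undecided")
  # sign tie among confirming pairs keeps the upper bound's sign
  v <- grnbounds:::edge_verdict(vt(list(TRUE, "below"), list(TRUE, "above")),
                                -1L)
  expect_identical(v$decision, "confirm")
  expect_identical(v$sign, -1L)
})

test_that("bounds update resolves empty-separatoid edges in one round", {
  # true network: A alone; upper bound wrongly proposes A->B and A->C
  genes <- c("A", "B", "C")
  upper <- signed_digraph(data.frame(from = c("A", "A"), to = c("B", "C"),
                                     sign = c(1L, 1L)), nodes = genes)
  ens <- structure(list(upper = upper,
                        lower = signed_digraph(NULL, nodes = genes),
                        initial_upper = upper, params = list(), call = NULL),
                   class = "grn_ensemble")
  expect_identical(nrow(uncertain_edges(ens)), 2L)
  kos <- list(character(0), "A")
  vals <- array(1, dim = c(3L, 2L, 4L))
  set.seed(81)
  vals <- vals * exp(array(stats::rnorm(length(vals), 0, 0.01), dim(vals)))
  vals[1L, 2L, ] <- 0
  vals[2L, 2L, ] <- vals[2L, 2L, ] * 0.2   # B responds: edge real
  dat <- make_dataset(vals, kos, genes)    # C does not: edge spurious
  up <- update(ens, dat)
  expect_identical(edge_key_set(up$lower), "A B 1")
  expect_identical(edge_key_set(up$upper), "A B 1")
  expect_identical(nrow(uncertain_edges(up)), 0L)
  # updating again changes nothing (idempotence)
  up2 <- update(up, dat)
  expect_true(graphs_identical(up2$upper, up$upper))
  expect_true(graphs_identical(up2$lower, up$lower))
})

test_that("update never removes lower-bound edges nor resurrects removed ones", {
  net <- random_grn(10, seed = 91)
  mod <- kinetic_model(net, sigma_int = 0.01, sigma_meas = 0.01, seed = 92)
  dat <- generate_compendium(mod, seed = 93)
  ens <- suppressWarnings(grn_ensemble(dat, w_cut = 0.3))
  lower_before <- edge_key_set(ens$lower, signed = FALSE)
  upper_before <- edge_key_set(ens$upper, signed = FALSE)
  # add double-KO data demanded by the separatoids
  seps <- compute_separatoids(ens)
  extra <- list()
  for (ed in seps) {
    for (s in ed$seps) {
      extra <- c(extra, list(s), list(sort(c(s, ed$i))))
    }
  }
  extra <- extra[!duplicated(vapply(extra, paste, "", collapse = ","))]
  extra <- extra[lengths(extra) > 0L]
  if (length(extra) > 0L) {
    dat <- bind_experiments(dat, generate_compendium(mod, extra, seed = 94))
  }
  up <- update(ens, dat)
  expect_true(all(lower_before %in% edge_key_set(up$lower, signed = FALSE)))
  expect_true(all(edge_key_set(up$upper, signed = FALSE) %in% upper_before))
  expect_true(all(edge_key_set(up$lower) %in% edge_key_set(up$upper)))
  # uncertain edges strictly decreased given informative double-KO data
  expect_lt(nrow(uncertain_edges(up)), nrow(uncertain_edges(ens)))
})

test_that("single-KO-only data with non-empty separatoids leave bounds unchanged", {
  ens <- example_bounds()
  genes <- ens$upper$nodes
  kos <- single_ko_design(genes)
  set.seed(95)
  vals <- array(stats::rlnorm(5 * 6 * 3, 0, 0.05), dim = c(5L, 6L, 3L))
  for (i in seq_along(kos)) for (k in kos[[i]])
    vals[match(k, genes), i, ] <- 0
  dat <- make_dataset(vals, kos, genes)
  up <- update(ens, dat)
  expect_true(graphs_identical(up$upper, ens$upper))
  expect_true(graphs_identical(up$lower, ens$lower))
})
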