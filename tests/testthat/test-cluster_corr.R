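test_that("correlation distance follows 1 - cor and rejects degenerate profiles", {
  x <- c(3, 1, 4, 1, 5, 9)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, max(x) - x), 2)
  y <- c(2, 7, 1, 8, 2, 8)
  expect_equal(correlation_distance(x, y),
               1 - oracle_spearman(x, y))
  expect_equal(correlation_distance(x, y, "pearson"), 1 - cor(x, y))
  expect_error(correlation_distance(x, rep(1, 6)), "zero-variance")
  expect_error(correlation_distance(x, y[1:3]), "length")
})

test_that("average-linkage heights match the brute-force agglomeration oracle (<= 12 items)", {
  set.seed(27)
  for (linkage in c("average", "complete")) {
    for (n_items in c(5, 9, 12)) {
      x <- matrix(rnorm(20 * n_items), 20, n_items,
                  dimnames = list(NULL, paste0("it", seq_len(n_items))))
      tree <- hierarchical_cluster(x, "samples", "spearman", linkage)
      d <- 1 - cor(x, method = "spearman")
      want <- oracle_agglomerate(as.dist(d), linkage)
      expect_equal(sort(tree$hc$height), sort(want$heights),
                   tolerance = 1e-12)
      got_coph <- as.matrix(stats::cophenetic(tree$hc))
      dimnames(want$cophenetic) <- dimnames(got_coph)
      expect_equal(got_coph, want$cophenetic, tolerance = 1e-12)
    }
  }
})

test_that("three hand-traced items merge in the hand order; duplicates join at height 0", {
  # pairwise Pearson distances force (a,b) first, then c
  x <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 3, 3.9), c = c(4, 1, 3, 2))
  tree <- hierarchical_cluster(x, "samples", "pearson", "average")
  expect_identical(tree$hc$merge[1, ], c(-1L, -2L))
  d <- 1 - cor(x)
  expect_equal(tree$hc$height[1], d["a", "b"])
  expect_equal(tree$hc$height[2], mean(d[c("a", "b"), "c"]))

  xd <- cbind(x, a2 = x[, "a"])
  treed <- hierarchical_cluster(xd, "samples", "pearson", "average")
  expect_equal(treed$hc$height[1], 0)

  expect_error(hierarchical_cluster(cbind(a = rep(1, 4), b = 1:4)),
               "zero-variance")
})

test_that("clustering separates two planted sample groups and is stable under column permutation", {
  set.seed(51)
  g <- matrix(rnorm(40 * 16), 40, 16)
  # two coherent planted groups: each has its own elevated gene block
  g[1:20, 9:16] <- g[1:20, 9:16] + 3
  g[21:40, 1:8] <- g[21:40, 1:8] + 3
  colnames(g) <- paste0("s", 1:16)
  tree <- hierarchical_cluster(g)
  k <- cut_tree(tree, 2)
  expect_identical(length(unique(k[1:8])), 1L)
  expect_identical(length(unique(k[9:16])), 1L)
  expect_false(k[1] == k[9])

  perm <- sample(16)
  treep <- hierarchical_cluster(g[, perm])
  expect_equal(sort(treep$hc$height), sort(tree$hc$height))
  kp <- cut_tree(treep, 2)[colnames(g)]
  expect_identical(length(unique(paste(k, kp))), 2L)

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  phy <- ape::read.tree(f)
  expect_identical(sort(phy$tip.label), sort(colnames(g)))
})

test_that("genome-wide correlation ranks a planted co-regulated block on top and is monotone-invariant", {
  set.seed(61)
  n <- 60
  z <- rnorm(n)
  vals <- matrix(exp(rnorm(2000 * n, 3, 0.4)), 2000, n)
  vals[1, ] <- exp(3 + 0.7 * z)                     # target
  for (i in 2:51) {
    vals[i, ] <- exp(3 + 0.4 * (0.8 * z + sqrt(1 - 0.64) * rnorm(n)))
  }
  em <- make_matrix(vals)
  ann <- simple_annotation(em)
  target <- rownames(em$values)[1]
  rk <- correlate_genomewide(em, target, ann)
  expect_false(target %in% rk$probeset)
  block <- rownames(em$values)[2:51]
  expect_gte(sum(rk$probeset[1:100] %in% block), 45)

  # a gene identical to the target ranks first with rho 1
  vals2 <- vals; vals2[2, ] <- vals[1, ] * 2
  em2 <- make_matrix(vals2)
  rk2 <- correlate_genomewide(em2, target, simple_annotation(em2))
  expect_identical(rk2$probeset[1], rownames(em2$values)[2])
  expect_equal(rk2$rho[1], 1)

  # monotone transform of the target leaves rho unchanged
  em3 <- expression_matrix(rbind(em$values, tgt2 = em$values[target, ]^3))
  rk3 <- correlate_genomewide(em3, "tgt2")
  m <- match(rk$probeset, rk3$probeset)
  expect_equal(rk3$rho[m], rk$rho, tolerance = 1e-12)

  expect_error(correlate_genomewide(
    make_matrix(matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE)),
    "ps001_at"), "constant target")
})

test_that("Spearman rho and p match direct computation; panel top-K counting collapses genes", {
  set.seed(71)
  n <- 30
  vals <- matrix(exp(rnorm(40 * n, 3, 0.5)), 40, n)
  em <- make_matrix(vals)
  ann <- simple_annotation(em)
  target <- rownames(em$values)[1]
  rk <- correlate_genomewide(em, target, ann)
  for (i in c(2, 17, 40)) {
    ps <- rownames(em$values)[i]
    want_rho <- oracle_spearman(vals[i, ], vals[1, ])
    expect_equal(rk$rho[rk$probeset == ps], want_rho, tolerance = 1e-12)
    tstat <- want_rho * sqrt((n - 2) / (1 - want_rho^2))
    expect_equal(rk$p[rk$probeset == ps], 2 * pt(-abs(tstat), n - 2),
                 tolerance = 1e-12)
  }
  top <- panel_in_top_k(rk, gene_panel(rk$symbol[1:5]), k = 10)
  expect_identical(top$count, 5L)
  none <- panel_in_top_k(rk, gene_panel("ZZZ"), k = 10)
  expect_identical(none$count, 0L)
})
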