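test_that("quartile stratification takes floor(n/4) extremes with deterministic tie-breaks", {
  em <- make_matrix(matrix(rep(1:8, each = 1), 1, 8))
  st <- stratify_by_quartiles(em, rownames(em$values)[1])
  expect_identical(sort(stratum_samples(st, "HIGH")), c("S07", "S08"))
  expect_identical(sort(stratum_samples(st, "LOW")), c("S01", "S02"))
  expect_identical(sum(st$stratum == "MEDIUM"), 4L)

  # ties across the boundary resolved by sample-id order
  emt <- make_matrix(matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 1, 8))
  stt <- stratify_by_quartiles(emt, rownames(emt$values)[1])
  expect_identical(sort(stratum_samples(stt, "LOW")), c("S01", "S02"))
  expect_identical(sort(stratum_samples(stt, "HIGH")), c("S07", "S08"))

  # strata are disjoint and exhaustive; HIGH dominates MEDIUM on values
  em2 <- random_matrix(1, 23, seed = 9)
  st2 <- stratify_by_quartiles(em2, rownames(em2$values)[1])
  expect_identical(length(stratum_samples(st2, "HIGH")), 5L)
  expect_identical(length(stratum_samples(st2, "LOW")), 5L)
  v <- em2$values[1, ]
  expect_gte(min(v[stratum_samples(st2, "HIGH")]),
             max(v[stratum_samples(st2, "MEDIUM")]))
  expect_error(stratify_by_quartiles(make_matrix(matrix(1:4, 1, 4)),
                                     "ps001_at"), "at least 8")
})

test_that("welch_t matches the closed-form oracle and handles degenerate input by convention", {
  got <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, -3.674, tolerance = 1e-3)
  expect_equal(got$df, 4)
  expect_equal(got$p, 0.0213, tolerance = 1e-3)
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 1)
    want <- oracle_welch(a, b)
    got <- welch_t(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    swapped <- welch_t(b, a)
    expect_equal(swapped$t, -got$t)
    expect_equal(swapped$p, got$p)
  }
  expect_equal(welch_t(c(2, 2), c(2, 2))[c("t", "p")], list(t = 0, p = 1))
  deg <- welch_t(c(2, 2), c(3, 3))
  expect_true(deg$degenerate)
})

test_that("benjamini_hochberg equals the brute-force step-up on random vectors", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(6)
  for (m in c(1, 2, 17, 1000)) {
    p <- runif(m)^sample(1:3, 1)
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential expression collapses genes to the min-p probeset and flips cleanly under group swap", {
  set.seed(33)
  vals <- matrix(exp(rnorm(12 * 10, 3, 0.3)), 12, 10)
  vals[1, 1:5] <- vals[1, 1:5] * 6      # strong probeset of gene X
  vals[2, 1:5] <- vals[2, 1:5] * 1.05   # weak probeset of gene X
  em <- make_matrix(vals)
  ann <- simple_annotation(em, c("X", "X", sprintf("N%02d", 3:12)))
  a <- colnames(em$values)[1:5]; b <- colnames(em$values)[6:10]
  de <- differential_expression(em, ann, a, b)
  x <- de[de$symbol == "X", ]
  expect_identical(x$probeset, rownames(em$values)[1])
  expect_identical(x$direction, "up")

  sw <- differential_expression(em, ann, b, a)
  m <- match(de$symbol, sw$symbol)
  expect_equal(sw$p[m], de$p)
  expect_equal(sw$fold[m], 1 / de$fold)
  up <- de$direction == "up"
  expect_identical(sw$direction[m][up], rep("down", sum(up)))

  expect_error(differential_expression(em, ann, a, c(b, a[1])), "overlap")
})

test_that("panel summary partitions panel genes and reports missing symbols", {
  set.seed(40)
  fix <- generate_cohorts(synthetic_spec(seed = 40))
  na <- normalize_per_chip(fix$cohort_a)
  nb <- normalize_per_chip(fix$cohort_b)
  merged <- expression_matrix(cbind(na$values, nb$values))
  de <- differential_expression(merged, fix$annotation,
                                colnames(nb$values), colnames(na$values))
  ps <- panel_de_summary(de, fix$panel)
  expect_identical(ps$up + ps$down + ps$unchanged + length(ps$missing), 73L)
  expect_true(all(fix$truth$panel_down_symbols %in%
                    c(ps$down_symbols, ps$unchanged_symbols)))
  # a symbol absent from the result is reported, not counted
  fake <- gene_panel(c(fix$panel$symbol[1], "NOT_A_GENE"))
  ps2 <- panel_de_summary(de, fake)
  expect_identical(ps2$missing, "NOT_A_GENE")
  empty <- panel_de_summary(de, gene_panel("ZZZ"))
  expect_identical(empty$up + empty$down + empty$unchanged, 0L)
})
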