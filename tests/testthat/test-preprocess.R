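test_that("per-chip then per-gene normalization drives column then row medians to 1", {
  em <- random_matrix(25, 7, seed = 11)
  chip <- normalize_per_chip(em)
  expect_equal(unname(apply(chip$values, 2, median)), rep(1, 7))
  gene <- normalize_per_gene(chip)
  expect_equal(unname(apply(gene$values, 1, median)),
               rep(1, nrow(gene$values)))
  # explicit small cases
  one <- make_matrix(matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(normalize_per_chip(one)$values[, 1]),
               c(0.5, 1, 1.5))
  row <- make_matrix(matrix(c(2, 4, 8), 1, 3))
  expect_equal(unname(normalize_per_gene(row)$values[1, ]), c(0.5, 1, 2))
  const <- make_matrix(matrix(5, 2, 3))
  expect_true(all(normalize_per_chip(const)$values == 1))
})

test_that("per-gene normalization preserves within-row sample ranking and drops zero-median rows", {
  em <- random_matrix(10, 6, seed = 2)
  gene <- normalize_per_gene(em)
  for (i in seq_len(nrow(em$values))) {
    expect_identical(order(gene$values[i, ]), order(em$values[i, ]))
  }
  vals <- em$values
  vals[3, ] <- 0
  withz <- expression_matrix(vals)
  expect_message(out <- normalize_per_gene(withz), "excluded")
  expect_identical(attr(out, "dropped"), rownames(vals)[3])
})

test_that("normalization rejects nonpositive sample medians by name", {
  vals <- matrix(c(0, 0, 0, 1, 2, 3), 3, 2,
                 dimnames = list(paste0("p", 1:3), c("bad", "good")))
  expect_error(normalize_per_chip(expression_matrix(vals)), "bad")
})

test_that("pcall_fraction counts PRESENT only, over the requested samples", {
  calls <- matrix(c("P", "P", "M", "A"), 1, 4)
  em <- make_matrix(matrix(1, 1, 4), calls)
  expect_equal(pcall_fraction(em, rownames(em$values)[1]), 0.5)
  expect_equal(pcall_fraction(em, rownames(em$values)[1],
                              samples = c("S01", "S02")), 1.0)
  allp <- make_matrix(matrix(1, 1, 10), matrix("P", 1, 10))
  expect_equal(pcall_fraction(allp, rownames(allp$values)[1]), 1.0)
  nop <- make_matrix(matrix(1, 1, 10), matrix("A", 1, 10))
  expect_equal(pcall_fraction(nop, rownames(nop$values)[1]), 0.0)
  expect_error(pcall_fraction(random_matrix(2, 2)), "call")
})

test_that("apply_filters keeps exactly the planted survivors, strictly above threshold, and is idempotent", {
  # 5 probesets x 10 samples: present fractions 1.0, 0.8, 0.9, 1.0, 0.0
  fr <- c(1, 0.8, 0.9, 1, 0)
  calls <- t(vapply(fr, function(f) {
    c(rep("P", round(10 * f)), rep("A", 10 - round(10 * f)))
  }, character(10)))
  em <- make_matrix(matrix(10, 5, 10), calls)
  ann <- simple_annotation(em, c("A1", "A2", "A3", "", "A5"))
  out <- apply_filters(em, ann, filter_spec(0.8))
  # 0.8 is removed (strict >), unannotated removed, absent removed
  expect_identical(rownames(out$values),
                   rownames(em$values)[c(1, 3)])
  again <- apply_filters(out, ann, filter_spec(0.8))
  expect_identical(again$values, out$values)
  # annotation requirement alone
  out2 <- apply_filters(em, ann, filter_spec(0, require_annotation = TRUE))
  expect_identical(rownames(out2$values), rownames(em$values)[-4])
  expect_warning(apply_filters(em, ann, filter_spec(1)), "survive")
})

test_that("collapse_by_max_expression matches a brute-force argmax over probesets", {
  set.seed(5)
  em <- random_matrix(20, 8, seed = 5)
  sym <- sample(sprintf("G%02d", 1:7), 20, replace = TRUE)
  ann <- simple_annotation(em, sym)
  out <- collapse_by_max_expression(em, ann)
  for (s in unique(sym)) {
    ids <- rownames(em$values)[sym == s]
    means <- rowMeans(em$values[ids, , drop = FALSE])
    expect_identical(out$probeset[out$symbol == s],
                     ids[which.max(means)])
  }
  # forced two-probeset case
  vals <- rbind(rep(5, 4), rep(50, 4))
  em2 <- make_matrix(vals)
  ann2 <- simple_annotation(em2, c("X", "X"))
  expect_identical(collapse_by_max_expression(em2, ann2)$probeset,
                   rownames(em2$values)[2])
})
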