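test_that("the generator is deterministic under a fixed seed and distinct across seeds", {
  a1 <- generate_cohorts(synthetic_spec(seed = 5))
  a2 <- generate_cohorts(synthetic_spec(seed = 5))
  expect_identical(a1$cohort_a$values, a2$cohort_a$values)
  expect_identical(a1$cohort_b$calls, a2$cohort_b$calls)
  expect_identical(a1$annotation, a2$annotation)
  b <- generate_cohorts(synthetic_spec(seed = 6))
  expect_false(identical(a1$cohort_a$values, b$cohort_a$values))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_cohorts(synthetic_spec(seed = 5, n_probesets = 200)))
  expect_identical(rnorm(1), before)
})

test_that("realized marginal structure tracks the spec across seeds", {
  cvs <- folds <- rhos <- hks <- numeric(0)
  for (seed in 1:5) {
    fix <- generate_cohorts(synthetic_spec(seed = seed))
    na <- normalize_per_chip(fix$cohort_a)
    tp <- fix$truth$target_probeset
    cvs <- c(cvs, coefficient_of_variation(na$values[tp, ]))
    folds <- c(folds, max(fix$cohort_a$values[tp, ]) /
                 min(fix$cohort_a$values[tp, ]))
    rk <- correlate_genomewide(na, tp, fix$annotation)
    rhos <- c(rhos, median(rk$rho[rk$symbol %in% fix$panel$symbol]))
    scr <- variability_screen(na, tp, annotation = fix$annotation)
    hks <- c(hks,
             scr$cv_table$cv_percent[scr$cv_table$role == "housekeeping"])
  }
  # target CV calibrated to 80% (tolerance band of the generator contract)
  expect_true(all(cvs > 70 & cvs < 90))
  expect_gt(median(folds), 20)         # wide target dynamic range
  expect_true(all(rhos > 0.6 & rhos < 0.8))
  expect_true(all(hks > 10 & hks < 55))  # housekeeping CVs stay low
})

test_that("detection calls follow intensity: high-mean genes mostly present, low-mean mostly absent", {
  fix <- generate_cohorts(synthetic_spec(seed = 3))
  em <- fix$cohort_a
  frac <- pcall_fraction(em)
  means <- rowMeans(log2(em$values))
  expect_gt(cor(means, frac, method = "spearman"), 0.8)
  expect_gt(mean(frac[means > 7]), 0.95)
  expect_lt(mean(frac[means < 3]), 0.25)
  # the target and nearly all panel probesets survive the >80% filter
  # (a strong responder can genuinely drop below detection in its lowest
  # expressors, as real mucin genes do)
  filt <- apply_filters(em, fix$annotation, filter_spec())
  expect_gte(mean(fix$panel$probeset %in% rownames(filt$values)), 0.95)
  expect_true(fix$truth$target_probeset %in% rownames(filt$values))
})

test_that("a null spec (no planted structure) yields uniform Welch p-values and few discoveries", {
  pvals <- numeric(0)
  n_sig <- integer(0)
  for (seed in 1:3) {
    spec <- synthetic_spec(seed = seed, n_probesets = 400,
                           panel_correlation = 0, panel_correlation_spread = 0,
                           target_fold_b = 1, n_panel_up = 0L,
                           n_panel_down = 0L)
    fix <- generate_cohorts(spec)
    na <- normalize_per_chip(fix$cohort_a)
    # split cohort A randomly: no structure separates the halves
    set.seed(seed)
    grp <- sample(colnames(na$values))
    de <- differential_expression(na, fix$annotation, grp[1:30], grp[31:60],
                                  exclude_symbols = "MUC5AC")
    # restrict to single-probeset genes: min-p collapsing biases multi-
    # probeset genes away from uniformity by construction
    single <- names(which(table(fix$annotation$symbol[
      fix$annotation$symbol != ""]) == 1))
    pvals <- c(pvals, de$p[de$symbol %in% single])
    n_sig <- c(n_sig, sum(de$significant))
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(sum(n_sig), 3L)
})

test_that("end_to_end_fixture bundles matrices, panel, truth and recovery bounds", {
  fix <- end_to_end_fixture(synthetic_spec(seed = 2, n_probesets = 300))
  expect_s3_class(fix$cohort_a, "expression_matrix")
  expect_s3_class(fix$panel, "gene_panel")
  expect_identical(nrow(fix$panel), 73L)
  expect_identical(length(fix$truth$panel_up_symbols), 28L)
  expect_identical(length(fix$truth$panel_down_symbols), 6L)
  expect_true(all(c("de_sensitivity_min", "de_fdr_max", "index_p_max") %in%
                    names(fix$expectations)))
  expect_identical(ncol(fix$cohort_a$values), 60L)
  expect_identical(ncol(fix$cohort_b$values), 72L)
})
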