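# Expressor-quartile stratification and filtered genome-wide differential
# expression.
#
# "Quartile" here is the count-based rule floor(n/4): a 60-sample cohort
# yields HIGH and LOW groups of 15, a 72-sample cohort groups of 18. Welch's
# unequal-variance t-test runs per probeset on per-chip normalized
# intensities; Benjamini-Hochberg correction is applied once over the whole
# filtered probeset universe, and multi-probeset genes are then collapsed to
# the probeset with the lowest raw p.

#' Stratify a cohort into expressor quartiles of a target probeset
#'
#' Samples are sorted by target expression (ties broken by sample-id order);
#' the top `floor(n/4)` become HIGH expressors, the bottom `floor(n/4)` LOW,
#' the remainder MEDIUM.
#'
#' @param em an `expression_matrix`.
#' @param target_probeset probeset id driving the stratification.
#' @param samples cohort sample ids (default: all columns).
#' @return object of class `stratified_cohort`: data.frame (`sample_id`,
#'   `target_expression`, `stratum`) plus attributes `target_probeset` and
#'   `quartile_n`.
#' @export
stratify_by_quartiles <- function(em, target_probeset, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(samples)) samples <- colnames(em$values)
  n <- length(samples)
  if (n < 8L) stop("need at least 8 samples to form quartile strata",
                   call. = FALSE)
  if (!target_probeset %in% rownames(em$values)) {
    stop("target probeset not in matrix: ", target_probeset, call. = FALSE)
  }
  expr <- em$values[target_probeset, samples]
  k <- n %/% 4L
  ord <- order(expr, samples)  # ascending; sample-id order breaks ties
  stratum <- rep("MEDIUM", n)
  stratum[ord[seq_len(k)]] <- "LOW"
  stratum[ord[seq.int(n - k + 1L, n)]] <- "HIGH"
  out <- data.frame(sample_id = samples, target_expression = unname(expr),
                    stratum = stratum, stringsAsFactors = FALSE)
  structure(out, class = c("stratified_cohort", "data.frame"),
            target_probeset = target_probeset, quartile_n = k)
}

#' Sample ids of one stratum
#' @param strat a `stratified_cohort`.
#' @param stratum `"HIGH"`, `"MEDIUM"` or `"LOW"`.
#' @return character vector of sample ids.
#' @export
stratum_samples <- function(strat, stratum = c("HIGH", "MEDIUM", "LOW")) {
  stratum <- match.arg(stratum)
  strat$sample_id[strat$stratum == stratum]
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom.
#' Degenerate inputs are resolved by convention: two constant equal groups
#' give `t = 0, p = 1`; two constant unequal groups are flagged with `p = 0`
#' and `degenerate = TRUE`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p` (two-sided) and `degenerate` flag.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (a[1L] == b[1L]) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  res <- t.test(a, b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the input order (monotone, capped at 1,
#'   elementwise >= raw).
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Genome-wide differential expression between two sample groups
#'
#' Per-probeset Welch t-test on per-chip normalized intensities, B-H
#' correction over all tested probesets, then collapsing of multi-probeset
#' genes to the probeset with the lowest raw p. Fold-change is the ratio of
#' group means (`mean_a / mean_b`); direction is "up" when group A's mean is
#' larger. Probesets of excluded symbols (the stratifying target's own
#' probesets, when comparing its expressor strata) are removed before
#' testing.
#'
#' @param em an `expression_matrix`, filtered and per-chip normalized.
#' @param annotation annotation data.frame (`probeset_id`, `symbol`).
#' @param group_a,group_b disjoint character vectors of sample ids; group A
#'   is the "case" group (HIGH expressors, stressed cohort).
#' @param alpha significance threshold on adjusted p.
#' @param exclude_symbols gene symbols whose probesets are dropped before
#'   testing.
#' @param transform `"log2"` (default) tests `log2(x + 1)` — the scale on
#'   which MAS5-style intensities are approximately normal and the Welch
#'   test keeps its power at quartile-sized groups; `"linear"` tests the
#'   normalized intensities as-is. Fold-changes are ratios of linear-scale
#'   group means under either setting.
#' @param collapse `"after_bh"` (default) corrects over probesets then picks
#'   the min-raw-p probeset per gene; `"before_bh"` collapses first and
#'   corrects over genes.
#' @return object of class `de_result`: data.frame with one row per gene
#'   (`symbol`, `probeset`, `mean_a`, `mean_b`, `fold`, `log2_fold`, `p`,
#'   `p_adj`, `direction`, `significant`), ordered by raw p.
#' @export
differential_expression <- function(em, annotation, group_a, group_b,
                                    alpha = 0.05,
                                    exclude_symbols = character(),
                                    transform = c("log2", "linear"),
                                    collapse = c("after_bh", "before_bh")) {
  stopifnot(inherits(em, "expression_matrix"))
  transform <- match.arg(transform)
  collapse <- match.arg(collapse)
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups overlap", call. = FALSE)
  }
  missing_s <- setdiff(c(group_a, group_b), colnames(em$values))
  if (length(missing_s)) stop("unknown sample(s): ",
                              paste(missing_s, collapse = ", "),
                              call. = FALSE)
  sym <- annotation$symbol[match(rownames(em$values),
                                 annotation$probeset_id)]
  keep <- !is.na(sym) & sym != "" & !(sym %in% exclude_symbols)
  ids <- rownames(em$values)[keep]
  sym <- sym[keep]
  va <- em$values[ids, group_a, drop = FALSE]
  vb <- em$values[ids, group_b, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  ta <- if (transform == "log2") log2(va + 1) else va
  tb <- if (transform == "log2") log2(vb + 1) else vb
  p <- vapply(seq_along(ids),
              function(i) welch_t(ta[i, ], tb[i, ])$p, numeric(1))
  tab <- data.frame(symbol = sym, probeset = ids, mean_a = mean_a,
                    mean_b = mean_b, p = p, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (collapse == "before_bh") {
    tab <- collapse_min_p(tab)
    tab$p_adj <- benjamini_hochberg(tab$p)
  } else {
    tab$p_adj <- benjamini_hochberg(tab$p)
    tab <- collapse_min_p(tab)
  }
  tab$fold <- tab$mean_a / tab$mean_b
  tab$log2_fold <- log2(tab$fold)
  tab$direction <- ifelse(tab$fold > 1, "up",
                          ifelse(tab$fold < 1, "down", "unchanged"))
  tab$significant <- tab$p_adj < alpha
  tab <- tab[order(tab$p, tab$symbol),
             c("symbol", "probeset", "mean_a", "mean_b", "fold", "log2_fold",
               "p", "p_adj", "direction", "significant")]
  rownames(tab) <- NULL
  structure(tab, class = c("de_result", "data.frame"), alpha = alpha)
}

# one row per symbol: the probeset with the lowest raw p (first-in-order on
# exact ties)
collapse_min_p <- function(tab) {
  ord <- order(tab$p, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab[!duplicated(tab$symbol), , drop = FALSE]
}

#' Summarize a differential-expression result over a gene panel
#'
#' Partitions the panel into up-regulated, down-regulated and unchanged genes
#' at the result's significance threshold; panel symbols absent from the
#' result are reported separately and not counted.
#'
#' @param de a `de_result`.
#' @param panel a [gene_panel()].
#' @return list with `up`, `down`, `unchanged` (counts), the corresponding
#'   symbol vectors (`up_symbols`, `down_symbols`, `unchanged_symbols`) and
#'   `missing` (panel symbols not present in the result).
#' @export
panel_de_summary <- function(de, panel) {
  stopifnot(inherits(de, "de_result"))
  hit <- de[de$symbol %in% panel$symbol, , drop = FALSE]
  missing <- setdiff(panel$symbol, hit$symbol)
  up <- hit$symbol[hit$significant & hit$direction == "up"]
  down <- hit$symbol[hit$significant & hit$direction == "down"]
  unchanged <- setdiff(hit$symbol, c(up, down))
  list(up = length(up), down = length(down), unchanged = length(unchanged),
       up_symbols = up, down_symbols = down, unchanged_symbols = unchanged,
       missing = missing)
}
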