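# Panel outlier-fraction index.
#
# For each panel gene, a "normal range" (mean +/- 2 SD) is fitted from a
# reference group (e.g. nonsmoker low-expressors). A sample's index is the
# percentage of panel genes whose expression falls strictly outside its
# normal range, in either direction: index = c * sum_g E_g with
# c = 100 / n_panel and E_g an indicator of being outside the range.

#' Fit per-gene 2-SD normal ranges from a reference group
#'
#' @param em an `expression_matrix` (per-chip normalized).
#' @param panel a [gene_panel()]; symbols without a bound probeset are
#'   resolved via `annotation` by highest mean expression over the reference
#'   samples. Panel genes with no matching probeset are dropped with a
#'   message (the index denominator shrinks accordingly).
#' @param reference_samples sample ids of the reference group (>= 2).
#' @param annotation annotation data.frame, needed when the panel has
#'   unbound symbols.
#' @param transform scale on which ranges are fitted and samples scored:
#'   `"log2"` (default, `log2(x + 1)` — consistent with the scale the
#'   differential-expression tests run on, and the scale on which
#'   MAS5-style intensities are approximately normal so the 2-SD range has
#'   its nominal coverage) or `"linear"`. Recorded in the fitted object;
#'   [compute_index()] always scores on the scale the range was fitted on.
#' @return object of class `normal_range`: data.frame (`symbol`, `probeset`,
#'   `mean`, `sd`, `lower`, `upper`, `degenerate`) with attribute
#'   `reference_samples`. `degenerate` flags genes whose reference SD is 0
#'   (range collapses to the mean).
#' @export
fit_normal_range <- function(em, panel, reference_samples,
                             annotation = NULL,
                             transform = c("log2", "linear")) {
  stopifnot(inherits(em, "expression_matrix"))
  transform <- match.arg(transform)
  if (length(reference_samples) < 2L) {
    stop("reference group needs at least 2 samples", call. = FALSE)
  }
  resolved <- resolve_panel_probesets(em, panel, annotation,
                                      reference_samples)
  vals <- em$values[resolved$probeset, reference_samples, drop = FALSE]
  if (transform == "log2") vals <- log2(vals + 1)
  mu <- rowMeans(vals)
  s <- apply(vals, 1L, sd)
  out <- data.frame(symbol = resolved$symbol, probeset = resolved$probeset,
                    mean = unname(mu), sd = unname(s),
                    lower = unname(mu - 2 * s), upper = unname(mu + 2 * s),
                    degenerate = s == 0, stringsAsFactors = FALSE)
  if (any(out$degenerate)) {
    message(sum(out$degenerate),
            " panel gene(s) with zero reference SD: range collapses to the ",
            "mean; deviations beyond a relative epsilon count as outside")
  }
  structure(out, class = c("normal_range", "data.frame"),
            reference_samples = reference_samples, transform = transform)
}

# Bind every panel symbol to a probeset: keep explicit bindings, resolve the
# rest by highest mean expression among the symbol's probesets; report and
# drop symbols with no probeset in the matrix.
resolve_panel_probesets <- function(em, panel, annotation,
                                    reference_samples) {
  probeset <- panel$probeset
  need <- is.na(probeset)
  if (any(need)) {
    if (is.null(annotation)) {
      stop("annotation required to resolve panel symbols to probesets",
           call. = FALSE)
    }
    choice <- collapse_by_max_expression(em, annotation,
                                         reference_samples = reference_samples)
    probeset[need] <- choice$probeset[match(panel$symbol[need],
                                            choice$symbol)]
  }
  present <- !is.na(probeset) & probeset %in% rownames(em$values)
  if (!any(present)) stop("no panel gene maps to the matrix", call. = FALSE)
  if (any(!present)) {
    message("panel gene(s) without matching probeset dropped: ",
            paste(panel$symbol[!present], collapse = ", "))
  }
  data.frame(symbol = panel$symbol[present], probeset = probeset[present],
             stringsAsFactors = FALSE)
}

#' Per-sample panel outlier-fraction index
#'
#' For each sample, counts the panel genes whose expression lies strictly
#' outside the fitted normal range (either direction) and reports the count
#' as a percentage of the evaluable panel. Genes with a degenerate
#' (zero-SD) range count a sample as outside when it deviates from the
#' reference mean by more than a relative epsilon of `1e-9`.
#'
#' @param em an `expression_matrix` on the same scale the range was fitted
#'   on.
#' @param range a `normal_range` from [fit_normal_range()].
#' @param samples sample ids to score (default: all columns).
#' @return object of class `index_result`: data.frame (`sample_id`,
#'   `n_outside`, `n_panel`, `index_percent`) with attribute
#'   `outside_genes` (named list of outside-range symbols per sample).
#' @export
compute_index <- function(em, range, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(range, "normal_range"))
  if (nrow(range) == 0L) stop("empty panel", call. = FALSE)
  if (is.null(samples)) samples <- colnames(em$values)
  vals <- em$values[range$probeset, samples, drop = FALSE]
  if (identical(attr(range, "transform"), "log2")) vals <- log2(vals + 1)
  tol <- ifelse(range$degenerate, 1e-9 * pmax(1, abs(range$mean)), 0)
  outside <- vals < (range$lower - tol) | vals > (range$upper + tol)
  n <- nrow(range)
  n_out <- colSums(outside)
  out <- data.frame(sample_id = samples, n_outside = unname(n_out),
                    n_panel = n, index_percent = unname(100 * n_out / n),
                    stringsAsFactors = FALSE)
  genes <- lapply(seq_along(samples),
                  function(j) range$symbol[outside[, j]])
  names(genes) <- samples
  structure(out, class = c("index_result", "data.frame"),
            outside_genes = genes, constant_c = 100 / n)
}

#' Compare panel-index distributions between two groups
#'
#' Two-sided Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise) plus the ratio of group mean
#' indices (group B relative to group A).
#'
#' @param index_a,index_b numeric vectors of per-sample index values
#'   (percent), both nonempty.
#' @return list with `U` (statistic of group A), `p.value`,
#'   `fold_difference` (`mean(index_b) / mean(index_a)`, `NA` when group A's
#'   mean is 0) and `method`.
#' @export
compare_index_groups <- function(index_a, index_b) {
  if (length(index_a) == 0L || length(index_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  fold <- if (mean(index_a) > 0) mean(index_b) / mean(index_a) else NA_real_
  pooled <- c(index_a, index_b)
  if (length(unique(pooled)) == 1L) {
    return(list(U = length(index_a) * length(index_b) / 2, p.value = 1,
                fold_difference = fold, method = "degenerate"))
  }
  exact <- !anyDuplicated(pooled) &&
    length(index_a) < 50 && length(index_b) < 50
  res <- suppressWarnings(wilcox.test(index_a, index_b,
                                      alternative = "two.sided",
                                      exact = exact, correct = !exact))
  list(U = unname(res$statistic), p.value = min(1, res$p.value),
       fold_difference = fold,
       method = if (exact) "exact" else "normal-approximation")
}
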