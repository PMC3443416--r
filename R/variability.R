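# Target-vs-housekeeping variability screen.
#
# The target gene (e.g. MUC5AC) is called highly variable when its
# coefficient of variation across samples exceeds that of every housekeeping
# gene and the Ansari-Bradley dispersion test rejects equality of spread for
# each pairwise comparison. The CV contrast is about *relative* spread, so
# the screen rescales each gene's vector by its own median (the per-gene
# normalization scale) before the rank test; on raw per-chip values a
# highly expressed control gene can have larger absolute spread than the
# target even when its CV is far smaller, and the test would miss the
# contrast it is meant to capture.

#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the n-1 standard deviation.
#'
#' @param values numeric vector, length >= 2, strictly positive mean.
#' @return CV as a percentage.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("CV undefined: mean must be > 0", call. = FALSE)
  }
  100 * sd(values) / m
}

#' Pick a housekeeping gene's probeset by highest CV
#'
#' Housekeeping genes with multiple probesets are represented by the probeset
#' with the highest cross-sample coefficient of variation (the conservative
#' choice when arguing the target is *more* variable than the controls).
#'
#' @param em an `expression_matrix`.
#' @param symbol gene symbol to resolve.
#' @param annotation annotation data.frame (`probeset_id`, `symbol`).
#' @param samples samples over which CV is computed (default: all).
#' @return the selected probeset id.
#' @export
select_housekeeping_probeset <- function(em, symbol, annotation,
                                         samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(samples)) samples <- colnames(em$values)
  ps <- annotation$probeset_id[annotation$symbol == symbol]
  ps <- intersect(ps, rownames(em$values))
  if (length(ps) == 0L) stop("no probeset found for symbol: ", symbol,
                             call. = FALSE)
  cvs <- apply(em$values[ps, samples, drop = FALSE], 1L,
               coefficient_of_variation)
  ps[which.max(cvs)]
}

#' Ansari-Bradley two-sample dispersion test
#'
#' Rank-based test of equal spread. Samples are location-aligned first
#' (classical assumption of equal centers does not hold across genes with
#' different expression levels); the exact null distribution is used for
#' small tie-free samples, otherwise the normal approximation with
#' tie-corrected variance.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_threshold use the exact distribution when
#'   `length(x) + length(y) <=` this and the pooled (aligned) sample is
#'   tie-free.
#' @param center location alignment applied to each sample before ranking:
#'   `"median"` (default), `"mean"`, or `"none"`.
#' @return list with `statistic` (AB rank statistic of `x`), `p.value`
#'   (two-sided, in (0, 1\]) and `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @export
ansari_bradley <- function(x, y, exact_threshold = 50,
                           center = c("median", "mean", "none")) {
  center <- match.arg(center)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (center == "median") {
    x <- x - median(x); y <- y - median(y)
  } else if (center == "mean") {
    x <- x - mean(x); y <- y - mean(y)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate data: all pooled values identical", call. = FALSE)
  }
  exact <- (length(x) + length(y)) <= exact_threshold &&
    !anyDuplicated(pooled)
  res <- suppressWarnings(ansari.test(x, y, alternative = "two.sided",
                                      exact = exact))
  list(statistic = unname(res$statistic),
       p.value = min(1, max(res$p.value, .Machine$double.xmin)),
       method = if (exact) "exact" else "normal-approximation")
}

#' Variability screen of a target gene against housekeeping controls
#'
#' Computes the cross-sample CV of the target probeset and of each
#' housekeeping gene (probeset resolved by [select_housekeeping_probeset()]),
#' plus a pairwise Ansari-Bradley dispersion test of target vs each control,
#' run on median-rescaled (per-gene normalized) vectors so that relative
#' spread — the quantity CV measures — is what is compared. The target is
#' flagged highly variable when its CV exceeds every control CV and all
#' dispersion tests reject at `alpha`.
#'
#' @param em an `expression_matrix`, per-chip normalized.
#' @param target_probeset probeset id quantifying the target gene.
#' @param housekeeping_symbols control gene symbols (default: the five
#'   classical controls ACTB, GAPDH, B2M, RPLP0, PPIA).
#' @param annotation annotation data.frame.
#' @param samples cohort sample ids (default: all).
#' @param alpha rejection level for the dispersion tests.
#' @return list with `cv_table` (data.frame: role, symbol, probeset,
#'   cv_percent, ab_p), `target_cv`, and `high_variability` flag.
#' @export
variability_screen <- function(em, target_probeset,
                               housekeeping_symbols = c("ACTB", "GAPDH",
                                                        "B2M", "RPLP0",
                                                        "PPIA"),
                               annotation, samples = NULL, alpha = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(samples)) samples <- colnames(em$values)
  if (!target_probeset %in% rownames(em$values)) {
    stop("target probeset not in matrix: ", target_probeset, call. = FALSE)
  }
  tgt <- em$values[target_probeset, samples]
  tgt_sym <- annotation$symbol[match(target_probeset, annotation$probeset_id)]
  tgt_cv <- coefficient_of_variation(tgt)
  rows <- data.frame(role = "target",
                     symbol = ifelse(is.na(tgt_sym), "", tgt_sym),
                     probeset = target_probeset, cv_percent = tgt_cv,
                     ab_p = NA_real_, stringsAsFactors = FALSE)
  for (hk in housekeeping_symbols) {
    ps <- select_housekeeping_probeset(em, hk, annotation, samples)
    v <- em$values[ps, samples]
    ab <- ansari_bradley(tgt / median(tgt), v / median(v))
    rows <- rbind(rows, data.frame(
      role = "housekeeping", symbol = hk, probeset = ps,
      cv_percent = coefficient_of_variation(v), ab_p = ab$p.value,
      stringsAsFactors = FALSE))
  }
  hk_rows <- rows[rows$role == "housekeeping", , drop = FALSE]
  flag <- all(tgt_cv > hk_rows$cv_percent) && all(hk_rows$ab_p < alpha)
  list(cv_table = rows, target_cv = tgt_cv, high_variability = flag)
}
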