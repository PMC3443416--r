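# GeneSpring-style normalization and detection-call filtering.
#
# Per-chip normalization divides each sample by its own median intensity over
# all probesets; per-gene normalization then divides each probeset's vector by
# its median across samples. Statistical testing downstream runs on per-chip
# normalized values; per-gene normalization is a display/clustering scale
# (it rescales each gene by one positive constant, leaving ranks, t statistics
# and fold-changes unchanged).

#' Per-chip median normalization
#'
#' Divides every sample column by that sample's median intensity across all
#' probesets, so each normalized column has median 1. The even-sized median is
#' the midpoint of the central pair.
#'
#' @param em an `expression_matrix`.
#' @return a normalized `expression_matrix` (call layer preserved).
#' @export
normalize_per_chip <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  med <- apply(em$values, 2L, median)
  bad <- !is.finite(med) | med <= 0
  if (any(bad)) {
    stop("per-chip normalization undefined for sample(s) with nonpositive ",
         "median: ", paste(colnames(em$values)[bad], collapse = ", "),
         call. = FALSE)
  }
  expression_matrix(sweep(em$values, 2L, med, "/"), em$calls)
}

#' Per-gene median normalization
#'
#' Divides each probeset row by its own median across samples (row medians
#' become 1). Rows whose median is not strictly positive cannot be scaled and
#' are dropped; their ids are recorded in the `dropped` attribute.
#'
#' @param em an `expression_matrix`.
#' @return a normalized `expression_matrix`; attribute `dropped` lists
#'   excluded probesets.
#' @export
normalize_per_gene <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  med <- apply(em$values, 1L, median)
  keep <- is.finite(med) & med > 0
  if (!all(keep)) {
    message(sum(!keep), " probeset(s) with nonpositive median excluded from ",
            "per-gene normalization")
  }
  out <- expression_matrix(
    sweep(em$values[keep, , drop = FALSE], 1L, med[keep], "/"),
    if (has_calls(em)) em$calls[keep, , drop = FALSE] else NULL)
  attr(out, "dropped") <- rownames(em$values)[!keep]
  out
}

#' Fraction of PRESENT detection calls
#'
#' @param em an `expression_matrix` with a call layer.
#' @param probeset single probeset id (or `NULL` to return the fraction for
#'   every probeset).
#' @param samples sample ids over which the fraction is computed (default:
#'   all samples). MARGINAL counts as not-present.
#' @return numeric fraction in \[0, 1\] (named vector when `probeset = NULL`).
#' @export
pcall_fraction <- function(em, probeset = NULL, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!has_calls(em)) {
    stop("detection-call layer required but absent", call. = FALSE)
  }
  if (is.null(samples)) samples <- colnames(em$values)
  missing_s <- setdiff(samples, colnames(em$values))
  if (length(missing_s)) stop("unknown sample(s): ",
                              paste(missing_s, collapse = ", "), call. = FALSE)
  calls <- em$calls[, samples, drop = FALSE]
  frac <- rowMeans(calls == "P")
  if (is.null(probeset)) return(frac)
  if (!probeset %in% names(frac)) stop("unknown probeset: ", probeset,
                                       call. = FALSE)
  unname(frac[probeset])
}

#' Filter specification for probeset screening
#'
#' @param min_pcall_fraction probesets must have a PRESENT-call fraction
#'   strictly greater than this threshold over `reference_samples`
#'   (default 0.8, the ">80% present" rule).
#' @param reference_samples sample ids over which the call fraction is
#'   computed (`NULL` = all samples of the filtered matrix).
#' @param require_annotation keep only probesets with a nonempty gene symbol.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(min_pcall_fraction = 0.8, reference_samples = NULL,
                        require_annotation = TRUE) {
  stopifnot(min_pcall_fraction >= 0, min_pcall_fraction <= 1)
  structure(list(min_pcall_fraction = min_pcall_fraction,
                 reference_samples = reference_samples,
                 require_annotation = isTRUE(require_annotation)),
            class = "filter_spec")
}

#' Apply detection-call and annotation filters
#'
#' Retains exactly the probesets whose PRESENT-call fraction over the
#' reference samples is strictly greater than the threshold and (when
#' required) that carry a nonempty gene symbol. Input probeset order is
#' preserved; the operation is idempotent.
#'
#' @param em an `expression_matrix` (call layer required when
#'   `spec$min_pcall_fraction > 0`).
#' @param annotation annotation data.frame (`probeset_id`, `symbol`); may be
#'   `NULL` when `require_annotation` is `FALSE`.
#' @param spec a [filter_spec()].
#' @return the filtered `expression_matrix`; attribute `n_removed` records
#'   how many probesets were dropped.
#' @export
apply_filters <- function(em, annotation = NULL, spec = filter_spec()) {
  stopifnot(inherits(em, "expression_matrix"), inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(em$values))
  names(keep) <- rownames(em$values)
  if (spec$min_pcall_fraction > 0) {
    ref <- spec$reference_samples
    if (is.null(ref)) ref <- colnames(em$values)
    frac <- pcall_fraction(em, samples = ref)
    keep <- keep & (frac > spec$min_pcall_fraction)
  }
  if (spec$require_annotation) {
    if (is.null(annotation)) {
      stop("annotation required when require_annotation = TRUE",
           call. = FALSE)
    }
    sym <- annotation$symbol[match(names(keep), annotation$probeset_id)]
    keep <- keep & !is.na(sym) & sym != ""
  }
  if (!any(keep)) warning("no probesets survive the filters", call. = FALSE)
  out <- subset_expression(em, probesets = names(keep)[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Choose one probeset per gene by highest expression
#'
#' For genes represented by multiple probesets, selects the probeset with the
#' highest mean (or median) expression over the reference samples — the rule
#' used to pick a target gene's reporting probeset.
#'
#' @param em an `expression_matrix`, typically per-chip normalized.
#' @param annotation annotation data.frame (`probeset_id`, `symbol`).
#' @param reference_samples samples over which expression is averaged
#'   (default: all).
#' @param estimator `"mean"` (default) or `"median"`.
#' @return data.frame with one row per annotated symbol: `symbol`,
#'   `probeset`, `expression` (the winning estimator value).
#' @export
collapse_by_max_expression <- function(em, annotation,
                                       reference_samples = NULL,
                                       estimator = c("mean", "median")) {
  stopifnot(inherits(em, "expression_matrix"))
  estimator <- match.arg(estimator)
  if (is.null(reference_samples)) reference_samples <- colnames(em$values)
  vals <- em$values[, reference_samples, drop = FALSE]
  est <- if (estimator == "mean") rowMeans(vals) else apply(vals, 1L, median)
  sym <- annotation$symbol[match(rownames(vals), annotation$probeset_id)]
  ok <- !is.na(sym) & sym != ""
  split_idx <- split(which(ok), sym[ok])
  rows <- lapply(names(split_idx), function(s) {
    idx <- split_idx[[s]]
    win <- idx[which.max(est[idx])]  # first max wins: deterministic tie-break
    data.frame(symbol = s, probeset = rownames(vals)[win],
               expression = unname(est[win]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$symbol), , drop = FALSE]
}
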