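# Hierarchical clustering of panel expression and genome-wide rank
# correlation to a target probeset.
#
# Microarray panel clustering uses Spearman correlation distance with
# average linkage; RNA-Seq clustering uses Pearson distance with complete
# linkage on log2 values. Distance is 1 - correlation in both cases.

#' Correlation distance between two profiles
#'
#' @param a,b equal-length numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return `1 - cor(a, b, method)`, in \[0, 2\].
#' @export
correlation_distance <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  if (length(a) < 3L) stop("profiles need at least 3 points", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero-variance profile: correlation undefined", call. = FALSE)
  }
  1 - cor(a, b, method = method)
}

#' Agglomerative hierarchical clustering on correlation distance
#'
#' Clusters samples (columns) or genes (rows) of an expression matrix using
#' `1 - correlation` dissimilarity and average or complete linkage.
#'
#' @param x numeric matrix, or an `expression_matrix`.
#' @param axis cluster `"samples"` (columns, default) or `"genes"` (rows).
#' @param distance_method `"spearman"` (default) or `"pearson"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return object of class `cluster_tree`: a list with the underlying
#'   `hclust` object (`hc`), `labels`, `axis`, `distance_method`, `linkage`.
#' @export
hierarchical_cluster <- function(x, axis = c("samples", "genes"),
                                 distance_method = c("spearman", "pearson"),
                                 linkage = c("average", "complete")) {
  axis <- match.arg(axis)
  distance_method <- match.arg(distance_method)
  linkage <- match.arg(linkage)
  if (inherits(x, "expression_matrix")) x <- x$values
  items <- if (axis == "samples") x else t(x)  # items in columns
  if (ncol(items) < 2L) stop("need at least 2 items to cluster",
                             call. = FALSE)
  zero_var <- apply(items, 2L, sd) == 0
  if (any(zero_var)) {
    stop("zero-variance item(s): ",
         paste(colnames(items)[zero_var], collapse = ", "), call. = FALSE)
  }
  d <- as.dist(1 - cor(items, method = distance_method))
  hc <- hclust(d, method = linkage)
  structure(list(hc = hc, labels = hc$labels, axis = axis,
                 distance_method = distance_method, linkage = linkage),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d %s, %s linkage on 1 - %s correlation\n",
              length(x$labels), x$axis, x$linkage, x$distance_method))
  invisible(x)
}

#' Cut a cluster tree into k groups
#' @param tree a `cluster_tree`.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_tree <- function(tree, k = 2L) {
  stopifnot(inherits(tree, "cluster_tree"))
  cutree(tree$hc, k = k)
}

#' Export a cluster tree as Newick
#'
#' Merge heights become branch lengths via `ape::as.phylo`.
#'
#' @param tree a `cluster_tree`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  ape::write.tree(ape::as.phylo(tree$hc), file = path)
  invisible(path)
}

# Spearman rho and two-sided p for a set of profiles against one target.
# p via the t approximation for n >= 10, exact (cor.test) below.
spearman_rho_p <- function(profiles, target) {
  n <- length(target)
  rho <- suppressWarnings(
    as.vector(cor(t(profiles), target, method = "spearman")))
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p[abs(rho) == 1] <- 0
  } else {
    p <- vapply(seq_len(nrow(profiles)), function(i) {
      suppressWarnings(cor.test(profiles[i, ], target,
                                method = "spearman")$p.value)
    }, numeric(1))
  }
  list(rho = rho, p = pmin(p, 1))
}

#' Genome-wide rank correlation to a target probeset
#'
#' Computes Spearman's rho (and a two-sided p-value) of every probeset
#' against the target probeset's expression, excluding the target itself
#' (and any further probesets of the target's own symbol, when annotation is
#' given). Probesets are ranked by descending rho by default — the relevant
#' ordering when looking for positively co-regulated genes — or by ascending
#' p.
#'
#' @param em an `expression_matrix`.
#' @param target_probeset probeset id of the target.
#' @param annotation optional annotation; when given, all probesets sharing
#'   the target's symbol are excluded and gene-level ranks are available.
#' @param samples cohort sample ids (default: all).
#' @param rank_by `"rho"` (descending, default) or `"p"` (ascending).
#' @return object of class `correlation_ranking`: data.frame (`probeset`,
#'   `symbol`, `rho`, `p`, `rank`) ordered by rank.
#' @export
correlate_genomewide <- function(em, target_probeset, annotation = NULL,
                                 samples = NULL, rank_by = c("rho", "p")) {
  stopifnot(inherits(em, "expression_matrix"))
  rank_by <- match.arg(rank_by)
  if (is.null(samples)) samples <- colnames(em$values)
  if (!target_probeset %in% rownames(em$values)) {
    stop("target probeset not in matrix: ", target_probeset, call. = FALSE)
  }
  target <- em$values[target_probeset, samples]
  if (length(unique(target)) == 1L) {
    stop("constant target: correlation undefined", call. = FALSE)
  }
  exclude <- target_probeset
  sym <- NULL
  if (!is.null(annotation)) {
    sym <- annotation$symbol[match(rownames(em$values),
                                   annotation$probeset_id)]
    tgt_sym <- sym[match(target_probeset, rownames(em$values))]
    if (!is.na(tgt_sym) && tgt_sym != "") {
      exclude <- rownames(em$values)[!is.na(sym) & sym == tgt_sym]
    }
  }
  keep <- setdiff(rownames(em$values), exclude)
  profiles <- em$values[keep, samples, drop = FALSE]
  res <- spearman_rho_p(profiles, target)
  tab <- data.frame(probeset = keep,
                    symbol = if (is.null(sym)) NA_character_ else
                      sym[match(keep, rownames(em$values))],
                    rho = res$rho, p = res$p, stringsAsFactors = FALSE)
  ord <- if (rank_by == "rho") order(-tab$rho, tab$p, tab$probeset) else
    order(tab$p, -tab$rho, tab$probeset)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, class = c("correlation_ranking", "data.frame"),
            target_probeset = target_probeset, rank_by = rank_by)
}

#' How many panel genes fall in the top-K of a correlation ranking
#'
#' Multi-probeset genes are collapsed to their best-ranked probeset; the
#' top-K *genes* of the ranking are then intersected with the panel.
#'
#' @param ranking a `correlation_ranking` with gene symbols.
#' @param panel a [gene_panel()].
#' @param k size of the top list (e.g. 300).
#' @return list with `count` and `symbols` (panel genes inside the top-K).
#' @export
panel_in_top_k <- function(ranking, panel, k = 300L) {
  stopifnot(inherits(ranking, "correlation_ranking"))
  if (all(is.na(ranking$symbol))) {
    stop("ranking has no gene symbols; rerun with annotation", call. = FALSE)
  }
  annotated <- ranking[!is.na(ranking$symbol) & ranking$symbol != "", ,
                       drop = FALSE]
  genes <- annotated$symbol[!duplicated(annotated$symbol)]  # best rank first
  top <- genes[seq_len(min(k, length(genes)))]
  hits <- intersect(panel$symbol, top)
  list(count = length(hits), symbols = hits)
}
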