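# Pipeline orchestration: the discovery arm (variability screen ->
# stratification -> genome-wide DE between expressor extremes) and the
# validation arm (cohort DE, panel summary, outlier-fraction index,
# clustering of the four expressor groups). Each stage writes a plain TSV
# artifact headed by a provenance comment (config hash) so reruns are
# byte-identical and inspectable.

#' Assemble and validate a pipeline configuration
#'
#' @param target_symbol gene symbol of the stratifying target.
#' @param target_probeset probeset id quantifying the target; `NULL` picks
#'   the target symbol's highest-expression probeset.
#' @param housekeeping_symbols control genes for the variability screen.
#' @param pcall_min strict lower bound on the PRESENT-call fraction.
#' @param alpha significance level used throughout.
#' @param out_dir directory artifacts are written into (created when
#'   missing).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(target_symbol = "MUC5AC",
                            target_probeset = NULL,
                            housekeeping_symbols = c("ACTB", "GAPDH", "B2M",
                                                     "RPLP0", "PPIA"),
                            pcall_min = 0.8, alpha = 0.05,
                            out_dir = tempfile("exprstrata_run_")) {
  stopifnot(pcall_min >= 0, pcall_min <= 1, alpha > 0, alpha < 1)
  structure(list(target_symbol = target_symbol,
                 target_probeset = target_probeset,
                 housekeeping_symbols = housekeeping_symbols,
                 pcall_min = pcall_min, alpha = alpha, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

write_artifact <- function(df, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# exprstrata config=%s", config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the discovery arm on one cohort
#'
#' Variability screen of the target against housekeeping genes, per-chip
#' normalization, detection-call and annotation filtering, quartile
#' stratification by the target probeset, and genome-wide differential
#' expression HIGH vs LOW expressors (the target's own probesets excluded).
#' Writes `cv_report.tsv`, `strata.tsv`, `de_results.tsv` and `config.yaml`
#' into `config$out_dir`.
#'
#' @param em cohort `expression_matrix` with a detection-call layer.
#' @param annotation annotation data.frame.
#' @param config a [pipeline_config()].
#' @return list with `screen`, `strata`, `de`, `target_probeset`,
#'   `filtered` (the filtered normalized matrix) and `out_dir`, invisibly
#'   mirrored on disk.
#' @export
run_discovery <- function(em, annotation, config = pipeline_config()) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(config, "pipeline_config"))
  if (config$pcall_min > 0 && !has_calls(em)) {
    stop("discovery stage 'filter': detection-call layer required when ",
         "pcall_min > 0", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  norm <- normalize_per_chip(em)
  target_probeset <- config$target_probeset
  if (is.null(target_probeset)) {
    tgt_ps <- annotation$probeset_id[annotation$symbol ==
                                       config$target_symbol]
    tgt_ps <- intersect(tgt_ps, rownames(norm$values))
    if (length(tgt_ps) == 0L) {
      stop("discovery stage 'target': no probeset for symbol ",
           config$target_symbol, call. = FALSE)
    }
    target_probeset <- tgt_ps[which.max(rowMeans(
      norm$values[tgt_ps, , drop = FALSE]))]
  }
  screen <- variability_screen(norm, target_probeset,
                               config$housekeeping_symbols, annotation,
                               alpha = config$alpha)
  filtered <- apply_filters(norm, annotation,
                            filter_spec(min_pcall_fraction = config$pcall_min,
                                        require_annotation = TRUE))
  strata <- stratify_by_quartiles(norm, target_probeset)
  de <- differential_expression(filtered, annotation,
                                group_a = stratum_samples(strata, "HIGH"),
                                group_b = stratum_samples(strata, "LOW"),
                                alpha = config$alpha,
                                exclude_symbols = config$target_symbol)
  write_artifact(screen$cv_table,
                 file.path(config$out_dir, "cv_report.tsv"), config)
  write_artifact(as.data.frame(strata),
                 file.path(config$out_dir, "strata.tsv"), config)
  write_artifact(as.data.frame(de),
                 file.path(config$out_dir, "de_results.tsv"), config)
  writeLines(yaml::as.yaml(unclass(config)),
             file.path(config$out_dir, "config.yaml"))
  list(screen = screen, strata = strata, de = de,
       target_probeset = target_probeset, filtered = filtered,
       out_dir = config$out_dir)
}

#' Run the validation arm on a second cohort against a fixed panel
#'
#' Cohort-level differential expression (cohort B vs cohort A on the merged
#' filtered universe), panel summary, the panel outlier-fraction index
#' referenced to cohort A's LOW expressors with a Mann-Whitney group
#' comparison, and hierarchical clustering (Spearman / average linkage) of
#' the four expressor groups (A-high, A-low, B-high, B-low) on per-gene
#' normalized panel expression. Writes `panel_summary.tsv`, `index.tsv` and
#' `cluster.nwk`.
#'
#' @param em_a,em_b the two cohort `expression_matrix` objects (with calls).
#' @param annotation annotation data.frame.
#' @param panel a [gene_panel()].
#' @param config a [pipeline_config()].
#' @return list with `de`, `panel_summary`, `index_a`, `index_b`,
#'   `index_test`, `tree`, `strata_a`, `strata_b`, `out_dir`.
#' @export
run_validation <- function(em_a, em_b, annotation, panel,
                           config = pipeline_config()) {
  stopifnot(inherits(em_a, "expression_matrix"),
            inherits(em_b, "expression_matrix"),
            inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  norm_a <- normalize_per_chip(em_a)
  norm_b <- normalize_per_chip(em_b)
  merged <- expression_matrix(
    cbind(norm_a$values, norm_b$values),
    if (has_calls(em_a) && has_calls(em_b)) cbind(em_a$calls, em_b$calls)
    else NULL)
  if (config$pcall_min > 0) {
    if (!has_calls(merged)) {
      stop("validation stage 'filter': detection-call layer required when ",
           "pcall_min > 0", call. = FALSE)
    }
    merged <- apply_filters(merged, annotation,
                            filter_spec(min_pcall_fraction = config$pcall_min,
                                        require_annotation = TRUE))
  }
  samples_a <- colnames(em_a$values)
  samples_b <- colnames(em_b$values)
  de <- differential_expression(merged, annotation,
                                group_a = samples_b, group_b = samples_a,
                                alpha = config$alpha)
  summary <- panel_de_summary(de, panel)

  target_probeset <- config$target_probeset
  if (is.null(target_probeset)) {
    tgt_ps <- intersect(
      annotation$probeset_id[annotation$symbol == config$target_symbol],
      rownames(norm_a$values))
    target_probeset <- tgt_ps[which.max(rowMeans(
      norm_a$values[tgt_ps, , drop = FALSE]))]
  }
  strata_a <- stratify_by_quartiles(norm_a, target_probeset)
  strata_b <- stratify_by_quartiles(norm_b, target_probeset)

  range <- fit_normal_range(merged, panel,
                            reference_samples = stratum_samples(strata_a,
                                                                "LOW"),
                            annotation = annotation)
  index_a <- compute_index(merged, range, samples_a)
  index_b <- compute_index(merged, range, samples_b)
  index_test <- compare_index_groups(index_a$index_percent,
                                     index_b$index_percent)

  four_groups <- c(stratum_samples(strata_a, "HIGH"),
                   stratum_samples(strata_a, "LOW"),
                   stratum_samples(strata_b, "HIGH"),
                   stratum_samples(strata_b, "LOW"))
  panel_ps <- intersect(
    resolve_panel_probesets(merged, panel, annotation,
                            stratum_samples(strata_a, "LOW"))$probeset,
    rownames(merged$values))
  heat <- normalize_per_gene(subset_expression(merged, panel_ps,
                                               four_groups))
  tree <- hierarchical_cluster(heat, axis = "samples",
                               distance_method = "spearman",
                               linkage = "average")

  idx <- rbind(cbind(cohort = "A", as.data.frame(index_a)),
               cbind(cohort = "B", as.data.frame(index_b)))
  write_artifact(idx, file.path(config$out_dir, "index.tsv"), config)
  write_artifact(data.frame(up = summary$up, down = summary$down,
                            unchanged = summary$unchanged,
                            missing = length(summary$missing)),
                 file.path(config$out_dir, "panel_summary.tsv"), config)
  write_newick(tree, file.path(config$out_dir, "cluster.nwk"))
  list(de = de, panel_summary = summary, index_a = index_a,
       index_b = index_b, index_test = index_test, tree = tree,
       strata_a = strata_a, strata_b = strata_b, out_dir = config$out_dir)
}
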