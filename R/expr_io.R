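# Detection-call codes used throughout (Affymetrix MAS5 convention).
CALL_CODES <- c("P", "M", "A")

#' Construct a validated expression matrix
#'
#' Container for probeset-level intensities with an optional parallel layer of
#' MAS5-style detection calls. Rows are probesets, columns are samples.
#'
#' @param values numeric matrix of nonnegative finite intensities with unique,
#'   nonempty rownames (probeset ids) and colnames (sample ids).
#' @param calls optional character matrix of detection calls, same dimensions
#'   and dimnames as `values`, entries in `"P"`, `"M"`, `"A"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `calls` (`NULL` when no call layer is attached).
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("ps", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m)
#' dim(em$values)
#' @export
expression_matrix <- function(values, calls = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  ids <- rownames(values)
  smp <- colnames(values)
  if (nrow(values) > 0 && (is.null(ids) || anyNA(ids) || any(ids == ""))) {
    stop("all probesets must have nonempty ids (rownames)", call. = FALSE)
  }
  if (is.null(smp) || anyNA(smp) || any(smp == "")) {
    stop("all samples must have nonempty ids (colnames)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate probeset ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(smp)) {
    stop("duplicate sample ids: ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(values < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (!is.null(calls)) {
    if (!is.matrix(calls) || !identical(dim(calls), dim(values))) {
      stop("call layer dimensions do not match the value matrix", call. = FALSE)
    }
    if (!all(calls %in% CALL_CODES)) {
      stop("detection calls must be one of P, M, A", call. = FALSE)
    }
    dimnames(calls) <- dimnames(values)
  }
  structure(list(values = values, calls = calls), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probesets x %d samples (%s call layer)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$calls)) "no" else "with"))
  invisible(x)
}

#' Test whether an expression matrix carries a detection-call layer
#' @param em an `expression_matrix`.
#' @return `TRUE` when a call layer is attached.
#' @export
has_calls <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  !is.null(em$calls)
}

read_table_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, comment.char = "")
}

to_numeric_matrix <- function(tab, path) {
  ids <- tab[[1L]]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(body) <- "double")
  if (anyNA(body)) {
    stop("non-numeric intensity value(s) in ", path, call. = FALSE)
  }
  rownames(body) <- ids
  body
}

#' Read a tab-delimited expression matrix (optionally with detection calls)
#'
#' Expects a UTF-8, tab-delimited file: first column probeset ids, header row
#' of sample ids, '.' decimal separator, no quoting. An optional parallel call
#' file of identical layout holds single-letter P/M/A codes.
#'
#' @param path value-matrix file.
#' @param call_path optional call-matrix file.
#' @return An [expression_matrix()] with file row/column order preserved.
#' @export
read_expression <- function(path, call_path = NULL) {
  tab <- read_table_strict(path)
  values <- to_numeric_matrix(tab, path)
  calls <- NULL
  if (!is.null(call_path)) {
    ctab <- read_table_strict(call_path)
    calls <- as.matrix(ctab[, -1L, drop = FALSE])
    rownames(calls) <- ctab[[1L]]
    if (!identical(dim(calls), dim(values))) {
      stop(sprintf(
        "call file %s is %dx%d but value file %s is %dx%d",
        call_path, nrow(calls), ncol(calls), path, nrow(values), ncol(values)),
        call. = FALSE)
    }
    if (!identical(rownames(calls), rownames(values)) ||
        !identical(colnames(calls), colnames(values))) {
      stop("call file ids do not match value file ids", call. = FALSE)
    }
  }
  expression_matrix(values, calls)
}

#' Write an expression matrix (and optionally its call layer) to TSV
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(m))` reproduces `m` bit-exactly.
#'
#' @param em an `expression_matrix`.
#' @param path destination for the value matrix.
#' @param call_path optional destination for the call layer (required when the
#'   matrix has calls and they should be persisted).
#' @param digits significant digits for intensities.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, call_path = NULL, digits = 17L) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("probeset_id", colnames(em$values)), collapse = "\t"), con)
  if (nrow(em$values) > 0) {
    body <- apply(em$values, 2L, function(col) sprintf("%.*g", digits, col))
    if (!is.matrix(body)) body <- matrix(body, nrow = nrow(em$values))
    writeLines(paste(rownames(em$values),
                     apply(body, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  if (!is.null(call_path) && has_calls(em)) {
    ccon <- file(call_path, open = "wt", encoding = "UTF-8")
    on.exit(close(ccon), add = TRUE)
    writeLines(paste(c("probeset_id", colnames(em$values)), collapse = "\t"),
               ccon)
    if (nrow(em$values) > 0) {
      writeLines(paste(rownames(em$calls),
                       apply(em$calls, 1L, paste, collapse = "\t"),
                       sep = "\t"), ccon)
    }
  }
  invisible(path)
}

#' Read a probeset-to-gene annotation table
#'
#' Two-column TSV (`probeset_id`, `symbol`); an empty symbol marks an
#' unannotated probeset. Symbols are case-sensitive and used verbatim.
#'
#' @param path annotation file.
#' @return data.frame with columns `probeset_id`, `symbol`.
#' @export
read_annotation <- function(path) {
  tab <- read_table_strict(path)
  if (ncol(tab) < 2L) stop("annotation needs two columns", call. = FALSE)
  ann <- data.frame(probeset_id = tab[[1L]], symbol = tab[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$probeset_id)) {
    stop("duplicate probeset id(s) in annotation", call. = FALSE)
  }
  ann
}

#' Read a sample metadata table
#'
#' First column `sample_id`, second column `group`; further columns are kept
#' as free-form covariates.
#'
#' @param path sample table file.
#' @return data.frame with at least `sample_id` and `group`.
#' @export
read_samples <- function(path) {
  tab <- read_table_strict(path)
  if (ncol(tab) < 2L) stop("sample table needs id and group columns",
                           call. = FALSE)
  names(tab)[1:2] <- c("sample_id", "group")
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample id(s)", call. = FALSE)
  }
  tab
}

#' Construct a gene panel
#'
#' An ordered list of gene symbols, each optionally bound to a probeset id.
#'
#' @param symbols character vector of unique gene symbols.
#' @param probesets optional parallel character vector of probeset ids (`NA`
#'   where unbound).
#' @return data.frame of class `gene_panel` with columns `symbol`, `probeset`.
#' @export
gene_panel <- function(symbols, probesets = NULL) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) stop("panel must contain at least one symbol",
                                  call. = FALSE)
  if (anyNA(symbols) || any(symbols == "")) {
    stop("panel symbols must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("duplicate panel symbol(s): ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(probesets)) probesets <- rep(NA_character_, length(symbols))
  stopifnot(length(probesets) == length(symbols))
  structure(data.frame(symbol = symbols, probeset = as.character(probesets),
                       stringsAsFactors = FALSE),
            class = c("gene_panel", "data.frame"))
}

#' Read a gene panel from TSV
#'
#' One symbol per line with an optional second column binding a probeset id
#' (header row required). Duplicate symbols are rejected.
#'
#' @param path panel file.
#' @return a [gene_panel()].
#' @export
read_panel <- function(path) {
  tab <- read_table_strict(path)
  probesets <- if (ncol(tab) >= 2L && names(tab)[2L] == "probeset") {
    ifelse(tab[[2L]] == "", NA_character_, tab[[2L]])
  } else NULL
  gene_panel(tab[[1L]], probesets)
}

#' The 73-gene airway MUC5AC-associated core panel
#'
#' Loads the fixed core-gene panel shipped with the package: 73 genes found
#' coordinately up-regulated with MUC5AC in the small airway epithelium,
#' grouped into nine functional categories (mucus components, differentiation
#' transcription factors and pathways, mucin post-translational modification,
#' vesicle transport, ER stress, secretory granule, secretion regulators, ion
#' channels).
#'
#' @return a [gene_panel()] of 73 symbols, with the functional category kept
#'   in a `category` attribute-free extra column.
#' @export
core_gene_panel <- function() {
  path <- system.file("extdata", "muc5ac_core_genes.tsv",
                      package = "exprstrata", mustWork = TRUE)
  tab <- read_table_strict(path)
  panel <- gene_panel(tab$symbol)
  panel$category <- tab$category
  panel
}

#' Read a gene-level count table with exon-model lengths
#'
#' TSV with columns `gene_id`, `length` (exon-model length in nucleotides),
#' then one nonnegative integer count column per sample.
#'
#' @param path count file.
#' @return list with `counts` (integer matrix genes x samples) and `lengths`
#'   (named numeric vector, nucleotides).
#' @export
read_counts <- function(path) {
  tab <- read_table_strict(path)
  if (ncol(tab) < 3L || names(tab)[2L] != "length") {
    stop("count table needs columns gene_id, length, then samples",
         call. = FALSE)
  }
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicate gene id(s)", call. = FALSE)
  lengths <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("gene lengths must be positive numbers", call. = FALSE)
  }
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "double")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  rownames(counts) <- ids
  names(lengths) <- ids
  list(counts = counts, lengths = lengths)
}

#' Subset an expression matrix by probesets and/or samples
#'
#' @param em an `expression_matrix`.
#' @param probesets,samples character vectors of ids to keep (default: all),
#'   in the order given.
#' @return the subsetted `expression_matrix` (call layer carried along).
#' @export
subset_expression <- function(em, probesets = NULL, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(probesets)) probesets <- rownames(em$values)
  if (is.null(samples)) samples <- colnames(em$values)
  missing_p <- setdiff(probesets, rownames(em$values))
  missing_s <- setdiff(samples, colnames(em$values))
  if (length(missing_p)) stop("unknown probeset(s): ",
                              paste(missing_p, collapse = ", "), call. = FALSE)
  if (length(missing_s)) stop("unknown sample(s): ",
                              paste(missing_s, collapse = ", "), call. = FALSE)
  expression_matrix(
    em$values[probesets, samples, drop = FALSE],
    if (has_calls(em)) em$calls[probesets, samples, drop = FALSE] else NULL)
}
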