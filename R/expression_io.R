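#' Replicate-level expression set
#'
#' Container for a gene x sample TPM matrix together with its sample design
#' (stage label and replicate ordinal per sample) and the ordered list of
#' developmental stages. This is the entry point of the pipeline: all
#' downstream indices consume the stage-level matrix produced by
#' [filter_low_expression()] and [collapse_replicates_median()].
#'
#' @param abundance numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); TPM units, non-negative.
#' @param design data.frame with columns `sample`, `stage`, `replicate`;
#'   one row per sample.
#' @param stage_order character vector of stage labels in developmental
#'   order. Defaults to order of first appearance in `design`.
#'
#' @return An object of class `ReplicateExpressionSet`.
#' @export
replicate_expression_set <- function(abundance, design,
                                     stage_order = unique(design$stage)) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate gene id: ",
         rownames(abundance)[duplicated(rownames(abundance))][1L])
  if (!all(is.finite(abundance)))
    stop("abundance contains non-finite values")
  if (any(abundance < 0)) {
    bad <- which(abundance < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance for gene '%s' in sample '%s'",
                 rownames(abundance)[bad[1L]], colnames(abundance)[bad[2L]]))
  }
  design <- as.data.frame(design)
  req <- c("sample", "stage", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns sample, stage, replicate")
  missing_design <- setdiff(colnames(abundance), design$sample)
  if (length(missing_design))
    stop("sample '", missing_design[1L], "' absent from design")
  extra <- setdiff(design$sample, colnames(abundance))
  if (length(extra))
    stop("design sample '", extra[1L], "' absent from expression matrix")
  if (!all(design$stage %in% stage_order))
    stop("design stage '", setdiff(design$stage, stage_order)[1L],
         "' not in stage_order")
  if (!all(stage_order %in% design$stage))
    stop("stage '", setdiff(stage_order, design$stage)[1L],
         "' has no samples")
  design <- design[match(colnames(abundance), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(
    list(abundance = abundance, design = design,
         stage_order = as.character(stage_order)),
    class = "ReplicateExpressionSet")
}

#' @export
print.ReplicateExpressionSet <- function(x, ...) {
  cat("ReplicateExpressionSet:", nrow(x$abundance), "genes x",
      ncol(x$abundance), "samples;",
      length(x$stage_order), "stages (",
      paste(x$stage_order, collapse = ", "), ")\n")
  invisible(x)
}

#' Read an expression table and its sample design
#'
#' The expression file is TSV with the gene id in the first column and one
#' column per sample; the design file is TSV with columns `sample`, `stage`,
#' `replicate`. Stage order is taken from first appearance in the design file.
#'
#' @param path path to the TSV expression matrix.
#' @param design_path path to the TSV design table.
#' @return A [replicate_expression_set()].
#' @export
read_expression_table <- function(path, design_path) {
  expr <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2L) stop("expression table needs gene id plus >= 1 sample column")
  genes <- as.character(expr[[1L]])
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  replicate_expression_set(mat, design)
}

#' Remove lowly expressed genes
#'
#' Retains exactly the genes whose mean TPM across *all* samples is at least
#' `threshold` (default 2). Applied on untransformed TPM before replicate
#' collapsing.
#'
#' @param set a `ReplicateExpressionSet`.
#' @param threshold non-negative mean-TPM cutoff.
#' @return The filtered `ReplicateExpressionSet`.
#' @export
filter_low_expression <- function(set, threshold = 2) {
  stopifnot(inherits(set, "ReplicateExpressionSet"), threshold >= 0)
  keep <- rowMeans(set$abundance) >= threshold
  if (!any(keep))
    stop("zero genes survive the mean-TPM filter at threshold ", threshold)
  set$abundance <- set$abundance[keep, , drop = FALSE]
  set
}

#' Collapse replicates to a stage-level matrix by the median
#'
#' One column per stage; each cell is the median TPM across that stage's
#' replicates (midpoint convention for even replicate counts).
#'
#' @param set a `ReplicateExpressionSet`.
#' @return A `StageExpressionMatrix` with `transform_tag = "none"`.
#' @export
collapse_replicates_median <- function(set) {
  stopifnot(inherits(set, "ReplicateExpressionSet"))
  stages <- set$stage_order
  row_median <- function(X) {
    # vectorized for the common small replicate counts
    switch(as.character(ncol(X)),
           "1" = X[, 1L],
           "2" = (X[, 1L] + X[, 2L]) / 2,
           "3" = pmax(pmin(X[, 1L], X[, 2L]),
                      pmin(pmax(X[, 1L], X[, 2L]), X[, 3L])),
           apply(X, 1L, stats::median))
  }
  out <- vapply(stages, function(s) {
    cols <- set$design$sample[set$design$stage == s]
    row_median(set$abundance[, cols, drop = FALSE])
  }, numeric(nrow(set$abundance)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(set$abundance), stages))
  stage_expression_matrix(out, transform_tag = "none")
}

#' Stage-level expression matrix
#'
#' @param abundance numeric gene x stage matrix with dimnames.
#' @param transform_tag one of `"none"`, `"sqrt"`, `"log2p1"`, `"rank"`.
#' @return An object of class `StageExpressionMatrix`.
#' @export
stage_expression_matrix <- function(abundance, transform_tag = "none") {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  transform_tag <- match.arg(transform_tag, c("none", "sqrt", "log2p1", "rank"))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("stage matrix must carry gene and stage dimnames")
  if (!all(is.finite(abundance)) || any(abundance < 0))
    stop("stage matrix must be finite and non-negative")
  structure(list(abundance = abundance,
                 stages = colnames(abundance),
                 transform_tag = transform_tag),
            class = "StageExpressionMatrix")
}

#' @export
print.StageExpressionMatrix <- function(x, ...) {
  cat("StageExpressionMatrix:", nrow(x$abundance), "genes x",
      length(x$stages), "stages; transform =", x$transform_tag, "\n")
  invisible(x)
}

#' Transform a stage-level expression matrix
#'
#' Variance-stabilising transforms applied after filtering and replicate
#' collapsing: square root (the default in downstream analyses),
#' `log2(TPM + 1)`, or a within-stage rank transform (ascending, ties
#' averaged). A matrix can only be transformed once; the regularized-log
#' family is deliberately not offered (see the methods vignette) and
#' `log2p1` is its documented stand-in.
#'
#' @param matrix a `StageExpressionMatrix` with `transform_tag == "none"`.
#' @param method one of `"sqrt"`, `"log2p1"`, `"rank"`, `"none"`.
#' @return The transformed `StageExpressionMatrix`.
#' @export
transform_expression <- function(matrix, method = c("sqrt", "log2p1", "rank", "none")) {
  stopifnot(inherits(matrix, "StageExpressionMatrix"))
  if (identical(method[1L], "rlog"))
    stop("rlog is not supported; use log2p1 (see methods vignette)")
  method <- match.arg(method)
  if (matrix$transform_tag != "none")
    stop("matrix already carries transform '", matrix$transform_tag,
         "'; double transformation rejected")
  ab <- matrix$abundance
  ab <- switch(method,
    none   = ab,
    sqrt   = sqrt(ab),
    log2p1 = log2(ab + 1),
    rank   = apply(ab, 2L, rank, ties.method = "average"))
  dimnames(ab) <- dimnames(matrix$abundance)
  stage_expression_matrix(ab, transform_tag = method)
}

#' Write a stage-level matrix as TSV
#'
#' @param matrix a `StageExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stage_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "StageExpressionMatrix"))
  df <- data.frame(gene_id = rownames(matrix$abundance),
                   matrix$abundance, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
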