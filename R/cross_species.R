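#' Read an OrthoFinder-style orthogroup table
#'
#' TSV with an orthogroup-id column followed by one column per species,
#' each cell a comma-separated gene list. A gene may belong to at most
#' one orthogroup.
#'
#' @param path TSV path.
#' @return An `OrthogroupMap`: named list orthogroup -> (species -> gene
#'   character vector).
#' @export
read_orthogroups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("orthogroup table needs id plus >= 1 species column")
  species <- names(tab)[-1L]
  og <- lapply(seq_len(nrow(tab)), function(i) {
    members <- lapply(tab[i, -1L, drop = FALSE], function(cell) {
      g <- trimws(strsplit(as.character(cell), ",")[[1L]])
      g[nzchar(g)]
    })
    stats::setNames(members, species)
  })
  names(og) <- tab[[1L]]
  orthogroup_map(og)
}

#' Construct an orthogroup map
#'
#' @param groups named list: orthogroup id -> named list of per-species
#'   gene character vectors.
#' @return An object of class `OrthogroupMap`.
#' @export
orthogroup_map <- function(groups) {
  if (is.null(names(groups))) stop("orthogroups must be named")
  species <- unique(unlist(lapply(groups, names)))
  for (sp in species) {
    genes <- unlist(lapply(groups, function(g) g[[sp]]), use.names = FALSE)
    if (anyDuplicated(genes))
      stop("gene '", genes[duplicated(genes)][1L],
           "' of species '", sp, "' belongs to more than one orthogroup")
  }
  structure(list(groups = groups, species = species), class = "OrthogroupMap")
}

#' @export
print.OrthogroupMap <- function(x, ...) {
  cat("OrthogroupMap:", length(x$groups), "orthogroups across",
      length(x$species), "species (", paste(x$species, collapse = ", "), ")\n")
  invisible(x)
}

#' Aggregate a gene-level stage matrix to orthogroup level
#'
#' Orthogroup abundance is the plain sum of member-gene TPM per stage
#' (genes treated as isoforms of the orthogroup). Genes assigned to no
#' orthogroup are dropped; their count is attached as attribute
#' `n_unassigned`. Input must be untransformed TPM: aggregation precedes
#' any transform.
#'
#' @param matrix a `StageExpressionMatrix` with `transform_tag == "none"`.
#' @param map an `OrthogroupMap`.
#' @param species which species' gene ids the matrix rows use.
#' @return An orthogroup x stage `StageExpressionMatrix`.
#' @export
aggregate_orthogroups <- function(matrix, map, species) {
  stopifnot(inherits(matrix, "StageExpressionMatrix"),
            inherits(map, "OrthogroupMap"))
  if (matrix$transform_tag != "none")
    stop("aggregate on untransformed TPM; got transform '", matrix$transform_tag, "'")
  if (!species %in% map$species)
    stop("species '", species, "' absent from orthogroup map")
  gene2og <- unlist(lapply(names(map$groups), function(og) {
    g <- map$groups[[og]][[species]]
    stats::setNames(rep(og, length(g)), g)
  }))
  genes <- rownames(matrix$abundance)
  assigned <- genes[genes %in% names(gene2og)]
  if (!length(assigned)) stop("no genes of the matrix belong to any orthogroup")
  og_of <- gene2og[assigned]
  agg <- rowsum(matrix$abundance[assigned, , drop = FALSE], group = og_of)
  out <- stage_expression_matrix(agg, transform_tag = "none")
  attr(out, "n_unassigned") <- length(genes) - length(assigned)
  out
}

# Square root of the Jensen-Shannon divergence (log base 2) of two
# probability vectors; bounded in [0, 1], a metric on the simplex.
jsd_distance <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  js <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(0, min(1, js)))
}

#' Stage-by-stage transcriptome distance between two series
#'
#' For every stage pair of two orthogroup-level matrices (inner join on
#' the shared orthogroup universe), one of: Pearson or Spearman
#' correlation, Manhattan distance, or the Jensen-Shannon distance (the
#' square root of the log2 Jensen-Shannon divergence of the two columns
#' normalized to probability vectors, bounded in \[0, 1\]). Correlations
#' and Manhattan are computed on the matrices as given (typically after a
#' `log2p1` transform); JSD normalizes each column itself.
#'
#' @param matA,matB orthogroup-indexed `StageExpressionMatrix` objects.
#' @param metric one of `"pearson"`, `"spearman"`, `"manhattan"`, `"jsd"`.
#' @return A `StageDistanceMatrix`: rows = stages of `matA`, columns =
#'   stages of `matB`.
#' @export
transcriptome_distance <- function(matA, matB,
                                   metric = c("pearson", "spearman",
                                              "manhattan", "jsd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(matA, "StageExpressionMatrix"),
            inherits(matB, "StageExpressionMatrix"))
  shared <- intersect(rownames(matA$abundance), rownames(matB$abundance))
  if (length(shared) < 2L) stop("need >= 2 shared orthogroups")
  A <- matA$abundance[shared, , drop = FALSE]
  B <- matB$abundance[shared, , drop = FALSE]
  if (metric %in% c("pearson", "spearman")) {
    vals <- stats::cor(A, B, method = metric)
  } else {
    vals <- matrix(NA_real_, ncol(A), ncol(B),
                   dimnames = list(colnames(A), colnames(B)))
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      a <- A[, i]; b <- B[, j]
      if (metric == "manhattan") {
        vals[i, j] <- sum(abs(a - b))
      } else {
        if (sum(a) == 0) stop("zero-sum column at stage '", colnames(A)[i], "'")
        if (sum(b) == 0) stop("zero-sum column at stage '", colnames(B)[j], "'")
        vals[i, j] <- jsd_distance(a, b)
      }
    }
  }
  structure(list(values = vals, metric = metric,
                 n_orthogroups = length(shared)),
            class = "StageDistanceMatrix")
}

#' @export
print.StageDistanceMatrix <- function(x, ...) {
  cat("StageDistanceMatrix (", x$metric, "), ", x$n_orthogroups,
      " shared orthogroups\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Best-match stage correspondence
#'
#' For each row stage, the column stage minimizing the distance (or
#' maximizing the correlation, for correlation metrics). Ties go to the
#' earlier column stage and are flagged.
#'
#' @param dist a `StageDistanceMatrix`.
#' @return data.frame with columns `stage_a`, `stage_b`, `value`, `tie`.
#' @export
match_stages <- function(dist) {
  stopifnot(inherits(dist, "StageDistanceMatrix"))
  V <- dist$values
  similarity <- dist$metric %in% c("pearson", "spearman")
  pick <- apply(V, 1L, function(row) {
    best <- if (similarity) max(row) else min(row)
    hits <- which(row == best)
    c(idx = unname(hits[1L]), tie = as.integer(length(hits) > 1L),
      value = unname(best))
  })
  data.frame(stage_a = rownames(V),
             stage_b = colnames(V)[pick["idx", ]],
             value = pick["value", ],
             tie = as.logical(pick["tie", ]),
             row.names = NULL)
}
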