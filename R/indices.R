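# Align a stage matrix and a stratum map on their shared gene set.
# Genes carrying only one kind of data are dropped (the indices are
# defined on genes with both expression and a stratum); the dropped
# counts are returned so callers can log them.
align_matrix_strata <- function(matrix, strata) {
  stopifnot(inherits(matrix, "StageExpressionMatrix"),
            inherits(strata, "StratumMap"))
  shared <- intersect(rownames(matrix$abundance), names(strata$values))
  if (!length(shared))
    stop("expression matrix and stratum map share no genes")
  E <- matrix$abundance[shared, , drop = FALSE]
  tot <- colSums(E)
  if (any(tot == 0))
    stop("stage '", matrix$stages[tot == 0][1L], "' has zero total abundance")
  list(E = E,
       s = as.numeric(strata$values[shared]),
       genes = shared,
       dropped_expr = nrow(matrix$abundance) - length(shared),
       dropped_strata = length(strata$values) - length(shared))
}

# Weighted-mean profile: value_s = sum_i s_i e_is / sum_i e_is.
# Shared by the observed index, the bootstrap and the permutation null.
weighted_profile <- function(E, s) {
  as.vector(crossprod(s, E)) / colSums(E)
}

#' Expression-weighted evolutionary index profile (TAI / TSI / TDI)
#'
#' The core statistic: for each stage s, the mean gene stratum weighted by
#' expression, `sum_i(stratum_i * e_is) / sum_i(e_is)`. With phylostrata
#' this is the transcriptome age index (TAI; lower = evolutionarily older
#' transcriptome), with tau-strata the transcriptome specificity index
#' (TSI) and with dN/dS deciles the transcriptome divergence index (TDI).
#' One engine serves all three: only the `StratumMap` changes.
#'
#' Genes present in only one input are dropped (counts kept in the result);
#' a stage with zero total abundance is an error.
#'
#' @param matrix a `StageExpressionMatrix` (typically sqrt-transformed TPM).
#' @param strata a `StratumMap`.
#' @param n_boot bootstrap replicates for the per-stage standard deviation;
#'   0 skips the bootstrap.
#' @param seed RNG seed for the bootstrap.
#' @return An `IndexProfile`: kind, stages, `value` and `sd` (named by
#'   stage), bootstrap settings and dropped-gene counts.
#' @export
weighted_index <- function(matrix, strata, n_boot = 0L, seed = NULL) {
  al <- align_matrix_strata(matrix, strata)
  value <- stats::setNames(weighted_profile(al$E, al$s), matrix$stages)
  kind <- switch(strata$kind, phylostratum = "TAI", tau_stratum = "TSI",
                 divergence_stratum = "TDI")
  sd <- stats::setNames(rep(NA_real_, length(value)), matrix$stages)
  if (n_boot > 0L)
    sd <- stats::setNames(bootstrap_sd(matrix, strata, n_boot = n_boot, seed = seed),
                          matrix$stages)
  structure(list(kind = kind, stages = matrix$stages, value = value, sd = sd,
                 n_boot = as.integer(n_boot), seed = seed,
                 transform_tag = matrix$transform_tag,
                 n_genes_used = length(al$genes),
                 n_dropped_expression = al$dropped_expr,
                 n_dropped_strata = al$dropped_strata),
            class = "IndexProfile")
}

#' @export
print.IndexProfile <- function(x, ...) {
  cat(x$kind, "profile (", x$n_genes_used, "genes, transform =",
      x$transform_tag, ")\n")
  print(round(rbind(value = x$value, sd = x$sd), 4))
  invisible(x)
}

#' Bootstrap standard deviation of an index profile
#'
#' Classical gene bootstrap: genes are resampled with replacement `n_boot`
#' times, the full weighted-mean profile is recomputed per resample, and
#' the per-stage standard deviation of the resampled profiles is returned.
#' Resampling is realised as multinomial per-gene counts, which is the
#' identical distribution computed by matrix products, chunked to bound
#' memory.
#'
#' @inheritParams weighted_index
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param chunk resamples per matrix-product chunk.
#' @return Numeric vector of per-stage standard deviations.
#' @export
bootstrap_sd <- function(matrix, strata, n_boot = 50000L, seed = NULL,
                         chunk = 1000L) {
  stopifnot(n_boot >= 1L)
  al <- align_matrix_strata(matrix, strata)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(al$E)
  if (n == 1L || length(unique(al$s)) == 1L)
    return(rep(0, ncol(al$E)))
  sums <- matrix(0, 2L, ncol(al$E))  # running sum and sum of squares
  done <- 0L
  while (done < n_boot) {
    m <- min(chunk, n_boot - done)
    C <- stats::rmultinom(m, size = n, prob = rep(1 / n, n))  # n x m counts
    num <- crossprod(C * al$s, al$E)   # m x stages
    den <- crossprod(C, al$E)
    vals <- num / den
    sums[1L, ] <- sums[1L, ] + colSums(vals)
    sums[2L, ] <- sums[2L, ] + colSums(vals^2)
    done <- done + m
  }
  mu <- sums[1L, ] / n_boot
  v <- pmax(0, (sums[2L, ] - n_boot * mu^2) / (n_boot - 1L))
  sqrt(v)
}

#' Per-gene contributions to the index (pTAI matrix)
#'
#' `entry(i, s) = stratum_i * e_is / sum_j(e_js)`: the additive share of
#' gene i in the stage-s index. Column sums reproduce the index profile
#' exactly.
#'
#' @inheritParams weighted_index
#' @return A gene x stage numeric matrix of class `ContributionMatrix`,
#'   with the matching `IndexProfile` values in attribute `profile`.
#' @export
contribution_matrix <- function(matrix, strata) {
  al <- align_matrix_strata(matrix, strata)
  W <- sweep(al$E, 2L, colSums(al$E), "/") * al$s
  dimnames(W) <- list(al$genes, matrix$stages)
  structure(W, class = c("ContributionMatrix", class(W)),
            profile = stats::setNames(weighted_profile(al$E, al$s), matrix$stages))
}

#' Top contributing genes at one stage, elbow-selected
#'
#' Genes are sorted by descending contribution at the stage; the cut point
#' is the index of maximum perpendicular distance between the sorted curve
#' and the chord joining its first and last points (the elbow). When the
#' curve has no curvature (all points on the chord, to numerical
#' tolerance), the elbow is undefined and the cut falls back to `cap`.
#' The maximum-distance point is the first gene of the background tail;
#' the selected head is everything strictly above it, capped at `cap`.
#'
#' @param contrib a `ContributionMatrix`.
#' @param stage stage label.
#' @param cap maximum number of genes returned (default 500).
#' @return Character vector of gene ids, ordered by descending contribution.
#' @export
top_contributors_elbow <- function(contrib, stage, cap = 500L) {
  stopifnot(inherits(contrib, "ContributionMatrix"), cap >= 1L)
  if (!stage %in% colnames(contrib)) stop("unknown stage '", stage, "'")
  v <- sort(contrib[, stage], decreasing = TRUE)
  m <- length(v)
  if (m <= 2L) return(names(v)[seq_len(min(m, cap))])
  x <- seq_len(m)
  # perpendicular distance of each point to the first-last chord
  dx <- m - 1; dy <- v[m] - v[1L]
  dist <- abs(dy * (x - 1L) - dx * (v - v[1L])) / sqrt(dx^2 + dy^2)
  if (max(dist) < sqrt(.Machine$double.eps) * max(1, abs(v[1L])))
    cut <- m  # linear decay: no elbow, fall back to the cap
  else
    cut <- max(1L, which.max(dist) - 1L)  # head ends just before the tail's first point
  names(v)[seq_len(min(cut, cap, m))]
}

#' Intersect driver-gene sets across stages
#'
#' The genes selected at every stage in `sets`, ordered by their mean rank
#' across the input lists (each list is assumed ordered by descending
#' contribution). Disjoint sets yield an empty vector, not an error.
#'
#' @param sets list of character vectors of gene ids.
#' @return Character vector of shared genes.
#' @export
intersect_drivers <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  shared <- Reduce(intersect, sets)
  if (!length(shared)) return(character(0))
  mean_rank <- rowMeans(vapply(sets, function(s) match(shared, s),
                               numeric(length(shared))))
  shared[order(mean_rank, shared)]
}
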