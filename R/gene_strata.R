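#' Per-gene integer stratum map
#'
#' A shared container for the three stratifications the weighted indices
#' consume: phylostrata (gene age ranks, 1 = evolutionarily oldest),
#' tau-strata (expression-specificity deciles) and divergence-strata
#' (dN/dS deciles, 1 = strongest purifying selection).
#'
#' @param values named integer vector, gene -> stratum in 1..K.
#' @param kind one of `"phylostratum"`, `"tau_stratum"`, `"divergence_stratum"`.
#' @param K number of strata; defaults to `max(values)`.
#' @return An object of class `StratumMap`.
#' @export
stratum_map <- function(values,
                        kind = c("phylostratum", "tau_stratum", "divergence_stratum"),
                        K = max(values)) {
  kind <- match.arg(kind)
  if (is.null(names(values))) stop("stratum values must be named by gene id")
  values <- stats::setNames(as.integer(round(values)), names(values))
  if (any(!is.finite(values)) || any(values < 1L) || any(values > K))
    stop("all strata must be integers in [1, ", K, "]")
  structure(list(kind = kind, values = values, K = as.integer(K)),
            class = "StratumMap")
}

#' @export
print.StratumMap <- function(x, ...) {
  cat("StratumMap (", x$kind, "): ", length(x$values), " genes, K = ",
      x$K, "\n", sep = "")
  invisible(x)
}

# Strip a trailing isoform suffix (".t1", ".1", "-RA", "_i2") from ids.
collapse_isoform_ids <- function(ids, isoform_pattern) {
  sub(isoform_pattern, "", ids)
}

#' Read a gene-age (phylostratum) table
#'
#' Reads a GenEra-style TSV (`gene  phylostratum  [rank_name]  [flag]`).
#' Isoform ids are collapsed to gene ids by stripping a suffix, and each
#' gene takes the *minimum* phylostratum among its isoforms — the oldest
#' isoform rule, since PS 1 is the evolutionarily oldest rank. Rows whose
#' flag column marks potential contamination are dropped.
#'
#' @param path TSV path.
#' @param max_ps largest admissible phylostratum.
#' @param isoform_pattern regex removed from ids to collapse isoforms to
#'   genes (default strips suffixes like `.t1`, `.m2`, `-RA`, `_i1`).
#' @param contamination_values flag-column values marking rows to drop.
#' @return A `StratumMap` of kind `"phylostratum"`.
#' @export
read_phylostratum_map <- function(path, max_ps,
                                  isoform_pattern = "([._-][tmi]?(RA|RB|[0-9]+))$",
                                  contamination_values = c("contamination", "putative_contamination")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("phylostratum table needs id and phylostratum columns")
  ids <- as.character(tab[[1L]])
  ps <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(ps))) stop("non-numeric phylostratum in row ", which(is.na(ps))[1L])
  bad <- ps < 1 | ps > max_ps | ps != round(ps)
  if (any(bad))
    stop("phylostratum ", ps[bad][1L], " for '", ids[bad][1L],
         "' outside [1, ", max_ps, "]")
  if (ncol(tab) >= 4L) {
    flagged <- tab[[ncol(tab)]] %in% contamination_values
    ids <- ids[!flagged]; ps <- ps[!flagged]
  }
  genes <- collapse_isoform_ids(ids, isoform_pattern)
  values <- tapply(as.integer(ps), genes, min)
  stratum_map(stats::setNames(as.integer(values), names(values)),
              kind = "phylostratum", K = as.integer(max_ps))
}

#' Expression specificity (tau) per gene
#'
#' For each gene, its stage vector is normalized by its own maximum and
#' tau = sum(1 - normalized) / (N - 1), with N the number of stages. Tau
#' is 0 for a uniformly expressed gene and 1 for single-stage expression.
#' Genes with all-zero expression have undefined tau: they are excluded
#' from `values` and listed in `undefined_genes` rather than silently set
#' to zero.
#'
#' @param matrix a `StageExpressionMatrix` with at least 2 stages.
#' @return A list of class `TauVector` with `values` (named numeric in
#'   \[0, 1\]), `n_stages` and `undefined_genes`.
#' @export
compute_tau <- function(matrix) {
  stopifnot(inherits(matrix, "StageExpressionMatrix"))
  ab <- matrix$abundance
  n_stages <- ncol(ab)
  if (n_stages < 2L) stop("tau needs >= 2 stages")
  mx <- apply(ab, 1L, max)
  defined <- mx > 0
  tau <- rowSums(1 - ab[defined, , drop = FALSE] / mx[defined]) / (n_stages - 1L)
  structure(list(values = tau, n_stages = n_stages,
                 undefined_genes = rownames(ab)[!defined]),
            class = "TauVector")
}

#' @export
print.TauVector <- function(x, ...) {
  cat("TauVector:", length(x$values), "genes over", x$n_stages, "stages;",
      length(x$undefined_genes), "undefined (all-zero)\n")
  invisible(x)
}

#' Stratify per-gene values into ascending deciles
#'
#' Rank-based deciles: gene i's stratum is `ceiling(10 * rank_i / n)` with
#' ranks taken in ascending value order, ties broken by gene-id order so
#' bins stay near-equal. The lowest ~10% of values land in stratum 1, the
#' top ~10% in stratum 10. If fewer than 10 distinct values exist, K is
#' reduced to the number of occupied strata. A warning reports a heavy tie
#' mass at the minimum (e.g. many exact-zero dN/dS values).
#'
#' @param values named numeric vector (gene -> value), finite.
#' @param kind stratum kind for the resulting map.
#' @return A `StratumMap`.
#' @export
stratify_deciles <- function(values, kind = c("tau_stratum", "divergence_stratum",
                                              "phylostratum")) {
  kind <- match.arg(kind)
  if (is.null(names(values))) stop("values must be named by gene id")
  if (any(!is.finite(values))) stop("non-finite value for gene '",
                                    names(values)[!is.finite(values)][1L], "'")
  n <- length(values)
  if (length(unique(values)) == 1L)
    return(stratum_map(stats::setNames(rep(1L, n), names(values)), kind = kind, K = 1L))
  tie_min <- mean(values == min(values))
  if (tie_min > 0.1)
    warning(sprintf("%.0f%% of values tied at the minimum; lowest strata are degenerate",
                    100 * tie_min))
  ord <- order(values, names(values))  # ties split by stable gene-id order
  r <- integer(n); r[ord] <- seq_len(n)
  strata <- as.integer(ceiling(10 * r / n))
  occupied <- sort(unique(strata))
  strata <- match(strata, occupied)  # compact to 1..K if bins emptied
  stratum_map(stats::setNames(as.integer(strata), names(values)),
              kind = kind, K = length(occupied))
}

#' Read a per-gene dN/dS table
#'
#' TSV with columns `gene` (or isoform id) and `dnds`. Isoforms are
#' collapsed by the same oldest-isoform rule used for gene ages: the
#' minimum ratio among a gene's isoforms is kept, mirroring the
#' lowest-stratum convention. The fraction of ratios below 1 (the share of
#' the gene set under detectable purifying selection) is attached as
#' attribute `frac_below_1` and reported via message.
#'
#' @param path TSV path.
#' @param isoform_pattern as in [read_phylostratum_map()].
#' @return Named numeric vector gene -> dN/dS, with attribute `frac_below_1`.
#' @export
read_dnds_table <- function(path, isoform_pattern = "([._-][tmi]?(RA|RB|[0-9]+))$") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("dN/dS table needs id and dnds columns")
  ids <- as.character(tab[[1L]])
  v <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(v))) stop("non-numeric dN/dS in row ", which(is.na(v))[1L])
  if (any(v < 0)) stop("negative dN/dS for '", ids[v < 0][1L], "'")
  genes <- collapse_isoform_ids(ids, isoform_pattern)
  out <- tapply(v, genes, min)
  out <- stats::setNames(as.numeric(out), names(out))
  attr(out, "frac_below_1") <- mean(out < 1)
  message(sprintf("dN/dS: %d genes, %.1f%% of ratios below 1",
                  length(out), 100 * attr(out, "frac_below_1")))
  out
}
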