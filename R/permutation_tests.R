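#' Early/mid/late stage modules for the hourglass test
#'
#' Stage-module membership is declared, never inferred: it encodes the
#' biological staging of the series at hand (e.g. early embryo stages vs
#' the presumptive phylotypic waist vs late stages).
#'
#' @param early,mid,late character vectors of stage labels; pairwise
#'   disjoint and each nonempty.
#' @return An object of class `StageModules`.
#' @export
stage_modules <- function(early, mid, late) {
  mods <- list(early = as.character(early), mid = as.character(mid),
               late = as.character(late))
  if (any(lengths(mods) == 0L)) stop("each stage module must be nonempty")
  all_stages <- unlist(mods, use.names = FALSE)
  if (anyDuplicated(all_stages))
    stop("stage '", all_stages[duplicated(all_stages)][1L],
         "' appears in more than one module")
  structure(mods, class = "StageModules")
}

#' Null index profiles under permuted gene strata
#'
#' Each permutation shuffles the stratum-to-gene assignment while the
#' expression matrix stays fixed, and the full weighted-mean profile is
#' recomputed. This is the shared null for all three shape tests: under
#' it, any profile shape arises only from which strata happen to sit on
#' which expression patterns.
#'
#' @inheritParams weighted_index
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param chunk permutations per matrix-product chunk.
#' @return An `n_perm` x n_stages matrix of null profiles (columns named
#'   by stage), with the observed profile in attribute `observed`.
#' @export
permute_null_profiles <- function(matrix, strata, n_perm, seed = NULL,
                                  chunk = 1000L) {
  stopifnot(n_perm >= 1L)
  al <- align_matrix_strata(matrix, strata)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(al$E)
  tot <- colSums(al$E)
  out <- matrix(NA_real_, n_perm, ncol(al$E),
                dimnames = list(NULL, matrix$stages))
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    P <- vapply(seq_len(m), function(i) al$s[sample.int(n)], numeric(n))
    out[done + seq_len(m), ] <- sweep(crossprod(P, al$E), 2L, tot, "/")
    done <- done + m
  }
  attr(out, "observed") <- stats::setNames(weighted_profile(al$E, al$s),
                                           matrix$stages)
  # a single occupied stratum makes every shape statistic identically zero;
  # flag it so the tests can report the degenerate case exactly
  attr(out, "constant_strata") <- length(unique(al$s)) == 1L
  out
}

# row-wise helpers over the null-profile matrix (one row per permutation)
row_means_cols <- function(M, cols) {
  if (length(cols) == 1L) M[, cols] else rowMeans(M[, cols, drop = FALSE])
}

row_vars <- function(M) {
  mu <- rowMeans(M)
  rowSums((M - mu)^2) / (ncol(M) - 1L)
}

perm_result <- function(test, observed, null_stats, n_perm, seed,
                        alternative = NULL, tail = c("upper", "lower"),
                        fit = c("gamma", "normal")) {
  tail <- match.arg(tail); fit <- match.arg(fit)
  degenerate <- isTRUE(stats::sd(null_stats) == 0 && all(null_stats == observed))
  if (tail == "upper")
    p_emp <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  else
    p_emp <- (1 + sum(null_stats <= observed)) / (n_perm + 1)
  if (degenerate) p_emp <- 1
  p_fit <- NA_real_
  m <- mean(null_stats); v <- stats::var(null_stats)
  if (!degenerate && isTRUE(v > 0)) {
    if (fit == "gamma" && m > 0) {
      # moment-matched gamma on the null statistics, upper tail
      p_fit <- stats::pgamma(observed, shape = m^2 / v, rate = m / v,
                             lower.tail = FALSE)
    } else {
      p_fit <- stats::pnorm(observed, mean = m, sd = sqrt(v),
                            lower.tail = (tail == "lower"))
    }
  }
  structure(list(test = test, observed = observed,
                 p_empirical = p_emp, p_fitted = p_fit,
                 null_mean = m, null_sd = stats::sd(null_stats),
                 n_perm = as.integer(n_perm), seed = seed,
                 alternative = alternative, degenerate = degenerate),
            class = "PermutationTestResult")
}

#' @export
print.PermutationTestResult <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.5g, p(empirical) = %.4g, p(fitted) = %.4g\n",
              x$test, x$observed, x$p_empirical, x$p_fitted))
  cat(sprintf("  null: mean %.5g, sd %.5g over %d permutations%s\n",
              x$null_mean, x$null_sd, x$n_perm,
              if (isTRUE(x$degenerate)) " [degenerate null]" else ""))
  invisible(x)
}

#' Flat-line permutation test
#'
#' Tests whether an index profile deviates from constancy across stages.
#' The statistic is the variance of the stage profile; the null is the
#' permuted-strata ensemble. The empirical p uses the add-one rule
#' `(1 + #[null >= obs]) / (n_perm + 1)` and is authoritative; a
#' moment-fitted gamma upper-tail p is reported as advisory. A degenerate
#' null (all genes in one stratum) yields p = 1 with a flag.
#'
#' @inheritParams permute_null_profiles
#' @return A `PermutationTestResult`.
#' @export
flat_line_test <- function(matrix, strata, n_perm = 50000L, seed = NULL) {
  if (length(matrix$stages) < 2L) stop("flat-line test needs >= 2 stages")
  nulls <- permute_null_profiles(matrix, strata, n_perm, seed)
  if (isTRUE(attr(nulls, "constant_strata")))
    return(perm_result("flat_line", 0, rep(0, n_perm), n_perm, seed,
                       tail = "upper", fit = "gamma"))
  obs <- stats::var(attr(nulls, "observed"))
  null_var <- row_vars(nulls)
  perm_result("flat_line", obs, null_var, n_perm, seed,
              tail = "upper", fit = "gamma")
}

#' Reductive hourglass permutation test
#'
#' One-sided test for a high-low-high profile across declared
#' early/mid/late modules. The statistic is
#' `D = min(mean(early) - mean(mid), mean(late) - mean(mid))`: both drops
#' into the waist must be large for D to be large. p is the one-sided
#' permuted-strata tail probability of D at least as large as observed.
#'
#' @inheritParams permute_null_profiles
#' @param modules a [stage_modules()] declaration.
#' @return A `PermutationTestResult`.
#' @export
reductive_hourglass_test <- function(matrix, strata, modules,
                                     n_perm = 50000L, seed = NULL) {
  stopifnot(inherits(modules, "StageModules"))
  missing_stage <- setdiff(unlist(modules), matrix$stages)
  if (length(missing_stage))
    stop("module stage '", missing_stage[1L], "' absent from matrix")
  nulls <- permute_null_profiles(matrix, strata, n_perm, seed)
  if (isTRUE(attr(nulls, "constant_strata")))
    return(perm_result("reductive_hourglass", 0, rep(0, n_perm), n_perm, seed,
                       tail = "upper", fit = "normal"))
  obs_prof <- attr(nulls, "observed")
  obs <- min(mean(obs_prof[modules$early]) - mean(obs_prof[modules$mid]),
             mean(obs_prof[modules$late]) - mean(obs_prof[modules$mid]))
  null_mid <- row_means_cols(nulls, modules$mid)
  null_D <- pmin(row_means_cols(nulls, modules$early) - null_mid,
                 row_means_cols(nulls, modules$late) - null_mid)
  perm_result("reductive_hourglass", obs, null_D, n_perm, seed,
              tail = "upper", fit = "normal")
}

#' One-sided pairwise index test between two stage groups
#'
#' The statistic is `mean(index over group A) - mean(index over group B)`;
#' p is the one-sided permuted-strata tail per `alternative`
#' (`"greater"`: A higher than B).
#'
#' @param group_a,group_b disjoint nonempty sets of stage labels.
#' @inheritParams permute_null_profiles
#' @param alternative `"greater"` or `"less"`.
#' @return A `PermutationTestResult`.
#' @export
pairwise_test <- function(group_a, group_b, matrix, strata,
                          alternative = c("greater", "less"),
                          n_perm = 50000L, seed = NULL) {
  alternative <- match.arg(alternative)
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b)) stop("both stage groups must be nonempty")
  if (length(intersect(group_a, group_b)))
    stop("stage groups overlap: '", intersect(group_a, group_b)[1L], "'")
  missing_stage <- setdiff(c(group_a, group_b), matrix$stages)
  if (length(missing_stage))
    stop("group stage '", missing_stage[1L], "' absent from matrix")
  nulls <- permute_null_profiles(matrix, strata, n_perm, seed)
  if (isTRUE(attr(nulls, "constant_strata")))
    return(perm_result("pairwise", 0, rep(0, n_perm), n_perm, seed,
                       alternative = alternative,
                       tail = if (alternative == "greater") "upper" else "lower",
                       fit = "normal"))
  obs_prof <- attr(nulls, "observed")
  obs <- mean(obs_prof[group_a]) - mean(obs_prof[group_b])
  null_d <- row_means_cols(nulls, group_a) - row_means_cols(nulls, group_b)
  perm_result("pairwise", obs, null_d, n_perm, seed,
              alternative = alternative,
              tail = if (alternative == "greater") "upper" else "lower",
              fit = "normal")
}
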