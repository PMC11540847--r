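#' Configuration for the synthetic developmental-transcriptome generator
#'
#' The generator emulates the data structure of a stage-resolved bulk
#' RNA-seq study of an organism with age-structured genes: a TPM matrix
#' with replicated stages, a skewed (old-heavy) phylostratum assignment,
#' per-gene dN/dS ratios dominated by purifying selection, and a
#' two-species orthogroup map. Shape profiles:
#'
#' * `hourglass` — genes in young phylostrata (`>= young_cutoff`) have
#'   their expression at mid-role stages multiplied by
#'   `repression_factor`, producing a transcriptomic waist by repression
#'   of young genes (not by boosting old ones).
#' * `early_conservation` — young-gene expression ramps linearly from
#'   `repression_factor` at the first stage to 1 at the last, giving a
#'   monotone increasing age profile.
#' * `flat` — ages and expression are independent (the null).
#' * `unicellular_high` — young genes repressed at all multicellular-role
#'   stages, so unicellular stages carry the young transcriptome.
#'
#' Defaults encode one fixed set of study conditions: 8,000 genes, five
#' stages with early/early/mid/mid/late roles, three replicates, eight
#' phylostrata with ~60% of genes in PS 1-3, young cutoff at PS 7,
#' repression factor 0.2, log-normal replicate noise (sd 0.25 on the log
#' scale) and per-gene per-stage profile variation (sd 0.5).
#'
#' @param n_genes,n_stages,n_replicates problem sizes.
#' @param n_phylostrata number of age ranks (PS 1 = oldest).
#' @param age_distribution probability vector over phylostrata; must sum
#'   to 1. Default is old-heavy.
#' @param profile one of `"hourglass"`, `"early_conservation"`, `"flat"`,
#'   `"unicellular_high"`.
#' @param repression_factor multiplicative down-scaling in (0, 1] applied
#'   to young-strata expression at the profile's designated stages.
#' @param young_cutoff phylostratum at or above which a gene counts as
#'   young.
#' @param noise_sd log-scale standard deviation of replicate noise.
#' @param stage_effect_sd log-scale sd of per-gene per-stage variation
#'   (independent of age), giving genes realistic non-flat profiles.
#' @param stage_roles character vector of length `n_stages` with values
#'   in early/mid/late (or unicellular/multicellular, optionally gamete).
#'   Defaults depend on `profile`.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline TPM.
#' @param dnds_frac_above_1 fraction of genes with dN/dS > 1.
#' @param divergence_boost expression multiplier at gamete-role stages
#'   for genes in the weakest-purifying-selection tail (top 20% dN/dS).
#' @param in_paralogue_rate probability an orthogroup carries an extra
#'   in-paralogue in the second species.
#' @param orthogroup_coverage fraction of genes assigned to any orthogroup.
#' @param seed RNG seed.
#' @return A validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes = 8000L, n_stages = 5L, n_replicates = 3L,
                             n_phylostrata = 8L,
                             age_distribution = NULL,
                             profile = c("hourglass", "early_conservation",
                                         "flat", "unicellular_high"),
                             repression_factor = 0.2,
                             young_cutoff = 7L,
                             noise_sd = 0.25,
                             stage_effect_sd = 0.5,
                             stage_roles = NULL,
                             baseline_meanlog = 3,
                             baseline_sdlog = 1.5,
                             dnds_frac_above_1 = 0.005,
                             divergence_boost = 3,
                             in_paralogue_rate = 0.1,
                             orthogroup_coverage = 0.9,
                             seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(age_distribution)) {
    # old-heavy, ~60% in PS 1-3, thinning toward young strata
    w <- c(0.30, 0.17, 0.13, 0.10, 0.08, 0.07, 0.08, 0.07)
    age_distribution <- if (n_phylostrata == 8L) w else {
      v <- 0.85^(seq_len(n_phylostrata) - 1L); v / sum(v)
    }
  }
  if (length(age_distribution) != n_phylostrata ||
      abs(sum(age_distribution) - 1) > 1e-8)
    stop("age_distribution must have length n_phylostrata and sum to 1")
  if (young_cutoff > n_phylostrata)
    stop("young_cutoff (", young_cutoff, ") exceeds n_phylostrata (",
         n_phylostrata, ")")
  if (repression_factor <= 0 || repression_factor > 1)
    stop("repression_factor must lie in (0, 1]")
  if (is.null(stage_roles)) {
    stage_roles <- if (profile == "unicellular_high") {
      n_uni <- max(1L, floor(n_stages / 3))
      c(rep("unicellular", n_uni), rep("multicellular", n_stages - n_uni))
    } else {
      n_e <- max(1L, round(0.4 * n_stages))
      n_m <- max(1L, round(0.4 * n_stages))
      c(rep("early", n_e), rep("mid", n_m),
        rep("late", max(1L, n_stages - n_e - n_m)))
    }
  }
  if (length(stage_roles) != n_stages)
    stop("stage_roles must cover all ", n_stages, " stages")
  structure(list(n_genes = as.integer(n_genes), n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates),
                 n_phylostrata = as.integer(n_phylostrata),
                 age_distribution = age_distribution, profile = profile,
                 repression_factor = repression_factor,
                 young_cutoff = as.integer(young_cutoff),
                 noise_sd = noise_sd, stage_effect_sd = stage_effect_sd,
                 stage_roles = stage_roles,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dnds_frac_above_1 = dnds_frac_above_1,
                 divergence_boost = divergence_boost,
                 in_paralogue_rate = in_paralogue_rate,
                 orthogroup_coverage = orthogroup_coverage,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a complete synthetic dataset
#'
#' Draws one dataset under a [synthetic_config()]: per gene a phylostratum
#' from the age distribution, a log-normal baseline, independent per-stage
#' log-normal variation, the profile's repression applied to young strata,
#' and log-normal replicate noise on top. dN/dS values are a mixture with
#' a configurable mass above 1; orthogroups pair each covered gene with a
#' partner in a second synthetic species, with occasional in-paralogues.
#' Identical seeds give identical output.
#'
#' @param config a `SyntheticConfig`.
#' @return List with `expression` (a `ReplicateExpressionSet`),
#'   `phylostrata` and `dnds` data.frames, `orthogroups`
#'   (an `OrthogroupMap`), `ps_map` (a ready `StratumMap`),
#'   `stage_means` (the noiseless gene x stage means) and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_genes; S <- config$n_stages; R <- config$n_replicates
  genes <- sprintf("g%05d", seq_len(n))
  stages <- sprintf("S%d", seq_len(S))
  roles <- config$stage_roles

  ps <- sample.int(config$n_phylostrata, n, replace = TRUE,
                   prob = config$age_distribution)
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  M <- baseline * matrix(exp(stats::rnorm(n * S, 0, config$stage_effect_sd)),
                         n, S, dimnames = list(genes, stages))

  # dN/dS: purifying-selection bulk in (0, 1), a small relaxed tail above 1
  above <- stats::runif(n) < config$dnds_frac_above_1
  dnds <- ifelse(above, 1 + stats::rexp(n, rate = 2), stats::rbeta(n, 2, 6))

  young <- ps >= config$young_cutoff
  rf <- config$repression_factor
  if (config$profile == "hourglass") {
    M[young, roles == "mid"] <- M[young, roles == "mid"] * rf
  } else if (config$profile == "early_conservation") {
    ramp <- seq(rf, 1, length.out = S)
    M[young, ] <- sweep(M[young, , drop = FALSE], 2L, ramp, "*")
  } else if (config$profile == "unicellular_high") {
    M[young, roles == "multicellular"] <-
      M[young, roles == "multicellular"] * rf
  }
  if (any(roles == "gamete")) {
    relaxed <- dnds >= stats::quantile(dnds, 0.8)
    M[relaxed, roles == "gamete"] <-
      M[relaxed, roles == "gamete"] * config$divergence_boost
  }

  samples <- as.vector(outer(seq_len(R), stages,
                             function(r, s) paste0(s, "_r", r)))
  design <- data.frame(sample = samples,
                       stage = rep(stages, each = R),
                       replicate = rep(seq_len(R), times = S))
  A <- M[, design$stage, drop = FALSE] *
    matrix(exp(stats::rnorm(n * S * R, 0, config$noise_sd)), n, S * R)
  colnames(A) <- design$sample

  covered <- stats::runif(n) < config$orthogroup_coverage
  idx <- which(covered)
  groups <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    b <- sprintf("B_g%05d", i)
    if (stats::runif(1) < config$in_paralogue_rate)
      b <- c(b, sprintf("B_g%05d_p", i))
    list(speciesA = genes[i], speciesB = b)
  })
  names(groups) <- sprintf("OG%06d", seq_along(idx))

  list(expression = replicate_expression_set(A, design, stage_order = stages),
       phylostrata = data.frame(gene = genes, phylostratum = ps),
       dnds = data.frame(gene = genes, dnds = dnds),
       orthogroups = orthogroup_map(groups),
       ps_map = stratum_map(stats::setNames(ps, genes), kind = "phylostratum",
                            K = config$n_phylostrata),
       stage_means = M,
       config = config)
}

#' Write a synthetic dataset as the pipeline's TSV input dialects
#'
#' Emits `expression.tsv`, `design.tsv`, `ages.tsv`, `dnds.tsv` and
#' `orthogroups.tsv` under `dir`.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- dataset$expression$abundance
  w(data.frame(gene_id = rownames(ab), ab, check.names = FALSE), "expression.tsv")
  w(dataset$expression$design, "design.tsv")
  w(dataset$phylostrata, "ages.tsv")
  w(dataset$dnds, "dnds.tsv")
  og <- dataset$orthogroups
  w(data.frame(orthogroup = names(og$groups),
               speciesA = vapply(og$groups, function(g)
                 paste(g$speciesA, collapse = ","), character(1)),
               speciesB = vapply(og$groups, function(g)
                 paste(g$speciesB, collapse = ","), character(1))),
    "orthogroups.tsv")
  invisible(dir)
}

# early/mid/late stage modules implied by a config's stage roles
modules_from_roles <- function(config, stages = sprintf("S%d", seq_len(config$n_stages))) {
  r <- config$stage_roles
  stage_modules(early = stages[r == "early"],
                mid = stages[r == "mid"],
                late = stages[r == "late"])
}

#' Rejection-rate report over repeated synthetic datasets
#'
#' Draws `n_datasets` datasets under `config` (seeds `seed + 1 .. seed +
#' n_datasets`), runs the shape tests appropriate to the configured
#' profile on each (after the standard prepare steps: mean-TPM filter,
#' median replicate collapsing, square-root transform), and reports the
#' fraction of datasets rejected at level `alpha` with an exact binomial
#' confidence interval. Under the `flat` profile this measures type-I
#' error; under the effect profiles it measures power.
#'
#' For early/mid/late-role profiles the flat-line and reductive-hourglass
#' tests are run (sharing one permutation null per dataset). For
#' `unicellular_high`, the one-sided pairwise test (unicellular >
#' multicellular) and the reductive-hourglass test restricted to the
#' multicellular stages are run.
#'
#' @param config a `SyntheticConfig`.
#' @param n_datasets number of simulated datasets (>= 20).
#' @param alpha rejection level.
#' @param n_perm permutations per test.
#' @param seed base seed.
#' @return data.frame with columns `test`, `n_datasets`, `rejections`,
#'   `rate`, `ci_lower`, `ci_upper`, plus attribute `p_values`.
#' @export
recovery_report <- function(config, n_datasets, alpha = 0.05,
                            n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(config, "SyntheticConfig"), n_datasets >= 20L)
  uni_mode <- config$profile == "unicellular_high" ||
    any(config$stage_roles %in% c("unicellular", "multicellular"))
  tests <- if (uni_mode) c("pairwise_uni_gt_multi", "hourglass_multicellular")
           else c("flat_line", "reductive_hourglass")
  p <- matrix(NA_real_, n_datasets, length(tests),
              dimnames = list(NULL, tests))
  for (i in seq_len(n_datasets)) {
    cfg <- config; cfg$seed <- seed + i
    ds <- generate_dataset(cfg)
    mat <- prepare_stage_matrix(ds$expression, min_tpm = 2, transform = "sqrt")
    if (uni_mode) {
      stages <- mat$stages
      uni <- stages[cfg$stage_roles == "unicellular"]
      multi <- stages[cfg$stage_roles == "multicellular"]
      p[i, 1L] <- pairwise_test(uni, multi, mat, ds$ps_map,
                                alternative = "greater", n_perm = n_perm,
                                seed = cfg$seed)$p_empirical
      sub <- stage_expression_matrix(
        mat$abundance[, multi, drop = FALSE], transform_tag = mat$transform_tag)
      k <- length(multi)
      if (k < 3L) stop("hourglass on multicellular stages needs >= 3 of them")
      mods <- stage_modules(early = multi[1L],
                            mid = multi[2:(k - 1L)],
                            late = multi[k])
      p[i, 2L] <- reductive_hourglass_test(sub, ds$ps_map, mods,
                                           n_perm = n_perm,
                                           seed = cfg$seed)$p_empirical
    } else {
      nulls <- permute_null_profiles(mat, ds$ps_map, n_perm, seed = cfg$seed)
      obs <- attr(nulls, "observed")
      null_var <- rowSums((nulls - rowMeans(nulls))^2) / (ncol(nulls) - 1L)
      p[i, 1L] <- (1 + sum(null_var >= stats::var(obs))) / (n_perm + 1)
      mods <- modules_from_roles(cfg, mat$stages)
      mcol <- function(M, cols) if (length(cols) == 1L) M[, cols]
              else rowMeans(M[, cols, drop = FALSE])
      obs_D <- min(mean(obs[mods$early]) - mean(obs[mods$mid]),
                   mean(obs[mods$late]) - mean(obs[mods$mid]))
      null_D <- pmin(mcol(nulls, mods$early) - mcol(nulls, mods$mid),
                     mcol(nulls, mods$late) - mcol(nulls, mods$mid))
      p[i, 2L] <- (1 + sum(null_D >= obs_D)) / (n_perm + 1)
    }
  }
  out <- do.call(rbind, lapply(tests, function(tn) {
    rej <- sum(p[, tn] < alpha)
    ci <- stats::binom.test(rej, n_datasets)$conf.int
    data.frame(test = tn, n_datasets = n_datasets, rejections = rej,
               rate = rej / n_datasets, ci_lower = ci[1L], ci_upper = ci[2L])
  }))
  attr(out, "p_values") <- p
  out
}
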