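#' Standard prepare steps: filter, collapse, transform
#'
#' The fixed order of the expression-preparation pipeline: mean-TPM
#' filtering on untransformed TPM across all samples, median replicate
#' collapsing, then the variance-stabilising transform.
#'
#' @param set a `ReplicateExpressionSet`.
#' @param min_tpm mean-TPM filter threshold (default 2).
#' @param transform transform applied after collapsing.
#' @return A `StageExpressionMatrix`.
#' @export
prepare_stage_matrix <- function(set, min_tpm = 2,
                                 transform = c("sqrt", "log2p1", "rank", "none")) {
  transform <- match.arg(transform)
  set <- filter_low_expression(set, threshold = min_tpm)
  mat <- collapse_replicates_median(set)
  transform_expression(mat, transform)
}

#' Run the full evolutionary-transcriptomics pipeline from one config
#'
#' Orchestrates prepare, stratification, index profiles with bootstrap
#' SDs, the shape tests, the contribution analysis and (optionally) the
#' cross-species distances, from a single configuration — either a named
#' list or a YAML file path. Every emitted table is accompanied by a
#' provenance record holding the seed, permutation and bootstrap counts,
#' transform, filter threshold and dropped-gene counts.
#'
#' Config fields: `expression`, `design`, `ages` (paths), `max_ps`;
#' optional `dnds`, `orthogroups`; `min_tpm` (default 2), `transform`
#' (default `"sqrt"`), `indices` (default `"TAI"`; any of TAI/TSI/TDI),
#' `modules` (list with `early`, `mid`, `late`), `pairwise` (list with
#' `group_a`, `group_b`, `alternative`), `n_perm` (default 50000),
#' `n_boot` (default 50000), `seed`, `out_dir`.
#'
#' @param config named list or path to a YAML file.
#' @return Invisibly, the result bundle: `profiles`, `tests`,
#'   `contributions`, `drivers`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("expression", "design", "ages", "max_ps")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config is missing field '", miss[1L], "'")
  cfg <- utils::modifyList(
    list(min_tpm = 2, transform = "sqrt", indices = "TAI",
         n_perm = 50000L, n_boot = 50000L, seed = 1L, out_dir = NULL),
    config)

  set <- read_expression_table(cfg$expression, cfg$design)
  check_stages <- function(stages, where) {
    bad <- setdiff(stages, set$stage_order)
    if (length(bad)) stop("config ", where, " references stage '", bad[1L],
                          "' absent from design")
  }
  if (!is.null(cfg$modules))
    check_stages(unlist(cfg$modules), "modules")
  if (!is.null(cfg$pairwise))
    check_stages(c(cfg$pairwise$group_a, cfg$pairwise$group_b), "pairwise")

  mat <- prepare_stage_matrix(set, min_tpm = cfg$min_tpm,
                              transform = cfg$transform)
  ps_map <- read_phylostratum_map(cfg$ages, max_ps = cfg$max_ps)

  strata_maps <- list(TAI = ps_map)
  if ("TSI" %in% cfg$indices) {
    tau <- compute_tau(mat)
    strata_maps$TSI <- stratify_deciles(tau$values, kind = "tau_stratum")
  }
  if ("TDI" %in% cfg$indices) {
    if (is.null(cfg$dnds)) stop("TDI requested but config has no dnds path")
    dnds <- read_dnds_table(cfg$dnds)
    strata_maps$TDI <- stratify_deciles(dnds, kind = "divergence_stratum")
  }
  strata_maps <- strata_maps[intersect(cfg$indices, names(strata_maps))]

  profiles <- lapply(names(strata_maps), function(kind)
    weighted_index(mat, strata_maps[[kind]], n_boot = cfg$n_boot,
                   seed = cfg$seed))
  names(profiles) <- names(strata_maps)

  tests <- list()
  tests$flat_line <- flat_line_test(mat, ps_map, n_perm = cfg$n_perm,
                                    seed = cfg$seed)
  if (!is.null(cfg$modules)) {
    mods <- stage_modules(cfg$modules$early, cfg$modules$mid, cfg$modules$late)
    tests$reductive_hourglass <- reductive_hourglass_test(
      mat, ps_map, mods, n_perm = cfg$n_perm, seed = cfg$seed)
  }
  if (!is.null(cfg$pairwise)) {
    tests$pairwise <- pairwise_test(
      cfg$pairwise$group_a, cfg$pairwise$group_b, mat, ps_map,
      alternative = if (is.null(cfg$pairwise$alternative)) "greater"
                    else cfg$pairwise$alternative,
      n_perm = cfg$n_perm, seed = cfg$seed)
  }

  contrib <- contribution_matrix(mat, ps_map)
  drivers <- lapply(mat$stages, function(s) top_contributors_elbow(contrib, s))
  names(drivers) <- mat$stages

  profile_TAI <- profiles$TAI
  provenance <- list(
    package_version = as.character(utils::packageVersion("phylotrax")),
    seed = cfg$seed, n_perm = cfg$n_perm, n_boot = cfg$n_boot,
    transform = cfg$transform, min_tpm = cfg$min_tpm,
    n_genes_input = nrow(set$abundance),
    n_genes_after_filter = nrow(mat$abundance),
    n_genes_indexed = profile_TAI$n_genes_used,
    n_dropped_no_stratum = profile_TAI$n_dropped_expression)

  bundle <- list(profiles = profiles, tests = tests,
                 contributions = contrib, drivers = drivers,
                 provenance = provenance)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  invisible(bundle)
}

#' Write a pipeline result bundle to disk
#'
#' Profiles and test results as TSV, contributions as TSV, provenance as
#' JSON.
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prof_df <- do.call(rbind, lapply(bundle$profiles, function(p)
    data.frame(kind = p$kind, stage = p$stages,
               value = as.numeric(p$value), sd = as.numeric(p$sd))))
  utils::write.table(prof_df, file.path(dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  test_df <- do.call(rbind, lapply(bundle$tests, function(t)
    data.frame(test = t$test, observed = t$observed,
               p_empirical = t$p_empirical, p_fitted = t$p_fitted,
               n_perm = t$n_perm)))
  utils::write.table(test_df, file.path(dir, "tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm <- bundle$contributions
  utils::write.table(
    data.frame(gene = rownames(cm), unclass(cm), check.names = FALSE),
    file.path(dir, "contributions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(bundle$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
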