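#!/usr/bin/env Rscript

# Permutation shape tests on the fixtures: the flat-line and reductive
# hourglass tests on the hourglass and null series, and the one-sided
# pairwise test (unicellular > multicellular) on the life cycle series.
# Writes results/shape_tests.tsv.

suppressPackageStartupMessages(library(phylotrax))

n_perm <- 10000L
load_mat <- function(name) {
  dir <- file.path("scratch", "fixtures", name)
  set <- read_expression_table(file.path(dir, "expression.tsv"),
                               file.path(dir, "design.tsv"))
  list(mat = prepare_stage_matrix(set),
       ps = read_phylostratum_map(file.path(dir, "ages.tsv"), max_ps = 8,
                                  isoform_pattern = "$^"))
}

rows <- list()
mods <- stage_modules(c("S1", "S2"), c("S3", "S4"), "S5")
for (name in c("hourglass", "flat")) {
  x <- load_mat(name)
  fl <- flat_line_test(x$mat, x$ps, n_perm = n_perm, seed = 7)
  hg <- reductive_hourglass_test(x$mat, x$ps, mods, n_perm = n_perm, seed = 7)
  cat(sprintf("%-10s flat-line p = %.4g; hourglass p = %.4g (D = %.4f)\n",
              name, fl$p_empirical, hg$p_empirical, hg$observed))
  rows[[length(rows) + 1]] <- data.frame(
    dataset = name, test = c("flat_line", "reductive_hourglass"),
    observed = c(fl$observed, hg$observed),
    p_empirical = c(fl$p_empirical, hg$p_empirical),
    p_fitted = c(fl$p_fitted, hg$p_fitted), n_perm = n_perm)
}

x <- load_mat("unicellular")
roles <- synthetic_config(profile = "unicellular_high", seed = 103)$stage_roles
uni <- x$mat$stages[roles == "unicellular"]
multi <- x$mat$stages[roles == "multicellular"]
pw <- pairwise_test(uni, multi, x$mat, x$ps, "greater",
                    n_perm = n_perm, seed = 7)
cat(sprintf("unicellular > multicellular: diff = %.4f, p = %.4g\n",
            pw$observed, pw$p_empirical))
rows[[length(rows) + 1]] <- data.frame(
  dataset = "unicellular", test = "pairwise_greater", observed = pw$observed,
  p_empirical = pw$p_empirical, p_fitted = pw$p_fitted, n_perm = n_perm)

out <- do.call(rbind, rows)
write.table(out, file.path("results", "shape_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/shape_tests.tsv\n")
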