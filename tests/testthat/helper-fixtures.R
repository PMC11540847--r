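# In-code fixtures and independent oracles used across the suite.

# gene x stage matrix with dimnames
msm <- function(values, genes = NULL, stages = NULL, transform = "none") {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(stages)) stages <- paste0("S", seq_len(ncol(m)))
  dimnames(m) <- list(genes, stages)
  stage_expression_matrix(m, transform_tag = transform)
}

smap <- function(strata, genes = paste0("g", seq_along(strata)),
                 kind = "phylostratum", K = max(strata)) {
  stratum_map(stats::setNames(strata, genes), kind = kind, K = K)
}

# small replicate set: 3 genes, 2 stages x 2 replicates unless overridden
tiny_set <- function(abundance = NULL) {
  if (is.null(abundance)) {
    abundance <- matrix(c(1, 2, 3, 4,
                          5, 6, 7, 8,
                          0, 0, 0, 8), 3, 4, byrow = TRUE)
  }
  dimnames(abundance) <- list(paste0("g", seq_len(nrow(abundance))),
                              c("a1", "a2", "b1", "b2"))
  design <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                       stage = c("SA", "SA", "SB", "SB"),
                       replicate = c(1, 2, 1, 2))
  replicate_expression_set(abundance, design)
}

# ---- independent index-engine oracles (deliberately coded three ways) ----

# 1: explicit double loop over genes and stages
oracle_index_loop <- function(E, s) {
  out <- numeric(ncol(E))
  for (j in seq_len(ncol(E))) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(E))) {
      num <- num + s[i] * E[i, j]
      den <- den + E[i, j]
    }
    out[j] <- num / den
  }
  out
}

# 2: per-stage vector sums
oracle_index_sums <- function(E, s) {
  vapply(seq_len(ncol(E)),
         function(j) sum(s * E[, j]) / sum(E[, j]), numeric(1))
}

# 3: long-format weighted mean via stats::weighted.mean
oracle_index_wm <- function(E, s) {
  long <- data.frame(stage = rep(seq_len(ncol(E)), each = nrow(E)),
                     stratum = rep(s, times = ncol(E)),
                     w = as.vector(E))
  vapply(split(long, long$stage),
         function(d) stats::weighted.mean(d$stratum, d$w), numeric(1))
}

# direct-summation tau oracle: loop over stages per gene
oracle_tau_gene <- function(e) {
  ehat <- e / max(e)
  acc <- 0
  for (v in ehat) acc <- acc + (1 - v)
  acc / (length(e) - 1)
}

# direct-summation Jensen-Shannon distance oracle (log2)
oracle_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  js <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) js <- js + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) js <- js + 0.5 * q[i] * log2(q[i] / m[i])
  }
  sqrt(js)
}

# random stage matrix + strata pair for property tests
random_instance <- function(n_genes = 200, n_stages = 6, K = 8) {
  E <- matrix(stats::rlnorm(n_genes * n_stages, 2, 1), n_genes, n_stages,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("S", seq_len(n_stages))))
  list(mat = stage_expression_matrix(E),
       strata = smap(sample.int(K, n_genes, replace = TRUE),
                     genes = rownames(E), K = K))
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
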