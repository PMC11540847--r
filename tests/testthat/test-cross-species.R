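test_that("orthogroup tables parse and reject shared genes", {
  tab <- data.frame(orthogroup = c("OG1", "OG2"),
                    spA = c("gA1,gA2", "gA3"),
                    spB = c("gB1", "gB2,gB3"))
  map <- read_orthogroups(write_tsv_tmp(tab))
  expect_equal(length(map$groups), 2L)
  expect_setequal(map$species, c("spA", "spB"))
  expect_equal(map$groups$OG1$spA, c("gA1", "gA2"))

  dup <- list(OG1 = list(spA = "g1"), OG2 = list(spA = "g1"))
  expect_error(orthogroup_map(dup), "more than one orthogroup")
})

test_that("orthogroup aggregation sums member TPM and logs unassigned genes", {
  mat <- msm(matrix(c(3, 6,
                      5, 1,
                      2, 2,
                      7, 0), 4, 2, byrow = TRUE),
             genes = c("gA", "gB", "gC", "gD"))
  map <- orthogroup_map(list(OG1 = list(spA = c("gA", "gB"), spB = "x1"),
                             OG2 = list(spA = "gC", spB = "x2")))
  agg <- aggregate_orthogroups(mat, map, "spA")
  expect_equal(unname(agg$abundance["OG1", ]), c(8, 7))   # sum rule
  expect_equal(unname(agg$abundance["OG2", ]), c(2, 2))   # single gene: identity
  expect_false("gD" %in% rownames(agg$abundance))
  expect_equal(attr(agg, "n_unassigned"), 1L)

  expect_error(aggregate_orthogroups(mat, map, "spZ"), "spZ")
  tr <- transform_expression(mat, "sqrt")
  expect_error(aggregate_orthogroups(tr, map, "spA"), "untransformed")

  # order of genes within an orthogroup does not matter
  map2 <- orthogroup_map(list(OG1 = list(spA = c("gB", "gA"), spB = "x1"),
                              OG2 = list(spA = "gC", spB = "x2")))
  agg2 <- aggregate_orthogroups(mat, map2, "spA")
  expect_equal(agg2$abundance, agg$abundance)
})

test_that("distance metrics reproduce self-distance and the hand example", {
  E <- matrix(c(1, 1, 0.5,
                0, 0, 0.5,
                2, 2, 1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("og", 1:3), paste0("S", 1:3)))
  mat <- stage_expression_matrix(E)
  for (m in c("pearson", "spearman")) {
    d <- transcriptome_distance(mat, mat, m)
    expect_equal(unname(d$values["S1", "S2"]), 1)
  }
  expect_equal(unname(transcriptome_distance(mat, mat, "manhattan")$values["S1", "S2"]), 0)
  expect_equal(unname(transcriptome_distance(mat, mat, "jsd")$values["S1", "S2"]), 0)

  # P = (1, 0), Q = (0.5, 0.5): JS divergence 0.31128, distance sqrt of that
  A <- matrix(c(1, 0), 2, 1, dimnames = list(c("og1", "og2"), "P"))
  B <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("og1", "og2"), "Q"))
  d <- transcriptome_distance(stage_expression_matrix(A),
                              stage_expression_matrix(B), "jsd")
  # mixture M = (0.75, 0.25); JS = 0.5*KL(P||M) + 0.5*KL(Q||M)
  js <- 0.5 * (1 * log2(1 / 0.75)) +
    0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25))
  expect_equal(js, 0.311278, tolerance = 1e-6)
  expect_equal(unname(d$values[1, 1]), sqrt(js), tolerance = 1e-12)
  expect_equal(unname(d$values[1, 1]), oracle_jsd(c(1, 0), c(0.5, 0.5)),
               tolerance = 1e-12)

  # disjoint support: maximal JS divergence is 1, distance 1
  A2 <- matrix(c(1, 0), 2, 1, dimnames = list(c("og1", "og2"), "P"))
  B2 <- matrix(c(0, 1), 2, 1, dimnames = list(c("og1", "og2"), "Q"))
  d2 <- transcriptome_distance(stage_expression_matrix(A2),
                               stage_expression_matrix(B2), "jsd")
  expect_equal(unname(d2$values[1, 1]), 1)
})

test_that("JSD is a metric on random probability-vector triples", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    p <- stats::runif(n); q <- stats::runif(n); r <- stats::runif(n)
    dpq <- oracle_jsd(p, q); dqr <- oracle_jsd(q, r); dpr <- oracle_jsd(p, r)
    expect_gte(dpq, 0); expect_lte(dpq, 1)
    expect_equal(dpq, oracle_jsd(q, p), tolerance = 1e-12)   # symmetry
    expect_lte(dpr, dpq + dqr + 1e-12)                       # triangle
    expect_equal(oracle_jsd(p, p), 0)                        # identity
    # package path agrees with the oracle
    A <- matrix(p, n, 1, dimnames = list(paste0("og", 1:n), "a"))
    B <- matrix(q, n, 1, dimnames = list(paste0("og", 1:n), "b"))
    got <- transcriptome_distance(stage_expression_matrix(A),
                                  stage_expression_matrix(B), "jsd")$values[1, 1]
    expect_equal(unname(got), dpq, tolerance = 1e-12)
  }
})

test_that("stage matching picks the argmin (or argmax for correlations)", {
  V <- matrix(c(0.1, 0.5, 0.9,
                0.7, 0.2, 0.4), 2, 3, byrow = TRUE,
              dimnames = list(c("A1", "A2"), c("B1", "B2", "B3")))
  d <- structure(list(values = V, metric = "jsd", n_orthogroups = 10),
                 class = "StageDistanceMatrix")
  m <- match_stages(d)
  expect_equal(m$stage_b, c("B1", "B2"))
  expect_false(any(m$tie))

  # ties: earlier stage chosen and flagged
  V2 <- matrix(c(0.3, 0.3, 0.5), 1, 3,
               dimnames = list("A1", c("B1", "B2", "B3")))
  d2 <- structure(list(values = V2, metric = "manhattan", n_orthogroups = 10),
                  class = "StageDistanceMatrix")
  m2 <- match_stages(d2)
  expect_equal(m2$stage_b, "B1")
  expect_true(m2$tie)

  # correlation: argmax
  d3 <- structure(list(values = V, metric = "pearson", n_orthogroups = 10),
                  class = "StageDistanceMatrix")
  expect_equal(match_stages(d3)$stage_b, c("B3", "B1"))
})

test_that("two synthetic species with shared structure match corresponding stages", {
  cfg <- synthetic_config(n_genes = 1200, profile = "hourglass", seed = 88)
  ds <- generate_dataset(cfg)
  mat <- prepare_stage_matrix(ds$expression, transform = "none")
  aggA <- aggregate_orthogroups(mat, ds$orthogroups, "speciesA")
  # a second "species": same orthogroup profiles with mild noise
  E <- aggA$abundance * matrix(exp(rnorm(length(aggA$abundance), 0, 0.1)),
                               nrow(aggA$abundance))
  dimnames(E) <- dimnames(aggA$abundance)
  aggB <- stage_expression_matrix(E)
  tA <- transform_expression(aggA, "log2p1")
  tB <- transform_expression(aggB, "log2p1")
  d <- transcriptome_distance(tA, tB, "jsd")
  m <- match_stages(d)
  expect_equal(m$stage_b, m$stage_a)   # best match is the same stage
})
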