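test_that("the weighted index reproduces hand-derived micro-examples", {
  # two genes, ps = (1, 8), stage abundances (3, 1): (1*3 + 8*1)/4 = 2.75
  mat <- msm(matrix(c(3, 1), 2, 1))
  prof <- weighted_index(mat, smap(c(1, 8)))
  expect_equal(unname(prof$value), 2.75)
  cm <- contribution_matrix(mat, smap(c(1, 8)))
  expect_equal(unname(cm[, 1]), c(0.75, 2.00))
  expect_equal(sum(cm[, 1]), 2.75)

  # constant stratum -> index equals that stratum everywhere
  mat2 <- msm(matrix(rlnorm(20), 5, 4))
  expect_equal(unname(weighted_index(mat2, smap(rep(4, 5)))$value), rep(4, 4))

  # single gene -> its stratum
  expect_equal(unname(weighted_index(msm(matrix(2, 1, 3)), smap(5))$value),
               rep(5, 3))
})

test_that("TAI, TSI and TDI agree with three independent naive oracles", {
  set.seed(101)
  for (rep in 1:5) {
    inst <- random_instance(200, 6)
    E <- inst$mat$abundance
    for (kind in c("phylostratum", "tau_stratum", "divergence_stratum")) {
      strata <- smap(sample.int(10, 200, replace = TRUE),
                     genes = rownames(E), kind = kind, K = 10)
      got <- unname(weighted_index(inst$mat, strata)$value)
      s <- as.numeric(strata$values[rownames(E)])
      for (oracle in list(oracle_index_loop, oracle_index_sums, oracle_index_wm)) {
        exp_val <- unname(oracle(E, s))
        expect_equal(got, exp_val, tolerance = 1e-10)
      }
    }
  }
})

test_that("index bounds, scale invariance and mass-shift monotonicity hold", {
  set.seed(202)
  for (rep in 1:50) {
    inst <- random_instance(60, 4)
    prof <- weighted_index(inst$mat, inst$strata)
    s <- inst$strata$values
    expect_true(all(prof$value >= min(s) & prof$value <= max(s)))

    # scaling one stage leaves that stage's index unchanged
    E2 <- inst$mat$abundance
    E2[, 2] <- E2[, 2] * runif(1, 0.1, 10)
    prof2 <- weighted_index(stage_expression_matrix(E2), inst$strata)
    expect_equal(prof2$value, prof$value, tolerance = 1e-12)

    # moving expression mass from a low- to a high-stratum gene raises the index
    lo <- names(which.min(s)); hi <- names(which.max(s))
    if (s[lo] < s[hi]) {
      E3 <- inst$mat$abundance
      shift <- 0.5 * E3[lo, 1]
      E3[lo, 1] <- E3[lo, 1] - shift
      E3[hi, 1] <- E3[hi, 1] + shift
      prof3 <- weighted_index(stage_expression_matrix(E3), inst$strata)
      expect_gt(prof3$value[1], prof$value[1])
    }
  }
})

test_that("genes without both kinds of data are dropped and counted", {
  mat <- msm(matrix(1:6, 3, 2), genes = c("g1", "g2", "g3"))
  strata <- smap(c(2, 4, 6), genes = c("g2", "g3", "g4"))
  prof <- weighted_index(mat, strata)
  expect_equal(prof$n_genes_used, 2L)
  expect_equal(prof$n_dropped_expression, 1L)
  expect_equal(prof$n_dropped_strata, 1L)

  zero <- msm(matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(weighted_index(zero, smap(c(1, 2))), "S2")
})

test_that("contribution columns conserve the index and respect zero weights", {
  set.seed(33)
  inst <- random_instance(80, 5)
  cm <- contribution_matrix(inst$mat, inst$strata)
  prof <- weighted_index(inst$mat, inst$strata)
  expect_equal(unname(colSums(cm)), unname(prof$value), tolerance = 1e-12)
  expect_true(all(cm >= 0))

  E <- inst$mat$abundance
  E["g5", 2] <- 0
  cm2 <- contribution_matrix(stage_expression_matrix(E), inst$strata)
  expect_equal(unname(cm2["g5", 2]), 0)

  # uniform expression: gene i contributes stratum_i / n
  n <- 10
  u <- msm(matrix(1, n, 3))
  su <- smap(sample.int(8, n, replace = TRUE))
  cmu <- contribution_matrix(u, su)
  expect_equal(unname(cmu[, 1]), unname(su$values) / n, tolerance = 1e-12)
})

test_that("bootstrap SD is zero for degenerate inputs and seed-reproducible", {
  mat <- msm(matrix(rlnorm(40), 10, 4))
  expect_equal(bootstrap_sd(mat, smap(rep(3, 10)), n_boot = 50, seed = 1),
               rep(0, 4))
  one <- msm(matrix(1:3, 1, 3))
  expect_equal(bootstrap_sd(one, smap(5), n_boot = 50, seed = 1), rep(0, 3))

  inst <- random_instance(100, 4)
  a <- bootstrap_sd(inst$mat, inst$strata, n_boot = 500, seed = 99)
  b <- bootstrap_sd(inst$mat, inst$strata, n_boot = 500, seed = 99)
  expect_identical(a, b)
})

test_that("bootstrap SD is stable across seeds within Monte-Carlo error", {
  set.seed(55)
  inst <- random_instance(200, 4)
  n_boot <- 5000
  sd1 <- bootstrap_sd(inst$mat, inst$strata, n_boot = n_boot, seed = 1)
  sd2 <- bootstrap_sd(inst$mat, inst$strata, n_boot = n_boot, seed = 2)
  # SE of a bootstrap SD estimate ~ sd / sqrt(2 (B - 1))
  se <- sd1 / sqrt(2 * (n_boot - 1))
  expect_true(all(abs(sd1 - sd2) < 3 * (se + se)))
})

test_that("elbow selection finds the head of a contribution curve", {
  # 3 dominant genes, then a flat tail: head of 3 expected
  E <- matrix(c(10, 9, 8, rep(0.1, 47)), 50, 1,
              dimnames = list(sprintf("g%02d", 1:50), "S1"))
  cm <- contribution_matrix(stage_expression_matrix(E),
                            smap(rep(1, 50), genes = rownames(E)))
  # brute-force oracle: max perpendicular distance over all cut points
  v <- sort(cm[, 1], decreasing = TRUE)
  x <- seq_along(v); m <- length(v)
  d <- abs((v[m] - v[1]) * (x - 1) - (m - 1) * (v - v[1])) /
    sqrt((m - 1)^2 + (v[m] - v[1])^2)
  expect_equal(unname(which.max(d)), 4L)  # tail starts at gene 4 -> head is 3
  picked <- top_contributors_elbow(cm, "S1")
  expect_equal(length(picked), 3L)
  expect_setequal(picked, c("g01", "g02", "g03"))

  # linear decay: no curvature, fall back to the cap
  El <- matrix(seq(50, 1), 50, 1,
               dimnames = list(sprintf("g%02d", 1:50), "S1"))
  cml <- contribution_matrix(stage_expression_matrix(El),
                             smap(rep(1, 50), genes = rownames(El)))
  expect_equal(length(top_contributors_elbow(cml, "S1", cap = 10)), 10L)
  expect_equal(length(top_contributors_elbow(cml, "S1")), 50L)

  # cap exceeding the population returns everything
  small <- contribution_matrix(msm(matrix(c(5, 3, 2, 1), 4, 1)),
                               smap(c(1, 2, 3, 4)))
  expect_lte(length(top_contributors_elbow(small, "S1", cap = 500)), 4L)
})

test_that("driver intersection is ordered set intersection", {
  expect_setequal(intersect_drivers(list(c("a", "b", "c"),
                                         c("b", "c", "d"),
                                         c("c", "b"))), c("b", "c"))
  expect_equal(intersect_drivers(list(c("x", "y"))), c("x", "y"))
  expect_equal(intersect_drivers(list("a", "b")), character(0))
  # ordering by mean rank across lists
  got <- intersect_drivers(list(c("a", "b", "c"), c("a", "c", "b")))
  expect_equal(got[1], "a")
})
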