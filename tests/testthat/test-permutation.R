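bp4 <- binary_phenotype(c(S1 = "low", S2 = "high", S3 = "high",
                          S4 = "high"))

test_that("exhaustive permutations enumerate each assignment once", {
  pm <- permute_classes(bp4, permutation_plan(mode = "exhaustive"))
  expect_equal(dim(pm), c(4L, 4L))
  expect_equal(colSums(pm == "low"), rep(1, 4))
  expect_equal(anyDuplicated(apply(pm, 2, paste, collapse = "")), 0L)

  big <- binary_phenotype(setNames(rep(c("low", "high"), c(10, 14)),
                                   sprintf("S%d", 1:24)))
  expect_error(
    permute_classes(big, permutation_plan(mode = "exhaustive",
                                          exhaustive_limit = 1000)),
    "monte_carlo")
})

test_that("monte carlo permutations preserve counts and obey the seed", {
  bp <- binary_phenotype(setNames(rep(c("low", "high"), c(4, 8)),
                                  sprintf("S%d", 1:12)))
  p1 <- permute_classes(bp, permutation_plan(50, seed = 7))
  p2 <- permute_classes(bp, permutation_plan(50, seed = 7))
  p3 <- permute_classes(bp, permutation_plan(50, seed = 8))
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_true(all(colSums(p1 == "low") == 4))
  # caller RNG state untouched
  set.seed(1); x <- runif(1)
  set.seed(1); permute_classes(bp, permutation_plan(5, seed = 3))
  expect_identical(runif(1), x)
})

test_that("expected_count matches the exhaustive 4-assignment oracle", {
  # 1 site, 4 strains, 1 low, 1 minor carrier: one assignment puts the
  # carrier in the low class (p = 0.25); the other three give p = 1
  gm <- gm_from_calls(list(c(1L, 0L, 0L, 0L)))
  plan <- permutation_plan(mode = "exhaustive")
  np <- null_pvalues(gm, bp4, plan)
  expect_equal(sort(as.vector(np)), c(0.25, 1, 1, 1))
  expect_equal(expected_count(gm, bp4, plan, 0.26), 0.25)
  expect_equal(expected_count(gm, bp4, plan, 0.25), 0)   # strict <
  expect_equal(expected_count(gm, bp4, plan, 1e-6), 0)
})

test_that("null p-values equal a per-permutation rescan", {
  gm <- random_gm(m = 40, s = 10, missing_rate = 0.1, seed = 12)
  bp <- binary_phenotype(setNames(rep(c("low", "high"), c(3, 7)),
                                  gm$strains))
  plan <- permutation_plan(20, seed = 5)
  np <- null_pvalues(gm, bp, plan)
  pm <- permute_classes(bp, plan)
  for (j in c(1, 7, 20)) {
    bp_j <- binary_phenotype(setNames(pm[, j], rownames(pm)))
    expect_equal(np[, j], assoc_scan(gm, bp_j)$p)
  }
})

test_that("monte carlo converges to the exhaustive expectation", {
  gm <- gm_from_calls(list(c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L),
                           c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 0L)))
  bp <- binary_phenotype(setNames(rep(c("low", "high"), c(3, 5)),
                                  sprintf("S%d", 1:8)))
  thr <- 0.3
  exact <- expected_count(gm, bp, permutation_plan(mode = "exhaustive"), thr)
  plan <- permutation_plan(1e5, seed = 42)
  np <- null_pvalues(gm, bp, plan)
  counts <- colSums(np < thr)
  mc <- mean(counts)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mc - exact), 3 * se + 1e-12)
})

test_that("expected_count is monotone non-decreasing in the threshold", {
  gm <- random_gm(m = 60, s = 12, missing_rate = 0.05, seed = 3)
  bp <- binary_phenotype(setNames(rep(c("low", "high"), c(4, 8)),
                                  gm$strains))
  grid <- exp(seq(log(1e-6), log(1), length.out = 50))
  ec <- expected_count(gm, bp, permutation_plan(200, seed = 2), grid)
  expect_true(all(diff(ec) >= 0))
})

test_that("identical plans give bit-identical nulls", {
  gm <- random_gm(m = 30, s = 10, seed = 6)
  bp <- binary_phenotype(setNames(rep(c("low", "high"), c(3, 7)),
                                  gm$strains))
  plan <- permutation_plan(100, seed = 11)
  expect_identical(null_pvalues(gm, bp, plan), null_pvalues(gm, bp, plan))
})

test_that("fdr_estimate and tp_fraction reproduce the reference arithmetic", {
  est <- fdr_estimate(3, 0.011)
  expect_equal(est$fdr, 0.011 / 3)
  expect_equal(est$fdr_percent, "0.4%")

  est2 <- fdr_estimate(837, 652)
  expect_equal(est2$fdr, 652 / 837)
  expect_equal(est2$fdr_percent, "78%")
  expect_equal(tp_fraction(837, 652), (837 - 652) / 837)
  expect_equal(est2$tp_percent, "22%")

  # undefined marker, never 0
  est0 <- fdr_estimate(0, 5)
  expect_true(is.na(est0$fdr))
  expect_equal(est0$fdr_percent, "undefined")
  expect_error(tp_fraction(0, 1), "observed_count > 0")
  expect_error(fdr_estimate(-1, 0), "non-negative")

  # floor at 0 and unclipped FDR above 1
  expect_equal(tp_fraction(10, 15), 0)
  expect_equal(fdr_estimate(10, 15)$fdr, 1.5)
  expect_equal(tp_fraction(10, 0), 1)
})

test_that("fdr + tp_fraction = 1 whenever fdr <= 1", {
  set.seed(14)
  for (i in 1:50) {
    obs <- sample(1:1000, 1)
    exp_ <- runif(1, 0, obs)
    est <- fdr_estimate(obs, exp_)
    expect_equal(est$fdr + est$tp_fraction, 1)
  }
})

test_that("threshold_for_expected inverts the null grid", {
  gm <- gm_from_calls(list(c(1L, 0L, 0L, 0L)))
  plan <- permutation_plan(mode = "exhaustive")
  # target 0.25 admits the p = 0.25 outcome; 0.2 excludes it
  expect_equal(threshold_for_expected(gm, bp4, plan, 0.25), 1)
  expect_equal(threshold_for_expected(gm, bp4, plan, 0.2), 0.25)
  # target 0: at or below the minimum null p
  np <- null_pvalues(gm, bp4, plan)
  expect_lte(threshold_for_expected(gm, bp4, plan, 0), min(np))
  expect_error(threshold_for_expected(gm, bp4, plan, -1), ">= 0")
})

test_that("threshold summaries reconcile with scan counts", {
  gm <- random_gm(m = 80, s = 14, missing_rate = 0, seed = 19)
  bp <- binary_phenotype(setNames(rep(c("low", "high"), c(4, 10)),
                                  gm$strains))
  plan <- permutation_plan(100, seed = 9)
  th <- c(0.001, 0.05, 0.5)
  summ <- threshold_summary(gm, bp, plan, th)
  res <- assoc_scan(gm, bp)
  expect_equal(summ$observed_count,
               vapply(th, function(t) sum(res$p < t), numeric(1)))
  expect_equal(summ$expected_count,
               expected_count(gm, bp, plan, th))
  defined <- summ$observed_count > 0
  expect_equal(summ$fdr[defined],
               (summ$expected_count / summ$observed_count)[defined])
})
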