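test_that("fisher_p matches frozen hand-derived tables", {
  # only one table compatible with the margins
  expect_equal(fisher_p(0, 5, 0, 19), 1)
  # unique minimum-probability table among the 6 with margins (5,19)x(5,19)
  expect_equal(fisher_p(5, 0, 0, 19), 1 / choose(24, 5), tolerance = 1e-12)
  expect_equal(fisher_p(5, 0, 0, 19, sided = "one"), 1 / choose(24, 5),
               tolerance = 1e-12)
  # margins (1,3)x(1,3): P(a=1)=1/4 kept, P(a=0)=3/4 excluded
  expect_equal(fisher_p(1, 0, 0, 3), 0.25)
})

test_that("fisher_p equals the enumeration oracle (spot totals)", {
  # the exhaustive total <= 30 sweep lives in test-acceptance.R
  fisher_cache_reset()
  worst <- 0
  for (tot in c(1:10, 17, 24)) {
    for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
      d <- tot - a - b - cc
      worst <- max(worst, abs(fisher_p(a, b, cc, d) -
                                fisher_oracle(a, b, cc, d)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("fisher_p agrees with stats::fisher.test on random tables", {
  set.seed(21)
  for (i in 1:300) {
    t <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    ours <- fisher_p(t[1], t[2], t[3], t[4])
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9,
                 info = paste(t, collapse = ","))
  }
})

test_that("fisher_p symmetry under simultaneous row/column swaps", {
  set.seed(4)
  for (i in 1:100) {
    t <- as.integer(sample(0:12, 4, replace = TRUE))
    p <- fisher_p(t[1], t[2], t[3], t[4])
    expect_equal(fisher_p(t[3], t[4], t[1], t[2]), p)  # swap rows
    expect_equal(fisher_p(t[2], t[1], t[4], t[3]), p)  # swap columns
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("p decreases monotonically toward separation at fixed margins", {
  # margins (8,16) x (8,16) over 24 strains; a = minor-in-low count
  ps <- vapply(0:8, function(a) fisher_p(a, 8 - a, 8 - a, 8 + a), numeric(1))
  # two-sided p peaks at the hypergeometric mode (a = 3 here), then falls
  # monotonically as the table moves toward separation
  expect_equal(ps[4], 1)
  expect_true(all(diff(ps[4:9]) <= 1e-12))
  one <- vapply(0:8, function(a)
    fisher_p(a, 8 - a, 8 - a, 8 + a, sided = "one"), numeric(1))
  expect_true(all(diff(one) <= 1e-12))  # one-sided tail is globally monotone
})

test_that("fisher_p memoization caches distinct tables and errors early", {
  fisher_cache_reset()
  p1 <- fisher_p(3, 4, 5, 6)
  st <- fisher_cache_stats()
  expect_equal(st$misses, 1)
  p2 <- fisher_p(3, 4, 5, 6)
  expect_identical(p1, p2)
  expect_equal(fisher_cache_stats()$hits, 1)
  expect_error(fisher_p(-1, 0, 0, 3), "non-negative")
})

test_that("build_table counts by (class, allele) with minor orientation", {
  # 4 strains, 1 low; the low strain alone carries the rarer allele
  gm <- gm_from_calls(list(c(1L, 0L, 0L, 0L)))
  bp <- binary_phenotype(c(S1 = "low", S2 = "high", S3 = "high",
                           S4 = "high"))
  t <- build_table(gm, 1, bp)
  expect_equal(unclass(t)[c("a", "b", "c", "d")],
               list(a = 1L, b = 0L, c = 0L, d = 3L))
  expect_false(t$degenerate)
  expect_error(build_table(gm, 2, bp), "out of range")

  mono <- gm_from_calls(list(c(0L, 0L, 0L, 0L)))
  tm <- build_table(mono, 1, bp)
  expect_true(tm$degenerate)
  expect_equal(tm$a + tm$c, 0L)
})

test_that("build_table equals a brute-force double loop on random data", {
  set.seed(17)
  for (rep in 1:5) {
    s <- sample(6:14, 1)
    gm <- random_gm(m = 15, s = s, missing_rate = 0.15, seed = rep)
    classes <- setNames(sample(c("low", "high"), s, replace = TRUE,
                               prob = c(0.3, 0.7)), gm$strains)
    bp <- binary_phenotype(classes)
    for (i in sample(15, 5)) {
      x <- gm$calls[i, ]
      obs <- !is.na(x)
      n1 <- sum(x[obs] == 1L)
      minor <- if (n1 < sum(obs) - n1) 1L else 0L  # tie -> allele 0
      a <- b <- cc <- d <- 0L
      for (j in seq_len(s)) {
        if (!obs[j]) next
        lo <- classes[j] == "low"
        mi <- x[j] == minor
        if (lo && mi) a <- a + 1L else if (lo) b <- b + 1L
        else if (mi) cc <- cc + 1L else d <- d + 1L
      }
      t <- build_table(gm, i, bp)
      expect_equal(c(t$a, t$b, t$c, t$d), c(a, b, cc, d))
    }
  }
})

test_that("assoc_scan preserves order, flags degenerates, matches per-site calls", {
  gm <- random_gm(m = 100, s = 12, missing_rate = 0.1, seed = 33)
  bp <- binary_phenotype(setNames(
    rep(c("low", "high"), c(3, 9)), gm$strains))
  res <- assoc_scan(gm, bp)
  expect_equal(nrow(res), 100L)
  expect_equal(res$pos, gm$sites$pos)
  for (i in sample(100, 12)) {
    t <- build_table(gm, i, bp)
    expect_equal(res$p[i],
                 if (t$degenerate) 1 else fisher_p(t$a, t$b, t$c, t$d))
  }
  expect_equal(res$neglog10_p, -log10(res$p))

  # perfectly separating site attains the minimum p
  sep <- c(rep(1L, 3), rep(0L, 9))
  gm2 <- gm_from_calls(c(list(sep), asplit(gm$calls[1:30, ], 1)),
                       strains = gm$strains)
  res2 <- assoc_scan(gm2, bp)
  expect_equal(which.min(res2$p), 1L)

  mono <- gm_from_calls(list(rep(0L, 12), rep(1L, 12)),
                        strains = gm$strains)
  resm <- assoc_scan(mono, bp)
  expect_true(all(resm$p == 1) && all(resm$degenerate))
})

test_that("scan cost is driven by distinct tables: cache hit-rate > 90%", {
  gm <- filter_biallelic(random_gm(m = 10000, s = 24, missing_rate = 0,
                                   seed = 8))
  bp <- binary_phenotype(setNames(
    rep(c("low", "high"), c(5, 19)), gm$strains))
  fisher_cache_reset()
  assoc_scan(gm, bp)
  expect_gt(fisher_cache_stats()$hit_rate, 0.9)
})

test_that("disjoint strain sets error; partial overlap warns", {
  gm <- random_gm(m = 5, s = 4, seed = 2)
  bp <- binary_phenotype(c(X1 = "low", X2 = "high"))
  expect_error(assoc_scan(gm, bp), "no overlap")
  bp2 <- binary_phenotype(setNames(c("low", "high", "high"),
                                   c(gm$strains[1:2], "X9")))
  expect_warning(assoc_scan(gm, bp2), "dropping 1")
})
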