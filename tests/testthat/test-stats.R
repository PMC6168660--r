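test_that("normality screening calibrates on normal and exponential samples", {
  normal_hits <- withr::with_seed(80, {
    mean(vapply(1:100, function(i)
      check_normality(rnorm(1000))$decision == "normal", logical(1)))
  })
  expect_gte(normal_hits, 0.9)
  expo_hits <- withr::with_seed(81, {
    mean(vapply(1:100, function(i)
      check_normality(rexp(1000))$decision == "non-normal", logical(1)))
  })
  expect_gte(expo_hits, 0.99)
  expect_error(check_normality(c(1, 2, 3)), "sample-size")
})

test_that("Friedman statistic hits its closed forms", {
  # identical conditions: no rank variation
  m0 <- matrix(rep(c(1, 2, 3, 4, 5), 3), nrow = 5)
  r0 <- friedman_test(m0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # maximal concordance, k = 3, n = 10: statistic = n (k - 1) = 20
  m1 <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10) +
    matrix(rnorm(30, sd = 0.01), nrow = 10)
  m1 <- t(apply(m1, 1, sort))
  expect_equal(friedman_test(m1)$statistic, 20)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)), "design error")
})

test_that("Friedman agrees with the base implementation and the exact null", {
  withr::with_seed(82, {
    for (i in 1:10) {
      m <- matrix(rnorm(19 * 5), 19, 5)
      mine <- friedman_test(m)
      base <- stats::friedman.test(m)
      expect_equal(mine$statistic, unname(base$statistic))
      expect_equal(mine$p, base$p.value)
    }
  })
  # exact enumeration over all (3!)^5 rank tables of a fixed 5 x 3 design
  m <- withr::with_seed(83, matrix(rnorm(15, sd = 1), 5, 3) +
                          rep(c(0, 0.8, 1.6), each = 5))
  exact_p <- friedman_exact_oracle(m)
  expect_lt(abs(friedman_test(m)$p - exact_p), 0.02)
})

test_that("Friedman holds its nominal type-I error", {
  rej <- withr::with_seed(84, {
    mean(vapply(1:2000, function(i)
      friedman_test(matrix(rnorm(19 * 7), 19, 7))$p < 0.05, logical(1)))
  })
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Wilcoxon signed-rank matches exact enumeration and its approximation", {
  # forced case: n = 5, all differences positive
  w <- wilcoxon_signed_rank(6:10, 1:5)
  expect_equal(w$p, 0.0625)
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "degenerate")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), c(0, 1, 2, 3)),
               "sample-size")
  approx_err <- withr::with_seed(85, {
    vapply(1:5, function(i) {
      a <- rnorm(12); b <- rnorm(12)
      w <- wilcoxon_signed_rank(a, b)
      expect_equal(w$p, wilcoxon_exact_oracle(a, b))
      abs(2 * pnorm(-abs(w$z)) - w$p)
    }, numeric(1))
  })
  # the continuity-corrected normal approximation tracks the exact
  # enumeration closely for a typical n = 12 sample (individual draws
  # can sit a few thousandths above the typical error)
  expect_lt(median(approx_err), 0.01)
  expect_lt(max(approx_err), 0.05)
  # cross-check against base R in the approximation regime
  withr::with_seed(86, {
    a <- rnorm(30); b <- rnorm(30)
    w <- wilcoxon_signed_rank(a, b)
    base <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                               correct = TRUE)
    expect_equal(w$p, base$p.value, tolerance = 1e-10)
  })
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.010, 0.040, 0.030)), c(0.030, 0.060, 0.060))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_error(holm_adjust(c(0.1, 1.2)), "value error")
  withr::with_seed(87, {
    for (i in 1:20) {
      p <- runif(sample(2:8, 1))
      h <- holm_adjust(p)
      expect_true(all(h >= p))
      expect_true(all(h <= pmin(1, p * length(p)))) # dominates Bonferroni
    }
  })
})

test_that("quartile splitting follows the remainder rule and ignores labels", {
  q252 <- quartile_split(1:252)
  expect_equal(as.vector(table(q252)), rep(63L, 4))
  q10 <- quartile_split(sample(1:10))
  expect_equal(as.vector(table(q10)), c(3L, 3L, 2L, 2L))
  # assignment depends only on session order
  so <- sample(1:20)
  expect_identical(quartile_split(so), quartile_split(so))
  expect_error(quartile_split(1:3), "sample error")
  expect_error(quartile_split(c(1, 1, 2, 3)), "strict order")
})

test_that("the paired JZS Bayes factor matches the quadrature oracle", {
  for (t in 0:4) {
    bf <- jzs_bf_t(t, 19)
    oracle <- jzs_bf_oracle(t, 19)
    expect_lt(abs(bf - oracle) / oracle, 1e-4)
  }
  expect_lt(jzs_bf_t(0, 19), 1)
  # strictly increasing in |t|
  bfs <- vapply(0:4, function(t) jzs_bf_t(t, 19), numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("evidence for a fixed effect accumulates with sample size", {
  bf_at <- function(n) {
    z <- qnorm(seq(0.5 / n, 1 - 0.5 / n, length.out = n)) # deterministic
    d <- 0.5 + z / sd(z)
    jzs_bf_paired(d, rep(0, n))
  }
  bfs <- vapply(c(10, 50, 200), bf_at, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_gt(bfs[3], 100)
  expect_error(jzs_bf_paired(1:5, 1:5 + 1), "degenerate")
})

test_that("the repeated-measures Bayes factor is calibrated", {
  null_bfs <- withr::with_seed(88, {
    vapply(1:100, function(i)
      bf_one_way_rm(matrix(rnorm(19 * 5), 19, 5), seed = i)$bf10, numeric(1))
  })
  expect_lt(median(null_bfs), 1)
  eff_bfs <- withr::with_seed(89, {
    vapply(1:100, function(i) {
      eff <- rep(seq(-1, 1, length.out = 5), each = 19)
      bf_one_way_rm(matrix(rnorm(19 * 5) + eff, 19, 5), seed = i)$bf10
    }, numeric(1))
  })
  expect_gte(mean(eff_bfs > 10), 0.95)
  expect_error(bf_one_way_rm(matrix(rnorm(20), 4, 5), draws = 100),
               "precision error")
})

test_that("Monte Carlo error of the RM Bayes factor shrinks like sqrt(draws)", {
  m <- withr::with_seed(90, matrix(rnorm(19 * 5), 19, 5))
  se1 <- mean(vapply(1:10, function(i)
    bf_one_way_rm(m, draws = 10000, seed = i)$mcse_log, numeric(1)))
  se2 <- mean(vapply(1:10, function(i)
    bf_one_way_rm(m, draws = 40000, seed = i)$mcse_log, numeric(1)))
  expect_gt(se1 / se2, 1.6)
  expect_lt(se1 / se2, 2.6)
})

test_that("Bayes factor bands follow the conventional thresholds", {
  expect_equal(interpret_bf(0.14), "moderate evidence for the null")
  expect_equal(interpret_bf(26.89), "strong evidence for the alternative")
  expect_equal(interpret_bf(1.0), "inconclusive")
  # boundaries belong to the lower band
  expect_equal(interpret_bf(0.1), "strong evidence for the null")
  expect_equal(interpret_bf(0.33), "moderate evidence for the null")
  expect_equal(interpret_bf(3), "inconclusive")
  expect_equal(interpret_bf(10), "moderate evidence for the alternative")
  expect_error(interpret_bf(0), "value error")
  expect_error(interpret_bf(-2), "value error")
})

test_that("cluster permutation test finds planted topographic effects", {
  labs <- default_channel_labels(64)
  pos <- montage_positions(labs)
  planted <- match(c("P3", "P1", "Pz", "P2", "P4", "CPz"), labs)
  hits <- withr::with_seed(91, {
    vapply(1:40, function(i) {
      D <- matrix(rnorm(19 * 64), 19, 64)
      D[, planted] <- D[, planted] + 1
      res <- cluster_permutation_test(D, pos, n_perm = 1000, seed = i)
      sig <- which(res$clusters$significant)
      if (length(sig) == 0) return(FALSE)
      found <- unlist(res$cluster_channels[sig])
      length(intersect(found, planted)) >= 4
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cluster permutation test degenerates gracefully", {
  pos <- montage_positions(default_channel_labels(64))
  res <- cluster_permutation_test(matrix(0, 19, 64) , pos, n_perm = 500,
                                  seed = 1)
  expect_equal(nrow(res$clusters), 0L)
  expect_error(cluster_permutation_test(matrix(rnorm(4 * 64), 4, 64), pos),
               "at least 5")
  expect_error(cluster_permutation_test(matrix(rnorm(19 * 64), 19, 64), pos,
                                        n_perm = 100), "precision error")
})
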