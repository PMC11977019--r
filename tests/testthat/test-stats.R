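test_that("Friedman statistic matches the closed form on hand fixtures", {
  # two subjects ranking three models identically: rank sums (2, 4, 6)
  m <- rbind(c(0.9, 0.7, 0.5), c(0.8, 0.6, 0.4))
  fr <- friedman_test(m)
  expect_equal(fr$statistic, 4)
  expect_equal(fr$dof, 2L)

  tied <- matrix(0.5, nrow = 4, ncol = 3)
  fr0 <- friedman_test(tied)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_value, 1)

  expect_error(friedman_test(cbind(1:4, 2:5)), "wilcoxon|Wilcoxon")
})

test_that("Friedman is rank-based: invariant to monotone transforms", {
  set.seed(51)
  m <- matrix(runif(30), 10, 3)
  expect_equal(friedman_test(exp(m))$statistic, friedman_test(m)$statistic)
  expect_equal(friedman_test(m^3)$statistic, friedman_test(m)$statistic)
})

test_that("Friedman agrees with stats::friedman.test on tie-free data", {
  set.seed(52)
  for (i in 1:5) {
    m <- matrix(sample(1:1000, 24), 8, 3)
    ref <- stats::friedman.test(m)
    fr <- friedman_test(m)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(fr$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("Friedman p is calibrated against a permutation null", {
  # n = 10, k = 3 with a genuine effect: in the rejection region, where
  # the decision is made, the chi-squared reference must agree with the
  # permutation null. (In the middle of the null distribution the
  # chi-squared approximation is coarser at this n because the exact
  # distribution is lumpy; tail calibration is what the test uses.)
  set.seed(53)
  m <- matrix(runif(30), 10, 3)
  m[, 1] <- m[, 1] + 0.45
  obs <- friedman_test(m)$statistic
  perm <- replicate(4000, {
    shuffled <- t(apply(m, 1, sample))
    friedman_test(shuffled)$statistic
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(friedman_test(m)$p_value - p_perm), 0.02)

  # and across the whole range the two p-values stay rank-consistent
  set.seed(59)
  chi_p <- perm_p <- numeric(6)
  for (i in 1:6) {
    mi <- matrix(runif(30), 10, 3)
    mi[, 1] <- mi[, 1] + (i - 1) * 0.15
    chi_p[i] <- friedman_test(mi)$p_value
    stat <- friedman_test(mi)$statistic
    null <- replicate(800, friedman_test(t(apply(mi, 1, sample)))$statistic)
    perm_p[i] <- mean(null >= stat - 1e-12)
  }
  expect_gt(cor(rank(chi_p), rank(perm_p)), 0.9)
})

test_that("Wilcoxon signed-rank is exact on small samples", {
  w <- wilcoxon_signed_rank(2:11, 1:10)
  expect_equal(w$statistic, 55)
  expect_equal(w$p_value, 2 / 1024)

  expect_warning(w0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(w0$p_value, 1)
  expect_equal(w0$statistic, 0)
})

test_that("exact Wilcoxon p equals the sign-pattern enumeration oracle", {
  set.seed(54)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    a <- runif(n); b <- runif(n)
    if (i %% 3 == 0) b <- a + sample(c(-2, -1, 1, 2), n, TRUE) / 10  # ties
    w <- wilcoxon_signed_rank(a, b)
    expect_equal(w$p_value, wilcoxon_enumeration_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon matches stats::wilcox.test without ties", {
  set.seed(55)
  for (i in 1:5) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    w <- wilcoxon_signed_rank(a, b)
    expect_equal(w$statistic, unname(ref$statistic))
    expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation tracks the reference", {
  set.seed(56)
  a <- rnorm(40); b <- rnorm(40, 0.3)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  w <- wilcoxon_signed_rank(a, b)
  expect_false(w$exact)
  expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("Benjamini-Hochberg adjusts by the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(57)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- benjamini_hochberg(p)
    # independent step-up oracle
    m <- length(p); o <- order(p)
    oracle <- numeric(m)
    oracle[o] <- rev(cummin(rev(m * p[o] / seq_len(m))))
    expect_equal(adj, pmin(1, oracle), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_equal(benjamini_hochberg(adj), benjamini_hochberg(adj))
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("model comparison mirrors the report structure", {
  set.seed(58)
  subjects <- sprintf("video_%02d", 1:10)
  dominant <- tibble::tibble(
    subject = rep(subjects, 3),
    model = rep(c("model1", "model2", "model3"), each = 10),
    f1 = c(runif(10, 0.9, 1.0), runif(10, 0.5, 0.7), runif(10, 0.45, 0.72)))

  rep3 <- compare_models(dominant, metrics = "f1")
  expect_equal(sum(rep3$test == "friedman"), 1L)
  expect_equal(sum(rep3$test == "wilcoxon"), 3L)
  expect_lt(rep3$p_value[rep3$test == "friedman"], 0.05)
  padj <- rep3[rep3$test == "wilcoxon", ]
  worst <- padj$p_adjusted[padj$comparison == "model2 vs model3"]
  expect_true(all(padj$p_adjusted[padj$comparison != "model2 vs model3"] <
                    worst))

  rep2 <- compare_models(dominant[dominant$model != "model3", ],
                         metrics = "f1")
  expect_equal(sum(rep2$test == "friedman"), 0L)
  expect_equal(sum(rep2$test == "wilcoxon"), 1L)

  same <- dominant
  same$f1 <- rep(runif(10), 3)
  suppressWarnings(rep_same <- compare_models(same, metrics = "f1"))
  expect_true(all(rep_same$p_adjusted >= 0.05, na.rm = TRUE))
})

test_that("test objects tidy into one-row tibbles", {
  td <- tidy(friedman_test(rbind(c(1, 2, 3), c(1, 2, 3))))
  expect_s3_class(td, "tbl_df")
  expect_equal(td$statistic, 4)
  expect_equal(td$dof, 2L)
  gl <- glance(wilcoxon_signed_rank(2:11, 1:10))
  expect_equal(gl$statistic, 55)
})
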