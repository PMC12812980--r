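test_that("spearman_rho is the Pearson correlation of average ranks", {
  expect_equal(spearman_rho(1:8, (1:8)^2), 1)          # monotone transform
  expect_equal(spearman_rho(1:8, rev(1:8)), -1)
  # tie-aware value frozen from the hand oracle (and base R agrees)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  expect_equal(spearman_rho(x, y), 0.9486833, tolerance = 1e-7)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  # invariance under strictly monotone transforms of either argument
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b), tolerance = 1e-12)
    expect_equal(spearman_rho(a, 3 * b + 1), spearman_rho(a, b), tolerance = 1e-12)
  }
  const <- spearman_rho(rep(1, 5), 1:5)
  expect_true(is.na(const))
  expect_true(attr(const, "undefined"))
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("correlation matrix covers all pairs with exact small-sample p-values", {
  # three taxa sharing one rank order: all three pairs perfectly correlated
  counts <- tibble::tibble(taxon_id = c("a", "b", "c"),
                           s1 = c(1, 10, 100), s2 = c(2, 20, 200),
                           s3 = c(3, 30, 300), s4 = c(4, 40, 400),
                           s5 = c(5, 50, 500))
  cm <- correlation_matrix(counts)
  expect_equal(nrow(cm), 3)
  expect_equal(cm$rho, rep(1, 3))
  # n = 5 < 10: the p-value is the exact two-sided permutation value; for a
  # perfect monotone pair that is 2/5! twice (rho = +-1) = 2/120
  expect_equal(cm$p, rep(2 / 120, 3))
  expect_error(correlation_matrix(counts[, 1:4]), "at least 4 samples")
})

test_that("exact permutation p agrees with cor.test on tie-free data", {
  set.seed(33)
  x <- rnorm(7); y <- rnorm(7)
  counts <- tibble::tibble(taxon_id = c("a", "b"), !!!setNames(as.list(as.data.frame(rbind(x, y))), paste0("s", 1:7)))
  p_pkg <- correlation_matrix(counts)$p
  p_ref <- cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("t-approximation p-values are calibrated under the null", {
  set.seed(55)
  # independent noise: the fraction of p < 0.05 should sit near 0.05
  reps <- 40
  hits <- numeric(reps)
  for (i in seq_len(reps)) {
    m <- matrix(rnorm(10 * 20), 10, 20)
    counts <- dplyr::bind_cols(tibble::tibble(taxon_id = paste0("t", 1:10)),
                               tibble::as_tibble(m, .name_repair = ~paste0("s", 1:20)))
    hits[i] <- mean(correlation_matrix(counts)$p < 0.05)
  }
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("BH adjustment equals the sort-definition oracle and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    # step-up property: sorted q is monotone in sorted p
    expect_true(all(diff(q[order(p)]) > -1e-12))
  }
  # NA entries pass through without joining the adjustment
  q <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_fdr(c(0.01, 0.04)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mantel test recovers identity and relabeling invariance", {
  d <- random_distance(8, seed = 41)
  r <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 100)  # resolution 1/(n_perm+1), identity is maximal
  # joint relabeling of both matrices leaves r at 1
  idx <- sample(8)
  r2 <- mantel_test(d[idx, idx], d[idx, idx], n_perm = 99, seed = 1)
  expect_equal(r2$r, 1)
  expect_error(mantel_test(d, d[1:7, 1:7]), "same dimension")
  dd <- d; dd[1, 2] <- dd[1, 2] + 1
  expect_error(mantel_test(dd, d), "symmetric")
})

test_that("exhaustive Mantel at n = 4 equals full 24-permutation enumeration", {
  set.seed(17)
  for (i in 1:5) {
    d1 <- random_distance(4)
    d2 <- random_distance(4)
    r <- mantel_test(d1, d2, exhaustive = TRUE)
    expect_equal(r$n_perm, 24)
    expect_equal(r$p, oracle_mantel_exact(d1, d2))
  }
})

test_that("Mantel permutation p-values are reproducible and well-formed", {
  d1 <- random_distance(10, seed = 2)
  d2 <- random_distance(10, seed = 3)
  a <- mantel_test(d1, d2, n_perm = 199, seed = 7)
  b <- mantel_test(d1, d2, n_perm = 199, seed = 7)
  expect_identical(a$r, b$r)
  expect_identical(a$p, b$p)
  expect_gt(a$p, 0)
  expect_lte(a$p, 1)
  expect_equal((a$p * (1 + 199)) %% 1, 0)  # resolution 1/(n_perm+1)
})

test_that("Mantel null p-values are super-uniform at the stated resolution", {
  set.seed(99)
  ps <- vapply(1:500, function(i) {
    d1 <- random_distance(7)
    d2 <- random_distance(7)
    mantel_test(d1, d2, n_perm = 99, seed = i)$p
  }, 1)
  grid <- seq(0.01, 1, by = 0.01)
  ecdf_vals <- vapply(grid, function(x) mean(ps <= x), 1)
  # one-sided KS-style bound: empirical CDF may not exceed uniform by more
  # than the 99% KS deviation for 500 draws
  expect_lt(max(ecdf_vals - grid), 1.63 / sqrt(500))
})

test_that("partial Mantel removes the control matrix linearly", {
  d1 <- random_distance(9, seed = 10)
  d2 <- random_distance(9, seed = 11)
  dc0 <- matrix(1, 9, 9); diag(dc0) <- 0  # constant off-diagonal: nothing to remove
  pm <- partial_mantel(d1, d2, dc0, n_perm = 99, seed = 1)
  mt <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  expect_equal(pm$r, mt$r, tolerance = 1e-9)
  # controlling for d2 itself leaves nothing
  self <- partial_mantel(d1, d2, d2, n_perm = 99, seed = 1)
  expect_lt(abs(self$r), 0.3)
})

test_that("partial Mantel recovers planted structure over a confounder", {
  set.seed(23)
  n <- 20
  z <- matrix(rnorm(n), ncol = 1)
  dc <- as.matrix(dist(z))
  d2 <- as.matrix(dist(rnorm(n)))
  noise <- as.matrix(dist(rnorm(n, sd = 0.3)))
  d1 <- 1.5 * d2 + 1 * dc + noise
  r <- partial_mantel(d1, d2, dc, n_perm = 999, seed = 5)
  expect_gt(r$r, 0)
  expect_lt(r$p, 0.05)
})

test_that("environment-community correlation flags constants and finds planted signals", {
  d <- random_distance(10, seed = 5)
  res <- env_community_correlation(rep(2, 10), d, n_perm = 99, seed = 1)
  expect_true(res$undefined)
  expect_true(is.na(res$r))
  # community distance monotone in |env_i - env_j|
  set.seed(31)
  env <- rnorm(20)
  comm <- as.matrix(dist(env))^1.3 + as.matrix(dist(rnorm(20, sd = 0.2)))
  r <- env_community_correlation(env, comm, n_perm = 999, seed = 2)
  expect_gt(r$r, 0)
  expect_lte(r$p, 0.05)
})

test_that("env-community null calibration: p below alpha at the nominal rate", {
  set.seed(77)
  ps <- vapply(1:200, function(i) {
    env <- rnorm(12)
    comm <- as.matrix(dist(rnorm(12)))
    env_community_correlation(env, comm, n_perm = 99, seed = i)$p
  }, 1)
  # binomial tolerance: 3 * sqrt(.05 * .95 / 200) ~ 0.046
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.05)
})
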