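test_that("Mahalanobis distance matches explicit pooled-covariance arithmetic on a 2D toy", {
  # 3 + 3 points, every quantity computable by hand
  A <- rbind(c(0, 0), c(1, 0), c(0, 1))
  B <- rbind(c(4, 4), c(5, 4), c(4, 5))
  X <- rbind(A, B)
  g <- rep(c("a", "b"), each = 3)
  fit <- pairwise_dfa(X, g, "a", "b", n_permutations = 0)
  # independent arithmetic: pooled covariance from group-centred scatter
  Sa <- crossprod(sweep(A, 2, colMeans(A)))
  Sb <- crossprod(sweep(B, 2, colMeans(B)))
  pooled <- (Sa + Sb) / (6 - 2)
  diff <- colMeans(A) - colMeans(B)
  d2 <- drop(t(diff) %*% solve(pooled) %*% diff)
  expect_equal(fit$mahalanobis_sq, d2, tolerance = 1e-9)
  expect_equal(fit$mahalanobis_distance, sqrt(d2), tolerance = 1e-9)
  expect_equal(fit$subspace_dim, 2L)
})

test_that("well-separated groups classify perfectly with a tiny permutation p", {
  set.seed(50)
  X <- rbind(matrix(rnorm(20 * 8, 0, 1), 20),
             matrix(rnorm(20 * 8, 10, 1), 20))  # shift 10x within-group SD
  g <- rep(c("a", "b"), each = 20)
  fit <- pairwise_dfa(X, g, "a", "b", n_permutations = 999, seed = 1)
  expect_equal(sum(diag(fit$loo_table)), 40)
  expect_lte(fit$permutation_p, 0.001)
  expect_equal(sum(fit$loo_table), 40)
})

test_that("Mahalanobis distance is invariant to invertible affine maps", {
  set.seed(51)
  X <- rbind(matrix(rnorm(15 * 6), 15), matrix(rnorm(15 * 6, 1), 15))
  g <- rep(c("a", "b"), each = 15)
  d0 <- pairwise_dfa(X, g, "a", "b", n_permutations = 0,
                     subspace_dim = 6)$mahalanobis_distance
  for (i in 1:5) {
    M <- matrix(rnorm(36), 6)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(36), 6)
    d1 <- pairwise_dfa(X %*% M + 2, g, "a", "b", n_permutations = 0,
                       subspace_dim = 6)$mahalanobis_distance
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})

test_that("permutation p is bit-reproducible under a fixed seed and varies across seeds", {
  set.seed(52)
  X <- matrix(rnorm(24 * 5), 24)
  g <- rep(c("a", "b"), each = 12)
  p1 <- pairwise_dfa(X, g, "a", "b", 199, seed = 7)$permutation_p
  p2 <- pairwise_dfa(X, g, "a", "b", 199, seed = 7)$permutation_p
  expect_identical(p1, p2)
  ps <- vapply(1:8, function(s) {
    pairwise_dfa(X, g, "a", "b", 199, seed = s)$permutation_p
  }, numeric(1))
  expect_gt(length(unique(ps)), 1)
})

test_that("LOO genuinely excludes the held-out observation", {
  # an extreme outlier is misassigned under LOO but would anchor its own
  # group if it leaked into the refit
  set.seed(53)
  X <- rbind(matrix(rnorm(10 * 4, 0, 0.5), 10),
             matrix(rnorm(10 * 4, 3, 0.5), 10),
             matrix(5 + rnorm(4, 0, 0.01), 1))  # labelled "a", sits past "b"
  g <- c(rep("a", 10), rep("b", 10), "a")
  fit <- pairwise_dfa(X, g, "a", "b", n_permutations = 0, subspace_dim = 4)
  expect_equal(fit$loo$assigned[21], "b")
})

test_that("LOO classifications agree with MASS equal-prior cross-validated LDA", {
  skip_if_not_installed("MASS")
  set.seed(54)
  X <- rbind(matrix(rnorm(18 * 4, 0, 1), 18), matrix(rnorm(18 * 4, 1.2, 1), 18))
  g <- rep(c("a", "b"), each = 18)
  fit <- pairwise_dfa(X, g, "a", "b", n_permutations = 0, subspace_dim = 4)
  ld <- MASS::lda(X, grouping = factor(g), prior = c(0.5, 0.5), CV = TRUE)
  agree <- mean(fit$loo$assigned == as.character(ld$class))
  expect_gte(agree, 0.94)
})

test_that("group-swap with a null movable group gives near-equal distances", {
  set.seed(55)
  X <- matrix(rnorm(45 * 6), 45)
  g <- c(rep("a", 20), rep("b", 20), rep("m", 5))
  sw <- group_swap_dfa(X, g, "m", "a", "b", n_permutations = 0,
                       subspace_dim = 6, seed = 1)
  r <- abs(log(sw$in_a$mahalanobis_distance / sw$in_b$mahalanobis_distance))
  expect_lt(r, 1.5)  # same order of magnitude under the symmetric null
})

test_that("group-swap identifies the distribution the movable group came from", {
  # movable drawn from host_a's distribution: placing it there gives the
  # larger distance; misplacing it triggers reassignments
  set.seed(56)
  X <- rbind(matrix(rnorm(20 * 6, 0, 1), 20),
             matrix(rnorm(20 * 6, 4, 1), 20),
             matrix(rnorm(5 * 6, 0, 1), 5))
  g <- c(rep("a", 20), rep("b", 20), rep("m", 5))
  sw <- group_swap_dfa(X, g, "m", "a", "b", n_permutations = 0,
                       subspace_dim = 6, seed = 2)
  expect_gt(sw$in_a$mahalanobis_distance, sw$in_b$mahalanobis_distance)
  expect_equal(sw$movable_misassigned[["in_a"]], 0L)
  expect_gte(sw$movable_misassigned[["in_b"]], 1L)
})

test_that("missing groups and degenerate sizes raise errors", {
  X <- matrix(rnorm(40), 10)
  g <- rep(c("a", "b"), each = 5)
  expect_error(pairwise_dfa(X, g, "a", "zzz"), "no observations")
  expect_error(pairwise_dfa(X[1:3, ], g[c(1, 2, 6)], "a", "b"), "at least")
  fitg <- gpa(simulate_skulls(skull_config(group_sizes = c(4, 4), seed = 57)))
  expect_error(pairwise_dfa(fitg, "nope", "a", "b"), "not found")
})

test_that("glance and tidy expose the DFA result tables", {
  set.seed(58)
  X <- rbind(matrix(rnorm(12 * 4), 12), matrix(rnorm(12 * 4, 2), 12))
  g <- rep(c("a", "b"), each = 12)
  fit <- pairwise_dfa(X, g, "a", "b", 99, seed = 3)
  gl <- glance(fit)
  expect_equal(gl$loo_total, 24L)
  expect_equal(nrow(tidy(fit)), 24L)
  expect_s3_class(autoplot(fit), "ggplot")
})
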