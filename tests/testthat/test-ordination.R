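test_that("species pooling is passthrough for singletons and idempotent for duplicates", {
  sk <- simulate_skulls(skull_config(group_sizes = 3, species_counts = 3,
                                     seed = 30))
  fit <- gpa(sk)
  pooled <- pool_by_species(fit)
  # one specimen per species: pooled tangent row equals the specimen's
  expect_equal(unname(pooled$tangent), unname(fit$tangent), tolerance = 1e-9)
  # duplicate a specimen into a two-member species: mean equals either copy
  sk2 <- dplyr::bind_rows(sk, dplyr::mutate(
    dplyr::filter(sk, specimen_id == sk$specimen_id[1]),
    specimen_id = "dup"))
  fit2 <- gpa(sk2)
  pooled2 <- pool_by_species(fit2)
  sp1 <- fit2$meta$taxon[1]
  expect_equal(pooled2$tangent[pooled2$meta$specimen_id == sp1, ],
               fit2$tangent[1, ], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("species means match direct coordinate averaging", {
  sk <- simulate_skulls(skull_config(group_sizes = 6, species_counts = 2,
                                     seed = 31))
  fit <- gpa(sk)
  pooled <- pool_by_species(fit)
  taxa <- fit$meta$taxon
  for (sp in unique(taxa)) {
    direct <- apply(fit$coords[, , taxa == sp, drop = FALSE], c(1, 2), mean)
    direct <- craniomorph:::center_config(direct)
    direct <- direct / sqrt(sum(direct^2))
    got <- pooled$coords[, , which(unique(taxa) == sp)]
    # up to the final re-rotation onto the consensus
    expect_lt(procrustes_distance(got, direct), 1e-6)
  }
  expect_equal(unname(pooled$centroid_sizes),
               unname(tapply(fit$centroid_sizes, taxa, mean)[unique(taxa)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCA of rank-1 data puts all variance on a PC1 parallel to the planted direction", {
  set.seed(32)
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  scores_true <- rnorm(25)
  X <- outer(scores_true, v) + 5
  res <- shape_pca(X)
  expect_equal(length(res$eigenvalues), 1L)
  expect_equal(res$variance_proportions[1], 1)
  expect_gt(abs(sum(res$loadings[1, ] * v)), 1 - 1e-9)
})

test_that("planted 4:1 variance ratio is recovered in variance proportions", {
  # oracle: analytic proportions of the generating covariance are 0.8 / 0.2
  set.seed(33)
  u <- c(1, rep(0, 19)); w <- c(0, 1, rep(0, 18))
  X <- outer(rnorm(500, 0, 2), u) + outer(rnorm(500, 0, 1), w)
  res <- shape_pca(X)
  expect_equal(res$variance_proportions[1], 0.8, tolerance = 0.05)
  expect_equal(res$variance_proportions[2], 0.2, tolerance = 0.05)
  expect_equal(sum(res$variance_proportions), 1, tolerance = 1e-9)
})

test_that("PCA bookkeeping: orthonormal loadings, zero-mean scores, full reconstruction", {
  set.seed(34)
  X <- matrix(rnorm(20 * 12), 20)
  res <- shape_pca(X)
  L <- res$loadings
  expect_equal(L %*% t(L), diag(nrow(L)), tolerance = 1e-9)
  S <- as.matrix(res$scores[, grepl("^PC", names(res$scores))])
  expect_lt(max(abs(colMeans(S))), 1e-9)
  rec <- S %*% L + rep(res$mean_vector, each = nrow(X))
  expect_equal(rec, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
})

test_that("PCA eigenvalues are invariant to pre-rotations of the raw specimens", {
  sk <- simulate_skulls(skull_config(group_sizes = 8, seed = 35))
  ev1 <- shape_pca(gpa(sk))$eigenvalues
  ev2 <- shape_pca(gpa(apply_rigid_motions(sk, 351)))$eigenvalues
  expect_equal(ev1, ev2, tolerance = 1e-8)
})

test_that("loading signs are deterministic (largest element positive)", {
  set.seed(36)
  X <- matrix(rnorm(15 * 8), 15)
  res <- shape_pca(X)
  for (j in seq_len(nrow(res$loadings))) {
    expect_gt(res$loadings[j, which.max(abs(res$loadings[j, ]))], 0)
  }
})

test_that("shape models reconstruct the consensus at score 0 and are linear in score", {
  sk <- simulate_skulls(skull_config(group_sizes = 10, seed = 37))
  fit <- gpa(sk)
  res <- shape_pca(fit)
  m0 <- shape_model(res, 1, 0)
  expect_equal(as.vector(t(m0)), unname(res$mean_vector), tolerance = 1e-12)
  mp <- shape_model(res, 2, 0.07)
  mm <- shape_model(res, 2, -0.07)
  expect_equal((mp + mm) / 2, m0, tolerance = 1e-12)
  # rank-1 reconstruction of the highest-scoring observation
  S <- as.matrix(res$scores[, grepl("^PC", names(res$scores))])
  i <- which.max(S[, 1])
  rec <- shape_model(res, 1, S[i, 1])
  direct <- craniomorph:::unflatten_config(
    res$mean_vector + S[i, 1] * res$loadings[1, ])
  expect_equal(rec, direct, tolerance = 1e-12)
  expect_error(shape_model(res, 999, 0), "out of range")
})

test_that("PC1 separates planted groups when effect is 5x noise", {
  # effect magnitude 5x the total noise magnitude sqrt(3k) * sigma
  sigma <- 0.004
  delta <- 5 * sqrt(99) * sigma
  sk <- simulate_skulls(skull_config(group_sizes = c(15, 15),
                                     effect_size = delta, noise_sd = sigma,
                                     seed = 38))
  res <- shape_pca(gpa(sk))
  s1 <- res$scores$PC1
  g <- res$scores$group
  btw <- (mean(s1[g == "group_1"]) - mean(s1[g == "group_2"]))^2
  wth <- mean(tapply(s1, g, var))
  expect_gt(btw / wth, 5)
})

test_that("PCA refuses a single observation", {
  expect_error(shape_pca(matrix(rnorm(10), 1)), "at least 2")
})
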