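test_that("centroid size has its closed form, homogeneity, and degenerate limit", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroid_size(sq), sqrt(8))
  set.seed(1)
  m <- matrix(rnorm(30), 10)
  expect_equal(centroid_size(m * 3.7), 3.7 * centroid_size(m))
  expect_equal(centroid_size(matrix(c(2, 5, -1), 1)), 0)
  expect_error(centroid_size(matrix(NA_real_, 2, 3)), "missing")
})

test_that("optimal superimposition recovers exact rotations with zero residual", {
  set.seed(2)
  src <- craniomorph:::center_config(matrix(rnorm(24), 8))
  rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 degrees about z
  fit <- optimal_superimposition(src, src %*% rz)
  expect_equal(fit$rotation, rz, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-18)
  same <- optimal_superimposition(src, src)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  expect_error(optimal_superimposition(src * 0, src), "zero size")
})

test_that("SVD rotation matches brute-force search over Euler angles", {
  set.seed(3)
  src <- craniomorph:::center_config(matrix(rnorm(12), 4))
  tgt <- craniomorph:::center_config(src %*% random_proper_rotation() +
                                       matrix(rnorm(12, 0, 0.1), 4))
  fit <- optimal_superimposition(src, tgt)
  # independent oracle: exhaustive grid over ZYZ Euler angles (6 deg steps)
  ang <- seq(0, 2 * pi, by = pi / 30)
  bng <- seq(0, pi, by = pi / 30)
  rotz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  roty <- function(b) rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  best <- Inf
  for (a in ang) for (b in bng) {
    ra <- src %*% rotz(a) %*% roty(b)
    for (c2 in ang) {
      r <- ra %*% rotz(c2)
      best <- min(best, sum((r - tgt)^2))
    }
  }
  expect_lte(fit$residual, best + 1e-12)
  # 6-degree grid: excess residual bounded by |src|^2 * (grid half-step)^2
  grid_tol <- sum(src^2) * (pi / 30)^2
  expect_lt(best - fit$residual, grid_tol)
})

test_that("GPA collapses similarity copies of one shape onto it", {
  tpl <- template_skull(scheme33, 1)
  sk <- simulate_skulls(skull_config(group_sizes = 6, noise_sd = 0,
                                     effect_size = 0, seed = 13))
  fit <- gpa(sk)
  for (i in seq_len(6)) {
    expect_lt(max(abs(fit$coords[, , i] - fit$coords[, , 1])), 1e-8)
  }
  expect_lt(procrustes_distance(fit$consensus, tpl), 1e-9)
  expect_true(fit$converged)
})

test_that("aligned configurations are centred with unit centroid size; consensus is their mean", {
  sk <- simulate_skulls(skull_config(group_sizes = c(6, 6), seed = 14))
  fit <- gpa(sk)
  for (i in seq_len(dim(fit$coords)[3])) {
    expect_lt(max(abs(colMeans(fit$coords[, , i]))), 1e-9)
    expect_equal(centroid_size(fit$coords[, , i]), 1, tolerance = 1e-9)
  }
  expect_equal(fit$consensus, apply(fit$coords, c(1, 2), mean),
               tolerance = 1e-9)
  expect_true(all(fit$centroid_sizes > 0))
})

test_that("two-shape GPA agrees with direct ordinary Procrustes", {
  set.seed(15)
  sk <- simulate_skulls(skull_config(group_sizes = 2, seed = 15))
  fit <- gpa(sk)
  d_gpa <- procrustes_distance(fit$coords[, , 1], fit$coords[, , 2])
  a <- craniomorph:::as_shape_array(sk, scheme33)$coords
  d_opa <- procrustes_distance(a[, , 1], a[, , 2])
  expect_equal(d_gpa, d_opa, tolerance = 1e-6)
})

test_that("GPA output is invariant to rigid motions and scalings of the input", {
  sk <- simulate_skulls(skull_config(group_sizes = c(5, 5), seed = 16))
  fit1 <- gpa(sk)
  sk2 <- apply_rigid_motions(sk, seed = 161)
  fit2 <- gpa(sk2)
  expect_lt(max(abs(fit1$coords - fit2$coords)), 1e-8)
  expect_lt(max(abs(fit1$tangent - fit2$tangent)), 1e-8)
})

test_that("the consensus minimises summed squared Procrustes distance", {
  sk <- simulate_skulls(skull_config(group_sizes = 8, seed = 17))
  fit <- gpa(sk)
  obj <- function(cons) {
    sum(apply(fit$coords, 3, function(x) {
      u <- cons / sqrt(sum(craniomorph:::center_config(cons)^2))
      optimal_superimposition(x, craniomorph:::center_config(u))$residual
    }))
  }
  base <- obj(fit$consensus)
  set.seed(18)
  for (j in 1:50) {
    pert <- fit$consensus + matrix(rnorm(99, 0, 1e-3), 33)
    expect_gte(obj(pert), base - 1e-10)
  }
})

test_that("tangent vectors are orthogonal to the consensus direction", {
  sk <- simulate_skulls(skull_config(group_sizes = 10, seed = 19))
  fit <- gpa(sk)
  cvec <- as.vector(t(fit$consensus))
  cvec <- cvec / sqrt(sum(cvec^2))
  expect_lt(max(abs(fit$tangent %*% cvec)), 1e-9)
})

test_that("procrustes_distance is a pseudmetric on shapes", {
  set.seed(20)
  shapes <- replicate(12, matrix(rnorm(30), 10), simplify = FALSE)
  a <- shapes[[1]]
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-9)
  for (i in 1:20) {
    tri <- sample(12, 3)
    x <- shapes[[tri[1]]]; y <- shapes[[tri[2]]]; z <- shapes[[tri[3]]]
    expect_equal(procrustes_distance(x, y), procrustes_distance(y, x),
                 tolerance = 1e-12)
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-9)
  }
})

test_that("pairwise alignment agrees with vegan's Procrustes rotation", {
  skip_if_not_installed("vegan")
  set.seed(21)
  x <- craniomorph:::center_config(matrix(rnorm(30), 10))
  y <- craniomorph:::center_config(matrix(rnorm(30), 10))
  x <- x / sqrt(sum(x^2)); y <- y / sqrt(sum(y^2))
  fit <- optimal_superimposition(y, x)
  v <- vegan::procrustes(x, y, scale = FALSE)
  if (det(v$rotation) > 0) {  # vegan permits reflections; compare when proper
    expect_equal(fit$residual, sum((y %*% v$rotation - x)^2), tolerance = 1e-8)
  }
  expect_equal(procrustes_distance(x, y)^2, fit$residual, tolerance = 1e-12)
})

test_that("GPA refuses incomplete specimens with actionable advice", {
  sk <- simulate_skulls(skull_config(group_sizes = 2, seed = 22))
  sk <- delete_landmarks(sk, 9, specimen = unique(sk$specimen_id)[1])
  expect_error(gpa(sk), "mirror_impute")
})
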