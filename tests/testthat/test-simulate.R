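test_that("the template skull is exactly symmetric, centred, and unit sized", {
  tpl <- template_skull(scheme33, 1)
  expect_equal(centroid_size(tpl), 1, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(tpl))), 1e-12)
  expect_true(all(tpl[scheme33$midline, 2] == 0))
  # reflecting in y = 0 and swapping pair members reproduces the template
  refl <- tpl
  refl[, 2] <- -refl[, 2]
  swapped <- refl
  swapped[scheme33$pairs[, 1], ] <- refl[scheme33$pairs[, 2], ]
  swapped[scheme33$pairs[, 2], ] <- refl[scheme33$pairs[, 1], ]
  expect_equal(swapped, tpl, tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- skull_config(group_sizes = c(4, 3), missingness = 0.3,
                      fossil_fraction = 0.5, allometry_size = 0.05, seed = 70)
  expect_identical(simulate_skulls(cfg), simulate_skulls(cfg))
  cfg2 <- skull_config(group_sizes = c(4, 3), seed = 71)
  expect_false(identical(simulate_skulls(cfg)$x, simulate_skulls(cfg2)$x))
})

test_that("with no noise and no effects every specimen is a rigid copy of the template", {
  tpl <- template_skull(scheme33, 1)
  sk <- simulate_skulls(skull_config(group_sizes = 5, noise_sd = 0,
                                     effect_size = 0, seed = 72))
  arr <- craniomorph:::as_shape_array(sk, scheme33)$coords
  for (i in 1:5) expect_lt(procrustes_distance(arr[, , i], tpl), 1e-9)
})

test_that("missingness hits only right-side members of fossil specimens", {
  cfg <- skull_config(group_sizes = c(10, 10), missingness = 0.5,
                      fossil_groups = "group_2", seed = 73)
  sk <- simulate_skulls(cfg)
  gone <- sk$landmark[is.na(sk$x)]
  expect_gt(length(gone), 0)
  expect_true(all(gone %in% scheme33$pairs[, 2]))
  fossil_ids <- unique(sk$specimen_id[sk$fossil])
  expect_true(all(sk$specimen_id[is.na(sk$x)] %in% fossil_ids))
  expect_setequal(unique(sk$group[sk$fossil]), "group_2")
})

test_that("generated tangent noise variance matches sigma^2 within 5%", {
  sigma <- 0.01
  sk <- simulate_skulls(skull_config(group_sizes = 1000, effect_size = 0,
                                     noise_sd = sigma, seed = 74))
  fit <- gpa(sk)
  # per-coordinate variance, over the 3k - 7 informative dimensions
  v <- procrustes_variance(fit$tangent) / (3 * 33 - 7)
  expect_equal(v, sigma^2, tolerance = 0.05)
})

test_that("a planted group separation is recovered at its magnitude by GPA + PCA", {
  delta <- 0.1
  sigma <- delta / 10
  set.seed(75)
  dir <- planted_vector(1, seed = 751)
  eff <- list(a = -dir * delta / 2, b = dir * delta / 2)
  cfg <- skull_config(group_sizes = c(a = 100, b = 100),
                      group_effect_vectors = eff, noise_sd = sigma, seed = 75)
  fit <- gpa(simulate_skulls(cfg))
  res <- shape_pca(fit)
  s <- res$scores
  sep <- sqrt(sum((colMeans(as.matrix(s[s$group == "a", grepl("^PC", names(s))])) -
                   colMeans(as.matrix(s[s$group == "b", grepl("^PC", names(s))])))^2))
  expect_equal(sep, delta, tolerance = 0.1)
})

test_that("the full pipeline separates planted groups (silhouette on two PCs)", {
  sk <- simulate_skulls(skull_config(group_sizes = c(20, 20),
                                     effect_size = 0.12, noise_sd = 0.01,
                                     missingness = 0.3, fossil_fraction = 0.3,
                                     seed = 76))
  fit <- gpa(suppressWarnings(mirror_impute(sk)))
  res <- shape_pca(fit)
  S <- as.matrix(res$scores[, c("PC1", "PC2")])
  g <- res$scores$group
  sil <- vapply(seq_len(nrow(S)), function(i) {
    d <- sqrt(rowSums(sweep(S, 2, S[i, ])^2))
    a <- mean(d[g == g[i]][-match(i, which(g == g[i]))])
    b <- mean(d[g != g[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("the study-mimic preset has the published sampling structure", {
  pre <- primate_preset(seed = 1, n_per_species = 2)
  expect_equal(unname(pre$species_counts), c(19L, 1L, 6L, 3L, 3L, 2L))
  sk <- simulate_skulls(pre)
  expect_equal(length(unique(sk$taxon)), 34L)
  expect_equal(length(unique(sk$specimen_id)), 68L)
  expect_setequal(unique(sk$clade), c("Haplorhini", "Strepsirrhini"))
  expect_true(all(sk$fossil[sk$group %in% c("Adapiformes",
                                            "fossil Lemuriformes")]))
  expect_false(any(sk$fossil[sk$group == "Anthropoidea"]))
})

test_that("config validation rejects impossible parameters", {
  expect_error(skull_config(group_sizes = 0), "group_sizes")
  expect_error(skull_config(missingness = 1.5), "missingness")
  expect_error(skull_config(noise_sd = -1), "noise_sd")
})
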