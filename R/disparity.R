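#' Procrustes variance of a group
#'
#' Morphological disparity measured as total variance: the sum over tangent
#' coordinates of their variance about the group mean, with divisor n - 1
#' (equivalently, the mean squared Procrustes tangent distance to the group
#' mean times n/(n-1)). A single observation has disparity 0.
#'
#' @param tangent_coords Numeric observation-by-coordinate matrix for one
#'   group.
#' @return Nonnegative scalar.
#' @export
procrustes_variance <- function(tangent_coords) {
  X <- rbind(tangent_coords)
  if (nrow(X) == 0) stop("empty group; disparity undefined", call. = FALSE)
  if (nrow(X) == 1) return(0)
  n <- nrow(X)
  cm <- colMeans(X)
  (sum(X^2) - n * sum(cm^2)) / (n - 1)
}

#' Disparity of every group in an aligned sample
#'
#' @param fit A `gpa_fit`.
#' @param group Name of the metadata column holding group labels.
#' @return Tibble with one row per group: `group`, `n`, `variance`.
#' @export
disparity <- function(fit, group = "group") {
  stopifnot(inherits(fit, "gpa_fit"))
  labels <- group_labels_from_meta(fit$meta, group)
  purrr::map_dfr(unique(labels), function(g) {
    tibble::tibble(
      group = g, n = sum(labels == g),
      variance = procrustes_variance(fit$tangent[labels == g, , drop = FALSE])
    )
  })
}

#' Bootstrap test for a difference in group disparity
#'
#' Tests whether two groups differ in Procrustes variance. The observed
#' statistic is `V_a - V_b`; its null distribution is built by resampling
#' observations with replacement from the pooled set into groups of the
#' original sizes, and the two-sided p-value uses the add-one estimator
#' `(1 + #{|null| >= |observed|}) / (1 + n_bootstrap)`.
#'
#' @param coords_a,coords_b Tangent-coordinate matrices of the two groups
#'   (each with at least 2 observations).
#' @param n_bootstrap Number of bootstrap resamples (default 999).
#' @param seed Integer seed.
#' @return Tibble with one row: `variance_a`, `variance_b`, `difference`,
#'   `p`, `n_bootstrap`, `seed`.
#' @export
disparity_difference_test <- function(coords_a, coords_b, n_bootstrap = 999,
                                      seed = 1) {
  if (n_bootstrap < 1) stop("n_bootstrap must be at least 1", call. = FALSE)
  A <- rbind(coords_a); B <- rbind(coords_b)
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  va <- procrustes_variance(A)
  vb <- procrustes_variance(B)
  obs <- va - vb
  pool <- rbind(A, B)
  na <- nrow(A); nb <- nrow(B); n <- na + nb
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_bootstrap)) {
    ia <- sample.int(n, na, replace = TRUE)
    ib <- sample.int(n, nb, replace = TRUE)
    nd <- procrustes_variance(pool[ia, , drop = FALSE]) -
      procrustes_variance(pool[ib, , drop = FALSE])
    if (abs(nd) >= abs(obs)) exceed <- exceed + 1L
  }
  tibble::tibble(variance_a = va, variance_b = vb, difference = obs,
                 p = (1 + exceed) / (1 + n_bootstrap),
                 n_bootstrap = n_bootstrap, seed = seed)
}

#' Test the disparity change from adding observations to a group
#'
#' Measures how much adding a set of observations (for example fossil taxa)
#' increases a group's Procrustes variance, and whether the increase is
#' significant. The statistic is `V(core + added) - V(core)`; under the
#' null that added observations are exchangeable with core ones, labels
#' are permuted on the union and the statistic recomputed, giving a
#' one-sided (increase) p-value with the add-one estimator.
#'
#' @param coords_core Tangent coordinates of the core group (>= 2 rows).
#' @param coords_added Tangent coordinates of the added observations
#'   (>= 1 row).
#' @param n_bootstrap Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble with one row: `variance_before`, `variance_after`,
#'   `difference`, `p`, `n_bootstrap`, `seed`.
#' @export
inclusion_test <- function(coords_core, coords_added, n_bootstrap = 999,
                           seed = 1) {
  if (n_bootstrap < 1) stop("n_bootstrap must be at least 1", call. = FALSE)
  core <- rbind(coords_core); add <- rbind(coords_added)
  if (nrow(core) < 2) stop("core group needs at least 2 observations",
                           call. = FALSE)
  if (nrow(add) < 1) stop("need at least 1 added observation", call. = FALSE)
  v_before <- procrustes_variance(core)
  union <- rbind(core, add)
  v_after <- procrustes_variance(union)
  obs <- v_after - v_before
  nc <- nrow(core); n <- nrow(union)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_bootstrap)) {
    perm_core <- union[sample.int(n, nc), , drop = FALSE]
    nd <- v_after - procrustes_variance(perm_core)
    if (nd >= obs) exceed <- exceed + 1L
  }
  tibble::tibble(variance_before = v_before, variance_after = v_after,
                 difference = obs, p = (1 + exceed) / (1 + n_bootstrap),
                 n_bootstrap = n_bootstrap, seed = seed)
}
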