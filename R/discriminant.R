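#' Pairwise linear discriminant analysis between two groups
#'
#' Computes the Mahalanobis distance between two group means, a permutation
#' p-value, and a leave-one-out cross-validation table. Shape data are
#' rank-deficient (3k tangent dimensions usually exceed the sample size),
#' so the two groups' pooled observations are first projected onto the
#' principal components of their own data, retaining
#' `min(n_a + n_b - 3, rank)` dimensions, which keeps the pooled
#' within-group covariance invertible. The permutation test shuffles group
#' labels and recomputes the distance; leave-one-out refits group means and
#' pooled covariance without the held-out observation (the PC subspace is
#' held fixed) and assigns it to the nearer mean by Mahalanobis distance,
#' ties going to `group_a`.
#'
#' @param x A `gpa_fit` or `shape_pca` (tangent coordinates / scores with
#'   metadata), or a plain observation-by-coordinate matrix.
#' @param group Name of the metadata column holding group labels, or (for
#'   the matrix method) a vector of labels.
#' @param group_a,group_b The two group names to compare.
#' @param n_permutations Number of label permutations for the p-value
#'   (default 999; 0 skips the test, `permutation_p` becomes `NA`).
#' @param seed Integer seed controlling the permutations.
#' @param subspace_dim Optional override of the retained PC dimension.
#' @param ... Unused.
#' @return An object of class `dfa_fit`: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `mahalanobis_distance` (D), `mahalanobis_sq` (D^2),
#'   `permutation_p` (add-one estimator), `n_permutations`, `loo` (tibble
#'   of per-observation true/assigned groups and discriminant scores),
#'   `loo_table` (2 x 2 counts, true x assigned), `misassigned`,
#'   `subspace_dim`, `seed`.
#' @examples
#' sk <- simulate_skulls(skull_config(group_sizes = c(10, 10),
#'                                    effect_size = 0.05, seed = 2))
#' fit <- gpa(sk)
#' pairwise_dfa(fit, group = "group", "group_1", "group_2",
#'              n_permutations = 99, seed = 1)
#' @export
pairwise_dfa <- function(x, group, group_a, group_b, n_permutations = 999,
                         seed = 1, subspace_dim = NULL, ...) {
  UseMethod("pairwise_dfa")
}

#' @rdname pairwise_dfa
#' @export
pairwise_dfa.gpa_fit <- function(x, group, group_a, group_b,
                                 n_permutations = 999, seed = 1,
                                 subspace_dim = NULL, ...) {
  labels <- group_labels_from_meta(x$meta, group)
  dfa_core(x$tangent, labels, group_a, group_b, n_permutations, seed,
           subspace_dim, obs_labels = x$meta$specimen_id)
}

#' @rdname pairwise_dfa
#' @export
pairwise_dfa.default <- function(x, group, group_a, group_b,
                                 n_permutations = 999, seed = 1,
                                 subspace_dim = NULL, ...) {
  X <- as.matrix(x)
  dfa_core(X, as.character(group), group_a, group_b, n_permutations, seed,
           subspace_dim,
           obs_labels = rownames(X) %||% paste0("obs_", seq_len(nrow(X))))
}

group_labels_from_meta <- function(meta, group) {
  if (!group %in% names(meta)) {
    stop("grouping column '", group, "' not found in metadata", call. = FALSE)
  }
  as.character(meta[[group]])
}

dfa_core <- function(X, labels, group_a, group_b, n_permutations, seed,
                     subspace_dim = NULL, obs_labels = NULL) {
  for (g in c(group_a, group_b)) {
    if (!g %in% labels) stop("group '", g, "' has no observations",
                             call. = FALSE)
  }
  idx <- labels %in% c(group_a, group_b)
  Z0 <- X[idx, , drop = FALSE]
  g <- labels[idx]
  obs <- (obs_labels %||% paste0("obs_", seq_along(labels)))[idx]
  n <- nrow(Z0)
  if (n < 4) stop("need at least 4 observations across the two groups",
                  call. = FALSE)
  if (sum(g == group_a) < 2 || sum(g == group_b) < 2) {
    stop("each group needs at least 2 observations for cross-validation",
         call. = FALSE)
  }
  # project onto the PCs of the pooled two-group data
  mu <- colMeans(Z0)
  sv <- svd(sweep(Z0, 2, mu))
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  d <- subspace_dim %||% min(n - 3L, rank)
  d <- max(1L, min(d, rank))
  Z <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], nrow = d)

  mahal <- function(Z, g) {
    za <- Z[g == group_a, , drop = FALSE]
    zb <- Z[g == group_b, , drop = FALSE]
    pooled <- (crossprod(sweep(za, 2, colMeans(za))) +
               crossprod(sweep(zb, 2, colMeans(zb)))) / (nrow(Z) - 2)
    diff <- colMeans(za) - colMeans(zb)
    drop(crossprod(diff, solve(pooled, diff)))
  }
  d2 <- tryCatch(mahal(Z, g), error = function(e) NA_real_)
  while (is.na(d2) && d > 1) {
    d <- d - 1L
    warning("singular pooled covariance; reducing DFA subspace to ", d,
            " dimensions", call. = FALSE)
    Z <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], nrow = d)
    d2 <- tryCatch(mahal(Z, g), error = function(e) NA_real_)
  }
  if (is.na(d2)) stop("pooled covariance singular in every subspace",
                      call. = FALSE)

  perm_p <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      pd2 <- tryCatch(mahal(Z, sample(g)), error = function(e) Inf)
      if (pd2 >= d2) exceed <- exceed + 1L
    }
    perm_p <- (1 + exceed) / (1 + n_permutations)
  }

  # leave-one-out: refit means and pooled covariance without observation i
  assigned <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    Zi <- Z[-i, , drop = FALSE]
    gi <- g[-i]
    za <- Zi[gi == group_a, , drop = FALSE]
    zb <- Zi[gi == group_b, , drop = FALSE]
    pooled <- (crossprod(sweep(za, 2, colMeans(za))) +
               crossprod(sweep(zb, 2, colMeans(zb)))) / (nrow(Zi) - 2)
    da <- drop(crossprod(Z[i, ] - colMeans(za),
                         solve(pooled, Z[i, ] - colMeans(za))))
    db <- drop(crossprod(Z[i, ] - colMeans(zb),
                         solve(pooled, Z[i, ] - colMeans(zb))))
    assigned[i] <- if (da <= db) group_a else group_b
    score[i] <- db - da  # positive favours group_a
  }
  loo <- tibble::tibble(label = obs, true = g, assigned = assigned,
                        score = score)
  tab <- table(factor(g, levels = c(group_a, group_b)),
               factor(assigned, levels = c(group_a, group_b)))
  structure(
    list(group_a = group_a, group_b = group_b,
         n_a = sum(g == group_a), n_b = sum(g == group_b),
         mahalanobis_distance = sqrt(d2), mahalanobis_sq = d2,
         permutation_p = perm_p, n_permutations = n_permutations,
         loo = loo, loo_table = tab,
         misassigned = loo[loo$true != loo$assigned, , drop = FALSE],
         subspace_dim = d, seed = seed),
    class = "dfa_fit"
  )
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat("<dfa_fit> ", x$group_a, " (n=", x$n_a, ") vs ", x$group_b,
      " (n=", x$n_b, ")\n", sep = "")
  cat("  Mahalanobis D = ", signif(x$mahalanobis_distance, 5),
      if (!is.na(x$permutation_p)) {
        paste0(", permutation p = ", signif(x$permutation_p, 3),
               " (", x$n_permutations, " permutations)")
      } else "", "\n", sep = "")
  cat("  LOO correct: ", sum(diag(x$loo_table)), "/", sum(x$loo_table),
      " (subspace dim ", x$subspace_dim, ")\n", sep = "")
  invisible(x)
}

#' Group-swap discriminant experiment
#'
#' Tests where a group of contested affinity belongs: the `movable` group
#' is merged first into `host_a` and then into `host_b`, and the pairwise
#' discriminant analysis between the two (augmented) hosts is run for each
#' placement. The placement consistent with the movable group's true
#' affinity yields the larger between-group Mahalanobis distance and fewer
#' cross-validation reassignments of movable observations.
#'
#' @inheritParams pairwise_dfa
#' @param movable Name of the group to be merged into each host in turn.
#' @param host_a,host_b The two host groups (disjoint from `movable`).
#' @return An object of class `swap_dfa`: `in_a` and `in_b` (the two
#'   `dfa_fit` results), `movable`, and `movable_misassigned` (counts of
#'   movable observations reassigned out of their host in each placement).
#' @export
group_swap_dfa <- function(x, group, movable, host_a, host_b,
                           n_permutations = 999, seed = 1,
                           subspace_dim = NULL, ...) {
  if (inherits(x, "gpa_fit")) {
    labels <- group_labels_from_meta(x$meta, group)
    X <- x$tangent
    obs <- x$meta$specimen_id
  } else {
    X <- as.matrix(x)
    labels <- as.character(group)
    obs <- rownames(X) %||% paste0("obs_", seq_len(nrow(X)))
  }
  groups <- list(movable = movable, host_a = host_a, host_b = host_b)
  for (g in unlist(groups)) {
    if (!g %in% labels) stop("group '", g, "' has no observations",
                             call. = FALSE)
  }
  run <- function(host) {
    lab <- labels
    lab[lab == movable] <- host
    dfa_core(X, lab, host_a, host_b, n_permutations, seed, subspace_dim,
             obs_labels = obs)
  }
  in_a <- run(host_a)
  in_b <- run(host_b)
  movable_obs <- obs[labels == movable]
  count_moved <- function(fit, host) {
    mis <- fit$misassigned
    sum(mis$label %in% movable_obs & mis$true == host)
  }
  structure(
    list(in_a = in_a, in_b = in_b, movable = movable,
         host_a = host_a, host_b = host_b,
         movable_misassigned = c(
           in_a = count_moved(in_a, host_a),
           in_b = count_moved(in_b, host_b)
         )),
    class = "swap_dfa"
  )
}

#' @export
print.swap_dfa <- function(x, ...) {
  cat("<swap_dfa> '", x$movable, "' merged into each of '", x$host_a,
      "' / '", x$host_b, "'\n", sep = "")
  cat("  D with movable in ", x$host_a, ": ",
      signif(x$in_a$mahalanobis_distance, 5),
      " (", x$movable_misassigned[["in_a"]], " movable reassigned)\n",
      sep = "")
  cat("  D with movable in ", x$host_b, ": ",
      signif(x$in_b$mahalanobis_distance, 5),
      " (", x$movable_misassigned[["in_b"]], " movable reassigned)\n",
      sep = "")
  invisible(x)
}
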