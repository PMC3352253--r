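# broom-style accessors: tidy() gives the component-level table of each
# fitted object, glance() a one-row summary, augment() observation-level
# quantities.

#' @rdname gpa
#' @param x A `gpa_fit`.
#' @method tidy gpa_fit
#' @export
tidy.gpa_fit <- function(x, ...) {
  shape_tbl(x$coords, x$meta)
}

#' @rdname gpa
#' @method glance gpa_fit
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(
    n_specimens = dim(x$coords)[3],
    n_landmarks = dim(x$coords)[1],
    converged = x$converged,
    n_iterations = x$n_iterations,
    total_variance = procrustes_variance(x$tangent),
    mean_centroid_size = mean(x$centroid_sizes)
  )
}

#' @rdname shape_pca
#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_proportion = x$variance_proportions,
    cumulative_proportion = cumsum(x$variance_proportions)
  )
}

#' @rdname shape_pca
#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(
    n_observations = nrow(x$scores),
    n_components = length(x$eigenvalues),
    total_variance = sum(x$eigenvalues),
    pc1_proportion = x$variance_proportions[1]
  )
}

#' @rdname shape_pca
#' @method augment shape_pca
#' @export
augment.shape_pca <- function(x, ...) {
  x$scores
}

#' @rdname regress_shape_on_size
#' @method glance allometry_fit
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(
    n_observations = nrow(x$residuals),
    size_covariate = x$size_covariate,
    percent_predicted = x$percent_predicted,
    slope_magnitude = sqrt(sum(x$slope^2))
  )
}

#' @rdname regress_shape_on_size
#' @method tidy allometry_fit
#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble::tibble(
    coordinate = colnames(x$residuals) %||%
      paste0("c", seq_along(x$slope)),
    intercept = x$intercept,
    slope = x$slope
  )
}

#' @rdname pairwise_dfa
#' @method tidy dfa_fit
#' @export
tidy.dfa_fit <- function(x, ...) {
  x$loo
}

#' @rdname pairwise_dfa
#' @method glance dfa_fit
#' @export
glance.dfa_fit <- function(x, ...) {
  tibble::tibble(
    group_a = x$group_a, group_b = x$group_b,
    n_a = x$n_a, n_b = x$n_b,
    mahalanobis_distance = x$mahalanobis_distance,
    permutation_p = x$permutation_p,
    n_permutations = x$n_permutations,
    loo_correct = sum(diag(x$loo_table)),
    loo_total = sum(x$loo_table),
    subspace_dim = x$subspace_dim
  )
}

#' @rdname group_swap_dfa
#' @method glance swap_dfa
#' @export
glance.swap_dfa <- function(x, ...) {
  tibble::tibble(
    movable = x$movable,
    placement = c(x$host_a, x$host_b),
    mahalanobis_distance = c(x$in_a$mahalanobis_distance,
                             x$in_b$mahalanobis_distance),
    permutation_p = c(x$in_a$permutation_p, x$in_b$permutation_p),
    movable_misassigned = unname(x$movable_misassigned),
    loo_correct = c(sum(diag(x$in_a$loo_table)),
                    sum(diag(x$in_b$loo_table))),
    loo_total = c(sum(x$in_a$loo_table), sum(x$in_b$loo_table))
  )
}
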