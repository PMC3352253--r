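#' Pool aligned specimens to species mean shapes
#'
#' Collapses a Procrustes-aligned sample to one observation per species to
#' reduce sampling effects: each species' aligned coordinates are averaged,
#' re-centred and re-scaled to unit centroid size, re-rotated to the
#' consensus, and re-projected to tangent space. Centroid size is pooled as
#' the mean of the specimens' centroid sizes. Metadata columns that are
#' constant within a species are kept; others are dropped.
#'
#' @param fit A `gpa_fit` from [gpa()].
#' @param taxa Per-specimen species labels; defaults to `fit$meta$taxon`.
#' @return A `gpa_fit` with one observation per species (in first-appearance
#'   order), sharing the original consensus and scheme.
#' @export
pool_by_species <- function(fit, taxa = fit$meta$taxon) {
  stopifnot(inherits(fit, "gpa_fit"))
  if (anyNA(taxa) || length(taxa) != dim(fit$coords)[3]) {
    stop("every specimen needs a species label", call. = FALSE)
  }
  sp <- unique(taxa)
  k <- dim(fit$coords)[1]
  X <- array(0, c(k, 3, length(sp)), dimnames = list(NULL, coord_cols, sp))
  cs <- numeric(length(sp))
  for (i in seq_along(sp)) {
    idx <- which(taxa == sp[i])
    m <- apply(fit$coords[, , idx, drop = FALSE], c(1, 2), mean)
    m <- center_config(m)
    m <- m / sqrt(sum(m^2))
    X[, , i] <- m %*% kabsch_rotation(m, fit$consensus)
    cs[i] <- mean(fit$centroid_sizes[idx])
  }
  tangent <- tangent_project(X, fit$consensus)
  rownames(tangent) <- sp
  meta <- fit$meta
  meta$specimen_id <- NULL
  keep <- vapply(names(meta), function(nm) {
    all(tapply(meta[[nm]], taxa, function(v) length(unique(v)) == 1))
  }, logical(1))
  meta <- meta[, keep, drop = FALSE]
  meta <- meta[match(sp, taxa), , drop = FALSE]
  meta <- dplyr::bind_cols(tibble::tibble(specimen_id = sp), meta)
  structure(
    list(coords = X, centroid_sizes = stats::setNames(cs, sp),
         consensus = fit$consensus, tangent = tangent, meta = meta,
         scheme = fit$scheme, converged = fit$converged,
         n_iterations = fit$n_iterations),
    class = "gpa_fit"
  )
}

#' Principal components analysis of shape
#'
#' Eigen-analysis of the covariance matrix (divisor n - 1) of tangent-space
#' shape coordinates — the standard shape-space ordination. Components are
#' ordered by eigenvalue; only non-null dimensions are retained (at most
#' n - 1; Procrustes alignment removes 7 of the 3k raw dimensions). Each
#' component's sign is fixed so its loading element of largest magnitude is
#' positive, making output deterministic across linear-algebra backends.
#'
#' @param x A `gpa_fit` (its tangent coordinates and metadata are used) or
#'   a plain numeric observation-by-coordinate matrix.
#' @param labels Optional observation labels (defaults to metadata
#'   `specimen_id` or rownames).
#' @param ... Unused.
#' @return An object of class `shape_pca`: `scores` (tibble of labels,
#'   metadata and `PC1..PCm` columns), `eigenvalues`,
#'   `variance_proportions` (summing to 1 over retained components),
#'   `loadings` (m x 3k matrix, orthonormal rows), `mean_vector`,
#'   `n_landmarks`, `meta`.
#' @export
shape_pca <- function(x, ...) UseMethod("shape_pca")

#' @rdname shape_pca
#' @export
shape_pca.gpa_fit <- function(x, ...) {
  res <- shape_pca_core(x$tangent, x$meta)
  res$n_landmarks <- dim(x$coords)[1]
  res
}

#' @rdname shape_pca
#' @export
shape_pca.default <- function(x, labels = rownames(x), ...) {
  x <- as.matrix(x)
  meta <- tibble::tibble(
    specimen_id = labels %||% paste0("obs_", seq_len(nrow(x)))
  )
  res <- shape_pca_core(x, meta)
  if (ncol(x) %% 3 == 0) res$n_landmarks <- ncol(x) %/% 3
  res
}

shape_pca_core <- function(X, meta) {
  n <- nrow(X)
  if (n < 2) stop("PCA needs at least 2 observations", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  keep <- which(ev > max(ev[1], .Machine$double.eps) * 1e-10)
  keep <- keep[keep <= n - 1]
  if (length(keep) == 0) keep <- 1L  # degenerate data: one null component
  loadings <- t(sv$v[, keep, drop = FALSE])
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = length(keep))
  # deterministic sign: largest-magnitude loading element positive
  for (j in seq_along(keep)) {
    piv <- which.max(abs(loadings[j, ]))
    if (loadings[j, piv] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- ev[keep]
  colnames(scores) <- paste0("PC", seq_along(keep))
  score_tbl <- dplyr::bind_cols(meta, tibble::as_tibble(scores))
  structure(
    list(scores = score_tbl, eigenvalues = ev,
         variance_proportions = ev / sum(ev), loadings = loadings,
         mean_vector = mu, n_landmarks = NA_integer_, meta = meta),
    class = "shape_pca"
  )
}

#' Model shape at a position along a principal component
#'
#' Reconstructs the landmark configuration `mean + score * loading` for a
#' chosen component — the shapes drawn as wireframes at the positive and
#' negative extremes of an ordination axis.
#'
#' @param result A `shape_pca`.
#' @param component Component index (1-based).
#' @param score Position along the component, in score units.
#' @return An n_landmarks x 3 coordinate matrix.
#' @export
shape_model <- function(result, component, score) {
  stopifnot(inherits(result, "shape_pca"))
  if (component < 1 || component > nrow(result$loadings)) {
    stop("component ", component, " out of range 1..",
         nrow(result$loadings), call. = FALSE)
  }
  v <- result$mean_vector + score * result$loadings[component, ]
  unflatten_config(v)
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(4, length(x$eigenvalues))
  cat("<shape_pca> ", nrow(x$scores), " observations, ",
      length(x$eigenvalues), " components\n", sep = "")
  cat("  variance: ",
      paste0("PC", seq_len(m), " ",
             sprintf("%.1f%%", 100 * x$variance_proportions[seq_len(m)]),
             collapse = ", "),
      if (length(x$eigenvalues) > m) ", ..." else "", "\n", sep = "")
  invisible(x)
}
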