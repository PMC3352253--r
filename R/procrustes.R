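#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard size measure in geometric morphometrics,
#' and the size covariate of the allometric regression. Landmarks with any
#' `NA` coordinate are excluded.
#'
#' @param coordinates Numeric matrix (n_landmarks x 3).
#' @return A positive scalar (0 for a single landmark).
#' @examples
#' centroid_size(rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)))
#' @export
centroid_size <- function(coordinates) {
  coordinates <- rbind(coordinates)
  keep <- stats::complete.cases(coordinates)
  if (!any(keep)) stop("all landmarks missing; centroid size undefined",
                       call. = FALSE)
  x <- coordinates[keep, , drop = FALSE]
  sqrt(sum(center_config(x)^2))
}

#' Least-squares rotation of one configuration onto another
#'
#' Computes the proper rotation (determinant +1; reflections are never
#' allowed, since left/right anatomy is fixed by the landmark scheme)
#' minimising the summed squared distances between `source %*% rotation`
#' and `target`, by singular value decomposition of the cross-product
#' matrix.
#'
#' @param source,target Centered n x 3 coordinate matrices with the same
#'   landmark count and nonzero centroid size.
#' @return List with `rotation` (3 x 3 orthogonal, det +1) and `residual`
#'   (the minimised sum of squared distances, >= 0).
#' @export
optimal_superimposition <- function(source, target) {
  if (!all(dim(source) == dim(target))) {
    stop("source and target must have the same dimensions", call. = FALSE)
  }
  if (sum(source^2) == 0 || sum(target^2) == 0) {
    stop("configurations of zero size cannot be superimposed", call. = FALSE)
  }
  rot <- kabsch_rotation(source, target)
  resid <- sum((source %*% rot - target)^2)
  list(rotation = rot, residual = max(resid, 0))
}

kabsch_rotation <- function(source, target) {
  m <- crossprod(source, target)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Removes translation, scale, and rotation from a sample of landmark
#' configurations: each configuration is centred and scaled to unit
#' centroid size, then iteratively rotated to the running consensus (the
#' arithmetic mean shape, itself re-centred and re-scaled each round) until
#' the consensus stabilises. The final solution is put in a canonical
#' orientation (consensus aligned to its own principal axes with a
#' deterministic proper sign rule), so the output is invariant to arbitrary
#' rigid motions and scalings of the input specimens. Aligned shapes are
#' also projected orthogonally onto the tangent space at the consensus,
#' giving the flat coordinates on which all downstream multivariate
#' statistics operate.
#'
#' @param df Long landmark tibble with no missing landmarks. Run
#'   [mirror_impute()] first (or drop incomplete landmarks) if fossils have
#'   gaps; `gpa()` refuses incomplete data.
#' @param scheme A [landmark_scheme].
#' @param tol Convergence tolerance on the root-summed-squared change of
#'   the consensus between iterations.
#' @param max_iter Maximum number of alignment sweeps.
#' @return An object of class `gpa_fit`: list with `coords`
#'   (k x 3 x n aligned array, unit centroid size), `centroid_sizes`
#'   (original units), `consensus` (k x 3, the arithmetic mean of the
#'   aligned shapes), `tangent`
#'   (n x 3k matrix of tangent-space coordinates, one row per specimen),
#'   `meta` (specimen metadata tibble), `scheme`, `converged`,
#'   `n_iterations`.
#' @examples
#' sk <- simulate_skulls(skull_config(group_sizes = c(5, 5), seed = 1))
#' fit <- gpa(sk)
#' fit
#' @export
gpa <- function(df, scheme = cranial_scheme(), tol = 1e-10, max_iter = 100L) {
  arr <- as_shape_array(df, scheme)
  if (!all(arr$present)) {
    bad <- colSums(!arr$present)
    stop("GPA requires complete configurations; ", sum(bad > 0),
         " specimen(s) have missing landmarks. Run mirror_impute() first ",
         "or exclude the affected landmarks.", call. = FALSE)
  }
  coords <- arr$coords
  n <- dim(coords)[3]
  cs <- apply(coords, 3, centroid_size)
  if (any(cs <= 0)) stop("degenerate specimen with zero centroid size",
                         call. = FALSE)
  X <- coords
  for (i in seq_len(n)) X[, , i] <- center_config(coords[, , i]) / cs[i]

  consensus <- X[, , 1]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      X[, , i] <- X[, , i] %*% kabsch_rotation(X[, , i], consensus)
    }
    new_cons <- apply(X, c(1, 2), mean)
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("GPA did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  # canonical orientation: consensus principal axes, proper and sign-fixed
  rot <- canonical_rotation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) {
    X[, , i] <- X[, , i] %*% rot
    X[, , i] <- X[, , i] %*% kabsch_rotation(X[, , i], consensus)
  }
  # report the consensus as the plain arithmetic mean of the aligned shapes
  # (unit scaling of the running consensus is only an iteration device)
  consensus <- apply(X, c(1, 2), mean)
  tangent <- tangent_project(X, consensus)
  rownames(tangent) <- dimnames(coords)[[3]]
  structure(
    list(coords = X, centroid_sizes = stats::setNames(cs, dimnames(coords)[[3]]),
         consensus = consensus, tangent = tangent, meta = arr$meta,
         scheme = scheme, converged = converged, n_iterations = iter),
    class = "gpa_fit"
  )
}

# Deterministic proper rotation sending a centered configuration to its
# principal axes. Signs of the first two axes are fixed so the coordinate
# of largest magnitude along each is positive; the third completes a
# right-handed frame.
canonical_rotation <- function(config) {
  eg <- eigen(crossprod(config), symmetric = TRUE)
  v <- eg$vectors
  for (j in 1:2) {
    proj <- config %*% v[, j]
    if (proj[which.max(abs(proj))] < 0) v[, j] <- -v[, j]
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  v
}

# Orthogonal projection of aligned (unit-size) shapes onto the tangent
# space at the consensus: t_i = x_i - (x_i . c) c with c the unit consensus
# vector, so every tangent vector is orthogonal to the consensus.
tangent_project <- function(X, consensus) {
  cvec <- flatten_config(consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  n <- dim(X)[3]
  out <- matrix(0, n, length(cvec))
  for (i in seq_len(n)) {
    x <- flatten_config(X[, , i])
    out[i, ] <- x - sum(x * cvec) * cvec
  }
  colnames(out) <- paste0(rep(seq_len(dim(X)[1]), each = 3), c("x", "y", "z"))
  out
}

#' Procrustes distance between two shapes
#'
#' The square root of the minimised summed squared differences after
#' centring, scaling both configurations to unit centroid size, and
#' optimally rotating one onto the other (partial Procrustes distance, the
#' standard metric of shape space near the consensus).
#'
#' @param a,b Numeric n x 3 landmark matrices.
#' @return Nonnegative scalar; 0 iff the shapes coincide up to similarity.
#' @export
procrustes_distance <- function(a, b) {
  ua <- center_config(a); ua <- ua / sqrt(sum(ua^2))
  ub <- center_config(b); ub <- ub / sqrt(sum(ub^2))
  sqrt(optimal_superimposition(ub, ua)$residual)
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("<gpa_fit> ", dim(x$coords)[3], " specimens, ",
      dim(x$coords)[1], " landmarks; ",
      if (x$converged) "converged" else "NOT converged", " in ",
      x$n_iterations, " iteration(s)\n", sep = "")
  cat("  centroid size range: ",
      paste(signif(range(x$centroid_sizes), 4), collapse = " - "), "\n",
      sep = "")
  invisible(x)
}
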