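#' Multivariate regression of shape on centroid size
#'
#' Fits ordinary least squares of every tangent-space shape coordinate on a
#' size covariate, pooled across all groups (one common allometric slope).
#' The residuals are the allometry-corrected shape data. By default the
#' covariate is raw centroid size, matching an analysis that regresses
#' shape on centroid size without transformation; log centroid size — the
#' other convention in the field — is available via `size_covariate`.
#'
#' @param x A `gpa_fit`, or a numeric observation-by-coordinate matrix.
#' @param sizes Centroid sizes (taken from the `gpa_fit` when omitted).
#' @param size_covariate `"raw"` (default) or `"log"`.
#' @param ... Unused.
#' @return An object of class `allometry_fit`: `intercept` and `slope`
#'   (3k-vectors; slope is shape change per unit covariate), `covariate`
#'   (the per-observation size values used), `size_covariate`, `fitted`,
#'   `residuals` (n x 3k, zero column means, uncorrelated with the
#'   covariate), `percent_predicted` (percentage of total shape variance
#'   explained by size), `meta`.
#' @export
regress_shape_on_size <- function(x, ...) UseMethod("regress_shape_on_size")

#' @rdname regress_shape_on_size
#' @export
regress_shape_on_size.gpa_fit <- function(x, size_covariate = c("raw", "log"),
                                          ...) {
  regress_shape_on_size.default(x$tangent, sizes = x$centroid_sizes,
                                size_covariate = size_covariate,
                                meta = x$meta)
}

#' @rdname regress_shape_on_size
#' @param meta Optional metadata tibble carried through to results.
#' @export
regress_shape_on_size.default <- function(x, sizes,
                                          size_covariate = c("raw", "log"),
                                          meta = NULL, ...) {
  size_covariate <- match.arg(size_covariate)
  X <- as.matrix(x)
  n <- nrow(X)
  if (n < 3) stop("allometric regression needs at least 3 observations",
                  call. = FALSE)
  if (length(sizes) != n || any(sizes <= 0)) {
    stop("need one positive centroid size per observation", call. = FALSE)
  }
  s <- if (size_covariate == "log") log(sizes) else as.numeric(sizes)
  if (stats::sd(s) == 0) {
    stop("size covariate is constant; allometric slope undefined",
         call. = FALSE)
  }
  sc <- s - mean(s)
  slope <- as.vector(crossprod(sc, sweep(X, 2, colMeans(X))) / sum(sc^2))
  fitted <- outer(sc, slope) + rep(colMeans(X), each = n)
  resid <- X - fitted
  ss_tot <- sum(sweep(X, 2, colMeans(X))^2)
  ss_fit <- sum(outer(sc, slope)^2)
  structure(
    list(intercept = colMeans(X) - mean(s) * slope, slope = slope,
         covariate = s, size_covariate = size_covariate,
         fitted = fitted, residuals = resid,
         percent_predicted = 100 * ss_fit / ss_tot,
         meta = meta %||% tibble::tibble(specimen_id = rownames(X) %||%
                                           paste0("obs_", seq_len(n)))),
    class = "allometry_fit"
  )
}

#' PCA of allometry-corrected shape
#'
#' Runs [shape_pca()] on the residuals of the multivariate regression of
#' shape on centroid size, removing the linear size-correlated component
#' of shape variation before ordination.
#'
#' @inheritParams regress_shape_on_size
#' @param model Optionally a pre-computed `allometry_fit`; fitted from `x`
#'   when omitted.
#' @return A `shape_pca` of the residual shape data. The `allometry`
#'   element holds the underlying `allometry_fit`.
#' @export
allometry_corrected_pca <- function(x, size_covariate = c("raw", "log"),
                                    model = NULL, ...) {
  if (is.null(model)) {
    model <- regress_shape_on_size(x, size_covariate = size_covariate, ...)
  }
  res <- shape_pca_core(model$residuals, model$meta)
  res$n_landmarks <- if (inherits(x, "gpa_fit")) dim(x$coords)[1] else
    if (ncol(model$residuals) %% 3 == 0) ncol(model$residuals) %/% 3 else
      NA_integer_
  res$allometry <- model
  res
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("<allometry_fit> ", nrow(x$residuals), " observations; ",
      x$size_covariate, " centroid size explains ",
      sprintf("%.2f%%", x$percent_predicted), " of shape variance\n",
      sep = "")
  invisible(x)
}
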