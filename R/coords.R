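# Internal bridging between the long landmark tibble (the user-facing
# interchange format: one row per specimen x landmark, columns
# specimen_id, taxon, <metadata...>, landmark, x, y, z) and the
# k x 3 x n coordinate array used by the numerical core. Missing landmarks
# are NA in x/y/z; a landmark is absent iff any of its coordinates is NA.

coord_cols <- c("x", "y", "z")
id_cols <- c("specimen_id", "taxon", "landmark")

assert_landmark_tbl <- function(df) {
  need <- c("specimen_id", "landmark", coord_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("landmark table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# meta columns = everything constant per specimen (anything not landmark/x/y/z)
meta_cols <- function(df) setdiff(names(df), c("landmark", coord_cols, "imputed"))

#' @keywords internal
#' @noRd
as_shape_array <- function(df, scheme) {
  assert_landmark_tbl(df)
  k <- scheme$n_landmarks
  ids <- unique(df$specimen_id)
  n <- length(ids)
  coords <- array(NA_real_, c(k, 3L, n),
                  dimnames = list(NULL, coord_cols, ids))
  for (i in seq_len(n)) {
    rows <- df[df$specimen_id == ids[i], , drop = FALSE]
    if (nrow(rows) != k || !setequal(rows$landmark, seq_len(k))) {
      stop("specimen '", ids[i], "' has ", nrow(rows),
           " landmark rows; scheme expects exactly ", k, call. = FALSE)
    }
    rows <- rows[order(rows$landmark), , drop = FALSE]
    coords[, , i] <- as.matrix(rows[, coord_cols])
  }
  # absent if any coordinate NA
  present <- apply(coords, c(1, 3), function(v) all(is.finite(v)))
  meta <- dplyr::distinct(df[, meta_cols(df), drop = FALSE])
  if (nrow(meta) != n) {
    stop("specimen metadata columns are not constant within specimens",
         call. = FALSE)
  }
  meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  list(coords = coords, present = present, meta = tibble::as_tibble(meta))
}

#' @keywords internal
#' @noRd
shape_tbl <- function(coords, meta, imputed = NULL) {
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  out <- tidyr::crossing(.row = seq_len(n), landmark = seq_len(k))
  out <- dplyr::bind_cols(meta[out$.row, , drop = FALSE],
                          out["landmark"])
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) coords[, , i]))
  out$x <- xyz[, 1]
  out$y <- xyz[, 2]
  out$z <- xyz[, 3]
  if (!is.null(imputed)) out$imputed <- as.vector(imputed)
  tibble::as_tibble(out)
}

flatten_config <- function(x) as.vector(t(x))        # (x1,y1,z1,x2,...)
unflatten_config <- function(v) matrix(v, ncol = 3, byrow = TRUE)

center_config <- function(x) sweep(x, 2, colMeans(x))
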