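#' Read 3D landmark configurations
#'
#' Reads landmark data from the standard morphometric text formats into the
#' package's long tabular form: one row per specimen and landmark, with
#' columns `specimen_id`, `taxon`, `landmark` (1-based, in scheme order),
#' and coordinates `x`, `y`, `z`. Missing landmarks (blank fields, `NA`
#' tokens, or the NTS missing sentinel declared in its header) come back as
#' `NA` coordinates.
#'
#' Supported formats:
#' * `csv` — long format with columns `specimen_id`, `taxon`, optional
#'   grouping columns, `landmark`, `x`, `y`, `z`.
#' * `tps` — `LM3=` blocks of x y z lines with `ID=` (and optionally
#'   `IMAGE=`) keys; the token `NA` marks a missing coordinate.
#' * `nts` — single NTS matrix file; a `1` in the fourth header field
#'   declares a missing-value sentinel given in the fifth field.
#' * `morphologika` — `[individuals]`/`[landmarks]`/`[dimensions]`/
#'   `[names]`/`[rawpoints]` sections (read-only).
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"tps"`, `"nts"`, `"morphologika"`.
#'   Guessed from the file extension when omitted.
#' @param scheme A [landmark_scheme]; defaults to [cranial_scheme()]. Used
#'   to check the landmark count.
#' @return A tibble in long landmark form.
#' @seealso [write_landmarks()]
#' @export
read_landmarks <- function(path, format = NULL, scheme = cranial_scheme()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("csv", "tps", "nts", "morphologika"))
  df <- switch(format,
    csv = read_landmarks_csv(path),
    tps = read_landmarks_tps(path),
    nts = read_landmarks_nts(path),
    morphologika = read_landmarks_morphologika(path)
  )
  check_against_scheme(df, scheme, path)
  df
}

#' Write 3D landmark configurations
#'
#' Writes a long landmark table to CSV, TPS, or NTS. Re-reading the file
#' with [read_landmarks()] reproduces the coordinates to within 1e-6 and
#' the missingness pattern exactly. Missing landmarks are written as empty
#' fields (CSV), `NA` tokens (TPS), or the declared sentinel `-999` (NTS).
#'
#' @param df Long landmark tibble (see [read_landmarks()]).
#' @param path Destination path.
#' @param format One of `"csv"`, `"tps"`, `"nts"`; guessed from the
#'   extension when omitted.
#' @param scheme A [landmark_scheme] used to validate the table.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(df, path, format = NULL, scheme = cranial_scheme()) {
  assert_landmark_tbl(df)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("csv", "tps", "nts"))
  if (nrow(df) > 0) check_against_scheme(df, scheme, path)
  switch(format,
    csv = write_landmarks_csv(df, path),
    tps = write_landmarks_tps(df, path, scheme),
    nts = write_landmarks_nts(df, path, scheme)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", tps = "tps", nts = "nts",
    txt = "morphologika",
    stop("cannot guess landmark format from extension '", ext,
         "'; pass `format`", call. = FALSE)
  )
}

check_against_scheme <- function(df, scheme, path) {
  if (nrow(df) == 0) return(invisible(df))
  k <- scheme$n_landmarks
  counts <- table(df$specimen_id)
  if (any(counts != k) || max(df$landmark) != k || min(df$landmark) != 1) {
    stop("'", path, "': landmark count does not match scheme (expected ",
         k, " per specimen)", call. = FALSE)
  }
  invisible(df)
}

## ---- CSV ----------------------------------------------------------------

read_landmarks_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_landmark_tbl(df)
  df$landmark <- as.integer(df$landmark)
  for (cc in coord_cols) df[[cc]] <- as.numeric(df[[cc]])
  # any NA coordinate marks the whole landmark absent
  bad <- !stats::complete.cases(df[, coord_cols])
  df[bad, coord_cols] <- NA_real_
  df
}

write_landmarks_csv <- function(df, path) {
  readr::write_csv(df, path, na = "", progress = FALSE)
}

## ---- TPS ----------------------------------------------------------------

read_landmarks_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  specs <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1; next }
    m <- regmatches(lines[i], regexec("^LM3=([0-9]+)$", lines[i],
                                      ignore.case = TRUE))[[1]]
    if (length(m) == 0) {
      stop("TPS parse error at line ", i, ": expected LM3= block header, got '",
           lines[i], "'", call. = FALSE)
    }
    k <- as.integer(m[2])
    if (i + k > length(lines)) {
      stop("TPS parse error at line ", i, ": block declares ", k,
           " landmarks but file ends early", call. = FALSE)
    }
    xyz <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      toks <- strsplit(lines[i + j], "[[:space:]]+")[[1]]
      if (length(toks) != 3) {
        stop("TPS parse error at line ", i + j,
             ": expected 3 coordinates", call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(toks))
      if (any(is.na(vals) & toupper(toks) != "NA")) {
        stop("TPS parse error at line ", i + j, ": non-numeric coordinate '",
             paste(toks, collapse = " "), "'", call. = FALSE)
      }
      xyz[j, ] <- vals
    }
    i <- i + k + 1
    id <- NULL
    while (i <= length(lines) && !grepl("^LM3=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      }
      if (lines[i] == "" && !is.null(id)) break
      i <- i + 1
    }
    if (is.null(id)) id <- paste0("specimen_", length(specs) + 1)
    xyz[!stats::complete.cases(xyz), ] <- NA_real_
    specs[[length(specs) + 1]] <- tibble::tibble(
      specimen_id = id, taxon = id, landmark = seq_len(k),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  if (length(specs) == 0) return(empty_landmark_tbl())
  dplyr::bind_rows(specs)
}

write_landmarks_tps <- function(df, path, scheme) {
  ids <- unique(df$specimen_id)
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "f", digits = 8))
  out <- character(0)
  for (id in ids) {
    rows <- df[df$specimen_id == id, , drop = FALSE]
    rows <- rows[order(rows$landmark), , drop = FALSE]
    out <- c(out, paste0("LM3=", nrow(rows)),
             paste(fmt(rows$x), fmt(rows$y), fmt(rows$z)),
             paste0("ID=", id), "")
  }
  writeLines(out, path)
}

## ---- NTS ----------------------------------------------------------------

# Header: "1 <n>L <k*3> <missing-flag> [sentinel] DIM=3"; one label line per
# specimen follows when the row count carries the L suffix.
read_landmarks_nts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "\"")]
  if (length(lines) == 0) return(empty_landmark_tbl())
  head_toks <- strsplit(lines[1], "[[:space:]]+")[[1]]
  if (length(head_toks) < 4) {
    stop("NTS parse error at line 1: malformed header", call. = FALSE)
  }
  labelled <- grepl("L$", head_toks[2], ignore.case = TRUE)
  n <- as.integer(sub("L$", "", head_toks[2], ignore.case = TRUE))
  if (n == 0) return(empty_landmark_tbl())
  p <- as.integer(head_toks[3])
  has_missing <- head_toks[4] == "1"
  sentinel <- if (has_missing) as.numeric(head_toks[5]) else NA_real_
  k <- p %/% 3L
  body <- lines[-1]
  labels <- if (labelled) {
    lab <- strsplit(body[1], "[[:space:]]+")[[1]]
    body <- body[-1]
    while (length(lab) < n && length(body)) {  # labels may wrap lines
      lab <- c(lab, strsplit(body[1], "[[:space:]]+")[[1]])
      body <- body[-1]
    }
    lab
  } else paste0("specimen_", seq_len(n))
  vals <- suppressWarnings(as.numeric(unlist(strsplit(body, "[[:space:]]+"))))
  if (anyNA(vals) || length(vals) != n * p) {
    stop("NTS parse error: expected ", n * p,
         " numeric values, found ", sum(!is.na(vals)), call. = FALSE)
  }
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  if (has_missing) mat[mat == sentinel] <- NA_real_
  purrr::map_dfr(seq_len(n), function(i) {
    xyz <- unflatten_config(mat[i, ])
    xyz[!stats::complete.cases(xyz), ] <- NA_real_
    tibble::tibble(specimen_id = labels[i], taxon = labels[i],
                   landmark = seq_len(k),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

write_landmarks_nts <- function(df, path, scheme) {
  ids <- unique(df$specimen_id)
  n <- length(ids)
  k <- if (n) scheme$n_landmarks else 0L
  header <- paste("1", paste0(n, "L"), k * 3L, "1", "-999", "DIM=3")
  rows <- vapply(ids, function(id) {
    r <- df[df$specimen_id == id, , drop = FALSE]
    r <- r[order(r$landmark), , drop = FALSE]
    v <- flatten_config(as.matrix(r[, coord_cols]))
    v[is.na(v)] <- -999
    paste(formatC(v, format = "f", digits = 8), collapse = " ")
  }, character(1))
  writeLines(c(header, paste(gsub("[[:space:]]", "_", ids), collapse = " "),
               rows), path)
}

## ---- Morphologika (read-only) -------------------------------------------

read_landmarks_morphologika <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  sect <- function(name) {
    i <- grep(paste0("^\\[", name, "\\]$"), lines, ignore.case = TRUE)
    if (length(i) != 1) {
      stop("Morphologika parse error: missing [", name, "] section",
           call. = FALSE)
    }
    i
  }
  n <- as.integer(lines[sect("individuals") + 1])
  k <- as.integer(lines[sect("landmarks") + 1])
  dim3 <- as.integer(lines[sect("dimensions") + 1])
  if (!identical(dim3, 3L)) {
    stop("Morphologika parse error: only 3D data supported", call. = FALSE)
  }
  names_i <- grep("^\\[names\\]$", lines, ignore.case = TRUE)
  labels <- if (length(names_i) == 1) {
    lines[(names_i + 1):(names_i + n)]
  } else paste0("specimen_", seq_len(n))
  raw_i <- sect("rawpoints")
  body <- lines[(raw_i + 1):length(lines)]
  body <- body[body != "" & !startsWith(body, "'")]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(body, "[[:space:]]+"))))
  vals[is.na(vals)] <- NA_real_
  if (length(vals) != n * k * 3) {
    stop("Morphologika parse error: expected ", n * k * 3,
         " coordinates, found ", length(vals), call. = FALSE)
  }
  purrr::map_dfr(seq_len(n), function(i) {
    xyz <- matrix(vals[((i - 1) * k * 3 + 1):(i * k * 3)], ncol = 3, byrow = TRUE)
    xyz[!stats::complete.cases(xyz), ] <- NA_real_
    tibble::tibble(specimen_id = labels[i], taxon = labels[i],
                   landmark = seq_len(k),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

empty_landmark_tbl <- function() {
  tibble::tibble(specimen_id = character(), taxon = character(),
                 landmark = integer(), x = double(), y = double(),
                 z = double())
}
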