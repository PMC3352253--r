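#' Define a landmark scheme
#'
#' A landmark scheme names every landmark in a configuration and records its
#' symmetry role: each landmark is either a midline (unpaired, sagittal)
#' point or one member of a bilateral left/right pair. The midline indices
#' and the pair members must together partition `1..n_landmarks` with no
#' repeats.
#'
#' @param names Character vector of landmark labels, in configuration order.
#' @param midline Integer indices (1-based) of midline landmarks.
#' @param pairs Two-column integer matrix (or list of length-2 vectors) of
#'   bilateral pairs, first column the left member, second the right.
#' @return An object of class `landmark_scheme` with fields `n_landmarks`,
#'   `names`, `midline`, and `pairs` (two-column matrix).
#' @examples
#' sc <- landmark_scheme(c("a", "bL", "bR"), midline = 1, pairs = rbind(c(2, 3)))
#' sc$n_landmarks
#' @export
landmark_scheme <- function(names, midline, pairs) {
  names <- as.character(names)
  k <- length(names)
  midline <- as.integer(midline)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  used <- c(midline, as.vector(pairs))
  if (length(used) != k || anyDuplicated(used) || !setequal(used, seq_len(k))) {
    stop("midline indices and bilateral pairs must partition 1..", k,
         " with no repeats", call. = FALSE)
  }
  structure(
    list(n_landmarks = k, names = names, midline = midline, pairs = pairs),
    class = "landmark_scheme"
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("<landmark_scheme> ", x$n_landmarks, " landmarks: ",
      length(x$midline), " midline, ", nrow(x$pairs), " bilateral pairs\n",
      sep = "")
  invisible(x)
}

#' The 33-landmark primate cranial scheme
#'
#' Three midline landmarks (landmarks 1-3) followed by fifteen bilateral
#' suture and dental landmarks digitised on both sides of the skull
#' (left/right pairs 4-5 through 32-33). Landmarks sit on cranial sutures,
#' the occipital condyles, and the upper tooth row, chosen to be locatable
#' on incomplete fossil crania.
#'
#' @return A [landmark_scheme] with 33 landmarks.
#' @examples
#' cranial_scheme()$n_landmarks
#' @export
cranial_scheme <- function() {
  midline_names <- c(
    "nasal-frontal suture",
    "parietal-frontal suture",
    "premaxilla-maxilla suture"
  )
  pair_names <- c(
    "basioccipital-basisphenoid-bulla suture",
    "jugal-squamosal ventral suture",
    "jugal-maxilla (orbit crest) suture",
    "jugal-maxilla (base of zygomatic arch) suture",
    "jugal-squamosal dorsal suture",
    "frontal-squamosal-alisphenoid suture",
    "parietal-frontal-squamosal suture",
    "lacrimal-frontal-maxilla suture",
    "basisphenoid-presphenoid suture",
    "occipital condyle extreme",
    "premaxilla-maxilla lateral suture",
    "anterior lateral M1",
    "posterior lateral M2",
    "canine lateral extreme",
    "canine mesial extreme"
  )
  nm <- c(midline_names,
          as.vector(rbind(paste("left", pair_names), paste("right", pair_names))))
  left <- seq(4L, 32L, by = 2L)
  landmark_scheme(nm, midline = 1:3, pairs = cbind(left, left + 1L))
}
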