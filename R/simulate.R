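#' Deterministic bilaterally symmetric template skull
#'
#' Builds the base configuration all synthetic specimens perturb: midline
#' landmarks lie exactly on the y = 0 sagittal plane, spread along the
#' anteroposterior (x) axis; each bilateral pair is mirrored in y with an
#' anatomically plausible lateral spread. The configuration is centred at
#' the origin with unit centroid size and is exactly symmetric by
#' construction.
#'
#' @param scheme A [landmark_scheme].
#' @param seed Integer seed fixing the (deterministic) geometry.
#' @return An n_landmarks x 3 coordinate matrix.
#' @export
template_skull <- function(scheme = cranial_scheme(), seed = 1L) {
  set.seed(seed)
  k <- scheme$n_landmarks
  coords <- matrix(0, k, 3)
  nm <- length(scheme$midline)
  coords[scheme$midline, 1] <- seq(-1, 1, length.out = max(nm, 2))[seq_len(nm)]
  coords[scheme$midline, 3] <- stats::runif(nm, -0.2, 0.6)
  np <- nrow(scheme$pairs)
  px <- stats::runif(np, -1, 1)
  py <- stats::runif(np, 0.15, 0.7)
  pz <- stats::runif(np, -0.5, 0.5)
  coords[scheme$pairs[, 1], ] <- cbind(px, py, pz)
  coords[scheme$pairs[, 2], ] <- cbind(px, -py, pz)
  # centring preserves the y = 0 midline because mean(y) is exactly 0
  coords <- sweep(coords, 2, c(mean(coords[, 1]), 0, mean(coords[, 3])))
  coords / centroid_size(coords)
}

# Orthonormal basis of the 7 similarity directions (3 translations, scaling,
# 3 rotations) at a template; planted effects are projected onto their
# complement so GPA cannot absorb any of the planted signal.
similarity_basis <- function(template) {
  k <- nrow(template)
  tvec <- flatten_config(template)
  trans <- cbind(rep(c(1, 0, 0), k), rep(c(0, 1, 0), k), rep(c(0, 0, 1), k))
  skew <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
               rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  rots <- vapply(skew, function(s) flatten_config(template %*% t(s)),
                 numeric(3 * k))
  qr.Q(qr(cbind(trans, tvec, rots)))
}

plant_vector <- function(template, magnitude, basis = similarity_basis(template)) {
  v <- stats::rnorm(3 * nrow(template))
  v <- v - basis %*% crossprod(basis, v)
  as.vector(v / sqrt(sum(v^2)) * magnitude)
}

#' Configuration for the synthetic skull generator
#'
#' Describes a multi-group sample of 33-landmark skulls with planted
#' statistical structure: per-group mean-shape displacements in tangent
#' space at the template, an allometric shape direction tied to log
#' centroid size, species-level shape offsets, per-coordinate Gaussian
#' digitising noise, log-normal centroid sizes, and fossil-style
#' missingness that removes right-side members of bilateral pairs.
#'
#' Group effect and allometry vectors are drawn deterministically from
#' `seed` (in the orthogonal complement of the similarity directions at the
#' template, so superimposition cannot absorb them) unless supplied
#' explicitly.
#'
#' @param group_sizes Integer vector of specimens per group; names become
#'   group labels (defaults `group_1..`).
#' @param species_counts Species per group (recycled; defaults to 1, i.e.
#'   each group is one species).
#' @param effect_size Magnitude of each group's mean displacement in
#'   Procrustes (tangent) units.
#' @param group_effect_vectors Optional list of explicit 3k-vectors, one
#'   per group.
#' @param allometry_size Magnitude of the allometric vector per unit log
#'   centroid size (0 = no allometry).
#' @param allometry_vector Optional explicit 3k allometric vector.
#' @param size_log_mean,size_log_sd Mean and sd of log centroid size
#'   (sizes in mm; defaults emulate ~100 mm crania).
#' @param noise_sd Per-coordinate Gaussian digitising/individual noise, in
#'   Procrustes units.
#' @param species_sd Sd of species-level tangent offsets, recycled per
#'   group (0 = none).
#' @param missingness Probability that a bilateral pair's right member is
#'   absent in a fossil-style specimen.
#' @param fossil_fraction Proportion of specimens per group flagged as
#'   fossil-style.
#' @param fossil_groups Group names whose specimens are all fossil-style.
#' @param clades Optional named character vector mapping group name to a
#'   higher clade label (adds a `clade` metadata column).
#' @param scheme A [landmark_scheme].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `skull_config`.
#' @seealso [simulate_skulls()], [primate_preset()]
#' @export
skull_config <- function(group_sizes = c(20, 20), species_counts = 1L,
                         effect_size = 0.05, group_effect_vectors = NULL,
                         allometry_size = 0, allometry_vector = NULL,
                         size_log_mean = log(100), size_log_sd = 0.2,
                         noise_sd = 0.01, species_sd = 0,
                         missingness = 0, fossil_fraction = 0,
                         fossil_groups = character(0), clades = NULL,
                         scheme = cranial_scheme(), seed = 1L) {
  n_groups <- length(group_sizes)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("group_", seq_len(n_groups))
  }
  species_counts <- rep_len(as.integer(species_counts), n_groups)
  species_sd <- rep_len(species_sd, n_groups)
  stopifnot(all(group_sizes >= 1), all(species_counts >= 1),
            noise_sd >= 0, missingness >= 0, missingness <= 1,
            fossil_fraction >= 0, fossil_fraction <= 1, size_log_sd >= 0)
  template <- template_skull(scheme, seed = 1L)
  basis <- similarity_basis(template)
  set.seed(as.integer(seed) %% 1000000L + 101L)  # structure stream
  if (is.null(group_effect_vectors)) {
    group_effect_vectors <- lapply(seq_len(n_groups), function(g) {
      plant_vector(template, effect_size, basis)
    })
  }
  names(group_effect_vectors) <- names(group_sizes)
  if (is.null(allometry_vector)) {
    allometry_vector <- plant_vector(template, allometry_size, basis)
  }
  structure(
    list(scheme = scheme, template = template, group_sizes = group_sizes,
         species_counts = species_counts,
         group_effect_vectors = group_effect_vectors,
         allometry_vector = allometry_vector,
         size_log_mean = size_log_mean, size_log_sd = size_log_sd,
         noise_sd = noise_sd, species_sd = species_sd,
         missingness = missingness, fossil_fraction = fossil_fraction,
         fossil_groups = fossil_groups, clades = clades,
         seed = as.integer(seed)),
    class = "skull_config"
  )
}

#' @export
print.skull_config <- function(x, ...) {
  cat("<skull_config> ", length(x$group_sizes), " group(s), ",
      sum(x$group_sizes), " specimens, noise sd ", x$noise_sd,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic skull-landmark dataset
#'
#' Draws every specimen as `template + group effect + species offset +
#' (log size - mean log size) * allometry vector + iid Gaussian noise` in
#' tangent space, rescales it to its drawn centroid size, applies a random
#' rigid motion, and (for fossil-style specimens) deletes right-side
#' members of bilateral pairs with the configured probability. Fully
#' reproducible from the config seed.
#'
#' @param config A [skull_config()].
#' @return A long landmark tibble with metadata columns `specimen_id`,
#'   `taxon`, `group`, `fossil` (and `clade` when the config maps groups to
#'   clades); missing landmarks have `NA` coordinates.
#' @export
simulate_skulls <- function(config) {
  stopifnot(inherits(config, "skull_config"))
  scheme <- config$scheme
  k <- scheme$n_landmarks
  template <- config$template
  tflat <- flatten_config(template)
  set.seed(config$seed)
  groups <- names(config$group_sizes)
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$group_sizes[[gi]]
    nsp <- config$species_counts[gi]
    sp_offsets <- lapply(seq_len(nsp), function(s) {
      if (config$species_sd[gi] > 0) {
        stats::rnorm(3 * k, 0, config$species_sd[gi])
      } else {
        numeric(3 * k)
      }
    })
    sp_of <- rep_len(seq_len(nsp), n)  # round-robin allocation to species
    all_fossil <- g %in% config$fossil_groups
    for (i in seq_len(n)) {
      logs <- stats::rnorm(1, config$size_log_mean, config$size_log_sd)
      v <- config$group_effect_vectors[[gi]] + sp_offsets[[sp_of[i]]] +
        (logs - config$size_log_mean) * config$allometry_vector +
        stats::rnorm(3 * k, 0, config$noise_sd)
      shape <- unflatten_config(tflat + v)
      shape <- shape / centroid_size(shape) * exp(logs)
      rot <- random_rotation()
      shape <- shape %*% rot
      shape <- sweep(shape, 2, stats::runif(3, -100, 100), `+`)
      fossil <- all_fossil || stats::runif(1) < config$fossil_fraction
      if (fossil && config$missingness > 0) {
        gone <- stats::runif(nrow(scheme$pairs)) < config$missingness
        shape[scheme$pairs[gone, 2], ] <- NA_real_
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        specimen_id = sprintf("%s_sp%02d_%03d", g, sp_of[i], i),
        taxon = sprintf("%s species %d", g, sp_of[i]),
        group = g,
        clade = if (!is.null(config$clades)) unname(config$clades[g]) else NA,
        fossil = fossil,
        landmark = seq_len(k),
        x = shape[, 1], y = shape[, 2], z = shape[, 3]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(config$clades)) out$clade <- NULL
  out
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Study-mimic synthetic preset: six euprimate groups
#'
#' A [skull_config()] that rehearses the design of a mixed extant/fossil
#' euprimate cranial study: six groups whose species counts echo a
#' real-world sampling (19 anthropoid, 1 tarsiiform, 6 extant lemuriform,
#' 3 fossil lemuriform, 3 lorisiform, and 2 adapiform species), a shared
#' clade axis separating haplorhines from strepsirrhines, adapiforms drawn
#' from the strepsirrhine side of that axis, larger species-level spread
#' among anthropoids (so haplorhine disparity exceeds strepsirrhine),
#' fossil lemurs displaced into novel morphospace, a planted allometric
#' direction, and fossil-style missingness on adapiforms and fossil
#' lemurs.
#'
#' @param seed Integer seed.
#' @param n_per_species Specimens per species (default 4).
#' @return A `skull_config` with a `clade` mapping
#'   (Haplorhini/Strepsirrhini) attached.
#' @export
primate_preset <- function(seed = 1L, n_per_species = 4L) {
  groups <- c("Anthropoidea", "Tarsiiformes", "extant Lemuriformes",
              "fossil Lemuriformes", "Lorisiformes", "Adapiformes")
  species_counts <- c(19L, 1L, 6L, 3L, 3L, 2L)
  group_sizes <- stats::setNames(species_counts * n_per_species, groups)
  clades <- stats::setNames(
    c("Haplorhini", "Haplorhini", "Strepsirrhini", "Strepsirrhini",
      "Strepsirrhini", "Strepsirrhini"),
    groups
  )
  scheme <- cranial_scheme()
  template <- template_skull(scheme, seed = 1L)
  basis <- similarity_basis(template)
  # magnitudes anchored to the scales typical of cross-primate cranial
  # samples: clade separation large enough to dominate the ordination,
  # species-level spread giving total Procrustes variances of order
  # 0.01-0.03 per clade, log centroid size spanning tarsier-to-ape sizes,
  # and an allometric component worth roughly a fifth of shape variance
  delta <- 0.18
  set.seed(as.integer(seed) %% 1000000L + 211L)
  axis_u <- plant_vector(template, 1, basis)     # clade separation axis
  w <- replicate(5, plant_vector(template, 1, basis), simplify = FALSE)
  eff <- list(
    "Anthropoidea"        = -0.5 * delta * axis_u,
    "Tarsiiformes"        = -0.5 * delta * axis_u + 0.25 * delta * w[[1]],
    "extant Lemuriformes" = +0.5 * delta * axis_u,
    "fossil Lemuriformes" = +0.5 * delta * axis_u + 0.45 * delta * w[[2]],
    "Lorisiformes"        = +0.5 * delta * axis_u + 0.20 * delta * w[[3]],
    "Adapiformes"         = +0.5 * delta * axis_u + 0.10 * delta * w[[4]]
  )
  allo <- plant_vector(template, 0.12, basis)
  skull_config(
    group_sizes = group_sizes, species_counts = species_counts,
    group_effect_vectors = eff, allometry_vector = allo,
    size_log_mean = log(100), size_log_sd = 0.6,
    noise_sd = 0.01,
    species_sd = c(0.017, 0.010, 0.011, 0.020, 0.011, 0.011),
    missingness = 0.4,
    fossil_groups = c("fossil Lemuriformes", "Adapiformes"),
    clades = clades, scheme = scheme, seed = seed
  )
}
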