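#' Pipeline configuration
#'
#' Bundles every switch of the full analysis sequence into one object:
#' input data (a long landmark tibble, a path readable by
#' [read_landmarks()], or a [skull_config()] to simulate), imputation,
#' species pooling, allometry mode, the list of pairwise discriminant
#' comparisons, the group-swap experiment, the disparity comparisons, the
#' resampling sizes, one root seed, and an output directory. All
#' stage-level randomness is derived from the root seed by stable
#' per-stage offsets, so a rerun with the same config is bit-identical.
#'
#' @param data Long landmark tibble, file path, or `skull_config`.
#' @param format File format for a path input (see [read_landmarks()]).
#' @param scheme A [landmark_scheme].
#' @param impute Impute missing bilateral landmarks first? (default TRUE)
#' @param pool_species Pool specimens to species mean shapes before
#'   ordination and discriminant analysis? (default TRUE)
#' @param allometry_mode `"raw_cs"` (regress shape on raw centroid size,
#'   the default), `"log_cs"`, or `"none"`.
#' @param group Metadata column naming the discriminant/disparity groups.
#' @param dfa_pairs `"all"` (every unordered pair of groups) or a list of
#'   2-vectors of group names; `NULL` skips pairwise DFA.
#' @param swap Optional list `(movable, host_a, host_b, group)` for the
#'   group-swap experiment; `group` defaults to the pipeline `group`
#'   column.
#' @param disparity_groups Optional list for disparity testing:
#'   `pairs` (list of 2-vectors compared by
#'   [disparity_difference_test()]) and `inclusion` (list of
#'   `(core, added)` 2-vectors tested by [inclusion_test()]), both named by
#'   groups in a chosen metadata column `column` (defaults to `group`).
#' @param n_permutations,n_bootstrap Resampling sizes (default 999).
#' @param seed Root seed.
#' @param output_dir Directory for CSV/JSON/TPS outputs; `NULL` keeps
#'   results in memory only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data, format = NULL, scheme = cranial_scheme(),
                            impute = TRUE, pool_species = TRUE,
                            allometry_mode = c("raw_cs", "log_cs", "none"),
                            group = "group", dfa_pairs = "all", swap = NULL,
                            disparity_groups = NULL,
                            n_permutations = 999, n_bootstrap = 999,
                            seed = 1L, output_dir = NULL) {
  allometry_mode <- match.arg(allometry_mode)
  structure(
    list(data = data, format = format, scheme = scheme, impute = impute,
         pool_species = pool_species, allometry_mode = allometry_mode,
         group = group, dfa_pairs = dfa_pairs, swap = swap,
         disparity_groups = disparity_groups,
         n_permutations = n_permutations, n_bootstrap = n_bootstrap,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

# fixed per-stage seed offsets: stable names, independent streams
stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, dfa = 23L, swap = 37L, disparity = 53L)
  (config$seed + offsets[[stage]] * 1009L) %% 2147483647L
}

#' Run the full cranial-shape analysis pipeline
#'
#' Executes the analysis sequence: (simulate or read) -> mirror-impute ->
#' GPA -> disparity on pre-allometry specimen coordinates -> optional
#' species pooling -> shape PCA -> allometric regression and residual PCA
#' -> pairwise DFA suite -> group-swap DFA. Disparity always runs before
#' allometric correction, and on specimen-level (unpooled) coordinates.
#' Every table written to `output_dir` is listed in the returned manifest
#' with a content hash; reruns with the same config are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: fitted objects (`gpa`,
#'   `gpa_pooled`, `pca`, `allometry`, `pca_corrected`, `dfa` list,
#'   `swap`, `disparity`, `disparity_tests`, `inclusion_tests`), the
#'   `manifest` tibble (stage, output, hash), and `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  note <- function(stage, name, object) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, output = name, hash = rlang::hash(object)
    )
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## data
  df <- with_stage("input", {
    if (inherits(config$data, "skull_config")) {
      cfg <- config$data
      cfg$seed <- stage_seed(config, "simulate")
      simulate_skulls(cfg)
    } else if (is.character(config$data)) {
      read_landmarks(config$data, format = config$format,
                     scheme = config$scheme)
    } else {
      config$data
    }
  })
  note("input", "landmarks", df)

  ## imputation
  if (config$impute) {
    df <- with_stage("impute", mirror_impute(df, config$scheme))
    note("impute", "imputation_report", attr(df, "imputation_report"))
  }

  ## superimposition
  fit <- with_stage("gpa", gpa(df, config$scheme))
  note("gpa", "aligned", fit$tangent)

  ## disparity before allometric correction, on specimen coordinates
  res_disp <- NULL; disp_tests <- NULL; incl_tests <- NULL
  if (!is.null(config$disparity_groups)) {
    dg <- config$disparity_groups
    col <- dg$column %||% config$group
    labels <- with_stage("disparity", group_labels_from_meta(fit$meta, col))
    res_disp <- disparity(fit, col)
    note("disparity", "group_variances", res_disp)
    sub <- function(g) fit$tangent[labels %in% g, , drop = FALSE]
    sd0 <- stage_seed(config, "disparity")
    disp_tests <- purrr::imap_dfr(dg$pairs %||% list(), function(pr, i) {
      dplyr::bind_cols(
        tibble::tibble(group_a = pr[1], group_b = pr[2]),
        disparity_difference_test(sub(pr[1]), sub(pr[2]),
                                  config$n_bootstrap, sd0 + i)
      )
    })
    incl_tests <- purrr::imap_dfr(dg$inclusion %||% list(), function(pr, i) {
      dplyr::bind_cols(
        tibble::tibble(core = pr[1], added = pr[2]),
        inclusion_test(sub(pr[1]), sub(pr[2]),
                       config$n_bootstrap, sd0 + 500L + i)
      )
    })
    if (!is.null(disp_tests)) note("disparity", "difference_tests", disp_tests)
    if (!is.null(incl_tests)) note("disparity", "inclusion_tests", incl_tests)
  }

  ## pooling
  fit_obs <- fit
  if (config$pool_species) {
    fit_obs <- with_stage("pool", pool_by_species(fit))
    note("pool", "species_means", fit_obs$tangent)
  }

  ## ordination
  pca <- with_stage("pca", shape_pca(fit_obs))
  note("pca", "variance_table", tidy(pca))

  ## allometry
  allo <- NULL; pca_corr <- NULL
  if (config$allometry_mode != "none") {
    cov_type <- if (config$allometry_mode == "log_cs") "log" else "raw"
    allo <- with_stage("allometry",
                       regress_shape_on_size(fit_obs, size_covariate = cov_type))
    pca_corr <- allometry_corrected_pca(fit_obs, model = allo)
    note("allometry", "regression", glance(allo))
    note("allometry", "corrected_variance_table", tidy(pca_corr))
  }

  ## pairwise DFA
  dfa_results <- NULL
  if (!is.null(config$dfa_pairs)) {
    labels <- group_labels_from_meta(fit_obs$meta, config$group)
    pairs <- if (identical(config$dfa_pairs, "all")) {
      g <- unique(labels)
      utils::combn(g, 2, simplify = FALSE)
    } else config$dfa_pairs
    sd0 <- stage_seed(config, "dfa")
    dfa_results <- with_stage("dfa", purrr::imap(pairs, function(pr, i) {
      pairwise_dfa(fit_obs, config$group, pr[1], pr[2],
                   n_permutations = config$n_permutations, seed = sd0 + i)
    }))
    names(dfa_results) <- vapply(pairs, paste, character(1), collapse = " vs ")
    note("dfa", "pairwise_results",
         purrr::map_dfr(dfa_results, glance))
  }

  ## group-swap experiment
  swap_res <- NULL
  if (!is.null(config$swap)) {
    sw <- config$swap
    swap_res <- with_stage("swap", group_swap_dfa(
      fit_obs, sw$group %||% config$group, sw$movable, sw$host_a, sw$host_b,
      n_permutations = config$n_permutations,
      seed = stage_seed(config, "swap")
    ))
    note("swap", "swap_results", glance(swap_res))
  }

  manifest <- dplyr::bind_rows(manifest)
  result <- list(
    gpa = fit, gpa_pooled = if (config$pool_species) fit_obs else NULL,
    pca = pca, allometry = allo, pca_corrected = pca_corr,
    dfa = dfa_results, swap = swap_res,
    disparity = res_disp, disparity_tests = disp_tests,
    inclusion_tests = incl_tests,
    manifest = manifest,
    config_hash = rlang::hash(config)
  )
  class(result) <- "pipeline_result"
  if (!is.null(config$output_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  readr::write_csv(tidy(result$gpa), out("aligned_coordinates.csv"))
  readr::write_csv(tibble::tibble(
    specimen_id = names(result$gpa$centroid_sizes),
    centroid_size = unname(result$gpa$centroid_sizes)
  ), out("centroid_sizes.csv"))
  cons <- tibble::tibble(specimen_id = "consensus", taxon = "consensus",
                         landmark = seq_len(nrow(result$gpa$consensus)),
                         x = result$gpa$consensus[, 1],
                         y = result$gpa$consensus[, 2],
                         z = result$gpa$consensus[, 3])
  write_landmarks(cons, out("consensus.tps"), format = "tps",
                  scheme = config$scheme)
  readr::write_csv(tidy(result$pca), out("pca_variance.csv"))
  readr::write_csv(augment(result$pca), out("pca_scores.csv"))
  if (!is.null(result$pca_corrected)) {
    readr::write_csv(tidy(result$pca_corrected),
                     out("pca_corrected_variance.csv"))
    readr::write_csv(augment(result$pca_corrected),
                     out("pca_corrected_scores.csv"))
  }
  if (!is.null(result$dfa)) {
    readr::write_csv(purrr::map_dfr(result$dfa, glance),
                     out("dfa_pairwise.csv"))
    jsonlite::write_json(
      purrr::map(result$dfa, function(f) list(
        group_a = f$group_a, group_b = f$group_b,
        mahalanobis_distance = f$mahalanobis_distance,
        permutation_p = f$permutation_p,
        loo_table = as.vector(f$loo_table)
      )),
      out("dfa_pairwise.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(result$swap)) {
    readr::write_csv(glance(result$swap), out("dfa_swap.csv"))
  }
  if (!is.null(result$disparity)) {
    readr::write_csv(result$disparity, out("disparity.csv"))
  }
  if (!is.null(result$disparity_tests) && nrow(result$disparity_tests)) {
    readr::write_csv(result$disparity_tests, out("disparity_tests.csv"))
  }
  if (!is.null(result$inclusion_tests) && nrow(result$inclusion_tests)) {
    readr::write_csv(result$inclusion_tests, out("inclusion_tests.csv"))
  }
  readr::write_csv(result$manifest, out("manifest.csv"))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages run: ",
      paste(unique(x$manifest$stage), collapse = ", "), "\n", sep = "")
  cat("  config hash ", x$config_hash, "\n", sep = "")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Reads the analysis switches of [pipeline_config()] from a YAML file;
#' the `data` field may be a landmark file path or `preset: primate` to
#' use [primate_preset()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- if (identical(y$preset, "primate")) {
    primate_preset(seed = y$seed %||% 1L)
  } else {
    y$data
  }
  pipeline_config(
    data = data, format = y$format,
    impute = y$impute %||% TRUE,
    pool_species = y$pool_species %||% TRUE,
    allometry_mode = y$allometry_mode %||% "raw_cs",
    group = y$group %||% "group",
    dfa_pairs = y$dfa_pairs %||% "all",
    swap = y$swap,
    disparity_groups = y$disparity_groups,
    n_permutations = y$n_permutations %||% 999,
    n_bootstrap = y$n_bootstrap %||% 999,
    seed = y$seed %||% 1L,
    output_dir = y$output_dir
  )
}
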