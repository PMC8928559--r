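#' Default pipeline configuration
#'
#' One place to see every constant the pipeline applies: variable-selection
#' size and correlation threshold, clustering cap, aridity/salinity
#' thresholds, the binarization decile, the calibration run design and the
#' subset caps. Override any entry through the `...` of [run_pipeline()] or
#' by editing a YAML file written with [write_config()].
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    top_n_variables = 15L,
    r_threshold = 0.5,
    cor_alpha = 0.05,
    max_k = 6L,
    elbow = "ratio",
    drought_iar_dm = 15,
    drought_iar_dm_f = 15,
    waterlogging_iar_dm = 25,
    salinity_lower = 2,
    salinity_upper = 4,
    binarize_quantile = 0.10,
    n_runs = 100L,
    train_frac = 0.75,
    stratify = TRUE,
    subset_cap = 30L,
    calibration_top_n = 30L,
    algorithms = suite_algorithms(),
    n_background = NULL,
    stages = list(
      selectvar = TRUE, elcmap = TRUE, indices = TRUE,
      filter = TRUE, calibrate = TRUE, overlaps = TRUE
    )
  )
}

#' @rdname default_config
#' @param config A config list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  modifyList(default_config(), yaml::read_yaml(path))
}

#' Run the predictive-characterization pipeline end to end
#'
#' Orchestrates the stages in their natural order — variable selection,
#' ELC-map construction, index computation, the three environmental-filter
#' selections, calibration modeling and the overlap report — writing each
#' stage's table to `out_dir` together with a manifest (configuration,
#' seed, row counts per stage) from which the run can be reproduced.
#' Stages can be toggled off via `config$stages`; a stage failure halts the
#' run with the stage's name while preserving completed outputs.
#'
#' @param stack A `pc_stack` of environmental layers.
#' @param occurrences Tibble of populations (see [read_occurrences()]).
#' @param evaluations Tibble of trait evaluations (see
#'   [read_evaluations()]), or `NULL` to skip calibration.
#' @param out_dir Output directory, created if needed.
#' @param config Configuration list (see [default_config()]).
#' @param registry Variable registry.
#' @param ... Individual config overrides (e.g. `n_runs = 25`).
#' @return A list with every stage's result plus `manifest`, invisibly
#'   written to `out_dir`.
#' @export
run_pipeline <- function(stack, occurrences, evaluations = NULL,
                         out_dir = tempfile("predchar_run_"),
                         config = default_config(),
                         registry = default_registry(), ...) {
  config <- modifyList(config, list(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  counts <- list(occurrences = nrow(occurrences))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = "predchar_pipeline_error"
      )
    })
  }

  if (isTRUE(config$stages$selectvar)) {
    res$ranking <- stage("selectvar", {
      rank_variables(occurrences, stack,
        registry = registry,
        n_background = config$n_background,
        seed = derive_seed(config$seed, "selectvar")
      ) |>
        prune_correlated(
          data = occurrences[intersect(registry$name, names(occurrences))],
          top_n = config$top_n_variables,
          r_threshold = config$r_threshold, alpha = config$cor_alpha
        )
    })
    readr::write_csv(res$ranking, file.path(out_dir, "ranking.csv"), progress = FALSE)
    counts$retained_variables <- sum(res$ranking$retained)
  }

  if (isTRUE(config$stages$elcmap)) {
    res$elc <- stage("elcmap", {
      vars <- retained_variables(res$ranking)
      elc_map(stack, vars,
        max_k = config$max_k, elbow = config$elbow,
        seed = derive_seed(config$seed, "elcmap")
      )
    })
    write_raster(res$elc$category_grid, file.path(out_dir, "elc_map.asc"), nodata = -9999)
    readr::write_csv(res$elc$legend, file.path(out_dir, "elc_legend.csv"), progress = FALSE)
    occurrences <- stage("elcmap", assign_category(res$elc, occurrences))
    counts$elc_categories <- nrow(res$elc$legend)
    counts$populations_assigned <- sum(!occurrences$elc_excluded)
  }

  if (isTRUE(config$stages$indices)) {
    occurrences <- stage("indices", add_env_indices(occurrences))
    readr::write_csv(occurrences, file.path(out_dir, "indexed.csv"), progress = FALSE)
  }

  if (isTRUE(config$stages$filter)) {
    res$drought <- stage("filter", select_drought(occurrences, cap = config$subset_cap))
    res$salinity <- stage("filter", select_salinity(occurrences, cap = config$subset_cap))
    res$waterlogging <- stage("filter", select_waterlogging(occurrences, cap = config$subset_cap))
    for (tr in c("drought", "salinity", "waterlogging")) {
      readr::write_csv(
        res[[tr]]$members,
        file.path(out_dir, paste0("subset_", tr, ".csv")),
        progress = FALSE
      )
      counts[[paste0(tr, "_selected")]] <- nrow(res[[tr]]$members)
    }
  }

  if (isTRUE(config$stages$calibrate) && !is.null(evaluations)) {
    res$calibration <- stage("calibrate", {
      labeled <- binarize_dsr(evaluations, quantile = config$binarize_quantile)
      env <- extract_at_points(stack, labeled[c("lon", "lat")])
      predictors <- retained_variables(res$ranking)
      labeled <- dplyr::bind_cols(
        labeled[setdiff(names(labeled), predictors)],
        env[predictors]
      )
      suite <- train_suite(labeled, predictors,
        algorithms = config$algorithms,
        n_runs = config$n_runs, train_frac = config$train_frac,
        stratify = config$stratify,
        seed = derive_seed(config$seed, "calibrate")
      )
      select_and_project(suite, occurrences, top_n = config$calibration_top_n)
    })
    readr::write_csv(res$calibration$summary, file.path(out_dir, "tss_summary.csv"),
      progress = FALSE
    )
    if (res$calibration$verdict == "ok") {
      readr::write_csv(
        select(
          res$calibration$projections,
          "pop_id", "suitability", "label"
        ),
        file.path(out_dir, "projections.csv"),
        progress = FALSE
      )
      readr::write_csv(res$calibration$top_subset,
        file.path(out_dir, "subset_calibration.csv"),
        progress = FALSE
      )
      counts$calibration_selected <- nrow(res$calibration$top_subset)
    }
    counts$calibration_verdict <- res$calibration$verdict
  }

  if (isTRUE(config$stages$overlaps) && isTRUE(config$stages$filter)) {
    subsets <- list(
      drought = res$drought, salinity = res$salinity,
      waterlogging = res$waterlogging
    )
    if (!is.null(res$calibration) && res$calibration$verdict == "ok") {
      subsets$calibration <- res$calibration$top_subset
    }
    res$overlaps <- stage("overlaps", do.call(summarize_overlaps, subsets))
    readr::write_csv(res$overlaps$membership, file.path(out_dir, "overlaps.csv"),
      progress = FALSE
    )
  }

  res$manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_hash = rlang::hash(config),
    counts = counts
  )
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  res$out_dir <- out_dir
  invisible(res)
}
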