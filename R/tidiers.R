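#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (variables of a ranking, members of a subset, runs of a suite, projected
#' populations of a calibration, legend rows of an ELC map), `glance()` a
#' one-row summary.
#'
#' @param x A predchar result object.
#' @param ... Unused.
#' @return A tibble.
#' @name predchar-tidiers
NULL

#' @rdname predchar-tidiers
#' @export
tidy.pc_ranking <- function(x, ...) {
  as_tibble(x)
}

#' @rdname predchar-tidiers
#' @export
tidy.pc_subset <- function(x, ...) {
  mutate(x$members, trait = x$trait, .before = 1)
}

#' @rdname predchar-tidiers
#' @export
glance.pc_subset <- function(x, ...) {
  tibble(
    trait = x$trait,
    n_selected = nrow(x$members),
    n_candidates = x$n_candidates,
    capped = x$capped,
    n_elc_categories = length(unique(stats::na.omit(x$members$elc_category)))
  )
}

#' @rdname predchar-tidiers
#' @export
tidy.pc_elc <- function(x, ...) {
  x$legend
}

#' @rdname predchar-tidiers
#' @export
glance.pc_elc <- function(x, ...) {
  tibble(
    n_categories = nrow(x$legend),
    k_bioclimatic = x$k[["bioclimatic"]],
    k_edaphic = x$k[["edaphic"]],
    k_geophysic = x$k[["geophysic"]],
    n_nodata_cells = sum(x$category_grid$values == 0)
  )
}

#' @rdname predchar-tidiers
#' @export
tidy.pc_runs <- function(x, ...) {
  x$runs
}

#' @rdname predchar-tidiers
#' @export
glance.pc_runs <- function(x, ...) {
  x$summary
}

#' @rdname predchar-tidiers
#' @export
tidy.pc_calibration <- function(x, ...) {
  if (x$verdict == "unmodelable") {
    return(tibble())
  }
  select(x$projections, dplyr::any_of(c("pop_id", "taxon", "country")),
    "suitability", "label"
  )
}

#' @rdname predchar-tidiers
#' @export
glance.pc_calibration <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    algorithm = x$algorithm,
    best_tss = x$tss,
    cutoff = x$cutoff,
    n_resistant = if (x$verdict == "ok") {
      sum(x$projections$label == "resistant", na.rm = TRUE)
    } else {
      0L
    },
    n_top_subset = nrow(x$top_subset)
  )
}

#' @rdname predchar-tidiers
#' @export
tidy.pc_overlap <- function(x, ...) {
  x$pairwise
}
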