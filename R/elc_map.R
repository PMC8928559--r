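#' Cluster one component's variables over the grid
#'
#' Runs k-means (25 restarts per k) on the z-standardized values of a
#' component's retained layers for k = 1..`max_k` and picks the number of
#' clusters with an elbow rule on the within-cluster sum of squares: the
#' smallest k >= 2 whose next decrease `wss(k) - wss(k+1)` falls below half
#' of the previous decrease `wss(k-1) - wss(k)`. If the rule never fires the
#' component keeps `max_k` clusters; a component with (near-)constant values
#' keeps a single cluster. The alternative reading of the stopping sentence
#' — stop when the decrease is less than half of `wss(k)` itself — is
#' available as `elbow = "absolute"`.
#'
#' @param mat Numeric matrix, one row per grid cell, one column per
#'   variable. Rows with missing values are excluded (assignment 0).
#' @param max_k Maximum clusters per component (default 6).
#' @param seed Integer seed (k-means restarts are seeded).
#' @param elbow `"ratio"` (default) or `"absolute"`.
#' @param n_init Random restarts per k.
#' @return A list: `k` (chosen), `assignments` (integer vector over rows of
#'   `mat`, 0 for incomplete rows), `wss` (length `max_k`), `centers`.
#' @export
cluster_component <- function(mat, max_k = 6, seed = 1L,
                              elbow = c("ratio", "absolute"), n_init = 25) {
  elbow <- match.arg(elbow)
  mat <- as.matrix(mat)
  cc <- complete.cases(mat)
  x <- mat[cc, , drop = FALSE]
  if (nrow(x) < 2) {
    abort("need at least two complete-case cells", class = "predchar_spec_error")
  }
  sds <- apply(x, 2, sd)
  x_std <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  n_distinct <- nrow(unique(x_std))
  if (max_k > n_distinct) {
    warn(sprintf("reducing max_k from %d to %d distinct cells", max_k, n_distinct))
    max_k <- n_distinct
  }
  wss <- rep(NA_real_, max_k)
  fits <- vector("list", max_k)
  wss[1] <- sum(scale(x_std, scale = FALSE)^2)
  for (k in seq_len(max_k)[-1]) {
    fits[[k]] <- with_seed(
      derive_seed(seed, "kmeans", k),
      kmeans(x_std, centers = k, nstart = n_init, iter.max = 50)
    )
    wss[k] <- fits[[k]]$tot.withinss
  }
  tot <- wss[1]
  k_star <- if (max_k == 1L || tot < 1e-12) {
    1L
  } else {
    chosen <- NA_integer_
    for (k in 2:max_k) {
      if (k + 1 > max_k) break
      dec_prev <- wss[k - 1] - wss[k]
      dec_next <- wss[k] - wss[k + 1]
      threshold <- if (elbow == "ratio") 0.5 * dec_prev else 0.5 * wss[k]
      if (dec_next < threshold) {
        chosen <- k
        break
      }
    }
    if (is.na(chosen)) max_k else chosen
  }
  assignments <- integer(nrow(mat))
  assignments[cc] <- if (k_star == 1L) 1L else fits[[k_star]]$cluster
  centers <- if (k_star == 1L) {
    matrix(colMeans(x_std), nrow = 1, dimnames = list(NULL, colnames(mat)))
  } else {
    fits[[k_star]]$centers
  }
  list(k = k_star, assignments = assignments, wss = wss, centers = centers)
}

# The elbow stopping rule in isolation, for a precomputed wss sequence.
elbow_k <- function(wss, elbow = "ratio") {
  max_k <- length(wss)
  if (max_k < 2) {
    return(max_k)
  }
  for (k in 2:max_k) {
    if (k + 1 > max_k) break
    threshold <- if (elbow == "ratio") 0.5 * (wss[k - 1] - wss[k]) else 0.5 * wss[k]
    if (wss[k] - wss[k + 1] < threshold) {
      return(k)
    }
  }
  max_k
}

#' Compose ecogeographic categories from the three component clusterings
#'
#' Every cell carries a (bioclimatic, edaphic, geophysic) cluster triple;
#' the distinct triples realized on the grid become the ELC categories,
#' numbered densely 1..n in row-major order over the sorted triples so
#' reruns are comparable. Cells missing any component are category 0
#' (no-data) and are excluded from downstream selections.
#'
#' @param component_grids Named list of three integer matrices
#'   (`bioclimatic`, `edaphic`, `geophysic`), cluster ids with 0 = missing.
#' @param spec Optional `pc_grid` supplying the georeference for the
#'   category grid (defaults to an index grid at origin).
#' @param k Optional named vector of cluster counts per component (defaults
#'   to the observed maxima).
#' @param wss Optional list of wss curves, carried for reporting.
#' @return A `pc_elc` object: `category_grid` (`pc_grid`), `component_grids`,
#'   `legend` (tibble mapping triples to category ids), `k`, `wss`.
#' @export
compose_categories <- function(component_grids, spec = NULL, k = NULL, wss = NULL) {
  comps <- elc_components()
  if (!all(comps %in% names(component_grids))) {
    abort("component_grids must be named bioclimatic/edaphic/geophysic",
      class = "predchar_spec_error"
    )
  }
  dims <- lapply(component_grids[comps], dim)
  if (length(unique(dims)) != 1) {
    abort("component grids have mismatched dimensions", class = "predchar_dimension_error")
  }
  b <- component_grids$bioclimatic
  e <- component_grids$edaphic
  g <- component_grids$geophysic
  ok <- b > 0 & e > 0 & g > 0
  triples <- tibble(bio = b[ok], eda = e[ok], geo = g[ok]) |>
    distinct() |>
    arrange(.data$bio, .data$eda, .data$geo) |>
    mutate(category = row_number())
  key <- function(bb, ee, gg) paste(bb, ee, gg, sep = "-")
  lut <- setNames(triples$category, key(triples$bio, triples$eda, triples$geo))
  cat_grid <- matrix(0L, nrow(b), ncol(b))
  cat_grid[ok] <- lut[key(b[ok], e[ok], g[ok])]
  values <- if (is.null(spec)) {
    pc_grid(cat_grid, xll = 0, yll = 0, cellsize = 1)
  } else {
    pc_grid(cat_grid, xll = spec$xll, yll = spec$yll, cellsize = spec$cellsize)
  }
  structure(
    list(
      category_grid = values,
      component_grids = component_grids[comps],
      legend = triples,
      k = k %||% vapply(component_grids[comps], max, numeric(1)),
      wss = wss
    ),
    class = "pc_elc"
  )
}

#' @export
print.pc_elc <- function(x, ...) {
  cat(sprintf(
    "<pc_elc> %d categories from %s clusters on a %d x %d grid (%d no-data cells)\n",
    nrow(x$legend),
    paste(x$k, collapse = " x "),
    nrow(x$category_grid$values), ncol(x$category_grid$values),
    sum(x$category_grid$values == 0)
  ))
  invisible(x)
}

#' Build an ELC map from a stack and a set of retained variables
#'
#' Convenience wrapper: clusters each component's retained layers with
#' [cluster_component()] and composes the categories with
#' [compose_categories()].
#'
#' @param stack A `pc_stack`.
#' @param variables Character vector of retained layer names (e.g. from
#'   [retained_variables()]); must cover all three components.
#' @param max_k,seed,elbow Passed to [cluster_component()].
#' @return A `pc_elc`.
#' @export
elc_map <- function(stack, variables, max_k = 6, seed = 1L, elbow = "ratio") {
  stopifnot(inherits(stack, "pc_stack"))
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing) > 0) {
    abort(
      paste0("variables not in stack: ", paste(missing, collapse = ", ")),
      class = "predchar_spec_error"
    )
  }
  ref <- stack$layers[[1]]
  nr <- nrow(ref$values)
  nc <- ncol(ref$values)
  comp_grids <- list()
  wss <- list()
  k <- c()
  for (comp in elc_components()) {
    vars <- variables[stack$component[variables] == comp]
    if (length(vars) == 0) {
      abort(
        sprintf("no retained variable for the %s component", comp),
        class = "predchar_spec_error"
      )
    }
    mat <- sapply(vars, function(v) as.vector(stack$layers[[v]]$values))
    cl <- cluster_component(matrix(mat, ncol = length(vars),
      dimnames = list(NULL, vars)
    ), max_k = max_k, seed = derive_seed(seed, comp), elbow = elbow)
    comp_grids[[comp]] <- matrix(cl$assignments, nr, nc)
    wss[[comp]] <- cl$wss
    k[comp] <- cl$k
  }
  compose_categories(comp_grids, spec = ref, k = k, wss = wss)
}

#' Assign ELC categories to populations
#'
#' Nearest-cell lookup of the category grid at each population's
#' coordinates. Populations falling outside the grid or on no-data
#' (category 0) cells receive `NA` and are flagged `elc_excluded`; such
#' populations are never entered into trait selections.
#'
#' @param elc A `pc_elc`.
#' @param populations Tibble with `lon` and `lat`.
#' @return The populations tibble with `elc_category` (integer, `NA` when
#'   unassignable) and `elc_excluded` (logical) columns.
#' @export
assign_category <- function(elc, populations) {
  stopifnot(inherits(elc, "pc_elc"))
  populations <- as_tibble(populations)
  assert_columns(populations, c("lon", "lat"), "populations")
  stack1 <- pc_stack(
    list(category = elc$category_grid),
    c(category = "geophysic")
  )
  ex <- extract_at_points(stack1, populations[c("lon", "lat")])
  category <- as.integer(ex$category)
  category[!is.na(category) & category == 0L] <- NA_integer_
  populations$elc_category <- category
  populations$elc_excluded <- is.na(category)
  populations
}
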