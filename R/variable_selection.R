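#' Rank ecogeographic variables by importance for the occurrence distribution
#'
#' Fits a random-forest classifier separating the cells where populations
#' occur from randomly drawn background cells of the territory, and scores
#' every registered variable by its permutation-based mean decrease in
#' accuracy (MDA). Latitude and longitude participate as geophysic
#' candidates. An alternative multiclass response on taxon identity is
#' available for runs where the taxa, rather than presence, are the signal
#' of interest.
#'
#' @param occurrences Tibble of populations with environmental columns (and
#'   `taxon` if `response = "taxon"`).
#' @param stack `pc_stack` supplying background cells (ignored for the taxon
#'   response).
#' @param registry Variable registry declaring component membership.
#' @param n_background Number of background cells; default 10 per presence
#'   cell, drawn without duplicates from valid cells not occupied by a
#'   presence.
#' @param response `"presence"` (default) or `"taxon"`.
#' @param ntree Trees in the forest.
#' @param seed Integer seed; results are reproducible bit for bit.
#' @return A `pc_ranking` tibble: `name`, `component`, `mda`, `rank` (within
#'   component, ties broken by name), `retained`, `dropped_because`.
#' @export
rank_variables <- function(occurrences, stack, registry = default_registry(),
                           n_background = NULL, response = c("presence", "taxon"),
                           ntree = 500, seed = 1L) {
  response <- match.arg(response)
  occurrences <- as_tibble(occurrences)
  vars <- intersect(registry$name, names(occurrences))
  if (length(vars) < 2) {
    abort("need at least two registered variables", class = "predchar_spec_error")
  }
  comp_of <- c(
    setNames(registry$component, registry$name),
    lon = "geophysic", lat = "geophysic"
  )
  pres <- occurrences[c("lon", "lat", vars)]
  all_missing <- vapply(pres, function(x) all(is.na(x)), logical(1))
  if (any(all_missing)) {
    warn(paste0(
      "excluding all-missing variable(s): ",
      paste(names(pres)[all_missing], collapse = ", ")
    ))
    pres <- pres[!all_missing]
    vars <- setdiff(vars, names(all_missing)[all_missing])
  }

  if (response == "presence") {
    stopifnot(inherits(stack, "pc_stack"))
    cells <- grid_coords(stack$layers[[1]])
    env <- extract_at_points(stack, cells[c("lon", "lat")])
    pres_cells <- unique(stats::na.omit(cell_index_of(stack, occurrences)))
    valid <- which(!env$on_nodata & !env$out_of_extent)
    pool <- setdiff(valid, pres_cells)
    n_bg <- min(n_background %||% (10L * nrow(pres)), length(pool))
    bg_idx <- with_seed(derive_seed(seed, "background"), sample(pool, n_bg))
    bg <- env[bg_idx, c("lon", "lat", vars)]
    dat <- bind_rows(pres, bg)
    y <- factor(rep(c("presence", "background"), c(nrow(pres), nrow(bg))))
  } else {
    dat <- pres
    y <- factor(occurrences$taxon)
  }

  cc <- complete.cases(dat)
  fit <- with_seed(derive_seed(seed, "forest"), {
    randomForest::randomForest(
      x = as.data.frame(dat[cc, ]), y = droplevels(y[cc]),
      ntree = ntree, importance = TRUE
    )
  })
  imp <- randomForest::importance(fit, type = 1) # mean decrease accuracy
  ranking <- tibble(
    name = rownames(imp),
    component = unname(comp_of[rownames(imp)]),
    mda = as.numeric(imp[, 1])
  ) |>
    group_by(.data$component) |>
    arrange(desc(.data$mda), .data$name, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    mutate(retained = NA, dropped_because = NA_character_)
  class(ranking) <- c("pc_ranking", class(ranking))
  attr(ranking, "response") <- response
  attr(ranking, "seed") <- seed
  ranking
}

cell_index_of <- function(stack, points) {
  ref <- stack$layers[[1]]
  nr <- nrow(ref$values)
  nc <- ncol(ref$values)
  col <- floor((points$lon - ref$xll) / ref$cellsize) + 1L
  row <- nr - floor((points$lat - ref$yll) / ref$cellsize)
  inside <- !is.na(col) & col >= 1 & col <= nc & row >= 1 & row <= nr
  ifelse(inside, (col - 1L) * nr + row, NA_integer_)
}

#' Prune correlated variables within each component
#'
#' Within each component, takes the `top_n` variables by MDA and scans them
#' in decreasing-importance order, retaining a variable only if its Pearson
#' correlation with every already-retained variable of the same component is
#' not significant at `alpha` or has `|r|` at or below `r_threshold`.
#' Correlations are computed on the occurrence-site values, since selection
#' concerns the environmental space the populations actually occupy. The
#' within-component importance maximum is always retained.
#'
#' @param ranking A `pc_ranking` from [rank_variables()].
#' @param data Tibble of occurrence-site variable values (one column per
#'   ranked variable).
#' @param top_n Variables considered per component (default 15). Set
#'   `pooled = TRUE` to apply `top_n` to the pooled ranking instead.
#' @param r_threshold Absolute Pearson correlation above which a variable is
#'   considered redundant (default 0.5).
#' @param alpha Significance level for the correlation test (default 0.05).
#' @param pooled Apply `top_n` across all components pooled rather than per
#'   component.
#' @return The ranking with `retained` filled in and `dropped_because`
#'   naming the higher-ranked variable responsible for each drop.
#' @export
prune_correlated <- function(ranking, data, top_n = 15, r_threshold = 0.5,
                             alpha = 0.05, pooled = FALSE) {
  stopifnot(inherits(ranking, "pc_ranking"))
  data <- as_tibble(data)
  ranking$retained <- FALSE
  ranking$dropped_because <- NA_character_
  if (pooled) {
    ord <- order(-ranking$mda, ranking$name)
    candidate <- rep(FALSE, nrow(ranking))
    candidate[ord[seq_len(min(top_n, length(ord)))]] <- TRUE
  } else {
    candidate <- ranking$rank <= top_n
  }
  for (comp in unique(ranking$component)) {
    rows <- which(candidate & ranking$component == comp & ranking$name %in% names(data))
    rows <- rows[order(-ranking$mda[rows], ranking$name[rows])]
    kept <- character(0)
    for (i in rows) {
      v <- ranking$name[i]
      blocker <- NA_character_
      for (u in kept) {
        ok <- sum(complete.cases(data[[v]], data[[u]])) >= 3
        if (!ok) next
        ct <- suppressWarnings(cor.test(data[[v]], data[[u]], method = "pearson"))
        if (!is.na(ct$estimate) && abs(ct$estimate) > r_threshold &&
          !is.na(ct$p.value) && ct$p.value < alpha) {
          blocker <- u
          break
        }
      }
      if (is.na(blocker)) {
        kept <- c(kept, v)
        ranking$retained[i] <- TRUE
      } else {
        ranking$dropped_because[i] <- blocker
      }
    }
  }
  ranking
}

#' Variables retained after pruning
#'
#' @param ranking A pruned `pc_ranking`.
#' @return Character vector of retained variable names, by component then
#'   rank.
#' @export
retained_variables <- function(ranking) {
  ranking |>
    filter(.data$retained) |>
    arrange(.data$component, .data$rank) |>
    pull(.data$name)
}
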