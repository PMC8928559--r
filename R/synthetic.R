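#' Synthetic ground truth for end-to-end testing
#'
#' Defines everything the synthetic generator needs and everything a test
#' needs to verify recovery: the number of environmental zones per component
#' (capped at 6, matching the clustering cap downstream), per-zone layer
#' values, the variables that genuinely drive where populations occur, the
#' logistic link generating Disease Severity Ratings, and the noise levels.
#' All downstream synthetic outputs are pure functions of the truth object
#' and the requested sizes: the same seed reproduces them bit for bit.
#'
#' @param seed Integer master seed; per-stage substreams are derived from it.
#' @param true_k Named integer vector: zones per component
#'   (`bioclimatic`, `edaphic`, `geophysic`), each between 1 and 6.
#' @param noise_sd Within-zone layer noise, as a fraction of each variable's
#'   characteristic spread (so one knob controls all layers).
#' @param informative Named numeric vector of log-intensity coefficients on
#'   standardized variables; occurrence sampling intensity is
#'   `exp(sum(beta * z))`.
#' @param dsr_link Named numeric vector of logistic coefficients (plus an
#'   `"(Intercept)"` entry) on standardized variables; severity is
#'   `100 * (1 - plogis(eta))` plus Gaussian noise, so high linear predictors
#'   mean resistance.
#' @param dsr_noise_sd Gaussian noise added to severity, in DSr units (0-100
#'   scale), before clipping.
#' @param taxa_weights Named sampling weights for taxon labels. Defaults to
#'   the observed composition of the European wild-lentil occurrence set
#'   (443 : 145 : 29 : 7 across the four taxa).
#' @param genebank_frac Fraction of populations given a genebank-held
#'   (`GE_`-prefixed) identifier (105/624 by default).
#' @param zones One of `"blocks"` (axis-aligned contiguous bands, default) or
#'   `"voronoi"` (zones grown around seeded centroids).
#' @return An object of class `pc_truth`.
#' @export
synthetic_truth <- function(seed = 1L,
                            true_k = c(bioclimatic = 4L, edaphic = 3L, geophysic = 3L),
                            noise_sd = 0.05,
                            informative = c(tmean_annual = 1),
                            dsr_link = c("(Intercept)" = -1, tmean_annual = 2,
                                         solar_annual = 1.3),
                            dsr_noise_sd = 8,
                            taxa_weights = c(
                              "L. nigricans" = 443, "L. ervoides" = 145,
                              "L. lamottei" = 29,
                              "L. culinaris ssp. orientalis" = 7
                            ),
                            genebank_frac = 105 / 624,
                            zones = c("blocks", "voronoi")) {
  zones <- match.arg(zones)
  stopifnot(all(elc_components() %in% names(true_k)))
  true_k <- as.integer(true_k[elc_components()])
  names(true_k) <- elc_components()
  if (any(true_k < 1L) || any(true_k > 6L)) {
    abort("true_k must be between 1 and 6 per component", class = "predchar_spec_error")
  }
  if (noise_sd < 0 || dsr_noise_sd < 0) {
    abort("noise sds must be >= 0", class = "predchar_spec_error")
  }
  registry <- default_registry()
  vt <- variable_scales()
  link_vars <- setdiff(names(dsr_link), "(Intercept)")
  bad <- setdiff(c(names(informative), link_vars), registry$name)
  if (length(bad) > 0) {
    abort(
      paste0("coefficients reference unregistered variables: ", paste(bad, collapse = ", ")),
      class = "predchar_spec_error"
    )
  }
  centers <- with_seed(derive_seed(seed, "centers"), {
    lapply(setNames(elc_components(), elc_components()), function(comp) {
      vars <- registry$name[registry$component == comp]
      vars <- setdiff(vars, derived_variables())
      k <- true_k[[comp]]
      # Mutually equidistant zone centers (a randomly rotated regular
      # simplex in standardized-variable space): each additional cluster
      # then explains a comparable share of variance, the regime the elbow
      # rule presumes for distinct adaptive scenarios.
      std <- simplex_centers(k, length(vars), separation = 2.5)
      m <- std * rep(vt$spread[match(vars, vt$name)], each = k) +
        rep(vt$base[match(vars, vt$name)], each = k)
      matrix(m, nrow = k, dimnames = list(NULL, vars))
    })
  })
  structure(
    list(
      seed = as.integer(seed), true_k = true_k, centers = centers,
      informative = informative, dsr_link = dsr_link,
      noise_sd = noise_sd, dsr_noise_sd = dsr_noise_sd,
      taxa_weights = taxa_weights / sum(taxa_weights),
      genebank_frac = genebank_frac, zones = zones,
      registry = registry, scales = vt
    ),
    class = "pc_truth"
  )
}

# k points in R^p with equal pairwise distances `separation` (vertices of a
# regular simplex; needs p >= k - 1, otherwise the points are spread at
# random on a sphere). The simplex is embedded through an orthonormal frame
# with (near-)equal row norms, so every coordinate carries an equal share of
# the between-center signal — no variable is left signal-free.
simplex_centers <- function(k, p, separation = 2.5) {
  if (k == 1L) {
    return(matrix(0, 1, p))
  }
  if (p >= k - 1) {
    e <- diag(k) - 1 / k
    v <- svd(e)$u[, seq_len(k - 1), drop = FALSE] # unit pairwise distance sqrt(2)
    x <- v %*% t(equal_norm_frame(p, k - 1L))
  } else {
    x <- matrix(rnorm(k * p), k, p)
    x <- x / sqrt(rowSums(x^2)) / sqrt(2)
  }
  x * separation / sqrt(2)
}

# p x m matrix with orthonormal columns and near-equal row norms, by
# alternating projections between the two constraint sets.
equal_norm_frame <- function(p, m) {
  q <- qr.Q(qr(matrix(rnorm(p * m), p, m)))
  target <- sqrt(m / p)
  for (i in 1:30) {
    norms <- sqrt(rowSums(q^2))
    q <- q * target / pmax(norms, 1e-9)
    q <- qr.Q(qr(q))
  }
  q
}

# Characteristic value and spread per registered variable, in native units.
# These anchor zone centers, layer noise and the standardization used by the
# occurrence and severity links (so ground truth does not depend on which
# sample was drawn).
variable_scales <- function() {
  tibble(
    name = default_registry()$name,
    base = c(
      14, 600, 1, 10, 8, 11, 15, 19, 60, 55, 45, 30,
      30, 35, 35, 1, 1.4, 100, 15000, 5000, 500
    ),
    spread = c(
      6, 350, 0.3, 4, 5, 5, 5, 5, 35, 30, 25, 20,
      18, 20, 20, 1, 0.2, 50, 4000, 2500, 450
    ),
    lower = c(
      -Inf, 0, 0.3, 2, rep(-Inf, 4), rep(0, 4),
      0, 0, 0, 0, 0.5, 0, 0, 0, 0
    ),
    upper = c(
      Inf, Inf, 2, Inf, rep(Inf, 8),
      95, 95, 95, Inf, Inf, Inf, Inf, Inf, Inf
    )
  )
}

# Variables whose layers are derived from other layers rather than drawn
# from zone centers: monthly climate follows the annual totals through a
# fixed Mediterranean seasonal shape, and silt closes the soil composition.
derived_variables <- function() {
  c(
    paste0("tmean_", c("mar", "apr", "may", "jun")),
    paste0("prec_", c("mar", "apr", "may", "jun")),
    "silt_pct"
  )
}

# Share of annual precipitation falling in each flowering month (at
# prec_seasonality = 1) and each month's position within the seasonal
# temperature cycle relative to the annual mean.
month_shapes <- function() {
  list(
    prec_share = c(mar = 0.10, apr = 0.09, may = 0.07, jun = 0.045),
    tmean_frac = c(mar = -0.55, apr = -0.30, may = 0.05, jun = 0.45)
  )
}

#' @export
print.pc_truth <- function(x, ...) {
  cat(sprintf(
    "<pc_truth> seed %d, zones per component: %s; informative: %s\n",
    x$seed,
    paste(sprintf("%s=%d", substr(names(x$true_k), 1, 3), x$true_k), collapse = " "),
    paste(names(x$informative), collapse = ", ")
  ))
  invisible(x)
}

# Contiguous partition of an n_rows x n_cols grid into k zones.
partition_zones <- function(n_rows, n_cols, k, style, orientation, rng_seed) {
  with_seed(rng_seed, {
    if (k == 1L) {
      return(matrix(1L, n_rows, n_cols))
    }
    if (style == "voronoi") {
      cx <- runif(k, 0.5, n_cols + 0.5)
      cy <- runif(k, 0.5, n_rows + 0.5)
      rows <- matrix(seq_len(n_rows), n_rows, n_cols)
      cols <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols)
      d <- sapply(seq_len(k), function(i) (rows - cy[i])^2 + (cols - cx[i])^2)
      return(matrix(max.col(-d, ties.method = "first"), n_rows, n_cols))
    }
    # Axis-aligned contiguous bands of near-equal width (boundaries jittered
    # by up to 10% of a band so components do not share break positions).
    band_assign <- function(len, k) {
      base_w <- len %/% k
      widths <- rep(base_w, k) + c(rep(1L, len %% k), rep(0L, k - len %% k))
      jitter <- max(0L, floor(base_w / 10))
      if (jitter > 0 && k > 1) {
        for (i in seq_len(k - 1)) {
          shift <- sample(-jitter:jitter, 1)
          shift <- max(min(shift, widths[i + 1] - 2L), 2L - widths[i])
          widths[i] <- widths[i] + shift
          widths[i + 1] <- widths[i + 1] - shift
        }
      }
      rep(seq_len(k), times = widths)
    }
    if (orientation == "cols") {
      z <- band_assign(n_cols, k)
      matrix(rep(z, each = n_rows), n_rows, n_cols)
    } else if (orientation == "rows") {
      z <- band_assign(n_rows, k)
      matrix(rep(z, times = n_cols), n_rows, n_cols)
    } else { # row-major runs: contiguous in reading order
      z <- band_assign(n_rows * n_cols, k)
      matrix(z, n_rows, n_cols, byrow = TRUE)
    }
  })
}

#' Generate a synthetic environmental stack
#'
#' Each component's layers are a mosaic of spatially contiguous zones — one
#' zone per cluster center in the truth — plus white noise, emulating the
#' spatial structure ELC mapping assumes (adaptive scenarios are contiguous
#' mosaics, not shuffled pixels). Topsoil silt is derived so that
#' clay + silt + sand is approximately 100, and bounded variables are clipped
#' to their physical range. The per-component zone membership grids are
#' attached as `attr(stack, "zones")` for recovery checks.
#'
#' @param truth A `pc_truth`.
#' @param n_rows,n_cols Grid dimensions.
#' @param xll,yll,cellsize Grid georeference (defaults: 2.5 arc-min cells in
#'   a Mediterranean-like window).
#' @param nodata_frac Fraction of cells masked as no-data across every layer
#'   (a shared coverage gap, as real environmental databases have); default
#'   1 percent.
#' @return A `pc_stack` with a `zones` attribute (list of three integer
#'   matrices).
#' @export
make_stack <- function(truth, n_rows = 60, n_cols = 60,
                       xll = 0, yll = 35, cellsize = 2.5 / 60,
                       nodata_frac = 0.01) {
  stopifnot(inherits(truth, "pc_truth"))
  if (n_rows * n_cols < sum(truth$true_k)) {
    abort("grid too small for the requested zones", class = "predchar_spec_error")
  }
  orientations <- c(bioclimatic = "cols", edaphic = "rows", geophysic = "runs")
  zones <- lapply(setNames(elc_components(), elc_components()), function(comp) {
    partition_zones(
      n_rows, n_cols, truth$true_k[[comp]], truth$zones,
      orientations[[comp]], derive_seed(truth$seed, paste0("zones_", comp))
    )
  })
  vt <- truth$scales
  layer_noise <- function(v) {
    with_seed(
      derive_seed(truth$seed, paste0("layer_", v)),
      matrix(rnorm(n_rows * n_cols, sd = truth$noise_sd * vt$spread[vt$name == v]),
        n_rows, n_cols
      )
    )
  }
  clip_var <- function(vals, v) {
    pmin(pmax(vals, vt$lower[vt$name == v]), vt$upper[vt$name == v])
  }
  layers <- list()
  for (comp in elc_components()) {
    centers <- truth$centers[[comp]]
    z <- zones[[comp]]
    for (v in colnames(centers)) {
      vals <- matrix(centers[z, v], n_rows, n_cols) + layer_noise(v)
      layers[[v]] <- pc_grid(clip_var(vals, v), xll = xll, yll = yll, cellsize = cellsize)
    }
  }
  # Monthly climate follows the annual layers through the seasonal shape:
  # spring precipitation is the annual total times the month's share times
  # the zone's seasonality factor, and monthly temperature sits at the
  # month's position within the zone's seasonal range.
  shapes <- month_shapes()
  for (m in names(shapes$prec_share)) {
    v <- paste0("prec_", m)
    vals <- layers$prec_annual$values * shapes$prec_share[[m]] *
      layers$prec_seasonality$values + layer_noise(v)
    layers[[v]] <- pc_grid(clip_var(vals, v), xll = xll, yll = yll, cellsize = cellsize)
    vt2 <- paste0("tmean_", m)
    tvals <- layers$tmean_annual$values +
      shapes$tmean_frac[[m]] * layers$tmean_seasonal_range$values + layer_noise(vt2)
    layers[[vt2]] <- pc_grid(clip_var(tvals, vt2), xll = xll, yll = yll, cellsize = cellsize)
  }
  # Close the topsoil composition: silt = 100 - clay - sand (plus its own
  # noise would break the sum tolerance, so it is derived exactly).
  silt <- 100 - layers$clay_pct$values - layers$sand_pct$values
  neg <- silt < 0
  if (any(neg)) { # rescale clay/sand where they overshoot
    tot <- layers$clay_pct$values + layers$sand_pct$values
    layers$clay_pct$values[neg] <- layers$clay_pct$values[neg] / tot[neg] * 100
    layers$sand_pct$values[neg] <- layers$sand_pct$values[neg] / tot[neg] * 100
    silt[neg] <- 0
  }
  layers$silt_pct <- pc_grid(silt, xll = xll, yll = yll, cellsize = cellsize)
  if (nodata_frac > 0) {
    mask <- with_seed(
      derive_seed(truth$seed, "nodata"),
      sample.int(n_rows * n_cols, round(nodata_frac * n_rows * n_cols))
    )
    for (nm in names(layers)) layers[[nm]]$values[mask] <- NA_real_
  }
  comp_tags <- setNames(truth$registry$component, truth$registry$name)
  stack <- pc_stack(layers[truth$registry$name], comp_tags)
  attr(stack, "zones") <- zones
  stack
}

standardize_env <- function(truth, env) {
  vt <- truth$scales
  out <- env
  for (v in intersect(names(env), vt$name)) {
    out[[v]] <- (env[[v]] - vt$base[vt$name == v]) / vt$spread[vt$name == v]
  }
  out
}

#' Sample synthetic population occurrences
#'
#' Cells are drawn without replacement with probability proportional to
#' `exp(sum(beta * z))` over the truth's informative variables, so those
#' variables genuinely shape the realized distribution (`beta = 0` gives
#' uniform occupancy). Each population is placed uniformly within its cell,
#' labelled with a taxon drawn from the truth's weights, and given an opaque
#' identifier; a fraction receive genebank-style `GE_` identifiers. The
#' per-cell sampling intensity is attached as `attr(result, "intensity")`.
#'
#' @param truth A `pc_truth`.
#' @param stack A `pc_stack` from [make_stack()].
#' @param n Number of populations (default 624, the size of the European
#'   wild-lentil occurrence set this generator mirrors).
#' @return A tibble of occurrence records with environmental values extracted
#'   at the sampled locations.
#' @export
sample_occurrences <- function(truth, stack, n = 624) {
  stopifnot(inherits(truth, "pc_truth"), inherits(stack, "pc_stack"))
  if (n <= 0) abort("n must be positive", class = "predchar_spec_error")
  cells <- grid_coords(stack$layers[[1]])
  env <- extract_at_points(stack, cells[c("lon", "lat")])
  valid <- !env$on_nodata & !env$out_of_extent
  if (!any(valid)) {
    abort("stack has no valid cells", class = "predchar_spec_error")
  }
  z <- standardize_env(truth, env[names(truth$informative)])
  eta <- as.matrix(z) %*% truth$informative
  eta <- eta - max(eta[valid])
  intensity <- ifelse(valid, exp(eta), 0)
  # populations exist regardless of layer coverage: cells lacking
  # environmental data are habitable at the typical intensity
  uncharacterized <- env$on_nodata & !env$out_of_extent
  intensity[uncharacterized] <- stats::median(intensity[valid])
  with_seed(derive_seed(truth$seed, "occurrences"), {
    idx <- sample(seq_len(nrow(cells)), n, replace = TRUE, prob = intensity)
    half <- stack$layers[[1]]$cellsize / 2
    lon <- cells$lon[idx] + runif(n, -half, half) * 0.98
    lat <- cells$lat[idx] + runif(n, -half, half) * 0.98
    taxa <- sample(names(truth$taxa_weights), n, replace = TRUE,
                   prob = truth$taxa_weights)
    ge <- runif(n) < truth$genebank_frac
    ids <- sprintf("%s_%07d", ifelse(ge, "GE", "ID"), sample.int(9.5e6, n))
    pts <- tibble(pop_id = ids, taxon = taxa, lon = lon, lat = lat,
                  country = "Synthetica")
    occ <- dplyr::bind_cols(
      pts,
      extract_at_points(stack, pts[c("lon", "lat")])[truth$registry$name]
    )
    occ$genebank_held <- ge
    attr(occ, "intensity") <- intensity
    attr(occ, "cell_index") <- idx
    occ
  })
}

#' Simulate Disease Severity Ratings
#'
#' Severity follows `DSr = 100 * (1 - plogis(eta)) + noise`, clipped to
#' [0, 100], where `eta` is the truth's logistic link evaluated on the
#' standardized environment of each record. Sites with high linear
#' predictors therefore sit at the resistant (low-DSr) end, concentrating
#' resistance where the link says it should be.
#'
#' @param truth A `pc_truth`.
#' @param points A tibble with `lon`, `lat` and the link's environmental
#'   columns (e.g. output of [sample_occurrences()]).
#' @param trait Trait label for the records (`"rust"` or `"broomrape"`).
#' @return A tibble of evaluation records (`accession_id`, `lon`, `lat`,
#'   `trait`, `dsr`) with the true linear predictor attached as
#'   `attr(result, "eta")`.
#' @export
simulate_dsr <- function(truth, points, trait = "rust") {
  stopifnot(inherits(truth, "pc_truth"))
  link_vars <- setdiff(names(truth$dsr_link), "(Intercept)")
  assert_columns(points, c("lon", "lat", link_vars), "points")
  z <- standardize_env(truth, as_tibble(points)[link_vars])
  eta <- as.numeric(as.matrix(z) %*% truth$dsr_link[link_vars]) +
    (truth$dsr_link[["(Intercept)"]] %||% 0)
  dsr <- with_seed(derive_seed(truth$seed, paste0("dsr_", trait)), {
    raw <- 100 * (1 - plogis(eta)) + rnorm(length(eta), sd = truth$dsr_noise_sd)
    pmin(pmax(raw, 0), 100)
  })
  out <- tibble(
    accession_id = sprintf("AC_%s_%04d", toupper(substr(trait, 1, 2)), seq_along(eta)),
    lon = points$lon, lat = points$lat, trait = trait, dsr = dsr
  )
  attr(out, "eta") <- eta
  out
}

#' Write a complete synthetic bundle to disk
#'
#' Materializes one simulated study on disk: the environmental stack as
#' ESRI ASCII grids, the occurrence and evaluation tables as CSV, and the
#' ground truth (seed, zone counts, link coefficients) as JSON.
#'
#' @param truth A `pc_truth`.
#' @param dir Output directory (created if needed).
#' @param n_rows,n_cols,n_occurrences,n_evaluations Sizes of the simulated
#'   study (defaults mirror the study this generator emulates).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(truth, dir, n_rows = 60, n_cols = 60,
                                   n_occurrences = 624, n_evaluations = 351) {
  dir.create(file.path(dir, "stack"), recursive = TRUE, showWarnings = FALSE)
  stack <- make_stack(truth, n_rows, n_cols)
  for (nm in names(stack$layers)) {
    write_raster(stack$layers[[nm]], file.path(dir, "stack", paste0(nm, ".asc")))
  }
  readr::write_csv(
    tibble(name = names(stack$component), component = unname(stack$component)),
    file.path(dir, "stack", "components.csv"), progress = FALSE
  )
  occ <- sample_occurrences(truth, stack, n = n_occurrences)
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  ev_sites <- with_seed(derive_seed(truth$seed, "eval_sites"), {
    occ[sample.int(nrow(occ), n_evaluations, replace = n_evaluations > nrow(occ)), ]
  })
  evals <- simulate_dsr(truth, ev_sites)
  readr::write_csv(evals, file.path(dir, "evaluations.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      seed = truth$seed, true_k = as.list(truth$true_k),
      informative = as.list(truth$informative),
      dsr_link = as.list(truth$dsr_link),
      noise_sd = truth$noise_sd, dsr_noise_sd = truth$dsr_noise_sd
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read back a synthetic stack written by [write_synthetic_bundle()]
#'
#' @param dir Directory containing `stack/` with `.asc` layers and
#'   `components.csv`.
#' @return A `pc_stack`.
#' @export
read_stack_dir <- function(dir) {
  comp <- readr::read_csv(file.path(dir, "stack", "components.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  layers <- lapply(
    setNames(comp$name, comp$name),
    function(nm) read_raster(file.path(dir, "stack", paste0(nm, ".asc")))
  )
  pc_stack(layers, setNames(comp$component, comp$name))
}
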