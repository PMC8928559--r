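#' Gridded environmental layers
#'
#' A `pc_grid` is a single gridded layer: a numeric matrix whose first row is
#' the northernmost row, together with a grid specification (lower-left corner
#' of the extent, square cell size in decimal degrees, and dimensions).
#' Coordinates are WGS84 decimal degrees and cells are addressed by their
#' centers. Missing cells are `NA` internally; the no-data sentinel only
#' appears in files on disk.
#'
#' An `EnvironmentalStack` (`pc_stack`) is a named list of `pc_grid` layers
#' sharing one grid specification, each tagged with the ecogeographic
#' component it belongs to (`bioclimatic`, `edaphic` or `geophysic`).
#'
#' @param values Numeric matrix, row 1 = north.
#' @param xll,yll Coordinates of the lower-left corner of the grid extent.
#' @param cellsize Cell edge length in decimal degrees; the default
#'   `2.5 / 60` is 2.5 arc-minutes.
#' @return `pc_grid()` returns a `pc_grid` object.
#' @examples
#' g <- pc_grid(matrix(1:12, nrow = 3), xll = 0, yll = 40)
#' grid_coords(g)
#' @export
pc_grid <- function(values, xll = 0, yll = 0, cellsize = 2.5 / 60) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cellsize <= 0) abort("cellsize must be > 0", class = "predchar_spec_error")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize),
    class = "pc_grid"
  )
}

#' @export
print.pc_grid <- function(x, ...) {
  cat(sprintf(
    "<pc_grid> %d x %d cells, cellsize %.6g deg, origin (%.6g, %.6g), %d NA\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll, sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.pc_grid <- function(x) dim(x$values)

grid_spec <- function(g) g[c("xll", "yll", "cellsize")]

same_spec <- function(a, b, tol = 1e-9) {
  isTRUE(all(abs(unlist(grid_spec(a)) - unlist(grid_spec(b))) < tol)) &&
    identical(dim(a$values), dim(b$values))
}

#' @rdname pc_grid
#' @param g A `pc_grid`.
#' @return `grid_coords()` returns a tibble of cell-center coordinates
#'   (`row`, `col`, `lon`, `lat`, `value`) in row-major order.
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values)
  nc <- ncol(g$values)
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  tibble(
    row = rows,
    col = cols,
    lon = g$xll + (cols - 0.5) * g$cellsize,
    lat = g$yll + (nr - rows + 0.5) * g$cellsize,
    value = as.vector(t(g$values))
  )
}

#' Assemble an environmental stack
#'
#' @param layers Named list of `pc_grid` objects on one shared grid.
#' @param component Named character vector (or list) mapping every layer name
#'   to one of `"bioclimatic"`, `"edaphic"`, `"geophysic"`.
#' @return A `pc_stack`.
#' @export
pc_stack <- function(layers, component) {
  if (is.null(names(layers)) || any(names(layers) == "")) {
    abort("all layers must be named", class = "predchar_spec_error")
  }
  component <- unlist(component)
  missing <- setdiff(names(layers), names(component))
  if (length(missing) > 0) {
    abort(
      paste0("layers without a component tag: ", paste(missing, collapse = ", ")),
      class = "predchar_spec_error"
    )
  }
  bad <- setdiff(unique(component[names(layers)]), elc_components())
  if (length(bad) > 0) {
    abort(
      paste0("unknown component(s): ", paste(bad, collapse = ", ")),
      class = "predchar_spec_error"
    )
  }
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!same_spec(ref, layers[[nm]])) {
      abort(
        sprintf("layer '%s' does not share the stack's grid specification", nm),
        class = "predchar_dimension_error"
      )
    }
  }
  structure(
    list(layers = layers, component = component[names(layers)]),
    class = "pc_stack"
  )
}

#' @export
print.pc_stack <- function(x, ...) {
  tab <- table(x$component)
  cat(sprintf(
    "<pc_stack> %d layers (%s) on a %d x %d grid\n",
    length(x$layers),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values)
  ))
  invisible(x)
}

#' Read and write ESRI ASCII grids
#'
#' Rasters are exchanged as ESRI ASCII grids, a plain-text format understood
#' by all major GIS tools. Values are written with full double precision so a
#' write/read round trip is lossless to within 1e-15 relative error (bit-exact
#' for integers); no-data cells are written as the sentinel and read back as
#' `NA`.
#'
#' @param path File path.
#' @param nodata No-data sentinel written to file (default -9999).
#' @return `read_raster()` returns a `pc_grid`; `write_raster()` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- list()
  n_hdr <- 0L
  for (p in kv) {
    key <- tolower(p[[1]])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(p[[2]])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[req]])) {
      abort(sprintf("ASCII grid header is missing '%s'", req), class = "predchar_schema_error")
    }
  }
  body <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc) {
    abort(
      sprintf("ASCII grid body has %d values, expected %d", length(body), nr * nc),
      class = "predchar_dimension_error"
    )
  }
  if (!is.null(hdr$nodata_value)) body[body == hdr$nodata_value] <- NA_real_
  pc_grid(
    matrix(body, nrow = nr, ncol = nc, byrow = TRUE),
    xll = hdr$xllcorner, yll = hdr$yllcorner, cellsize = hdr$cellsize
  )
}

#' @rdname read_raster
#' @param g A `pc_grid` to write.
#' @export
write_raster <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "pc_grid"))
  v <- g$values
  if (any(!is.na(v) & v == nodata)) {
    abort("grid contains cells equal to the no-data sentinel", class = "predchar_spec_error")
  }
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", g$xll),
    sprintf("yllcorner %.17g", g$yll),
    sprintf("cellsize %.17g", g$cellsize),
    sprintf("NODATA_value %.17g", nodata)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Extract layer values at point locations
#'
#' Nearest-cell-center extraction of every layer of a stack at a set of
#' longitude/latitude points. Points outside the grid extent, or falling on
#' no-data cells, yield `NA` values and are flagged rather than dropped.
#'
#' @param stack A `pc_stack`.
#' @param points Data frame with `lon` and `lat` columns (decimal degrees).
#' @return A tibble with one row per point: `lon`, `lat`, one column per
#'   layer, plus logical flags `out_of_extent` and `on_nodata`.
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(inherits(stack, "pc_stack"))
  points <- as_tibble(points)
  assert_columns(points, c("lon", "lat"), "points")
  ref <- stack$layers[[1]]
  nr <- nrow(ref$values)
  nc <- ncol(ref$values)
  col <- floor((points$lon - ref$xll) / ref$cellsize) + 1L
  row <- nr - floor((points$lat - ref$yll) / ref$cellsize)
  # A point sitting exactly on the top/right edge belongs to the edge cell.
  col[points$lon == ref$xll + nc * ref$cellsize] <- nc
  row[points$lat == ref$yll + nr * ref$cellsize] <- 1L
  inside <- !is.na(col) & !is.na(row) & col >= 1L & col <= nc & row >= 1L & row <= nr
  idx <- ifelse(inside, (col - 1L) * nr + row, NA_integer_)
  vals <- lapply(stack$layers, function(g) {
    out <- rep(NA_real_, nrow(points))
    out[inside] <- g$values[idx[inside]]
    out
  })
  out <- tibble(lon = points$lon, lat = points$lat)
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out$out_of_extent <- !inside
  out$on_nodata <- inside & Reduce(`|`, lapply(vals, is.na))
  out
}
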