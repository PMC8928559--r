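#' Variable registry
#'
#' The registry declares every ecogeographic variable the pipeline may use:
#' its name, the component it belongs to (bioclimatic, edaphic or geophysic),
#' units and a short description. Occurrence tables are validated against it,
#' and latitude/longitude participate as geophysic candidates during variable
#' selection.
#'
#' @param name,component,units,description Equal-length character vectors.
#' @return A tibble with class `pc_registry`.
#' @export
variable_registry <- function(name, component, units = NA_character_,
                              description = NA_character_) {
  if (anyDuplicated(name)) {
    abort("registry variable names must be unique", class = "predchar_spec_error")
  }
  bad <- setdiff(unique(component), elc_components())
  if (length(bad) > 0) {
    abort(
      paste0("unknown component(s): ", paste(bad, collapse = ", ")),
      class = "predchar_spec_error"
    )
  }
  out <- tibble(
    name = as.character(name),
    component = as.character(component),
    units = units,
    description = description
  )
  class(out) <- c("pc_registry", class(out))
  out
}

#' Default registry of synthetic ecogeographic variables
#'
#' The variable set the synthetic generator emulates: a compact stand-in for
#' the large bioclimatic/edaphic/geophysic catalogues real pipelines draw
#' from. It carries everything the downstream stages need — annual and
#' March-June monthly temperature and precipitation for the aridity indices,
#' topsoil composition and conductivity for the texture/salinity rules, and
#' radiation/terrain variables.
#'
#' @return A `pc_registry` tibble.
#' @export
default_registry <- function() {
  variable_registry(
    name = c(
      "tmean_annual", "prec_annual", "prec_seasonality", "tmean_seasonal_range",
      "tmean_mar", "tmean_apr", "tmean_may", "tmean_jun",
      "prec_mar", "prec_apr", "prec_may", "prec_jun",
      "clay_pct", "sand_pct", "silt_pct", "ec_topsoil",
      "bulk_density", "water_capacity",
      "solar_annual", "solar_dec", "elevation"
    ),
    component = c(
      rep("bioclimatic", 12),
      rep("edaphic", 6),
      rep("geophysic", 3)
    ),
    units = c(
      "degC", "mm", "ratio", "degC",
      rep("degC", 4), rep("mm", 4),
      "%", "%", "%", "dS/m", "kg/dm3", "mm/m",
      "kJ/m2/day", "kJ/m2/day", "m"
    ),
    description = c(
      "annual mean temperature", "annual precipitation",
      "spring precipitation share relative to a uniform year",
      "seasonal temperature range",
      "March mean temperature", "April mean temperature",
      "May mean temperature", "June mean temperature",
      "March precipitation", "April precipitation",
      "May precipitation", "June precipitation",
      "topsoil clay fraction", "topsoil sand fraction",
      "topsoil silt fraction", "topsoil electrical conductivity",
      "topsoil bulk density (fine earth)",
      "topsoil available water capacity to wilting point",
      "annual solar radiation", "December solar radiation", "elevation"
    )
  )
}

#' Read a population occurrence table
#'
#' Reads a delimited table of georeferenced wild populations: one row per
#' population with an opaque `pop_id`, taxon, WGS84 coordinates, country,
#' per-population ecogeographic variable values and (optionally) an ELC
#' category. Populations held in genebanks are recognised by a `pop_id`
#' beginning with `"GE"`. Unparseable numeric cells become `NA`, never 0.
#'
#' @param path Path to a delimited text file with a header row.
#' @param registry A `pc_registry`; environmental columns not in the registry
#'   are rejected.
#' @param col_map Optional named character vector mapping canonical column
#'   names (`pop_id`, `taxon`, `lon`, `lat`, `country`, `elc_category`) to the
#'   header names actually used in the file.
#' @param delim Field separator (default comma; use `";"` for semicolon
#'   exports).
#' @return A tibble of populations with a `genebank_held` column derived from
#'   the `pop_id` prefix.
#' @export
read_occurrences <- function(path, registry = default_registry(),
                             col_map = NULL, delim = ",") {
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  assert_columns(raw, c("pop_id", "taxon", "lon", "lat"), basename(path))
  validate_occurrences(build_occurrences(raw, registry))
}

build_occurrences <- function(raw, registry) {
  numeric_cols <- intersect(
    c("lon", "lat", "elc_category", registry$name),
    names(raw)
  )
  unknown <- setdiff(
    names(raw),
    c("pop_id", "taxon", "lon", "lat", "country", "source", "elc_category",
      "genebank_held", registry$name)
  )
  if (length(unknown) > 0) {
    warn(paste0(
      "ignoring columns not in the variable registry: ",
      paste(unknown, collapse = ", ")
    ))
    raw <- raw[setdiff(names(raw), unknown)]
  }
  out <- as_tibble(raw)
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    out[[col]] <- v
  }
  out$genebank_held <- startsWith(out$pop_id, "GE")
  out
}

#' Validate a population occurrence table
#'
#' Checks coordinate ranges and `pop_id` uniqueness; returns the table
#' invisibly unchanged if valid.
#'
#' @param occurrences A tibble as returned by [read_occurrences()].
#' @export
validate_occurrences <- function(occurrences) {
  assert_columns(occurrences, c("pop_id", "taxon", "lon", "lat"), "occurrences")
  dup <- unique(occurrences$pop_id[duplicated(occurrences$pop_id)])
  if (length(dup) > 0) {
    abort(
      paste0("duplicate pop_id: ", paste(dup, collapse = ", ")),
      class = "predchar_validation_error"
    )
  }
  bad_lon <- which(!is.na(occurrences$lon) & abs(occurrences$lon) > 180)
  bad_lat <- which(!is.na(occurrences$lat) & abs(occurrences$lat) > 90)
  if (length(bad_lon) + length(bad_lat) > 0) {
    abort(
      sprintf(
        "coordinates out of range in rows: %s",
        paste(unique(c(bad_lon, bad_lat)), collapse = ", ")
      ),
      class = "predchar_validation_error"
    )
  }
  occurrences
}

#' Read a trait evaluation table
#'
#' Reads accession-level field evaluations: accession id, coordinates, trait
#' (`rust` or `broomrape`) and the Disease Severity Rating `dsr`, a 0-100
#' score where low values indicate resistance. The binary `resistant` label
#' is left unset until [binarize_dsr()] is applied.
#'
#' @inheritParams read_occurrences
#' @param col_map Optional mapping for `accession_id`, `lon`, `lat`, `trait`,
#'   `dsr`.
#' @return A tibble of evaluation records.
#' @export
read_evaluations <- function(path, col_map = NULL, delim = ",") {
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  assert_columns(raw, c("accession_id", "lon", "lat", "trait", "dsr"), basename(path))
  out <- as_tibble(raw)
  for (col in c("lon", "lat", "dsr")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  bad <- which(!is.na(out$dsr) & (out$dsr < 0 | out$dsr > 100))
  if (length(bad) > 0) {
    abort(
      sprintf("dsr outside [0, 100] in rows: %s", paste(bad, collapse = ", ")),
      class = "predchar_validation_error"
    )
  }
  out
}

#' @rdname read_occurrences
#' @param occurrences A tibble of populations to write.
#' @export
write_occurrences <- function(occurrences, path) {
  readr::write_csv(occurrences, path, progress = FALSE)
  invisible(path)
}
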