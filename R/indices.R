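#' De Martonne aridity indices
#'
#' The annual De Martonne index is `P / (T + 10)`, with `P` the annual
#' precipitation (mm), `T` the annual mean temperature (degrees C) and 10 a
#' constant keeping the denominator positive in temperate climates. The
#' monthly variant is `12 * Pm / (Tm + 10)` on monthly precipitation and
#' temperature, and the flowering-season index is the mean of the monthly
#' indices for March-June, the period when drought most affects development
#' in lentils and related legumes. Lower values mean more arid sites.
#'
#' The index is undefined for temperatures at or below -10 degrees C; such
#' records raise a domain error rather than being clamped, so callers must
#' flag and exclude them explicitly.
#'
#' @param p Annual precipitation, mm (vectorized).
#' @param t Annual mean temperature, degrees C.
#' @return A numeric vector of index values (`NA` where inputs are `NA`).
#' @examples
#' demartonne_annual(500, 15) # 20
#' demartonne_monthly(25, 14) # 12.5
#' @export
demartonne_annual <- function(p, t) {
  check_demartonne_domain(p, t)
  p / (t + 10)
}

#' @rdname demartonne_annual
#' @param pm Monthly precipitation, mm.
#' @param tm Monthly mean temperature, degrees C.
#' @export
demartonne_monthly <- function(pm, tm) {
  check_demartonne_domain(pm, tm)
  12 * pm / (tm + 10)
}

#' @rdname demartonne_annual
#' @param pm_flowering,tm_flowering Numeric matrices (or data frames) with
#'   one column per flowering month (March, April, May, June) and one row per
#'   record.
#' @export
demartonne_flowering <- function(pm_flowering, tm_flowering) {
  pm <- as.matrix(pm_flowering)
  tm <- as.matrix(tm_flowering)
  if (ncol(pm) != 4L || ncol(tm) != 4L) {
    abort("flowering indices need the four months March-June", class = "predchar_spec_error")
  }
  monthly <- matrix(demartonne_monthly(as.vector(pm), as.vector(tm)), nrow = nrow(pm))
  rowMeans(monthly)
}

check_demartonne_domain <- function(p, t) {
  if (any(!is.na(t) & t <= -10)) {
    abort(
      "De Martonne index undefined for temperature <= -10 degC; flag and exclude such records",
      class = "predchar_domain_error"
    )
  }
  if (any(!is.na(p) & p < 0)) {
    abort("precipitation must be >= 0", class = "predchar_domain_error")
  }
  invisible(NULL)
}

#' Rule-table classifications: aridity, soil texture, soil salinity
#'
#' Three classification schemes applied to population sites. All interval
#' bins are left-closed/right-open, consistent with the printed aridity
#' bounds (e.g. an index of exactly 10 is semi-arid, exactly 60 per-humid).
#'
#' * `classify_aridity()` bins a De Martonne index into
#'   deserts/extremely arid `[0,5)`, semi-desert/arid `[5,10)`,
#'   semi-arid `[10,20)`, sub-humid `[20,30)`, humid `[30,60)` and
#'   per-humid `[60,Inf)`.
#' * `classify_texture()` applies the poorly-drained-soil texture rules to
#'   topsoil clay/silt/sand percentages, evaluated in fixed order with the
#'   first match winning: Clay (clay >= 40, sand <= 45, silt < 40),
#'   Silty Clay (clay >= 40, silt >= 40), Sandy Clay (clay >= 35,
#'   sand > 45), Silty Clay Loam (27 <= clay < 40, sand <= 20), else Other.
#'   The rules never overlap on the 1 percent composition grid, but the
#'   order is fixed for safety.
#' * `classify_salinity()` bins topsoil electrical conductivity (dS/m) into
#'   non-saline `[0,2)`, slightly `[2,4)`, moderately `[4,8)`, strongly
#'   `[8,16)` and very strongly saline `[16,Inf)`.
#'
#' @param i De Martonne index values (>= 0).
#' @return A factor with the class labels in increasing-severity order.
#' @examples
#' classify_aridity(c(3, 10, 25, 60))
#' classify_texture(45, 15, 40) # Clay
#' classify_salinity(3) # slightly saline
#' @export
classify_aridity <- function(i) {
  if (any(!is.na(i) & i < 0)) {
    abort("aridity index must be >= 0", class = "predchar_domain_error")
  }
  cut(i,
    breaks = c(0, 5, 10, 20, 30, 60, Inf), right = FALSE,
    labels = c(
      "deserts/extremely arid", "semi-desert/arid", "semi-arid",
      "sub-humid", "humid", "per-humid"
    )
  )
}

#' @rdname classify_aridity
#' @param clay,silt,sand Topsoil fractions in percent; each triple must sum
#'   to 100 within `sum_tol`.
#' @param sum_tol Allowed deviation of `clay + silt + sand` from 100
#'   (absorbs rounding in soil databases).
#' @export
classify_texture <- function(clay, silt, sand, sum_tol = 2) {
  total <- clay + silt + sand
  bad <- which(!is.na(total) & abs(total - 100) > sum_tol)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "clay+silt+sand outside 100 +/- %g in rows: %s", sum_tol,
        paste(head(bad, 5), collapse = ", ")
      ),
      class = "predchar_validation_error"
    )
  }
  known <- !is.na(total)
  pick <- function(current, cond, label) {
    ifelse(is.na(current) & !is.na(cond) & cond, label, current)
  }
  res <- rep(NA_character_, length(total))
  res <- pick(res, clay >= 40 & sand <= 45 & silt < 40, "Clay")
  res <- pick(res, clay >= 40 & silt >= 40, "Silty Clay")
  res <- pick(res, clay >= 35 & sand > 45, "Sandy Clay")
  res <- pick(res, clay >= 27 & clay < 40 & sand <= 20, "Silty Clay Loam")
  res <- pick(res, known, "Other")
  factor(res, levels = c("Clay", "Silty Clay", "Sandy Clay", "Silty Clay Loam", "Other"))
}

#' @rdname classify_aridity
#' @param ec Topsoil electrical conductivity, dS/m (>= 0).
#' @export
classify_salinity <- function(ec) {
  if (any(!is.na(ec) & ec < 0)) {
    abort("conductivity must be >= 0", class = "predchar_domain_error")
  }
  cut(ec,
    breaks = c(0, 2, 4, 8, 16, Inf), right = FALSE,
    labels = c(
      "non-saline", "slightly saline", "moderately saline",
      "strongly saline", "very strongly saline"
    )
  )
}

#' Append aridity indices and rule classifications to a population table
#'
#' Data-frame-first wrapper over the index and rule functions: computes the
#' annual and flowering De Martonne indices and the aridity, texture and
#' salinity classes from named columns, appending `iar_dm`, `iar_dm_f`,
#' `aridity_class`, `texture_class` and `salinity_class`.
#'
#' @param populations Tibble of populations with environmental columns.
#' @param p_col,t_col Names of the annual precipitation and annual mean
#'   temperature columns.
#' @param pm_cols,tm_cols Names of the March-June monthly precipitation and
#'   temperature columns (in month order).
#' @param clay_col,silt_col,sand_col,ec_col Topsoil composition and
#'   conductivity columns.
#' @return The input tibble with the five derived columns appended.
#' @export
add_env_indices <- function(populations,
                            p_col = "prec_annual", t_col = "tmean_annual",
                            pm_cols = c("prec_mar", "prec_apr", "prec_may", "prec_jun"),
                            tm_cols = c("tmean_mar", "tmean_apr", "tmean_may", "tmean_jun"),
                            clay_col = "clay_pct", silt_col = "silt_pct",
                            sand_col = "sand_pct", ec_col = "ec_topsoil") {
  populations <- as_tibble(populations)
  assert_columns(
    populations, c(p_col, t_col, pm_cols, tm_cols, clay_col, silt_col, sand_col, ec_col),
    "populations"
  )
  populations$iar_dm <- demartonne_annual(populations[[p_col]], populations[[t_col]])
  populations$iar_dm_f <- demartonne_flowering(
    populations[pm_cols], populations[tm_cols]
  )
  populations$aridity_class <- classify_aridity(populations$iar_dm)
  populations$texture_class <- classify_texture(
    populations[[clay_col]], populations[[silt_col]], populations[[sand_col]]
  )
  populations$salinity_class <- classify_salinity(populations[[ec_col]])
  populations
}
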