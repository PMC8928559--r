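test_that("the generator is a pure function of seed and sizes", {
  a <- tiny_study(seed = 9)
  b <- tiny_study(seed = 9)
  expect_identical(a$stack$layers$tmean_annual$values, b$stack$layers$tmean_annual$values)
  expect_identical(a$occ, b$occ, ignore_attr = TRUE)
  expect_identical(a$evals$dsr, b$evals$dsr)
  c <- tiny_study(seed = 10)
  expect_false(identical(a$occ$pop_id, c$occ$pop_id))
})

test_that("degenerate truths produce degenerate stacks", {
  truth <- synthetic_truth(
    seed = 1,
    true_k = c(bioclimatic = 1, edaphic = 1, geophysic = 1), noise_sd = 0
  )
  st <- make_stack(truth, 10, 10, nodata_frac = 0)
  for (nm in names(st$layers)) {
    expect_equal(diff(range(st$layers[[nm]]$values)), 0)
  }
})

test_that("zone triples are bounded by the product of component counts", {
  truth <- synthetic_truth(seed = 4)
  st <- make_stack(truth, 40, 40)
  z <- attr(st, "zones")
  triples <- unique(paste(z$bioclimatic, z$edaphic, z$geophysic))
  expect_lte(length(triples), 4 * 3 * 3)
  expect_gte(length(triples), max(truth$true_k))
})

test_that("a grid too small for the zones is rejected, as is n <= 0", {
  truth <- synthetic_truth(seed = 1)
  expect_error(make_stack(truth, 2, 2), class = "predchar_spec_error")
  st <- make_stack(truth, 20, 20)
  expect_error(sample_occurrences(truth, st, n = 0), class = "predchar_spec_error")
})

test_that("with zero intensity coefficients occupancy is uniform across zones", {
  truth <- synthetic_truth(seed = 21, informative = c(prec_annual = 0))
  st <- make_stack(truth, 40, 40)
  occ <- sample_occurrences(truth, st, n = 5000)
  z <- attr(st, "zones")$bioclimatic
  cell <- attr(occ, "cell_index")
  counts <- table(z[cell])
  sizes <- table(z)
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(counts), p = as.vector(sizes) / sum(sizes))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("a strong positive coefficient pulls occurrences toward high values", {
  truth <- synthetic_truth(seed = 22, informative = c(prec_annual = 3))
  st <- make_stack(truth, 40, 40)
  occ <- sample_occurrences(truth, st, n = 400)
  grid_mean <- mean(st$layers$prec_annual$values, na.rm = TRUE)
  tt <- stats::t.test(stats::na.omit(occ$prec_annual),
    mu = grid_mean, alternative = "greater"
  )
  expect_lt(tt$p.value, 1e-6)
})

test_that("the taxon mix follows the configured weights", {
  truth <- synthetic_truth(seed = 5)
  st <- make_stack(truth, 40, 40)
  occ <- sample_occurrences(truth, st, n = 624)
  expect_equal(nrow(occ), 624)
  tab <- sort(table(occ$taxon), decreasing = TRUE)
  expect_equal(names(tab)[1], "L. nigricans")
  expect_gt(tab[["L. nigricans"]], tab[["L. ervoides"]])
})

test_that("a flat severity link yields DSr 50 exactly and extremes saturate", {
  truth0 <- synthetic_truth(
    seed = 1, dsr_link = c("(Intercept)" = 0), dsr_noise_sd = 0
  )
  pts <- tibble::tibble(lon = 1:5, lat = 1:5)
  ev <- simulate_dsr(truth0, pts)
  expect_equal(ev$dsr, rep(50, 5))

  truth_hi <- synthetic_truth(
    seed = 1, dsr_link = c("(Intercept)" = 30), dsr_noise_sd = 0
  )
  ev_hi <- simulate_dsr(truth_hi, pts)
  expect_equal(ev_hi$dsr, rep(0, 5), tolerance = 1e-8)
})

test_that("resistance concentrates where the link predicts it", {
  study <- tiny_study(seed = 13, n_occ = 400, n_eval = 400, dsr_noise_sd = 3)
  eta <- attr(study$evals, "eta")
  ok <- !is.na(eta) # sites on no-data cells carry no environment
  top_eta <- ok & eta >= quantile(eta[ok], 0.9)
  expect_lt(
    mean(study$evals$dsr[top_eta]),
    quantile(study$evals$dsr[ok], 0.25)
  )
})

test_that("a bundle written to disk reads back consistently", {
  dir <- withr::local_tempdir()
  truth <- synthetic_truth(seed = 3)
  write_synthetic_bundle(truth, dir, n_rows = 20, n_cols = 20,
    n_occurrences = 50, n_evaluations = 30
  )
  st <- read_stack_dir(dir)
  expect_equal(sort(names(st$layers)), sort(default_registry()$name))
  direct <- make_stack(truth, 20, 20)
  expect_equal(st$layers$clay_pct$values, direct$layers$clay_pct$values,
    tolerance = 1e-12
  )
  occ <- read_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ), 50)
  truth_json <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth_json$seed, 3)
})
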