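test_that("binarization thresholds at the first decile with strict inequality", {
  rec <- tibble::tibble(dsr = seq(0, 90, by = 10))
  out <- binarize_dsr(rec)
  # type-7 decile of 0,10,...,90 is 9: only DSr = 0 is strictly below
  expect_equal(attr(out, "threshold"), 9)
  expect_equal(attr(out, "n_resistant"), 1)
  expect_equal(sum(out$resistant), 1)

  none <- binarize_dsr(rec, quantile = 0)
  expect_equal(attr(none, "n_resistant"), 0)

  expect_error(binarize_dsr(tibble::tibble(dsr = rep(50, 20))),
    class = "predchar_domain_error"
  )
  expect_error(binarize_dsr(tibble::tibble(dsr = 1:5)), class = "predchar_spec_error")
})

test_that("binarization counts partition the records", {
  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(20:400, 1)
      q <- runif(1, 0.05, 0.5)
      rec <- tibble::tibble(dsr = round(runif(n, 0, 100), 1))
      out <- binarize_dsr(rec, quantile = q)
      expect_equal(attr(out, "n_resistant") + attr(out, "n_sensitive"), n)
      expect_lte(attr(out, "n_resistant"), ceiling(q * n))
      expect_true(all(rec$dsr[out$resistant] < attr(out, "threshold")))
    }
  })
})

test_that("TSS matches its closed form and symmetries", {
  expect_equal(tss(5, 0, 7, 0), 1)
  expect_equal(tss(0, 5, 0, 7), -1)
  expect_equal(tss(3, 1, 4, 2), 0.75 + 4 / 6 - 1)
  # predicting everything as one class scores zero
  expect_equal(tss(4, 0, 0, 6), 0)
  expect_equal(tss(0, 4, 6, 0), 0)
  # class symmetry
  withr::with_seed(6, {
    m <- matrix(sample(0:20, 40, replace = TRUE), ncol = 4) + 1
    expect_equal(
      tss(m[, 1], m[, 2], m[, 3], m[, 4]),
      tss(m[, 3], m[, 4], m[, 1], m[, 2])
    )
  })
  expect_error(tss(0, 0, 3, 1), class = "predchar_domain_error")
})

test_that("performance bins follow the five-class index", {
  expect_equal(as.character(classify_performance(0.588)), "Fair")
  expect_equal(as.character(classify_performance(0.828)), "Excellent")
  expect_equal(as.character(classify_performance(0.05)), "Fail")
  expect_equal(
    as.character(classify_performance(c(-0.3, 0.2, 0.4, 0.6, 0.8, 1))),
    c("Fail", "Poor", "Fair", "Good", "Excellent", "Excellent")
  )
})

test_that("the surface range envelope is a per-variable quantile box", {
  pres <- data.frame(a = as.numeric(1:100), b = rep(5, 100))
  env <- sre_envelope(pres)
  expect_equal(predict(env, data.frame(a = 50, b = 5)), 1)
  expect_equal(predict(env, data.frame(a = 200, b = -50)), 0)
  expect_equal(predict(env, data.frame(a = 200, b = 5)), 0.5)
  # bounds at the 2.5th/97.5th percentiles of 1..100
  q <- unname(quantile(1:100, c(0.025, 0.975)))
  expect_equal(env$bounds$a, q)
  expect_equal(predict(env, data.frame(a = q[2] + 0.01, b = 5)), 0.5)
  expect_error(sre_envelope(pres[1, , drop = FALSE]), class = "predchar_domain_error")
})

test_that("every algorithm solves a cleanly separable problem", {
  rec <- separable_records(n = 120)
  suite <- train_suite(rec, c("v1", "v2", "v3"), n_runs = 5, seed = 3)
  expect_true(all(!suite$runs$failed))
  expect_true(all(suite$summary$mean_tss >= 0.95))
})

test_that("suites are reproducible and runs refittable from their seeds", {
  rec <- separable_records(n = 80)
  s1 <- train_suite(rec, c("v1", "v2"), algorithms = c("GLM", "RF"), n_runs = 4, seed = 9)
  s2 <- train_suite(rec, c("v1", "v2"), algorithms = c("GLM", "RF"), n_runs = 4, seed = 9)
  expect_identical(s1$runs, s2$runs)
  best <- s1$runs[which.max(s1$runs$tss), ]
  refit <- refit_run(s1, best$algorithm, best$run)
  p_test <- predchar:::predict_prob(refit$model, s1$data[refit$test, ])
  expect_equal(
    predchar:::confusion_tss(p_test, s1$y[refit$test], refit$cutoff / 1000),
    best$tss
  )
})

test_that("stratified splits keep both classes in train and test", {
  rec <- separable_records(n = 80)
  y <- as.integer(rec$resistant)
  for (s in 1:20) {
    sp <- predchar:::split_indices(y, 0.75, TRUE, s)
    expect_gte(sum(y[sp$train] == 1), 1)
    expect_gte(sum(y[sp$test] == 1), 1)
    expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
  }
})

test_that("a variable absent from the model has zero permutation importance", {
  rec <- separable_records(n = 100)
  dat <- as.data.frame(rec[c("v1", "v2")])
  fit <- suppressWarnings(glm(resistant ~ v1,
    data = cbind(dat, resistant = rec$resistant), family = binomial()
  ))
  model <- structure(
    list(algorithm = "GLM", model = fit, vars = c("v1", "v2")),
    class = "pc_model"
  )
  imp <- permutation_importance(model, dat, n_perm = 20, seed = 1)
  expect_equal(unname(imp["v2"]), 0)
  expect_gt(imp["v1"], 0.5)
})

test_that("the driving variable earns the top importance in a fitted model", {
  rec <- separable_records(n = 150)
  model <- predchar:::fit_algorithm("RF", rec[c("v1", "v2", "v3")],
    as.integer(rec$resistant),
    params = list(rf_ntree = 200)
  )
  imp <- permutation_importance(model, rec[c("v1", "v2", "v3")], n_perm = 20, seed = 2)
  expect_gt(max(imp[c("v1", "v2")]), imp["v3"])
})

test_that("projection labels respect the cutoff and the top subset is capped", {
  study <- tiny_study(seed = 19, n_occ = 300, n_eval = 200)
  lab <- binarize_dsr(study$evals)
  preds <- c("tmean_annual", "solar_annual", "prec_annual", "water_capacity")
  lab <- dplyr::bind_cols(lab, study$eval_sites[preds])
  suite <- train_suite(lab, preds, algorithms = c("GLM", "CTA", "SRE"), n_runs = 5, seed = 4)
  res <- select_and_project(suite, study$occ, top_n = 10, n_perm = 10)
  expect_equal(res$verdict, "ok")
  proj <- res$projections
  expect_true(all(proj$suitability >= 0 & proj$suitability <= 1000, na.rm = TRUE))
  lab_ok <- ifelse(proj$suitability > res$cutoff, "resistant", "sensitive")
  expect_identical(proj$label, lab_ok)
  expect_lte(nrow(res$top_subset), 10)
  expect_true(all(diff(res$top_subset$suitability) <= 0))
  expect_true(all(res$top_subset$label == "resistant"))
})

test_that("shuffled labels are declared unmodelable", {
  # enough records per environmental zone that a single label permutation
  # carries no learnable chance association
  study <- tiny_study(seed = 23, n_occ = 300, n_eval = 250)
  lab <- binarize_dsr(study$evals)
  lab$resistant <- withr::with_seed(1, sample(lab$resistant))
  preds <- c("tmean_annual", "solar_annual", "prec_annual")
  lab <- dplyr::bind_cols(lab, study$eval_sites[preds])
  suite <- train_suite(lab, preds, algorithms = c("GLM", "CTA", "RF"), n_runs = 15, seed = 6)
  expect_true(all(suite$summary$mean_tss < 0.2, na.rm = TRUE))
  res <- select_and_project(suite, study$occ)
  expect_equal(res$verdict, "unmodelable")
  expect_equal(nrow(res$projections), 0)
})

test_that("a model dominated by an excluded variable is skipped", {
  withr::with_seed(41, {
    n <- 200
    lonlike <- rnorm(n)
    other <- rnorm(n)
    rec <- tibble::tibble(
      resistant = lonlike + rnorm(n, sd = 0.4) > 1,
      lonlike = lonlike, other = other
    )
  })
  suite <- train_suite(rec, c("lonlike", "other"),
    algorithms = c("GLM", "RF"), n_runs = 5, seed = 8
  )
  pops <- tibble::tibble(
    pop_id = sprintf("P%03d", 1:50),
    lonlike = rnorm(50), other = rnorm(50)
  )
  res_all <- select_and_project(suite, pops, n_perm = 10)
  expect_length(res_all$dominated, 0)
  # with the single driver excluded, every candidate model is dominated by it
  expect_error(
    select_and_project(suite, pops, exclude_variables = "lonlike", n_perm = 10),
    class = "predchar_pipeline_error"
  )
  # choose= always overrides
  forced <- select_and_project(suite, pops, choose = "GLM", n_perm = 10)
  expect_equal(forced$algorithm, "GLM")
})
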