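test_that("the variable driving sampling intensity ranks first in its component", {
  # within-zone noise is raised so same-component layers decorrelate and the
  # true driver is identifiable among its proxies
  hits <- 0
  for (s in 1:5) {
    truth <- synthetic_truth(
      seed = 100 + s, informative = c(water_capacity = 3),
      true_k = c(bioclimatic = 2, edaphic = 3, geophysic = 2),
      noise_sd = 0.4
    )
    st <- make_stack(truth, 30, 30)
    occ <- sample_occurrences(truth, st, n = 150)
    rk <- rank_variables(occ, st, ntree = 200, seed = s)
    top_edaphic <- rk$name[rk$component == "edaphic" & rk$rank == 1]
    hits <- hits + (top_edaphic == "water_capacity")
  }
  expect_gte(hits, 4)
})

test_that("rankings are reproducible for a fixed seed and tie-broken by name", {
  study <- tiny_study(seed = 31, n_occ = 100)
  a <- rank_variables(study$occ, study$stack, ntree = 100, seed = 7)
  b <- rank_variables(study$occ, study$stack, ntree = 100, seed = 7)
  expect_identical(a$mda, b$mda)
  expect_identical(a$rank, b$rank)
  # ranks are a permutation within each component
  for (comp in unique(a$component)) {
    r <- a$rank[a$component == comp]
    expect_setequal(r, seq_along(r))
  }
})

test_that("greedy pruning drops a correlated variable and keeps independents", {
  # hand-checkable scan: var2 correlated with higher-MDA var1, var3 free
  ranking <- tibble::tibble(
    name = c("var1", "var2", "var3"),
    component = "edaphic",
    mda = c(10, 8, 5),
    rank = 1:3, retained = NA, dropped_because = NA_character_
  )
  class(ranking) <- c("pc_ranking", class(ranking))
  withr::with_seed(8, {
    v1 <- rnorm(200)
    data <- tibble::tibble(
      var1 = v1,
      var2 = 0.95 * v1 + rnorm(200, sd = 0.2),
      var3 = rnorm(200)
    )
  })
  pruned <- prune_correlated(ranking, data)
  expect_identical(retained_variables(pruned), c("var1", "var3"))
  expect_equal(pruned$dropped_because[pruned$name == "var2"], "var1")
})

test_that("mutually independent variables are all retained", {
  ranking <- tibble::tibble(
    name = paste0("v", 1:4), component = "bioclimatic",
    mda = c(4, 3, 2, 1), rank = 1:4, retained = NA, dropped_because = NA_character_
  )
  class(ranking) <- c("pc_ranking", class(ranking))
  data <- withr::with_seed(9, tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(800), 200)), paste0("v", 1:4)
  )))
  pruned <- prune_correlated(ranking, data)
  expect_true(all(pruned$retained))
})

test_that("pruning never removes the within-component importance maximum", {
  for (s in 1:5) {
    withr::with_seed(s, {
      n_var <- 6
      base <- rnorm(100)
      data <- tibble::as_tibble(setNames(as.data.frame(
        sapply(1:n_var, function(i) 0.7 * base + rnorm(100, sd = 0.5))
      ), paste0("v", 1:n_var)))
      ranking <- tibble::tibble(
        name = paste0("v", 1:n_var),
        component = rep(c("bioclimatic", "edaphic"), each = 3),
        mda = rnorm(n_var)
      ) |>
        dplyr::group_by(component) |>
        dplyr::arrange(dplyr::desc(mda), .by_group = TRUE) |>
        dplyr::mutate(rank = dplyr::row_number()) |>
        dplyr::ungroup()
      class(ranking) <- c("pc_ranking", class(ranking))
      pruned <- prune_correlated(ranking, data)
      for (comp in unique(pruned$component)) {
        expect_true(pruned$retained[pruned$component == comp & pruned$rank == 1])
      }
    })
  }
})

test_that("a duplicated layer splits importance rather than dominating", {
  truth <- synthetic_truth(seed = 55, informative = c(prec_annual = 2))
  st <- make_stack(truth, 30, 30)
  st$layers$prec_dup <- st$layers$prec_annual
  st$component <- c(st$component, prec_dup = "bioclimatic")
  occ <- sample_occurrences(truth, st, n = 150)
  occ$prec_dup <- occ$prec_annual
  reg <- default_registry()
  reg <- dplyr::bind_rows(reg, tibble::tibble(
    name = "prec_dup", component = "bioclimatic", units = "mm", description = "copy"
  ))
  rk <- rank_variables(occ, st, registry = reg, ntree = 300, seed = 2)
  mda_orig <- rk$mda[rk$name == "prec_annual"]
  mda_dup <- rk$mda[rk$name == "prec_dup"]
  expect_gt(mda_orig, 0)
  expect_gt(mda_dup, 0)
  expect_lt(max(mda_orig, mda_dup) / max(min(mda_orig, mda_dup), 1e-9), 4)
})

test_that("an all-missing variable is excluded with a warning", {
  study <- tiny_study(seed = 12, n_occ = 60)
  occ <- study$occ
  occ$elevation <- NA_real_
  expect_warning(
    rk <- rank_variables(occ, study$stack, ntree = 50, seed = 1),
    "elevation"
  )
  expect_false("elevation" %in% rk$name)
})
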