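test_that("well-separated blobs recover their cluster count", {
  withr::with_seed(4, {
    centers <- rbind(c(0, 0), c(10, 0), c(5, 9))
    mat <- centers[rep(1:3, each = 80), ] + matrix(rnorm(480, sd = 0.3), 240)
  })
  cl <- cluster_component(mat, max_k = 6, seed = 2)
  expect_equal(cl$k, 3)
  # assignments agree with the generating blobs up to relabelling
  blob <- rep(1:3, each = 80)
  tab <- table(blob, cl$assignments)
  expect_equal(sum(apply(tab, 1, max)), 240)
})

test_that("a constant layer collapses to a single cluster", {
  mat <- matrix(5, 50, 2)
  expect_warning(cl <- cluster_component(mat, max_k = 6, seed = 1), "max_k")
  expect_equal(cl$k, 1)
  expect_lt(cl$wss[1], 1e-10)
  expect_true(all(cl$assignments == 1))
})

test_that("the elbow inequality stops at the first sub-50% decrease", {
  # geometric wss with ratio 0.4: every decrease is 40% of the previous,
  # so the rule fires at the first eligible k
  wss_geo <- 100 * 0.4^(0:5)
  expect_equal(predchar:::elbow_k(wss_geo), 2)
  # linear decay never fires until the curve flattens
  wss_lin <- c(100, 75, 50, 25, 24.9, 24.8)
  expect_equal(predchar:::elbow_k(wss_lin), 4)
  # exactly-halving decreases never satisfy the strict inequality -> max_k
  expect_equal(predchar:::elbow_k(c(100, 50, 25, 12.5, 6.25, 3.125)), 6)
  expect_equal(predchar:::elbow_k(c(100, 60, 30, 14, 6, 2)), 6)
  # absolute variant compares against half the current wss
  expect_equal(predchar:::elbow_k(c(100, 80, 70, 65, 62, 60), "absolute"), 2)
})

test_that("incomplete cells get assignment zero", {
  withr::with_seed(5, {
    mat <- matrix(rnorm(200), 100, 2)
    mat[c(3, 50), 1] <- NA
  })
  cl <- cluster_component(mat, max_k = 3, seed = 1)
  expect_equal(which(cl$assignments == 0), c(3L, 50L))
})

test_that("categories enumerate the realized cluster triples", {
  b <- matrix(rep(1:2, each = 8), 4, 4)
  e <- matrix(rep(1:2, times = 8), 4, 4)
  g <- matrix(rep(c(1, 2), c(8, 8)), 4, 4, byrow = TRUE)
  elc <- compose_categories(list(bioclimatic = b, edaphic = e, geophysic = g))
  expect_equal(nrow(elc$legend), 8) # all 2x2x2 triples realized
  # remove one triple from the grid -> 7 categories
  g2 <- g
  g2[b == 1 & e == 1 & g == 1] <- 2
  elc7 <- compose_categories(list(bioclimatic = b, edaphic = e, geophysic = g2))
  expect_equal(nrow(elc7$legend), 7)
  # legend is a bijection onto 1..n
  expect_setequal(elc$legend$category, 1:8)
  expect_equal(nrow(dplyr::distinct(elc$legend[c("bio", "eda", "geo")])), 8)
})

test_that("cells missing any component become category zero", {
  b <- matrix(1L, 3, 3)
  e <- matrix(1L, 3, 3)
  g <- matrix(1L, 3, 3)
  b[2, 2] <- 0L
  elc <- compose_categories(list(bioclimatic = b, edaphic = e, geophysic = g))
  expect_equal(elc$category_grid$values[2, 2], 0)
  expect_equal(sum(elc$category_grid$values == 0), 1)
  expect_error(
    compose_categories(list(
      bioclimatic = b, edaphic = e, geophysic = matrix(1L, 2, 3)
    )),
    class = "predchar_dimension_error"
  )
})

test_that("category count is monotone in each component's resolution", {
  # nested refinement: splitting a cluster can only add categories
  b1 <- matrix(rep(1:2, each = 8), 4, 4)
  b2 <- matrix(rep(1:4, each = 4), 4, 4) # refines b1
  e <- matrix(rep(1:2, times = 8), 4, 4)
  g <- matrix(1L, 4, 4)
  n1 <- nrow(compose_categories(list(bioclimatic = b1, edaphic = e, geophysic = g))$legend)
  n2 <- nrow(compose_categories(list(bioclimatic = b2, edaphic = e, geophysic = g))$legend)
  expect_gte(n2, n1)
})

test_that("population category assignment is nearest-cell with exclusion flags", {
  vals <- matrix(c(1L, 2L, 0L, 3L), 2, 2)
  elc <- compose_categories(list(
    bioclimatic = vals, edaphic = pmin(vals, 1L), geophysic = pmin(vals, 1L)
  ))
  elc$category_grid <- pc_grid(vals, xll = 0, yll = 0, cellsize = 1)
  pops <- tibble::tibble(
    pop_id = c("a", "b", "c", "d"),
    lon = c(0.5, 0.5, 1.5, 9),
    lat = c(1.5, 0.5, 1.5, 9)
  )
  out <- assign_category(elc, pops)
  expect_equal(out$elc_category, c(1L, 2L, NA, NA)) # grid cell [1,2] is 0
  expect_equal(out$elc_excluded, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("the ELC map is reproducible for a fixed seed", {
  study <- tiny_study(seed = 17)
  m1 <- elc_map(study$stack, names(study$stack$layers), seed = 11)
  m2 <- elc_map(study$stack, names(study$stack$layers), seed = 11)
  expect_identical(m1$category_grid$values, m2$category_grid$values)
  expect_identical(m1$legend, m2$legend)
})
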