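test_that("drought selection applies both thresholds and ranks by flowering aridity", {
  pops <- filter_populations(5,
    iar_dm = c(14, 14, 13, 14, 16),
    iar_dm_f = c(16, 9, 13, 11, 9)
  )
  sel <- select_drought(pops)
  # pop 1 fails the flowering filter, pop 5 the annual filter
  expect_setequal(sel$members$pop_id, pops$pop_id[2:4])
  expect_equal(sel$members$rank_key, c(9, 11, 13))
  expect_equal(sel$members$rank, 1:3)
  expect_false(sel$capped)
})

test_that("boundary values are excluded by the strict comparators", {
  pops <- filter_populations(3,
    iar_dm = c(15, 14.99, 25),
    iar_dm_f = c(10, 10, 10),
    texture = "Clay"
  )
  d <- select_drought(pops)
  expect_equal(d$members$pop_id, pops$pop_id[2]) # iar_dm = 15 fails "< 15"
  w <- select_waterlogging(pops)
  expect_equal(nrow(w$members), 0) # iar_dm = 25 fails "> 25"
})

test_that("salinity falls back to the slightly-saline tier and reports it", {
  fresh <- filter_populations(4, iar_dm = 20, ec = c(0.5, 1, 1.5, 1.9))
  empty <- select_salinity(fresh)
  expect_equal(empty$tier, 2L)
  expect_true(empty$tier1_empty)
  expect_equal(nrow(empty$members), 0)

  one <- filter_populations(4, iar_dm = 20, ec = c(0.5, 3.1, 1.5, 1.9))
  hit <- select_salinity(one)
  expect_equal(hit$tier, 2L)
  expect_equal(hit$members$pop_id, one$pop_id[2])

  briny <- filter_populations(3, iar_dm = 20, ec = c(5, 3.1, 1))
  tier1 <- select_salinity(briny)
  expect_equal(tier1$tier, 1L)
  expect_equal(tier1$members$pop_id, briny$pop_id[1])
})

test_that("waterlogging requires poor drainage and humid sites", {
  pops <- filter_populations(4,
    iar_dm = c(40, 26, 40, 24),
    texture = c("Other", "Clay", "Silty Clay", "Clay")
  )
  sel <- select_waterlogging(pops)
  expect_setequal(sel$members$pop_id, pops$pop_id[2:3])
  # ranked from most humid down
  expect_equal(sel$members$rank_key, c(40, 26))
})

test_that("populations without a usable ELC category never enter selections", {
  pops <- filter_populations(4,
    iar_dm = 10, iar_dm_f = 10,
    excluded = c(FALSE, TRUE, FALSE, TRUE)
  )
  sel <- select_drought(pops)
  expect_setequal(sel$members$pop_id, pops$pop_id[c(1, 3)])
})

test_that("joint and sequential filtering agree", {
  withr::with_seed(33, {
    pops <- filter_populations(200,
      iar_dm = runif(200, 5, 35),
      iar_dm_f = runif(200, 5, 35)
    )
  })
  sel <- select_drought(pops, cap = 1000)
  joint <- pops$pop_id[pops$iar_dm < 15 & pops$iar_dm_f < 15]
  expect_setequal(sel$members$pop_id, joint)
})

test_that("capping is proportional across ELC categories", {
  pops <- filter_populations(10, iar_dm = 10)
  expect_equal(nrow(proportional_subset(pops |> dplyr::mutate(rank_key = iar_dm), cap = 30)), 10)

  two_cat <- filter_populations(60, iar_dm = 10, elc = rep(c(1L, 2L), c(40, 20))) |>
    dplyr::mutate(rank_key = seq_len(60))
  capped <- proportional_subset(two_cat, cap = 30)
  expect_equal(nrow(capped), 30)
  expect_equal(as.vector(table(capped$elc_category)), c(20, 10))

  uneven <- filter_populations(61, iar_dm = 10, elc = rep(c(1L, 2L), c(41, 20))) |>
    dplyr::mutate(rank_key = seq_len(61))
  capped2 <- proportional_subset(uneven, cap = 30)
  # largest remainder: quotas 20.16 / 9.84 -> 20 / 10
  expect_equal(as.vector(table(capped2$elc_category)), c(20, 10))
})

test_that("quotas are filled with each category's best-ranked candidates", {
  pops <- filter_populations(40, iar_dm = 10, elc = rep(1:2, each = 20)) |>
    dplyr::mutate(rank_key = c(20:1, 1:20))
  capped <- proportional_subset(pops, cap = 10)
  by_cat <- split(capped$rank_key, capped$elc_category)
  expect_equal(sort(by_cat[["1"]]), 1:5) # best (lowest) keys in category 1
  expect_equal(sort(by_cat[["2"]]), 1:5)
})

test_that("subset size is always min(n, cap) and quotas sum to cap", {
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(5:80, 1)
      cap <- sample(3:30, 1)
      pops <- filter_populations(n,
        iar_dm = runif(n, 5, 30),
        elc = sample(1:4, n, replace = TRUE)
      ) |> dplyr::mutate(rank_key = runif(n))
      out <- proportional_subset(pops, cap = cap)
      expect_equal(nrow(out), min(n, cap))
    }
  })
})

test_that("overlap report counts shared populations", {
  a <- filter_populations(5, iar_dm = 10)
  b <- a[3:5, ]
  b$pop_id[2:3] <- c("ID_X1", "ID_X2")
  disjoint <- summarize_overlaps(
    one = a[1:2, ], two = tibble::tibble(pop_id = c("Z1", "Z2"))
  )
  expect_true(all(disjoint$pairwise$overlap == 0))

  shared <- summarize_overlaps(one = a, two = b)
  expect_equal(shared$pairwise$overlap, 1) # only pop 3 in both
  expect_equal(sum(shared$membership$n_subsets == 2), 1)
  expect_equal(length(shared$all_subsets), 1)
})

test_that("selections are pure functions of the input table", {
  pops <- filter_populations(30,
    iar_dm = runif(30, 5, 20), iar_dm_f = runif(30, 5, 20)
  )
  expect_identical(
    select_drought(pops)$members,
    select_drought(pops)$members
  )
})
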