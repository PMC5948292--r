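test_that("invalid specs fail with the offending field named", {
  expect_error(population_spec(n_individuals = 0), "n_individuals")
  expect_error(population_spec(100, n_base_years = 1), "n_base_years")
  expect_error(population_spec(100, zero_claim_prob = 1.5),
               "zero_claim_prob")
  expect_error(population_spec(100, target_mean_claims = -3),
               "target_mean_claims")
  expect_error(population_spec(100, decile_targets = rev(1:10)),
               "decile_targets")
  expect_error(population_spec(100, persistence_rho = 2), "persistence_rho")
  expect_error(population_spec(100, age_range = c(10, 99)), "age_range")
})

test_that("generated panels are balanced, adult-only and seed-deterministic", {
  spec <- population_spec(n_individuals = 2000, seed = 11)
  p1 <- generate_panel(spec)
  p2 <- generate_panel(spec)
  expect_identical(p1, p2)
  ny <- n_base_years(p1) + 1L
  expect_true(all(table(p1$person_id) == ny))
  expect_equal(nrow(p1), 2000 * ny)
  expect_true(all(p1$age >= 18))
  # ages fixed per person across years
  expect_true(all(tapply(p1$age, p1$person_id,
                         function(a) length(unique(a))) == 1))
  expect_true(all(p1$supp_claims >= 0) && all(p1$basic_claims >= 0))
  # a different seed gives a different panel
  p3 <- generate_panel(population_spec(n_individuals = 2000, seed = 12))
  expect_false(identical(p1$supp_claims, p3$supp_claims))
})

test_that("degenerate mixture: zero_claim_prob = 1 yields all-zero claims", {
  p <- generate_panel(population_spec(500, zero_claim_prob = 1, seed = 2))
  expect_true(all(p$supp_claims == 0))
  p2 <- generate_panel(population_spec(500, zero_claim_prob = 0, seed = 2))
  expect_true(all(p2$supp_claims > 0))
})

test_that("claims mixture is calibrated: zero share, mean, cap, persistence", {
  panel <- mid_panel()
  y <- panel$supp_claims
  expect_lt(abs(mean(y == 0) - 0.30), 0.02)
  expect_lt(abs(mean(y) / 221 - 1), 0.05)
  expect_true(all(y <= 35000))
  # adjacent-year log-claims correlation among two-year positives
  nb <- n_base_years(panel)
  y4 <- panel$supp_claims[panel$base_year_index == nb - 1]
  y5 <- panel$supp_claims[panel$base_year_index == nb]
  pos <- y4 > 0 & y5 > 0
  expect_lt(abs(cor(log(y4[pos]), log(y5[pos])) - 0.65), 0.05)
})

test_that("risk gradient: morbidity flags and age raise expected claims", {
  panel <- mid_panel()
  expect_gt(mean(panel$supp_claims[panel$pcg]),
            mean(panel$supp_claims[!panel$pcg]))
  expect_gt(mean(panel$supp_claims[panel$dcg]),
            mean(panel$supp_claims[!panel$dcg]))
  old <- panel$age >= 65
  expect_gt(mean(panel$supp_claims[old]), mean(panel$supp_claims[!old]))
})

test_that("decile_summary keeps tie groups together and shares sum to 100", {
  ds <- decile_summary(c(0, 0, 0, 0, 0, 10, 20, 30, 40, 50))
  expect_equal(ds$share, c(50, 0, 0, 0, 0, 10, 10, 10, 10, 10))
  expect_equal(ds$mean[1], 0)
  expect_equal(ds$mean[6:10], c(10, 20, 30, 40, 50))
  # all-equal input: one tie group, mean is the common value
  ds2 <- decile_summary(rep(7.5, 40))
  expect_equal(ds2$share[1], 100)
  expect_equal(ds2$mean[1], 7.5)
  expect_equal(sum(ds2$share), 100)
  expect_error(decile_summary(numeric(0)), "empty")
  expect_error(decile_summary(c(1, -2)), ">= 0")
})

test_that("decile_summary matches a sort-and-chunk oracle on tie-free data", {
  set.seed(99)
  x <- exp(rnorm(1000, 4, 1.2)) + runif(1000)  # continuous, no ties
  ds <- decile_summary(x)
  s <- sort(x)
  oracle <- vapply(1:10, function(k) mean(s[((k - 1) * 100 + 1):(k * 100)]),
                   numeric(1))
  expect_equal(ds$mean, oracle)
  expect_equal(ds$share, rep(10, 10))
  expect_false(is.unsorted(ds$mean))
})

test_that("panel CSV round trip is the identity; invalid files are rejected", {
  panel <- generate_panel(population_spec(300, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(as.data.frame(panel), as.data.frame(back))
  expect_equal(n_individuals(back), 300)
  expect_equal(n_base_years(back), 5)

  # person missing one year -> unbalanced
  df <- utils::read.csv(path)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[-2, ], bad, row.names = FALSE)
  expect_error(read_panel(bad), "unbalanced")

  # missing column
  utils::write.csv(df[, -10], bad, row.names = FALSE)
  expect_error(read_panel(bad), "missing required columns")

  # non-numeric claims
  df2 <- df
  df2$supp_claims <- as.character(df2$supp_claims)
  df2$supp_claims[1] <- "abc"
  utils::write.csv(df2, bad, row.names = FALSE)
  expect_error(read_panel(bad), "supp_claims")
})
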