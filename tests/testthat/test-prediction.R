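test_that("age-gender classes partition adults into 28 cells", {
  grid <- expand.grid(age = 18:99, sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  cls <- age_gender_class(grid$age, grid$sex)
  expect_true(all(cls %in% 1:28))
  expect_equal(sort(unique(cls)), 1:28)
  # each person maps to exactly one class; band edges behave
  expect_equal(age_gender_class(c(18, 24, 25, 84, 85, 99),
                                rep("female", 6)),
               c(1L, 1L, 3L, 25L, 27L, 27L))
  expect_error(age_gender_class(17, "male"), "18")
})

test_that("discretize_prior matches a brute-force rank oracle, ties to lower bin", {
  set.seed(21)
  x <- c(rep(0, 40), exp(rnorm(60, 4, 1)))[sample(100)]
  d <- discretize_prior(x, 10)
  # oracle: smallest bin whose cutpoint is >= x, ties to the lower side
  oracle <- vapply(x, function(v) {
    k <- which(v <= d$cutpoints)
    if (length(k)) min(k) else 10L
  }, integer(1))
  expect_equal(d$bins, as.integer(oracle))
  expect_true(all(d$bins[x == 0] == 1L))  # the zero mass sits in the lowest bin

  # 20 distinct values, 20 bins: one value per vigintile
  v <- sort(runif(20))
  expect_equal(discretize_prior(v, 20)$bins, 1:20)

  expect_equal(discretize_prior(rep(3, 15), 5)$bins, rep(1L, 15))
  expect_error(discretize_prior(1:3, 10), "at least")
  expect_error(discretize_prior(numeric(0), 10), "empty")

  # frozen cutpoints reproduce the assignment on new data
  d2 <- discretize_prior(x, 10, cutpoints = d$cutpoints)
  expect_equal(d2$bins, d$bins)
})

test_that("damped IRLS agrees with stats::glm on well-conditioned gamma data", {
  set.seed(31)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  mu <- exp(1 + 0.5 * x1 - 0.8 * x2)
  y <- rgamma(n, shape = 2, scale = mu / 2)
  X <- cbind(1, x1, x2)
  ours <- shisim:::gamma_log_irls(X, y)
  ref <- glm(y ~ x1 + x2, family = Gamma(link = "log"))
  expect_true(ours$converged)
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(ours$deviance, deviance(ref), tolerance = 1e-6)
})

test_that("constant claims give a degenerate fit predicting the constant", {
  panel <- generate_panel(population_spec(150, seed = 3))
  panel$supp_claims <- rep(300, nrow(panel))
  fit <- suppressWarnings(fit_claims_glm(panel, 1))
  prior <- panel[panel$base_year_index == 0, ]
  expect_equal(suppressWarnings(predict_claims(fit, prior)),
               rep(300, 150), tolerance = 1e-6)
})

test_that("refitting the same panel gives identical coefficients", {
  panel <- mid_panel()
  f1 <- suppressWarnings(fit_claims_glm(panel, 2))
  f2 <- suppressWarnings(fit_claims_glm(panel, 2))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_true(f1$converged)
  expect_error(fit_claims_glm(panel, 0), "target_year")
})

test_that("predictions are positive, finite, and nearly mean-balanced", {
  panel <- mid_panel()
  nb <- n_base_years(panel)
  fit <- mid_predictors()[[nb]]
  prior <- panel[panel$base_year_index == nb - 1, ]
  cur <- panel[panel$base_year_index == nb, ]
  pred <- predict_claims(fit, prior)
  expect_true(all(is.finite(pred)) && all(pred > 0))
  expect_lt(abs(mean(pred) / mean(cur$supp_claims) - 1), 0.05)
  # all-reference covariates predict exp(intercept)
  ref <- data.frame(age = 18, sex = "female",
                    ethnicity = fit$xlevels$ethnicity[1],
                    urbanization = fit$xlevels$urbanization[1],
                    pcg = FALSE, dcg = FALSE,
                    basic_claims = 0, supp_claims = 0)
  expect_equal(predict_claims(fit, ref),
               exp(fit$coefficients[["(Intercept)"]]))
})

test_that("generator-true covariate effects are recovered on the covariate layout", {
  fit <- suppressWarnings(fit_claims_glm(
    mid_panel(), n_base_years(mid_panel()),
    terms = c("ag_class", "pcg", "dcg", "urbanization", "ethnicity")))
  expect_lt(abs(fit$coefficients[["pcgTRUE"]] - log(2)), 0.2)
  expect_lt(abs(fit$coefficients[["dcgTRUE"]] - log(1.8)), 0.2)
})

test_that("unseen factor levels fall back to the reference with a warning", {
  fit <- mid_predictors()[[1]]
  nd <- mid_panel()[mid_panel()$base_year_index == 0, ][1:5, ]
  nd$ethnicity <- "martian"
  expect_warning(p <- predict_claims(fit, nd), "unseen")
  expect_true(all(is.finite(p)))
})

test_that("predictor JSON round trip preserves predictions", {
  fit <- mid_predictors()[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  write_predictor(fit, path)
  back <- read_predictor(path)
  nd <- mid_panel()[mid_panel()$base_year_index == 0, ][1:50, ]
  expect_equal(predict_claims(back, nd), predict_claims(fit, nd))
  expect_equal(back$decile_cutpoints, fit$decile_cutpoints)
})

test_that("predicted-claims deciles are strictly increasing on calibrated panels", {
  panel <- mid_panel()
  nb <- n_base_years(panel)
  pred <- predict_claims(mid_predictors()[[nb]],
                         panel[panel$base_year_index == nb - 1, ])
  ds <- decile_summary(pred)
  expect_true(all(diff(ds$mean) > 0))
})
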