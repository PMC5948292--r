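# shared fixtures, built once per test run and cached
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# mid-size panel for statistical checks
mid_panel <- function() {
  memo("mid_panel", generate_panel(population_spec(n_individuals = 10000,
                                                   seed = 5)))
}

mid_predictors <- function() {
  memo("mid_predictors", suppressWarnings(fit_all_predictors(mid_panel())))
}

# large panel at the calibrated study scale, shared by the acceptance checks
big_panel <- function() {
  memo("big_panel", generate_panel(population_spec(n_individuals = 50000,
                                                   seed = 1)))
}

big_predictors <- function() {
  memo("big_predictors", suppressWarnings(fit_all_predictors(big_panel())))
}

# published calibration constants used across tests
TABLE1_DECILES <- c(0, 0, 13.58, 44.71, 101.18, 147.70, 213.06, 271.98,
                    429.37, 996.32)
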