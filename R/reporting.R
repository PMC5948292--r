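#' Uptake trajectory plot
#'
#' Plots mean insurance uptake per simulated year, one line per rating
#' scheme, solid/dashed by opt-out probability, with the central 90%
#' replicate band. Following the headline presentation of such analyses,
#' the individual (full risk rating) scheme is omitted by default because
#' its trajectory is near-indistinguishable from the 140-class scheme;
#' `include_individual = TRUE` adds it.
#'
#' @param summary_df combined scenario summary (from
#'   [run_scenarios()]`$summary` or the pipeline's summary CSV) with
#'   columns `sim_year`, `uptake_mean`, `uptake_q05`, `uptake_q95`,
#'   `scheme`, `opt_out_prob`.
#' @param include_individual logical.
#' @return a ggplot object.
#' @export
uptake_plot <- function(summary_df, include_individual = FALSE) {
  df <- summary_df
  if (!include_individual) df <- df[df$scheme != "individual", ]
  df$p_lab <- sprintf("p = %.2f", df$opt_out_prob)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sim_year,
                                   y = 100 * .data$uptake_mean,
                                   colour = .data$scheme,
                                   linetype = .data$p_lab)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$uptake_q05,
                                      ymax = 100 * .data$uptake_q95,
                                      fill = .data$scheme),
                         alpha = 0.12, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Simulation year",
                  y = "Uptake of supplementary insurance (%)",
                  colour = "Premium rating", linetype = "Opt-out",
                  fill = "Premium rating") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Read a JSON run configuration
#'
#' The configuration has a `population` section (arguments of
#' [population_spec()]), a `simulation` section (`horizon`, `schemes`,
#' `opt_out_probs`, `loading`, `operating_risk_premium`, `n_replicates`)
#' and a top-level `seed`. Missing entries take the package defaults.
#'
#' @param path JSON file path.
#' @param seed optional seed overriding the file's seed.
#' @return list with elements `population` (a `population_spec`) and
#'   `simulation` (a list), plus `seed`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- seed %||% raw$seed %||% 1L
  pop_args <- raw$population %||% list()
  if (!is.null(pop_args$covariate_prevalences))
    pop_args$covariate_prevalences <-
      lapply(pop_args$covariate_prevalences, unlist)
  pop_args$seed <- seed
  if (is.null(pop_args$n_individuals))
    stop("run config: population$n_individuals is required")
  pop <- do.call(population_spec, pop_args)
  sim <- raw$simulation %||% list()
  sim$horizon <- sim$horizon %||% 25L
  sim$schemes <- sim$schemes %||% c("community", "age_gender_28",
                                    "age_gender_quintile_140", "individual")
  sim$opt_out_probs <- sim$opt_out_probs %||% c(0.05, 0.10)
  sim$loading <- sim$loading %||% 0.23
  sim$operating_risk_premium <- sim$operating_risk_premium %||% 100
  sim$n_replicates <- sim$n_replicates %||% 1L
  list(population = pop, simulation = sim, seed = as.integer(seed))
}

#' End-to-end analysis pipeline
#'
#' Runs the four stages — generate the synthetic panel, fit the per-year
#' claims predictors, simulate every (scheme, opt-out probability)
#' scenario, and report figures and tables — writing all outputs under
#' `out_dir`. Each stage can also be run separately
#' ([pipeline_generate()], [pipeline_fit()], [pipeline_simulate()],
#' [pipeline_report()]); later stages read the files written by earlier
#' ones. A run manifest (`manifest.json`) records the configuration, seed,
#' package version and MD5 digests of every text output, so a re-run with
#' the same configuration reproduces the outputs digest-for-digest.
#'
#' @param config path to a JSON run configuration, or the list returned by
#'   [read_run_config()].
#' @param out_dir output directory (created if missing).
#' @param seed optional seed override.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config, seed) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pipeline_generate(cfg, out_dir)
  pipeline_fit(cfg, out_dir)
  pipeline_simulate(cfg, out_dir)
  pipeline_report(cfg, out_dir)
  write_manifest(cfg, out_dir)
}

#' @rdname run_pipeline
#' @export
pipeline_generate <- function(config, out_dir) {
  panel <- generate_panel(config$population)
  write_panel(panel, file.path(out_dir, "panel.csv"))
  invisible(panel)
}

#' @rdname run_pipeline
#' @export
pipeline_fit <- function(config, out_dir) {
  panel_path <- file.path(out_dir, "panel.csv")
  if (!file.exists(panel_path))
    stop("pipeline_fit: missing ", panel_path, "; run the generate stage first")
  panel <- read_panel(panel_path)
  predictors <- fit_all_predictors(panel)
  for (d in seq_along(predictors))
    write_predictor(predictors[[d]],
                    file.path(out_dir, sprintf("predictor_year%d.json", d)))
  invisible(predictors)
}

#' @rdname run_pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  panel_path <- file.path(out_dir, "panel.csv")
  if (!file.exists(panel_path))
    stop("pipeline_simulate: missing ", panel_path)
  panel <- read_panel(panel_path)
  pred_paths <- file.path(out_dir, sprintf("predictor_year%d.json",
                                           seq_len(n_base_years(panel))))
  if (!all(file.exists(pred_paths)))
    stop("pipeline_simulate: missing predictor files; run the fit stage first")
  predictors <- lapply(pred_paths, read_predictor)
  sim <- config$simulation
  base_cfg <- simulation_config(
    horizon = sim$horizon, loading = sim$loading,
    operating_risk_premium = sim$operating_risk_premium,
    seed = config$seed, n_replicates = sim$n_replicates)
  scen <- run_scenarios(panel, schemes = sim$schemes,
                        opt_out_probs = sim$opt_out_probs,
                        config = base_cfg, predictors = predictors)
  write.csv(scen$trajectories, file.path(out_dir, "trajectories.csv"),
            row.names = FALSE)
  write.csv(scen$summary, file.path(out_dir, "scenario_summary.csv"),
            row.names = FALSE)
  invisible(scen)
}

#' @rdname run_pipeline
#' @export
pipeline_report <- function(config, out_dir) {
  summ_path <- file.path(out_dir, "scenario_summary.csv")
  if (!file.exists(summ_path))
    stop("pipeline_report: missing ", summ_path, "; run the simulate stage first")
  summary_df <- read.csv(summ_path)
  panel <- read_panel(file.path(out_dir, "panel.csv"))
  nb <- n_base_years(panel)
  last <- panel[panel$base_year_index == nb, ]
  write.csv(decile_summary(last$supp_claims),
            file.path(out_dir, "actual_claims_deciles.csv"),
            row.names = FALSE)
  pred <- read_predictor(file.path(out_dir,
                                   sprintf("predictor_year%d.json", nb)))
  prior <- panel[panel$base_year_index == nb - 1L, ]
  write.csv(decile_summary(predict_claims(pred, prior)),
            file.path(out_dir, "predicted_claims_deciles.csv"),
            row.names = FALSE)
  # the plot is drawn from the summary CSV, never recomputed
  p <- uptake_plot(summary_df)
  ggplot2::ggsave(file.path(out_dir, "uptake.png"), p,
                  width = 8, height = 5, dpi = 150)
  final <- summary_df[summary_df$sim_year == max(summary_df$sim_year), ]
  lines <- c("Final-year uptake by scenario:",
             sprintf("  %-26s p=%.2f  %5.1f%%", final$scheme,
                     final$opt_out_prob, 100 * final$uptake_mean))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(summary_df)
}

write_manifest <- function(config, out_dir) {
  files <- list.files(out_dir, pattern = "\\.(csv|json|txt)$")
  files <- setdiff(files, "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("shisim")),
    seed = config$seed,
    population = unclass(config$population),
    simulation = config$simulation,
    outputs = digests
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
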