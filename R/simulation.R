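#' Map a simulation year onto the looped data years
#'
#' The market simulation runs for more years than the data contain by
#' looping the available cycle years over and over; individual health is
#' therefore "reset" at the start of each cycle.
#'
#' @param sim_year simulation year index (>= 0).
#' @param n_base_years number of cycle years in the panel.
#' @return 0-based cycle-year index, `sim_year %% n_base_years`.
#' @export
#' @examples
#' loop_base_year(0:24, 5)
loop_base_year <- function(sim_year, n_base_years) {
  stopifnot(all(sim_year >= 0), n_base_years >= 1)
  as.integer(sim_year %% n_base_years)
}

#' Configuration of a market simulation run
#'
#' @param horizon number of simulated decision years (default 25).
#' @param opt_out_prob probability that an insured for whom the policy is
#'   not expected to be beneficial opts out in a given year (0.05 in the
#'   baseline scenario, 0.10 under stronger adverse selection).
#' @param scheme premium rating scheme, see [set_premiums()].
#' @param loading proportional loading fee (default 0.23).
#' @param operating_risk_premium fixed Pratt risk premium used for the
#'   profitability classification (default EUR 100).
#' @param seed integer seed; opt-out draws are keyed by (replicate,
#'   sim_year) so trajectories are reproducible and order-independent.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param opt_in_prob probability that an uninsured person for whom the
#'   policy is beneficial opts back in (default 1: deterministic opt-in;
#'   0 disables opt-in, useful for spiral-direction diagnostics).
#' @param ties_beneficial tie rule of [is_beneficial()].
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(horizon = 25L,
                              opt_out_prob = 0.05,
                              scheme = "community",
                              loading = 0.23,
                              operating_risk_premium = 100,
                              seed = 1L,
                              n_replicates = 1L,
                              opt_in_prob = 1,
                              ties_beneficial = TRUE) {
  stopifnot(horizon >= 1, opt_out_prob >= 0, opt_out_prob <= 1,
            loading >= 0, operating_risk_premium >= 0,
            opt_in_prob >= 0, opt_in_prob <= 1, n_replicates >= 1)
  scheme <- match.arg(scheme, RATING_SCHEMES)
  structure(list(horizon = as.integer(horizon),
                 opt_out_prob = opt_out_prob,
                 scheme = scheme,
                 loading = loading,
                 operating_risk_premium = operating_risk_premium,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 opt_in_prob = opt_in_prob,
                 ties_beneficial = ties_beneficial),
            class = "simulation_config")
}

#' Apply the yearly enrolment flows
#'
#' Pure bookkeeping of the four yearly market flows given the enrolment
#' state, the profitability classification and the realized opt-out (and
#' optionally opt-in) draws:
#' insured and not beneficial may opt out (flow 3); the remaining insured
#' keep the policy (flow 4); uninsured and beneficial opt back in (flow 5);
#' uninsured and not beneficial remain out (flow 6). The four flows
#' partition the population. In the first simulated year flows 3 and 4 play
#' the roles of the initial opt-out/keep flows (1 and 2), with flows 5 and
#' 6 empty because everyone starts insured.
#'
#' @param insured logical vector: current enrolment.
#' @param beneficial logical vector: profitability classification for the
#'   coming year.
#' @param optout logical vector: realized opt-out indicator (only consulted
#'   for insured, not-beneficial persons).
#' @param optin logical vector: realized opt-in indicator (only consulted
#'   for uninsured, beneficial persons); defaults to everyone.
#' @return list with `insured` (new enrolment) and `flows` (named integer
#'   vector `opt_out`, `keep`, `opt_in`, `stay_out`).
#' @export
apply_flows <- function(insured, beneficial, optout,
                        optin = rep(TRUE, length(insured))) {
  stopifnot(length(beneficial) == length(insured),
            length(optout) == length(insured))
  out3 <- insured & !beneficial & optout
  keep4 <- insured & !out3
  in5 <- !insured & beneficial & optin
  stay6 <- !insured & !in5
  list(insured = keep4 | in5,
       flows = c(opt_out = sum(out3), keep = sum(keep4),
                 opt_in = sum(in5), stay_out = sum(stay6)))
}

# internal: reshape the panel into person x data-year matrices and
# precompute everything the yearly step needs
build_sim_inputs <- function(panel, predictors) {
  nb <- n_base_years(panel)
  n <- n_individuals(panel)
  if (length(predictors) != nb)
    stop("need one fitted predictor per cycle year (", nb, ")")
  panel <- panel[order(panel$person_id, panel$base_year_index), ]
  ny <- nb + 1L
  stopifnot(nrow(panel) == n * ny)
  claims <- matrix(panel$supp_claims, nrow = n, ncol = ny, byrow = TRUE)
  year0 <- panel[panel$base_year_index == 0L, ]
  ag <- age_gender_class(year0$age, year0$sex)
  # per-data-year expense quintiles, cutpoints frozen on the full population
  Q <- vapply(seq_len(ny), function(j)
    quintile_of_prior(claims[, j])$bins, integer(n))
  # predicted claims for each cycle year, from the prior data year's records
  pred <- vapply(seq_len(nb), function(d) {
    prior <- panel[panel$base_year_index == d - 1L, ]
    predict_claims(predictors[[d]], prior)
  }, numeric(n))
  list(n = n, nb = nb, ag = ag, claims = claims, Q = Q, pred = pred,
       person_id = year0$person_id)
}

#' Run the multi-year market simulation
#'
#' Simulates the opt-out/opt-in dynamics of the supplementary insurance
#' market. Every simulated year `s`:
#'
#' 1. the premium schedule for year `s` is fitted on the year-`s-1` insured
#'    pool's realized claims (grouped, for the 140-class scheme, by the
#'    quintile of the year before that), with the loading applied;
#' 2. every person is classified via [is_beneficial()] using their
#'    predicted claims for year `s` and the premium of their *current*
#'    age-gender class and expense quintile;
#' 3. insured, not-beneficial persons opt out with probability
#'    `opt_out_prob` (independent seeded draws); insured beneficial persons
#'    keep the policy; uninsured beneficial persons opt back in; the rest
#'    stay out ([apply_flows()]).
#'
#' Year 0 is the base year: everyone is insured. Data years are looped via
#' [loop_base_year()]. If the insured pool empties, the trajectory ends
#' with status `"collapsed"` for that replicate.
#'
#' @param panel an `insured_panel`.
#' @param config a [simulation_config()].
#' @param predictors list of fitted [claims_predictor] objects, one per
#'   cycle year; fitted on the fly when omitted.
#' @param inputs precomputed simulation inputs (internal reuse across
#'   scenarios); overrides `panel`/`predictors` reshaping.
#' @param keep_classification logical; when `TRUE`, the per-year
#'   profitability classification of replicate 1 is returned under
#'   `$classification` (a list of logical vectors).
#' @return an object of class `market_run`: `trajectories` (one row per
#'   replicate and simulated year with uptake, premium and claims summaries
#'   and the four flow counts), `summary` (per-year mean and central 90%
#'   band of uptake over replicates), `status` (per replicate), `config`.
#' @export
run_market <- function(panel, config, predictors = NULL, inputs = NULL,
                       keep_classification = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(inputs)) {
    if (is.null(predictors)) predictors <- fit_all_predictors(panel)
    inputs <- build_sim_inputs(panel, predictors)
  }
  n <- inputs$n; nb <- inputs$nb
  rp <- config$operating_risk_premium
  rows <- vector("list", config$n_replicates)
  status <- character(config$n_replicates)
  classification <- if (keep_classification) list() else NULL

  for (r in seq_len(config$n_replicates)) {
    insured <- rep(TRUE, n)
    traj <- vector("list", config$horizon + 1L)
    d0 <- loop_base_year(0L, nb) + 1L
    traj[[1]] <- data.frame(
      replicate = r, sim_year = 0L, data_year = d0, n_insured = n,
      uptake = 1, mean_premium = NA_real_,
      pool_mean_claims = mean(inputs$claims[, d0 + 1L]),
      flow_opt_out = NA_integer_, flow_keep = NA_integer_,
      flow_opt_in = NA_integer_, flow_stay_out = NA_integer_)
    status[r] <- "completed"
    for (s in seq_len(config$horizon)) {
      d <- loop_base_year(s, nb) + 1L        # data year of year s
      dp <- loop_base_year(s - 1L, nb) + 1L  # data year of year s-1
      pool_idx <- which(insured)
      if (length(pool_idx) == 0L) {
        status[r] <- "collapsed"
        break
      }
      pool <- data.frame(
        supp_claims = inputs$claims[pool_idx, dp + 1L],
        ag_class = inputs$ag[pool_idx],
        quintile = inputs$Q[pool_idx, dp])   # quintile of data year dp - 1
      sched <- set_premiums(pool, config$scheme, config$loading)
      prem <- premium_for(sched, inputs$ag, inputs$Q[, dp + 1L],
                          predicted = inputs$pred[, d])
      ben <- is_beneficial(inputs$pred[, d], prem, rp,
                           config$ties_beneficial)
      draws <- with_seed(derive_seed(config$seed, r, s), {
        u_out <- runif(n)
        u_in <- if (config$opt_in_prob < 1) runif(n) else NULL
        list(out = u_out, inn = u_in)
      })
      optout <- draws$out < config$opt_out_prob
      optin <- if (config$opt_in_prob >= 1) rep(TRUE, n)
               else if (config$opt_in_prob <= 0) rep(FALSE, n)
               else draws$inn < config$opt_in_prob
      fl <- apply_flows(insured, ben, optout, optin)
      insured <- fl$insured
      if (keep_classification && r == 1L)
        classification[[s]] <- ben
      ni <- sum(insured)
      traj[[s + 1L]] <- data.frame(
        replicate = r, sim_year = s, data_year = d, n_insured = ni,
        uptake = ni / n,
        mean_premium = if (ni) mean(prem[insured]) else NA_real_,
        pool_mean_claims = if (ni) mean(inputs$claims[insured, d + 1L])
                           else NA_real_,
        flow_opt_out = fl$flows[["opt_out"]],
        flow_keep = fl$flows[["keep"]],
        flow_opt_in = fl$flows[["opt_in"]],
        flow_stay_out = fl$flows[["stay_out"]])
    }
    rows[[r]] <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  }
  trajectories <- do.call(rbind, rows)
  rownames(trajectories) <- NULL
  summ <- aggregate(uptake ~ sim_year, trajectories, function(u)
    c(mean = mean(u), q05 = unname(quantile(u, 0.05)),
      q95 = unname(quantile(u, 0.95))))
  summary_df <- data.frame(sim_year = summ$sim_year,
                           uptake_mean = summ$uptake[, "mean"],
                           uptake_q05 = summ$uptake[, "q05"],
                           uptake_q95 = summ$uptake[, "q95"])
  pm <- aggregate(cbind(mean_premium, pool_mean_claims) ~ sim_year,
                  trajectories, mean, na.action = stats::na.pass)
  summary_df <- merge(summary_df, pm, by = "sim_year")
  structure(list(trajectories = trajectories, summary = summary_df,
                 status = status, config = config,
                 classification = classification),
            class = "market_run")
}

#' @export
print.market_run <- function(x, ...) {
  cfg <- x$config
  final <- x$summary[x$summary$sim_year == max(x$summary$sim_year), ]
  cat(sprintf("<market_run> scheme %s, p = %.2f, %d replicate(s), %d years\n",
              cfg$scheme, cfg$opt_out_prob, cfg$n_replicates, cfg$horizon))
  cat(sprintf("  final-year uptake %.1f%% (90%% band %.1f-%.1f%%)\n",
              100 * final$uptake_mean, 100 * final$uptake_q05,
              100 * final$uptake_q95))
  if (any(x$status == "collapsed"))
    cat(sprintf("  %d replicate(s) collapsed\n",
                sum(x$status == "collapsed")))
  invisible(x)
}

#' Run a grid of rating-scheme / opt-out scenarios
#'
#' Convenience driver that fits the claims predictors once and runs
#' [run_market()] for every combination of rating scheme and opt-out
#' probability with paired seeds (the same opt-out draws are used in every
#' scenario, so scenario differences are not masked by Monte-Carlo noise).
#'
#' @param panel an `insured_panel`.
#' @param schemes character vector of rating schemes.
#' @param opt_out_probs numeric vector of opt-out probabilities.
#' @param config a base [simulation_config()]; its `scheme` and
#'   `opt_out_prob` are overridden per scenario.
#' @param predictors optional pre-fitted predictor list.
#' @return an object of class `scenario_set`: `runs` (named list of
#'   `market_run`), `trajectories` and `summary` (combined data frames with
#'   `scheme` and `opt_out_prob` columns).
#' @export
run_scenarios <- function(panel,
                          schemes = c("community", "age_gender_28",
                                      "age_gender_quintile_140",
                                      "individual"),
                          opt_out_probs = c(0.05, 0.10),
                          config = simulation_config(),
                          predictors = NULL) {
  if (is.null(predictors)) predictors <- fit_all_predictors(panel)
  inputs <- build_sim_inputs(panel, predictors)
  runs <- list()
  for (sch in schemes) for (p in opt_out_probs) {
    cfg <- config
    cfg$scheme <- sch
    cfg$opt_out_prob <- p
    key <- sprintf("%s_p%g", sch, p)
    runs[[key]] <- run_market(config = cfg, inputs = inputs,
                              panel = NULL)
  }
  tag <- function(df, sch, p) {
    df$scheme <- sch; df$opt_out_prob <- p; df
  }
  traj <- do.call(rbind, mapply(function(run, key) {
    tag(run$trajectories, run$config$scheme, run$config$opt_out_prob)
  }, runs, names(runs), SIMPLIFY = FALSE))
  summ <- do.call(rbind, lapply(runs, function(run)
    tag(run$summary, run$config$scheme, run$config$opt_out_prob)))
  rownames(traj) <- rownames(summ) <- NULL
  structure(list(runs = runs, trajectories = traj, summary = summ),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("<scenario_set>\n")
  last <- x$summary[x$summary$sim_year ==
                      max(x$summary$sim_year), ]
  for (i in seq_len(nrow(last)))
    cat(sprintf("  %-26s p=%.2f  final uptake %5.1f%%\n",
                last$scheme[i], last$opt_out_prob[i],
                100 * last$uptake_mean[i]))
  invisible(x)
}
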