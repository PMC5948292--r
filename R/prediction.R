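#' Age-gender risk classes
#'
#' Maps age and sex to one of 28 risk classes: 14 age bands (18-24, 25-29,
#' ..., 80-84, 85+) crossed with sex. These classes serve both as a covariate
#' of the claims prediction model and as the grouping of the age-gender
#' premium rating scheme.
#'
#' @param age numeric vector of ages (>= 18).
#' @param sex character vector, `"female"` or `"male"`.
#' @return integer vector of class ids in 1..28 (female = odd, male = even
#'   within each band).
#' @export
#' @examples
#' age_gender_class(c(18, 30, 90), c("female", "male", "female"))
age_gender_class <- function(age, sex) {
  edges <- c(18, 25, seq(30, 85, by = 5))  # 14 bands, last is 85+
  band <- findInterval(age, edges)
  band[band > 14L] <- 14L
  if (any(band < 1L)) stop("age_gender_class: ages below 18 not supported")
  as.integer((band - 1L) * 2L + ifelse(sex == "female", 1L, 2L))
}

N_AG_CLASSES <- 28L

#' Discretize prior-year claims into empirical quantile bins
#'
#' Computes empirical-quantile cutpoints (inverse-ECDF quantiles) and assigns
#' each value to a bin, with ties deterministically assigned to the lower
#' bin: a value equal to a cutpoint falls in the bin below it. With heavy
#' point masses (e.g. many zeros) several cutpoints coincide and the
#' swallowed bins stay empty, all mass going to the lowest such bin.
#'
#' @param claims numeric vector of claims (>= 0).
#' @param n_bins number of bins: 20 (vigintiles), 10 (deciles) or
#'   5 (quintiles).
#' @param cutpoints optionally, previously frozen cutpoints to reuse instead
#'   of recomputing them (length `n_bins - 1`).
#' @return list with `cutpoints` (length `n_bins - 1`, non-decreasing) and
#'   `bins` (integer vector in 1..`n_bins`).
#' @export
#' @examples
#' discretize_prior(c(0, 0, 5, 10, 20), n_bins = 5)
discretize_prior <- function(claims, n_bins, cutpoints = NULL) {
  if (length(claims) == 0) stop("discretize_prior: empty claims vector")
  if (is.null(cutpoints)) {
    if (length(claims) < n_bins)
      stop("discretize_prior: need at least n_bins = ", n_bins,
           " observations to form bins")
    probs <- seq_len(n_bins - 1) / n_bins
    cutpoints <- unname(quantile(claims, probs = probs, type = 1,
                                 names = FALSE))
  }
  stopifnot(length(cutpoints) == n_bins - 1, !is.unsorted(cutpoints))
  bins <- findInterval(claims, cutpoints, left.open = TRUE) + 1L
  list(cutpoints = cutpoints, bins = as.integer(bins))
}

#' Quintile classification of prior healthcare expenses
#'
#' Convenience wrapper around [discretize_prior()] with 5 bins; used as the
#' extra rating factor of the 140-class premium scheme.
#'
#' @inheritParams discretize_prior
#' @return list with `cutpoints` (length 4) and `bins` (1..5).
#' @export
quintile_of_prior <- function(claims, cutpoints = NULL) {
  discretize_prior(claims, n_bins = 5L, cutpoints = cutpoints)
}

PREDICTOR_TERMS <- c("ag_class", "pcg", "dcg", "urbanization", "ethnicity",
                     "bi_vigintile", "shi_decile")

# internal: assemble the model frame for target data year `target_year`
# (outcome) from year target_year - 1 information
prediction_frame <- function(panel, target_year,
                             vigintile_cutpoints = NULL,
                             decile_cutpoints = NULL) {
  nb <- n_base_years(panel)
  if (target_year < 1 || target_year > nb)
    stop("target_year must be in 1..", nb,
         " (a prior data year must exist)")
  prior <- panel[panel$base_year_index == target_year - 1L, ]
  cur <- panel[panel$base_year_index == target_year, ]
  stopifnot(identical(prior$person_id, cur$person_id))
  vig <- discretize_prior(prior$basic_claims, 20L, vigintile_cutpoints)
  dec <- discretize_prior(prior$supp_claims, 10L, decile_cutpoints)
  mf <- data.frame(
    person_id = prior$person_id,
    y = cur$supp_claims,
    ag_class = factor(age_gender_class(prior$age, prior$sex),
                      levels = 1:N_AG_CLASSES),
    pcg = prior$pcg,
    dcg = prior$dcg,
    urbanization = factor(prior$urbanization),
    ethnicity = factor(prior$ethnicity),
    bi_vigintile = factor(vig$bins, levels = 1:20),
    shi_decile = factor(dec$bins, levels = 1:10),
    stringsAsFactors = FALSE
  )
  attr(mf, "vigintile_cutpoints") <- vig$cutpoints
  attr(mf, "decile_cutpoints") <- dec$cutpoints
  mf
}

#' Fit the individual claims prediction model
#'
#' Fits a gamma generalized linear model with log link of year-`t`
#' supplementary claims on year-`t-1` information: 28 age-gender classes,
#' PCG and DCG morbidity flags, urbanization, ethnicity, the vigintile of
#' prior-year basic-insurance expenses and the decile of prior-year
#' supplementary claims. The gamma likelihood has no support at zero;
#' person-years with zero claims enter as `zero_value` (EUR 0.01 by
#' default), the simplest faithful treatment of a point mass at zero under
#' this family.
#'
#' Discretization cutpoints are computed on the full panel population of the
#' prior year and frozen inside the returned predictor, so an individual's
#' risk signal does not depend on who else is enrolled.
#'
#' @param panel an `insured_panel`.
#' @param target_year data-year index of the outcome (1..`n_base_years`);
#'   prior-year information comes from `target_year - 1`.
#' @param terms character vector of design terms to include; defaults to the
#'   full layout. Restricting terms (e.g. dropping the prior-claims bins) is
#'   useful for covariate-effect recovery studies.
#' @param zero_value positive value substituted for zero claims.
#' @param maxit IRLS iteration cap.
#' @return an object of class `claims_predictor` carrying coefficients, the
#'   factor levels observed at fit time, frozen cutpoints, the fitted year,
#'   dispersion and a convergence flag.
#' @export
fit_claims_glm <- function(panel, target_year,
                           terms = PREDICTOR_TERMS,
                           zero_value = 0.01,
                           maxit = 100) {
  stopifnot(inherits(panel, "insured_panel"))
  terms <- match.arg(terms, PREDICTOR_TERMS, several.ok = TRUE)
  mf <- prediction_frame(panel, target_year)
  mf$y <- pmax(mf$y, zero_value)
  # drop factor levels with no observations; record them so prediction can
  # fall back to the reference level with a warning
  dropped <- list()
  for (tm in intersect(terms, c("ag_class", "urbanization", "ethnicity",
                                "bi_vigintile", "shi_decile"))) {
    empty <- setdiff(levels(mf[[tm]]), unique(as.character(mf[[tm]])))
    if (length(empty)) {
      dropped[[tm]] <- empty
      warning(sprintf("term '%s': empty cells for level(s) %s dropped",
                      tm, paste(empty, collapse = ", ")), call. = FALSE)
    }
    mf[[tm]] <- droplevels(mf[[tm]])
  }
  # factors collapsing to a single level (or constant logicals) carry no
  # information and cannot enter the design; record and drop them
  constant <- vapply(terms, function(tm) {
    v <- mf[[tm]]
    if (is.factor(v)) nlevels(v) < 2 else length(unique(v)) < 2
  }, logical(1))
  if (any(constant))
    warning("constant term(s) dropped from the design: ",
            paste(terms[constant], collapse = ", "), call. = FALSE)
  active <- terms[!constant]
  form <- if (length(active))
    stats::as.formula(paste("~", paste(active, collapse = " + ")))
  else ~1
  X <- model.matrix(form, mf)
  fit <- gamma_log_irls(X, mf$y, maxit = maxit)
  if (!fit$converged)
    stop(sprintf(
      "gamma GLM did not converge within %d iterations (last deviance %.6g)",
      maxit, fit$deviance))
  xlevels <- lapply(mf[intersect(terms, c("ag_class", "urbanization",
                                          "ethnicity", "bi_vigintile",
                                          "shi_decile"))], levels)
  structure(list(
    coefficients = fit$coefficients,
    terms = active,
    requested_terms = terms,
    xlevels = xlevels,
    dropped_levels = dropped,
    vigintile_cutpoints = attr(mf, "vigintile_cutpoints"),
    decile_cutpoints = attr(mf, "decile_cutpoints"),
    fitted_year = as.integer(target_year),
    dispersion = fit$dispersion,
    converged = fit$converged,
    zero_value = zero_value,
    null_deviance = fit$null_deviance,
    deviance = fit$deviance
  ), class = "claims_predictor")
}

# internal: maximum-likelihood fit of a gamma GLM with log link by iterative
# reweighted least squares with step halving on any deviance increase.
# stats::glm's IRLS only halves the step when the deviance becomes
# non-finite, which lets it oscillate and fail on responses spanning six
# orders of magnitude (EUR 0.01 .. 35,000); damping on every increase makes
# the iteration globally stable. Cross-checked against stats::glm in the
# test suite on well-conditioned data.
gamma_log_irls <- function(X, y, maxit = 100, tol = 1e-10) {
  stopifnot(all(y > 0))
  n <- nrow(X); p <- ncol(X)
  dev_fun <- function(mu) 2 * sum(-log(y / mu) + (y - mu) / mu)
  # start at the Gaussian fit on log(y); aliased columns pinned to zero
  ls0 <- stats::lm.fit(X, log(y))
  aliased <- is.na(ls0$coefficients)
  beta <- ifelse(aliased, 0, ls0$coefficients)
  Xw <- X[, !aliased, drop = FALSE]
  bw <- beta[!aliased]
  eta <- drop(Xw %*% bw)
  mu <- exp(eta)
  dev <- dev_fun(mu)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    z <- eta + (y - mu) / mu       # working response; weights are 1
    bls <- stats::lm.fit(Xw, z)$coefficients
    bls[is.na(bls)] <- bw[is.na(bls)]
    lambda <- 1
    repeat {
      bnew <- bw + lambda * (bls - bw)
      eta_new <- drop(Xw %*% bnew)
      mu_new <- exp(eta_new)
      dev_new <- dev_fun(mu_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-8 * (abs(dev) + 0.1))
        break
      lambda <- lambda / 2
      if (lambda < 1e-12) { dev_new <- dev; bnew <- bw
        eta_new <- eta; mu_new <- mu; break }
    }
    done <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    bw <- bnew; eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (done) { converged <- TRUE; break }
  }
  coefficients <- rep(NA_real_, p)
  names(coefficients) <- colnames(X)
  coefficients[!aliased] <- bw
  mu0 <- mean(y)
  list(coefficients = coefficients,
       converged = converged,
       deviance = dev,
       null_deviance = dev_fun(rep(mu0, n)),
       dispersion = sum(((y - mu) / mu)^2) / (n - sum(!aliased)))
}

#' @export
print.claims_predictor <- function(x, ...) {
  cat("<claims_predictor> gamma GLM (log link)\n")
  cat(sprintf("  target data year %d, %d coefficients, dispersion %.3f\n",
              x$fitted_year, length(x$coefficients), x$dispersion))
  cat(sprintf("  deviance %.1f (null %.1f)\n", x$deviance, x$null_deviance))
  invisible(x)
}

# internal: design matrix for new prior-year data under a fitted layout
predictor_design <- function(model, newdata) {
  if (!length(model$terms))
    return(matrix(1, nrow(newdata), 1,
                  dimnames = list(NULL, "(Intercept)")))
  vig <- discretize_prior(newdata$basic_claims, 20L,
                          model$vigintile_cutpoints)
  dec <- discretize_prior(newdata$supp_claims, 10L,
                          model$decile_cutpoints)
  raw <- list(
    ag_class = as.character(age_gender_class(newdata$age, newdata$sex)),
    pcg = newdata$pcg,
    dcg = newdata$dcg,
    urbanization = as.character(newdata$urbanization),
    ethnicity = as.character(newdata$ethnicity),
    bi_vigintile = as.character(vig$bins),
    shi_decile = as.character(dec$bins)
  )
  mf <- data.frame(row.names = seq_len(nrow(newdata)))
  for (tm in model$terms) {
    v <- raw[[tm]]
    if (is.character(v)) {
      lev <- model$xlevels[[tm]]
      unseen <- !(v %in% lev)
      if (any(unseen)) {
        warning(sprintf(
          "term '%s': %d record(s) in unseen level(s) mapped to reference",
          tm, sum(unseen)), call. = FALSE)
        v[unseen] <- lev[1]
      }
      mf[[tm]] <- factor(v, levels = lev)
    } else {
      mf[[tm]] <- v
    }
  }
  form <- stats::as.formula(paste("~", paste(model$terms, collapse = " + ")))
  model.matrix(form, data = mf)
}

#' Predict individual supplementary claims
#'
#' Applies a fitted [fit_claims_glm()] model to prior-year records and
#' returns `exp(linear predictor)`, the expected supplementary claims for
#' the following year. Predictions are strictly positive and finite for
#' every insured. Records in factor levels unseen at fit time fall back to
#' the reference level with a warning.
#'
#' @param model a `claims_predictor`.
#' @param newdata data.frame of prior-year records with columns `age`,
#'   `sex`, `ethnicity`, `urbanization`, `pcg`, `dcg`, `basic_claims`,
#'   `supp_claims`.
#' @return numeric vector of predicted claims (EUR).
#' @export
predict_claims <- function(model, newdata) {
  stopifnot(inherits(model, "claims_predictor"))
  X <- predictor_design(model, newdata)
  beta <- model$coefficients
  keep <- !is.na(beta)
  eta <- as.numeric(X[, names(beta)[keep], drop = FALSE] %*% beta[keep])
  out <- exp(eta)
  stopifnot(all(is.finite(out)), all(out > 0))
  out
}

#' Fit claims predictors for every cycle year
#'
#' Fits one gamma GLM per cycle year (data years `1..n_base_years`), each on
#' the full baseline population, as used by the market simulation. The
#' models are fitted once and reused across simulation loop cycles: the
#' prediction represents the insured's own expectation, which exists whether
#' or not they currently hold the policy.
#'
#' @inheritParams fit_claims_glm
#' @return list of `claims_predictor`, one per cycle year.
#' @export
fit_all_predictors <- function(panel, terms = PREDICTOR_TERMS,
                               zero_value = 0.01) {
  nb <- n_base_years(panel)
  lapply(seq_len(nb), function(ty)
    fit_claims_glm(panel, ty, terms = terms, zero_value = zero_value))
}

#' Serialize a claims predictor to JSON and back
#'
#' @param model a `claims_predictor`.
#' @param path JSON file path.
#' @return `write_predictor()` returns `path` invisibly; `read_predictor()`
#'   returns a `claims_predictor`.
#' @export
write_predictor <- function(model, path) {
  stopifnot(inherits(model, "claims_predictor"))
  obj <- unclass(model)
  obj$coefficients <- as.list(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$fitted_year <- as.integer(obj$fitted_year)
  obj$xlevels <- lapply(obj$xlevels, as.character)
  if (length(obj$dropped_levels) == 0) obj$dropped_levels <- list()
  structure(obj, class = "claims_predictor")
}
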