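RATING_SCHEMES <- c("community", "age_gender_28", "age_gender_quintile_140",
                    "individual")

#' Set premiums for the next year from the current insured pool
#'
#' Computes the premium schedule for year `t + 1` as the fitted group mean of
#' year-`t` supplementary claims in the insured pool, times `1 + loading`.
#' The group structure depends on the rating scheme:
#'
#' * `community` - a single rate: pool mean claims times `1 + loading`.
#' * `age_gender_28` - one rate per age-gender class, from a saturated OLS
#'   of year-`t` claims on age-gender dummies; a saturated dummy OLS is
#'   algebraically the per-cell mean, which is how it is computed.
#' * `age_gender_quintile_140` - one rate per age-gender class crossed with
#'   the quintile of prior (year `t - 1`) expenses, again as saturated OLS
#'   cell means.
#' * `individual` - each person's premium is their own predicted claims
#'   times `1 + loading`; the schedule carries no table and rates are
#'   supplied at lookup time via the `predicted` argument of
#'   [premium_for()].
#'
#' Cells that are empty in the (possibly shrunken) pool fall back to the
#' enclosing age-gender rate, and failing that to the community rate, with a
#' warning.
#'
#' @param pool data.frame of the year-`t` insured pool with columns
#'   `supp_claims` (year-`t` claims), `ag_class` (1..28, see
#'   [age_gender_class()]) and, for the 140-class scheme, `quintile`
#'   (1..5, the quintile of year `t - 1` expenses used to fit the OLS).
#' @param scheme one of `"community"`, `"age_gender_28"`,
#'   `"age_gender_quintile_140"`, `"individual"`.
#' @param loading proportional loading fee (default 0.23).
#' @return an object of class `premium_schedule` with elements `scheme`,
#'   `loading`, `rates` (length 1, 28 or 140; `NULL` for individual rating),
#'   `fallback_rate` (the community rate) and `filled` (which cells were
#'   fallback-filled).
#' @export
#' @examples
#' pool <- data.frame(supp_claims = c(100, 300), ag_class = c(1, 2),
#'                    quintile = c(1, 1))
#' set_premiums(pool, "age_gender_28", loading = 0.23)$rates[1:2]
set_premiums <- function(pool, scheme = RATING_SCHEMES, loading = 0.23) {
  scheme <- match.arg(scheme)
  if (is.null(pool) || nrow(pool) == 0)
    stop("set_premiums: empty insured pool")
  if (loading < 0) stop("set_premiums: loading must be >= 0")
  y <- pool$supp_claims
  community_rate <- mean(y) * (1 + loading)
  rates <- NULL
  filled <- logical(0)
  if (scheme == "age_gender_28") {
    cell <- factor(pool$ag_class, levels = 1:N_AG_CLASSES)
    means <- tapply(y, cell, mean)
    rates <- as.numeric(means) * (1 + loading)
    filled <- is.na(rates)
    if (any(filled)) {
      warning(sprintf("%d empty age-gender cell(s) filled with community rate",
                      sum(filled)), call. = FALSE)
      rates[filled] <- community_rate
    }
  } else if (scheme == "age_gender_quintile_140") {
    cell <- factor((pool$ag_class - 1L) * 5L + pool$quintile,
                   levels = 1:(N_AG_CLASSES * 5L))
    means <- tapply(y, cell, mean)
    rates <- as.numeric(means) * (1 + loading)
    ag_cell <- factor(pool$ag_class, levels = 1:N_AG_CLASSES)
    ag_rates <- as.numeric(tapply(y, ag_cell, mean)) * (1 + loading)
    filled <- is.na(rates)
    if (any(filled)) {
      warning(sprintf(
        "%d empty age-gender-quintile cell(s) filled from fallback chain",
        sum(filled)), call. = FALSE)
      ag_of_cell <- rep(1:N_AG_CLASSES, each = 5L)
      fb <- ag_rates[ag_of_cell[filled]]
      fb[is.na(fb)] <- community_rate
      rates[filled] <- fb
    }
  } else if (scheme == "community") {
    rates <- community_rate
  }
  if (!is.null(rates)) rates <- pmax(rates, 0)
  structure(list(
    scheme = scheme,
    loading = loading,
    rates = rates,
    fallback_rate = max(community_rate, 0),
    filled = filled,
    n_pool = nrow(pool)
  ), class = "premium_schedule")
}

#' @export
print.premium_schedule <- function(x, ...) {
  cat(sprintf("<premium_schedule> scheme %s, loading %.0f%%, pool n = %d\n",
              x$scheme, 100 * x$loading, x$n_pool))
  if (!is.null(x$rates))
    cat(sprintf("  %d rate(s), range EUR %.2f - %.2f\n", length(x$rates),
                min(x$rates), max(x$rates)))
  invisible(x)
}

#' Premium charged to an insured under a schedule
#'
#' Looks up the rate of each record's risk group. Per the market rules, the
#' lookup uses the record's *current* year-`t` age-gender class and
#' quintile, while the schedule itself was fitted on year `t - 1` groups.
#'
#' @param schedule a [set_premiums()] schedule.
#' @param ag_class integer vector of current age-gender classes (1..28).
#' @param quintile integer vector of current expense quintiles (1..5);
#'   required for the 140-class scheme.
#' @param predicted numeric vector of individual predicted claims; required
#'   for the individual scheme.
#' @return numeric vector of premiums (EUR).
#' @export
premium_for <- function(schedule, ag_class, quintile = NULL,
                        predicted = NULL) {
  stopifnot(inherits(schedule, "premium_schedule"))
  switch(schedule$scheme,
    community = rep(schedule$rates, length(ag_class)),
    age_gender_28 = schedule$rates[ag_class],
    age_gender_quintile_140 = {
      if (is.null(quintile))
        stop("premium_for: quintile required for the 140-class scheme")
      schedule$rates[(ag_class - 1L) * 5L + quintile]
    },
    individual = {
      if (is.null(predicted))
        stop("premium_for: predicted claims required for individual rating")
      pmax(predicted * (1 + schedule$loading), 0)
    }
  )
}

#' Serialize a premium schedule to CSV
#'
#' Writes one row per risk group (`group_key`, `rate`); the individual
#' scheme has no group table and writes only the loading.
#'
#' @param schedule a `premium_schedule`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_premium_schedule <- function(schedule, path) {
  if (is.null(schedule$rates)) {
    df <- data.frame(group_key = "individual_x_loading",
                     rate = 1 + schedule$loading)
  } else {
    df <- data.frame(group_key = seq_along(schedule$rates),
                     rate = schedule$rates)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
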