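#' Pratt risk premium
#'
#' The amount above expected claims a risk-averse insured is willing to pay
#' for coverage, computed from the Pratt approximation as half the variance
#' of the insured loss times the absolute risk-aversion coefficient:
#' `RP = 0.5 * variance * r`.
#'
#' With the claims variances observed in the study period (24,596 and
#' 28,703 EUR^2) and published risk-aversion coefficients between 0.00094
#' and 0.0067 per EUR, this brackets the risk premium between roughly EUR 12
#' and EUR 96; the market simulation operates with a fixed EUR 100.
#'
#' @param variance variance of the insured claims (EUR^2), >= 0.
#' @param r Pratt absolute risk-aversion coefficient (1/EUR), >= 0.
#' @return risk premium in EUR (unrounded; round only for reporting).
#' @export
#' @examples
#' round(risk_premium(24596, 0.00094))  # lower bound
#' round(risk_premium(28703, 0.0067))   # upper bound
risk_premium <- function(variance, r) {
  if (any(variance < 0)) stop("risk_premium: variance must be >= 0")
  if (any(r < 0)) stop("risk_premium: r must be >= 0")
  0.5 * variance * r
}

#' Is holding the policy expected to be financially beneficial?
#'
#' A risk-averse insured keeps (or takes up) the policy when predicted
#' claims plus the risk premium reach the premium of their risk group:
#' `predicted + rp >= premium`. Exact ties count as beneficial, mirroring
#' the risk-neutral rule that a policy is purchased when predicted claims
#' equal or exceed the premium; set `ties_beneficial = FALSE` to flip the
#' tie rule.
#'
#' @param predicted predicted claims (EUR), >= 0.
#' @param premium premium charged (EUR), >= 0.
#' @param rp risk premium (EUR), >= 0.
#' @param ties_beneficial logical; whether exact ties count as beneficial.
#' @return logical vector.
#' @export
#' @examples
#' is_beneficial(500, 500, 0)    # TRUE: risk-neutral tie
#' is_beneficial(390, 500, 100)  # FALSE: 490 < 500
is_beneficial <- function(predicted, premium, rp,
                          ties_beneficial = TRUE) {
  if (any(predicted < 0) || any(premium < 0) || any(rp < 0))
    stop("is_beneficial: all arguments must be >= 0")
  if (ties_beneficial) predicted + rp >= premium else predicted + rp > premium
}
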