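# Analytic power of a two-sample MR test for a continuous outcome.

#' Power of a two-sample MR test (continuous outcome)
#'
#' Normal-approximation power for detecting a causal effect `beta` (SD of
#' outcome per SD of exposure) with an instrument explaining a fraction
#' `r2_exposure` of the exposure variance, in an outcome GWAS of
#' `n_outcome` individuals, at two-sided significance level `alpha`.  The
#' test statistic is approximately normal with unit variance and
#' non-centrality `sqrt(NCP)` where
#' `NCP = n_outcome * r2_exposure * beta^2`, giving
#' `power = 1 - Phi(z - sqrt(NCP)) + Phi(-z - sqrt(NCP))` with
#' `z = qnorm(1 - alpha/2)`.  At `beta = 0` the power equals `alpha`
#' exactly (the size of the test).
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param r2_exposure Fraction of exposure variance explained by the
#'   instrument, in (0, 1).
#' @param beta Hypothesized causal effect (SD/SD); vectorized.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(n_outcome, r2_exposure, beta, alpha = 0.05) {
  if (n_outcome <= 0) stop("n_outcome must be positive")
  if (r2_exposure <= 0 || r2_exposure >= 1) {
    stop("r2_exposure must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ncp <- sqrt(n_outcome * r2_exposure * beta^2)
  zq <- qnorm(1 - alpha / 2)
  # at ncp = 0 the closed form collapses to the size of the test
  ifelse(ncp == 0, alpha, 1 - pnorm(zq - ncp) + pnorm(-zq - ncp))
}
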