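# Two-step network MR: exposure -> mediator (step 1) and mediator ->
# outcome (step 2), combined into a product-of-coefficients indirect
# effect with the Sobel standard error.

#' Two-step network MR mediation with the Sobel test
#'
#' Given an MR estimate `a` of the exposure on the mediator (step 1) and
#' `b` of the mediator on the outcome (step 2), the indirect effect of the
#' exposure on the outcome through the mediator is `a * b`.  Its
#' first-order Sobel standard error is
#' `sqrt(a^2 * se_b^2 + b^2 * se_a^2)`; `exact_se = TRUE` adds the
#' second-order `se_a^2 * se_b^2` term.  Significance is a two-sided
#' normal test of `z = indirect / se_indirect`.
#'
#' When a total-effect estimate of the exposure on the outcome is
#' supplied, the proportion mediated `indirect / total` is reported, but
#' only when `|total|` exceeds its standard error, to avoid unstable
#' ratios.
#'
#' @param step1 `mr_estimate` of the exposure on the mediator.
#' @param step2 `mr_estimate` of the mediator on the outcome; its
#'   `exposure_id` must equal `step1$outcome_id`.
#' @param exact_se Include the product-of-variances term in the Sobel SE.
#' @param total Optional `mr_estimate` of the total exposure-on-outcome
#'   effect.
#' @return One-row data.frame of class `mediation_result` with columns
#'   `exposure_id, mediator_id, outcome_id, a, se_a, b, se_b, indirect,
#'   se_indirect, z, pval, prop_mediated`.
#' @export
two_step_mediation <- function(step1, step2, exact_se = FALSE, total = NULL) {
  if (!identical(step1$outcome_id, step2$exposure_id)) {
    stop(sprintf(
      "mediator mismatch: step 1 outcome is '%s' but step 2 exposure is '%s'",
      step1$outcome_id, step2$exposure_id))
  }
  a <- step1$beta; se_a <- step1$se
  b <- step2$beta; se_b <- step2$se
  indirect <- a * b
  v <- a^2 * se_b^2 + b^2 * se_a^2
  if (exact_se) v <- v + se_a^2 * se_b^2
  se_ind <- sqrt(v)
  z <- if (se_ind > 0) indirect / se_ind else 0
  prop <- NA_real_
  if (!is.null(total) && abs(total$beta) > total$se) {
    prop <- indirect / total$beta
  }
  out <- data.frame(
    exposure_id = step1$exposure_id, mediator_id = step1$outcome_id,
    outcome_id = step2$outcome_id,
    a = a, se_a = se_a, b = b, se_b = se_b,
    indirect = indirect, se_indirect = se_ind, z = z,
    pval = 2 * pnorm(-abs(z)), prop_mediated = prop,
    stringsAsFactors = FALSE)
  class(out) <- c("mediation_result", "data.frame")
  out
}
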