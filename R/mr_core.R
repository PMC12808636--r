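# Causal-effect estimators on harmonized summary data, and FDR control.
#
# All estimators report a point estimate with a normal-theory standard
# error, a symmetric 95% CI (beta +/- 1.959964 * se) and a two-sided normal
# p-value.  Two-sided normal rather than t reference is used throughout:
# at GWAS sample sizes the distinction is negligible and the choice keeps
# results exactly reproducible.

new_mr_estimate <- function(exposure_id, outcome_id, method, beta, se, n_snp,
                            egger_intercept = NA_real_,
                            egger_intercept_pval = NA_real_,
                            model = NA_character_) {
  z <- if (se > 0) beta / se else if (beta == 0) 0 else sign(beta) * Inf
  out <- data.frame(
    exposure_id = exposure_id, outcome_id = outcome_id, method = method,
    beta = beta, se = se,
    ci_low = beta - .Z95 * se, ci_high = beta + .Z95 * se,
    pval = 2 * pnorm(-abs(z)), n_snp = as.integer(n_snp),
    egger_intercept = egger_intercept,
    egger_intercept_pval = egger_intercept_pval,
    model = model, stringsAsFactors = FALSE)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

.as_pair <- function(pair) {
  if (inherits(pair, "harmonized_dataset")) {
    p <- mr_pairs(pair)
    if (nrow(p) != 1) {
      stop("wald_ratio needs exactly one non-excluded variant; got ",
           nrow(p), " (use mr_ivw for multiple instruments)")
    }
    attr(p, "exposure_id") <- pair$exposure_id
    attr(p, "outcome_id") <- pair$outcome_id
    p
  } else {
    as.data.frame(pair)
  }
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect of the exposure on the outcome is
#' `beta_y / beta_x`.  The default first-order (delta-method) standard
#' error is `se_y / |beta_x|`; the second-order form additionally
#' propagates the exposure uncertainty:
#' `sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#'
#' @param pair A one-row data.frame with `beta_x, se_x, beta_y, se_y`
#'   (e.g. a row of [mr_pairs()]), or a [harmonized_dataset] with exactly
#'   one non-excluded variant.
#' @param se_order `"first"` (default) or `"second"`.
#' @param exposure_id,outcome_id Trait labels for the report (taken from
#'   the dataset when one is supplied).
#' @return A one-row `mr_estimate` data.frame.
#' @export
wald_ratio <- function(pair, se_order = c("first", "second"),
                       exposure_id = "exposure", outcome_id = "outcome") {
  se_order <- match.arg(se_order)
  p <- .as_pair(pair)
  exposure_id <- attr(p, "exposure_id") %||% exposure_id
  outcome_id <- attr(p, "outcome_id") %||% outcome_id
  if (isTRUE(p$excluded)) stop("cannot estimate from an excluded pair")
  if (p$beta_x == 0) {
    stop("exposure effect is zero for instrument '", p$rsid %||% "?",
         "': Wald ratio undefined")
  }
  beta <- p$beta_y / p$beta_x
  se <- if (se_order == "first") {
    p$se_y / abs(p$beta_x)
  } else {
    sqrt(p$se_y^2 / p$beta_x^2 + p$beta_y^2 * p$se_x^2 / p$beta_x^4)
  }
  new_mr_estimate(exposure_id, outcome_id, "wald", beta, se, 1L,
                  model = se_order)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_y^2`.  The fixed-effect standard error is
#' `sqrt(1 / sum(w * beta_x^2))`; the multiplicative random-effects model
#' inflates it by `sqrt(max(1, Q / (n_snp - 1)))` where `Q` is Cochran's
#' heterogeneity statistic, so dispersion never deflates the SE.  With
#' `model = "auto"` (default) the fixed model is used below 4 instruments
#' and random effects otherwise.  A single instrument reduces exactly to
#' the first-order Wald ratio.
#'
#' @param data A [harmonized_dataset].
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return A one-row `mr_estimate` data.frame (`model` column records the
#'   model actually applied).
#' @export
mr_ivw <- function(data, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  p <- mr_pairs(data)
  n <- nrow(p)
  if (n < 1) stop("IVW requires at least one non-excluded variant")
  if (n == 1) {
    # degenerate case: identical to the first-order Wald ratio
    return(new_mr_estimate(data$exposure_id, data$outcome_id, "ivw",
                           p$beta_y / p$beta_x, p$se_y / abs(p$beta_x), 1L,
                           model = "fixed"))
  }
  w <- 1 / p$se_y^2
  sxx <- sum(w * p$beta_x^2)
  beta <- sum(w * p$beta_x * p$beta_y) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (p$beta_y - beta * p$beta_x)^2)
  phi <- q / (n - 1)
  if (model == "auto") model <- if (n < 4) "fixed" else "random"
  se <- if (model == "random") se_fixed * sqrt(max(1, phi)) else se_fixed
  new_mr_estimate(data$exposure_id, data$outcome_id, "ivw", beta, se, n,
                  model = model)
}

# Weighted least squares of y on x with intercept; returns fixed
# (dispersion = 1) covariance terms and the residual dispersion.
.wls_line <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  den <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / den
  intercept <- (swxx * swy - swx * swxy) / den
  rss <- sum(w * (y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept,
       se_slope_fixed = sqrt(sw / den),
       se_intercept_fixed = sqrt(swxx / den),
       sigma2 = rss / (length(x) - 2))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an intercept
#' (weights `1/se_y^2`), after orienting all exposure effects positive.
#' The slope is the causal estimate; a non-zero intercept signals
#' directional horizontal pleiotropy and its two-sided normal p-value is
#' reported as the pleiotropy test.  Standard errors are scaled by
#' `max(1, sigma)` so that residual under-dispersion never shrinks them
#' below the fixed-effect value.
#'
#' @param data A [harmonized_dataset] with at least 3 usable variants.
#' @return A one-row `mr_estimate` data.frame with `egger_intercept` and
#'   `egger_intercept_pval` filled in.
#' @export
mr_egger <- function(data) {
  p <- mr_pairs(data)
  n <- nrow(p)
  if (n < 3) stop("MR-Egger requires at least 3 instruments; got ", n)
  sgn <- ifelse(p$beta_x < 0, -1, 1)
  bx <- p$beta_x * sgn
  by <- p$beta_y * sgn
  w <- 1 / p$se_y^2
  fit <- .wls_line(bx, by, w)
  scale <- sqrt(max(1, fit$sigma2))
  se_slope <- fit$se_slope_fixed * scale
  se_int <- fit$se_intercept_fixed * scale
  int_p <- 2 * pnorm(-abs(fit$intercept / se_int))
  new_mr_estimate(data$exposure_id, data$outcome_id, "egger",
                  fit$slope, se_slope, n,
                  egger_intercept = fit$intercept,
                  egger_intercept_pval = int_p)
}

# Weight-interpolated 50th percentile of ratio estimates (Bowden et al.
# style): cumulative standardized weights, linear interpolation at 0.5.
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  k <- max(which(cw < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

.ratio_weights <- function(p) {
  ratio <- p$beta_y / p$beta_x
  se_ratio <- p$se_y / abs(p$beta_x)
  list(ratio = ratio, w = 1 / se_ratio^2)
}

# Parametric bootstrap SE shared by the median and mode estimators:
# redraw (beta_x, beta_y) from their sampling distributions and recompute.
.boot_se <- function(p, estimator, n_boot, seed) {
  n <- nrow(p)
  withr::with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(n, p$beta_x, p$se_x)
      by <- rnorm(n, p$beta_y, p$se_y)
      bx[bx == 0] <- .Machine$double.eps
      estimator(by / bx, bx^2 / p$se_y^2)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance
#' weight-interpolated 50th percentile; consistent when at least half the
#' weight comes from valid instruments.  The standard error is a
#' parametric bootstrap with a fixed seed.
#'
#' @param data A [harmonized_dataset] with at least 3 usable variants.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Bootstrap seed (default 1234).
#' @return A one-row `mr_estimate` data.frame.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1234) {
  p <- mr_pairs(data)
  if (nrow(p) < 3) {
    stop("weighted median requires at least 3 instruments; got ", nrow(p))
  }
  rw <- .ratio_weights(p)
  beta <- .weighted_median(rw$ratio, rw$w)
  se <- .boot_se(p, .weighted_median, n_boot, seed)
  new_mr_estimate(data$exposure_id, data$outcome_id, "weighted_median",
                  beta, se, nrow(p))
}

# Mode of the weighted kernel-smoothed density of ratio estimates
# (Hartwig et al. style).  Bandwidth: phi * 0.9 * min(sd, mad) * n^(-1/5),
# falling back to the SD when the MAD degenerates to zero (e.g. exactly
# bimodal ratios); all-equal ratios return that common value.
.weighted_mode <- function(r, w, phi = 1) {
  s_sd <- sd(r)
  if (!is.finite(s_sd) || s_sd == 0) return(r[1])
  s_mad <- mad(r)
  s <- 0.9 * min(s_sd, if (s_mad > 0) s_mad else s_sd) * length(r)^(-1 / 5)
  h <- phi * s
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- as.vector(outer(grid, r, function(g, ri) dnorm(g - ri, sd = h)) %*% w)
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance-weighted normal-kernel density of the
#' per-SNP Wald ratios; consistent when the largest group of instruments
#' sharing the same ratio is valid (plurality rule).  Standard error by
#' parametric bootstrap with a fixed seed.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the MAD-based default kernel
#'   bandwidth (default 1).
#' @return A one-row `mr_estimate` data.frame.
#' @export
mr_weighted_mode <- function(data, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1234) {
  p <- mr_pairs(data)
  if (nrow(p) < 3) {
    stop("weighted mode requires at least 3 instruments; got ", nrow(p))
  }
  rw <- .ratio_weights(p)
  beta <- .weighted_mode(rw$ratio, rw$w, bandwidth_factor)
  se <- .boot_se(p, function(r, w) .weighted_mode(r, w, bandwidth_factor),
                 n_boot, seed)
  new_mr_estimate(data$exposure_id, data$outcome_id, "weighted_mode",
                  beta, se, nrow(p))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) with rejection at
#' adjusted `p <= q`.
#'
#' @param pvals Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (monotone step-up adjusted p-values) and
#'   `reject` (logical flags).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  adjusted <- p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Reconstruct a normal Wald confidence interval from a beta and p-value
#'
#' Inverts the two-sided normal test to recover the implied standard error
#' `|beta| / qnorm(1 - pval/2)` and returns the symmetric
#' `level` confidence interval.  Useful for checking the internal
#' consistency of published estimate/CI/p triplets.
#'
#' @param beta Point estimate (non-zero).
#' @param pval Two-sided normal p-value in (0, 1).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(se, ci_low, ci_high)`.
#' @export
normal_ci_from_beta_p <- function(beta, pval, level = 0.95) {
  if (beta == 0) stop("beta must be non-zero to recover a standard error")
  if (pval <= 0 || pval >= 1) stop("pval must lie strictly in (0, 1)")
  se <- abs(beta) / qnorm(1 - pval / 2)
  zq <- qnorm(1 - (1 - level) / 2)
  c(se = se, ci_low = beta - zq * se, ci_high = beta + zq * se)
}

#' Bind MR estimates into a single results table
#'
#' @param estimates List of `mr_estimate` rows.
#' @return data.frame with one row per estimate.
#' @export
mr_results_table <- function(estimates) {
  out <- do.call(rbind, lapply(estimates, as.data.frame))
  rownames(out) <- NULL
  out
}
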