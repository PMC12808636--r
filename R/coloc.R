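# Bayesian colocalization of two traits in a cis region via per-SNP
# Wakefield approximate Bayes factors, under the single-causal-variant
# assumption (hypotheses H0-H4).

#' Colocalization configuration
#'
#' Priors and thresholds for the approximate-Bayes-factor colocalization.
#' `p1`/`p2` are the per-SNP prior probabilities that a variant is causal
#' for trait 1 / trait 2 only, `p12` the prior that one variant is causal
#' for both.  `W1`/`W2` are the prior variances of the (standardized)
#' effect sizes; 0.15^2 is the conventional quantitative-trait default.
#'
#' @param p1,p2 Per-SNP priors for a trait-specific causal variant
#'   (default 1e-4 each).
#' @param p12 Per-SNP prior for a shared causal variant (default 1e-5);
#'   must satisfy `0 <= p12 <= min(p1, p2)` (zero disables H4).
#' @param W1,W2 Prior effect variances (default `0.15^2`).
#' @param maf_min Variants with minor allele frequency below this are
#'   excluded from the region (default 0.01).
#' @param window Region half-width around the lead variant in bp
#'   (default 1e6).
#' @param h4_threshold Posterior probability above which colocalization
#'   (or, for H3, distinct causal variants) is called (default 0.75).
#' @return List of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         W1 = 0.15^2, W2 = 0.15^2,
                         maf_min = 0.01, window = 1e6,
                         h4_threshold = 0.75) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("p1 and p2 must lie in (0, 1)")
  }
  if (p12 < 0 || p12 > min(p1, p2)) {
    stop("p12 must satisfy 0 <= p12 <= min(p1, p2)")
  }
  if (W1 <= 0 || W2 <= 0) stop("prior effect variances must be positive")
  structure(list(p1 = p1, p2 = p2, p12 = p12, W1 = W1, W2 = W2,
                 maf_min = maf_min, window = window,
                 h4_threshold = h4_threshold),
            class = "coloc_config")
}

#' Wakefield log approximate Bayes factor for one association
#'
#' For an estimate `beta` with standard error `se` and a normal effect
#' prior with variance `W`, the log-ABF in favour of association is
#' `0.5 * log(V / (V + W)) + 0.5 * z^2 * W / (V + W)` with `V = se^2` and
#' `z = beta / se`.
#'
#' @param beta,se Effect estimate and standard error (vectorized).
#' @param W Prior effect variance.
#' @return Numeric vector of log-ABFs.
#' @export
log_abf <- function(beta, se, W) {
  if (any(se <= 0)) stop("se must be positive")
  if (W < 0) stop("prior variance W must be non-negative")
  v <- se^2
  z2 <- (beta / se)^2
  r <- W / (v + W)
  0.5 * log1p(-r) + 0.5 * z2 * r
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Combines per-SNP log-ABFs for two traits over the same variants into
#' posterior probabilities of: H0 no association with either trait; H1/H2
#' association with trait 1 / trait 2 only; H3 both traits, two distinct
#' causal variants; H4 both traits, one shared causal variant.
#' Accumulation is in log space with log-sum-exp throughout, so arbitrarily
#' strong signals cannot overflow.
#'
#' @param labf1,labf2 Equal-length vectors of per-SNP log-ABFs for the two
#'   traits (same variants, same order).
#' @param cfg A [coloc_config()].
#' @return Object of class `coloc_result`: list with `pp` (named vector
#'   `PP.H0`..`PP.H4` summing to 1), `n_snps`, `labf1`, `labf2` and
#'   `verdict` (see [call_colocalization()]).
#' @export
coloc_posteriors <- function(labf1, labf2, cfg = coloc_config()) {
  if (length(labf1) != length(labf2)) {
    stop("labf1 and labf2 must have the same length")
  }
  m <- length(labf1)
  if (!m) stop("empty region")
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  lw <- c(h0 = 0,
          h1 = log(cfg$p1) + l1,
          h2 = log(cfg$p2) + l2,
          h3 = -Inf,
          h4 = if (cfg$p12 > 0) log(cfg$p12) + l12 else -Inf)
  if (m > 1) {
    # sum over ordered pairs of distinct SNPs: S1*S2 - S12, in log space
    d <- l12 - (l1 + l2)          # <= 0 up to rounding
    if (d < -1e-15) {
      lw["h3"] <- log(cfg$p1) + log(cfg$p2) + l1 + l2 + log1p(-exp(d))
    }
  }
  mx <- max(lw)
  pp <- exp(lw - mx)
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.H", 0:4)
  res <- structure(list(pp = pp, n_snps = m, labf1 = labf1, labf2 = labf2,
                        verdict = NA_character_),
                   class = "coloc_result")
  res$verdict <- call_colocalization(res, cfg)
  res
}

#' Call a colocalization verdict from posterior probabilities
#'
#' `"colocalized"` when `PP.H4` exceeds the threshold, `"distinct"` when
#' `PP.H3` exceeds it, `"underpowered"` otherwise.
#'
#' @param result A `coloc_result` (or a 5-vector of posteriors H0..H4).
#' @param cfg A [coloc_config()] supplying `h4_threshold`.
#' @return Character verdict.
#' @export
call_colocalization <- function(result, cfg = coloc_config()) {
  pp <- if (inherits(result, "coloc_result")) result$pp else result
  if (pp[5] > cfg$h4_threshold) return("colocalized")
  if (pp[4] > cfg$h4_threshold) return("distinct")
  "underpowered"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs, verdict: %s\n", x$n_snps, x$verdict))
  print(round(x$pp, 4))
  invisible(x)
}

#' Colocalize two traits from summary-statistic tables
#'
#' Convenience wrapper: intersects the two tables by rsid (optionally
#' restricted to `window` bp around `center_pos` on `chrom`), drops
#' variants with minor allele frequency below `cfg$maf_min` in either
#' study or with irreconcilable alleles (a warning reports the count),
#' computes per-SNP log-ABFs for each trait and returns the posterior
#' hypothesis probabilities.  Only z-scale quantities enter the ABFs, so
#' no sign alignment is needed, but allele sanity is still checked.
#'
#' @param trait1,trait2 [sumstat_table] objects.
#' @param cfg A [coloc_config()].
#' @param chrom,center_pos Optional region restriction (chromosome and
#'   center of a `cfg$window` half-width window).
#' @return A `coloc_result`.
#' @export
coloc_sumstats <- function(trait1, trait2, cfg = coloc_config(),
                           chrom = NULL, center_pos = NULL) {
  stopifnot(inherits(trait1, "sumstat_table"),
            inherits(trait2, "sumstat_table"))
  d1 <- trait1$data
  if (!is.null(center_pos)) {
    keep <- abs(d1$pos - center_pos) <= cfg$window
    if (!is.null(chrom)) keep <- keep & d1$chrom == chrom
    d1 <- d1[keep, , drop = FALSE]
  }
  common <- intersect(d1$rsid, trait2$data$rsid)
  if (!length(common)) stop("no shared variants in the region")
  d1 <- d1[match(common, d1$rsid), ]
  d2 <- trait2$data[match(common, trait2$data$rsid), ]

  # allele sanity: same unordered allele set (directly or as complement)
  set_ok <- mapply(function(a1, b1, a2, b2) {
    s1 <- sort(c(a1, b1))
    identical(s1, sort(c(a2, b2))) ||
      identical(s1, sort(c(.complement(a2), .complement(b2))))
  }, d1$ea, d1$nea, d2$ea, d2$nea)
  if (any(!set_ok)) {
    warning(sum(!set_ok), " variant(s) dropped for allele mismatch")
  }
  maf1 <- pmin(d1$eaf, 1 - d1$eaf)
  maf2 <- pmin(d2$eaf, 1 - d2$eaf)
  maf_ok <- (is.na(maf1) | maf1 >= cfg$maf_min) &
    (is.na(maf2) | maf2 >= cfg$maf_min)
  keep <- set_ok & maf_ok
  if (!any(keep)) stop("no variants left after allele/MAF filtering")
  d1 <- d1[keep, , drop = FALSE]
  d2 <- d2[keep, , drop = FALSE]

  res <- coloc_posteriors(log_abf(d1$beta, d1$se, cfg$W1),
                          log_abf(d2$beta, d2$se, cfg$W2), cfg)
  res$rsids <- d1$rsid
  res
}
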