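# Shared fixtures and independent oracles used across the test files.

# quick summary-stat table with internally consistent p-values
make_table <- function(rsid, ea, nea, beta, se, eaf = 0.3,
                       pos = seq_along(rsid) * 1000L, chrom = "1",
                       n = 10000L, trait_id = "trait",
                       trait_type = "exposure", pval = NULL) {
  explicit_p <- !is.null(pval)
  if (!explicit_p) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-320)
  build <- function() {
    sumstat_table(data.frame(rsid = rsid, chrom = chrom, pos = pos,
                             ea = ea, nea = nea, eaf = eaf,
                             beta = beta, se = se, pval = pval, n = n,
                             stringsAsFactors = FALSE),
                  trait_id = trait_id, trait_type = trait_type)
  }
  # fixtures with hand-picked p-values trip the z/p coherence warning
  if (explicit_p) suppressWarnings(build()) else build()
}

# random non-palindromic table for property tests
random_table <- function(n, seed, trait_id = "trait",
                         trait_type = "exposure") {
  withr::with_seed(seed, {
    pairs <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                      "T", "G", "G", "T", "T", "C", "C", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairs), n, replace = TRUE)
    beta <- rnorm(n, 0, 0.1)
    se <- runif(n, 0.01, 0.05)
    make_table(sprintf("rs%04d", seq_len(n)), pairs[pick, 1], pairs[pick, 2],
               beta, se, eaf = runif(n, 0.05, 0.95),
               trait_id = trait_id, trait_type = trait_type)
  })
}

# harmonized dataset assembled directly from effect vectors
make_hd <- function(beta_x, se_x, beta_y, se_y,
                    exposure_id = "exposure", outcome_id = "outcome") {
  n <- length(beta_x)
  harmonized_dataset(data.frame(
    rsid = sprintf("rs%04d", seq_len(n)), ea = "A", nea = "G",
    beta_x = beta_x, se_x = se_x, eaf_x = 0.3,
    beta_y = beta_y, se_y = se_y, eaf_y = 0.3,
    action = "aligned", excluded = FALSE, exclusion_reason = "",
    stringsAsFactors = FALSE), exposure_id, outcome_id)
}

# two-sample single/multi-SNP summary-stat draw without LD: true exposure
# effects bx, causal effect theta, optional per-SNP direct outcome effects
sim_hd <- function(bx_true, theta, se_x, se_y, pleio = 0) {
  n <- length(bx_true)
  bx <- rnorm(n, bx_true, se_x)
  by <- rnorm(n, theta * bx_true + pleio, se_y)
  make_hd(bx, rep_len(se_x, n), by, rep_len(se_y, n))
}

# brute-force BH step-up oracle: adjusted p by min-over-tail
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# brute-force colocalization oracle: enumerate all (M+1)^2 single-causal
# configurations with raw exponentials
coloc_enumerate <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(l1)
  b1 <- exp(l1); b2 <- exp(l2)
  w <- c(1, 0, 0, 0, 0)
  for (j in seq_len(m)) w[2] <- w[2] + p1 * b1[j]
  for (k in seq_len(m)) w[3] <- w[3] + p2 * b2[k]
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (j == k) {
        w[5] <- w[5] + p12 * b1[j] * b2[j]
      } else {
        w[4] <- w[4] + p1 * p2 * b1[j] * b2[k]
      }
    }
  }
  setNames(w / sum(w), paste0("PP.H", 0:4))
}

# independent greedy clumping oracle for small variant sets
clump_oracle <- function(rsids, pvals, ld, r2_clump) {
  o <- order(pvals, rsids)
  kept <- character(0)
  for (i in o) {
    r <- rsids[i]
    ok <- TRUE
    for (k in kept) {
      if (ld[r, k]^2 > r2_clump) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, r)
  }
  kept
}
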