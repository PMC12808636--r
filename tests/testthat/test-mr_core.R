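# Causal-effect estimators and FDR control.

test_that("Wald ratio reproduces the closed-form estimate and SEs", {
  pair <- data.frame(rsid = "rs1", beta_x = 2, se_x = 0.1,
                     beta_y = 1, se_y = 0.2)
  est <- wald_ratio(pair)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$ci_low, 0.5 - qnorm(0.975) * 0.1)
  expect_equal(est$ci_high, 0.5 + qnorm(0.975) * 0.1)

  null_est <- wald_ratio(data.frame(beta_x = 2, se_x = 0.1,
                                    beta_y = 0, se_y = 0.2))
  expect_equal(null_est$beta, 0)
  expect_equal(null_est$pval, 1)

  est2 <- wald_ratio(pair, se_order = "second")
  expect_equal(est2$se, sqrt(0.2^2 / 4 + 1 * 0.1^2 / 16))
  expect_equal(est2$se, 0.10308, tolerance = 1e-4)

  expect_error(wald_ratio(data.frame(beta_x = 0, se_x = 0.1,
                                     beta_y = 1, se_y = 0.2, rsid = "rsZ")),
               "rsZ")
})

test_that("second-order Wald SE matches a Monte-Carlo delta oracle within 3%", {
  mc_sd <- withr::with_seed(99, {
    bx <- rnorm(1e6, 2, 0.1)
    by <- rnorm(1e6, 1, 0.2)
    sd(by / bx)
  })
  est <- wald_ratio(data.frame(beta_x = 2, se_x = 0.1, beta_y = 1,
                               se_y = 0.2), se_order = "second")
  expect_lt(abs(est$se - mc_sd) / mc_sd, 0.03)
})

test_that("IVW reduces to the Wald ratio for one SNP and matches weighted LS", {
  hd1 <- make_hd(beta_x = -1.7, se_x = 0.05, beta_y = 0.4, se_y = 0.11)
  ivw1 <- mr_ivw(hd1)
  wald1 <- wald_ratio(mr_pairs(hd1))
  expect_identical(ivw1$beta, wald1$beta)
  expect_identical(ivw1$se, wald1$se)
  expect_identical(ivw1$pval, wald1$pval)

  # two identical SNPs: same estimate, SE shrinks by sqrt(2)
  hd2 <- make_hd(beta_x = c(1, 1), se_x = 0.05, beta_y = c(0.5, 0.5),
                 se_y = c(0.1, 0.1))
  ivw2 <- mr_ivw(hd2)
  expect_equal(ivw2$beta, 0.5)
  expect_equal(ivw2$se, 0.1 / sqrt(2))
  expect_equal(ivw2$model, "fixed")
})

test_that("IVW CI covers the true effect at close to nominal rate (16 SNPs)", {
  hits <- withr::with_seed(2024, {
    sum(vapply(1:100, function(i) {
      hd <- sim_hd(bx_true = runif(16, 0.1, 0.4), theta = 0.24,
                   se_x = 0.004, se_y = 0.02)
      est <- mr_ivw(hd)
      est$ci_low <= 0.24 && 0.24 <= est$ci_high
    }, logical(1)))
  })
  expect_gte(hits, 93)
})

test_that("Egger recovers exact lines and its intercept flags directional pleiotropy", {
  # points exactly on a line through the origin
  bx <- c(0.1, 0.2, 0.3, 0.4)
  hd0 <- make_hd(bx, 0.01, 0.7 * bx, c(0.01, 0.02, 0.01, 0.03))
  e0 <- mr_egger(hd0)
  expect_equal(e0$beta, 0.7)
  expect_equal(e0$egger_intercept, 0, tolerance = 1e-12)

  # exact interpolation of beta_y = 0.05 + 0.3 * beta_x
  hd1 <- make_hd(bx, 0.01, 0.05 + 0.3 * bx, c(0.01, 0.02, 0.01, 0.03))
  e1 <- mr_egger(hd1)
  expect_equal(e1$beta, 0.3)
  expect_equal(e1$egger_intercept, 0.05)

  expect_error(mr_egger(make_hd(c(1, 1), 0.1, c(1, 1), 0.1)), "3")

  # constant +0.05 direct outcome effect across 50 SNPs: intercept
  # detected in at least 80% of 200 replicates
  detect <- withr::with_seed(7, {
    mean(vapply(1:200, function(i) {
      hd <- sim_hd(bx_true = runif(50, 0.05, 0.5), theta = 0.2,
                   se_x = 0.002, se_y = 0.02, pleio = 0.05)
      mr_egger(hd)$egger_intercept_pval < 0.05
    }, logical(1)))
  })
  expect_gte(detect, 0.80)
})

test_that("Egger with its intercept constrained to zero equals fixed-effect IVW", {
  for (seed in 1:20) {
    hd <- withr::with_seed(seed, {
      sim_hd(bx_true = runif(8, 0.1, 0.5), theta = rnorm(1, 0, 0.3),
             se_x = 0.01, se_y = runif(8, 0.01, 0.05))
    })
    p <- mr_pairs(hd)
    w <- 1 / p$se_y^2
    # the shared weighted-LS normal equations with the intercept column
    # removed collapse to the IVW slope and fixed-effect SE
    slope0 <- sum(w * p$beta_x * p$beta_y) / sum(w * p$beta_x^2)
    se0 <- sqrt(1 / sum(w * p$beta_x^2))
    ivw <- mr_ivw(hd, model = "fixed")
    expect_equal(ivw$beta, slope0)
    expect_equal(ivw$se, se0)
  }
})

test_that("weighted median interpolates the 50% weight point", {
  hd <- make_hd(beta_x = c(1, 1, 1), se_x = 0.01,
                beta_y = c(1, 2, 3), se_y = 0.1)
  est <- mr_weighted_median(hd, n_boot = 200, seed = 1)
  expect_equal(est$beta, 2)

  # all ratios equal: estimate is that constant, bootstrap SE collapses
  hd_c <- make_hd(beta_x = c(1, 2, 4), se_x = 1e-6,
                  beta_y = 0.7 * c(1, 2, 4), se_y = c(1e-6, 2e-6, 4e-6))
  est_c <- mr_weighted_median(hd_c, n_boot = 200, seed = 1)
  expect_equal(est_c$beta, 0.7)
  expect_lt(est_c$se, 1e-4)
})

test_that("weighted median resists balanced pleiotropy better than IVW", {
  wins <- withr::with_seed(31, {
    mean(vapply(1:200, function(i) {
      n <- 20
      pleio <- c(rep(0, n / 2), sample(c(-1, 1), n / 2, TRUE) * 1.0)
      hd <- sim_hd(bx_true = runif(n, 0.1, 0.5), theta = 0.3,
                   se_x = 0.005, se_y = 0.03, pleio = pleio)
      med <- mr_weighted_median(hd, n_boot = 2, seed = i)$beta
      ivw <- mr_ivw(hd)$beta
      abs(med - 0.3) < abs(ivw - 0.3)
    }, logical(1)))
  })
  expect_gte(wins, 0.90)
})

test_that("weighted mode finds the plurality ratio", {
  # all ratios equal
  hd_c <- make_hd(beta_x = c(1, 2, 4), se_x = 1e-6,
                  beta_y = 0.7 * c(1, 2, 4), se_y = c(1e-6, 2e-6, 4e-6))
  expect_equal(mr_weighted_mode(hd_c, n_boot = 2, seed = 1)$beta, 0.7)

  # bimodal ratios, 7 at 0.3 vs 3 at 1.0 with equal weights: the larger
  # mode wins (checked against the exact density grid the estimator uses)
  hd_b <- make_hd(beta_x = rep(1, 10), se_x = 0.01,
                  beta_y = c(rep(0.3, 7), rep(1.0, 3)), se_y = 0.1)
  est_b <- mr_weighted_mode(hd_b, n_boot = 2, seed = 1)
  expect_lt(abs(est_b$beta - 0.3), 0.1)

  # permutation symmetry
  perm <- c(4, 9, 1, 7, 10, 2, 6, 3, 8, 5)
  hd_p <- make_hd(beta_x = rep(1, 10), se_x = 0.01,
                  beta_y = c(rep(0.3, 7), rep(1.0, 3))[perm], se_y = 0.1)
  expect_equal(mr_weighted_mode(hd_p, n_boot = 2, seed = 1)$beta, est_b$beta)
})

test_that("all estimators are equivariant under a joint sign flip", {
  hd <- withr::with_seed(5, {
    sim_hd(bx_true = runif(10, 0.1, 0.5), theta = 0.25,
           se_x = 0.01, se_y = 0.03)
  })
  flipped <- make_hd(-mr_pairs(hd)$beta_x, mr_pairs(hd)$se_x,
                     -mr_pairs(hd)$beta_y, mr_pairs(hd)$se_y)
  for (f in list(mr_ivw, mr_egger,
                 function(d) mr_weighted_median(d, n_boot = 50, seed = 2),
                 function(d) mr_weighted_mode(d, n_boot = 50, seed = 2))) {
    expect_equal(f(hd)$beta, f(flipped)$beta, tolerance = 1e-10)
  }
})

test_that("BH step-up matches direct enumeration and a brute-force oracle", {
  one <- bh_fdr(0.04, q = 0.05)
  expect_true(one$reject)
  expect_equal(one$adjusted, 0.04)

  four <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(four$reject))  # p(4) = 0.04 <= (4/4) * 0.05

  for (seed in 1:100) {
    p <- withr::with_seed(seed, runif(sample(1:30, 1))^2)
    expect_equal(bh_fdr(p)$adjusted, bh_oracle(p))
  }
  expect_equal(bh_fdr(numeric(0)),
               list(adjusted = numeric(0), reject = logical(0)))
})

test_that("the Wald test has nominal type-I error under the null", {
  rejections <- withr::with_seed(314, {
    mean(vapply(1:5000, function(i) {
      bx <- rnorm(1, 0.3, 0.01)      # strong instrument, F >> 30
      by <- rnorm(1, 0, 0.02)        # no causal effect
      wald_ratio(data.frame(beta_x = bx, se_x = 0.01,
                            beta_y = by, se_y = 0.02))$pval < 0.05
    }, logical(1)))
  })
  expect_gte(rejections, 0.04)
  expect_lte(rejections, 0.06)
})

test_that("Wald and IVW CI coverage is near nominal at study scale", {
  # one strong cis-pQTL (F ~ 700), protein-on-outcome effect -0.26,
  # sampling noise at the two GWAS sample sizes
  n_exp <- 35559; n_out <- 39620
  sdg <- sqrt(2 * 0.3 * 0.7)
  se_x <- 1 / (sdg * sqrt(n_exp))
  se_y <- 1 / (sdg * sqrt(n_out))
  bx_true <- sqrt(0.02) / sdg
  cover <- withr::with_seed(2718, {
    mean(vapply(1:1000, function(i) {
      bx <- rnorm(1, bx_true, se_x)
      by <- rnorm(1, -0.26 * bx_true, se_y)
      est <- wald_ratio(data.frame(beta_x = bx, se_x = se_x,
                                   beta_y = by, se_y = se_y))
      est$ci_low <= -0.26 && -0.26 <= est$ci_high
    }, logical(1)))
  })
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.97)
})

test_that("published-style CI bounds are recovered from beta and p", {
  ci <- normal_ci_from_beta_p(-0.07, 4.4e-5)
  expect_equal(unname(ci["ci_low"]), -0.104, tolerance = 1e-2)
  expect_error(normal_ci_from_beta_p(0, 0.05), "non-zero")
})
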