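# Synthetic GWAS summary statistics with known causal truth.
#
# Summary statistics are simulated directly on the z-score scale:
# marginal standardized effects are the LD-propagated joint effects
# (marginal = R %*% joint, with per-SNP per-allele effects scaled by
# sqrt(2*maf*(1-maf))), and a single multivariate-normal noise draw with
# covariance R is added per trait, so LD structure appears in the noise
# exactly as in real regional statistics.  This is distributionally
# equivalent to an individual-level simulation under the standard
# linear-model approximation, and orders of magnitude faster.

#' AR(1) linkage-disequilibrium matrix
#'
#' Correlation `r[i, j] = rho^|i - j|`; positive definite for
#' `0 <= rho < 1` and deterministic given its inputs.
#'
#' @param n_snps Number of variants.
#' @param rho AR(1) decay parameter in \[0, 1).
#' @param rsids Variant names (defaults to `rs00001, ...`).
#' @return An [ld_matrix].
#' @export
simulate_ld <- function(n_snps, rho, rsids = sprintf("rs%05d", seq_len(n_snps))) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  ld_matrix(r, rsids)
}

#' Define a simulation scenario
#'
#' Bundles the generative truth for one cis region: region size and LD,
#' study sample sizes, allele-frequency range, the causal configuration
#' and effect sizes, and the seed.  Defaults emulate the study setting the
#' package targets: an exposure (protein) GWAS of N = 35,559, an outcome
#' (childhood BMI) GWAS of N = 39,620, a ~1 Mb cis region of 200 SNPs with
#' AR(1) LD (rho = 0.9), one strong cis-pQTL explaining ~2% of the protein
#' variance, and a protein-on-outcome effect of -0.26 SD/SD.
#'
#' Causal configurations:
#' \describe{
#' \item{h0}{no causal variant for either trait;}
#' \item{h1}{outcome-only causal variant;}
#' \item{h2}{exposure-only causal variant (a null protein: instrumented
#'   but with no effect on the outcome);}
#' \item{h3}{distinct causal variants for the two traits (positions n/4
#'   and 3n/4, so their LD blocks are essentially independent);}
#' \item{h4}{one shared causal variant: the outcome inherits
#'   `causal_effect_out` times the exposure effect;}
#' \item{pleiotropy}{as h4, plus a direct per-allele effect
#'   `direct_pleiotropy` of each causal variant on the outcome;}
#' \item{mediation}{exposure -> mediator -> outcome chain with effects
#'   `mediator_params = c(a, b)`; a third (mediator) table is emitted;}
#' \item{reverse}{the outcome trait is causally upstream: it has its own
#'   causal variants and the exposure inherits `causal_effect_out` times
#'   the outcome effects.}
#' }
#'
#' @param n_snps Number of variants in the region (default 200).
#' @param rho AR(1) LD parameter (default 0.9).
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes (defaults
#'   35559 and 39620).
#' @param maf_range Minor-allele-frequency range for simulated variants
#'   (default c(0.05, 0.5)).
#' @param causal_config One of `"h0", "h1", "h2", "h3", "h4",
#'   "pleiotropy", "mediation", "reverse"`.
#' @param n_causal Number of causal variants per causal trait (default 1;
#'   evenly spaced across the region, total variance explained split
#'   equally among them).
#' @param exposure_ve Total exposure variance explained by its causal
#'   variants (default 0.02).  Ignored when `causal_effect_exp` is given.
#' @param causal_effect_exp Optional per-allele causal effect on the
#'   exposure (SD units); overrides `exposure_ve`.
#' @param causal_effect_out Causal effect of the upstream trait on the
#'   downstream trait in SD/SD (default -0.26).  In `h1`/`h3` it scales
#'   the outcome's own variant effect against `sqrt(exposure_ve)`; in
#'   `reverse` it is the outcome-on-exposure effect.
#' @param direct_pleiotropy Per-allele direct effect of each causal
#'   variant on the outcome (SD units; `pleiotropy` config only).
#' @param mediator_params Numeric `c(a, b)`: exposure-on-mediator and
#'   mediator-on-outcome effects (`mediation` config only).
#' @param n_mediator Mediator GWAS sample size (default 155961).
#' @param seed Integer seed; the whole simulation is deterministic given
#'   the scenario.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(n_snps = 200, rho = 0.9,
                         n_exp = 35559, n_out = 39620,
                         maf_range = c(0.05, 0.5),
                         causal_config = c("h4", "h0", "h1", "h2", "h3",
                                           "pleiotropy", "mediation",
                                           "reverse"),
                         n_causal = 1,
                         exposure_ve = 0.02,
                         causal_effect_exp = NULL,
                         causal_effect_out = -0.26,
                         direct_pleiotropy = 0,
                         mediator_params = NULL,
                         n_mediator = 155961,
                         seed = 1) {
  causal_config <- match.arg(causal_config)
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5 || maf_range[1] >= maf_range[2]) {
    stop("maf_range must lie within (0.01, 0.5)")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (n_causal < 1 || n_causal > n_snps) stop("invalid n_causal")
  if (causal_config == "mediation" &&
      (is.null(mediator_params) || length(mediator_params) != 2)) {
    stop("mediation config requires mediator_params = c(a, b)")
  }
  structure(list(n_snps = n_snps, rho = rho, n_exp = n_exp, n_out = n_out,
                 maf_range = maf_range, causal_config = causal_config,
                 n_causal = n_causal, exposure_ve = exposure_ve,
                 causal_effect_exp = causal_effect_exp,
                 causal_effect_out = causal_effect_out,
                 direct_pleiotropy = direct_pleiotropy,
                 mediator_params = mediator_params,
                 n_mediator = n_mediator, seed = seed),
            class = "sim_scenario")
}

#' Named scenario presets
#'
#' `"paper_scale_eng"`, `"paper_scale_fabp4"` and `"paper_scale_h4"` are
#' shared-causal-variant (h4) regions whose instrument strength and causal
#' effect reproduce, respectively, a very strong cis-pQTL with a small
#' protective effect (-0.07 SD/SD), a modest cis-pQTL with a large
#' protective effect (-0.33 SD/SD), and an intermediate protein
#' (-0.26 SD/SD at 2% variance explained).  `"paper_scale_h3"` places
#' distinct causal variants for the two traits with regional z-scores
#' around 8 each.  `"null_535"` is an instrumented protein with no effect
#' on the outcome (an h2 region), the building block of proteome-wide null
#' batches.
#'
#' @param name Preset name.
#' @param seed Seed to attach to the scenario.
#' @return A [sim_scenario()].
#' @export
scenario_preset <- function(name = c("paper_scale_eng", "paper_scale_fabp4",
                                     "paper_scale_h4", "paper_scale_h3",
                                     "null_535"),
                            seed = 1) {
  name <- match.arg(name)
  switch(name,
    paper_scale_eng = sim_scenario(causal_config = "h4",
                                   exposure_ve = 0.085,
                                   causal_effect_out = -0.07, seed = seed),
    paper_scale_fabp4 = sim_scenario(causal_config = "h4",
                                     exposure_ve = 0.0034,
                                     causal_effect_out = -0.33, seed = seed),
    paper_scale_h4 = sim_scenario(causal_config = "h4",
                                  exposure_ve = 0.02,
                                  causal_effect_out = -0.26, seed = seed),
    paper_scale_h3 = sim_scenario(causal_config = "h3",
                                  exposure_ve = 0.0018,
                                  causal_effect_out = 0.95, seed = seed),
    null_535 = sim_scenario(causal_config = "h2",
                            exposure_ve = 0.02,
                            causal_effect_out = 0, seed = seed))
}

# one z-scale GWAS: z_hat = sqrt(n) * R %*% joint_std + MVN(0, R)
.sim_trait <- function(joint_std, R, chol_R, n, sdg) {
  z_true <- sqrt(n) * as.vector(R %*% joint_std)
  noise <- as.vector(rnorm(length(joint_std)) %*% chol_R)
  z <- z_true + noise
  se <- 1 / (sdg * sqrt(n))
  list(beta = z * se, se = se, pval = pmax(2 * pnorm(-abs(z)), 1e-320),
       z_true = z_true)
}

.sim_table <- function(sim, meta, trait_id, trait_type, n) {
  sumstat_table(data.frame(
    rsid = meta$rsid, chrom = meta$chrom, pos = meta$pos,
    ea = meta$ea, nea = meta$nea, eaf = meta$maf,
    beta = sim$beta, se = sim$se, pval = sim$pval, n = n,
    stringsAsFactors = FALSE), trait_id, trait_type)
}

#' Simulate paired GWAS summary statistics for one cis region
#'
#' Generates exposure and outcome (and, for the mediation configuration,
#' mediator) summary-statistic tables under the scenario's causal truth,
#' together with the LD matrix, the gene annotation of the simulated
#' protein and a truth record carrying every generative parameter.
#' Deterministic: the same scenario (including its seed) yields
#' bit-identical tables.
#'
#' @param scenario A [sim_scenario()].
#' @return List of class `sim_dataset` with elements `exposure`,
#'   `outcome`, optionally `mediator` ([sumstat_table]s), `ld`
#'   ([ld_matrix]), `gene` (one-row annotation data.frame) and `truth`.
#' @export
simulate_sumstats <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  n <- sc$n_snps
  R <- simulate_ld(n, sc$rho)
  withr::with_seed(sc$seed, {
    maf <- runif(n, sc$maf_range[1], sc$maf_range[2])
    # non-palindromic allele pairs keep every simulated variant usable
    pairs <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                      "T", "G", "G", "T", "T", "C", "C", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairs), n, replace = TRUE)
    step <- max(1L, as.integer(floor(1e6 / n)))
    meta <- data.frame(rsid = rownames(R), chrom = "1",
                       pos = 10000000L + (seq_len(n) - 1L) * step,
                       ea = pairs[pick, 1], nea = pairs[pick, 2],
                       maf = maf, stringsAsFactors = FALSE)
    sdg <- sqrt(2 * maf * (1 - maf))

    causal_at <- function(k) {
      if (k == 1) return(as.integer(ceiling(n / 2)))
      as.integer(round(seq(1, n, length.out = k + 2)))[2:(k + 1)]
    }
    idx_main <- causal_at(sc$n_causal)
    idx_h3_exp <- max(1L, as.integer(round(n / 4)))
    idx_h3_out <- min(n, as.integer(round(3 * n / 4)))

    # standardized (per-SD-genotype) joint effects
    b_std_at <- function(idx) {
      b <- numeric(n)
      if (!is.null(sc$causal_effect_exp)) {
        b[idx] <- sc$causal_effect_exp * sdg[idx]
      } else {
        b[idx] <- sqrt(sc$exposure_ve / length(idx))
      }
      b
    }
    cfg <- sc$causal_config
    b_exp <- switch(cfg,
      h0 = numeric(n), h1 = numeric(n),
      reverse = sc$causal_effect_out * b_std_at(idx_main),
      h3 = b_std_at(idx_h3_exp),
      b_std_at(idx_main))          # h2, h4, pleiotropy, mediation
    b_med <- NULL
    b_out <- switch(cfg,
      h0 = numeric(n),
      h1 = sc$causal_effect_out * sqrt(sc$exposure_ve) *
        replace(numeric(n), idx_main, 1),
      h2 = numeric(n),
      h3 = sc$causal_effect_out * sqrt(sc$exposure_ve) *
        replace(numeric(n), idx_h3_out, 1),
      h4 = sc$causal_effect_out * b_exp,
      pleiotropy = sc$causal_effect_out * b_exp +
        replace(numeric(n), idx_main, sc$direct_pleiotropy * sdg[idx_main]),
      mediation = {
        b_med <- sc$mediator_params[1] * b_exp
        sc$mediator_params[2] * b_med
      },
      reverse = b_std_at(idx_main))

    chol_R <- chol(R)
    class(chol_R) <- "matrix"
    sim_exp <- .sim_trait(b_exp, R, chol_R, sc$n_exp, sdg)
    sim_out <- .sim_trait(b_out, R, chol_R, sc$n_out, sdg)
    sim_med <- if (!is.null(b_med)) {
      .sim_trait(b_med, R, chol_R, sc$n_mediator, sdg)
    }

    causal_exposure <- meta$rsid[which(b_exp != 0)]
    causal_outcome <- meta$rsid[which(b_out != 0)]
    lead <- if (cfg == "h3") idx_h3_exp else idx_main[1]
    gene <- data.frame(gene_id = "GENE1", chrom = "1",
                       tss = meta$pos[lead], stringsAsFactors = FALSE)

    out <- list(
      exposure = .sim_table(sim_exp, meta, "protein", "exposure", sc$n_exp),
      outcome = .sim_table(sim_out, meta, "BMI", "outcome", sc$n_out),
      ld = R, gene = gene,
      truth = list(scenario = unclass(sc),
                   causal_exposure = causal_exposure,
                   causal_outcome = causal_outcome,
                   joint_std_exposure = b_exp,
                   joint_std_outcome = b_out,
                   maf = maf, pos = meta$pos,
                   z_true_exposure = sim_exp$z_true,
                   z_true_outcome = sim_out$z_true))
    if (!is.null(sim_med)) {
      out$mediator <- .sim_table(sim_med, meta, "pct_body_fat", "mediator",
                                 sc$n_mediator)
      out$truth$joint_std_mediator <- b_med
    }
    structure(out, class = "sim_dataset")
  })
}

#' Simulate a proteome panel: many cis regions against one outcome GWAS
#'
#' Builds `n_proteins` independent cis regions, the first `n_signal` of
#' them from `signal_scenario` (by default a shared-causal-variant region
#' at study scale) and the rest from `null_scenario` (instrumented
#' proteins with no effect on the outcome).  Each protein is placed on its
#' own chromosome with its own variant identifiers, and the outcome table
#' is the union of all regional outcome statistics, as in a genome-wide
#' outcome GWAS scan.  Per-region seeds are derived deterministically from
#' `seed`.
#'
#' @param n_proteins Number of proteins (default 10).
#' @param n_signal How many of them carry the signal scenario (default 1).
#' @param signal_scenario,null_scenario [sim_scenario()]s used as
#'   templates (their `seed` fields are overridden per region).
#' @param seed Master seed.
#' @return List of class `sim_panel` with `proteins` (named list of
#'   [sumstat_table]s), `outcome` ([sumstat_table]), `annotations`
#'   (data.frame), `lds` (named list of [ld_matrix]), and `truth`
#'   (per-protein truth records).
#' @export
simulate_panel <- function(n_proteins = 10, n_signal = 1,
                           signal_scenario = scenario_preset("paper_scale_h4"),
                           null_scenario = scenario_preset("null_535"),
                           seed = 1) {
  region_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                                    n_proteins))
  proteins <- list(); lds <- list(); truth <- list()
  annotations <- NULL
  outcome_data <- NULL
  outcome_tpl <- NULL
  for (k in seq_len(n_proteins)) {
    sc <- if (k <= n_signal) signal_scenario else null_scenario
    sc$seed <- region_seeds[k]
    sim <- simulate_sumstats(sc)
    id <- sprintf("P%03d", k)
    pre <- sprintf("c%02d_", k)
    chrom <- as.character(k)
    for (tb in c("exposure", "outcome")) {
      sim[[tb]]$data$rsid <- paste0(pre, sim[[tb]]$data$rsid)
      sim[[tb]]$data$chrom <- chrom
    }
    sim$exposure$trait_id <- id
    dimnames(sim$ld) <- lapply(dimnames(sim$ld), function(x) paste0(pre, x))
    sim$gene$gene_id <- id
    sim$gene$chrom <- chrom
    proteins[[id]] <- sim$exposure
    lds[[id]] <- sim$ld
    annotations <- rbind(annotations, sim$gene)
    outcome_data <- rbind(outcome_data, sim$outcome$data)
    outcome_tpl <- sim$outcome
    sim$truth$causal_exposure <- paste0(pre, sim$truth$causal_exposure)
    sim$truth$causal_outcome <- paste0(pre, sim$truth$causal_outcome)
    truth[[id]] <- sim$truth
  }
  outcome <- sumstat_table(outcome_data, trait_id = "BMI",
                           trait_type = "outcome")
  structure(list(proteins = proteins, outcome = outcome,
                 annotations = annotations, lds = lds, truth = truth),
            class = "sim_panel")
}

#' Write a simulated dataset to a directory
#'
#' Emits the standard summary-stat TSVs, the LD matrix, the gene
#' annotation and the truth record (JSON).
#'
#' @param sim A `sim_dataset` from [simulate_sumstats()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  if (!is.null(sim$mediator)) {
    write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  }
  write_ld_matrix(sim$ld, file.path(dir, "ld.txt"))
  write.table(sim$gene, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build a local trait-association (PheWAS) fixture table
#'
#' Produces, for each requested instrument, the requested number of
#' genome-wide-significant trait associations per category, plus
#' non-significant background rows, in random order.  Used to exercise the
#' confounder screen without any external lookup.
#'
#' @param rsids Instrument variant identifiers.
#' @param categories Trait categories (default the four used for
#'   obesity-related screens: anthropometric, pubertal, sociodemographic,
#'   nutritional).
#' @param hits_per_category Integer vector (recycled over categories): the
#'   number of significant trait associations per category for each
#'   instrument.
#' @param n_background Non-significant background rows (default 25).
#' @param seed Seed.
#' @return data.frame with columns `rsid, trait, category, pval`.
#' @export
make_phewas_table <- function(rsids,
                              categories = c("anthropometric", "pubertal",
                                             "sociodemographic",
                                             "nutritional"),
                              hits_per_category = 0,
                              n_background = 25, seed = 1) {
  if (!length(categories)) stop("categories must be nonempty")
  hits <- rep_len(hits_per_category, length(categories))
  withr::with_seed(seed, {
    rows <- list()
    for (r in rsids) {
      for (k in seq_along(categories)) {
        if (hits[k] > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            rsid = r,
            trait = sprintf("%s_trait_%d", categories[k], seq_len(hits[k])),
            category = categories[k],
            pval = 10^runif(hits[k], -30, log10(5e-8) - 0.5),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (n_background > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        rsid = sample(rsids, n_background, replace = TRUE),
        trait = sprintf("background_trait_%d", seq_len(n_background)),
        category = sample(categories, n_background, replace = TRUE),
        pval = runif(n_background, 1e-6, 1),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
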