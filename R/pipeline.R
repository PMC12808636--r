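# Orchestration of the proteome-wide analysis: instrument selection ->
# harmonization -> discovery MR -> FDR -> colocalization -> confounder
# screen -> mediation -> reverse MR -> power, with per-protein reports
# and attrition accounting.

#' Pipeline configuration
#'
#' All thresholds of the proteome-wide MR run in one place.
#'
#' @param cis_window cis window around the TSS in bp (default 1e6).
#' @param p_max Instrument significance threshold (default 5e-8).
#' @param f_min Minimum instrument F-statistic, exclusive (default 10).
#' @param r2_clump LD-clumping r-squared (default 0.001).
#' @param palindrome_maf Palindrome exclusion MAF threshold (default 0.42).
#' @param fdr_q FDR level for discovery significance (default 0.05).
#' @param proxy_r2 Minimum r-squared for proxy instruments (default 0.8).
#' @param coloc A [coloc_config()].
#' @param wald_se_order `"first"` or `"second"` order Wald SE.
#' @param power_alpha Significance level used for the per-protein power
#'   estimate (default 0.05).
#' @param do_reverse Run reverse MR (outcome instruments on each
#'   significant protein) when possible (default TRUE).
#' @param n_boot,seed Bootstrap replicates and seed for the
#'   median/mode estimators used in reverse MR.
#' @return List of class `pwmr_config`.
#' @export
pwmr_config <- function(cis_window = 1e6, p_max = 5e-8, f_min = 10,
                        r2_clump = 0.001, palindrome_maf = 0.42,
                        fdr_q = 0.05, proxy_r2 = 0.8,
                        coloc = coloc_config(), wald_se_order = "first",
                        power_alpha = 0.05, do_reverse = TRUE,
                        n_boot = 1000, seed = 1234) {
  stopifnot(cis_window > 0, p_max > 0, p_max <= 1, f_min >= 0,
            r2_clump > 0, r2_clump <= 1,
            palindrome_maf > 0, palindrome_maf < 0.5,
            fdr_q > 0, fdr_q < 1, proxy_r2 > 0, proxy_r2 <= 1)
  structure(list(cis_window = cis_window, p_max = p_max, f_min = f_min,
                 r2_clump = r2_clump, palindrome_maf = palindrome_maf,
                 fdr_q = fdr_q, proxy_r2 = proxy_r2, coloc = coloc,
                 wald_se_order = wald_se_order, power_alpha = power_alpha,
                 do_reverse = do_reverse, n_boot = n_boot, seed = seed),
            class = "pwmr_config")
}

#' Count an instrument's trait associations per category
#'
#' PheWAS-style confounder screen against a local trait-association table:
#' counts, per category, the distinct traits associated with the
#' instrument at `p <= p_threshold`.  Trait labels not covered by the
#' category assignment are bucketed as `"other"` (with a message).  An
#' rsid absent from the table yields all-zero counts.
#'
#' @param rsid Instrument variant (or its proxy).
#' @param table data.frame with columns `rsid, trait, pval` and either a
#'   `category` column or labels covered by `category_map`.
#' @param p_threshold Association significance threshold (default 5e-8).
#' @param category_map Optional named character vector mapping trait
#'   labels to categories (overrides a `category` column).
#' @return Named integer vector of per-category counts (all categories
#'   present in the table, zeros included).
#' @export
screen_confounders <- function(rsid, table, p_threshold = 5e-8,
                               category_map = NULL) {
  table <- as.data.frame(table)
  if (!is.null(category_map)) {
    cat_col <- unname(category_map[table$trait])
    n_unknown <- sum(is.na(cat_col))
    if (n_unknown > 0) {
      message(n_unknown, " trait label(s) not in category_map; bucketed as 'other'")
      cat_col[is.na(cat_col)] <- "other"
    }
    table$category <- cat_col
  }
  if (is.null(table$category)) stop("table needs a 'category' column or a category_map")
  cats <- sort(unique(table$category))
  hits <- table[table$rsid == rsid & table$pval <= p_threshold, , drop = FALSE]
  counts <- vapply(cats, function(cg) {
    length(unique(hits$trait[hits$category == cg]))
  }, integer(1))
  setNames(as.integer(counts), cats)
}

#' Reverse MR: all four estimators on one harmonized dataset
#'
#' Runs IVW, MR-Egger (with its intercept test), weighted median and
#' weighted mode on the same instruments, as used when testing whether the
#' outcome trait causally affects a protein.  With fewer than 3 usable
#' instruments only IVW is returned (a single instrument reduces to the
#' Wald ratio).
#'
#' @param data A [harmonized_dataset] of outcome instruments against the
#'   protein GWAS.
#' @param n_boot,seed Bootstrap settings for the median/mode estimators.
#' @return Named list of `mr_estimate` rows (`ivw`, and when at least 3
#'   instruments are available `egger`, `weighted_median`,
#'   `weighted_mode`).
#' @export
reverse_mr <- function(data, n_boot = 1000, seed = 1234) {
  n <- nrow(mr_pairs(data))
  if (n < 1) stop("reverse MR requires at least one usable instrument")
  out <- list(ivw = mr_ivw(data))
  if (n >= 3) {
    out$egger <- mr_egger(data)
    out$weighted_median <- mr_weighted_median(data, n_boot = n_boot, seed = seed)
    out$weighted_mode <- mr_weighted_mode(data, n_boot = n_boot, seed = seed)
  }
  out
}

# variance in the exposure explained by a set of instruments
# (standardized trait, per-allele betas)
.instrument_r2 <- function(instr) {
  if (!nrow(instr) || any(is.na(instr$eaf))) return(NA_real_)
  sum(2 * instr$eaf * (1 - instr$eaf) * instr$beta_x^2)
}

.protein_report <- function(id, status, instruments = NULL, estimate = NULL) {
  list(protein = id, status = status, instruments = instruments,
       estimate = estimate, fdr_adjusted_p = NA_real_, significant = FALSE,
       coloc = NULL, confounder_counts = NULL, mediation = NULL,
       reverse = NULL, power = NA_real_)
}

#' Run the proteome-wide MR pipeline
#'
#' For each protein: select cis instruments, substitute LD proxies for
#' instruments missing from the outcome GWAS, harmonize, and estimate the
#' causal effect (Wald ratio for a single instrument, IVW otherwise).
#' Benjamini-Hochberg FDR is applied across all successfully tested
#' proteins; FDR-significant proteins then get colocalization, the
#' confounder screen (when a PheWAS table is supplied), two-step mediation
#' (when a mediator is supplied), reverse MR (when enabled and outcome
#' instruments are found in the protein GWAS) and an analytic power
#' estimate at the observed effect.  Per-protein failures are recorded in
#' the report and never abort the run.
#'
#' @param proteins Named list of exposure [sumstat_table]s; names must
#'   match `annotations$gene_id`.
#' @param outcome Outcome [sumstat_table].
#' @param annotations data.frame with `gene_id, chrom, tss`.
#' @param ld Optional [ld_matrix] or named list of matrices (one per
#'   protein) for clumping, proxies and reverse-MR instrument selection.
#' @param phewas Optional local trait-association table for
#'   [screen_confounders()].
#' @param mediator Optional list with `table` (a [sumstat_table]) and
#'   `instruments` (rsids instrumenting the mediator) for two-step MR.
#' @param config A [pwmr_config()].
#' @return Object of class `pwmr_result`: list with `results` (one row
#'   per protein), `reports` (per-protein detail), `summary` (attrition
#'   counts) and `config`.
#' @export
run_pwmr <- function(proteins, outcome, annotations, ld = NULL,
                     phewas = NULL, mediator = NULL,
                     config = pwmr_config()) {
  stopifnot(inherits(outcome, "sumstat_table"))
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop("'proteins' must be a named list (names = gene ids)")
  }
  ld_for <- function(id) {
    if (is.null(ld)) return(NULL)
    if (inherits(ld, "ld_matrix")) return(ld)
    ld[[id]]
  }

  reports <- list()
  for (id in names(proteins)) {
    tab <- proteins[[id]]
    gene <- annotations[annotations$gene_id == id, , drop = FALSE]
    if (!nrow(gene)) {
      reports[[id]] <- .protein_report(id, "no_annotation")
      next
    }
    instr <- select_cis_instruments(tab, gene[1, ], window = config$cis_window,
                                    p_max = config$p_max, f_min = config$f_min,
                                    ld = ld_for(id), r2_clump = config$r2_clump)
    if (!nrow(instr)) {
      reports[[id]] <- .protein_report(id, "no_instrument")
      next
    }
    # proxy substitution for instruments absent from the outcome GWAS
    usable <- character(0)
    for (r in instr$rsid) {
      if (r %in% outcome$data$rsid) {
        usable <- c(usable, r)
      } else if (!is.null(ld_for(id)) && r %in% rownames(ld_for(id))) {
        prox <- find_proxy(r, outcome, ld_for(id), r2_min = config$proxy_r2)
        if (!is.na(prox) && prox %in% tab$data$rsid) usable <- c(usable, prox)
      }
    }
    usable <- unique(usable)
    if (!length(usable)) {
      reports[[id]] <- .protein_report(id, "not_testable", instruments = instr)
      next
    }
    hd <- tryCatch(
      harmonize(subset_sumstats(tab, usable), outcome,
                palindrome_maf_threshold = config$palindrome_maf),
      error = function(e) NULL)
    if (is.null(hd) || nrow(mr_pairs(hd)) == 0) {
      reports[[id]] <- .protein_report(id, "failed_harmonization",
                                       instruments = instr)
      next
    }
    hd$exposure_id <- id
    est <- tryCatch({
      if (nrow(mr_pairs(hd)) == 1) {
        wald_ratio(hd, se_order = config$wald_se_order,
                   exposure_id = id, outcome_id = outcome$trait_id)
      } else {
        mr_ivw(hd)
      }
    }, error = function(e) NULL)
    if (is.null(est)) {
      reports[[id]] <- .protein_report(id, "failed_estimation",
                                       instruments = instr)
      next
    }
    rep <- .protein_report(id, "tested", instruments = instr, estimate = est)
    rep$hd <- hd
    reports[[id]] <- rep
  }

  # FDR across all tested proteins
  tested <- names(reports)[vapply(reports, function(r) r$status == "tested",
                                  logical(1))]
  if (length(tested)) {
    pv <- vapply(reports[tested], function(r) r$estimate$pval, numeric(1))
    fdr <- bh_fdr(pv, q = config$fdr_q)
    for (k in seq_along(tested)) {
      reports[[tested[k]]]$fdr_adjusted_p <- fdr$adjusted[k]
      reports[[tested[k]]]$significant <- fdr$reject[k]
    }
  }

  # downstream analyses for FDR-significant proteins
  for (id in tested) {
    rep <- reports[[id]]
    if (!rep$significant) next
    tab <- proteins[[id]]
    lead <- rep$instruments[1, ]
    rep$coloc <- tryCatch(
      coloc_sumstats(tab, outcome, cfg = config$coloc,
                     chrom = lead$chrom, center_pos = lead$pos),
      error = function(e) NULL)
    if (!is.null(phewas)) {
      rep$confounder_counts <- screen_confounders(lead$rsid, phewas,
                                                  p_threshold = config$p_max)
    }
    if (!is.null(mediator)) {
      rep$mediation <- tryCatch({
        hd1 <- harmonize(subset_sumstats(tab, mr_pairs(rep$hd)$rsid),
                         mediator$table,
                         palindrome_maf_threshold = config$palindrome_maf)
        hd1$exposure_id <- id
        step1 <- if (nrow(mr_pairs(hd1)) == 1) {
          wald_ratio(hd1, se_order = config$wald_se_order, exposure_id = id,
                     outcome_id = mediator$table$trait_id)
        } else mr_ivw(hd1)
        med_exp <- subset_sumstats(mediator$table, mediator$instruments)
        med_exp$trait_type <- "exposure"
        hd2 <- harmonize(med_exp, outcome,
                         palindrome_maf_threshold = config$palindrome_maf)
        step2 <- if (nrow(mr_pairs(hd2)) == 1) {
          wald_ratio(hd2, se_order = config$wald_se_order,
                     exposure_id = mediator$table$trait_id,
                     outcome_id = outcome$trait_id)
        } else mr_ivw(hd2)
        two_step_mediation(step1, step2, total = rep$estimate)
      }, error = function(e) NULL)
    }
    if (isTRUE(config$do_reverse)) {
      rep$reverse <- tryCatch({
        out_instr <- select_instruments(outcome, p_max = config$p_max,
                                        f_min = config$f_min,
                                        ld = ld_for(id),
                                        r2_clump = config$r2_clump)
        out_exp <- subset_sumstats(outcome, out_instr$rsid)
        out_exp$trait_type <- "exposure"
        hd_rev <- harmonize(out_exp, tab,
                            palindrome_maf_threshold = config$palindrome_maf)
        reverse_mr(hd_rev, n_boot = config$n_boot, seed = config$seed)
      }, error = function(e) NULL)
    }
    r2 <- .instrument_r2(rep$instruments)
    if (!is.na(r2) && r2 > 0 && r2 < 1) {
      rep$power <- mr_power(median(outcome$data$n), r2, rep$estimate$beta,
                            alpha = config$power_alpha)
    }
    reports[[id]] <- rep
  }

  results <- do.call(rbind, lapply(reports, function(r) {
    est <- r$estimate
    data.frame(
      protein = r$protein, status = r$status,
      n_instruments = if (is.null(r$instruments)) 0L else nrow(r$instruments),
      lead_instrument = if (!is.null(r$instruments) && nrow(r$instruments)) {
        r$instruments$rsid[1]
      } else NA_character_,
      method = if (is.null(est)) NA_character_ else est$method,
      n_snp = if (is.null(est)) NA_integer_ else est$n_snp,
      beta = if (is.null(est)) NA_real_ else est$beta,
      se = if (is.null(est)) NA_real_ else est$se,
      ci_low = if (is.null(est)) NA_real_ else est$ci_low,
      ci_high = if (is.null(est)) NA_real_ else est$ci_high,
      pval = if (is.null(est)) NA_real_ else est$pval,
      fdr_adjusted_p = r$fdr_adjusted_p,
      significant = r$significant,
      pp_h4 = if (is.null(r$coloc)) NA_real_ else unname(r$coloc$pp[5]),
      pp_h3 = if (is.null(r$coloc)) NA_real_ else unname(r$coloc$pp[4]),
      coloc_verdict = if (is.null(r$coloc)) NA_character_ else r$coloc$verdict,
      power = r$power,
      stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL

  statuses <- results$status
  summary <- list(
    n_proteins = length(proteins),
    no_annotation = sum(statuses == "no_annotation"),
    no_instrument = sum(statuses == "no_instrument"),
    instrumented = sum(!statuses %in% c("no_annotation", "no_instrument")),
    not_testable = sum(statuses == "not_testable"),
    failed_harmonization = sum(statuses == "failed_harmonization"),
    failed_estimation = sum(statuses == "failed_estimation"),
    tested = sum(statuses == "tested"),
    significant = sum(results$significant),
    colocalized = sum(results$coloc_verdict == "colocalized", na.rm = TRUE),
    fdr_q = config$fdr_q)

  structure(list(results = results, reports = reports, summary = summary,
                 config = config),
            class = "pwmr_result")
}

#' @export
print.pwmr_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<pwmr_result> %d proteins: %d instrumented, %d tested, ",
    "%d FDR-significant (q = %g), %d colocalized\n"),
    s$n_proteins, s$instrumented, s$tested, s$significant, s$fdr_q,
    s$colocalized))
  invisible(x)
}

#' Write the per-protein results table and summary
#'
#' Emits `results.tsv` (one row per protein) and `summary.json` under
#' `dir`.
#'
#' @param x A `pwmr_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pwmr_result <- function(x, dir) {
  stopifnot(inherits(x, "pwmr_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(x$results, file.path(dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the pipeline from a declarative config file
#'
#' Reads a YAML (or JSON) configuration with keys `exposures` (named map
#' of gene id to summary-stat TSV path), `outcome`, `annotations`, and
#' optionally `ld`, `phewas`, `mediator` (`table` + `instruments`), plus
#' any threshold overrides accepted by [pwmr_config()], then calls
#' [run_pwmr()].
#'
#' @param path Path to the config file.
#' @return A `pwmr_result`.
#' @export
run_pwmr_files <- function(path) {
  cfg <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  }
  for (key in c("exposures", "outcome", "annotations")) {
    if (is.null(cfg[[key]])) stop("config lacks required key '", key, "'")
  }
  proteins <- lapply(names(cfg$exposures), function(id) {
    read_sumstats(cfg$exposures[[id]], trait_id = id, trait_type = "exposure")
  })
  names(proteins) <- names(cfg$exposures)
  outcome <- read_sumstats(cfg$outcome, trait_id = "outcome",
                           trait_type = "outcome")
  annotations <- read_gene_annotation(cfg$annotations)
  ld <- if (!is.null(cfg$ld)) read_ld_matrix(cfg$ld)
  phewas <- if (!is.null(cfg$phewas)) {
    read.delim(cfg$phewas, sep = "\t", stringsAsFactors = FALSE)
  }
  mediator <- if (!is.null(cfg$mediator)) {
    list(table = read_sumstats(cfg$mediator$table, trait_id = "mediator",
                               trait_type = "mediator"),
         instruments = as.character(cfg$mediator$instruments))
  }
  opts <- cfg[intersect(names(cfg), names(formals(pwmr_config)))]
  config <- do.call(pwmr_config, opts)
  run_pwmr(proteins, outcome, annotations, ld = ld, phewas = phewas,
           mediator = mediator, config = config)
}
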