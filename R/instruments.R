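# cis-pQTL instrument selection, instrument strength, LD clumping, proxies.

#' Build a validated LD correlation matrix
#'
#' @param r Square numeric matrix of pairwise allelic correlations in
#'   \[-1, 1\], symmetric with unit diagonal.
#' @param rsids Variant identifiers (defaults to `rownames(r)`).
#' @return The matrix with `dimnames` set and class `ld_matrix`.
#' @export
ld_matrix <- function(r, rsids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(rsids) || length(rsids) != nrow(r)) {
    stop("rsids must match the LD matrix dimension")
  }
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (min(r) < -1 - 1e-8 || max(r) > 1 + 1e-8) {
    stop("LD correlations must lie in [-1, 1]")
  }
  dimnames(r) <- list(rsids, rsids)
  class(r) <- c("ld_matrix", class(matrix()))
  r
}

#' Read an LD matrix from text
#'
#' Format: first line holds whitespace-separated rsids; each following line
#' is one row of the correlation matrix.
#'
#' @param path Path to the file.
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path) {
  lines <- readLines(path)
  rsids <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  r <- do.call(rbind, vals)
  ld_matrix(r, rsids)
}

#' Write an LD matrix to text
#'
#' @param ld An [ld_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(ld), collapse = " "), con)
  for (i in seq_len(nrow(ld))) {
    writeLines(paste(sprintf("%.17g", ld[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a gene annotation table (`gene_id chrom tss`, tab-delimited)
#'
#' @param path Path to the file.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  d <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("gene_id", "chrom", "tss")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  d$tss <- as.integer(d$tss)
  if (any(is.na(d$tss) | d$tss < 1L)) stop("tss must be a positive integer")
  d[need]
}

#' Single-SNP instrument strength (F-statistic)
#'
#' Uses the single-instrument approximation `F = (beta / se)^2`, the square
#' of the Wald z-score of the SNP-exposure association.  `F > 10` is the
#' conventional weak-instrument cutoff.
#'
#' @param beta,se Effect and standard error (vectorized).
#' @return Non-negative F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

# Greedy p-value-ordered LD clumping.  `order` must already be the desired
# priority (ascending p, ties by rsid).  Variants missing from `ld` are
# treated as independent.
.greedy_clump <- function(rsids, ld, r2_clump) {
  kept <- character(0)
  for (r in rsids) {
    if (!length(kept)) {
      kept <- r
      next
    }
    if (!(r %in% rownames(ld))) {
      kept <- c(kept, r)
      next
    }
    others <- intersect(kept, rownames(ld))
    r2 <- if (length(others)) ld[r, others]^2 else numeric(0)
    if (!length(r2) || max(r2) <= r2_clump) kept <- c(kept, r)
  }
  kept
}

#' Select cis-pQTL instruments for a protein
#'
#' Retains variants within `window` bp of the gene's transcription start
#' site, with association p-value at or below `p_max` and F-statistic
#' strictly above `f_min`.  If an LD matrix is supplied, greedy clumping in
#' ascending p-value order removes any variant with `r^2 > r2_clump` to a
#' variant already retained, leaving an LD-independent instrument set.
#' Output order is deterministic: ascending p-value, ties broken by rsid.
#'
#' @param table [sumstat_table] of the exposure (protein) GWAS.
#' @param gene One-row data.frame or list with `gene_id`, `chrom`, `tss`.
#' @param window cis window around the TSS in bp (default 1e6).
#' @param p_max Genome-wide significance threshold (default 5e-8).
#' @param f_min Minimum instrument strength, exclusive (default 10).
#' @param ld Optional [ld_matrix] for clumping.
#' @param r2_clump Maximum allowed squared correlation between retained
#'   instruments (default 0.001).
#' @return data.frame of instruments with columns `rsid, gene_id, chrom,
#'   pos, ea, nea, beta_x, se_x, eaf, pval, n, f_stat, distance_to_tss`;
#'   zero rows when nothing passes the filters.
#' @export
select_cis_instruments <- function(table, gene, window = 1e6, p_max = 5e-8,
                                   f_min = 10, ld = NULL, r2_clump = 0.001) {
  stopifnot(inherits(table, "sumstat_table"))
  gene <- as.list(gene)
  d <- table$data
  dist <- d$pos - as.integer(gene$tss)
  keep <- d$chrom == as.character(gene$chrom) &
    abs(dist) <= window &
    d$pval <= p_max
  d <- d[keep, , drop = FALSE]
  dist <- dist[keep]
  if (nrow(d)) {
    f <- f_statistic(d$beta, d$se)
    keep2 <- f > f_min
    d <- d[keep2, , drop = FALSE]
    dist <- dist[keep2]
    f <- f[keep2]
  } else {
    f <- numeric(0)
  }
  o <- order(d$pval, d$rsid)
  d <- d[o, , drop = FALSE]
  dist <- dist[o]
  f <- f[o]
  if (!is.null(ld) && nrow(d) > 1) {
    kept <- .greedy_clump(d$rsid, ld, r2_clump)
    sel <- d$rsid %in% kept
    d <- d[sel, , drop = FALSE]
    dist <- dist[sel]
    f <- f[sel]
  }
  data.frame(rsid = d$rsid, gene_id = rep(gene$gene_id, nrow(d)),
             chrom = d$chrom, pos = d$pos, ea = d$ea, nea = d$nea,
             beta_x = d$beta, se_x = d$se, eaf = d$eaf, pval = d$pval,
             n = d$n, f_stat = f, distance_to_tss = dist,
             stringsAsFactors = FALSE)
}

#' Select genome-wide instruments without a cis constraint
#'
#' Used for outcome traits (e.g. BMI instruments in reverse MR) and
#' mediators: p-value and F filters plus optional LD clumping, identical to
#' [select_cis_instruments()] but without the TSS window.
#'
#' @inheritParams select_cis_instruments
#' @return data.frame of instruments (same columns as
#'   [select_cis_instruments()], minus `gene_id` / `distance_to_tss`).
#' @export
select_instruments <- function(table, p_max = 5e-8, f_min = 10,
                               ld = NULL, r2_clump = 0.001) {
  stopifnot(inherits(table, "sumstat_table"))
  d <- table$data
  d <- d[d$pval <= p_max, , drop = FALSE]
  if (nrow(d)) {
    f <- f_statistic(d$beta, d$se)
    d <- d[f > f_min, , drop = FALSE]
  }
  o <- order(d$pval, d$rsid)
  d <- d[o, , drop = FALSE]
  if (!is.null(ld) && nrow(d) > 1) {
    kept <- .greedy_clump(d$rsid, ld, r2_clump)
    d <- d[d$rsid %in% kept, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Find an LD proxy for a variant in an outcome table
#'
#' Returns the variant present in `outcome` with the largest squared
#' correlation to `rsid`, provided it reaches `r2_min`; ties are broken by
#' rsid string order.  A query that is itself present in the outcome table
#' is its own proxy (`r^2 = 1`).
#'
#' @param rsid Query variant (must be present in `ld`).
#' @param outcome [sumstat_table] in which a proxy is sought.
#' @param ld [ld_matrix] covering the query and candidate variants.
#' @param r2_min Minimum squared correlation for a usable proxy
#'   (default 0.8).
#' @return The proxy rsid, or `NA_character_` when no candidate reaches
#'   `r2_min`.
#' @export
find_proxy <- function(rsid, outcome, ld, r2_min = 0.8) {
  stopifnot(inherits(outcome, "sumstat_table"))
  if (!(rsid %in% rownames(ld))) {
    stop("variant '", rsid, "' not present in the LD matrix")
  }
  cand <- intersect(rownames(ld), outcome$data$rsid)
  if (!length(cand)) return(NA_character_)
  r2 <- ld[rsid, cand]^2
  o <- order(-r2, cand)
  best <- cand[o[1]]
  if (r2[o[1]] >= r2_min) best else NA_character_
}
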