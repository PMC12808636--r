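# GWAS summary statistics: container, I/O and allele harmonization.

SUMSTAT_COLS <- c("rsid", "chrom", "pos", "ea", "nea", "eaf", "beta",
                  "se", "pval", "n")

#' Build a summary-statistic table for one trait
#'
#' Wraps per-variant GWAS association records into a validated container.
#' Each record carries the variant identifier, location, effect (`ea`) and
#' other (`nea`) alleles, effect-allele frequency, the per-allele effect
#' `beta` in SD units of the trait with its standard error, the two-sided
#' p-value and the sample size.  Rows that violate basic range constraints
#' (duplicated rsid, `se <= 0`, `eaf` outside (0,1), `pval` outside (0,1],
#' `n <= 0`, identical alleles) are dropped with a message stating the count.
#'
#' Rows where the reported p-value is grossly inconsistent with the normal
#' z-statistic `beta/se` (more than 10% relative disagreement on the z scale)
#' trigger a warning but are retained, since rounding in published tables can
#' exceed that bound without invalidating the record.
#'
#' @param data data.frame with columns `rsid, chrom, pos, ea, nea, eaf, beta,
#'   se, pval, n` (`eaf` may be `NA`).
#' @param trait_id Identifier of the trait (e.g. protein or outcome name).
#' @param trait_type One of `"exposure"`, `"outcome"`, `"mediator"`.
#' @return An object of class `sumstat_table`: a list with elements
#'   `trait_id`, `trait_type` and `data`.
#' @export
sumstat_table <- function(data, trait_id,
                          trait_type = c("exposure", "outcome", "mediator")) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTAT_COLS, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[SUMSTAT_COLS]
  data$rsid <- as.character(data$rsid)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$ea <- toupper(as.character(data$ea))
  data$nea <- toupper(as.character(data$nea))
  for (col in c("eaf", "beta", "se", "pval")) data[[col]] <- as.numeric(data[[col]])
  data$n <- as.integer(round(as.numeric(data$n)))

  ok <- !is.na(data$rsid) & nzchar(data$rsid) &
    !duplicated(data$rsid) &
    !is.na(data$pos) & data$pos >= 1L &
    !is.na(data$ea) & !is.na(data$nea) & data$ea != data$nea &
    (is.na(data$eaf) | (data$eaf > 0 & data$eaf < 1)) &
    !is.na(data$se) & data$se > 0 &
    !is.na(data$beta) &
    !is.na(data$pval) & data$pval > 0 & data$pval <= 1 &
    !is.na(data$n) & data$n > 0L
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf("sumstat_table('%s'): dropped %d invalid row(s)",
                    trait_id, n_bad))
  }
  data <- data[ok, , drop = FALSE]
  if (!nrow(data)) stop("no parseable rows for trait '", trait_id, "'")
  rownames(data) <- NULL

  # z / p coherence check (warn only; published tables are rounded)
  z <- abs(data$beta / data$se)
  z_p <- qnorm(pmin(data$pval, 1) / 2, lower.tail = FALSE)
  check <- is.finite(z_p) & z > 1 & data$pval < 0.5
  bad_zp <- sum(check & abs(z_p - z) / pmax(z, 1e-12) > 0.10)
  if (bad_zp > 0) {
    warning(sprintf(
      "sumstat_table('%s'): %d row(s) have p-values inconsistent with beta/se (>10%% on z scale)",
      trait_id, bad_zp))
  }

  structure(list(trait_id = trait_id, trait_type = trait_type, data = data),
            class = "sumstat_table")
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("<sumstat_table> %s (%s): %d variants\n",
              x$trait_id, x$trait_type, nrow(x$data)))
  print(head(x$data, 5))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Expects a tab-delimited file with a header; `"."` encodes missing values.
#' Arbitrary column names are mapped onto the canonical set through
#' `dialect`, a named character vector whose names are the canonical columns
#' (`rsid, chrom, pos, ea, nea, eaf, beta, se, pval, n`) and whose values are
#' the corresponding headers in the file.
#'
#' @inheritParams sumstat_table
#' @param path Path to the file.
#' @param dialect Optional named character vector renaming file headers onto
#'   canonical column names.
#' @param sep Field separator (tab by default).
#' @return A [sumstat_table].
#' @export
read_sumstats <- function(path, trait_id, trait_type = "exposure",
                          dialect = NULL, sep = "\t") {
  raw <- read.delim(path, sep = sep, header = TRUE, na.strings = ".",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    bad <- setdiff(unname(dialect), names(raw))
    if (length(bad)) {
      stop("dialect refers to column(s) absent from file: ",
           paste(bad, collapse = ", "))
    }
    for (canon in names(dialect)) {
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(SUMSTAT_COLS, names(raw))
  if (length(missing_cols)) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sumstat_table(raw, trait_id = trait_id, trait_type = trait_type)
}

#' Write a summary-statistic table to tab-delimited text
#'
#' Numeric fields are written with enough digits (`%.17g`) that a
#' write/read round trip reproduces the values exactly; missing values are
#' written as `"."`.
#'
#' @param x A [sumstat_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstat_table"))
  d <- x$data
  fmt <- function(v) ifelse(is.na(v), ".", sprintf("%.17g", v))
  out <- data.frame(rsid = d$rsid, chrom = d$chrom, pos = d$pos,
                    ea = d$ea, nea = d$nea,
                    eaf = fmt(d$eaf), beta = fmt(d$beta), se = fmt(d$se),
                    pval = fmt(d$pval), n = d$n,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a summary-statistic table to a set of variants
#'
#' @param x A [sumstat_table].
#' @param rsids Variant identifiers to keep (order preserved from `x`).
#' @return A [sumstat_table] with only the matching records.
#' @export
subset_sumstats <- function(x, rsids) {
  stopifnot(inherits(x, "sumstat_table"))
  keep <- x$data$rsid %in% rsids
  if (!any(keep)) {
    stop("none of the requested variants are present in '", x$trait_id, "'")
  }
  x$data <- x$data[keep, , drop = FALSE]
  rownames(x$data) <- NULL
  x
}

#' Is a SNP palindromic (strand-ambiguous)?
#'
#' A biallelic SNP is palindromic when its two alleles are complementary
#' (A/T or C/G), so the same pair of alleles is observed on either strand.
#' Returns `NA` for non-SNP alleles (length > 1), which are outside the
#' palindrome logic.
#'
#' @param ea,nea Effect and other allele (single bases, vectorized).
#' @return Logical vector; `NA` where either allele is not a single base.
#' @export
is_palindromic <- function(ea, nea) {
  ea <- toupper(as.character(ea))
  nea <- toupper(as.character(nea))
  out <- rep(NA, length(ea))
  snp <- nchar(ea) == 1L & nchar(nea) == 1L &
    ea %in% c("A", "C", "G", "T") & nea %in% c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out[snp] <- comp[ea[snp]] == nea[snp]
  out
}

.complement <- function(a) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(a, ""), function(ch) {
    if (all(ch %in% names(comp))) paste(rev(comp[ch]), collapse = "") else NA_character_
  }, character(1))
}

#' Construct a harmonized exposure/outcome dataset
#'
#' Low-level constructor used by [harmonize()] and by simulation helpers that
#' assemble harmonized pairs directly.  `pairs` must contain the columns
#' `rsid, ea, nea, beta_x, se_x, eaf_x, beta_y, se_y, eaf_y, action,
#' excluded, exclusion_reason`.
#'
#' @param pairs data.frame of harmonized per-variant pairs.
#' @param exposure_id,outcome_id Trait identifiers.
#' @return An object of class `harmonized_dataset`.
#' @export
harmonized_dataset <- function(pairs, exposure_id, outcome_id) {
  need <- c("rsid", "ea", "nea", "beta_x", "se_x", "eaf_x",
            "beta_y", "se_y", "eaf_y", "action", "excluded",
            "exclusion_reason")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) {
    stop("pairs lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(pairs$rsid)) stop("duplicate rsids in harmonized pairs")
  bad <- pairs$excluded != (nzchar(pairs$exclusion_reason))
  if (any(bad)) stop("exclusion_reason must be nonempty iff excluded")
  rownames(pairs) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 pairs = pairs),
            class = "harmonized_dataset")
}

#' @export
print.harmonized_dataset <- function(x, ...) {
  cat(sprintf("<harmonized_dataset> %s ~ %s: %d pairs (%d excluded)\n",
              x$exposure_id, x$outcome_id, nrow(x$pairs),
              sum(x$pairs$excluded)))
  invisible(x)
}

#' Non-excluded pairs of a harmonized dataset
#'
#' @param data A [harmonized_dataset].
#' @return data.frame of the pairs with `excluded == FALSE`.
#' @export
mr_pairs <- function(data) {
  stopifnot(inherits(data, "harmonized_dataset"))
  data$pairs[!data$pairs$excluded, , drop = FALSE]
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Takes the intersection of variants by rsid and aligns the outcome effect
#' to the exposure's effect allele:
#' \itemize{
#' \item identical allele pairs are kept as-is (`action = "aligned"`);
#' \item swapped alleles have the outcome beta negated and `eaf` replaced by
#'   `1 - eaf` (`action = "flipped"`); for non-palindromic SNPs a strand
#'   (complement) representation difference is resolved the same way;
#' \item palindromic SNPs (A/T, C/G) cannot be aligned from allele labels.
#'   When the minor allele frequency exceeds `palindrome_maf_threshold` in
#'   either study the variant is excluded
#'   (`reason = "palindromic_intermediate_maf"`); otherwise strand is
#'   inferred by effect-allele-frequency concordance: the outcome is flipped
#'   iff `|eaf_x - eaf_y| > |eaf_x - (1 - eaf_y)|` (`action =
#'   "freq_inferred"`).  Palindromic SNPs lacking a frequency in either
#'   study are excluded (`reason = "palindromic_missing_eaf"`);
#' \item allele pairs that cannot be reconciled are excluded
#'   (`reason = "allele_mismatch"`).
#' }
#'
#' @param exposure,outcome [sumstat_table] objects.
#' @param palindrome_maf_threshold Palindromic SNPs with
#'   `min(eaf, 1 - eaf)` strictly above this value in either study are
#'   excluded as strand-ambiguous (default 0.42).
#' @return A [harmonized_dataset].
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_threshold = 0.42) {
  stopifnot(inherits(exposure, "sumstat_table"),
            inherits(outcome, "sumstat_table"))
  if (palindrome_maf_threshold <= 0 || palindrome_maf_threshold >= 0.5) {
    stop("palindrome_maf_threshold must be in (0, 0.5)")
  }
  common <- intersect(exposure$data$rsid, outcome$data$rsid)
  if (!length(common)) {
    stop(sprintf("no shared variants between '%s' and '%s'",
                 exposure$trait_id, outcome$trait_id))
  }
  ex <- exposure$data[match(common, exposure$data$rsid), ]
  ou <- outcome$data[match(common, outcome$data$rsid), ]
  n <- length(common)

  action <- rep("aligned", n)
  excluded <- rep(FALSE, n)
  reason <- rep("", n)
  beta_y <- ou$beta
  eaf_y <- ou$eaf

  pal <- is_palindromic(ex$ea, ex$nea)
  for (i in seq_len(n)) {
    same <- ex$ea[i] == ou$ea[i] && ex$nea[i] == ou$nea[i]
    swap <- ex$ea[i] == ou$nea[i] && ex$nea[i] == ou$ea[i]
    if (isTRUE(pal[i])) {
      # palindrome: allele labels cannot distinguish strand
      if (!(same || swap)) {
        excluded[i] <- TRUE; reason[i] <- "allele_mismatch"; next
      }
      if (is.na(ex$eaf[i]) || is.na(ou$eaf[i])) {
        excluded[i] <- TRUE; reason[i] <- "palindromic_missing_eaf"; next
      }
      maf_x <- min(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- min(ou$eaf[i], 1 - ou$eaf[i])
      if (maf_x > palindrome_maf_threshold || maf_y > palindrome_maf_threshold) {
        excluded[i] <- TRUE; reason[i] <- "palindromic_intermediate_maf"; next
      }
      flip <- abs(ex$eaf[i] - ou$eaf[i]) > abs(ex$eaf[i] - (1 - ou$eaf[i]))
      if (flip) {
        beta_y[i] <- -ou$beta[i]
        eaf_y[i] <- 1 - ou$eaf[i]
      }
      action[i] <- "freq_inferred"
    } else {
      # non-palindromic SNP or indel: exact or swapped match, with a
      # complement (strand) retry for SNPs only
      if (same) {
        action[i] <- "aligned"
      } else if (swap) {
        beta_y[i] <- -ou$beta[i]
        eaf_y[i] <- if (is.na(ou$eaf[i])) NA_real_ else 1 - ou$eaf[i]
        action[i] <- "flipped"
      } else if (!is.na(pal[i])) {
        cea <- .complement(ou$ea[i]); cnea <- .complement(ou$nea[i])
        if (identical(ex$ea[i], cea) && identical(ex$nea[i], cnea)) {
          action[i] <- "aligned"
        } else if (identical(ex$ea[i], cnea) && identical(ex$nea[i], cea)) {
          beta_y[i] <- -ou$beta[i]
          eaf_y[i] <- if (is.na(ou$eaf[i])) NA_real_ else 1 - ou$eaf[i]
          action[i] <- "flipped"
        } else {
          excluded[i] <- TRUE; reason[i] <- "allele_mismatch"
        }
      } else {
        excluded[i] <- TRUE; reason[i] <- "allele_mismatch"
      }
    }
  }

  action[excluded] <- "excluded"
  pairs <- data.frame(
    rsid = common, ea = ex$ea, nea = ex$nea,
    beta_x = ex$beta, se_x = ex$se, eaf_x = ex$eaf,
    pval_x = ex$pval, n_x = ex$n,
    beta_y = beta_y, se_y = ou$se, eaf_y = eaf_y,
    pval_y = ou$pval, n_y = ou$n,
    action = action, excluded = excluded, exclusion_reason = reason,
    stringsAsFactors = FALSE)
  harmonized_dataset(pairs, exposure$trait_id, outcome$trait_id)
}

#' Write the harmonization exclusion audit trail
#'
#' One row per excluded variant: `rsid exposure outcome reason`.
#'
#' @param data A [harmonized_dataset].
#' @param path Output TSV path.
#' @param append Append to an existing audit file (without re-writing the
#'   header) rather than overwrite.
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(data, path, append = FALSE) {
  stopifnot(inherits(data, "harmonized_dataset"))
  excl <- data$pairs[data$pairs$excluded, , drop = FALSE]
  out <- data.frame(rsid = excl$rsid,
                    exposure = rep(data$exposure_id, nrow(excl)),
                    outcome = rep(data$outcome_id, nrow(excl)),
                    reason = excl$exclusion_reason,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !append, append = append)
  invisible(path)
}
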