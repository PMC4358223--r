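#' Marker and sample quality control
#'
#' Implements the standard chip-QC filters applied before genomic evaluation:
#' sample call rate, SNP call rate, minor allele frequency, Hardy-Weinberg
#' equilibrium and removal of sex-chromosome markers. Filters are per-sample /
#' per-SNP predicates, so they are idempotent and their order (within a
#' level) does not change the retained set.
#'
#' @param geno allele-dose matrix (`NA` = missing) with a `map` attribute.
#' @param min_call_rate minimum fraction of non-missing genotypes for a
#'   sample (default 0.90) or SNP (default 0.98).
#' @return a list with elements `geno` (the filtered matrix) and `report`
#'   (a `qc_report`: counts in/out and per-rule removal counts).
#' @examples
#' ped <- sim_pedigree(30, 1, seed = 1)
#' g <- gene_drop(ped, 100, seed = 1)
#' res <- filter_snps(g, min_maf = 0.05)
#' res$report
#' @export
filter_samples <- function(geno, min_call_rate = 0.90) {
  cr <- rowMeans(!is.na(geno))
  keep <- cr >= min_call_rate
  if (!any(keep)) stop("all samples removed by call-rate filter")
  out <- geno[keep, , drop = FALSE]
  attr(out, "map") <- attr(geno, "map")
  rep <- qc_report(n_samples_in = nrow(geno), n_samples_out = sum(keep),
                   n_snps_in = ncol(geno), n_snps_out = ncol(geno),
                   removed = c(sample_call_rate = sum(!keep)),
                   thresholds = c(min_sample_call_rate = min_call_rate))
  list(geno = out, report = rep)
}

#' @param min_maf minimum minor-allele frequency (computed on the current
#'   sample).
#' @param autosomes_only drop SNPs whose map chromosome is X/Y/XY/MT (dog
#'   autosomes are labelled 1-38).
#' @param hwe_alpha nominal significance level for the HWE test before
#'   Bonferroni correction; the per-SNP threshold is
#'   `hwe_alpha / hwe_denominator`.
#' @param hwe_denominator Bonferroni denominator; defaults to the number of
#'   SNPs tested.
#' @rdname filter_samples
#' @export
filter_snps <- function(geno, min_call_rate = 0.98, min_maf = 0.01,
                        autosomes_only = TRUE, hwe_alpha = 0.05,
                        hwe_denominator = NULL) {
  map <- snp_map(geno)
  m <- ncol(geno)
  keep <- rep(TRUE, m)
  removed <- c(snp_call_rate = 0L, maf = 0L, hwe = 0L, sex_chromosome = 0L)

  cr <- colMeans(!is.na(geno))
  bad <- cr < min_call_rate
  removed["snp_call_rate"] <- sum(bad & keep)
  keep <- keep & !bad

  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad <- is.na(maf) | maf < min_maf
  removed["maf"] <- sum(bad & keep)
  keep <- keep & !bad

  if (is.null(hwe_denominator)) hwe_denominator <- max(sum(keep), 1L)
  thr <- hwe_alpha / hwe_denominator
  pv <- apply(geno, 2, function(x) {
    x <- x[!is.na(x)]
    hwe_test(c(sum(x == 2), sum(x == 1), sum(x == 0)))
  })
  bad <- pv < thr
  removed["hwe"] <- sum(bad & keep)
  keep <- keep & !bad

  if (autosomes_only) {
    bad <- toupper(as.character(map$chr)) %in% c("X", "Y", "XY", "MT", "M",
                                                 "39", "40", "41")
    removed["sex_chromosome"] <- sum(bad & keep)
    keep <- keep & !bad
  }

  if (!any(keep)) stop("all SNPs removed by marker QC")
  out <- geno[, keep, drop = FALSE]
  attr(out, "map") <- map[keep, , drop = FALSE]
  rep <- qc_report(n_samples_in = nrow(geno), n_samples_out = nrow(geno),
                   n_snps_in = m, n_snps_out = sum(keep), removed = removed,
                   thresholds = c(min_snp_call_rate = min_call_rate,
                                  min_maf = min_maf,
                                  hwe_threshold = thr))
  list(geno = out, report = rep)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation at the estimated allele frequency.
#' Monomorphic SNPs return p = 1 (no test possible; the MAF filter removes
#' them separately).
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return the p-value.
#' @examples
#' hwe_test(c(25, 50, 25)) # exact HWE proportions: p = 1
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3 || any(counts < 0)) stop("need 3 non-negative counts")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - e)^2 / e)
  unname(pchisq(stat, df = 1, lower.tail = FALSE))
}

qc_report <- function(n_samples_in, n_samples_out, n_snps_in, n_snps_out,
                      removed, thresholds) {
  structure(list(n_samples_in = n_samples_in, n_samples_out = n_samples_out,
                 n_snps_in = n_snps_in, n_snps_out = n_snps_out,
                 removed = removed, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: samples %d -> %d, SNPs %d -> %d\n",
              x$n_samples_in, x$n_samples_out, x$n_snps_in, x$n_snps_out))
  for (k in names(x$removed))
    cat(sprintf("  removed by %-16s %d\n", paste0(k, ":"), x$removed[[k]]))
  invisible(x)
}

#' @export
format.qc_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
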