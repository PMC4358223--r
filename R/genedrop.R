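#' Gene-drop SNP genotypes down a pedigree
#'
#' Simulates phased biallelic genotypes for every pedigree animal by gene
#' dropping. Founder haplotypes are drawn at reference-allele frequencies
#' sampled so the minor-allele frequency falls in `founder_maf_range` (the
#' reference allele is the minor or major allele with equal probability);
#' with `ld_rho > 0`, founder haplotypes follow a first-order (AR(1))
#' dependence between adjacent loci, creating haplotype blocks. Non-founders
#' inherit one gamete per parent, formed by copying the parental haplotypes
#' with recombination along each chromosome (`morgans_per_chr` genetic
#' length, Haldane model on an evenly spaced map), so founder LD decays
#' realistically instead of being destroyed by independent per-locus
#' transmission. An animal with an unknown parent draws that gamete from the
#' founder distribution. Per-locus marginals are Hardy-Weinberg in founders
#' and Mendelian in offspring regardless of the LD settings.
#'
#' @param ped a validated `ped` data frame.
#' @param n_snps number of loci to simulate.
#' @param founder_maf_range length-2 numeric in (0, 0.5], range of founder
#'   minor-allele frequencies.
#' @param seed integer seed.
#' @param chromosomes number of autosomes over which to spread the map,
#'   labelled 1..chromosomes.
#' @param ld_rho AR(1) correlation between adjacent loci in founder
#'   haplotypes (0 = linkage equilibrium founders).
#' @param morgans_per_chr genetic length of each chromosome in Morgans.
#' @return integer allele-dose matrix (animals x SNPs, values 0/1/2) with
#'   rownames = animal ids, colnames = SNP names, and attributes `map`
#'   (data frame `chr`, `snp`, `pos`) and `founder_freq`.
#' @examples
#' ped <- sim_pedigree(20, 1, seed = 1)
#' g <- gene_drop(ped, n_snps = 50, seed = 2)
#' dim(g)
#' @export
gene_drop <- function(ped, n_snps, founder_maf_range = c(0.05, 0.5),
                      seed = 1L, chromosomes = 38L, ld_rho = 0,
                      morgans_per_chr = 1) {
  validate_pedigree(ped)
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (founder_maf_range[1] <= 0 || founder_maf_range[2] > 0.5 ||
      founder_maf_range[1] > founder_maf_range[2])
    stop("founder_maf_range must lie within (0, 0.5]")
  set.seed(seed)
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  maf <- runif(n_snps, founder_maf_range[1], founder_maf_range[2])
  flip <- runif(n_snps) < 0.5
  p <- ifelse(flip, 1 - maf, maf) # reference-allele frequency
  qn <- stats::qnorm(p)

  chr <- sort(rep(seq_len(chromosomes), length.out = n_snps))
  chr_start <- !duplicated(chr)
  # Haldane recombination fraction between adjacent loci on a chromosome
  rl <- morgans_per_chr / pmax(tabulate(chr)[chr] - 1, 1)
  r_adj <- 0.5 * (1 - exp(-2 * rl))
  r_adj[chr_start] <- 0.5 # independent chromosomes

  chr_idx <- split(seq_len(n_snps), chr)
  innov_sd <- sqrt(1 - ld_rho^2)
  founder_hap <- function() {
    if (ld_rho <= 0) return(rbinom(n_snps, 1L, p))
    z <- rnorm(n_snps)
    for (idx in chr_idx) { # stationary AR(1) restarted per chromosome
      x <- z[idx]
      if (length(x) > 1) x[-1] <- x[-1] * innov_sd
      z[idx] <- stats::filter(x, ld_rho, method = "recursive")
    }
    as.integer(z < qn)
  }
  gamete <- function(h1, h2) {
    sw <- runif(n_snps) < r_adj
    sw[chr_start] <- runif(sum(chr_start)) < 0.5
    use2 <- cumsum(sw) %% 2L == 1L
    ifelse(use2, h2, h1)
  }

  H1 <- matrix(0L, n, n_snps)
  H2 <- matrix(0L, n, n_snps)
  for (i in seq_len(n)) {
    H1[i, ] <- if (s[i] > 0L) gamete(H1[s[i], ], H2[s[i], ]) else founder_hap()
    H2[i, ] <- if (d[i] > 0L) gamete(H1[d[i], ], H2[d[i], ]) else founder_hap()
  }
  geno <- H1 + H2
  snp <- sprintf("snp%05d", seq_len(n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chr), seq_along),
                use.names = FALSE) * 1000L
  dimnames(geno) <- list(ped$id, snp)
  attr(geno, "map") <- data.frame(chr = chr, snp = snp, pos = pos)
  attr(geno, "founder_freq") <- p
  geno
}

#' SNP map metadata of a genotype matrix
#'
#' @param geno a dose matrix from [gene_drop()] or [read_plink()].
#' @return data frame with columns `chr`, `snp`, `pos`.
#' @export
snp_map <- function(geno) {
  m <- attr(geno, "map")
  if (is.null(m))
    m <- data.frame(chr = 1L, snp = colnames(geno),
                    pos = seq_len(ncol(geno)))
  m
}
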