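#' Simulate hip-score phenotypes on a pedigree
#'
#' Generates true breeding values (either infinitesimal via Mendelian
#' sampling down the pedigree, or from QTL effects on supplied genotypes),
#' adds fixed effects (sex, daily-exercise category, a weak age trend) and
#' residual noise on the latent log scale, and converts the liability to an
#' integer hip score and its 18 side-by-component scores. See
#' [trait_architecture()] for the generative model.
#'
#' @param ped a validated `ped` data frame.
#' @param arch a [trait_architecture()] object.
#' @param geno optional allele-dose matrix covering (at least) all pedigree
#'   animals; required when `arch$n_qtl > 0`.
#' @param seed integer seed.
#' @return list with elements
#'   \describe{
#'     \item{pheno}{data frame: `id`, `sex`, `age_days`, `exercise`, the 18
#'       per-side component columns (`NA_right`, `NA_left`, ...), the three
#'       laxity totals, `HS`, `THS`, `Index`.}
#'     \item{true_bv}{named vector of true breeding values (liability
#'       scale).}
#'     \item{true_qtl}{data frame (`snp`, `effect`) or `NULL` for the
#'       infinitesimal model.}
#'   }
#' @examples
#' ped <- sim_pedigree(60, 2, seed = 1)
#' sim <- sim_phenotypes(ped, trait_architecture(), seed = 1)
#' hist(sim$pheno$HS)
#' @export
sim_phenotypes <- function(ped, arch = trait_architecture(), geno = NULL,
                           seed = 1L) {
  validate_pedigree(ped)
  if (!inherits(arch, "trait_arch")) stop("arch must be a trait_architecture()")
  set.seed(seed)
  n <- nrow(ped)

  true_qtl <- NULL
  if (arch$n_qtl > 0L) {
    if (is.null(geno)) stop("QTL architecture requires genotypes")
    if (!all(as.character(ped$id) %in% rownames(geno)))
      stop("genotypes must cover every pedigree animal for QTL simulation")
    geno <- geno[as.character(ped$id), , drop = FALSE]
    m <- ncol(geno)
    if (arch$n_qtl > m) stop("more QTL requested than SNPs available")
    qtl <- sort(sample.int(m, arch$n_qtl))
    beta <- rnorm(arch$n_qtl, 0, arch$qtl_effect_sd)
    p <- colMeans(geno[, qtl, drop = FALSE]) / 2
    expvar <- sum(2 * p * (1 - p) * beta^2)
    if (expvar <= 0) stop("sampled QTL are monomorphic; increase MAF range")
    beta <- beta * sqrt(arch$sigma2_a / expvar)
    bv <- drop(sweep(geno[, qtl, drop = FALSE], 2, 2 * p) %*% beta)
    true_qtl <- data.frame(snp = colnames(geno)[qtl], effect = beta)
  } else {
    bv <- mendelian_bv(ped, arch$sigma2_a)
  }
  names(bv) <- ped$id

  age <- runif(n, 365, 1825)
  exercise <- sample(1:4, n, replace = TRUE, prob = c(0.15, 0.35, 0.35, 0.15))
  fixed <- arch$mean_liability +
    ifelse(ped$sex == "M", arch$sex_effect, 0) +
    arch$exercise_effects[exercise] +
    arch$age_effect_fn(age)
  liab <- fixed + bv + rnorm(n, 0, sqrt(arch$sigma2_e))
  hs <- pmin(pmax(round(exp(liab) - 1), 0), 106)

  comp <- allocate_components(hs, arch$component_loadings)
  right <- comp[, seq(1, 17, by = 2), drop = FALSE]
  left <- comp[, seq(2, 18, by = 2), drop = FALSE]
  colnames(right) <- paste0(hip_components, "_right")
  colnames(left) <- paste0(hip_components, "_left")
  totals <- right + left
  colnames(totals) <- paste0(hip_components, "_total")

  pheno <- data.frame(id = ped$id, sex = ped$sex, age_days = age,
                      exercise = exercise, check.names = FALSE)
  pheno <- cbind(pheno, right, left,
                 totals[, paste0(c("NA", "SUB", "CrAE"), "_total")])
  pheno$HS <- as.integer(hs)
  pheno$THS <- compute_ths(pheno$HS)
  pheno$Index <- compute_index(totals)
  list(pheno = pheno, true_bv = bv, true_qtl = true_qtl)
}

## infinitesimal breeding values: founder draws N(0, sigma2_a), offspring =
## mean of known parental values + Mendelian deviate with the exact
## inbreeding-adjusted variance, so cov(a) = sigma2_a * A by construction
mendelian_bv <- function(ped, sigma2_a) {
  n <- nrow(ped)
  if (sigma2_a == 0) return(numeric(n))
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  f <- inbreeding(ped)
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], -1)
  dvec <- 0.5 - 0.25 * (fs + fd)
  dvec[s == 0L & d == 0L] <- 1
  bv <- numeric(n)
  ms <- rnorm(n, 0, sqrt(sigma2_a * dvec))
  for (i in seq_len(n)) {
    pa <- 0
    if (s[i] > 0L) pa <- pa + 0.5 * bv[s[i]]
    if (d[i] > 0L) pa <- pa + 0.5 * bv[d[i]]
    bv[i] <- pa + ms[i]
  }
  bv
}

## split each animal's HS over the 18 side-by-component cells by a capped
## multinomial draw; overflow above a cell's scheme maximum is reallocated to
## the remaining open cells (feasible because sum of caps = 106 >= HS)
allocate_components <- function(hs, loadings) {
  caps <- rep(hip_component_max, each = 2) # r/l interleaved
  pr <- rep(loadings / 2, each = 2)
  out <- matrix(0L, length(hs), 18)
  colnames(out) <- paste0(rep(hip_components, each = 2), c("_r", "_l"))
  for (i in seq_along(hs)) {
    h <- hs[i]
    if (h == 0) next
    cell <- as.vector(rmultinom(1, h, pr))
    over <- cell > caps
    while (any(over)) {
      excess <- sum(cell[over] - caps[over])
      cell[over] <- caps[over]
      open <- which(cell < caps)
      add <- as.vector(rmultinom(1, excess, pmax(pr[open], 1e-9)))
      cell[open] <- cell[open] + add
      over <- cell > caps
    }
    out[i, ] <- cell
  }
  out
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper producing the structure the analysis assumes: a
#' multi-generation pedigree in which older cohorts are phenotyped but not
#' genotyped while the youngest cohort(s) carry both phenotypes and SNP
#' genotypes.
#'
#' @inheritParams sim_pedigree
#' @param n_snps number of SNPs to gene-drop (0 skips genotypes).
#' @param arch a [trait_architecture()].
#' @param genotyped_cohorts integer vector of cohort indices whose animals are
#'   genotyped; default the final cohort.
#' @param phenotyped_cohorts cohorts with phenotype records; default all
#'   non-founder cohorts.
#' @param founder_maf_range,ld_rho passed to [gene_drop()].
#' @param seed integer seed; internal stages use offsets of it.
#' @return list of class `chd_cohort`: `pedigree`, `genotypes` (genotyped
#'   subset only), `phenotypes` (phenotyped animals only), `true_bv`,
#'   `true_qtl`, `genotyped_ids`, `arch`.
#' @examples
#' co <- sim_chd_cohort(n_founders = 80, n_generations = 2, n_snps = 100,
#'                      seed = 1)
#' nrow(co$phenotypes); nrow(co$genotypes)
#' @export
sim_chd_cohort <- function(n_founders, n_generations, n_snps = 0L,
                           arch = trait_architecture(),
                           offspring_per_sire_mean = 1.63,
                           offspring_per_dam_mean = 1.10,
                           generation_size = n_founders,
                           genotyped_cohorts = n_generations,
                           phenotyped_cohorts = seq_len(n_generations),
                           founder_maf_range = c(0.05, 0.5),
                           ld_rho = 0, seed = 1L) {
  ped <- sim_pedigree(n_founders, n_generations,
                      offspring_per_sire_mean, offspring_per_dam_mean,
                      generation_size, seed = seed)
  geno_all <- NULL
  if (n_snps > 0L || arch$n_qtl > 0L) {
    if (n_snps < arch$n_qtl) stop("n_snps must be at least n_qtl")
    geno_all <- gene_drop(ped, n_snps, founder_maf_range, seed = seed + 1000L,
                          ld_rho = ld_rho)
  }
  sim <- sim_phenotypes(ped, arch, geno = geno_all, seed = seed + 2000L)
  gids <- ped$id[ped$cohort %in% genotyped_cohorts]
  pids <- ped$id[ped$cohort %in% phenotyped_cohorts]
  geno <- if (!is.null(geno_all)) {
    g <- geno_all[as.character(gids), , drop = FALSE]
    attr(g, "map") <- attr(geno_all, "map")
    g
  }
  structure(list(
    pedigree = ped,
    genotypes = geno,
    phenotypes = sim$pheno[sim$pheno$id %in% pids, , drop = FALSE],
    true_bv = sim$true_bv,
    true_qtl = sim$true_qtl,
    genotyped_ids = gids,
    arch = arch), class = "chd_cohort")
}

#' @export
print.chd_cohort <- function(x, ...) {
  cat(sprintf(
    "<chd_cohort: %d animals in pedigree, %d phenotyped, %d genotyped (%s SNPs)>\n",
    nrow(x$pedigree), nrow(x$phenotypes),
    length(x$genotyped_ids),
    if (is.null(x$genotypes)) "no" else ncol(x$genotypes)))
  invisible(x)
}
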