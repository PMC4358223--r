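test_that("fold partitions are balanced, exhaustive and deterministic", {
  f <- make_folds(1179, 5, seed = 1)
  expect_equal(sort(tabulate(f$fold, 5), decreasing = TRUE),
               c(236, 236, 236, 236, 235))
  expect_equal(1179 - min(tabulate(f$fold, 5)), 944) # largest training set
  expect_equal(tabulate(make_folds(10, 5, seed = 2)$fold, 5), rep(2L, 5))
  expect_identical(make_folds(100, 7, seed = 9)$fold,
                   make_folds(100, 7, seed = 9)$fold)
  for (n in c(7, 23, 100)) {
    for (k in c(2, 3, 5)) {
      fd <- make_folds(n, k, seed = n + k)$fold
      sizes <- tabulate(fd, k)
      expect_equal(sum(sizes), n)
      expect_lte(diff(range(sizes)), 1)
    }
  }
  expect_error(make_folds(3, 5), "k <= n")
})

test_that("predictive ability rescales the validation correlation", {
  pa <- predictive_ability(c(1, 2, 3, 4), c(1.1, 2.3, 2.9, 3.8), h2 = 0.25)
  expect_equal(pa$pa, pa$r / 0.5)
  # uncorrelated vectors give zero on both scales
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  pa0 <- predictive_ability(x, y, h2 = 0.5)
  expect_equal(pa0$r, 0); expect_equal(pa0$pa, 0)
  pa1 <- predictive_ability(c(1, 2, 3), c(3, 1, 2), h2 = 1)
  expect_equal(pa1$pa, pa1$r)
  expect_error(predictive_ability(1:3, c(2, 2, 2), 0.5), "zero variance")
  expect_error(predictive_ability(1:2, 1:2, 0.5), "3 paired")
  expect_error(predictive_ability(1:3, 1:3, 0), "h2")
})

test_that("marker subset sizes follow the ceiling rule", {
  snps <- sprintf("s%06d", seq_len(106282))
  sizes <- sapply(c(0.01, 0.10, 0.20, 0.50, 0.75),
                  function(f) length(select_snps(snps, f, "random", seed = 1)))
  expect_equal(sizes, c(1063L, 10629L, 21257L, 53141L, 79712L))
  expect_equal(select_snps(snps, 1, "random", seed = 1), snps)
  expect_error(select_snps(character(0), 0.5), "empty")
  expect_error(select_snps(snps, 0), "fraction")
  # random selection is without replacement and seed-stable
  s1 <- select_snps(snps, 0.01, "random", seed = 3)
  expect_equal(anyDuplicated(s1), 0L)
  expect_identical(s1, select_snps(snps, 0.01, "random", seed = 3))
  # top_gwas takes the head of the ranking
  expect_equal(select_snps(letters[1:10], 0.3, "top_gwas",
                           ranking = rev(letters[1:10])),
               c("j", "i", "h"))
})

test_that("single-marker regression matches the lm oracle", {
  set.seed(10)
  n <- 40
  g <- matrix(rbinom(n * 5, 2, 0.4), n, 5,
              dimnames = list(paste0("a", 1:n), paste0("s", 1:5)))
  y <- setNames(rnorm(n) + 0.6 * g[, 2], rownames(g))
  rk <- gwas_rank(y, g)
  for (j in 1:5) {
    ref <- summary(lm(y ~ g[, j]))$coefficients
    row <- rk[rk$index == j, ]
    expect_equal(row$beta, ref[2, 1], tolerance = 1e-10)
    expect_equal(row$p, ref[2, 4], tolerance = 1e-10)
  }
  expect_equal(rk$snp[1], "s2")
  # monomorphic marker gets p = 1
  g2 <- cbind(g, mono = 1L)
  expect_equal(gwas_rank(y, g2)$p[6], 1)
})

test_that("GWAS p-values are uniform under the null and find a real QTL", {
  set.seed(11)
  n <- 400
  g <- matrix(rbinom(n * 501, 2, runif(501, 0.1, 0.5)), n, 501, byrow = TRUE,
              dimnames = list(paste0("a", 1:n), paste0("s", 1:501)))
  ynull <- setNames(rnorm(n), rownames(g))
  pv <- gwas_rank(ynull, g)$p
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # QTL explaining ~20% of variance among 500 null SNPs ranks first
  firsts <- sapply(1:10, function(seed) {
    set.seed(100 + seed)
    x <- g[, 1]
    beta <- sqrt(0.2 / 0.8 / var(x))
    y <- setNames(x * beta + rnorm(n), rownames(g))
    gwas_rank(y, g)$index[1] == 1
  })
  expect_gte(mean(firsts), 0.9)
})

test_that("GWAS ranking is equivariant under marker relabeling", {
  set.seed(12)
  g <- matrix(rbinom(600, 2, 0.3), 60, 10,
              dimnames = list(paste0("a", 1:60), paste0("s", 1:10)))
  y <- setNames(rnorm(60), rownames(g))
  rk <- gwas_rank(y, g)
  perm <- sample(10)
  rk2 <- gwas_rank(y, g[, perm])
  expect_equal(rk2$snp[order(rk2$p)], rk$snp[order(rk$p)])
})

test_that("cross-validation is deterministic and honest under permutation", {
  co <- shared_cohort()
  vc <- list(sigma2_a = 0.16, sigma2_e = 0.24)
  cv1 <- cross_validate(co, "gblup", k = 5, seed = 3, varcomp = vc)
  cv2 <- cross_validate(co, "gblup", k = 5, seed = 3, varcomp = vc)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_equal(cv1$per_fold$pa * sqrt(cv1$h2), cv1$per_fold$r)
  # permuting phenotypes against genotypes destroys the signal
  cop <- co
  set.seed(13)
  perm <- sample(nrow(cop$phenotypes))
  keep <- c("id", "sex", "age_days", "exercise")
  cop$phenotypes[, setdiff(names(cop$phenotypes), keep)] <-
    cop$phenotypes[perm, setdiff(names(cop$phenotypes), keep)]
  cvp <- cross_validate(cop, "gblup", k = 5, seed = 3, varcomp = vc)
  expect_lt(abs(cvp$mean_r), 0.12)
  expect_lt(abs(cvp$mean_r), abs(cv1$mean_r))
})

test_that("validation phenotypes cannot influence their own GEBVs", {
  co <- shared_cohort()
  vc <- list(sigma2_a = 0.16, sigma2_e = 0.24)
  gids <- as.character(intersect(co$genotyped_ids, co$phenotypes$id))
  folds <- make_folds(length(gids), 5, seed = 4)
  val1 <- gids[folds$fold == 1]
  train <- setdiff(gids, val1)
  fit_ebv <- function(ph) {
    tr <- ph[ph$id %in% as.integer(train), ]
    lmfit <- lm(THS ~ sex + age_spline(age_days), data = tr)
    ytr <- setNames(tr$THS - predict(lmfit, newdata = tr), tr$id)
    coef(gp_fit("gblup", ytr[train], geno = co$genotypes,
                varcomp = vc))[val1]
  }
  ph2 <- co$phenotypes
  rows <- ph2$id %in% as.integer(val1)
  ph2$THS[rows] <- rev(ph2$THS[rows]) # perturb validation phenotypes only
  expect_identical(fit_ebv(co$phenotypes), fit_ebv(ph2))
})

test_that("genomic information beats shallow-pedigree prediction", {
  # only the genotyped cohorts carry phenotypes, so pedigree prediction can
  # lean only on the weak half-sib structure within them
  arch <- trait_architecture(n_qtl = 150, sigma2_a = 0.16, sigma2_e = 0.24)
  wins <- sapply(1:2, function(seed) {
    co <- sim_chd_cohort(300, 2, n_snps = 4000, arch = arch,
                         genotyped_cohorts = 1:2, phenotyped_cohorts = 1:2,
                         ld_rho = 0.95, seed = seed)
    vc <- list(sigma2_a = 0.16, sigma2_e = 0.24)
    gb <- cross_validate(co, "gblup", k = 5, seed = seed, varcomp = vc)
    bl <- cross_validate(co, "blup", k = 5, seed = seed, varcomp = vc)
    gb$mean_pa - bl$mean_pa
  })
  expect_gt(mean(wins), 0)
})

test_that("density experiment coincides for random and ranked at full density", {
  co <- shared_cohort()
  vc <- list(sigma2_a = 0.16, sigma2_e = 0.24)
  dens <- suppressMessages(
    density_experiment(co, fractions = 1, modes = c("random", "top_gwas",
                                                    "biased"),
                       k = 5, seed = 5, varcomp = vc))
  expect_equal(dens$mean_r[dens$mode == "top_gwas"],
               dens$mean_r[dens$mode == "random"], tolerance = 1e-10)
  expect_equal(dens$mean_r[dens$mode == "biased"],
               dens$mean_r[dens$mode == "random"], tolerance = 1e-10)
  expect_true(all(dens$n_snps == ncol(co$genotypes)))
})
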