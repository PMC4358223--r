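test_that("mixed-model solver reduces to ridge shrinkage in the scalar case", {
  K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
  expect_equal(unname(mixed_model_solve(c(a = 1), K, lambda = 1)["a"]), 0.5)
  expect_equal(unname(mixed_model_solve(c(a = 1), K, lambda = 3)["a"]), 0.25)
  # infinite-noise limit shrinks everything to zero
  expect_lt(max(abs(mixed_model_solve(c(a = 1, b = -2), K, lambda = 1e8))),
            1e-6)
  expect_error(mixed_model_solve(c(a = 1), K, lambda = 0), "positive")
  expect_error(mixed_model_solve(c(z = 1), K, lambda = 1), "absent")
})

test_that("covariance and precision parameterizations agree", {
  set.seed(3)
  ped <- sim_pedigree(20, 2, generation_size = 15, seed = 3)
  A <- a_matrix(ped)
  ids <- as.character(ped$id)
  y <- setNames(rnorm(10), ids[seq(5, 50, by = 5)])
  a_cov <- mixed_model_solve(y, A, lambda = 1.4)
  a_prec <- mixed_model_solve(y, a_inverse(ped), lambda = 1.4)
  expect_equal(a_cov, a_prec[names(a_cov)], tolerance = 1e-8)
})

test_that("GBLUP equals the ridge-regression back-solution", {
  for (seed in 1:3) {
    set.seed(seed)
    ped <- sim_pedigree(50, 1, seed = seed)
    g <- gene_drop(ped, 200, founder_maf_range = c(0.1, 0.5), seed = seed)
    train <- rownames(g)[1:60]
    y <- setNames(rnorm(60), train)
    for (lam in c(0.5, 2, 10)) {
      ebv <- coef(gp_fit("gblup", y, geno = g, lambda = lam))
      p <- colMeans(g) / 2
      Z <- sweep(sweep(g, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
      m <- ncol(Z); Zt <- Z[train, ]
      alpha <- t(Zt) %*% solve(Zt %*% t(Zt) + lam * m * diag(length(y)), y)
      expect_lt(max(abs(ebv - drop(Z %*% alpha))), 1e-8)
    }
  }
})

test_that("genotypically identical animals receive identical GEBVs", {
  co <- shared_cohort()
  g <- co$genotypes
  twin <- rbind(g, clone = g[1, ])
  rownames(twin)[nrow(twin)] <- "clone"
  y <- shared_adjusted()[rownames(g)[1:150]]
  fit <- gp_fit("gblup", y, geno = twin, lambda = 2)
  expect_equal(unname(coef(fit)["clone"]), unname(coef(fit)[rownames(g)[1]]),
               tolerance = 1e-10)
  # SNP order does not matter
  set.seed(4)
  fit2 <- gp_fit("gblup", y, geno = twin[, sample(ncol(twin))], lambda = 2)
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-10)
})

test_that("predictors are invariant to animal ordering", {
  co <- shared_cohort()
  y <- shared_adjusted()[as.character(co$genotyped_ids[1:120])]
  g <- co$genotypes
  set.seed(5)
  perm <- sample(nrow(g))
  f1 <- gp_fit("gblup", y, geno = g, lambda = 2)
  f2 <- gp_fit("gblup", y, geno = g[perm, ], lambda = 2)
  expect_equal(coef(f1), coef(f2)[names(coef(f1))], tolerance = 1e-9)
  f3 <- gp_fit("blup", y, pedigree = co$pedigree, lambda = 2)
  expect_equal(sort(names(coef(f3))), sort(as.character(co$pedigree$id)))
})

test_that("single-step collapses to GBLUP and BLUP in its limiting cases", {
  set.seed(6)
  ped <- sim_pedigree(60, 2, seed = 6)
  g <- gene_drop(ped, 300, seed = 6) # everyone genotyped
  ids <- as.character(ped$id)
  y <- setNames(rnorm(80), ids[1:80])
  ss <- gp_fit("single_step", y, pedigree = ped, geno = g, lambda = 2)
  Gstar <- 0.95 * unclass(g_matrix(g)) + 0.05 * unclass(a_matrix(ped))
  attr(Gstar, "kind") <- "G"
  gb <- mixed_model_solve(y, Gstar, lambda = 2)
  expect_lt(max(abs(coef(ss) - gb[names(coef(ss))])), 1e-8)
  # no genotypes: pedigree BLUP
  Hinv <- h_inverse(ped, g[0, , drop = FALSE])
  ss0 <- mixed_model_solve(y, Hinv, lambda = 2)
  bl <- coef(gp_fit("blup", y, pedigree = ped, lambda = 2))
  expect_lt(max(abs(ss0 - bl[names(ss0)])), 1e-8)
})

test_that("chain settings enforce the cycle accounting", {
  ch <- chain_settings(100, 50, 2, seed = 1)
  expect_equal(total_cycles(ch), 200)
  expect_error(chain_settings(-1, 10, 1), "invalid")
  expect_error(chain_settings(10, 0, 1), "invalid")
  expect_equal(total_cycles(chain_settings()), 340000)
})

test_that("Bayes C returns null effects for null phenotypes", {
  co <- shared_cohort()
  ids <- as.character(co$genotyped_ids[1:100])
  y <- setNames(rep(0, 100), ids)
  fit <- gp_fit("bayes_c", y, geno = co$genotypes,
                sigma2_snp_bounds = c(0, 1),
                chain = chain_settings(300, 100, 2, seed = 2))
  expect_lt(max(abs(fit$alpha)), 0.02)
  expect_lt(max(abs(coef(fit))), 0.2)
})

test_that("Bayes C with pi = 1 agrees with GBLUP", {
  co <- shared_cohort()
  y <- shared_adjusted()[as.character(co$genotyped_ids)]
  fg <- gp_fit("gblup", y, geno = co$genotypes, lambda = 1.5)
  fb <- gp_fit("bayes_c", y, geno = co$genotypes, pi_fixed = 1,
               chain = chain_settings(600, 300, 2, seed = 3))
  expect_gt(cor(coef(fg), coef(fb)[names(coef(fg))]), 0.98)
  expect_gt(fb$sigma2_e_mean, 0) # residual variance stays positive
})

test_that("Bayes C recovers a sparse architecture", {
  arch <- trait_architecture(n_qtl = 10, sigma2_a = 0.2, sigma2_e = 0.2)
  hits <- pis <- numeric(3)
  for (seed in 1:3) {
    co <- sim_chd_cohort(250, 2, n_snps = 1000, arch = arch,
                         genotyped_cohorts = 1:2, seed = seed)
    y <- setNames(adjust_phenotypes(co$phenotypes, "THS", ~ sex)$THS_adj,
                  co$phenotypes$id)[as.character(co$genotyped_ids)]
    fit <- gp_fit("bayes_c", y, geno = co$genotypes,
                  chain = chain_settings(1000, 400, 3, seed = seed))
    top <- names(sort(fit$inclusion_prob, decreasing = TRUE))[1:10]
    hits[seed] <- mean(top %in% co$true_qtl$snp)
    pis[seed] <- fit$pi_mean
  }
  expect_gt(mean(hits), 0.4) # causal loci dominate the inclusion ranking
  expect_lt(mean(pis), 0.08) # posterior pi concentrates near 10/1000
  expect_gt(mean(pis), 0.003)
})

test_that("fit front end validates its inputs", {
  co <- shared_cohort()
  y <- shared_adjusted()[as.character(co$genotyped_ids[1:50])]
  expect_error(gp_fit("gblup", y, geno = co$genotypes), "varcomp")
  expect_error(gp_fit("blup", y, lambda = 1), "pedigree")
  expect_error(gp_fit("gblup", c(y, NA), geno = co$genotypes, lambda = 1),
               "finite")
  fit <- gp_fit("gblup", y, geno = co$genotypes,
                varcomp = list(sigma2_a = 0.1, sigma2_e = 0.3))
  expect_equal(fit$lambda, 3)
  expect_error(predict(fit, "no-such-animal"), "no EBV")
})
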