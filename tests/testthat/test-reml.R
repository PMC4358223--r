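test_that("heritability is the printed variance ratio", {
  expect_equal(round(heritability(73.13, 51.12), 2), 0.59)
  expect_equal(round(heritability(2.88, 3.65), 2), 0.44)
  expect_equal(heritability(0, 5), 0)
  expect_error(heritability(0, 0), "zero")
  expect_error(heritability(-1, 2), ">= 0")
})

test_that("profiled REML matches a dense grid-search oracle on a tiny fit", {
  set.seed(20)
  ped <- sim_pedigree(10, 1, generation_size = 10, seed = 20)
  A <- a_matrix(ped)
  sim <- sim_phenotypes(ped, trait_architecture(sigma2_a = 0.2,
                                                sigma2_e = 0.2), seed = 20)
  fit <- reml_fit(THS ~ sex, sim$pheno, A)
  # independent oracle: dense restricted likelihood on a lambda grid
  y <- sim$pheno$THS
  X <- model.matrix(~sex, sim$pheno)
  K <- unclass(A)
  n <- length(y); p <- ncol(X)
  dense_rll <- function(gam) {
    W <- gam * K + diag(n)
    Wi <- solve(W)
    xtwx <- t(X) %*% Wi %*% X
    b <- solve(xtwx, t(X) %*% Wi %*% y)
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Wi %*% r) / (n - p)
    -0.5 * ((n - p) * log(s2) + determinant(W)$modulus +
              determinant(xtwx)$modulus)
  }
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 400))
  vals <- sapply(grid, dense_rll)
  expect_gte(fit$loglik, max(vals) - 1e-6)
  # profile is unimodal over the grid (single interior rise-and-fall)
  expect_lte(sum(diff(sign(diff(vals))) != 0), 1)
})

test_that("REML is invariant to shifting all phenotypes", {
  ped <- sim_pedigree(120, 2, seed = 25)
  A <- a_matrix(ped)
  sim <- sim_phenotypes(ped, trait_architecture(), seed = 25)
  f1 <- reml_fit(THS ~ sex, sim$pheno, A)
  shifted <- sim$pheno; shifted$THS <- shifted$THS + 3.7
  f2 <- reml_fit(THS ~ sex, shifted, A)
  expect_equal(f1$sigma2_a, f2$sigma2_a, tolerance = 1e-6)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
})

test_that("REML returns a boundary estimate when there is no genetic signal", {
  ped <- sim_pedigree(150, 2, seed = 26)
  A <- a_matrix(ped)
  sim <- sim_phenotypes(ped, trait_architecture(sigma2_a = 0,
                                                sigma2_e = 0.4), seed = 26)
  fit <- reml_fit(THS ~ sex, sim$pheno, A)
  expect_lt(fit$h2, 0.08)
  expect_gte(fit$h2, 0)
})

test_that("REML guards against unusable relationship structures", {
  ped <- sim_pedigree(40, 1, seed = 27)
  sim <- sim_phenotypes(ped, seed = 27)
  K <- diag(nrow(ped))
  dimnames(K) <- list(ped$id, ped$id)
  expect_warning(reml_fit(THS ~ 1, sim$pheno, K), "identifiable")
  Kbad <- unclass(a_matrix(ped)); Kbad[1, 2] <- Kbad[2, 1] <- 5
  expect_error(reml_fit(THS ~ 1, sim$pheno, Kbad), "positive semidefinite")
  expect_error(reml_fit(THS ~ 1, sim$pheno[1:10, ],
                        unname(unclass(a_matrix(ped)))), "dimnames")
})

test_that("fixed-effect adjustment removes the simulated sex effect", {
  arch <- trait_architecture(sex_effect = 0.4)
  ped <- sim_pedigree(400, 1, seed = 28)
  sim <- sim_phenotypes(ped, arch, seed = 28)
  raw_gap <- with(sim$pheno, mean(THS[sex == "M"]) - mean(THS[sex == "F"]))
  expect_gt(raw_gap, 0.2)
  adj <- adjust_phenotypes(sim$pheno, "THS", ~ sex)
  gap <- with(adj, mean(THS_adj[sex == "M"]) - mean(THS_adj[sex == "F"]))
  expect_lt(abs(gap), 1e-10)
  expect_lt(abs(mean(adj$THS_adj)), 1e-10)
})

test_that("adjustment handles the empty spec and missing covariates", {
  ped <- sim_pedigree(30, 1, seed = 29)
  sim <- sim_phenotypes(ped, seed = 29)
  adj <- adjust_phenotypes(sim$pheno, "THS", ~ 1)
  expect_equal(adj$THS_adj, sim$pheno$THS - mean(sim$pheno$THS))
  ph <- sim$pheno; ph$age_days[3] <- NA
  expect_error(adjust_phenotypes(ph, "THS", ~ sex + age_days), "age_days")
  expect_error(adjust_phenotypes(ph, "THS", ~ nope), "nope")
  expect_error(adjust_phenotypes(ph, "XX", ~ sex), "XX")
})
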