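test_that("A matrix reproduces textbook relationships", {
  founders <- sim_pedigree(6, 0, seed = 1)
  expect_equal(unname(strip_relmat(a_matrix(founders))), diag(6))
  ped <- halfsib_ped()
  A <- a_matrix(ped)
  expect_equal(A["1", "4"], 0.5)   # parent-offspring
  expect_equal(A["4", "5"], 0.25)  # half sibs
  expect_equal(A["6", "6"], 1.125) # offspring of half-sib mating
})

test_that("A matrix equals the recursive kinship oracle on random pedigrees", {
  for (seed in 1:3) {
    ped <- sim_pedigree(14, 2, generation_size = 12, seed = seed)
    expect_lt(max(abs(strip_relmat(a_matrix(ped)) - kinship_oracle(ped))), 1e-12)
  }
})

test_that("Henderson A-inverse matches dense inversion", {
  founders <- sim_pedigree(5, 0, seed = 1)
  expect_equal(unname(strip_relmat(a_inverse(founders))), diag(5))
  trio <- halfsib_ped()[1:4, ] # two founders + unrelated + offspring
  expect_lt(max(abs(strip_relmat(a_inverse(trio)) -
                      solve(strip_relmat(a_matrix(trio))))), 1e-10)
  ped <- sim_pedigree(100, 3, seed = 23) # ~200+ animals with immigrants
  A <- strip_relmat(a_matrix(ped))
  expect_lt(max(abs(A %*% strip_relmat(a_inverse(ped)) - diag(nrow(A)))), 1e-8)
})

test_that("G matrix follows the standardized-dose construction", {
  g <- matrix(c(0L, 2L, 2L, 0L), 2, 2,
              dimnames = list(c("x", "y"), c("s1", "s2")))
  G <- g_matrix(g)
  expect_equal(strip_relmat(G), matrix(c(2, -2, -2, 2), 2, 2,
                                  dimnames = dimnames(g)[c(1, 1)]))
  ped <- sim_pedigree(300, 0, seed = 31)
  gg <- gene_drop(ped, 800, founder_maf_range = c(0.1, 0.5), seed = 31)
  G2 <- g_matrix(gg)
  expect_equal(strip_relmat(G2), t(strip_relmat(G2)))
  expect_gt(min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  expect_lt(abs(mean(diag(G2)) - 1), 0.05) # VanRaden scaling
  expect_error(g_matrix(cbind(gg, mono = 0L)), "monomorphic")
})

test_that("G is invariant to SNP and animal permutations", {
  set.seed(37)
  ped <- sim_pedigree(40, 1, seed = 37)
  g <- gene_drop(ped, 120, seed = 37)
  G <- strip_relmat(g_matrix(g))
  expect_equal(strip_relmat(g_matrix(g[, sample(ncol(g))])), G)
  perm <- sample(nrow(g))
  expect_equal(strip_relmat(g_matrix(g[perm, ]))[rownames(G), colnames(G)], G)
})

test_that("H-inverse matches the dense block-formula oracle", {
  ped <- halfsib_ped()[1:5, ]
  g <- gene_drop(ped, 300, seed = 3)[c("3", "4", "5"), ]
  pf <- colMeans(g) / 2
  g <- g[, pf > 0 & pf < 1]
  idx <- 3:5
  A <- strip_relmat(a_matrix(ped))
  A22 <- A[idx, idx]
  Gstar <- 0.95 * strip_relmat(g_matrix(g)) + 0.05 * A22
  oracle <- strip_relmat(a_inverse(ped))
  oracle[idx, idx] <- oracle[idx, idx] + solve(Gstar) - solve(A22)
  expect_lt(max(abs(strip_relmat(h_inverse(ped, g)) - oracle)), 1e-10)
  # literal element-replacement variant
  oracle2 <- strip_relmat(a_inverse(ped))
  oracle2[idx, idx] <- solve(Gstar)
  expect_lt(max(abs(strip_relmat(h_inverse(ped, g, mode = "paper")) - oracle2)),
            1e-10)
})

test_that("H-inverse limiting cases collapse to G or A", {
  co <- shared_cohort()
  ped <- co$pedigree
  # no genotyped animals: H^-1 = A^-1
  empty <- co$genotypes[0, , drop = FALSE]
  expect_equal(strip_relmat(h_inverse(ped, empty)), strip_relmat(a_inverse(ped)))
  # all animals genotyped: H^-1 = (blended G)^-1
  gall <- gene_drop(ped, 400, seed = 77)
  Hi <- h_inverse(ped, gall, blend = 0.05)
  Gstar <- 0.95 * strip_relmat(g_matrix(gall)) +
    0.05 * strip_relmat(a_matrix(ped))
  expect_lt(max(abs(strip_relmat(Hi) - solve(Gstar))), 1e-6)
})

test_that("blending with the pedigree block restores positive definiteness", {
  ped <- sim_pedigree(30, 1, seed = 41)
  g <- gene_drop(ped, 20, seed = 41) # fewer SNPs than animals: singular G
  A22 <- strip_relmat(a_matrix(ped))
  for (w in c(0.05, 0.2)) {
    Gs <- (1 - w) * strip_relmat(g_matrix(g)) + w * A22
    expect_gt(min(eigen(Gs, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})
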