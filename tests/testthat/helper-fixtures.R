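# shared fixtures, built once per test run

# strip relmat tagging so values can be compared against plain matrices
strip_relmat <- function(x) {
  x <- unclass(x)
  attr(x, "kind") <- NULL
  x
}

# hand-written 6-animal pedigree ending in a half-sib mating:
# 4 and 5 share sire 1; their offspring 6 has F = 0.125
halfsib_ped <- function() {
  ped <- data.frame(id = 1:6,
                    sire = c(0, 0, 0, 1, 1, 4),
                    dam = c(0, 0, 0, 2, 3, 5),
                    sex = c("M", "F", "F", "M", "F", "M"),
                    cohort = c(0, 0, 0, 1, 1, 2))
  class(ped) <- c("ped", "data.frame")
  ped
}

# independent kinship oracle: textbook recursion on (ordered) pedigrees
# a(i,i) = 1 + a(s_i, d_i)/2 ; a(i,j) = (a(j, s_i) + a(j, d_i))/2 for j < i
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  a <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i == j) {
      if (s[i] == 0 || d[i] == 0) return(1)
      return(1 + 0.5 * a(s[i], d[i]))
    }
    if (j > i) { k <- i; i <- j; j <- k }
    0.5 * (a(j, s[i]) + a(j, d[i]))
  }
  outer(seq_len(n), seq_len(n), Vectorize(a))
}

# medium cohort with genotypes, reused across prediction/evaluation tests
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sim_chd_cohort(
        n_founders = 150, n_generations = 2, n_snps = 400,
        arch = trait_architecture(n_qtl = 80, sigma2_a = 0.16,
                                  sigma2_e = 0.24),
        genotyped_cohorts = 1:2, seed = 42)
    }
    cache
  }
})

# adjusted training phenotypes for the shared cohort
shared_adjusted <- function(co = shared_cohort(), fixed = ~ sex) {
  adj <- adjust_phenotypes(co$phenotypes, "THS", fixed)
  setNames(adj$THS_adj, adj$id)
}
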