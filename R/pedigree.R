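#' Simulate a multi-generation dog pedigree
#'
#' Generates a pedigree with discrete cohorts and the small half-sib family
#' structure typical of a screened companion-dog population. For each
#' offspring cohort the number of sires is set to `generation_size /
#' offspring_per_sire_mean` (and likewise for dams), every used parent gets
#' at least one offspring and the remainder are dealt at random, so the
#' realized offspring-per-sire mean tracks the requested one. When the
#' previous cohort cannot supply that many parents of a sex, additional
#' unrelated "immigrant" parents (unknown-parent animals labelled with the
#' previous cohort index) are created — mirroring how a real cohort is bred
#' from a much wider registered population than its own ancestors, and
#' embedding the study animals in a larger pedigree.
#'
#' @param n_founders number of founder animals (cohort 0), alternating sexes.
#' @param n_generations number of offspring cohorts to append (0 returns
#'   founders only).
#' @param offspring_per_sire_mean target mean offspring per used sire
#'   (default 1.63).
#' @param offspring_per_dam_mean target mean offspring per used dam
#'   (default 1.10).
#' @param generation_size number of offspring per cohort; default
#'   `n_founders`.
#' @param allow_immigrant_parents create unrelated parents when the previous
#'   cohort is too small to meet the parent counts; with `FALSE`, available
#'   parents are reused instead (family sizes then exceed the target).
#' @param seed integer seed governing all randomness in the construction.
#'
#' @return An object of class `ped` (a data frame) with columns `id`, `sire`,
#'   `dam` (0 = unknown), `sex` (`"M"`/`"F"`) and `cohort`. Rows are ordered
#'   so every parent precedes its offspring.
#' @examples
#' ped <- sim_pedigree(n_founders = 40, n_generations = 2, seed = 1)
#' table(ped$cohort)
#' @export
sim_pedigree <- function(n_founders, n_generations,
                         offspring_per_sire_mean = 1.63,
                         offspring_per_dam_mean = 1.10,
                         generation_size = n_founders,
                         allow_immigrant_parents = TRUE,
                         seed = 1L) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (offspring_per_sire_mean < 1 || offspring_per_dam_mean < 1)
    stop("mean offspring per parent must be >= 1")
  set.seed(seed)

  sex <- rep(c("M", "F"), length.out = n_founders)
  id <- seq_len(n_founders)
  sire <- dam <- rep(0L, n_founders)
  cohort <- rep(0L, n_founders)
  if (!any(sex == "M") || !any(sex == "F"))
    stop("degenerate pedigree: founders must include both sexes")

  for (g in seq_len(n_generations)) {
    n_off <- generation_size
    slots <- list()
    for (sx in c("M", "F")) {
      target <- if (sx == "M") offspring_per_sire_mean else
        offspring_per_dam_mean
      pool <- id[cohort == g - 1L & sex == sx]
      if (length(pool) < 1)
        stop("degenerate pedigree: cohort ", g - 1L,
             " lacks animals of one sex")
      n_par <- max(1L, min(round(n_off / target), n_off))
      if (length(pool) < n_par && allow_immigrant_parents) {
        n_new <- n_par - length(pool)
        new_id <- max(id) + seq_len(n_new)
        id <- c(id, new_id)
        sire <- c(sire, rep(0L, n_new))
        dam <- c(dam, rep(0L, n_new))
        sex <- c(sex, rep(sx, n_new))
        cohort <- c(cohort, rep(g - 1L, n_new))
        pool <- c(pool, new_id)
      }
      used <- pool[sample.int(length(pool), min(n_par, length(pool)))]
      sizes <- rep(1L, length(used)) +
        drop(rmultinom(1, n_off - length(used),
                       rep(1, length(used))))
      sl <- rep(used, times = sizes)
      slots[[sx]] <- sl[sample.int(length(sl))]
    }
    new_id <- max(id) + seq_len(n_off)
    id <- c(id, new_id)
    sire <- c(sire, slots[["M"]])
    dam <- c(dam, slots[["F"]])
    sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
    cohort <- c(cohort, rep(g, n_off))
  }

  ped <- data.frame(id = as.integer(id), sire = as.integer(sire),
                    dam = as.integer(dam), sex = sex,
                    cohort = as.integer(cohort))
  class(ped) <- c("ped", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks that ids are unique, that every known parent appears earlier in the
#' record order (which also guarantees acyclicity), and that sires are male
#' and dams female.
#'
#' @param ped a `ped` data frame (columns `id`, `sire`, `dam`, `sex`,
#'   `cohort`).
#' @return `ped`, invisibly; stops with an informative error otherwise.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "sire", "dam", "sex")
  if (!all(req %in% names(ped))) stop("pedigree must have columns ",
                                      paste(req, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("duplicate animal ids")
  pos <- match(ped$id, ped$id)
  sp <- match(ped$sire, ped$id)
  dp <- match(ped$dam, ped$id)
  known_s <- ped$sire != 0
  known_d <- ped$dam != 0
  if (anyNA(sp[known_s]) || anyNA(dp[known_d]))
    stop("parent id not present in pedigree")
  if (any(sp[known_s] >= pos[known_s]) || any(dp[known_d] >= pos[known_d]))
    stop("parents must precede offspring in record order")
  if (any(ped$sex[sp[known_s]] != "M")) stop("some sires are not male")
  if (any(ped$sex[dp[known_d]] != "F")) stop("some dams are not female")
  invisible(ped)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal inbreeding coefficients F (so that the diagonal of the
#' numerator relationship matrix is 1 + F) without forming the dense matrix,
#' using the L-D decomposition of A.
#'
#' @param ped a validated `ped` data frame.
#' @return numeric vector of inbreeding coefficients, in pedigree order.
#' @export
inbreeding <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  f <- numeric(n)
  dvec <- numeric(n) # Mendelian-sampling variance coefficients D_i
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) f[s[i]] else -1
    fd <- if (d[i] > 0L) f[d[i]] else -1
    dvec[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0L || d[i] == 0L) {
      f[i] <- 0 # founder or half-founder: no common ancestry tracked
      next
    }
    # a_ii = sum_j v_j^2 D_j over the generalized-Cholesky row of animal i
    v <- numeric(i)
    v[i] <- 1
    aii <- 0
    for (j in seq(i, 1L)) {
      vj <- v[j]
      if (vj == 0) next
      aii <- aii + vj * vj * dvec[j]
      if (s[j] > 0L) v[s[j]] <- v[s[j]] + 0.5 * vj
      if (d[j] > 0L) v[d[j]] <- v[d[j]] + 0.5 * vj
    }
    f[i] <- aii - 1
  }
  f
}
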