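#' Relationship matrices for pedigree, genomic and single-step models
#'
#' `a_matrix()` builds Wright's numerator relationship matrix A by the tabular
#' method; `a_inverse()` builds its sparse inverse directly via Henderson's
#' rules with Meuwissen-Luo inbreeding coefficients; `g_matrix()` builds the
#' genomic relationship matrix G from standardized allele doses (VanRaden's
#' second model, `G = Z'Z / n` with per-SNP centring `2p` and scaling
#' `1/sqrt(2p(1-p))`); `h_inverse()` combines the two for single-step
#' evaluation.
#'
#' @param ped a validated `ped` data frame (see [sim_pedigree()]).
#' @return `a_matrix()`: a dense symmetric matrix of class `relmat` with
#'   attribute `kind = "A"`, dimnames = animal ids.
#' @examples
#' ped <- sim_pedigree(20, 2, seed = 1)
#' A <- a_matrix(ped)
#' range(diag(A)) # 1 + inbreeding coefficient
#' @export
a_matrix <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si > 0L) row <- row + 0.5 * A[j, si]
      if (di > 0L) row <- row + 0.5 * A[j, di]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  new_relmat(A, "A")
}

#' @rdname a_matrix
#' @return `a_inverse()`: a sparse symmetric `Matrix` of class `relmat`,
#'   attribute `kind = "A_inverse"`.
#' @export
a_inverse <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  f <- inbreeding(ped)
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], -1)
  din <- 1 / (0.5 - 0.25 * (fs + fd)) # inverse Mendelian variance
  dii <- ifelse(s == 0L & d == 0L, 1, din)
  # Henderson's rules, vectorized over animals
  i_all <- seq_len(n)
  ks <- which(s > 0L); kd <- which(d > 0L); kb <- which(s > 0L & d > 0L)
  ii <- c(i_all, ks, s[ks], kd, d[kd], s[ks], d[kd], s[kb], d[kb])
  jj <- c(i_all, s[ks], ks, d[kd], kd, s[ks], d[kd], d[kb], s[kb])
  xx <- c(dii,
          -0.5 * dii[ks], -0.5 * dii[ks], -0.5 * dii[kd], -0.5 * dii[kd],
          0.25 * dii[ks], 0.25 * dii[kd], 0.25 * dii[kb], 0.25 * dii[kb])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Ainv <- as.matrix(Ainv)
  Ainv <- (Ainv + t(Ainv)) / 2
  dimnames(Ainv) <- list(ped$id, ped$id)
  new_relmat(Ainv, "A_inverse")
}

#' Genomic relationship matrix (VanRaden, standardized doses)
#'
#' @param geno animals x SNPs allele-dose matrix (0/1/2, `NA` = missing) with
#'   animal ids as rownames. Missing doses are mean-imputed to `2p` before
#'   standardization, which preserves centring.
#' @param freq optional per-SNP reference-allele frequencies; by default
#'   computed from the supplied (analysis) sample.
#' @return `g_matrix()`: dense symmetric `relmat`, attribute `kind = "G"`.
#' @rdname a_matrix
#' @export
g_matrix <- function(geno, freq = NULL) {
  geno <- as.matrix(geno)
  if (is.null(freq)) freq <- colMeans(geno, na.rm = TRUE) / 2
  if (any(freq <= 0 | freq >= 1))
    stop("monomorphic SNPs present; apply a MAF filter before building G")
  n <- ncol(geno)
  Z <- sweep(geno, 2, 2 * freq)
  Z[is.na(Z)] <- 0 # mean imputation after centring
  Z <- sweep(Z, 2, sqrt(2 * freq * (1 - freq)), "/")
  G <- tcrossprod(Z) / n
  dimnames(G) <- list(rownames(geno), rownames(geno))
  new_relmat(G, "G")
}

#' Single-step combined relationship inverse
#'
#' Two constructions are available. `mode = "misztal"` (default) is the
#' standard single-step form `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]` over the
#' genotyped block, where `A22` is the pedigree relationship among genotyped
#' animals and `G* = (1 - blend) G + blend A22` is the stabilized genomic
#' matrix. `mode = "paper"` instead overwrites the genotyped-block elements
#' of `A^-1` with the corresponding elements of `G*^-1` (a literal
#' element-replacement rule, retained for sensitivity analysis).
#'
#' @param geno_ids ids (matching `ped$id`) of the genotyped animals, i.e.
#'   `rownames(geno)`.
#' @param mode `"misztal"` or `"paper"`.
#' @param blend weight on `A22` when stabilizing G before inversion.
#' @rdname a_matrix
#' @export
h_inverse <- function(ped, geno, mode = c("misztal", "paper"), blend = 0.05) {
  mode <- match.arg(mode)
  Ainv <- a_inverse(ped)
  if (is.null(geno) || nrow(geno) == 0) return(new_relmat(Ainv, "H_inverse"))
  ids <- rownames(geno)
  idx <- match(ids, as.character(ped$id))
  if (anyNA(idx)) stop("genotyped animals absent from pedigree: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  A <- a_matrix(ped)
  A22 <- unclass(A)[idx, idx, drop = FALSE]
  G <- unclass(g_matrix(geno))
  Gstar <- (1 - blend) * G + blend * A22
  ev <- min(eigen(Gstar, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8)
    stop("G is singular even after blending; increase `blend` ",
         "(current weight ", blend, ")")
  Ginv <- solve(Gstar)
  H <- as.matrix(Ainv)
  if (mode == "misztal") {
    A22inv <- solve(A22)
    H[idx, idx] <- H[idx, idx] + Ginv - A22inv
  } else {
    H[idx, idx] <- Ginv
  }
  dimnames(H) <- list(ped$id, ped$id)
  new_relmat(H, "H_inverse")
}

new_relmat <- function(x, kind) {
  attr(x, "kind") <- kind
  class(x) <- unique(c("relmat", class(x)))
  x
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat kind=%s, %d x %d>\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Flag pedigree-genotype inconsistencies
#'
#' Compares genomic and pedigree relationships over the genotyped animals and
#' flags pairs whose values disagree by more than `margin` — typically
#' recording errors (mislabeled samples, wrong parentage).
#'
#' @inheritParams h_inverse
#' @param margin absolute disagreement above which a pair is flagged.
#' @return data frame with columns `id1`, `id2`, `a`, `g`, `delta`.
#' @export
relatedness_check <- function(ped, geno, margin = 0.35) {
  ids <- rownames(geno)
  idx <- match(ids, as.character(ped$id))
  if (anyNA(idx)) stop("genotyped animals absent from pedigree")
  A22 <- unclass(a_matrix(ped))[idx, idx, drop = FALSE]
  G <- unclass(g_matrix(geno))
  dlt <- G - A22
  up <- which(upper.tri(dlt) & abs(dlt) > margin, arr.ind = TRUE)
  data.frame(id1 = ids[up[, 1]], id2 = ids[up[, 2]],
             a = A22[up], g = G[up], delta = dlt[up])
}
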