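#' Solve the mixed-model equations for one kinship-structured random effect
#'
#' Computes best linear unbiased predictions of additive values for the model
#' `y = a + e`, `a ~ N(0, sigma2_a K)`, `e ~ N(0, sigma2_e I)` on
#' pre-adjusted (mean-zero) phenotypes, where `lambda = sigma2_e / sigma2_a`.
#' Animals without phenotype records receive EBVs propagated through the
#' relationship structure. Two parameterizations are accepted: a covariance
#' matrix (kind A or G), solved in its training block, or a precision matrix
#' (kind `A_inverse` / `H_inverse`), solved via Henderson's equations —
#' required for single-step where only `H^-1` is available.
#'
#' @param y named numeric vector of adjusted phenotypes (names = animal ids
#'   present in `K`).
#' @param K relationship matrix (or its inverse, see `inverse`) with animal
#'   ids as dimnames; EBVs are returned for every id in `K`.
#' @param lambda positive variance ratio `sigma2_e / sigma2_a`.
#' @param inverse `TRUE` if `K` is a precision (inverse-relationship) matrix.
#'   Defaults to `TRUE` when `K` carries a `kind` attribute ending in
#'   `"_inverse"`.
#' @return named vector of EBVs for all ids of `K`.
#' @examples
#' K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
#' mixed_model_solve(c(a = 1), K, lambda = 1) # ridge shrinkage 1/(1+lambda)
#' @export
mixed_model_solve <- function(y, K, lambda,
                              inverse = grepl("_inverse$",
                                              attr(K, "kind") %||% "")) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  ids <- rownames(K)
  if (is.null(ids)) stop("K must carry animal ids as dimnames")
  if (is.null(names(y))) stop("y must be named by animal id")
  ti <- match(names(y), ids)
  if (anyNA(ti)) stop("animals absent from relationship matrix: ",
                      paste(head(names(y)[is.na(ti)]), collapse = ", "))
  K <- as.matrix(K)
  if (inverse) {
    n <- nrow(K)
    C <- lambda * K
    diag(C)[ti] <- diag(C)[ti] + 1
    rhs <- numeric(n)
    rhs[ti] <- y
    a <- solve(C, rhs)
  } else {
    V <- K[ti, ti, drop = FALSE]
    diag(V) <- diag(V) + lambda
    a <- drop(K[, ti, drop = FALSE] %*% solve(V, y))
  }
  setNames(drop(a), ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain settings for the Bayes C Gibbs sampler
#'
#' @param burn_in cycles discarded before recording.
#' @param n_samples number of recorded draws.
#' @param thin cycles between recorded draws.
#' @param seed integer seed for the sampler.
#' @return object of class `chain_settings`; `total_cycles(x)` returns
#'   `burn_in + n_samples * thin`.
#' @examples
#' total_cycles(chain_settings()) # the full-length production chain
#' @export
chain_settings <- function(burn_in = 40000L, n_samples = 30000L, thin = 10L,
                           seed = 1L) {
  if (burn_in < 0 || n_samples < 1 || thin < 1) stop("invalid chain settings")
  structure(list(burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_settings")
}

#' @rdname chain_settings
#' @param x a `chain_settings` object.
#' @export
total_cycles <- function(x) x$burn_in + x$n_samples * x$thin

#' @export
print.chain_settings <- function(x, ...) {
  cat(sprintf("<chain: burn-in %d + %d samples x thin %d = %d cycles>\n",
              x$burn_in, x$n_samples, x$thin, total_cycles(x)))
  invisible(x)
}

#' Fit a breeding-value predictor
#'
#' Unified front end to the four predictors compared in this package:
#' \describe{
#'   \item{`"blup"`}{pedigree BLUP: kinship = Wright's A over the pedigree;
#'     uses phenotypes of any pedigree animal supplied in `y`.}
#'   \item{`"gblup"`}{genomic BLUP: kinship = VanRaden G over the genotyped
#'     animals; equivalent to ridge regression on standardized SNP doses.}
#'   \item{`"bayes_c"`}{spike-and-slab SNP model fitted by Gibbs sampling: a
#'     proportion `pi` of SNPs have effects with common variance
#'     `sigma2_snp`, the rest none; `pi` carries a Beta(2,2) prior and
#'     `sigma2_snp` a bounded flat prior. Doses are centred by `2p` but not
#'     scaled. GEBV = centred doses times posterior-mean effects.}
#'   \item{`"single_step"`}{BLUP on the combined pedigree-genomic `H^-1`,
#'     using phenotypes of both genotyped and ungenotyped animals.}
#' }
#' All methods consume pre-adjusted (fixed-effect-corrected) phenotypes; see
#' [adjust_phenotypes()]. Validation animals simply carry no entry in `y` and
#' receive EBVs through the relationship structure (or their genotypes).
#'
#' @param method one of `"blup"`, `"gblup"`, `"bayes_c"`, `"single_step"`.
#' @param y named numeric vector of adjusted phenotypes of the training
#'   animals.
#' @param pedigree `ped` data frame (required for blup / single_step).
#' @param geno dose matrix over training + validation animals (required for
#'   gblup / bayes_c / single_step).
#' @param varcomp a [reml_fit()] object or list with `sigma2_a` and
#'   `sigma2_e`; used to form `lambda`. Alternatively give `lambda` directly.
#' @param lambda variance ratio `sigma2_e / sigma2_a`.
#' @param chain [chain_settings()] for Bayes C.
#' @param pi_prior Beta prior parameters for `pi` (Bayes C).
#' @param sigma2_snp_bounds bounds of the flat prior on the SNP-effect
#'   variance; default `c(0, 10 * var(y))`.
#' @param pi_fixed optionally fix `pi` instead of sampling it (`pi_fixed = 1`
#'   makes Bayes C equivalent to GBLUP / ridge regression).
#' @param sigma2_snp_fixed optionally fix the SNP-effect variance.
#' @param h_mode,blend passed to [h_inverse()] (single_step).
#' @return object of class `gp_fit` with elements `method`, `ebv` (named
#'   vector over all animals the method covers), `lambda`, and for Bayes C
#'   `alpha`, `inclusion_prob`, `pi_mean`, `sigma2_snp_mean`,
#'   `sigma2_e_mean`, `mu_mean`, `chain`, `ess` (effective sample size of the
#'   genetic-variance trace).
#' @examples
#' co <- sim_chd_cohort(60, 2, n_snps = 80, seed = 3)
#' adj <- adjust_phenotypes(co$phenotypes, "THS", ~ sex)
#' ytr <- setNames(adj$THS_adj, adj$id)[as.character(co$genotyped_ids)]
#' fit <- gp_fit("gblup", ytr, geno = co$genotypes, lambda = 2)
#' head(coef(fit))
#' @export
gp_fit <- function(method = c("blup", "gblup", "bayes_c", "single_step"),
                   y, pedigree = NULL, geno = NULL,
                   varcomp = NULL, lambda = NULL,
                   chain = chain_settings(), pi_prior = c(2, 2),
                   sigma2_snp_bounds = NULL, pi_fixed = NULL,
                   sigma2_snp_fixed = NULL,
                   h_mode = c("misztal", "paper"), blend = 0.05) {
  method <- match.arg(method)
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  if (is.null(lambda) && method != "bayes_c") {
    if (is.null(varcomp))
      stop("supply either lambda or varcomp (a reml_fit or list)")
    lambda <- varcomp$sigma2_e / varcomp$sigma2_a
  }
  fit <- switch(method,
    blup = {
      if (is.null(pedigree)) stop("pedigree BLUP needs a pedigree")
      Ainv <- a_inverse(pedigree)
      list(ebv = mixed_model_solve(y, Ainv, lambda))
    },
    gblup = {
      if (is.null(geno)) stop("GBLUP needs genotypes")
      G <- g_matrix(geno)
      list(ebv = mixed_model_solve(y, G, lambda))
    },
    single_step = {
      if (is.null(pedigree) || is.null(geno))
        stop("single-step needs pedigree and genotypes")
      Hinv <- h_inverse(pedigree, geno, mode = match.arg(h_mode),
                        blend = blend)
      list(ebv = mixed_model_solve(y, Hinv, lambda))
    },
    bayes_c = {
      if (is.null(geno)) stop("Bayes C needs genotypes")
      bayes_c_core(y, geno, chain, pi_prior, sigma2_snp_bounds,
                   pi_fixed, sigma2_snp_fixed)
    })
  structure(c(list(method = method, lambda = lambda,
                   n_train = length(y)), fit),
            class = c(paste0("gp_", method), "gp_fit"))
}

bayes_c_core <- function(y, geno, chain, pi_prior, sigma2_snp_bounds,
                         pi_fixed = NULL, sigma2_snp_fixed = NULL) {
  if (!inherits(chain, "chain_settings")) stop("chain must be chain_settings()")
  ids <- rownames(geno)
  ti <- match(names(y), ids)
  if (anyNA(ti)) stop("training animals absent from genotype matrix: ",
                      paste(head(names(y)[is.na(ti)]), collapse = ", "))
  p <- colMeans(geno, na.rm = TRUE) / 2 # frequencies among genotyped animals
  Z <- sweep(geno, 2, 2 * p) # centred, NOT scaled
  Z[is.na(Z)] <- 0
  if (is.null(sigma2_snp_bounds)) sigma2_snp_bounds <- c(0, 10 * var(y))
  set.seed(chain$seed)
  res <- bayesc_gibbs(Z[ti, , drop = FALSE], as.numeric(y),
                      chain$burn_in, chain$n_samples, chain$thin,
                      pi_prior[1], pi_prior[2],
                      sigma2_snp_bounds[1], sigma2_snp_bounds[2],
                      pi_fixed %||% -1, sigma2_snp_fixed %||% -1)
  ebv <- setNames(drop(Z %*% res$alpha_mean), ids)
  var_trace <- res$genvar_trace
  list(ebv = ebv, alpha = setNames(res$alpha_mean, colnames(geno)),
       inclusion_prob = setNames(res$inclusion_prob, colnames(geno)),
       pi_mean = res$pi_mean, sigma2_snp_mean = res$sigma2_snp_mean,
       sigma2_e_mean = res$sigma2_e_mean, mu_mean = res$mu_mean,
       chain = chain, ess = ess(var_trace))
}

## crude autocorrelation-based effective sample size of a chain trace
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  cut <- if (length(pos)) pos[1] else length(rho)
  n / (1 + 2 * sum(rho[seq_len(cut)]))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit method=%s, %d training records, %d EBVs>\n",
              x$method, x$n_train, length(x$ebv)))
  if (x$method == "bayes_c")
    cat(sprintf("  posterior means: pi=%.4f sigma2_snp=%.3g sigma2_e=%.3g\n",
                x$pi_mean, x$sigma2_snp_mean, x$sigma2_e_mean))
  invisible(x)
}

#' @export
coef.gp_fit <- function(object, ...) object$ebv

#' Extract EBVs for chosen animals
#'
#' @param object a `gp_fit`.
#' @param ids animal ids (default: all covered by the fit).
#' @param ... unused.
#' @return named vector of EBVs.
#' @export
predict.gp_fit <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$ebv)
  ids <- as.character(ids)
  miss <- setdiff(ids, names(object$ebv))
  if (length(miss)) stop("no EBV for animals: ",
                         paste(head(miss), collapse = ", "))
  object$ebv[ids]
}

#' @export
summary.gp_fit <- function(object, ...) {
  cat(sprintf("Method: %s\n", object$method))
  print(summary(object$ebv))
  invisible(object)
}
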