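#' Animal-model REML by eigendecomposition
#'
#' Fits the single-random-effect animal model
#' `y = X b + a + e`, `a ~ N(0, sigma2_a K)`, `e ~ N(0, sigma2_e I)`,
#' where `K` is a relationship matrix (pedigree A or genomic G) over the
#' phenotyped animals. The restricted likelihood is profiled over the
#' variance ratio `gamma = sigma2_a / sigma2_e` after rotating the data by
#' the eigenvectors of `K`, which makes each likelihood evaluation O(n p)
#' and the optimization a bounded 1-D search — exact for this model class.
#' Standard errors come from the inverse of a finite-difference observed
#' information matrix in `(sigma2_a, sigma2_e)`, with the heritability SE by
#' the delta method.
#'
#' @param formula model formula, e.g. `THS ~ sex + exercise + age_spline(age_days)`.
#'   The left-hand side is the trait; the right-hand side the fixed effects.
#' @param data data frame of phenotypes and covariates, one row per animal,
#'   with an id column matching the dimnames of `kinship`.
#' @param kinship symmetric relationship matrix whose dimnames cover every
#'   animal in `data`.
#' @param id name of the id column in `data`.
#' @param gamma_bounds search interval for the variance ratio.
#' @return object of class `reml_fit` with components `sigma2_a`, `sigma2_e`,
#'   `h2`, `se` (named vector), `beta` (fixed effects), `loglik` (restricted
#'   log-likelihood at the optimum, up to a constant), `gamma`, `n`, `p`.
#' @examples
#' ped <- sim_pedigree(150, 2, seed = 1)
#' sim <- sim_phenotypes(ped, trait_architecture(), seed = 1)
#' A <- a_matrix(ped)
#' fit <- reml_fit(THS ~ sex, sim$pheno, A)
#' fit$h2
#' @export
reml_fit <- function(formula, data, kinship, id = "id",
                     gamma_bounds = c(1e-6, 1e6)) {
  ids <- as.character(data[[id]])
  kid <- rownames(kinship)
  if (is.null(kid)) stop("kinship matrix must carry animal ids as dimnames")
  if (!all(ids %in% kid))
    stop("kinship matrix does not cover animals: ",
         paste(head(setdiff(ids, kid)), collapse = ", "))
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design matrix is rank deficient")
  K <- as.matrix(kinship)[ids, ids]
  n <- length(y); p <- ncol(X)

  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("relationship matrix is not positive semidefinite")
  dvals <- pmax(eg$values, 0)
  if (sd(dvals) < 1e-10)
    warning("relationship matrix has no structure; ",
            "sigma2_a and sigma2_e are not separately identifiable")
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)

  prof <- function(lgamma) {
    w <- exp(lgamma) * dvals + 1
    xtwx <- crossprod(Xs, Xs / w)
    beta <- solve(xtwx, crossprod(Xs, ys / w))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / w)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * log(s2e) + sum(log(w)) +
              determinant(xtwx, logarithm = TRUE)$modulus)
  }
  opt <- optimize(prof, log(gamma_bounds), maximum = TRUE, tol = 1e-8)
  gamma <- exp(opt$maximum)

  w <- gamma * dvals + 1
  xtwx <- crossprod(Xs, Xs / w)
  beta <- drop(solve(xtwx, crossprod(Xs, ys / w)))
  names(beta) <- colnames(X)
  r <- ys - Xs %*% beta
  s2e <- sum(r^2 / w) / (n - p)
  s2a <- gamma * s2e
  h2 <- heritability(s2a, s2e)

  ll2 <- function(th) { # restricted ll in (sigma2_a, sigma2_e)
    w <- th[1] * dvals + th[2]
    if (any(w <= 0)) return(-Inf)
    xtwx <- crossprod(Xs, Xs / w)
    b <- solve(xtwx, crossprod(Xs, ys / w))
    r <- ys - Xs %*% b
    -0.5 * (sum(log(w)) + determinant(xtwx, logarithm = TRUE)$modulus +
              sum(r^2 / w))
  }
  se <- reml_se(ll2, c(s2a, s2e), h2)

  structure(list(sigma2_a = s2a, sigma2_e = s2e, h2 = h2, se = se,
                 beta = beta, gamma = gamma,
                 loglik = as.numeric(prof(opt$maximum)), n = n, p = p,
                 formula = formula),
            class = "reml_fit")
}

## delta-method SEs from a finite-difference observed information matrix
reml_se <- function(ll2, theta, h2) {
  hstep <- pmax(1e-4 * theta, 1e-6)
  H <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    H[i, j] <- (ll2(theta + ei + ej) - ll2(theta + ei - ej) -
                  ll2(theta - ei + ej) + ll2(theta - ei - ej)) /
      (4 * hstep[i] * hstep[j])
  }
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 2, 2))
  tot <- sum(theta)
  grad_h2 <- c(theta[2], -theta[1]) / tot^2
  se_h2 <- sqrt(max(drop(t(grad_h2) %*% V %*% grad_h2), 0))
  c(sigma2_a = sqrt(max(V[1, 1], 0)), sigma2_e = sqrt(max(V[2, 2], 0)),
    h2 = se_h2)
}

#' Narrow-sense heritability
#'
#' @param sigma2_a additive genetic variance.
#' @param sigma2_e residual variance.
#' @return `sigma2_a / (sigma2_a + sigma2_e)`.
#' @examples
#' heritability(0.11, 0.29)
#' @export
heritability <- function(sigma2_a, sigma2_e) {
  if (any(sigma2_a < 0) || any(sigma2_e < 0)) stop("variances must be >= 0")
  tot <- sigma2_a + sigma2_e
  if (any(tot == 0)) stop("total variance is zero; heritability undefined")
  sigma2_a / tot
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("Animal-model REML fit\n")
  cat(sprintf("  sigma2_a = %.4f (SE %.4f)\n", x$sigma2_a, x$se["sigma2_a"]))
  cat(sprintf("  sigma2_e = %.4f (SE %.4f)\n", x$sigma2_e, x$se["sigma2_e"]))
  cat(sprintf("  h2       = %.3f (SE %.3f)\n", x$h2, x$se["h2"]))
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  out <- list(varcomp = data.frame(
    component = c("sigma2_a", "sigma2_e", "h2"),
    estimate = c(object$sigma2_a, object$sigma2_e, object$h2),
    se = unname(object$se)),
    beta = object$beta, n = object$n, loglik = object$loglik)
  class(out) <- "summary.reml_fit"
  out
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  cat(sprintf("Animal-model REML (n = %d, restricted logLik = %.3f)\n",
              x$n, x$loglik))
  print(x$varcomp, row.names = FALSE)
  cat("Fixed effects:\n")
  print(x$beta)
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' Natural cubic spline basis for age at scoring
#'
#' Convenience wrapper for use in model formulas: a natural cubic spline with
#' four interior knots at the age quantiles, approximating a smooth age
#' trend.
#'
#' @param age numeric vector, age in days.
#' @return spline basis matrix (see [splines::ns()]).
#' @export
age_spline <- function(age) splines::ns(age, df = 5)

#' Adjust phenotypes for fixed effects
#'
#' Regresses a trait on the specified fixed effects by least squares and
#' returns the residuals, which are the inputs to the breeding-value
#' predictors. With an intercept-only formula the trait is simply centred.
#'
#' @param data phenotype data frame (one row per animal).
#' @param trait name of the trait column.
#' @param fixed one-sided formula of fixed effects, e.g.
#'   `~ sex + age_spline(age_days)`; sex-only adjustment (`~ sex`) is the
#'   convention for single-step evaluation, where age is unavailable for
#'   ancestor records.
#' @param id name of the id column.
#' @return `data` with an added column `<trait>_adj` of residuals
#'   (mean zero).
#' @examples
#' ped <- sim_pedigree(60, 1, seed = 1)
#' sim <- sim_phenotypes(ped, seed = 1)
#' adj <- adjust_phenotypes(sim$pheno, "THS", ~ sex)
#' mean(adj$THS_adj)
#' @export
adjust_phenotypes <- function(data, trait, fixed = ~1, id = "id") {
  if (!trait %in% names(data)) stop("trait column not found: ", trait)
  vars <- all.vars(fixed)
  miss <- vars[!vars %in% names(data)]
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  for (v in vars) {
    bad <- is.na(data[[v]])
    if (any(bad))
      stop("covariate ", v, " missing for animals: ",
           paste(head(data[[id]][bad]), collapse = ", "))
  }
  labs <- attr(stats::terms(fixed), "term.labels")
  f <- if (length(labs) == 0) stats::as.formula(paste(trait, "~ 1"))
       else stats::reformulate(labs, response = trait)
  fit <- lm(f, data = data)
  data[[paste0(trait, "_adj")]] <- unname(residuals(fit))
  data
}
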