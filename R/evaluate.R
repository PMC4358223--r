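#' Random k-fold partition of animals
#'
#' Shuffles the animals with the given seed and deals them round-robin, so
#' fold sizes differ by at most one; the first `n %% k` folds carry the extra
#' animal (1,179 animals in 5 folds gives four folds of 236 and one of 235).
#'
#' @param n number of animals.
#' @param k number of folds.
#' @param seed integer seed (the partition is deterministic given the seed).
#' @return object of class `fold_assignment`: list with `n`, `k`, `fold`
#'   (per-animal fold index in input order) and `seed`.
#' @examples
#' table(make_folds(1179, 5, seed = 1)$fold)
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 1 || k > n) stop("need 1 <= k <= n")
  set.seed(seed)
  ord <- sample.int(n)
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k), length.out = n)
  structure(list(n = n, k = k, fold = fold, seed = seed),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<%d animals in %d folds (sizes %s)>\n", x$n, x$k,
              paste(tabulate(x$fold, x$k), collapse = ", ")))
  invisible(x)
}

#' Predictive ability of EBVs
#'
#' The Pearson correlation `r` between EBVs and adjusted phenotypes of a
#' validation set, and the predictive ability `PA = r / sqrt(h2)`, which
#' rescales `r` to the accuracy scale (a phenotype can correlate with the
#' true breeding value by at most `sqrt(h2)`).
#'
#' @param ebv numeric vector of EBVs.
#' @param pheno_adj adjusted phenotypes, same animals and order.
#' @param h2 heritability of the trait, in (0, 1].
#' @return list with elements `r` and `pa`.
#' @examples
#' predictive_ability(c(1, 2, 3), c(1.2, 1.9, 3.3), h2 = 0.27)
#' @export
predictive_ability <- function(ebv, pheno_adj, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (length(ebv) != length(pheno_adj) || length(ebv) < 3)
    stop("need at least 3 paired values")
  if (sd(ebv) == 0 || sd(pheno_adj) == 0)
    stop("zero variance; correlation undefined")
  r <- cor(ebv, pheno_adj)
  list(r = r, pa = r / sqrt(h2))
}

#' Cross-validated accuracy of a breeding-value predictor
#'
#' Runs the k-fold cross-validation design used to compare the predictors:
#' the genotyped, phenotyped animals are partitioned into folds; each fold in
#' turn is the validation set, its phenotypes are withheld from training, and
#' the per-fold correlation `r` of validation EBVs with validation adjusted
#' phenotypes (and `PA = r / sqrt(h2)`) is averaged over folds. Pedigree
#' methods (`blup`, `single_step`) additionally train on phenotyped but
#' ungenotyped animals. Fixed-effect adjustment uses age and sex for
#' `blup`/`gblup`/`bayes_c` and sex alone for `single_step` (the only
#' covariate assumed available for ancestor records); `h2` comes from the
#' full-sample REML fit unless variance components are supplied.
#'
#' @param cohort a `chd_cohort` (or a list with the same elements).
#' @param method predictor name, see [gp_fit()].
#' @param trait trait column in `cohort$phenotypes` (default `"THS"`).
#' @param k number of folds.
#' @param seed seed for the fold partition (and the Bayes C chain).
#' @param varcomp optional [reml_fit()] or `list(sigma2_a, sigma2_e)`;
#'   estimated by pedigree REML on the full phenotyped sample when `NULL`.
#' @param folds optional precomputed [make_folds()] assignment over the
#'   genotyped, phenotyped animals (in `genotyped_ids` order).
#' @param fixed,fixed_ss adjustment formulas for the standard and
#'   single-step paths.
#' @param adjust_scope `"full"` estimates fixed effects on the full
#'   phenotyped sample (the conventional adjusted-phenotype workflow);
#'   `"train"` re-estimates them within each training set, which avoids the
#'   small leakage of the full-sample adjustment.
#' @param snps optional character vector restricting the marker panel
#'   (genomic methods).
#' @param chain Bayes C [chain_settings()]; its seed is combined with `seed`.
#' @param ... further arguments passed to [gp_fit()].
#' @return object of class `gp_cv`: data frame `per_fold` (fold, n_val, r,
#'   pa), scalars `mean_r`, `mean_pa`, `h2`, `method`, `trait`.
#' @examples
#' co <- sim_chd_cohort(100, 2, n_snps = 150, seed = 1)
#' cv <- cross_validate(co, "gblup", k = 5, seed = 1,
#'                      varcomp = list(sigma2_a = 0.11, sigma2_e = 0.29))
#' cv$mean_r
#' @export
cross_validate <- function(cohort, method = c("blup", "gblup", "bayes_c",
                                              "single_step"),
                           trait = "THS", k = 5, seed = 1L, varcomp = NULL,
                           folds = NULL,
                           fixed = ~ sex + age_spline(age_days),
                           fixed_ss = ~ sex,
                           adjust_scope = c("full", "train"),
                           snps = NULL, chain = chain_settings(2000L, 500L, 4L),
                           ...) {
  method <- match.arg(method)
  adjust_scope <- match.arg(adjust_scope)
  ph <- cohort$phenotypes
  if (!trait %in% names(ph)) stop("trait column not found: ", trait)
  gids <- as.character(intersect(cohort$genotyped_ids, ph$id))
  if (length(gids) < k) stop("fewer genotyped phenotyped animals than folds")
  if (is.null(folds)) folds <- make_folds(length(gids), k, seed)
  if (folds$n != length(gids)) stop("fold assignment size mismatch")
  fml <- if (method == "single_step") fixed_ss else fixed

  if (is.null(varcomp)) {
    A <- a_matrix(cohort$pedigree)
    f <- stats::as.formula(paste(
      trait, "~", paste(deparse(fml[[2]]), collapse = "")))
    varcomp <- reml_fit(f, ph, A)
  }
  h2 <- heritability(varcomp$sigma2_a, varcomp$sigma2_e)
  lambda <- varcomp$sigma2_e / varcomp$sigma2_a

  geno <- cohort$genotypes
  if (!is.null(snps) && !is.null(geno)) {
    geno <- geno[, snps, drop = FALSE]
  }
  # relationship structures that do not depend on the fold
  pre <- switch(method,
    blup = list(K = a_inverse(cohort$pedigree)),
    gblup = list(K = g_matrix(geno[gids, , drop = FALSE])),
    single_step = list(K = h_inverse(cohort$pedigree,
                                     geno[gids, , drop = FALSE], ...)),
    bayes_c = list())

  adjust_for <- function(train_ids) {
    if (adjust_scope == "full") return(adjust_phenotypes(ph, trait, fml))
    tr <- ph[ph$id %in% as.integer(train_ids) | ph$id %in% train_ids, ,
             drop = FALSE]
    fit <- lm(stats::as.formula(paste(
      trait, "~", paste(deparse(fml[[2]]), collapse = ""))), data = tr)
    out <- ph
    out[[paste0(trait, "_adj")]] <-
      ph[[trait]] - unname(predict(fit, newdata = ph))
    out
  }

  per <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    val_ids <- gids[folds$fold == f]
    train_g <- setdiff(gids, val_ids)
    train_ids <- if (method %in% c("blup", "single_step")) {
      union(train_g, setdiff(as.character(ph$id), gids))
    } else train_g
    adj <- adjust_for(train_ids)
    ycol <- setNames(adj[[paste0(trait, "_adj")]], adj$id)
    ytr <- ycol[train_ids]
    fit <- switch(method,
      blup = gp_fit("blup", ytr, pedigree = cohort$pedigree,
                    lambda = lambda),
      gblup = structure(list(method = "gblup", lambda = lambda,
                             n_train = length(ytr),
                             ebv = mixed_model_solve(ytr, pre$K, lambda)),
                        class = c("gp_gblup", "gp_fit")),
      single_step = structure(list(method = "single_step", lambda = lambda,
                                   n_train = length(ytr),
                                   ebv = mixed_model_solve(ytr, pre$K,
                                                           lambda)),
                              class = c("gp_single_step", "gp_fit")),
      bayes_c = {
        ch <- chain_settings(chain$burn_in, chain$n_samples, chain$thin,
                             seed = chain$seed + 7L * f + seed)
        gp_fit("bayes_c", ytr, geno = geno[gids, , drop = FALSE],
               chain = ch, ...)
      })
    ev <- predict(fit, val_ids)
    pa <- predictive_ability(ev, ycol[val_ids], h2)
    per[[f]] <- data.frame(fold = f, n_val = length(val_ids),
                           r = pa$r, pa = pa$pa)
  }
  per <- do.call(rbind, per)
  structure(list(per_fold = per, mean_r = mean(per$r), mean_pa = mean(per$pa),
                 h2 = h2, lambda = lambda, method = method, trait = trait,
                 k = folds$k, seed = seed),
            class = "gp_cv")
}

#' @export
print.gp_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s for %s: mean r = %.3f, mean PA = %.3f (h2 = %.3f)\n",
              x$k, x$method, x$trait, x$mean_r, x$mean_pa, x$h2))
  invisible(x)
}

#' Single-marker GWAS ranking
#'
#' Regresses adjusted phenotypes on each SNP's allele dose by least squares
#' and ranks SNPs by the two-sided t-test p-value of the slope (ascending,
#' ties broken by marker index). No relatedness correction is applied, so
#' p-values are anticonservative under family structure; the ranking is used
#' only to pre-select markers, not for association claims.
#'
#' @param y named vector of adjusted phenotypes.
#' @param geno dose matrix covering the animals in `y`.
#' @return data frame sorted by p-value: `snp`, `index`, `beta`, `t`, `p`.
#'   Monomorphic SNPs receive p = 1.
#' @export
gwas_rank <- function(y, geno) {
  ids <- rownames(geno)
  ti <- match(names(y), ids)
  if (anyNA(ti)) stop("animals absent from genotype matrix")
  X <- geno[ti, , drop = FALSE]
  X[is.na(X)] <- NA # keep explicit
  n <- length(y)
  xm <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2, xm)
  Xc[is.na(Xc)] <- 0 # mean-imputed doses drop out of the slope
  yc <- y - mean(y)
  sxx <- colSums(Xc^2)
  sxy <- drop(crossprod(Xc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  sse <- pmax(sum(yc^2) - beta^2 * sxx, 0)
  se <- sqrt(sse / (n - 2) / pmax(sxx, .Machine$double.eps))
  tval <- ifelse(sxx > 0 & se > 0, beta / se, 0)
  p <- ifelse(sxx > 0, 2 * pt(-abs(tval), df = n - 2), 1)
  out <- data.frame(snp = colnames(geno), index = seq_len(ncol(geno)),
                    beta = beta, t = tval, p = p)
  out[order(out$p, out$index), , drop = FALSE]
}

#' Select a marker subset
#'
#' @param snps character vector of all marker names (in map order).
#' @param fraction fraction of markers to keep, in (0, 1]; the subset size is
#'   `ceiling(fraction * length(snps))`, the rounding rule that reproduces
#'   the standard thinning behaviour.
#' @param mode `"random"` (uniform without replacement) or `"top_gwas"`
#'   (head of the supplied ranking).
#' @param seed seed for random selection.
#' @param ranking for `mode = "top_gwas"`: a [gwas_rank()] result or a
#'   character vector of markers in rank order.
#' @return character vector of selected marker names (in original map order
#'   for `random`, rank order for `top_gwas`).
#' @examples
#' length(select_snps(paste0("s", 1:106282), 0.10, "random", seed = 1))
#' @export
select_snps <- function(snps, fraction, mode = c("random", "top_gwas"),
                        seed = 1L, ranking = NULL) {
  mode <- match.arg(mode)
  if (length(snps) == 0) stop("empty SNP list")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  size <- ceiling(fraction * length(snps))
  if (mode == "random") {
    set.seed(seed)
    return(snps[sort(sample.int(length(snps), size))])
  }
  if (is.null(ranking)) stop("top_gwas mode needs a ranking")
  rk <- if (is.data.frame(ranking)) ranking$snp else ranking
  rk <- rk[rk %in% snps]
  utils::head(rk, size)
}

#' Marker-density and pre-selection experiment
#'
#' For each marker fraction and selection mode, rebuilds the genomic
#' relationship matrix from the marker subset and reruns GBLUP
#' cross-validation. `"random"` thins markers uniformly (one draw per
#' fraction); `"top_gwas"` ranks markers by a GWAS within each training set
#' (honest pre-selection); `"biased"` ranks them once on the full data —
#' training plus validation — which leaks validation information and is
#' included only to quantify that upward bias (its rows are flagged).
#'
#' @inheritParams cross_validate
#' @param fractions numeric vector of marker fractions.
#' @param modes subset of `c("random", "top_gwas", "biased")`.
#' @return data frame: `fraction`, `mode`, `n_snps`, `mean_r`, `mean_pa`,
#'   `biased`.
#' @export
density_experiment <- function(cohort, fractions = c(0.01, 0.1, 0.2, 0.5,
                                                     0.75, 1),
                               modes = c("random", "top_gwas", "biased"),
                               trait = "THS", k = 5, seed = 1L,
                               varcomp = NULL,
                               fixed = ~ sex + age_spline(age_days)) {
  modes <- match.arg(modes, several.ok = TRUE)
  ph <- cohort$phenotypes
  gids <- as.character(intersect(cohort$genotyped_ids, ph$id))
  geno <- cohort$genotypes[gids, , drop = FALSE]
  snps <- colnames(geno)
  folds <- make_folds(length(gids), k, seed)
  if (is.null(varcomp)) {
    A <- a_matrix(cohort$pedigree)
    f <- stats::as.formula(paste(
      trait, "~", paste(deparse(fixed[[2]]), collapse = "")))
    varcomp <- reml_fit(f, ph, A)
  }
  h2 <- heritability(varcomp$sigma2_a, varcomp$sigma2_e)
  lambda <- varcomp$sigma2_e / varcomp$sigma2_a
  adj <- adjust_phenotypes(ph, trait, fixed)
  ycol <- setNames(adj[[paste0(trait, "_adj")]], adj$id)

  run_cv <- function(subset_fun) {
    rs <- pas <- numeric(folds$k)
    for (f in seq_len(folds$k)) {
      val_ids <- gids[folds$fold == f]
      train_g <- setdiff(gids, val_ids)
      sub <- subset_fun(f, train_g)
      G <- g_matrix(geno[, sub, drop = FALSE])
      ebv <- mixed_model_solve(ycol[train_g], G, lambda)
      pa <- predictive_ability(ebv[val_ids], ycol[val_ids], h2)
      rs[f] <- pa$r; pas[f] <- pa$pa
    }
    c(mean(rs), mean(pas))
  }

  full_rank <- NULL
  rows <- list()
  for (mode in modes) {
    if (mode == "biased" && is.null(full_rank))
      full_rank <- gwas_rank(ycol[gids], geno)
    for (fr in fractions) {
      size <- ceiling(fr * length(snps))
      res <- switch(mode,
        random = {
          sub <- select_snps(snps, fr, "random", seed = seed + round(1000 * fr))
          run_cv(function(f, tr) sub)
        },
        top_gwas = run_cv(function(f, tr) {
          rk <- gwas_rank(ycol[tr], geno)
          select_snps(snps, fr, "top_gwas", ranking = rk)
        }),
        biased = run_cv(function(f, tr)
          select_snps(snps, fr, "top_gwas", ranking = full_rank)))
      rows[[length(rows) + 1L]] <-
        data.frame(fraction = fr, mode = mode, n_snps = size,
                   mean_r = res[1], mean_pa = res[2],
                   biased = mode == "biased")
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$biased))
    message("note: 'biased' rows rank SNPs using validation data ",
            "and overstate accuracy by construction")
  out
}
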