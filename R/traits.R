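#' Hip-score component definitions and trait transforms
#'
#' The UK hip-scoring scheme grades nine radiographic components per hip:
#' Norberg angle (NA), subluxation (SUB), cranial acetabular edge (CrAE),
#' dorsal acetabular edge (DAE), cranial effective acetabular rim (CrEAR),
#' acetabular fossa (AF), caudal acetabular edge (CAE), femoral head/neck
#' exostosis (FHNE) and femoral head recontouring (FHR). All components score
#' 0-6 except CAE (0-5), so one hip totals at most 53 and the total hip score
#' (HS, both hips) lies in 0-106, 0 being a perfect hip.
#'
#' @format `hip_components` is a character vector of the nine component
#'   abbreviations in scheme order; `hip_component_max` the per-hip maximum of
#'   each; `chd_index_weights` the component weights of the optimum selection
#'   index against hip dysplasia.
#' @name hip_components
NULL

#' @rdname hip_components
#' @export
hip_components <- c("NA", "SUB", "CrAE", "DAE", "CrEAR", "AF", "CAE",
                    "FHNE", "FHR")

#' @rdname hip_components
#' @export
hip_component_max <- setNames(c(6L, 6L, 6L, 6L, 6L, 6L, 5L, 6L, 6L),
                              hip_components)

#' @rdname hip_components
#' @export
chd_index_weights <- setNames(
  c(0.538, 0.546, 0.121, -0.184, -0.126, -0.310, -0.186, 0.371, 0.564),
  hip_components)

#' Log-transformed total hip score
#'
#' `THS = log(1 + HS)`, the standard transform that tames the strong right
#' skew of the raw hip score.
#'
#' @param hs integer-valued total hip score(s) in 0..106.
#' @return `log(1 + hs)`, same length as `hs`.
#' @examples
#' compute_ths(c(0, 10, 106))
#' @export
compute_ths <- function(hs) {
  if (any(hs < 0 | hs > 106)) stop("hip score must lie between 0 and 106")
  log(1 + hs)
}

#' Optimum selection index over hip-score components
#'
#' Weighted sum of the nine (total, i.e. left+right) component scores using
#' the published index weights, which up-weight the heritable laxity
#' components (NA, SUB, FHR) relative to their unit weighting in HS.
#'
#' @param components numeric vector (or 9-column matrix, one row per animal)
#'   of component scores in the order `hip_components`.
#' @return numeric index value(s).
#' @examples
#' compute_index(c(1, 0, 0, 0, 0, 0, 0, 0, 0)) # == weight of NA
#' @export
compute_index <- function(components) {
  if (is.matrix(components) || is.data.frame(components)) {
    components <- as.matrix(components)
    if (ncol(components) != 9) stop("expected 9 component columns")
    return(drop(components %*% chd_index_weights))
  }
  if (length(components) != 9) stop("expected exactly 9 component values")
  sum(components * chd_index_weights)
}

#' Describe a simulated trait architecture
#'
#' Bundles the generative parameters for hip-score-like phenotypes. The trait
#' is generated on the log scale (the THS scale): a latent liability
#' `L = mu + sex + exercise + age + a + e` with additive values `a` of
#' variance `sigma2_a` and residuals of variance `sigma2_e`; the hip score is
#' `HS = round(exp(L) - 1)` clamped to 0..106, and component scores are a
#' capped multinomial allocation of HS across the 18 side-by-component cells
#' with per-component allocation weights `component_loadings`. Components
#' receiving a larger share of HS inherit more of the additive signal, so the
#' default loadings give CrAE the smallest share (and hence the lowest
#' component heritability).
#'
#' @param n_qtl number of causal SNPs; 0 requests a purely polygenic
#'   (infinitesimal, pedigree-driven) architecture.
#' @param qtl_effect_sd relative spread of raw QTL effect draws before they
#'   are rescaled so the additive variance equals `sigma2_a` exactly.
#' @param sigma2_a additive genetic variance on the liability (THS) scale.
#' @param sigma2_e residual variance on the liability scale.
#' @param mean_liability mean of the latent log-scale liability; the default
#'   2.35 corresponds to a median HS around 10.
#' @param sex_effect additive liability shift for males.
#' @param exercise_effects liability shifts for daily-exercise categories
#'   1-4.
#' @param age_effect_fn function of age in days returning a liability shift;
#'   the default is a weak linear trend (age effects in scored dogs under 5
#'   years are small).
#' @param component_loadings 9 non-negative allocation weights (order
#'   `hip_components`), normalized internally.
#' @return object of class `trait_arch` (a list), with derived element
#'   `target_h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#' @export
trait_architecture <- function(n_qtl = 0L,
                               qtl_effect_sd = 1,
                               sigma2_a = 0.11,
                               sigma2_e = 0.29,
                               mean_liability = 2.35,
                               sex_effect = 0.1,
                               exercise_effects = c(0, 0.04, 0.07, 0.10),
                               age_effect_fn = function(age) 2e-5 * (age - 1000),
                               component_loadings = c(0.22, 0.22, 0.05, 0.10,
                                                      0.08, 0.10, 0.07, 0.08,
                                                      0.08)) {
  if (sigma2_a < 0 || sigma2_e <= 0) stop("variances must be positive")
  h2 <- sigma2_a / (sigma2_a + sigma2_e)
  if (h2 < 0 || h2 >= 1) stop("target heritability must lie in [0, 1)")
  if (length(exercise_effects) != 4) stop("need 4 exercise-category effects")
  if (length(component_loadings) != 9 || any(component_loadings < 0))
    stop("component_loadings must be 9 non-negative weights")
  structure(list(
    n_qtl = as.integer(n_qtl), qtl_effect_sd = qtl_effect_sd,
    sigma2_a = sigma2_a, sigma2_e = sigma2_e, target_h2 = h2,
    mean_liability = mean_liability, sex_effect = sex_effect,
    exercise_effects = exercise_effects, age_effect_fn = age_effect_fn,
    component_loadings = component_loadings / sum(component_loadings)),
    class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf(
    "<trait_arch: %s, sigma2_a=%.3g sigma2_e=%.3g (h2=%.3f)>\n",
    if (x$n_qtl > 0) paste0(x$n_qtl, " QTL") else "infinitesimal",
    x$sigma2_a, x$sigma2_e, x$target_h2))
  invisible(x)
}
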