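#' Per-marker gamma factors
#'
#' The gamma factor of marker m is the relatedness-induced shrinkage of the
#' naive score statistic,
#' `gamma_m = sigma2 * (g'_m Vinv g_m) / (g'_m g_m)` with `g_m` the centered
#' genotype vector and `V = sigma2_g R + sigma2_e I`.  Under a polygenic
#' architecture the factors are nearly constant across markers and well
#' approximated by their analytic average [gamma_bar()]; this near-constancy
#' is what licenses the GRAMMAR+ transformation.  With `R = I`,
#' `gamma_m = 1` exactly.  Monomorphic markers have no gamma and are flagged.
#'
#' @param fit a `polygenic` fit.
#' @param region a `genotype_region` (or plain genotype matrix) aligned with
#'   the fit's individuals.
#' @return A `gamma_factors` list: `gamma` (per marker, NA for monomorphic),
#'   `gamma_bar` (analytic), `mean`, `var` (empirical moments over
#'   polymorphic markers), `monomorphic` (logical).
#' @export
gamma_factors <- function(fit, region) {
  G <- if (inherits(region, "genotype_region")) region$G else as.matrix(region)
  stopifnot(nrow(G) == fit$n)
  Gc <- sweep(G, 2, colMeans(G))
  css <- colSums(Gc * Gc)
  mono <- css <= 0
  gamma <- rep(NA_real_, ncol(G))
  if (any(!mono)) {
    Gp <- Gc[, !mono, drop = FALSE]
    VG <- .vinv(fit, Gp)
    gamma[!mono] <- fit$sigma2 * colSums(Gp * VG) / css[!mono]
  }
  if (any(mono)) message(sum(mono), " monomorphic marker(s) excluded from gamma")
  structure(list(gamma = gamma, gamma_bar = gamma_bar(fit),
                 mean = mean(gamma[!mono]),
                 var = stats::var(gamma[!mono]),
                 monomorphic = mono),
            class = "gamma_factors")
}

#' @export
print.gamma_factors <- function(x, ...) {
  cat(sprintf(
    "Gamma factors: %d markers (%d monomorphic)\n  mean %.5f, var %.3g; analytic gamma_bar %.5f\n",
    length(x$gamma), sum(x$monomorphic), x$mean, x$var, x$gamma_bar))
  invisible(x)
}

#' Analytic averaged gamma factor
#'
#' The expected gamma factor of a random marker whose genotypic covariance
#' between individuals is proportional to R (as for gene-dropped variants):
#' `gamma_bar = sigma2 * tr(Vinv H R H) / tr(H R H)` with
#' `H = I - 11'/N` the centering projector, evaluated in O(N) from the
#' eigen-cache of R.  Depends only on the heritability, the total variance
#' and the relationship matrix; equals 1 when `R = I` or `h2 = 0`, and lies
#' in (0, 1] for PSD R with unit diagonal, since relatedness can only
#' shrink the naive score statistic.
#'
#' @param fit a `polygenic` fit.
#' @return scalar gamma_bar.
#' @export
gamma_bar <- function(fit) {
  lam <- fit$eigR$values
  dv <- fit$sigma2_g * lam + fit$sigma2_e
  n <- length(lam)
  u1 <- drop(crossprod(fit$eigR$vectors, rep(1, n)))   # U' 1
  tr_VR <- sum(lam / dv)
  oRVo <- sum(u1^2 * lam / dv)     # 1' R Vinv 1  (shared eigenbasis)
  oRo <- sum(u1^2 * lam)           # 1' R 1
  oVo <- sum(u1^2 / dv)            # 1' Vinv 1
  num <- tr_VR - 2 * oRVo / n + oRo * oVo / n^2
  den <- sum(lam) - oRo / n
  fit$sigma2 * num / den
}

#' Phenotype transformations for unrelated-sample machinery
#'
#' Produces one of the three trait presentations used throughout the
#' package, each tagged with its provenance:
#' \describe{
#'   \item{`"original"`}{the covariate-centered trait `ytilde = y - X alpha`.}
#'   \item{`"env_residual"`}{environmental residuals
#'     `ytilde - u_hat = sigma2_e Vinv ytilde` (BLUP-subtracted).}
#'   \item{`"grammar_plus"`}{the GRAMMAR+ transformation
#'     `y+ = (sigma2 / sqrt(gamma_bar)) Vinv ytilde`.  Simple-regression
#'     score statistics on `y+` with residual variance `sigma2` approximate
#'     the exact mixed-model score statistics (exactly so when `R = I`), and
#'     the sample variance of `y+` is approximately `sigma2`, so software
#'     that re-estimates the residual variance stays calibrated.}
#'   \item{`"grammar_gamma"`}{the single-SNP-oriented variant that scales by
#'     `sigma2 / gamma_bar` instead of `sigma2 / sqrt(gamma_bar)`.}
#' }
#'
#' @param fit a `polygenic` fit.
#' @param type transformation tag.
#' @return A `transformed_trait`: numeric vector (names = ids) with
#'   attributes `transform`, `sigma2`, `gamma_bar` and `h2`.
#' @examples
#' ped <- sim_pedigree(n_families = 10, generations = 3, seed = 1)
#' eg  <- relmat_eigen(pedigree_relmat(ped))
#' y   <- sim_phenotype(eg, h2 = 0.5, sigma2 = 1, seed = 2)
#' fit <- polygenic(y, relmat = eg)
#' yp  <- transform_trait(fit, "grammar_plus")
#' c(var(yp), fit$sigma2)
#' @export
transform_trait <- function(fit, type = c("grammar_plus", "env_residual",
                                          "original", "grammar_gamma")) {
  type <- match.arg(type)
  gb <- gamma_bar(fit)
  yt <- fit$ytilde
  v <- switch(type,
    original      = yt,
    env_residual  = drop(fit$sigma2_e * .vinv(fit, yt)),
    grammar_plus  = drop(fit$sigma2 / sqrt(gb) * .vinv(fit, yt)),
    grammar_gamma = drop(fit$sigma2 / gb * .vinv(fit, yt)))
  names(v) <- fit$ids
  structure(v, transform = type, sigma2 = fit$sigma2, gamma_bar = gb,
            h2 = fit$h2, class = "transformed_trait")
}

#' @export
print.transformed_trait <- function(x, ...) {
  cat(sprintf("Transformed trait (%s): n = %d, var = %.4g, sigma2 = %.4g\n",
              attr(x, "transform"), length(x), stats::var(as.numeric(x)),
              attr(x, "sigma2")))
  invisible(x)
}

#' Simple-regression per-marker scores on a transformed trait
#'
#' For each polymorphic marker, the simple-regression effect estimate and
#' score statistic on the supplied (transformed) trait:
#' `beta_m = (g'_m y) / (g'_m g_m)` and
#' `T_m = (g'_m y)^2 / (sigma2 * g'_m g_m)` with centered genotypes.  On a
#' GRAMMAR+ trait these approximate the exact mixed-model statistics of
#' [mixed_score()] (exactly for unrelated samples).
#'
#' @param trait a `transformed_trait` (or plain numeric vector).
#' @param region a `genotype_region` or genotype matrix, sample-aligned.
#' @param sigma2 residual variance used in the score denominator; defaults
#'   to the `sigma2` carried by the trait.
#' @return data.frame with columns `snp`, `maf`, `beta`, `score`;
#'   monomorphic markers are excluded.
#' @export
simple_score <- function(trait, region, sigma2 = attr(trait, "sigma2")) {
  G <- if (inherits(region, "genotype_region")) region$G else as.matrix(region)
  y <- as.numeric(trait)
  stopifnot(nrow(G) == length(y))
  if (is.null(sigma2)) stop("sigma2 must be supplied for a plain trait vector")
  Gc <- sweep(G, 2, colMeans(G))
  css <- colSums(Gc * Gc)
  keep <- css > 0
  s <- drop(crossprod(Gc[, keep, drop = FALSE], y))
  p <- colMeans(G)[keep]
  snp <- if (inherits(region, "genotype_region")) region$snp[keep]
         else paste0("snp", which(keep))
  data.frame(snp = snp, maf = pmin(p, 1 - p),
             beta = s / css[keep],
             score = s^2 / (sigma2 * css[keep]),
             row.names = NULL)
}

#' Exact mixed-model per-marker score statistics
#'
#' The exact related-sample score statistic for each marker,
#' `T_m = (g'_m Vinv ytilde)^2 / (g'_m Vinv g_m)` with centered genotypes,
#' computed by solves against the fitted `V`.  Serves as the oracle against
#' which the GRAMMAR+ approximation is judged.
#'
#' @param fit a `polygenic` fit.
#' @param region a `genotype_region` or genotype matrix.
#' @param ytilde centered trait; defaults to the fit's `y - X alpha`.
#' @return data.frame with columns `snp`, `maf`, `beta`, `score`.
#' @export
mixed_score <- function(fit, region, ytilde = fit$ytilde) {
  G <- if (inherits(region, "genotype_region")) region$G else as.matrix(region)
  stopifnot(nrow(G) == fit$n)
  Gc <- sweep(G, 2, colMeans(G))
  css <- colSums(Gc * Gc)
  keep <- css > 0
  Gp <- Gc[, keep, drop = FALSE]
  Vy <- drop(.vinv(fit, ytilde))
  num <- drop(crossprod(Gp, Vy))
  den <- colSums(Gp * .vinv(fit, Gp))
  p <- colMeans(G)[keep]
  snp <- if (inherits(region, "genotype_region")) region$snp[keep]
         else paste0("snp", which(keep))
  data.frame(snp = snp, maf = pmin(p, 1 - p),
             beta = num / den, score = num^2 / den, row.names = NULL)
}
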