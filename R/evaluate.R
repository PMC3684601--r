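#' Sliding windows over an ordered variant list
#'
#' Per-chromosome windows of `window` markers shifted by `shift` markers in
#' marker-index space.  Enumeration stops once a window reaches the last
#' marker of the chromosome; a trailing partial window is kept iff it holds
#' at least 2 markers, so every marker is covered except possibly a
#' remainder shorter than 2.  `shift = window` gives disjoint blocks.
#'
#' @param chrom chromosome label per variant (in sorted order), or a
#'   `genotype_region` whose `chrom` is used.
#' @param window window length in markers (default 20).
#' @param shift shift in markers (default 10).
#' @return data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive global variant indices).
#' @examples
#' sliding_windows(rep("1", 35), window = 20, shift = 10)
#' @export
sliding_windows <- function(chrom, window = 20, shift = 10) {
  if (inherits(chrom, "genotype_region")) chrom <- chrom$chrom
  stopifnot(window >= 2, shift >= 1)
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    n <- length(idx)
    if (n < 2) next
    s <- 1L
    repeat {
      e <- min(s + window - 1L, n)
      if (e - s + 1L >= 2L)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = idx[s],
                                              end = idx[e])
      if (e >= n) break
      s <- s + shift
      if (s > n) break
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

#' Empirical type I error at nominal thresholds
#'
#' The proportion of null-region P values at or below each nominal alpha,
#' with binomial standard errors `sqrt(p(1-p)/n)`.
#'
#' @param p null-region P values (pooled across replicates).
#' @param alphas nominal levels.
#' @return data.frame with columns `alpha`, `rate`, `se`, `n`.
#' @export
type1_error <- function(p, alphas = c(0.01, 0.05, 0.1)) {
  p <- p[!is.na(p)]
  n <- length(p)
  if (n == 0) stop("no null P values supplied")
  rate <- vapply(alphas, function(a) mean(p <= a), numeric(1))
  data.frame(alpha = alphas, rate = rate,
             se = sqrt(rate * (1 - rate) / n), n = n)
}

#' Empirical significance threshold from a pooled null distribution
#'
#' The alpha-quantile of the null P values by the lower-order-statistic
#' convention: the `floor(alpha * n)`-th smallest value.  Testing at this
#' threshold fixes the realized type I error at `alpha` regardless of how
#' miscalibrated the nominal P values are.
#'
#' @param p pooled null P values.
#' @param alpha target type I error.
#' @return scalar threshold on the P-value scale.
#' @export
empirical_threshold <- function(p, alpha = 0.05) {
  p <- sort(p[!is.na(p)])
  k <- floor(alpha * length(p))
  if (k < 1) stop("insufficient null realizations for alpha = ", alpha)
  p[k]
}

#' Empirical power at a threshold
#'
#' Proportion of causal-region P values at or below `threshold`, with
#' binomial standard error.  Use an [empirical_threshold()] for power at a
#' fixed realized type I error ("empirical power"), or the nominal alpha
#' itself ("nominal power").
#'
#' @param p causal-region P values.
#' @param threshold significance cutoff.
#' @return list with `power`, `se`, `n`.
#' @export
empirical_power <- function(p, threshold) {
  p <- p[!is.na(p)]
  pw <- mean(p <= threshold)
  list(power = pw, se = sqrt(pw * (1 - pw) / length(p)), n = length(p))
}

#' Replicate simulation study: calibration and power of the kernel test
#'
#' The package's evaluation harness.  A fixed multi-family pedigree is
#' simulated once; each replicate gene-drops fresh genotypes, draws a
#' polygenic trait (plus optional causal regions), fits the polygenic model
#' (optionally with leading kinship principal components as covariates),
#' produces the requested trait presentations, and runs the weighted kernel
#' test on every marker window under every weight scheme.  Null windows pooled across
#' replicates estimate type I error and empirical thresholds; causal windows
#' estimate empirical and nominal power.
#'
#' @param n_replicates number of trait replicates.
#' @param ped a `pedigree`; if NULL one is simulated from `n_families`,
#'   `generations`, `offspring`.
#' @param n_families,generations,offspring pedigree layout (see
#'   [sim_pedigree()]).
#' @param n_markers markers gene-dropped per replicate.
#' @param window,shift marker windows (see [sliding_windows()]);
#'   `shift = window` (default) gives disjoint regions.
#' @param prop_common proportion of common variants in the MAF spectrum.
#' @param h2,sigma2 background heritability and total variance.
#' @param causal NULL for a null study, or a list with `regions` (window
#'   indices), `n_causal` (variants per region), `q2` (per-variant variance
#'   fraction) and `signs` (effect sign pattern, e.g. `c(1, 1, 1, -1, -1)`).
#' @param schemes named list of beta weight parameter pairs, e.g.
#'   `list(w1 = c(0.5, 0.5), w2 = c(1, 1), w3 = c(1, 25))`.
#' @param transforms trait presentations to evaluate.
#' @param pcs number of kinship principal components used as covariates
#'   (default 0: the default pedigree layout has unrelated families, so
#'   there is no between-family structure for PCs to absorb; set e.g. 10
#'   when emulating designs with between-family relatedness).
#' @param convention beta-weight convention.
#' @param resampling permutations per test (0 = mixture P values only).
#' @param alphas nominal levels for the type I error summary.
#' @param seed master seed; per-replicate child seeds are drawn from it, so
#'   the full study is reproducible.
#' @param verbose print per-replicate progress.
#' @return A `famkernel_study` list: `results` (long data.frame: replicate,
#'   region, causal, transform, scheme, n_markers, Q, p, p_resampling),
#'   `type1` (per transform x scheme x alpha), `thresholds`, `power`
#'   (empirical and nominal, when causal), `failed` (replicates skipped),
#'   and `config`.
#' @export
run_study <- function(n_replicates = 10, ped = NULL, n_families = 50,
                      generations = 3, offspring = 2, n_markers = 200,
                      window = 20, shift = window, prop_common = 0.5,
                      h2 = 0.5, sigma2 = 1, causal = NULL,
                      schemes = list(w2 = c(1, 1)),
                      transforms = c("original", "env_residual",
                                     "grammar_plus"),
                      pcs = 0, convention = "pdf_squared", resampling = 0,
                      alphas = c(0.01, 0.05, 0.1), seed = 1,
                      verbose = FALSE) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates + 1L)
  if (is.null(ped))
    ped <- sim_pedigree(n_families, generations, offspring,
                        seed = rep_seeds[length(rep_seeds)])
  eg <- relmat_eigen(pedigree_relmat(ped))
  n <- length(eg$ids)
  X <- matrix(1, n, 1, dimnames = list(eg$ids, "(Intercept)"))
  if (pcs > 0) {
    R <- eg$vectors %*% (eg$values * t(eg$vectors))
    rownames(R) <- colnames(R) <- eg$ids
    X <- cbind(X, kinship_pcs(R, k = pcs))
  }
  wins <- sliding_windows(rep("1", n_markers), window = window, shift = shift)
  nw <- nrow(wins)
  causal_windows <- if (is.null(causal)) integer(0) else causal$regions
  if (length(causal_windows) && max(causal_windows) > nw)
    stop("causal region index exceeds the number of windows")

  rows <- vector("list", n_replicates)
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(
      .study_replicate(r, ped, eg, X, wins, causal, n_markers, prop_common,
                       h2, sigma2, schemes, transforms, convention,
                       resampling, rep_seeds[2L * r - 1L], rep_seeds[2L * r]),
      error = function(e) {
        warning("replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) failed <- failed + 1L else rows[[r]] <- res
    if (verbose && r %% 50 == 0) message("replicate ", r, "/", n_replicates)
  }
  results <- do.call(rbind, rows)

  grid <- unique(results[, c("transform", "scheme")])
  type1 <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- results$transform == grid$transform[i] &
           results$scheme == grid$scheme[i] & !results$causal
    t1 <- type1_error(results$p[sel], alphas)
    cbind(transform = grid$transform[i], scheme = grid$scheme[i], t1)
  }))
  thresholds <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- results$transform == grid$transform[i] &
           results$scheme == grid$scheme[i] & !results$causal
    thr <- tryCatch(empirical_threshold(results$p[sel], 0.05),
                    error = function(e) NA_real_)
    data.frame(transform = grid$transform[i], scheme = grid$scheme[i],
               alpha = 0.05, threshold = thr)
  }))
  power <- NULL
  if (length(causal_windows)) {
    power <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      sel <- results$transform == grid$transform[i] &
             results$scheme == grid$scheme[i] & results$causal
      thr <- thresholds$threshold[thresholds$transform == grid$transform[i] &
                                  thresholds$scheme == grid$scheme[i]]
      emp <- empirical_power(results$p[sel], thr)
      nom <- empirical_power(results$p[sel], 0.05)
      data.frame(transform = grid$transform[i], scheme = grid$scheme[i],
                 empirical = emp$power, empirical_se = emp$se,
                 nominal = nom$power, nominal_se = nom$se, n = emp$n)
    }))
  }
  structure(list(results = results, type1 = type1, thresholds = thresholds,
                 power = power, failed = failed,
                 config = list(n_replicates = n_replicates, n = n,
                               n_markers = n_markers, window = window,
                               shift = shift, h2 = h2, sigma2 = sigma2,
                               pcs = pcs, causal = causal,
                               prop_common = prop_common, seed = seed)),
            class = "famkernel_study")
}

.study_replicate <- function(r, ped, eg, X, wins, causal, n_markers,
                             prop_common, h2, sigma2, schemes, transforms,
                             convention, resampling, seed_g, seed_y) {
  mafs <- sim_mafs(n_markers, prop_common, seed = seed_g)
  G <- gene_drop(ped, mafs, seed = seed_g + 1L)
  causal_spec <- NULL
  causal_windows <- integer(0)
  if (!is.null(causal)) {
    causal_windows <- causal$regions
    set.seed(seed_g + 2L)
    cols <- unlist(lapply(causal_windows, function(wd) {
      idx <- wins$start[wd]:wins$end[wd]
      poly <- idx[colMeans(G[, idx, drop = FALSE]) > 0 &
                  colMeans(G[, idx, drop = FALSE]) < 1]
      if (length(poly) < causal$n_causal)
        stop("too few polymorphic markers for causal region ", wd)
      sample(poly, causal$n_causal)
    }))
    p <- colMeans(G[, cols, drop = FALSE])
    p <- pmin(p, 1 - p)
    beta <- causal_effects(p, q2 = causal$q2, signs = causal$signs,
                           sigma2 = sigma2)
    causal_spec <- list(G = G[, cols, drop = FALSE], beta = beta)
  }
  y <- sim_phenotype(eg, h2 = h2, sigma2 = sigma2, causal = causal_spec,
                     seed = seed_y)
  fit <- polygenic(y, X = X, relmat = eg)
  traits <- lapply(transforms, function(tt) transform_trait(fit, tt))
  names(traits) <- transforms

  out <- list()
  for (wd in seq_len(nrow(wins))) {
    reg <- genotype_region(G[, wins$start[wd]:wins$end[wd], drop = FALSE],
                           chrom = wins$chrom[wd],
                           pos = wins$start[wd]:wins$end[wd])
    if (sum(!reg$monomorphic) < 2) next
    for (sc in names(schemes)) for (tt in transforms) {
      kt <- kernel_test(traits[[tt]], reg, weights = schemes[[sc]],
                        convention = convention, covariates = X,
                        resampling = resampling,
                        seed = if (resampling > 0) seed_y + wd else NULL)
      out[[length(out) + 1L]] <- data.frame(
        replicate = r, region = wd, causal = wd %in% causal_windows,
        transform = tt, scheme = sc, n_markers = kt$n_markers,
        Q = kt$statistic, p = kt$p.value,
        p_resampling = if (is.null(kt$p.resampling)) NA_real_
                       else kt$p.resampling)
    }
  }
  do.call(rbind, out)
}

#' @export
print.famkernel_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Kernel-test simulation study: %d replicates, N = %d, %d markers, %d PCs\n",
    cfg$n_replicates, cfg$n, cfg$n_markers, cfg$pcs))
  if (x$failed > 0) cat("  failed replicates:", x$failed, "\n")
  cat("\nType I error (null regions):\n")
  print(x$type1, row.names = FALSE)
  if (!is.null(x$power)) {
    cat("\nPower at the empirical and nominal 0.05 thresholds:\n")
    print(x$power, row.names = FALSE)
  }
  invisible(x)
}
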