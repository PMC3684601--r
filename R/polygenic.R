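#' Fit the null polygenic mixed model
#'
#' Fits `y = X alpha + u + e` with `cov(u) = sigma2_g R`,
#' `cov(e) = sigma2_e I` by restricted (or full) maximum likelihood.  After
#' rotating into the eigenbasis of R the covariance is diagonal,
#' `V = sigma2 * diag(h2 * lambda_i + 1 - h2)`, and for fixed heritability
#' `h2` the fixed effects and the total variance `sigma2` are profiled out in
#' closed form; the profile likelihood is maximised over `h2` on \[0, 1\] by
#' a grid-bracketed Brent search, so the fit is deterministic.  Boundary
#' optima (h2 at 0 or 1) are valid fits and flagged.
#'
#' @param y numeric trait vector, a `sample_frame`, or a formula (see
#'   Methods).
#' @param X design matrix including an intercept column (default:
#'   intercept only).
#' @param relmat a `relmat`, a plain symmetric matrix, or a `relmat_eigen`
#'   cache.  Must be positive semi-definite (see [condition_psd()]).
#' @param method `"REML"` (default) or `"ML"`.
#' @param data,formula for the formula interface: `polygenic(trait ~ age +
#'   sex, data = df, relmat = R)`; `data` rows must align with `relmat` ids
#'   via `rownames(data)` or a column `id`.
#' @param ... passed between methods.
#' @return An object of class `"polygenic"` with components `alpha`
#'   (fixed effects), `sigma2_g`, `sigma2_e`, `sigma2`, `h2`, `logLik`,
#'   `method`, `boundary`, `ytilde` (= y - X alpha), `eigR` (the
#'   `relmat_eigen` cache), `y`, `X`, `ids`, `n`.
#' @examples
#' ped <- sim_pedigree(n_families = 10, generations = 3, seed = 1)
#' eg  <- relmat_eigen(pedigree_relmat(ped))
#' y   <- sim_phenotype(eg, h2 = 0.5, sigma2 = 1, seed = 2)
#' fit <- polygenic(y, relmat = eg)
#' fit$h2
#' @export
polygenic <- function(y, ...) UseMethod("polygenic")

#' @rdname polygenic
#' @export
polygenic.formula <- function(y, data, relmat, method = c("REML", "ML"), ...) {
  formula <- y
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  yy <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ids <- if (!is.null(data$id)) as.character(data$id)[
           as.integer(rownames(mf))] else rownames(mf)
  frame <- sample_frame(ids, yy, X)
  fit <- polygenic.sample_frame(frame, relmat = relmat, method = method, ...)
  fit$call <- match.call()
  fit
}

#' @rdname polygenic
#' @export
polygenic.sample_frame <- function(y, relmat, method = c("REML", "ML"), ...) {
  frame <- y
  eg <- relmat_eigen(relmat)
  if (!identical(frame$ids, eg$ids)) {
    idx <- match(frame$ids, eg$ids)
    if (anyNA(idx))
      stop("sample id(s) absent from the relationship matrix: ",
           paste(utils::head(frame$ids[is.na(idx)], 5), collapse = ", "))
    if (length(idx) != length(eg$ids))
      stop("relationship matrix covers individuals not in the sample frame; ",
           "subset it first")
    # reorder the eigen-cache rows to the frame's order (permutes R)
    eg$vectors <- eg$vectors[idx, , drop = FALSE]
    eg$ids <- frame$ids
  }
  fit <- polygenic.default(frame$y, X = frame$X, relmat = eg,
                           method = method, ...)
  fit$ids <- frame$ids
  fit
}

#' @rdname polygenic
#' @export
polygenic.default <- function(y, X = NULL, relmat, method = c("REML", "ML"),
                              ...) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  C <- ncol(X)
  if (n <= C + 2) stop("need more individuals than covariates + 2")
  eg <- relmat_eigen(relmat)
  if (length(eg$values) != n)
    stop("relationship matrix dimension does not match the sample size")
  lam <- eg$values
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  profile <- function(h2) {
    d <- h2 * lam + (1 - h2)
    if (any(d <= 0)) return(list(nll = Inf))
    w <- 1 / d
    Xw <- Xs * w
    XtWX <- crossprod(Xs, Xw)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = Inf))
    alpha <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, ys)))
    r <- ys - drop(Xs %*% alpha)
    rss <- sum(w * r * r)
    if (!is.finite(rss) || rss <= 0) return(list(nll = Inf))
    if (method == "REML") {
      s2 <- rss / (n - C)
      ll <- -0.5 * ((n - C) * (log(2 * pi * s2) + 1) + sum(log(d)) +
                    2 * sum(log(diag(ch))))
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + sum(log(d)))
    }
    list(nll = -ll, alpha = drop(alpha), s2 = s2, ll = ll)
  }

  hi <- 1 - 1e-6
  grid <- seq(0, hi, length.out = 21)
  nll_grid <- vapply(grid, function(h) profile(h)$nll, numeric(1))
  if (all(!is.finite(nll_grid))) stop("non-finite likelihood over the h2 grid")
  i <- which.min(nll_grid)
  lo_b <- grid[max(1, i - 1)]
  hi_b <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(h) profile(h)$nll, interval = c(lo_b, hi_b),
                         tol = 1e-6)
  h2 <- if (opt$objective <= nll_grid[i]) opt$minimum else grid[i]
  best <- profile(h2)
  if (!is.finite(best$ll)) stop("non-finite likelihood at the optimum")
  boundary <- h2 < 1e-4 || h2 > 1 - 1e-4
  if (h2 < 1e-4 && profile(0)$nll <= best$nll + 1e-10) { h2 <- 0; best <- profile(0) }
  alpha <- best$alpha
  names(alpha) <- colnames(X)
  sigma2 <- best$s2
  fit <- structure(list(
    alpha = alpha, sigma2_g = h2 * sigma2, sigma2_e = (1 - h2) * sigma2,
    sigma2 = sigma2, h2 = h2, logLik = best$ll, method = method,
    boundary = boundary, n = n,
    ytilde = y - drop(X %*% alpha),
    y = y, X = X, ids = eg$ids, eigR = eg,
    call = match.call()), class = "polygenic")
  fit
}

# Apply Vinv = (sigma2_g R + sigma2_e I)^{-1} to a vector/matrix via the
# eigen-cache.
.vinv <- function(fit, v) {
  d <- fit$sigma2_g * fit$eigR$values + fit$sigma2_e
  U <- fit$eigR$vectors
  U %*% (crossprod(U, v) / d)
}

#' @export
print.polygenic <- function(x, digits = 4, ...) {
  cat("Polygenic mixed model (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, h2 = %.4f%s, sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$n, x$h2, if (x$boundary) " (boundary)" else "",
              x$sigma2_g, x$sigma2_e))
  cat(sprintf("  logLik = %.4f\n", x$logLik))
  cat("  fixed effects:\n")
  print(round(x$alpha, digits))
  invisible(x)
}

#' @export
summary.polygenic <- function(object, ...) {
  gb <- gamma_bar(object)
  out <- list(fit = object, gamma_bar = gb,
              var_ytilde = stats::var(object$ytilde))
  class(out) <- "summary.polygenic"
  out
}

#' @export
print.summary.polygenic <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  gamma_bar = %.4f (GRAMMAR+ scaling %0.4f)\n",
              x$gamma_bar, x$fit$sigma2 / sqrt(x$gamma_bar)))
  cat(sprintf("  var(y - X alpha) = %.4g\n", x$var_ytilde))
  invisible(x)
}

#' @export
coef.polygenic <- function(object, ...) object$alpha

#' @export
logLik.polygenic <- function(object, ...) {
  structure(object$logLik, df = length(object$alpha) + 2, class = "logLik")
}

#' @export
fitted.polygenic <- function(object, ...) {
  drop(object$X %*% object$alpha) + predict(object)
}

#' Polygenic BLUP
#'
#' `predict()` on a polygenic fit returns the BLUP of the polygenic
#' component, `u_hat = sigma2_g R Vinv (y - X alpha)`.
#' @param object a `polygenic` fit.
#' @param ... unused.
#' @export
predict.polygenic <- function(object, ...) {
  d <- object$sigma2_g * object$eigR$values + object$sigma2_e
  U <- object$eigR$vectors
  # sigma2_g * R * Vinv * ytilde, all in the eigenbasis
  drop(U %*% (object$sigma2_g * object$eigR$values / d *
              crossprod(U, object$ytilde)))
}

#' Residuals from a polygenic fit
#'
#' `type = "environmental"` gives `e_hat = ytilde - u_hat`
#' (equivalently `sigma2_e * Vinv * ytilde`), the trait stripped of both
#' fixed effects and the BLUP polygenic component; `type = "marginal"` gives
#' `ytilde = y - X alpha`.
#'
#' @param object a `polygenic` fit.
#' @param type `"environmental"` or `"marginal"`.
#' @param ... unused.
#' @export
residuals.polygenic <- function(object,
                                type = c("environmental", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "marginal") return(object$ytilde)
  object$ytilde - predict(object)
}

#' Simulate traits from a fitted polygenic model
#'
#' Draws `nsim` new trait vectors `X alpha + u + e` with
#' `u ~ N(0, sigma2_g R)` and `e ~ N(0, sigma2_e I)` at the fitted
#' parameter values.
#'
#' @param object a `polygenic` fit.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return N x nsim matrix (or vector when `nsim = 1`).
#' @export
simulate.polygenic <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  U <- object$eigR$vectors
  s <- sqrt(object$sigma2_g * object$eigR$values)
  mu <- drop(object$X %*% object$alpha)
  out <- vapply(seq_len(nsim), function(i) {
    u <- drop(U %*% (s * stats::rnorm(n)))
    mu + u + stats::rnorm(n, sd = sqrt(object$sigma2_e))
  }, numeric(n))
  if (nsim == 1) drop(out) else out
}
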