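#' @title Relationship matrices
#' @description Internal constructor for the `relmat` class: a symmetric
#'   N x N additive relationship matrix (2 x kinship) tagged with the sample
#'   ids and its provenance (`"pedigree"`, `"genomic"` or `"file"`).
#' @param R symmetric numeric matrix.
#' @param ids character vector of individual ids (length `nrow(R)`).
#' @param source provenance tag.
#' @param jitter diagonal jitter added by [condition_psd()], if any.
#' @return A `relmat` matrix.
#' @keywords internal
new_relmat <- function(R, ids, source = "file", jitter = 0) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R), length(ids) == nrow(R))
  if (max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R))))
    stop("relationship matrix must be symmetric")
  R <- (R + t(R)) / 2
  dimnames(R) <- list(ids, ids)
  structure(R, ids = as.character(ids), source = source, jitter = jitter,
            class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("Relationship matrix (%d x %d), source: %s\n",
              nrow(x), ncol(x), attr(x, "source")))
  cat(sprintf("  diagonal: mean %.4f, range [%.4f, %.4f]\n",
              mean(diag(x)), min(diag(x)), max(diag(x))))
  off <- x[upper.tri(x)]
  cat(sprintf("  off-diagonal: mean %.4f, range [%.4f, %.4f]\n",
              mean(off), min(off), max(off)))
  if (attr(x, "jitter") > 0)
    cat(sprintf("  PSD jitter applied: %.3g\n", attr(x, "jitter")))
  invisible(x)
}

#' Genomic relationship matrix from genome-wide genotypes
#'
#' Allelic-correlation (homozygosity-weighted) estimator on the allele-dosage
#' scale: with dosages `d = 2g` and allele frequency `p_m` per variant,
#' `R_ij = (1/M) * sum_m (d_im - 2 p_m)(d_jm - 2 p_m) / (2 p_m (1 - p_m))`.
#' Variants with minor allele frequency below `maf_floor` are excluded.
#'
#' With sample-frequency centering (the default) the off-diagonal entries are
#' biased downward by roughly `-1/(N-1)` in small or strongly related
#' samples, since the frequencies themselves absorb relatedness; supply
#' known (e.g. founder) frequencies via `freqs` when an unbiased estimate
#' is needed.
#'
#' @param G N x M coded genotype matrix (entries 0, 0.5, 1; rownames = ids).
#' @param maf_floor minimum minor allele frequency (default 0.01).
#' @param ids individual ids; defaults to `rownames(G)`.
#' @param freqs optional vector of known allele frequencies on the coded
#'   scale (one per variant); default: sample means.
#' @return A `relmat` with `source = "genomic"`.
#' @export
genomic_relmat <- function(G, maf_floor = 0.01, ids = rownames(G),
                           freqs = NULL) {
  stopifnot(is.matrix(G))
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(G)))
  p <- if (is.null(freqs)) colMeans(G, na.rm = TRUE) else freqs
  stopifnot(length(p) == ncol(G))
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_floor & maf > 0
  if (!any(keep)) stop("all variants removed by the MAF floor")
  if (sum(keep) < 10 * nrow(G))
    message("genomic relationship estimated from only ", sum(keep),
            " variants (< 10 x N); estimates will be noisy")
  D <- 2 * G[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(D, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(D))
  R <- tcrossprod(Z) / ncol(Z)
  new_relmat(R, ids = ids, source = "genomic")
}

#' Principal components of a relationship matrix
#'
#' Eigenvectors of the double-centered (Gower-centered) relationship matrix
#' for the `k` largest eigenvalues, used as covariates to absorb
#' between-family structure.  Each component has unit norm and a
#' deterministic sign (entry of largest magnitude positive).
#'
#' @param R a `relmat` (or symmetric matrix).
#' @param k number of components (default 10).
#' @return N x k matrix with attribute `"values"` (the eigenvalues).
#' @export
kinship_pcs <- function(R, k = 10) {
  n <- nrow(R)
  if (k >= n) stop("k must be smaller than the number of individuals")
  Rc <- scale(R, center = TRUE, scale = FALSE)
  Rc <- t(scale(t(Rc), center = TRUE, scale = FALSE))   # Gower centering
  eg <- eigen((Rc + t(Rc)) / 2, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PC", seq_len(k))
  rownames(V) <- rownames(R)
  structure(V, values = eg$values[seq_len(k)])
}

#' Condition a relationship matrix to be positive semi-definite
#'
#' If the smallest eigenvalue is negative, adds `|lambda_min| + 1e-8` to the
#' diagonal (recorded in the `jitter` attribute); otherwise the input is
#' returned unchanged.
#'
#' @param R a `relmat` or symmetric matrix.
#' @return A PSD `relmat`.
#' @export
condition_psd <- function(R) {
  ids <- attr(R, "ids")
  if (is.null(ids)) ids <- rownames(R)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(R)))
  src <- attr(R, "source")
  if (is.null(src)) src <- "file"
  lmin <- min(eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin >= 0) {
    if (inherits(R, "relmat")) return(R)
    return(new_relmat(unclass(R), ids = ids, source = src))
  }
  jit <- abs(lmin) + 1e-8
  message("conditioning relationship matrix: adding ", signif(jit, 3),
          " to the diagonal")
  new_relmat(unclass(R) + diag(jit, nrow(R)), ids = ids, source = src,
             jitter = jit)
}

#' Cache the eigendecomposition of a relationship matrix
#'
#' The polygenic fit, trait simulation and GRAMMAR+ transformation all work
#' in the eigenbasis of R.  For replicate studies on a fixed pedigree the
#' decomposition is computed once and passed around.
#'
#' @param R a `relmat`.
#' @return A `relmat_eigen` list with `values` (clipped at 0), `vectors`,
#'   `ids` and `source`.
#' @export
relmat_eigen <- function(R) {
  if (inherits(R, "relmat_eigen")) return(R)
  ids <- attr(R, "ids")
  if (is.null(ids)) ids <- rownames(R)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(R)))
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("relationship matrix is not PSD; apply condition_psd() first")
  structure(list(values = pmax(eg$values, 0), vectors = eg$vectors,
                 ids = as.character(ids),
                 source = if (is.null(attr(R, "source"))) "file"
                          else attr(R, "source")),
            class = "relmat_eigen")
}
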