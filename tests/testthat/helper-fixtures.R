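# Shared fixtures, all built in code at test time.

# Trio + extra family pedigree data frames used across files.
trio_ped <- function() {
  as_pedigree(data.frame(
    fid = "F1", id = c("dad", "mum", "kid"),
    father = c("0", "0", "dad"), mother = c("0", "0", "mum"),
    sex = c(1L, 2L, 1L)))
}

# dad/mum -> sib1, sib2; dad/step -> half sib
sib_ped <- function() {
  as_pedigree(data.frame(
    fid = "F1",
    id = c("dad", "mum", "step", "sib1", "sib2", "half"),
    father = c("0", "0", "0", "dad", "dad", "dad"),
    mother = c("0", "0", "0", "mum", "mum", "step"),
    sex = c(1L, 2L, 2L, 1L, 2L, 1L)))
}

# full-sib mating: child of sib1 x sib2 is inbred with F = 1/4
inbred_ped <- function() {
  as_pedigree(data.frame(
    fid = "F1", id = c("gpa", "gma", "sib1", "sib2", "inbred"),
    father = c("0", "0", "gpa", "gpa", "sib1"),
    mother = c("0", "0", "gma", "gma", "sib2"),
    sex = c(1L, 2L, 1L, 2L, 2L)))
}

# Construct a polygenic-fit stub at fixed variance components, for exercising
# the transform algebra without an actual REML fit.
fixed_fit <- function(R, h2, sigma2 = 1, y = NULL, X = NULL) {
  eg <- relmat_eigen(R)
  n <- length(eg$values)
  if (is.null(y)) y <- numeric(n)
  if (is.null(X)) X <- matrix(1, n, 1)
  structure(list(alpha = 0, sigma2_g = h2 * sigma2,
                 sigma2_e = (1 - h2) * sigma2, sigma2 = sigma2, h2 = h2,
                 logLik = NA_real_, method = "fixed", boundary = FALSE,
                 n = n, ytilde = y - mean(y), y = y, X = X,
                 ids = eg$ids, eigR = eg),
            class = "polygenic")
}

# Write a small VCF; gt is a variants x samples character matrix of GT fields.
write_test_vcf <- function(path, gt, chrom = NULL, pos = NULL,
                           ref = NULL, alt = NULL,
                           samples = paste0("s", seq_len(ncol(gt)))) {
  m <- nrow(gt)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(m), function(i)
    paste(c(chrom[i], pos[i], paste0("v", i), ref[i], alt[i], ".", "PASS",
            ".", "GT", gt[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

# Dense-matrix REML/ML log-likelihood, independent of the package's
# eigen-rotated implementation (direct solves).
dense_loglik <- function(y, X, R, h2, method = "REML") {
  n <- length(y); C <- ncol(X)
  D <- h2 * R + (1 - h2) * diag(n)
  Di <- solve(D)
  XtDX <- t(X) %*% Di %*% X
  alpha <- solve(XtDX, t(X) %*% Di %*% y)
  r <- y - X %*% alpha
  rss <- drop(t(r) %*% Di %*% r)
  if (method == "REML") {
    s2 <- rss / (n - C)
    -0.5 * ((n - C) * (log(2 * pi * s2) + 1) +
            determinant(D)$modulus + determinant(XtDX)$modulus)
  } else {
    s2 <- rss / n
    -0.5 * (n * (log(2 * pi * s2) + 1) + determinant(D)$modulus)
  }
}
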