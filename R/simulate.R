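#' Draw a minor allele frequency spectrum
#'
#' Mixture of common and rare variants: with probability `prop_common` the
#' MAF is Uniform(0.05, 0.5); otherwise it is rare, `0.005 + 0.045 *
#' Beta(1, 3)` (right-skewed mass below 0.05).
#'
#' @param m number of variants.
#' @param prop_common proportion of common variants (default 0.5).
#' @param seed optional integer seed.
#' @return MAF vector in (0, 0.5].
#' @export
sim_mafs <- function(m, prop_common = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  common <- stats::runif(m) < prop_common
  maf <- numeric(m)
  maf[common] <- stats::runif(sum(common), 0.05, 0.5)
  maf[!common] <- 0.005 + 0.045 * stats::rbeta(sum(!common), 1, 3)
  maf
}

#' Simulate a polygenic quantitative trait
#'
#' Draws `y = mu + D beta + u + e` with `u ~ N(0, sigma2_g R)` (via the
#' eigen-factor of R), `e ~ N(0, sigma2_e I)`, `sigma2_g = h2 * sigma2`,
#' `sigma2_e = (1 - h2) * sigma2`.  Causal effects, when given, act on the
#' allele-dosage scale `D = 2 G`, so each causal variant contributes
#' `beta^2 * 2 p (1 - p)` to the trait variance.
#'
#' @param relmat a `relmat` or `relmat_eigen` for the polygenic covariance.
#' @param h2 narrow-sense heritability of the polygenic background in
#'   \[0, 1).
#' @param sigma2 total background variance `sigma2_g + sigma2_e`.
#' @param mu trait mean.
#' @param causal optional list with `G` (N x K coded causal genotypes) and
#'   `beta` (length-K dosage-scale effects).
#' @param seed optional integer seed.
#' @return numeric trait vector (names = ids).
#' @export
sim_phenotype <- function(relmat, h2 = 0.5, sigma2 = 1, mu = 0,
                          causal = NULL, seed = NULL) {
  stopifnot(h2 >= 0, h2 < 1, sigma2 > 0)
  if (!is.null(seed)) set.seed(seed)
  eg <- relmat_eigen(relmat)
  n <- length(eg$values)
  u <- if (h2 > 0)
    drop(eg$vectors %*% (sqrt(h2 * sigma2 * eg$values) * stats::rnorm(n)))
  else numeric(n)
  y <- mu + u + stats::rnorm(n, sd = sqrt((1 - h2) * sigma2))
  if (!is.null(causal)) {
    stopifnot(ncol(causal$G) == length(causal$beta), nrow(causal$G) == n)
    y <- y + drop((2 * causal$G) %*% causal$beta)
  }
  names(y) <- eg$ids
  y
}

#' Dosage-scale causal effect sizes at fixed per-variant variance
#'
#' Returns `beta_k = sign_k * sqrt(q2 * sigma2 / (2 p_k (1 - p_k)))`: every
#' causal variant explains the fraction `q2` of `sigma2`, which encodes the
#' "lower MAF, larger effect" architecture; `signs` may mix directions (the
#' regime where kernel tests outperform collapsing).
#'
#' @param maf causal minor allele frequencies.
#' @param q2 per-variant fraction of `sigma2` explained.
#' @param signs vector of +1/-1 (recycled).
#' @param sigma2 background variance the fraction refers to.
#' @return effect-size vector (dosage scale).
#' @export
causal_effects <- function(maf, q2 = 0.005, signs = c(1, -1), sigma2 = 1) {
  stopifnot(all(maf > 0), all(maf < 1))
  s <- rep_len(signs, length(maf))
  s * sqrt(q2 * sigma2 / (2 * maf * (1 - maf)))
}

#' Write simulated data through the standard formats
#'
#' Emits a gene-dropped dataset as VCF + pedigree TSV + phenotype TSV so the
#' real I/O path can be exercised end-to-end.
#'
#' @param ped a `pedigree`.
#' @param G coded genotype matrix (rows = `ped$id`).
#' @param y trait vector.
#' @param dir output directory.
#' @param chrom chromosome label for all variants.
#' @return named list of the three file paths.
#' @export
write_sim_data <- function(ped, G, y, dir, chrom = "1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "sim.vcf")
  ids <- ped$id
  m <- ncol(G)
  D <- round(2 * G)
  gt <- matrix(c("0/0", "0/1", "1/1")[D + 1L], nrow = nrow(G))
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", chrom, ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c(chrom, j * 100L, paste0("snp", j), "A", "G", ".", "PASS", ".",
            "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf)
  pedf <- file.path(dir, "sim.ped.tsv")
  utils::write.table(
    data.frame(FID = ped$fid, IID = ped$id, PAT = ped$father,
               MAT = ped$mother, SEX = ped$sex),
    pedf, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  phef <- file.path(dir, "sim.pheno.tsv")
  utils::write.table(data.frame(IID = ids, trait = as.numeric(y)),
                     phef, sep = "\t", quote = FALSE, row.names = FALSE)
  list(vcf = vcf, pedigree = pedf, phenotypes = phef)
}
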