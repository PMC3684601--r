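#' Construct a genotype region
#'
#' Wraps an N x M coded genotype matrix (entries 0, 0.5, 1 = minor-allele
#' count / 2) with its variant metadata.  Missing genotypes are imputed to
#' the variant's mean coded value (keeps the score-statistic algebra exact on
#' complete matrices); the number imputed is reported.  Minor allele
#' frequencies are recomputed from the matrix.
#'
#' @param G N x M numeric matrix, entries in \{0, 0.5, 1, NA\}.
#' @param chrom chromosome label(s), length 1 or M.
#' @param pos integer vector of 1-based positions (length M), or NULL.
#' @param ids individual ids (length N); defaults to `rownames(G)`.
#' @param snp variant ids; defaults to `colnames(G)`.
#' @return A `genotype_region` list with elements `G`, `maf`, `chrom`,
#'   `pos`, `ids`, `snp` and `monomorphic` (logical per variant).
#' @export
genotype_region <- function(G, chrom = "0", pos = NULL, ids = rownames(G),
                            snp = colnames(G)) {
  stopifnot(is.matrix(G), ncol(G) >= 1)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(G)))
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(G)))
  if (is.null(pos)) pos <- seq_len(ncol(G))
  chrom <- rep_len(as.character(chrom), ncol(G))
  nmiss <- sum(is.na(G))
  if (nmiss > 0) {
    message("imputing ", nmiss, " missing genotype(s) to variant means")
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  ok <- G >= 0 & G <= 1
  if (!all(ok)) stop("genotypes must lie in [0, 1] on the coded scale")
  p <- colMeans(G)
  maf <- pmin(p, 1 - p)
  structure(list(G = G, maf = maf, chrom = chrom, pos = as.integer(pos),
                 ids = as.character(ids), snp = as.character(snp),
                 monomorphic = apply(G, 2, function(g) all(g == g[1]))),
            class = "genotype_region")
}

#' @export
print.genotype_region <- function(x, ...) {
  cat(sprintf("Genotype region: %d individuals x %d variants (%d monomorphic)\n",
              nrow(x$G), ncol(x$G), sum(x$monomorphic)))
  cat(sprintf("  chrom %s, positions %d..%d, MAF range [%.4f, %.4f]\n",
              paste(unique(x$chrom), collapse = ","),
              min(x$pos), max(x$pos), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Subset a genotype region by variant index
#' @param region a `genotype_region`.
#' @param idx integer vector of variant indices.
#' @return A `genotype_region` over the selected variants.
#' @export
subset_region <- function(region, idx) {
  genotype_region(region$G[, idx, drop = FALSE], chrom = region$chrom[idx],
                  pos = region$pos[idx], ids = region$ids,
                  snp = region$snp[idx])
}

#' Read diploid biallelic genotypes from a VCF file
#'
#' Reads GT fields from a VCF (via the vcfR package), keeps biallelic
#' autosomal SNP records, and codes genotypes as minor-allele count / 2
#' (0, 0.5, 1).  The minor allele is determined per variant from the sample
#' allele frequency, ties (frequency exactly 0.5) broken toward ALT, so the
#' coding is invariant under REF/ALT relabeling.  Missing GT stays missing
#' until region construction, where it is mean-imputed.
#'
#' @param path path to a VCF 4.x file (plain text or gzipped).
#' @param sample_order character vector of sample ids defining the row order
#'   of the output; every id must be present in the VCF.  NULL keeps the
#'   VCF's own order.
#' @return A `genotype_region` covering all retained variants.
#' @export
read_vcf_genotypes <- function(path, sample_order = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
           nchar(fix[, "ALT"]) != 1
  sexchr <- toupper(sub("^CHR", "", toupper(chrom))) %in% c("X", "Y", "MT", "M")
  keep <- !multi & !sexchr
  if (any(multi)) message("skipping ", sum(multi),
                          " multiallelic/non-SNP record(s)")
  if (any(sexchr)) message("skipping ", sum(sexchr),
                           " non-autosomal record(s)")
  if (!any(keep)) stop("no biallelic autosomal SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (!is.null(sample_order)) {
    missing <- setdiff(sample_order, samples)
    if (length(missing))
      stop("sample id(s) not in VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, sample_order, drop = FALSE]
    samples <- sample_order
  }
  gt_clean <- gsub("\\|", "/", gt)
  code <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  alt <- matrix(code[gt_clean], nrow = nrow(gt), ncol = ncol(gt))
  bad <- !is.na(gt_clean) & gt_clean != "./." & gt_clean != "." &
         !(gt_clean %in% names(code))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt[w[1], w[2]], "' at record ", w[1],
         " (", fix[w[1], "CHROM"], ":", fix[w[1], "POS"], ")")
  }
  # minor-allele orientation per variant; ties toward ALT
  af <- rowMeans(alt, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  alt[flip, ] <- 2 - alt[flip, , drop = FALSE]
  G <- t(alt) / 2
  rownames(G) <- samples
  colnames(G) <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                        fix[, "ID"])
  genotype_region(G, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ids = samples)
}

#' Read a phenotype/covariate table
#'
#' Reads a TSV with a header row; the first column (or `id_col`) holds
#' individual ids.  Rows with a missing trait value are dropped (count
#' reported).  Covariates are column-bound after a prepended intercept.
#'
#' @param path TSV path.
#' @param trait name of the trait column.
#' @param covariate_names character vector of covariate column names
#'   (default none: intercept-only design).
#' @param id_col name of the id column (default: first column).
#' @return A `sample_frame` list: `ids`, `y` (named numeric) and `X`
#'   (N x (1 + C) design matrix, first column the intercept).
#' @export
read_phenotypes <- function(path, trait, covariate_names = character(),
                            id_col = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(id_col)) id_col <- names(tab)[1]
  for (cn in c(id_col, trait, covariate_names))
    if (!cn %in% names(tab))
      stop("column '", cn, "' not found; available: ",
           paste(names(tab), collapse = ", "))
  y <- suppressWarnings(as.numeric(tab[[trait]]))
  keep <- !is.na(y)
  if (any(!keep)) message("dropping ", sum(!keep),
                          " row(s) with missing trait values")
  tab <- tab[keep, , drop = FALSE]
  y <- y[keep]
  ids <- as.character(tab[[id_col]])
  X <- cbind(`(Intercept)` = 1)
  if (length(covariate_names)) {
    cv <- as.matrix(tab[, covariate_names, drop = FALSE])
    storage.mode(cv) <- "double"
    if (anyNA(cv)) stop("missing covariate values are not supported")
    X <- cbind(`(Intercept)` = 1, cv)
  } else {
    X <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  }
  names(y) <- ids
  rownames(X) <- ids
  sample_frame(ids, y, X)
}

#' Construct a sample frame
#' @param ids individual ids.
#' @param y numeric trait vector.
#' @param X design matrix with exactly one intercept column (prepended when
#'   absent).
#' @return A `sample_frame` list.
#' @export
sample_frame <- function(ids, y, X = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  if (is.null(X)) X <- matrix(1, length(y), 1,
                              dimnames = list(ids, "(Intercept)"))
  X <- as.matrix(X)
  n_int <- sum(apply(X, 2, function(cc) all(cc == 1)))
  if (n_int == 0) X <- cbind(`(Intercept)` = 1, X)
  else if (n_int > 1) stop("design matrix has more than one intercept column")
  if (length(y) != length(ids) || nrow(X) != length(ids))
    stop("phenotype/covariate row count must equal the number of ids")
  structure(list(ids = ids, y = as.numeric(y), X = X), class = "sample_frame")
}

#' Write / read a relationship matrix in GCTA text layout
#'
#' `write_grm()` writes the lower triangle as `<prefix>.grm` lines
#' `i j n_snps value` (1-based indices) with an id sidecar `<prefix>.grm.id`
#' (`FID IID`); `read_grm()` reads the pair back.  Round-trip agreement is
#' within 1e-9 (values printed with 15 significant digits).
#'
#' @param R symmetric relationship matrix.
#' @param ids individual ids (length `nrow(R)`).
#' @param prefix file prefix; `.grm` and `.grm.id` are appended.
#' @param n_snps marker count recorded per entry (provenance only).
#' @return `write_grm()` the prefix, invisibly; `read_grm()` a `relmat`.
#' @export
write_grm <- function(R, ids, prefix, n_snps = 0L) {
  if (length(ids) != nrow(R)) stop("id count must match matrix dimension")
  if (max(abs(R - t(R))) > 1e-8) stop("relationship matrix must be symmetric")
  n <- nrow(R)
  ij <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  lines <- sprintf("%d\t%d\t%d\t%.15g", ij[, 1], ij[, 2], n_snps,
                   R[ij])
  writeLines(lines, paste0(prefix, ".grm"))
  writeLines(sprintf("%s\t%s", ids, ids), paste0(prefix, ".grm.id"))
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  idtab <- utils::read.table(paste0(prefix, ".grm.id"),
                             colClasses = "character")
  ids <- idtab[[2]]
  n <- length(ids)
  tab <- utils::read.table(paste0(prefix, ".grm"))
  R <- matrix(0, n, n)
  R[cbind(tab[[1]], tab[[2]])] <- tab[[4]]
  R[cbind(tab[[2]], tab[[1]])] <- tab[[4]]
  new_relmat(R, ids = ids, source = "file")
}

#' Write a (possibly transformed) trait as a phenotype TSV
#'
#' The headline use of the GRAMMAR+ transformation: write the transformed
#' trait so external unrelated-sample kernel software can consume it.
#'
#' @param trait numeric vector (e.g. a `transformed_trait`), names = ids.
#' @param path output TSV path.
#' @param name trait column name.
#' @export
write_phenotypes <- function(trait, path, name = "trait") {
  ids <- names(trait)
  if (is.null(ids)) ids <- attr(trait, "ids")
  if (is.null(ids)) ids <- paste0("ind", seq_along(trait))
  tab <- data.frame(IID = ids, value = as.numeric(trait))
  names(tab)[2] <- name
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
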