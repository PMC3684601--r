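#' Read a FAM-like pedigree file
#'
#' Reads a whitespace- or tab-delimited pedigree file with columns
#' family id, individual id, father id, mother id, sex (`0` = missing
#' parent; sex coded 1 = male, 2 = female, 0/NA = unknown).  The table is
#' validated: individual ids must be unique, every named parent must be
#' present in the file, the parent-offspring graph must be acyclic, and the
#' sexes of named fathers/mothers must be consistent.
#'
#' @param path path to the pedigree file.  A header line is detected
#'   automatically (first field equal to `"FID"`, case-insensitive).
#' @return A `pedigree` object: a data.frame with columns `fid`, `id`,
#'   `father`, `mother`, `sex` and `founder` (logical; both parents missing).
#' @examples
#' f <- tempfile()
#' writeLines(c("F1 dad 0 0 1", "F1 mum 0 0 2", "F1 kid dad mum 1"), f)
#' ped <- read_pedigree(f)
#' sum(ped$founder)
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(raw) < 5)
    stop("pedigree file must have >= 5 columns (FID IID PAT MAT SEX)")
  if (toupper(raw[1, 1]) %in% c("FID", "FAMID", "FAMILY")) raw <- raw[-1, , drop = FALSE]
  ped <- data.frame(fid = raw[[1]], id = raw[[2]], father = raw[[3]],
                    mother = raw[[4]], sex = suppressWarnings(as.integer(raw[[5]])),
                    stringsAsFactors = FALSE)
  as_pedigree(ped)
}

#' Construct and validate a pedigree object
#'
#' @param ped data.frame with columns `fid`, `id`, `father`, `mother`, `sex`
#'   (`"0"` or `NA` for a missing parent).
#' @return A validated `pedigree` data.frame with a logical `founder` column.
#' @export
as_pedigree <- function(ped) {
  stopifnot(all(c("fid", "id", "father", "mother") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  ped$father[is.na(ped$father)] <- "0"
  ped$mother[is.na(ped$mother)] <- "0"
  if (is.null(ped$sex)) ped$sex <- NA_integer_
  if (anyDuplicated(ped$id))
    stop("duplicated individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  for (col in c("father", "mother")) {
    named <- setdiff(ped[[col]], c("0", ped$id))
    if (length(named))
      stop("missing ", col, " id(s) not present in pedigree: ",
           paste(named, collapse = ", "))
  }
  bad_f <- ped$sex[match(setdiff(ped$father, "0"), ped$id)]
  if (any(bad_f %in% 2L)) stop("individual named as father has sex coded female")
  bad_m <- ped$sex[match(setdiff(ped$mother, "0"), ped$id)]
  if (any(bad_m %in% 1L)) stop("individual named as mother has sex coded male")
  ord <- .pedigree_order(ped)            # errors on cycles
  ped$founder <- ped$father == "0" & ped$mother == "0"
  attr(ped, "order") <- ord
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Topological order (ancestors before descendants) by iterated founder
# stripping; a cycle leaves individuals whose parents never resolve.
.pedigree_order <- function(ped) {
  n <- nrow(ped)
  placed <- logical(n)
  ord <- integer(0)
  idx <- seq_len(n)
  fa <- match(ped$father, ped$id)  # NA for missing parent
  mo <- match(ped$mother, ped$id)
  ok <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  repeat {
    ready <- !placed & ok(fa) & ok(mo)
    if (!any(ready)) break
    ord <- c(ord, idx[ready])
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree cycle detected involving individual(s): ",
         paste(ped$id[!placed], collapse = ", "))
  ord
}

#' Pedigree relationship matrix (2 x kinship)
#'
#' Computes the additive relationship matrix `R = 2 * Phi` from a pedigree by
#' the standard recursive kinship algorithm: founders are unrelated and
#' non-inbred, `Phi(i,i) = (1 + Phi(f_i, m_i)) / 2` and
#' `Phi(i,j) = (Phi(f_i, j) + Phi(m_i, j)) / 2` for `j` not a descendant of
#' `i`.  An individual with exactly one known parent is treated as having an
#' unknown, unrelated founder for the missing parent (a message is emitted).
#'
#' @param ped a `pedigree` object.
#' @return A `relmat` object: symmetric N x N matrix with `ids` and a
#'   `source = "pedigree"` attribute, rows/columns ordered as `ped$id`.
#' @examples
#' ped <- sim_pedigree(n_families = 2, generations = 2, offspring = 2, seed = 1)
#' R <- pedigree_relmat(ped)
#' range(diag(R))
#' @export
pedigree_relmat <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  half <- xor(is.na(fa), is.na(mo))
  if (any(half))
    message(sum(half), " individual(s) with one known parent; ",
            "missing parent treated as unknown founder")
  ord <- attr(ped, "order")
  K <- matrix(0, n, n)
  for (i in ord) {
    f <- fa[i]; m <- mo[i]
    kf <- if (is.na(f)) rep(0, n) else K[f, ]
    km <- if (is.na(m)) rep(0, n) else K[m, ]
    kin_fm <- if (is.na(f) || is.na(m)) 0 else K[f, m]
    row <- (kf + km) / 2
    K[i, ] <- row
    K[, i] <- row
    K[i, i] <- 0.5 * (1 + kin_fm)
  }
  R <- 2 * K
  dimnames(R) <- list(ped$id, ped$id)
  new_relmat(R, ids = ped$id, source = "pedigree")
}

#' Simulate a multi-family pedigree
#'
#' Builds `n_families` non-overlapping families.  Each family starts from one
#' founder couple; in every subsequent generation each couple produces
#' `offspring` children, and each child is paired with an unrelated,
#' married-in founder so the family keeps branching.  `generations = 1`
#' yields founders only (relationship matrix I).
#'
#' @param n_families number of independent families.
#' @param generations total number of generations (>= 1).
#' @param offspring number of children per couple (constant, or a function
#'   `function(n)` returning `n` sibship sizes for stochastic sibships).
#' @param seed integer seed; the construction is deterministic given it.
#' @return A `pedigree` object.
#' @export
sim_pedigree <- function(n_families = 50, generations = 3, offspring = 2,
                         seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%03d", f)
    cnt <- 0L
    nid <- function() { cnt <<- cnt + 1L; sprintf("%s_I%03d", fid, cnt) }
    tab <- data.frame(fid = character(), id = character(), father = character(),
                      mother = character(), sex = integer(),
                      stringsAsFactors = FALSE)
    add <- function(id, fa, mo, sex)
      tab <<- rbind(tab, data.frame(fid = fid, id = id, father = fa,
                                    mother = mo, sex = sex,
                                    stringsAsFactors = FALSE))
    p1 <- nid(); add(p1, "0", "0", 1L)
    if (generations == 1L) { rows[[f]] <- tab; next }
    p2 <- nid(); add(p2, "0", "0", 2L)
    couples <- list(c(p1, p2))
    for (g in seq_len(generations - 1L)) {
      nxt <- list()
      last <- g == generations - 1L
      for (cp in couples) {
        nk <- if (is.function(offspring)) offspring(1L) else offspring
        for (k in seq_len(nk)) {
          sex <- if (k %% 2L == 1L) 1L else 2L
          kid <- nid(); add(kid, cp[1], cp[2], sex)
          if (!last) {
            sp <- nid(); add(sp, "0", "0", if (sex == 1L) 2L else 1L)
            nxt[[length(nxt) + 1L]] <- if (sex == 1L) c(kid, sp) else c(sp, kid)
          }
        }
      }
      couples <- nxt
    }
    rows[[f]] <- tab
  }
  as_pedigree(do.call(rbind, rows))
}

#' Gene-drop genotypes down a pedigree
#'
#' Simulates unlinked biallelic genotypes: founder allele counts are drawn
#' `Binomial(2, maf)` per variant, and each offspring receives one allele per
#' parent, transmitted with probability equal to half the parental allele
#' count.  Genotypes are returned in the package's coded scale
#' \{0, 0.5, 1\} (minor-allele count / 2).
#'
#' @param ped a `pedigree` object.
#' @param founder_mafs vector of founder minor allele frequencies, one per
#'   variant.
#' @param seed integer seed.
#' @return N x M matrix of coded genotypes with rownames `ped$id`.
#' @export
gene_drop <- function(ped, founder_mafs, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), all(founder_mafs >= 0),
            all(founder_mafs <= 1))
  set.seed(seed)
  n <- nrow(ped)
  m <- length(founder_mafs)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  D <- matrix(0L, n, m)                  # allele counts 0/1/2
  for (i in attr(ped, "order")) {
    af <- if (is.na(fa[i])) stats::rbinom(m, 1L, founder_mafs)
          else stats::rbinom(m, 1L, D[fa[i], ] / 2)
    am <- if (is.na(mo[i])) stats::rbinom(m, 1L, founder_mafs)
          else stats::rbinom(m, 1L, D[mo[i], ] / 2)
    D[i, ] <- af + am
  }
  G <- D / 2
  rownames(G) <- ped$id
  G
}
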