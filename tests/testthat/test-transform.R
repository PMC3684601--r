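test_that("gamma factors are exactly 1 for unrelated samples", {
  set.seed(101)
  n <- 40
  fit <- fixed_fit(diag(n), h2 = 0.7, sigma2 = 2, y = rnorm(n))
  G <- matrix(rbinom(n * 10, 2, 0.3) / 2, n)
  gf <- gamma_factors(fit, G)
  expect_equal(gf$gamma, rep(1, 10), tolerance = 1e-10)
  expect_equal(gf$gamma_bar, 1, tolerance = 1e-12)
})

test_that("gamma of the 4-sample toy matches direct matrix inversion", {
  R <- rbind(c(1, .5, 0, 0), c(.5, 1, 0, 0), c(0, 0, 1, .5), c(0, 0, .5, 1))
  fit <- fixed_fit(R, h2 = 0.5, sigma2 = 1, y = rep(0, 4))
  g <- c(0, 0.5, 0.5, 1)
  gf <- gamma_factors(fit, matrix(g, ncol = 1))
  V <- 0.5 * R + 0.5 * diag(4)
  gc <- g - mean(g)
  expect_equal(gf$gamma[1],
               drop(t(gc) %*% solve(V, gc)) / sum(gc^2), tolerance = 1e-10)
})

test_that("monomorphic markers are flagged and excluded from gamma", {
  set.seed(102)
  n <- 30
  fit <- fixed_fit(diag(n), h2 = 0.3, y = rnorm(n))
  G <- cbind(rbinom(n, 2, 0.4) / 2, rep(0.5, n))
  expect_message(gamma_factors(fit, G), "monomorphic")
  gf <- suppressMessages(gamma_factors(fit, G))
  expect_true(is.na(gf$gamma[2]))
  expect_false(gf$monomorphic[1])
})

test_that("the averaged gamma matches the empirical marker mean", {
  ped <- sim_pedigree(n_families = 20, generations = 3, seed = 111)
  R <- pedigree_relmat(ped)
  fit <- fixed_fit(R, h2 = 0.5, sigma2 = 1, y = rnorm(nrow(R)))
  G <- gene_drop(ped, runif(1500, 0.05, 0.5), seed = 112)
  gf <- gamma_factors(fit, G)
  expect_equal(gf$mean, gf$gamma_bar, tolerance = 0.02)
  expect_lte(gf$gamma_bar, 1)
  expect_gt(gf$gamma_bar, 0)
})

test_that("GRAMMAR+ scaling gives the derived transformed-trait variance", {
  # cov(y+) = (sigma2^2/gamma_bar) Vinv, so E var(y+) ~= sigma2 *
  # (sigma2 * tr(Vinv)/N) / gamma_bar
  ped <- sim_pedigree(n_families = 50, generations = 3, seed = 121)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.5, sigma2 = 1, seed = 122)
  fit <- polygenic(y, relmat = eg)
  yp <- transform_trait(fit, "grammar_plus")
  harm <- mean(fit$sigma2 / (fit$sigma2_g * eg$values + fit$sigma2_e))
  expect_equal(var(as.numeric(yp)), fit$sigma2 * harm / gamma_bar(fit),
               tolerance = 0.1)
})

test_that("transformations are scale-equivariant and score-invariant", {
  ped <- sim_pedigree(n_families = 10, generations = 3, seed = 131)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.5, seed = 132)
  G <- gene_drop(ped, rep(0.3, 15), seed = 133)
  f1 <- polygenic(y, relmat = eg)
  f2 <- polygenic(3 * y, relmat = eg)
  y1 <- transform_trait(f1, "grammar_plus")
  y2 <- transform_trait(f2, "grammar_plus")
  expect_equal(as.numeric(y2), 3 * as.numeric(y1), tolerance = 1e-3)
  s1 <- simple_score(y1, G)
  s2 <- simple_score(y2, G)
  expect_equal(s2$score, s1$score, tolerance = 1e-4)
  expect_equal(s2$beta, 3 * s1$beta, tolerance = 1e-4)
})

test_that("GRAMMAR-Gamma and GRAMMAR+ differ by the sqrt of gamma_bar", {
  ped <- sim_pedigree(n_families = 10, generations = 3, seed = 141)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.6, seed = 142)
  fit <- polygenic(y, relmat = eg)
  gp <- transform_trait(fit, "grammar_plus")
  gg <- transform_trait(fit, "grammar_gamma")
  expect_equal(as.numeric(gg) * sqrt(gamma_bar(fit)), as.numeric(gp),
               tolerance = 1e-10)
  expect_equal(attr(gg, "transform"), "grammar_gamma")
})

test_that("simple scores on GRAMMAR+ equal exact mixed-model scores when R = I", {
  set.seed(151)
  n <- 60
  for (h2 in c(0.2, 0.8)) {
    fit <- fixed_fit(diag(n), h2 = h2, sigma2 = 1.7, y = rnorm(n))
    G <- matrix(rbinom(n * 8, 2, runif(8, 0.1, 0.5)) / 2, n, byrow = FALSE)
    yp <- transform_trait(fit, "grammar_plus")
    sp <- simple_score(yp, G)
    sm <- mixed_score(fit, G)
    expect_equal(sp$score, sm$score, tolerance = 1e-10)
  }
})

test_that("simple scores track exact scores closely in related samples", {
  ped <- sim_pedigree(n_families = 50, generations = 3, seed = 161)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.5, sigma2 = 1, seed = 162)
  fit <- polygenic(y, relmat = eg)
  G <- gene_drop(ped, sim_mafs(2000, seed = 163), seed = 164)
  yp <- transform_trait(fit, "grammar_plus")
  sp <- simple_score(yp, G)
  sm <- mixed_score(fit, G)
  expect_equal(sp$snp, sm$snp)
  expect_gt(cor(sp$score, sm$score), 0.99)
  expect_equal(mean(sp$score) / mean(sm$score), 1, tolerance = 0.05)
})

test_that("a zero transformed trait yields zero scores", {
  n <- 20
  fit <- fixed_fit(diag(n), h2 = 0.5, y = rep(0, n))
  G <- matrix(rbinom(n * 4, 2, 0.4) / 2, n)
  yz <- structure(rep(0, n), sigma2 = 1, class = "transformed_trait")
  expect_equal(simple_score(yz, G)$score, rep(0, 4))
})
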