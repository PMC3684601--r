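test_that("beta weights match their closed forms", {
  expect_equal(beta_weights(c(0.05, 0.2, 0.5), 1, 1, "pdf"), rep(1, 3))
  expect_equal(beta_weights(0.1, 1, 25, "pdf"), 25 * 0.9^24, tolerance = 1e-10)
  expect_equal(beta_weights(0.5, 0.5, 0.5, "pdf"), 2 / pi, tolerance = 1e-10)
  # squared-density convention (the kernel default)
  expect_equal(beta_weights(0.1, 1, 25), (25 * 0.9^24)^2, tolerance = 1e-8)
  expect_error(beta_weights(0, 1, 25), "mafs")
})

test_that("exact mixed scores reduce to regression scores for R = I and match hand algebra", {
  set.seed(201)
  n <- 50
  y <- rnorm(n)
  fit <- fixed_fit(diag(n), h2 = 0.4, sigma2 = 1, y = y)
  G <- matrix(rbinom(n * 5, 2, 0.3) / 2, n)
  sm <- mixed_score(fit, G)
  Gc <- sweep(G, 2, colMeans(G))
  yt <- y - mean(y)
  expect_equal(sm$score,
               drop(crossprod(Gc, yt))^2 / colSums(Gc^2), tolerance = 1e-10)

  # 4-sample toy against dense linear algebra
  R <- rbind(c(1, .5, 0, 0), c(.5, 1, 0, 0), c(0, 0, 1, .5), c(0, 0, .5, 1))
  y4 <- c(0.2, -1, 0.4, 1.1)
  fit4 <- fixed_fit(R, h2 = 0.5, sigma2 = 1, y = y4)
  g <- c(0, 0.5, 0.5, 1)
  sm4 <- mixed_score(fit4, matrix(g, ncol = 1))
  V <- 0.5 * R + 0.5 * diag(4)
  gc <- g - mean(g)
  yt4 <- y4 - mean(y4)
  expect_equal(sm4$score,
               drop(t(gc) %*% solve(V, yt4))^2 / drop(t(gc) %*% solve(V, gc)),
               tolerance = 1e-10)
})

test_that("exact mixed scores are asymptotically chi-square(1) under the null", {
  ped <- sim_pedigree(n_families = 30, generations = 3, seed = 211)
  eg <- relmat_eigen(pedigree_relmat(ped))
  scores <- c()
  for (r in 1:5) {
    y <- sim_phenotype(eg, h2 = 0.5, sigma2 = 1, seed = 212 + r)
    fit <- polygenic(y, relmat = eg)
    G <- gene_drop(ped, runif(2000, 0.05, 0.5), seed = 300 + r)
    scores <- c(scores, mixed_score(fit, G)$score)
  }
  expect_gte(mean(scores), 0.95)
  expect_lte(mean(scores), 1.05)
})

test_that("Q equals the naive weighted sum of per-marker scores", {
  ped <- sim_pedigree(n_families = 10, generations = 3, seed = 221)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.5, seed = 222)
  fit <- polygenic(y, relmat = eg)
  yp <- transform_trait(fit, "grammar_plus")
  G <- gene_drop(ped, c(0.3, 0.1, 0.45), seed = 223)
  reg <- genotype_region(G)
  kt <- kernel_test(yp, reg, weights = c(1, 25))
  w <- beta_weights(reg$maf, 1, 25)
  sc <- simple_score(yp, reg)
  expect_equal(kt$statistic, sum(w * sc$score), tolerance = 1e-8)
  # quadratic-form path agrees with the weighted sum
  Gc <- sweep(G, 2, colMeans(G))
  q2 <- famkernel:::.q_quadform(as.numeric(yp), Gc, w / colSums(Gc^2),
                                fit$sigma2)
  expect_equal(kt$statistic, q2, tolerance = 1e-8)
})

test_that("single-marker and degenerate-weight regions behave as score tests", {
  set.seed(231)
  n <- 100
  y <- rnorm(n)
  fit <- fixed_fit(diag(n), h2 = 0, sigma2 = 1, y = y)
  yp <- transform_trait(fit, "grammar_plus")
  g <- matrix(rbinom(n, 2, 0.3) / 2, ncol = 1)
  kt <- kernel_test(yp, g, weights = c(1, 1), sigma2 = 1)
  expect_equal(kt$statistic, simple_score(yp, g, sigma2 = 1)$score,
               tolerance = 1e-10)
  expect_equal(kt$lambda, 1, tolerance = 1e-8)

  G3 <- matrix(rbinom(3 * n, 2, 0.3) / 2, n)
  kt0 <- kernel_test(yp, G3, weights = rep(0, 3), sigma2 = 1)
  expect_equal(kt0$statistic, 0)
  expect_equal(kt0$p.value, 1)
})

test_that("null eigenvalues are correct for orthogonal markers and conserve trace", {
  # two orthogonal, equal-variance centered markers with unit weights
  g1 <- c(0, 0, 1, 1, 0, 0, 1, 1) / 2
  g2 <- c(0, 1, 0, 1, 1, 0, 1, 0) / 2
  G <- cbind(g1, g2)
  yz <- structure(rnorm(8), sigma2 = 1, class = "transformed_trait")
  kt <- kernel_test(yz, G, weights = c(1, 1), sigma2 = 1)
  expect_equal(sort(kt$lambda), c(1, 1), tolerance = 1e-8)

  # trace identity on a random instance
  set.seed(241)
  n <- 60
  G <- matrix(rbinom(n * 10, 2, runif(10, 0.05, 0.5)) / 2, n, byrow = FALSE)
  yv <- structure(rnorm(n), sigma2 = 1.3, class = "transformed_trait")
  kt2 <- kernel_test(yv, G, weights = c(0.5, 0.5), sigma2 = 1.3)
  reg <- genotype_region(G)
  keep <- !reg$monomorphic
  Gc <- sweep(G[, keep], 2, colMeans(G[, keep]))
  Gp <- Gc - outer(rep(1, n), colMeans(Gc))
  wt <- beta_weights(reg$maf[keep], 0.5, 0.5) / colSums(Gc^2)
  expect_equal(sum(kt2$lambda), sum(diag(crossprod(Gp) * tcrossprod(sqrt(wt)))),
               tolerance = 1e-8)
})

test_that("mixture P values invert chi-square quantiles exactly", {
  expect_equal(as.numeric(pvalue_mixture(qchisq(0.95, 1), 1)), 0.05,
               tolerance = 1e-8)
  expect_equal(as.numeric(pvalue_mixture(qchisq(0.95, 2), c(1, 1))), 0.05,
               tolerance = 1e-8)
  expect_equal(as.numeric(pvalue_mixture(qchisq(0.5, 5), rep(1, 5))), 0.5,
               tolerance = 1e-8)
  expect_true(attr(pvalue_mixture(3, c(0.5, 1.5)), "method") %in%
              c("imhof", "liu"))
  # never exactly zero
  expect_gt(as.numeric(pvalue_mixture(1e6, c(1, 2))), 0)
})

test_that("mixture P values agree with Monte Carlo for random eigenvalue sets", {
  set.seed(251)
  for (i in 1:3) {
    lam <- rexp(5)
    draws <- colSums(lam * matrix(rchisq(5 * 2e5, df = 1), nrow = 5))
    q <- quantile(draws, 0.95, names = FALSE)
    p <- as.numeric(pvalue_mixture(q, lam))
    se <- sqrt(0.05 * 0.95 / 2e5)
    expect_lt(abs(p - 0.05), 3 * se + 1e-4)
  }
})

test_that("the Liu fallback approximates the tail well", {
  lam <- c(2, 1, 0.5, 0.25)
  for (q in c(5, 10, 20)) {
    expect_lt(abs(famkernel:::.pvalue_liu(q, lam) -
                  famkernel:::.pvalue_imhof(q, lam)), 0.01)
  }
})

test_that("resampling P values use the add-one estimator and are reproducible", {
  set.seed(261)
  n <- 120
  g <- rbinom(n, 2, 0.3) / 2
  y <- 3 * (g - mean(g)) + rnorm(n, sd = 0.1)   # overwhelming signal
  yt <- structure(y, sigma2 = 1, class = "transformed_trait")
  kt <- kernel_test(yt, matrix(g, ncol = 1), weights = c(1, 1), sigma2 = 1,
                    resampling = 999, seed = 7)
  expect_equal(kt$p.resampling, 1 / 1000)
  kt2 <- kernel_test(yt, matrix(g, ncol = 1), weights = c(1, 1), sigma2 = 1,
                     resampling = 999, seed = 7)
  expect_identical(kt$p.resampling, kt2$p.resampling)
  expect_error(kernel_test(yt, matrix(g, ncol = 1), sigma2 = 1,
                           resampling = 50), "at least 100")
})

test_that("the exact related-sample kernel test coincides with the simple one for R = I", {
  set.seed(271)
  n <- 80
  y <- rnorm(n)
  fit <- fixed_fit(diag(n), h2 = 0.5, sigma2 = 1, y = y)
  G <- matrix(rbinom(n * 6, 2, runif(6, 0.1, 0.5)) / 2, n, byrow = FALSE)
  yp <- transform_trait(fit, "grammar_plus")
  k1 <- kernel_test(yp, G, weights = c(1, 25))
  k2 <- kernel_test_exact(fit, G, weights = c(1, 25))
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-8)
  expect_equal(k1$p.value, k2$p.value, tolerance = 1e-6)
})
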