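test_that("with R = I the fit reduces to ordinary least squares", {
  set.seed(21)
  n <- 80
  y <- rnorm(n, mean = 3)
  fit <- polygenic(y, relmat = diag(n))
  # V = sigma2 * I for any h2: total variance and mean match OLS
  expect_equal(unname(fit$alpha["(Intercept)"]), mean(y), tolerance = 1e-6)
  expect_equal(fit$sigma2, var(y) * (n - 1) / (n - 1), tolerance = 0.02)
  expect_equal(fit$ytilde, y - mean(y), tolerance = 1e-6)
  # transforms collapse to the centered trait / its scaled copy
  yp <- transform_trait(fit, "grammar_plus")
  expect_equal(as.numeric(yp), fit$ytilde, tolerance = 1e-8)
  er <- transform_trait(fit, "env_residual")
  expect_equal(as.numeric(er), (fit$sigma2_e / fit$sigma2) * fit$ytilde,
               tolerance = 1e-8)
})

test_that("the profile optimum dominates a dense heritability grid", {
  ped <- sim_pedigree(n_families = 6, generations = 3, offspring = 2, seed = 31)
  R <- pedigree_relmat(ped)
  eg <- relmat_eigen(R)
  set.seed(32)
  X <- cbind(1, age = rnorm(length(eg$ids)))
  y <- sim_phenotype(eg, h2 = 0.6, sigma2 = 2, seed = 33) + 0.5 * X[, 2]
  for (method in c("REML", "ML")) {
    fit <- polygenic(y, X = X, relmat = eg, method = method)
    grid_ll <- vapply(seq(0, 0.999, length.out = 101), function(h)
      dense_loglik(y, X, unclass(R), h, method = method), numeric(1))
    expect_gte(fit$logLik + 1e-6, max(grid_ll))
    # normal equations under the Vhat inner product
    d <- fit$sigma2_g * eg$values + fit$sigma2_e
    viy <- eg$vectors %*% (crossprod(eg$vectors, fit$ytilde) / d)
    expect_lt(max(abs(crossprod(X, viy))), 1e-6)
  }
})

test_that("REML is equivariant under affine rescaling of the trait", {
  ped <- sim_pedigree(n_families = 8, generations = 3, seed = 41)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.5, sigma2 = 1, seed = 42)
  f1 <- polygenic(y, relmat = eg)
  f2 <- polygenic(5 * y + 7, relmat = eg)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-4)
  expect_equal(f2$sigma2_g, 25 * f1$sigma2_g, tolerance = 1e-3)
  expect_equal(f2$sigma2_e, 25 * f1$sigma2_e, tolerance = 1e-3)
  expect_equal(gamma_bar(f2), gamma_bar(f1), tolerance = 1e-6)
})

test_that("the ML likelihood matches the dense multivariate normal density", {
  ped <- sim_pedigree(n_families = 5, generations = 3, seed = 51)
  R <- pedigree_relmat(ped)
  y <- sim_phenotype(relmat_eigen(R), h2 = 0.4, sigma2 = 1.5, seed = 52)
  fit <- polygenic(y, relmat = R, method = "ML")
  n <- length(y)
  V <- fit$sigma2_g * unclass(R) + fit$sigma2_e * diag(n)
  r <- fit$ytilde
  ll_dense <- -0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                      drop(t(r) %*% solve(V, r)))
  expect_equal(fit$logLik, as.numeric(ll_dense), tolerance = 1e-6)
})

test_that("a pure-noise trait yields near-zero heritability estimates", {
  ped <- sim_pedigree(n_families = 60, generations = 3, seed = 61)
  eg <- relmat_eigen(pedigree_relmat(ped))
  set.seed(62)
  h2s <- vapply(1:20, function(i) {
    y <- rnorm(length(eg$ids))
    polygenic(y, relmat = eg)$h2
  }, numeric(1))
  expect_gte(mean(h2s <= 0.1), 0.9)
})

test_that("environmental residuals equal the direct matrix formula", {
  ped <- as_pedigree(data.frame(
    fid = "F1", id = c("a", "b", "c", "d", "e", "f"),
    father = c("0", "0", "a", "a", "0", "c"),
    mother = c("0", "0", "b", "b", "0", "e"),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L)))
  R <- pedigree_relmat(ped)
  y <- c(0.3, -1.2, 0.7, 2.1, -0.4, 0.9)
  fit <- fixed_fit(R, h2 = 0.6, sigma2 = 1.3, y = y)
  n <- 6
  V <- fit$sigma2_g * unclass(R) + fit$sigma2_e * diag(n)
  yt <- fit$ytilde
  uhat <- fit$sigma2_g * unclass(R) %*% solve(V, yt)
  expect_equal(residuals(fit, type = "environmental"),
               unname(drop(yt - uhat)), tolerance = 1e-10)
  # grammar_plus against the direct formula as well
  gb <- gamma_bar(fit)
  expect_equal(as.numeric(transform_trait(fit, "grammar_plus")),
               unname(drop(fit$sigma2 / sqrt(gb) * solve(V, yt))),
               tolerance = 1e-10)
})

test_that("h2 = 0 makes environmental residuals equal the centered trait", {
  ped <- sim_pedigree(n_families = 10, generations = 3, seed = 71)
  R <- pedigree_relmat(ped)
  fit <- fixed_fit(R, h2 = 0, sigma2 = 1, y = rnorm(nrow(R)))
  expect_equal(residuals(fit, type = "environmental"), fit$ytilde,
               tolerance = 1e-12)
  expect_equal(gamma_bar(fit), 1, tolerance = 1e-12)
})

test_that("centering is translation-invariant and BLUPs decompose the trait", {
  ped <- sim_pedigree(n_families = 8, generations = 3, seed = 81)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.5, seed = 82)
  f1 <- polygenic(y, relmat = eg)
  f2 <- polygenic(y + 100, relmat = eg)
  expect_equal(f1$ytilde, f2$ytilde, tolerance = 1e-6)
  # ytilde = uhat + ehat
  expect_equal(predict(f1) + residuals(f1, "environmental"), f1$ytilde,
               tolerance = 1e-10)
})

test_that("formula and sample_frame interfaces agree with the default one", {
  ped <- sim_pedigree(n_families = 6, generations = 3, seed = 91)
  eg <- relmat_eigen(pedigree_relmat(ped))
  n <- length(eg$ids)
  set.seed(92)
  age <- rnorm(n, 50, 8)
  y <- sim_phenotype(eg, h2 = 0.5, seed = 93) + 0.02 * age
  df <- data.frame(trait = y, age = age, row.names = eg$ids)
  f_formula <- polygenic(trait ~ age, data = df, relmat = eg)
  f_default <- polygenic(y, X = cbind(1, age = age), relmat = eg)
  expect_equal(f_formula$h2, f_default$h2, tolerance = 1e-8)
  expect_equal(unname(coef(f_formula)), unname(coef(f_default)),
               tolerance = 1e-8)
  frame <- sample_frame(eg$ids, y, cbind(1, age = age))
  f_frame <- polygenic(frame, relmat = eg)
  expect_equal(f_frame$logLik, f_default$logLik, tolerance = 1e-10)
})

test_that("simulate() reproduces the fitted covariance structure", {
  ped <- sim_pedigree(n_families = 20, generations = 3, seed = 95)
  eg <- relmat_eigen(pedigree_relmat(ped))
  y <- sim_phenotype(eg, h2 = 0.6, sigma2 = 2, seed = 96)
  fit <- polygenic(y, relmat = eg)
  ys <- simulate(fit, nsim = 200, seed = 97)
  expect_equal(dim(ys), c(fit$n, 200))
  expect_equal(mean(apply(ys, 2, var)), fit$sigma2, tolerance = 0.15)
})
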