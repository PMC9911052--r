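# Simulated trait over a genotype matrix: y = Z beta_qtl + noise at given h2
sim_trait <- function(g, n_qtl, h2, seed) {
  set.seed(seed)
  m <- ncol(g$dosages)
  idx <- sample(m, n_qtl)
  b <- rnorm(n_qtl)
  bv <- as.vector(g$dosages[, idx, drop = FALSE] %*% b)
  b <- b * sqrt(h2 / var(bv))
  bv <- bv * sqrt(h2 / var(bv))
  y <- bv + rnorm(nrow(g$dosages), 0, sqrt(1 - h2))
  names(y) <- rownames(g$dosages)
  true <- numeric(m)
  true[idx] <- b
  list(y = y, true = true)
}

test_that("a constant phenotype yields zero effects with a warning", {
  g <- random_geno(12, 6, seed = 1)
  y <- stats::setNames(rep(3.2, 12), rownames(g$dosages))
  expect_warning(fit <- fit_rrblup(g, y), "no residual variance")
  expect_equal(unname(coef(fit)), rep(0, 6))
})

test_that("at fixed lambda the BLUP equals the explicit ridge solution", {
  g <- random_geno(5, 3, seed = 2)
  y <- stats::setNames(c(1.2, -0.4, 0.8, 2.1, 0.3), rownames(g$dosages))
  lam <- 2.5
  fit <- fit_rrblup(g, y, lambda = lam)
  # independent oracle: direct linear solve on centred genotypes
  Zc <- scale(g$dosages, scale = FALSE)
  oracle <- solve(crossprod(Zc) + lam * diag(3), crossprod(Zc, y - mean(y)))
  expect_equal(unname(coef(fit)), as.vector(oracle), tolerance = 1e-10)
})

test_that("eigendecomposition REML matches a naive restricted-likelihood
           optimizer on a small instance", {
  g <- random_geno(30, 8, seed = 3)
  tr <- sim_trait(g, 5, 0.6, seed = 4)
  fit <- fit_rrblup(g, tr$y)

  # oracle: profile REML via explicit n x n covariance algebra
  Zc <- scale(g$dosages, scale = FALSE)
  K <- tcrossprod(Zc)
  n <- 30; X <- matrix(1, n, 1); p <- 1
  y <- unname(tr$y)
  negll <- function(t) {
    Vs <- K + exp(t) * diag(n)
    Vi <- solve(Vs)
    XVX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
    su2 <- drop(y %*% P %*% y) / (n - p)
    (n - p) * log(su2) + determinant(Vs)$modulus + determinant(XVX)$modulus
  }
  opt <- optimize(negll, c(-18, 18), tol = 1e-12)
  delta <- exp(opt$minimum)
  Vs <- K + delta * diag(n)
  Vi <- solve(Vs)
  XVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
  su2 <- drop(y %*% P %*% y) / (n - p)
  expect_equal(fit$varcomp$sigma2_u, su2, tolerance = 1e-6)
  expect_equal(fit$varcomp$sigma2_e, delta * su2, tolerance = 1e-6)
  # and the BLUP from the oracle route
  u <- drop(crossprod(Zc, P %*% y))
  expect_equal(unname(coef(fit)), unname(u), tolerance = 1e-6)
})

test_that("effects are scale equivariant and orientation aware", {
  g <- random_geno(60, 40, seed = 5)
  tr <- sim_trait(g, 10, 0.5, seed = 6)
  fit1 <- fit_rrblup(g, tr$y)
  fit2 <- fit_rrblup(g, tr$y * 3)
  # (equal up to the 1-D REML search tolerance)
  expect_equal(unname(coef(fit2)), 3 * unname(coef(fit1)),
               tolerance = 1e-6)

  # flipping one marker's counted allele flips only that effect
  gf <- g
  gf$dosages[, 7] <- 2 - gf$dosages[, 7]
  fit3 <- fit_rrblup(gf, tr$y)
  expect_equal(unname(coef(fit3)[7]), -unname(coef(fit1)[7]),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit3)[-7]), unname(coef(fit1)[-7]),
               tolerance = 1e-6)

  # BayesC is pathwise scale equivariant under a fixed seed because its
  # variance priors are data-derived
  fb1 <- fit_bayesc(g, tr$y, pi = 0.8, iters = 300, burnin = 50, seed = 9)
  fb2 <- fit_bayesc(g, tr$y * 3, pi = 0.8, iters = 300, burnin = 50,
                    seed = 9)
  expect_equal(unname(coef(fb2)), 3 * unname(coef(fb1)), tolerance = 1e-8)
})

test_that("estimated effects track true effects and improve with n", {
  g_small <- random_geno(100, 300, seed = 7)
  g_big <- random_geno(400, 300, seed = 77)
  tr_s <- sim_trait(g_small, 150, 0.5, seed = 8)
  tr_b <- sim_trait(g_big, 150, 0.5, seed = 8)
  r_small <- cor(coef(fit_rrblup(g_small, tr_s$y)), tr_s$true)
  r_big <- cor(coef(fit_rrblup(g_big, tr_b$y)), tr_b$true)
  expect_gt(r_small, 0)
  expect_gt(r_big, r_small)
})

test_that("BayesC honours its zero-fraction prior", {
  g <- random_geno(150, 120, seed = 10)
  tr <- sim_trait(g, 20, 0.6, seed = 11)
  # pi = 1: everything excluded, exactly
  fb <- fit_bayesc(g, tr$y, pi = 1, iters = 200, burnin = 50, seed = 1)
  expect_equal(unname(coef(fb)), rep(0, 120))

  # pi = 0: every marker stays in the model and the posterior mean
  # approaches the ridge solution at the matched variance ratio
  fb0 <- fit_bayesc(g, tr$y, pi = 0, iters = 1500, burnin = 300, seed = 2)
  lam <- fb0$varcomp$sigma2_e / fb0$varcomp$sigma2_alpha
  fr <- fit_rrblup(g, tr$y, lambda = lam)
  expect_gt(cor(coef(fb0), coef(fr)), 0.95)
  expect_true(all(fb0$inclusion_prob == 1))
})

test_that("BayesC ranks large-effect QTL by inclusion probability", {
  set.seed(12)
  hits <- 0
  for (rep in 1:10) {
    g <- random_geno(200, 400)
    idx <- sample(400, 5)
    bv <- as.vector(g$dosages[, idx] %*% rep(1, 5))
    y <- stats::setNames(bv + rnorm(200, 0, sd(bv) * 0.7),
                         rownames(g$dosages))
    fb <- fit_bayesc(g, y, pi = 0.95, iters = 600, burnin = 150,
                     seed = 100 + rep)
    top <- order(fb$inclusion_prob, decreasing = TRUE)[1:40]  # top decile
    if (all(idx %in% top)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("phenotyped-subset estimation predicts over all genotypes", {
  g <- random_geno(120, 80, seed = 13, group = rep(c(0, 1, 2), each = 40))
  tr <- sim_trait(g, 30, 0.7, seed = 14)
  modern <- g$group == 2
  ph <- data.frame(sample = rownames(g$dosages)[modern],
                   y = unname(tr$y[modern]))
  fit <- fit_rrblup(g, ph, trait = "y")
  expect_equal(fit$n, sum(modern))
  pred <- predict(fit, g)
  expect_length(pred, 120)
  expect_gt(cor(pred, tr$y), 0.3)
})

test_that("fixed-effect covariates are absorbed before marker estimation", {
  g <- random_geno(150, 60, seed = 15)
  tr <- sim_trait(g, 20, 0.6, seed = 16)
  batch <- rep(c(0, 5), length.out = 150)      # large nuisance shift
  ph <- data.frame(sample = rownames(g$dosages),
                   y = unname(tr$y) + batch, batch = batch)
  fit_cov <- fit_rrblup(g, ph, trait = "y", covariates = "batch")
  fit_clean <- fit_rrblup(g, tr$y)
  expect_gt(cor(coef(fit_cov), coef(fit_clean)), 0.99)
  expect_error(fit_rrblup(g, ph, trait = "y", covariates = "nope"),
               "covariate")
})
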