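test_that("constant phenotypes give zero marker effects", {
  g <- toy_genotype(10, 6, seed = 1)
  y <- stats::setNames(rep(5, 10), line_ids(g))
  fit <- fit_rrblup(g, y)
  expect_true(all(fit$marker_effects == 0))
  pred <- predict_gebv(fit, g)
  expect_true(all(pred$gebv == 5))
})

test_that("fixed-lambda ridge matches the closed form", {
  # 2-line toy: Z = [1, -1]', y = (1, -1), lambda = 1 -> effect 2/3
  d <- matrix(c(2, 0, 1, 1, 0, 2), 3, 2,
              dimnames = list(paste0("L", 1:3), c("m1", "m2")))
  # use the first marker only: centered column is (1, 0, -1); build the
  # exact spec instance with 2 lines instead
  d2 <- matrix(c(2, 0), 2, 1, dimnames = list(c("A", "B"), "m1"))
  fit <- fit_rrblup(d2, c(A = 1, B = -1), lambda = 1)
  expect_equal(unname(fit$marker_effects), 2 / 3, tolerance = 1e-10)

  # random instances: effects = (Z'Z + lambda I)^{-1} Z' (y - mu)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50; m <- 20
    d <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                dimnames = list(paste0("L", 1:n), paste0("s", 1:m)))
    y <- rnorm(n)
    lam <- exp(runif(1, -2, 3))
    fit <- fit_rrblup(d, stats::setNames(y, rownames(d)), lambda = lam)
    Z <- scale(d, scale = FALSE)
    H <- tcrossprod(Z) + lam * diag(n)
    Hi1 <- solve(H, rep(1, n))
    mu <- sum(Hi1 * y) / sum(Hi1)
    expected <- solve(crossprod(Z) + lam * diag(m), crossprod(Z, y - mu))
    expect_equal(unname(fit$marker_effects), as.vector(expected),
                 tolerance = 1e-8)
  }
})

test_that("REML optimum beats a 50-point lambda grid", {
  sim <- small_sim(n_markers = 200, seed = 31)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  fit <- fit_rrblup(sim$genotype, y)
  crit_opt <- fit$reml$criterion(fit$reml$log_lambda)
  grid <- seq(-10, 10, length.out = 50)
  expect_true(all(crit_opt <= vapply(grid, fit$reml$criterion,
                                     numeric(1)) + 1e-6))
})

test_that("rrBLUP GEBVs agree with an independent gBLUP oracle", {
  sim <- small_sim(n_markers = 500, sizes = c(NSS = 60, SS = 20, TST = 80,
                                              MIXED = 40), seed = 17)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  d <- sim$genotype$dosages[names(y), ]
  fit <- fit_rrblup(d, y)
  gebv <- predict_gebv(fit, d)
  oracle <- gblup_oracle(d, as.numeric(y))
  expect_gte(stats::cor(gebv$gebv, oracle$gebv), 0.999)
})

test_that("Bayesian chains are seed-deterministic", {
  sim <- small_sim(n_markers = 100, sizes = c(NSS = 20, SS = 10, TST = 30,
                                              MIXED = 10), seed = 23)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  f1 <- fit_bayes(sim$genotype, y, "BayesB", iters = 300, burnin = 100,
                  thin = 2, seed = 99)
  f2 <- fit_bayes(sim$genotype, y, "BayesB", iters = 300, burnin = 100,
                  thin = 2, seed = 99)
  expect_identical(f1$marker_effects, f2$marker_effects)
  expect_identical(f1$variance_components, f2$variance_components)
  f3 <- fit_bayes(sim$genotype, y, "BayesB", iters = 300, burnin = 100,
                  thin = 2, seed = 100)
  expect_false(identical(f1$marker_effects, f3$marker_effects))
})

test_that("BRR tracks rrBLUP and BayesC with pi = 0 collapses to BRR", {
  sim <- small_sim(n_markers = 300, sizes = c(NSS = 50, SS = 20, TST = 80,
                                              MIXED = 50), seed = 29)
  y <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  d <- sim$genotype$dosages[names(y), ]
  rr <- predict_gebv(fit_rrblup(d, y), d)
  brr <- fit_bayes(d, y, "BRR", iters = 2000, burnin = 500, thin = 2,
                   seed = 4)
  expect_gte(stats::cor(predict_gebv(brr, d)$gebv, rr$gebv), 0.98)
  bc0 <- fit_bayes(d, y, "BayesC", iters = 2000, burnin = 500, thin = 2,
                   seed = 4, hyper = list(pi_zero = 0, estimate_pi = FALSE))
  expect_gte(stats::cor(predict_gebv(bc0, d)$gebv,
                        predict_gebv(brr, d)$gebv), 0.99)
})

test_that("Gibbs residual variance lands near truth on a conjugate-friendly design", {
  set.seed(5)
  n <- 200; m <- 60
  d <- matrix(sample(0:2, n * m, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), n, m,
              dimnames = list(paste0("L", 1:n), paste0("s", 1:m)))
  Z <- scale(d, scale = FALSE)
  g_true <- rnorm(m, 0, sqrt(1 / m))
  y <- stats::setNames(as.vector(Z %*% g_true) + rnorm(n, 0, 1),
                       rownames(d))
  for (model in c("BRR", "BayesA", "BL")) {
    fit <- fit_bayes(d, y, model, iters = 2500, burnin = 500, thin = 2,
                     seed = 6)
    expect_lt(abs(fit$variance_components$sigma2_e - 1) / 1, 0.2)
  }
})

test_that("GEBV scoring is exact, centered and linear", {
  g <- toy_genotype(12, 8, seed = 3)
  set.seed(4)
  y <- stats::setNames(rnorm(12), line_ids(g))
  fit <- fit_rrblup(g, y)
  pred <- predict_gebv(fit, g)
  manual <- fit$intercept +
    sweep(g$dosages, 2, fit$centers) %*% fit$marker_effects
  expect_equal(pred$gebv, as.vector(manual))

  # a line sitting exactly at the training centers scores the intercept
  center_line <- matrix(fit$centers, 1,
                        dimnames = list("C", names(fit$centers)))
  expect_equal(predict_gebv(fit, center_line)$gebv, fit$intercept)

  # doubling one marker effect doubles its contribution
  fit2 <- fit
  k <- 3
  fit2$marker_effects[k] <- 2 * fit$marker_effects[k]
  delta <- predict_gebv(fit2, g)$gebv - pred$gebv
  expect_equal(delta,
               (g$dosages[, k] - fit$centers[k]) * fit$marker_effects[k],
               ignore_attr = TRUE)

  # marker mismatch errors
  expect_error(predict_gebv(fit, g$dosages[, 1:5]), "lack")
})

test_that("model name normalisation accepts the common spellings", {
  g <- toy_genotype(15, 10, seed = 8)
  set.seed(1)
  y <- stats::setNames(rnorm(15), line_ids(g))
  f <- fit_bayes(g, y, "bayesc", iters = 200, burnin = 50, seed = 1)
  expect_equal(f$model, "BayesC")
  expect_error(fit_bayes(g, y, "bayesZ", iters = 200, burnin = 50),
               "unknown Bayesian model")
  expect_error(fit_bayes(g, y, "BRR", iters = 100, burnin = 100), "exceed")
})
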