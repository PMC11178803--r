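# Exact GP core: kernel, marginal likelihood, fitting, posterior, NLPD.

test_that("Matern-5/2 kernel matches its closed form", {
  p <- kernel_params(lengthscale = 2, outputscale = 1.7, noise = 0)
  # r = 0
  expect_equal(matern52_gram(matrix(0), matrix(0), p)[1, 1], 1.7)
  # r = lengthscale
  k <- matern52_gram(matrix(0), matrix(2), p)[1, 1]
  expect_equal(k, 1.7 * (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)), tolerance = 1e-12)
  # exact symmetry
  set.seed(1)
  A <- matrix(rnorm(24), 8)
  K <- matern52_gram(A, A, p)
  expect_identical(K, t(K))
  expect_error(matern52_gram(matrix(0, 1, 2), matrix(0, 1, 3), p), "width")
})

test_that("Gram matrices are positive semi-definite after jitter", {
  for (s in 1:20) {
    set.seed(s)
    A <- matrix(rnorm(15 * 3), 15)
    K <- matern52_gram(A, A, kernel_params(runif(1, 0.3, 3), runif(1, 0.5, 2), 0))
    ev <- min(eigen(K + diag(1e-8, 15), symmetric = TRUE,
                    only.values = TRUE)$values)
    expect_gte(ev, 0)
  }
})

test_that("log marginal likelihood reproduces closed-form cases", {
  # 1 point, unit variance: standard normal at 0
  st <- gp_state(matrix(0), 0, kernel_params(1, 1, 0))
  expect_equal(log_marginal_likelihood(st), -0.5 * log(2 * pi),
               tolerance = 1e-7)
  # 2 points, identity covariance, y = (1, 1)
  st2 <- gp_state(matrix(c(0, 1e6), 2), c(1, 1), kernel_params(1e-6, 1, 0))
  expect_equal(log_marginal_likelihood(st2), -1 - log(2 * pi),
               tolerance = 1e-6)
})

test_that("LML and posterior match the dense-formula oracle", {
  for (s in 1:25) {
    inst <- random_gp_instance(s)
    st <- gp_state(inst$X, inst$y, inst$params)
    or <- oracle_gp(inst$X, inst$y, inst$Xs, inst$params)
    expect_equal(log_marginal_likelihood(st), or$lml, tolerance = 1e-8)
    pr <- posterior_predict(st, inst$Xs)
    expect_equal(pr$mean, or$mean, tolerance = 1e-8)
    expect_equal(pr$variance, or$var, tolerance = 1e-8)
  }
})

test_that("noiseless GP interpolates its training points", {
  set.seed(3)
  X <- matrix(rnorm(12 * 2), 12)
  y <- sin(X[, 1]) + X[, 2]
  st <- gp_state(X, y, kernel_params(1.5, 1, 1e-12))
  pr <- posterior_predict(st, X)
  expect_lt(max(abs(pr$mean - y)), 1e-4)
  expect_lt(max(pr$variance), 1e-6)
})

test_that("far queries revert to the prior", {
  set.seed(4)
  X <- matrix(rnorm(10), 10, 1)
  y <- rnorm(10)
  p <- kernel_params(0.5, 1.3, 0.2)
  st <- gp_state(X, y, p)
  pr <- posterior_predict(st, matrix(1e6, 1, 1))
  expect_equal(pr$mean, 0, tolerance = 1e-6)
  expect_equal(pr$variance, p$outputscale + p$noise, tolerance = 1e-6)
})

test_that("duplicating a training point never increases variance there", {
  set.seed(5)
  X <- matrix(rnorm(8), 8, 1)
  y <- rnorm(8)
  p <- kernel_params(1, 1, 0.1)
  v1 <- posterior_predict(gp_state(X, y, p), X[1, , drop = FALSE])$variance
  X2 <- rbind(X, X[1, ])
  y2 <- c(y, y[1])
  v2 <- posterior_predict(gp_state(X2, y2, p), X[1, , drop = FALSE])$variance
  expect_lte(v2, v1 + 1e-10)
})

test_that("fit_gp improves on its initialization and recovers lengthscale", {
  set.seed(6)
  X <- matrix(runif(60, -3, 3), 30, 2)
  y <- gp_draw_dataset(X, kernel_params(1, 1, 0.01), seed = 6)
  init <- kernel_params(0.3, 0.5, 0.3)
  st0 <- gp_state(X, y, init)
  st <- fit_gp(X, y, init)
  expect_gte(log_marginal_likelihood(st),
             log_marginal_likelihood(st0) - 1e-6)
  expect_error(fit_gp(matrix(0, 1, 1), 0), "at least 2")

  hits <- 0
  for (s in 1:10) {
    Xr <- matrix(runif(200, -4, 4), 100, 2)
    yr <- gp_draw_dataset(Xr, kernel_params(1, 1, 0.01), seed = 50 + s)
    fit <- fit_gp(Xr, yr)
    l <- fit$params$lengthscale
    if (l >= 0.5 && l <= 2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("NLPD matches closed forms and is monotone in confidence", {
  pr <- predictive_distribution(rep(0, 5), rep(1, 5), "original")
  expect_equal(nlpd(pr, rep(0, 5)), 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(nlpd(pr, rep(0, 5), aggregate = "sum"),
               5 * 0.5 * log(2 * pi), tolerance = 1e-12)
  # mu - t = 3 sigma
  s2 <- 0.49
  pr3 <- predictive_distribution(3 * sqrt(s2), s2, "original")
  expect_equal(nlpd(pr3, 0), 0.5 * log(2 * pi * s2) + 4.5, tolerance = 1e-12)
  # shrinking variance at the correct mean strictly decreases NLPD
  vals <- vapply(c(2, 1, 0.5, 0.1),
                 function(v) nlpd(predictive_distribution(0, v, "original"), 0),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  # permutation invariance
  set.seed(7)
  mu <- rnorm(20); va <- runif(20, 0.2, 2); tg <- rnorm(20)
  perm <- sample(20)
  expect_equal(nlpd(predictive_distribution(mu, va, "original"), tg),
               nlpd(predictive_distribution(mu[perm], va[perm], "original"),
                    tg[perm]))
})
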