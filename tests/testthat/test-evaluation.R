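# Splits, standardization, metrics, repeated evaluation, cluster summary.

test_that("random splits follow the floor/floor/remainder rule", {
  rx <- rep(tiny_grid(seed = 41), length.out = 100)
  sp <- make_splits(rx, c(0.7, 0.1, 0.2), seed = 9)
  expect_length(sp$train, 70)
  expect_length(sp$val, 10)
  expect_length(sp$test, 20)
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, 1:100)
  # determinism
  sp2 <- make_splits(rx, c(0.7, 0.1, 0.2), seed = 9)
  expect_identical(sp, sp2)
})

test_that("split partitioning holds across a fuzz grid of sizes and seeds", {
  base <- tiny_grid(seed = 42)
  for (case in 1:50) {
    set.seed(case)
    n <- sample(10:200, 1)
    seed <- sample(1e6, 1)
    rx <- rep(base, length.out = n)
    sp <- make_splits(rx, c(0.7, 0.1, 0.2), seed = seed)
    idx <- c(sp$train, sp$val, sp$test)
    expect_identical(sort(idx), seq_len(n))
    expect_identical(anyDuplicated(idx), 0L)
    expect_identical(sp, make_splits(rx, c(0.7, 0.1, 0.2), seed = seed))
  }
})

test_that("leave-component-out splits exclude held-out components from train", {
  rx <- tiny_grid(seed = 43)
  additives <- unique(vapply(rx, function(r) unname(r$components[["additive"]]),
                             character(1)))
  held <- additives[1]
  sp <- make_splits(rx, c(0.8, 0.2, 0), seed = 1,
                    mode = "leave_component_out", role = "additive",
                    held_out = held)
  test_adds <- vapply(rx[sp$test], function(r) unname(r$components[["additive"]]),
                      character(1))
  train_adds <- vapply(rx[sp$train], function(r) unname(r$components[["additive"]]),
                       character(1))
  expect_true(all(test_adds == held))
  expect_false(held %in% train_adds)
  expect_error(make_splits(rx, c(0.8, 0.2, 0), 1, "leave_component_out",
                           "additive", "not-a-smiles"), "held-out")
})

test_that("the standardizer round-trips and rejects degenerate input", {
  y <- c(0, 100)
  st <- standardizer(y)
  z <- st$transform(y)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  set.seed(10)
  yr <- runif(50, 0, 100)
  st2 <- standardizer(yr)
  expect_equal(st2$inverse(st2$transform(yr)), yr, tolerance = 1e-10)
  expect_error(standardizer(rep(5, 10)), "constant")
})

test_that("regression metrics match hand computations", {
  pr <- predictive_distribution(c(1, 2, 3), rep(1, 3), "original")
  m <- regression_metrics(pr, c(3, 2, 1))
  expect_equal(m$rmse, sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(m$mae, 4 / 3, tolerance = 1e-12)
  expect_equal(m$r2, -3, tolerance = 1e-12)

  # perfect prediction
  pr2 <- predictive_distribution(c(3, 2, 1), rep(0.5, 3), "original")
  m2 <- regression_metrics(pr2, c(3, 2, 1))
  expect_equal(m2$rmse, 0)
  expect_equal(m2$mae, 0)
  expect_equal(m2$r2, 1)

  # constant offset
  pr3 <- predictive_distribution(c(3, 2, 1) + 2, rep(1, 3), "original")
  m3 <- regression_metrics(pr3, c(3, 2, 1))
  expect_equal(m3$rmse, 2)
  expect_equal(m3$mae, 2)

  expect_error(regression_metrics(pr, rep(1, 3)), "zero-variance")
  expect_true(m$rmse >= m$mae)
})

test_that("metrics are permutation invariant", {
  set.seed(12)
  mu <- rnorm(30); va <- runif(30, 0.5, 2); tg <- rnorm(30)
  perm <- sample(30)
  m1 <- regression_metrics(predictive_distribution(mu, va, "original"), tg)
  m2 <- regression_metrics(predictive_distribution(mu[perm], va[perm],
                                                   "original"), tg[perm])
  expect_equal(m1, m2)
})

test_that("repeated evaluation aggregates runs with standard errors", {
  rx <- tiny_grid(seed = 44, noise_sd = 3)
  res <- repeated_evaluation("gp", rx, list(type = "morgan"),
                             config = list(init = kernel_params(3, 1, 0.2)),
                             n_runs = 3, train_fractions = c(0.7, 0.5),
                             base_seed = 7)
  expect_equal(nrow(res$runs), 6)
  expect_equal(nrow(res$aggregate), 2)
  expect_true(all(c("rmse_mean", "rmse_se", "nlpd_mean") %in%
                  names(res$aggregate)))
  expect_true(all(res$aggregate$rmse_se >= 0))
  # run seeds are base_seed + run index
  expect_identical(unique(res$runs$seed), c(8, 9, 10))
  # default ladder includes the 5:95 split and default runs are 10
  expect_true(0.05 %in% eval(formals(repeated_evaluation)$train_fractions))
  expect_equal(eval(formals(repeated_evaluation)$n_runs), 10L)
})

test_that("cluster summary recovers separated structure", {
  set.seed(13)
  blob1 <- matrix(rnorm(40 * 5, 0), 40)
  blob2 <- matrix(rnorm(40 * 5, 8), 40)
  emb <- rbind(blob1, blob2)
  yields <- c(runif(40, 0, 20), runif(40, 80, 100))
  cs <- cluster_summary(emb, yields, k = 2, seed = 3)
  truth <- rep(1:2, each = 40)
  tab <- table(cs$assignment, truth)
  # perfect agreement up to label swap
  expect_equal(sum(apply(tab, 1, max)), 80)
  expect_equal(nrow(cs$summary), 2)
  lows <- cs$summary$median_yield[order(cs$summary$median_yield)]
  expect_lt(lows[1], 20)
  expect_gt(lows[2], 80)

  # k = 1 collapses to the overall median
  cs1 <- cluster_summary(emb, yields, k = 1)
  expect_equal(cs1$summary$median_yield, median(yields))
  expect_error(cluster_summary(emb[1:3, ], yields[1:3], k = 5), "exceeds")
  # default k mirrors the reference analysis
  expect_equal(eval(formals(cluster_summary)$k), 4L)
})
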