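# Deep kernel: extractors, joint training, prediction, GNN baseline.

test_that("the feed-forward extractor is deterministic in eval mode", {
  cfg <- ffnn_config(10, hidden = 8, d_emb = 4)
  par <- dklgp:::ffnn_init(cfg, seed = 1)
  x <- matrix(rnorm(30), 3)
  e1 <- ffnn_extract(x, par, cfg, mode = "eval")
  e2 <- ffnn_extract(x, par, cfg, mode = "eval")
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(3L, 4L))
  expect_error(ffnn_extract(matrix(0, 1, 7), par, cfg), "width")
  # all-zero weights give the zero embedding
  zpar <- lapply(par, function(p) p * 0)
  expect_true(all(ffnn_extract(x, zpar, cfg) == 0))
})

test_that("deep-kernel Gram matrices stay PSD for random extractors", {
  set.seed(11)
  cfg <- ffnn_config(6, hidden = 8, d_emb = 3)
  for (s in 1:10) {
    par <- dklgp:::ffnn_init(cfg, seed = s)
    Z <- ffnn_extract(matrix(rnorm(60), 10), par, cfg)
    K <- matern52_gram(Z, Z, kernel_params(1, 1, 0))
    ev <- min(eigen(K + diag(1e-8, 10), symmetric = TRUE,
                    only.values = TRUE)$values)
    expect_gte(ev, 0)
  }
})

test_that("MPNN embeddings are invariant to atom order and role order", {
  smis <- c(aryl_halide = "Clc1ccccc1", ligand = "CP(C)C",
            base = "CCN(CC)CC", additive = "Oc1ccccc1")
  graphs <- lapply(smis, mol_to_graph)
  cfg <- mpnn_config(d_atom = node_feature_width(), h = 8, T_mp = 2,
                     M_s2s = 2, hidden = 16, d_emb = 5)
  for (s in 1:10) {
    par <- dklgp:::mpnn_init(cfg, seed = s)
    e0 <- mpnn_extract(graphs, par, cfg)
    # role permutation
    e_role <- mpnn_extract(graphs[sample(4)], par, cfg)
    expect_lt(max(abs(e0 - e_role)), 1e-6)
    # atom permutation of a random component
    k <- sample(4, 1)
    g <- graphs[[k]]
    perm <- sample(g$n_atoms)
    inv <- order(perm)
    g2 <- g
    g2$x <- g$x[perm, , drop = FALSE]
    g2$edges <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
    graphs2 <- graphs
    graphs2[[k]] <- g2
    e_atom <- mpnn_extract(graphs2, par, cfg)
    expect_lt(max(abs(e0 - e_atom)), 1e-6)
  }
})

test_that("a single-node graph with zero message rounds still embeds", {
  g <- mol_to_graph("C")
  cfg <- mpnn_config(d_atom = node_feature_width(), h = 4, T_mp = 0,
                     M_s2s = 1, hidden = 8, d_emb = 3)
  par <- dklgp:::mpnn_init(cfg, seed = 2)
  e <- mpnn_extract(list(a = g), par, cfg)
  expect_length(e, 3)
  expect_true(all(is.finite(e)))
})

test_that("default deep-kernel config follows the training protocol", {
  cfg <- dkl_config()
  expect_equal(cfg$epochs, 400L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$dropout, 0.1)
})

test_that("joint training increases the marginal likelihood", {
  rx <- tiny_grid(seed = 21)
  cfg <- dkl_config(epochs = 60, seed = 3, hidden = 32, d_emb = 8)
  st <- train_dkl(rx, list(type = "morgan"), cfg)
  n <- length(st$lml_trace)
  expect_gt(mean(st$lml_trace[(n - 9):n]), st$lml_trace[1])
  expect_true(all(is.finite(st$lml_trace)))
})

test_that("identity extractor reduces the deep kernel to the plain GP", {
  set.seed(31)
  X <- matrix(rnorm(20 * 3), 20)
  y <- gp_draw_dataset(X, kernel_params(1.2, 1, 0.05), seed = 31)
  yields <- pmin(pmax(y * 10 + 50, 0), 100)
  rx <- lapply(seq_len(20), function(i)
    reaction(c(a = "C"), yields[i], validate = FALSE))
  cfg <- dkl_config(extractor = "identity", epochs = 5, center = FALSE,
                    init = kernel_params(1.2, 1, 0.05), lr = 0)
  st <- train_dkl(rx, config = cfg, features = X)
  # with lr 0 the kernel stays at its initialization: predictions must
  # match gp_core exactly
  std <- standardizer(yields)
  gp <- gp_state(X, std$transform(yields), kernel_params(1.2, 1, 0.05))
  pr_gp <- posterior_predict(gp, X)
  pr_dkl <- dkl_predict(st, rx, features = X)
  expect_equal(pr_dkl$mean, std$inverse(pr_gp$mean), tolerance = 1e-10)
  expect_equal(pr_dkl$variance, pr_gp$variance * std$sd^2, tolerance = 1e-10)
})

test_that("deep-kernel predictions are consistent and on the yield scale", {
  rx <- tiny_grid(seed = 22)
  cfg <- dkl_config(epochs = 40, seed = 4, hidden = 16, d_emb = 4)
  st <- train_dkl(rx, list(type = "morgan"), cfg)
  pr <- dkl_predict(st, rx[c(1, 1, 5)])
  expect_identical(pr$scale_tag, "original")
  # duplicated query rows give identical mean/variance pairs
  expect_equal(pr$mean[1], pr$mean[2])
  expect_equal(pr$variance[1], pr$variance[2])
  expect_true(all(pr$variance > 0))
  # featurizer mismatch is caught
  expect_error(dkl_predict(st, rx, features = matrix(0, 36, 7)),
               "featurizer mismatch")
})

test_that("seeded training is reproducible", {
  rx <- tiny_grid(seed = 23)
  cfg <- dkl_config(epochs = 15, seed = 5, hidden = 16, d_emb = 4)
  s1 <- train_dkl(rx, list(type = "morgan"), cfg)
  s2 <- train_dkl(rx, list(type = "morgan"), cfg)
  expect_identical(s1$lml_trace, s2$lml_trace)
  expect_identical(s1$params, s2$params)
})

test_that("the GNN baseline shares the MPNN architecture and fits a toy grid", {
  rx <- tiny_grid(seed = 24, noise_sd = 0)
  cfg <- dkl_config(extractor = "mpnn", epochs = 150, seed = 6, h = 8,
                    T_mp = 1, M_s2s = 1, hidden = 16, d_emb = 8, lr = 0.01)
  model <- gnn_baseline(rx, cfg)
  # trunk architecture identical to the deep kernel's graph branch
  dk_arch <- mpnn_config(d_atom = node_feature_width(), h = cfg$h,
                         T_mp = cfg$T_mp, M_s2s = cfg$M_s2s,
                         hidden = cfg$hidden, d_emb = cfg$d_emb,
                         dropout = cfg$dropout)
  expect_identical(model$arch, dk_arch)
  # squared-error training loss decreases substantially on a noiseless
  # additive grid
  n <- length(model$loss_trace)
  expect_lt(mean(model$loss_trace[(n - 9):n]), 0.35 * model$loss_trace[1])
  # point predictions only
  mu <- gnn_predict(model, rx)
  expect_true(is.numeric(mu) && is.null(dim(mu)))
  expect_length(mu, length(rx))
})

test_that("embeddings feed the cluster analysis and checkpoints round-trip", {
  rx <- tiny_grid(seed = 25)
  cfg <- dkl_config(epochs = 20, seed = 8, hidden = 16, d_emb = 4)
  st <- train_dkl(rx, list(type = "morgan"), cfg)
  emb <- dkl_embeddings(st, rx)
  expect_equal(dim(emb), c(length(rx), 4L))
  cs <- cluster_summary(emb, reaction_yields(rx), k = 2, reactions = rx)
  expect_equal(sum(cs$summary$size), length(rx))
  expect_length(cs$composition, 2)

  path <- withr::local_tempfile(fileext = ".rds")
  save_dkl(st, path)
  st2 <- load_dkl(path)
  p1 <- dkl_predict(st, rx[1:5])
  p2 <- dkl_predict(st2, rx[1:5])
  expect_identical(p1, p2)
})
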