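# Shared fixtures, generated in code. Small grids keep the suite fast.

tiny_grid <- function(seed = 7L, noise_sd = 2, interaction = 0) {
  synth_reaction_grid(grid_spec(
    counts = c(aryl_halide = 3, ligand = 2, base = 2, additive = 3),
    interaction_strength = interaction, noise_sd = noise_sd, seed = seed))
}

# dense-formula GP oracle: direct inverse and explicit determinant
oracle_gp <- function(X, y, Xs, params) {
  K <- matern52_gram(X, X, params) + diag(params$noise, nrow(X))
  Ki <- solve(K)
  lml <- -0.5 * drop(t(y) %*% Ki %*% y) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    nrow(X) / 2 * log(2 * pi)
  Ks <- matern52_gram(Xs, X, params)
  Kss <- matern52_gram(Xs, Xs, params)
  list(lml = lml,
       mean = drop(Ks %*% Ki %*% y),
       var = diag(Kss - Ks %*% Ki %*% t(Ks)) + params$noise)
}

random_gp_instance <- function(seed, n_max = 20L, d_max = 8L) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  d <- sample(2:d_max, 1)
  list(X = matrix(rnorm(n * d), n),
       y = rnorm(n),
       Xs = matrix(rnorm(5 * d), 5),
       params = kernel_params(lengthscale = runif(1, 0.5, 3),
                              outputscale = runif(1, 0.3, 2),
                              noise = runif(1, 0.05, 0.5)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
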