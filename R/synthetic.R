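# Synthetic HTE-style reaction grids with known yield structure, so the
# whole pipeline (featurization -> deep kernel -> evaluation -> BO) is
# testable without any external dataset.

# Toy SMILES vocabularies: simple substituted aromatics and amines chosen to
# parse under any standard SMILES reader. Sized to cover the reference
# 15 x 4 x 3 x 23 grid.
.toy_vocab <- list(
  aryl_halide = c(
    "Clc1ccccc1", "Brc1ccccc1", "Ic1ccccc1",
    "Clc1ccncc1", "Brc1ccncc1", "Ic1ccncc1",
    "Clc1cccnc1", "Brc1cccnc1", "Ic1cccnc1",
    "Cc1ccccc1Cl", "Cc1ccccc1Br", "Cc1ccccc1I",
    "Clc1ccc(C)cc1", "Brc1ccc(C)cc1", "Ic1ccc(C)cc1"
  ),
  ligand = c(
    "CP(C)C", "CCP(CC)CC", "CC(C)P(C(C)C)C(C)C",
    "c1ccc(P(c2ccccc2)c2ccccc2)cc1"
  ),
  base = c(
    "CCN(CC)CC", "C1CCC2=NCCCN2CC1", "C1CCNCC1"
  ),
  additive = c(
    "Oc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "CNc1ccccc1", "Cc1ccccc1",
    "CCc1ccccc1", "Fc1ccccc1", "N#Cc1ccccc1", "O=Cc1ccccc1",
    "CC(=O)c1ccccc1", "COC(=O)c1ccccc1", "OCc1ccccc1", "NCc1ccccc1",
    "C=Cc1ccccc1",
    "c1ccoc1", "Cc1ccoc1", "CCc1ccoc1",
    "c1ccsc1", "Cc1ccsc1", "CCc1ccsc1",
    "c1ccncc1", "Cc1ccncc1", "COc1ccncc1"
  )
)

#' Specification of a synthetic reaction grid
#'
#' Yields follow a main-effects-plus-interactions model:
#' \code{clip(base + sum(role main effects) + sum(pairwise interactions)
#' + N(0, noise_sd), 0, 100)}. By default interactions are sampled only for
#' aryl halide x additive pairs, echoing additive poisoning of specific
#' substrates.
#'
#' @param counts named per-role component counts; default
#'   \code{c(aryl_halide = 15, ligand = 4, base = 3, additive = 23)}, the
#'   reference grid shape.
#' @param main_effect_range main effects are drawn uniformly from this range.
#' @param interaction_strength interactions drawn uniform on
#'   \code{[-strength, strength]}; 0 disables them.
#' @param interaction_pairs list of role pairs that interact.
#' @param noise_sd Gaussian noise standard deviation (yield points).
#' @param base_yield grid-level intercept.
#' @param subsample fraction of grid rows kept (seeded), emulating
#'   incomplete plates.
#' @param seed RNG seed; generation is fully deterministic per seed.
#' @param vocab per-role SMILES vocabularies (defaults packaged).
#' @return list of class \code{grid_spec}.
#' @export
grid_spec <- function(counts = c(aryl_halide = 15, ligand = 4, base = 3,
                                 additive = 23),
                      main_effect_range = c(-10, 10),
                      interaction_strength = 20,
                      interaction_pairs = list(c("aryl_halide", "additive")),
                      noise_sd = 5, base_yield = 50, subsample = 1,
                      seed = 1L, vocab = .toy_vocab) {
  stopifnot(all(counts >= 1), noise_sd >= 0, subsample > 0, subsample <= 1)
  for (role in names(counts))
    if (length(vocab[[role]]) < counts[[role]])
      stop("vocabulary for role '", role, "' has ", length(vocab[[role]]),
           " entries, fewer than requested ", counts[[role]], call. = FALSE)
  structure(list(counts = counts, main_effect_range = main_effect_range,
                 interaction_strength = interaction_strength,
                 interaction_pairs = interaction_pairs, noise_sd = noise_sd,
                 base_yield = base_yield, subsample = subsample,
                 seed = as.integer(seed), vocab = vocab),
            class = "grid_spec")
}

#' Generate a synthetic reaction grid
#'
#' @param spec a \code{grid_spec}.
#' @return list of \code{reaction} objects covering the (optionally
#'   subsampled) Cartesian grid; yields in [0, 100].
#' @export
synth_reaction_grid <- function(spec = grid_spec()) {
  roles <- names(spec$counts)
  set.seed(spec$seed)
  comp <- lapply(roles, function(role)
    spec$vocab[[role]][seq_len(spec$counts[[role]])])
  names(comp) <- roles
  effects <- lapply(roles, function(role)
    stats::runif(spec$counts[[role]], spec$main_effect_range[1],
                 spec$main_effect_range[2]))
  names(effects) <- roles

  idx <- expand.grid(lapply(spec$counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(idx) <- roles
  n <- nrow(idx)

  yield <- rep(spec$base_yield, n)
  for (role in roles) yield <- yield + effects[[role]][idx[[role]]]
  for (pair in spec$interaction_pairs) {
    if (spec$interaction_strength == 0) next
    r1 <- pair[1]; r2 <- pair[2]
    inter <- matrix(stats::runif(spec$counts[[r1]] * spec$counts[[r2]],
                                 -spec$interaction_strength,
                                 spec$interaction_strength),
                    spec$counts[[r1]], spec$counts[[r2]])
    yield <- yield + inter[cbind(idx[[r1]], idx[[r2]])]
  }
  if (spec$noise_sd > 0) yield <- yield + stats::rnorm(n, 0, spec$noise_sd)
  yield <- pmin(pmax(yield, 0), 100)

  keep <- seq_len(n)
  if (spec$subsample < 1)
    keep <- sort(sample.int(n, max(1L, floor(n * spec$subsample))))

  lapply(keep, function(i) {
    comps <- vapply(roles, function(role) comp[[role]][idx[[role]][i]],
                    character(1))
    reaction(comps, yield = yield[i], id = paste0("rx", i), validate = FALSE)
  })
}

#' Draw correlated targets from a GP prior
#'
#' One sample from \code{N(0, K + noise I)} with \code{K} the Matern-5/2
#' Gram matrix of the supplied features. Used for oracle-equivalence and
#' parameter-recovery simulations.
#'
#' @param features input matrix.
#' @param params a \code{kernel_params}.
#' @param seed RNG seed.
#' @return numeric vector of length \code{nrow(features)}.
#' @export
gp_draw_dataset <- function(features, params = kernel_params(), seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  K <- matern52_gram(features, features, params)
  if (params$outputscale == 0 && params$noise == 0) return(numeric(n))
  cf <- .chol_jitter(K, params$noise)
  set.seed(seed)
  as.numeric(t(cf$L) %*% stats::rnorm(n))
}
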