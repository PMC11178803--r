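# dklgp

Deep kernel learning Gaussian processes for chemical reaction-yield
prediction and Bayesian reaction optimization, in pure R.

## Who this is for

High-throughput experimentation (HTE) screens combinatorial grids of
reaction conditions — aryl halide x ligand x base x additive in the
canonical C–N coupling layout — and records a yield in [0, 100] per
combination. Chemists and cheminformaticians working with such tables need
two things a plain regression does not give: **calibrated uncertainty** on
every predicted yield, and a principled way to pick the **next experiment**
when the budget is small. `dklgp` provides both with exact Gaussian
processes whose covariance is learned by a neural network.

## The model

A GP prior `y(·) ~ GP(0, k(·,·))` with a Matérn-5/2 base kernel (no ARD),

```
k(x, x') = s² (1 + √5 r/ℓ + 5r²/(3ℓ²)) exp(−√5 r/ℓ),   r = ‖x − x'‖,
```

is either applied directly to reaction features (fingerprints,
descriptors) or composed with a neural feature extractor `g_φ`:

```
k_DKL(x, x') = k(g_φ(x), g_φ(x') | θ).
```

All parameters `{θ, φ, σ²}` are trained jointly by maximizing the exact
log marginal likelihood

```
log p(y|X) = −½ yᵀ(K + σ²I)⁻¹y − ½ log|K + σ²I| − (n/2) log 2π
```

with full-batch Adam (defaults: 400 epochs, learning rate 0.001, dropout
0.1 on the fully connected layers). Predictions use the standard GP
posterior mean and variance, de-standardized to yield units. Extractors:
a two-layer feed-forward network for vector inputs, and a message-passing
network (edge-conditioned messages, GRU updates, set2set readout, summed
role embeddings) for molecular graphs. Candidate selection uses expected
improvement, `EI(x) = σ(x)(zΦ(z) + φ(z))`, `z = (μ(x) − f⁺)/σ(x)`, over a
discrete held-out pool.

Featurization from SMILES: concatenated per-component Morgan fingerprints
(radius 2, 512 bits each, 2048 per reaction), a differential reaction
fingerprint (hashed symmetric difference of circular substructures, 2048
bits), descriptor-table concatenation, and annotated molecular graphs.
See `vignettes/deep-kernel-yields.Rmd` for the full account of the model,
defaults and limitations.

## Worked example

```r
library(dklgp)

# synthetic HTE grid: 4 x 3 x 2 x 4 components, additive-poisoning
# interactions (±20), noise sd 5
spec <- grid_spec(counts = c(aryl_halide = 4, ligand = 3, base = 2, additive = 4),
                  interaction_strength = 20, noise_sd = 5, seed = 42)
reactions <- synth_reaction_grid(spec)         # 96 reactions
split <- make_splits(reactions, c(0.7, 0.1, 0.2), seed = 1)

features <- featurize_reactions(reactions, list(type = "morgan"))  # 96 x 2048
model <- train_dkl(reactions[split$train],
                   config = dkl_config(epochs = 100, seed = 1),
                   features = features[split$train, ],
                   val_reactions = reactions[split$val],
                   val_features = features[split$val, ])
pred <- dkl_predict(model, reactions[split$test],
                    features = features[split$test, ])
regression_metrics(pred, reaction_yields(reactions[split$test]))
#>    rmse   mae   r2  nlpd spearman_rho
#> 1 8.141 7.038 0.75 3.544       -0.081
```

The model explains 75% of the held-out yield variance on this small grid
(RMSE 8.1 yield points against noise sd 5), and each prediction comes with
a standard deviation in yield units:

```r
data.frame(predicted = round(pred$mean[1:3], 1),
           sd        = round(sqrt(pred$variance[1:3]), 1),
           observed  = round(reaction_yields(reactions[split$test])[1:3], 1))
#>   predicted  sd observed
#> 1      64.4 9.5     65.4
#> 2      77.1 9.8     80.2
#> 3      53.7 9.7     41.6
```

The NLPD (3.54 here) is the mean negative Gaussian log density of the
held-out yields under the predictive distribution — lower is better, and
it punishes over- and under-confidence alike. The Spearman column
correlates |error| with predicted sd; on 20 test points it is noisy by
nature.

For sequential optimization over a candidate pool:

```r
pool <- candidate_pool(reactions)
trial <- run_bo(pool, policy = "ei", surrogate = "gp", seed = 1)
tail(trial$trace, 3)   # candidate picked, revealed yield, incumbent best
```

A command-line wrapper covering the synth / evaluate / bo pipeline ships
in `inst/cli/dklgp.R` (`Rscript <path> --help`).

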