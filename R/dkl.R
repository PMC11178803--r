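# Deep kernel learning: k_DKL(x, x') = k_Matern52(g(x), g(x') | theta).
# All extractor weights, kernel hyperparameters and the noise variance are
# one parameter group, trained jointly by full-batch gradient ascent on the
# exact GP log marginal likelihood. The gradient with respect to the
# embedding matrix is computed in closed form and back-propagated through
# the extractor tape.

#' Featurize reactions according to a featurizer specification
#'
#' @param reactions list of \code{reaction} objects.
#' @param spec list with \code{type} in \code{"morgan"} (options \code{mode},
#'   \code{radius}, \code{bits}), \code{"descriptor"} (option \code{tables}),
#'   or \code{"graph"} (option \code{config}).
#' @return a \code{feature_matrix}, or a list of per-reaction graph lists for
#'   \code{type = "graph"}.
#' @export
featurize_reactions <- function(reactions, spec = list(type = "morgan")) {
  switch(spec$type,
    morgan = morgan_reaction_fp(
      reactions,
      radius = spec$radius %||% 2L,
      bits_per_component = spec$bits %||% 512L,
      mode = spec$mode %||% "concat"),
    descriptor = descriptor_concat(reactions, spec$tables),
    graph = reactions_to_graphs(reactions, spec$config %||% graph_config()),
    stop("unknown featurizer type: ", spec$type, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deep kernel training configuration
#'
#' Defaults follow the reference training protocol: 400 epochs of full-batch
#' Adam at learning rate 0.001, dropout 0.1 on the fully connected layers,
#' embedding width 64.
#'
#' @param extractor \code{"ffnn"}, \code{"mpnn"}, or \code{"identity"}
#'   (no network; the deep kernel degenerates to a plain GP trained by Adam).
#' @param epochs training epochs (default 400).
#' @param lr Adam learning rate (default 0.001).
#' @param seed RNG seed for initialization and dropout.
#' @param hidden,d_emb,dropout feed-forward settings.
#' @param h,T_mp,M_s2s message-passing settings (graph extractor only).
#' @param init kernel initialization, a \code{kernel_params}, or
#'   \code{"median"} (default): lengthscale set to the median pairwise
#'   distance of the initial embeddings, outputscale 1, noise 0.5 on the
#'   standardized targets. Because all parameters share the single small
#'   learning rate, the kernel initialization doubles as a weak prior.
#' @param center subtract training-set column means from vector inputs
#'   before the extractor (default TRUE; ignored for graphs).
#' @param eval_every with a validation set: evaluate validation RMSE in
#'   evaluation mode every this many epochs and keep the best snapshot
#'   (default 10).
#' @return list of class \code{dkl_config}.
#' @export
dkl_config <- function(extractor = c("ffnn", "mpnn", "identity"),
                       epochs = 400L, lr = 0.001, seed = 1L,
                       hidden = 256L, d_emb = 64L, dropout = 0.1,
                       h = 64L, T_mp = 3L, M_s2s = 3L,
                       init = "median", center = TRUE, eval_every = 10L) {
  structure(list(extractor = match.arg(extractor), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed), hidden = as.integer(hidden),
                 d_emb = as.integer(d_emb), dropout = dropout,
                 h = as.integer(h), T_mp = as.integer(T_mp),
                 M_s2s = as.integer(M_s2s), init = init, center = center,
                 eval_every = as.integer(eval_every)),
            class = "dkl_config")
}

.forward_embeddings <- function(inputs, params, arch, config, mode) {
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_input(tape, p))
  node <- switch(config$extractor,
    identity = ad_input(tape, inputs),
    ffnn = ffnn_forward(tape, pn, ad_input(tape, inputs), arch, mode),
    mpnn = mpnn_forward(tape, pn, inputs, arch, mode))
  list(tape = tape, node = node, pnodes = pn)
}

#' Train a deep kernel model
#'
#' @param reactions list of \code{reaction} objects with observed yields
#'   (>= 10 reactions).
#' @param featurizer featurizer specification (see
#'   \code{\link{featurize_reactions}}); use \code{type = "graph"} with
#'   \code{extractor = "mpnn"}.
#' @param config a \code{dkl_config}.
#' @param features optional precomputed output of
#'   \code{featurize_reactions(reactions, featurizer)} to avoid re-featurizing.
#' @param val_reactions optional validation reactions; when given, the
#'   snapshot with the best validation RMSE (checked every
#'   \code{config$eval_every} epochs, extractor in evaluation mode) is
#'   returned instead of the final epoch.
#' @param val_features optional precomputed validation featurization.
#' @return a \code{dkl_state}: extractor parameters, kernel hyperparameters,
#'   standardization constants, cached training embeddings and the LML trace.
#' @export
train_dkl <- function(reactions, featurizer = list(type = "morgan"),
                      config = dkl_config(), features = NULL,
                      val_reactions = NULL, val_features = NULL) {
  if (length(reactions) < 10)
    stop("need at least 10 training reactions", call. = FALSE)
  y_raw <- reaction_yields(reactions)
  std <- standardizer(y_raw)
  y <- std$transform(y_raw)

  inputs <- if (is.null(features)) featurize_reactions(reactions, featurizer)
            else features
  center <- NULL
  if (config$extractor == "mpnn") {
    if (!is.list(inputs) || is.matrix(inputs))
      stop("mpnn extractor needs graph featurization", call. = FALSE)
    inputs <- batch_graphs(inputs)
    arch <- mpnn_config(d_atom = ncol(inputs$X), h = config$h,
                        T_mp = config$T_mp, M_s2s = config$M_s2s,
                        hidden = config$hidden, d_emb = config$d_emb,
                        dropout = config$dropout)
    params <- mpnn_init(arch, seed = config$seed)
  } else {
    inputs <- unclass(as.matrix(inputs))
    if (isTRUE(config$center)) {
      center <- colMeans(inputs)
      inputs <- sweep(inputs, 2, center)
    }
    if (config$extractor == "ffnn") {
      arch <- ffnn_config(ncol(inputs), config$hidden, config$d_emb,
                          config$dropout)
      params <- ffnn_init(arch, seed = config$seed)
    } else {
      arch <- NULL
      params <- list()
    }
  }

  init <- config$init
  if (identical(init, "median")) {
    fw0 <- .forward_embeddings(inputs, params, arch, config, "eval")
    Z0 <- fw0$node$value
    set.seed(config$seed)
    i1 <- sample.int(nrow(Z0), min(nrow(Z0), 128L))
    i2 <- sample.int(nrow(Z0), min(nrow(Z0), 128L))
    med <- stats::median(.pdist(Z0[i1, , drop = FALSE], Z0[i2, , drop = FALSE]))
    init <- kernel_params(max(med, 1e-3), 1, 0.5)
  }
  raw <- softplus_inv(c(init$lengthscale, max(init$outputscale, 1e-6),
                        max(init$noise, 1e-6)))
  st <- adam_init(c(params, list(.kern = matrix(raw, 1))))
  all_par <- c(params, list(.kern = matrix(raw, 1)))
  trace <- numeric(config$epochs)

  # validation tracking
  val_in <- NULL
  if (!is.null(val_reactions)) {
    val_in <- if (is.null(val_features))
      featurize_reactions(val_reactions, featurizer) else val_features
    if (config$extractor == "mpnn") {
      val_in <- batch_graphs(val_in)
    } else {
      val_in <- unclass(as.matrix(val_in))
      if (!is.null(center)) val_in <- sweep(val_in, 2, center)
    }
    val_y <- reaction_yields(val_reactions)
  }
  best <- list(rmse = Inf, par = all_par)

  score_val <- function(all_par) {
    params <- all_par[setdiff(names(all_par), ".kern")]
    raw <- drop(all_par$.kern)
    kp <- kernel_params(softplus(raw[1]), softplus(raw[2]), softplus(raw[3]))
    Ztr <- .forward_embeddings(inputs, params, arch, config, "eval")$node$value
    Zva <- .forward_embeddings(val_in, params, arch, config, "eval")$node$value
    gp <- gp_state(Ztr, y, kp)
    mu <- std$inverse(posterior_predict(gp, Zva)$mean)
    sqrt(mean((mu - val_y)^2))
  }

  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    params <- all_par[setdiff(names(all_par), ".kern")]
    raw <- drop(all_par$.kern)
    fw <- .forward_embeddings(inputs, params, arch, config,
                              mode = if (config$extractor == "identity")
                                       "eval" else "train")
    Z <- fw$node$value
    lg <- .lml_grad(Z, y, raw, want_dZ = TRUE)
    if (!is.finite(lg$lml))
      stop("non-finite marginal likelihood at epoch ", ep, call. = FALSE)
    trace[ep] <- lg$lml
    grads <- list(.kern = matrix(-lg$grad, 1))
    if (config$extractor != "identity") {
      ad_backward(fw$tape, fw$node, -lg$dZ)   # minimize -LML
      for (k in names(params)) grads[[k]] <- fw$pnodes[[k]]$grad
    }
    upd <- adam_step(all_par, grads, st, lr = config$lr)
    all_par <- upd$params
    st <- upd$state
    if (!is.null(val_in) &&
        (ep %% config$eval_every == 0L || ep == config$epochs)) {
      vr <- score_val(all_par)
      if (vr < best$rmse) best <- list(rmse = vr, par = all_par)
    }
  }
  if (!is.null(val_in) && is.finite(best$rmse)) all_par <- best$par

  params <- all_par[setdiff(names(all_par), ".kern")]
  raw <- drop(all_par$.kern)
  fw <- .forward_embeddings(inputs, params, arch, config, mode = "eval")
  kp <- kernel_params(softplus(raw[1]), softplus(raw[2]), softplus(raw[3]))
  gp <- gp_state(fw$node$value, y, kp)

  structure(list(params = params, arch = arch, config = config,
                 featurizer = featurizer, kernel = kp, gp = gp,
                 standardizer = std, center = center, lml_trace = trace,
                 val_rmse = if (is.null(val_in)) NA_real_ else best$rmse,
                 version = "dklgp-1"),
            class = "dkl_state")
}

#' Predict yields with a trained deep kernel model
#'
#' The extractor runs in evaluation mode (no dropout); posterior mean and
#' variance are de-standardized to yield units.
#'
#' @param state a \code{dkl_state}.
#' @param reactions list of \code{reaction} objects to predict.
#' @param features optional precomputed featurization matching the training
#'   featurizer spec.
#' @return a \code{predictive_distribution} on the original yield scale.
#' @export
dkl_predict <- function(state, reactions, features = NULL) {
  inputs <- if (is.null(features))
    featurize_reactions(reactions, state$featurizer) else features
  config <- state$config
  if (config$extractor == "mpnn") {
    inputs <- batch_graphs(inputs)
  } else {
    inputs <- unclass(as.matrix(inputs))
    if (!is.null(state$arch) && ncol(inputs) != state$arch$d_in)
      stop("featurizer mismatch: query width ", ncol(inputs),
           " != trained width ", state$arch$d_in, call. = FALSE)
    if (!is.null(state$center)) inputs <- sweep(inputs, 2, state$center)
  }
  fw <- .forward_embeddings(inputs, state$params, state$arch, config, "eval")
  pred <- posterior_predict(state$gp, fw$node$value)
  predictive_distribution(
    state$standardizer$inverse(pred$mean),
    pred$variance * state$standardizer$sd^2,
    "original")
}

#' Extract learned reaction embeddings from a trained model
#'
#' Runs the extractor in evaluation mode and returns the embedding matrix
#' that feeds the base kernel; the input to cluster analyses of the learned
#' feature space (see \code{\link{cluster_summary}}).
#'
#' @param state a \code{dkl_state}.
#' @param reactions list of \code{reaction} objects.
#' @param features optional precomputed featurization.
#' @return numeric matrix, one row per reaction.
#' @export
dkl_embeddings <- function(state, reactions, features = NULL) {
  inputs <- if (is.null(features))
    featurize_reactions(reactions, state$featurizer) else features
  if (state$config$extractor == "mpnn") {
    inputs <- batch_graphs(inputs)
  } else {
    inputs <- unclass(as.matrix(inputs))
    if (!is.null(state$center)) inputs <- sweep(inputs, 2, state$center)
  }
  .forward_embeddings(inputs, state$params, state$arch, state$config,
                      "eval")$node$value
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint holds the architecture specification, all parameters, the
#' kernel hyperparameters, standardizer constants, featurizer tag and a
#' format version.
#'
#' @param state a \code{dkl_state}.
#' @param path checkpoint file path.
#' @return \code{save_dkl}: the path, invisibly. \code{load_dkl}: the
#'   restored \code{dkl_state}.
#' @export
save_dkl <- function(state, path) {
  stopifnot(inherits(state, "dkl_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_dkl
#' @export
load_dkl <- function(path) {
  state <- readRDS(path)
  if (!identical(state$version, "dklgp-1"))
    stop("unsupported checkpoint version: ", state$version, call. = FALSE)
  state
}

#' Train the stand-alone GNN regression baseline
#'
#' Uses a message-passing trunk architecturally identical to the graph
#' branch of the deep kernel, followed by a linear regression head, trained
#' with squared error. Point predictions only; no predictive variance.
#'
#' @param reactions list of \code{reaction} objects with observed yields.
#' @param config a \code{dkl_config} (extractor forced to \code{"mpnn"}).
#' @param graphs optional precomputed graph featurization.
#' @return a \code{gnn_model} with \code{predict} via
#'   \code{\link{gnn_predict}}.
#' @export
gnn_baseline <- function(reactions, config = dkl_config(extractor = "mpnn"),
                         graphs = NULL) {
  config$extractor <- "mpnn"
  y_raw <- reaction_yields(reactions)
  std <- standardizer(y_raw)
  y <- std$transform(y_raw)
  gl <- if (is.null(graphs)) reactions_to_graphs(reactions) else graphs
  batch <- batch_graphs(gl)
  arch <- mpnn_config(d_atom = ncol(batch$X), h = config$h,
                      T_mp = config$T_mp, M_s2s = config$M_s2s,
                      hidden = config$hidden, d_emb = config$d_emb,
                      dropout = config$dropout)
  params <- mpnn_init(arch, seed = config$seed)
  set.seed(config$seed)
  params$out_W <- .rmat(config$d_emb, 1, sqrt(1 / config$d_emb))
  params$out_b <- matrix(0, 1, 1)
  st <- adam_init(params)
  loss_trace <- numeric(config$epochs)

  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    tape <- ad_tape()
    pn <- lapply(params, function(p) ad_input(tape, p))
    emb <- mpnn_forward(tape, pn, batch, arch, "train")
    pred <- ad_add(tape, ad_matmul(tape, emb, pn$out_W), pn$out_b)
    resid <- pred$value[, 1] - y
    loss_trace[ep] <- mean(resid^2)
    if (!is.finite(loss_trace[ep]))
      stop("non-finite loss at epoch ", ep, call. = FALSE)
    ad_backward(tape, pred, matrix(2 * resid / length(y), ncol = 1))
    grads <- lapply(pn, function(n) n$grad)
    upd <- adam_step(params, grads, st, lr = config$lr)
    params <- upd$params
    st <- upd$state
  }
  structure(list(params = params, arch = arch, config = config,
                 standardizer = std, loss_trace = loss_trace),
            class = "gnn_model")
}

#' Predict with the GNN baseline
#' @param model a \code{gnn_model}.
#' @param reactions list of \code{reaction} objects.
#' @param graphs optional precomputed graphs.
#' @return numeric vector of point predictions in yield units (no variance).
#' @export
gnn_predict <- function(model, reactions, graphs = NULL) {
  gl <- if (is.null(graphs)) reactions_to_graphs(reactions) else graphs
  batch <- batch_graphs(gl)
  tape <- ad_tape()
  pn <- lapply(model$params, function(p) ad_input(tape, p))
  emb <- mpnn_forward(tape, pn, batch, model$arch, "eval")
  pred <- ad_add(tape, ad_matmul(tape, emb, pn$out_W), pn$out_b)
  model$standardizer$inverse(pred$value[, 1])
}
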