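# Neural feature extractors for the deep kernel:
#  * a two-layer feed-forward network for vector inputs (fingerprints,
#    descriptors), dropout 0.1 on both fully connected layers in training;
#  * a message-passing network for molecular graphs: edge-conditioned linear
#    messages, sum aggregation, GRU state updates, set2set readout, sum over
#    the per-role graph vectors, then the same feed-forward head.
#
# Both run on the autodiff tape; evaluation mode disables dropout and is
# fully deterministic.

.rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Feed-forward extractor configuration
#' @param d_in input width.
#' @param hidden hidden layer width (default 256).
#' @param d_emb embedding width fed to the base kernel (default 64).
#' @param dropout dropout rate on the two fully connected layers (default 0.1).
#' @return list of class \code{ffnn_config}.
#' @export
ffnn_config <- function(d_in, hidden = 256L, d_emb = 64L, dropout = 0.1) {
  structure(list(d_in = as.integer(d_in), hidden = as.integer(hidden),
                 d_emb = as.integer(d_emb), dropout = dropout),
            class = "ffnn_config")
}

ffnn_init <- function(config, seed = 1L) {
  set.seed(seed)
  with(config, list(
    W1 = .rmat(d_in, hidden, sqrt(2 / d_in)), b1 = matrix(0, 1, hidden),
    W2 = .rmat(hidden, d_emb, sqrt(2 / hidden)), b2 = matrix(0, 1, d_emb)
  ))
}

# batched tape forward; params_nodes is a named list of tape nodes
ffnn_forward <- function(tape, params_nodes, Xnode, config,
                         mode = c("eval", "train")) {
  mode <- match.arg(mode)
  h <- ad_relu(tape, ad_add(tape, ad_matmul(tape, Xnode, params_nodes$W1),
                            params_nodes$b1))
  if (mode == "train" && config$dropout > 0) {
    m1 <- matrix(stats::rbinom(length(h$value), 1, 1 - config$dropout),
                 nrow(h$value))
    h <- ad_dropout(tape, h, m1, config$dropout)
  }
  z <- ad_add(tape, ad_matmul(tape, h, params_nodes$W2), params_nodes$b2)
  if (mode == "train" && config$dropout > 0) {
    m2 <- matrix(stats::rbinom(length(z$value), 1, 1 - config$dropout),
                 nrow(z$value))
    z <- ad_dropout(tape, z, m2, config$dropout)
  }
  z
}

#' Apply the feed-forward extractor to feature vectors
#'
#' @param x a feature vector or matrix (rows = reactions).
#' @param params weights as produced by the trainers (named list).
#' @param config an \code{ffnn_config}.
#' @param mode \code{"eval"} (deterministic) or \code{"train"} (dropout on).
#' @return embedding matrix, one row per input row.
#' @export
ffnn_extract <- function(x, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (ncol(x) != config$d_in)
    stop("input width ", ncol(x), " != configured d_in ", config$d_in,
         call. = FALSE)
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_input(tape, p))
  ffnn_forward(tape, pn, ad_input(tape, x), config, mode)$value
}

#' Message-passing extractor configuration
#' @param d_atom node feature width.
#' @param d_edge edge feature width.
#' @param h node state width (default 64).
#' @param T_mp message-passing rounds (default 3).
#' @param M_s2s set2set processing steps (default 3).
#' @param hidden,d_emb,dropout feed-forward head (input 2h) settings.
#' @return list of class \code{mpnn_config}.
#' @export
mpnn_config <- function(d_atom, d_edge = edge_feature_width(), h = 64L,
                        T_mp = 3L, M_s2s = 3L, hidden = 256L, d_emb = 64L,
                        dropout = 0.1) {
  structure(list(d_atom = as.integer(d_atom), d_edge = as.integer(d_edge),
                 h = as.integer(h), T_mp = as.integer(T_mp),
                 M_s2s = as.integer(M_s2s), hidden = as.integer(hidden),
                 d_emb = as.integer(d_emb), dropout = dropout),
            class = "mpnn_config")
}

mpnn_init <- function(config, seed = 1L) {
  set.seed(seed)
  h <- config$h
  p <- list(
    Win = .rmat(config$d_atom, h, sqrt(2 / config$d_atom)),
    We  = .rmat(config$d_edge, h * h, sqrt(1 / (config$d_edge * h))),
    # GRU
    Wz = .rmat(h, h, sqrt(1 / h)), Uz = .rmat(h, h, sqrt(1 / h)),
    bz = matrix(0, 1, h),
    Wr = .rmat(h, h, sqrt(1 / h)), Ur = .rmat(h, h, sqrt(1 / h)),
    br = matrix(0, 1, h),
    Wh = .rmat(h, h, sqrt(1 / h)), Uh = .rmat(h, h, sqrt(1 / h)),
    bh = matrix(0, 1, h),
    # set2set LSTM: input 2h, hidden h
    Li = .rmat(3 * h, 4 * h, sqrt(1 / (3 * h))), Lb = matrix(0, 1, 4 * h)
  )
  head <- ffnn_init(ffnn_config(2 * h, config$hidden, config$d_emb,
                                config$dropout), seed = seed + 1L)
  names(head) <- paste0("head_", names(head))
  c(p, head)
}

# Pack a list-of-reactions-of-graphs into flat arrays for batched forward.
# Unordered edges are expanded to two directed arcs here.
batch_graphs <- function(graph_lists) {
  X <- list(); src <- integer(0); dst <- integer(0); eattr <- list()
  gid_nodes <- integer(0); rid_graphs <- integer(0)
  offset <- 0L; g_count <- 0L
  for (ri in seq_along(graph_lists)) {
    for (g in graph_lists[[ri]]) {
      if (g$n_atoms < 1) stop("empty graph in batch", call. = FALSE)
      g_count <- g_count + 1L
      X[[g_count]] <- g$x
      gid_nodes <- c(gid_nodes, rep(g_count, g$n_atoms))
      rid_graphs <- c(rid_graphs, ri)
      if (nrow(g$edges)) {
        src <- c(src, offset + g$edges[, 1], offset + g$edges[, 2])
        dst <- c(dst, offset + g$edges[, 2], offset + g$edges[, 1])
        eattr[[length(eattr) + 1L]] <- rbind(g$edge_attr, g$edge_attr)
      }
      offset <- offset + g$n_atoms
    }
  }
  list(X = do.call(rbind, X), src = src, dst = dst,
       eattr = if (length(eattr)) do.call(rbind, eattr)
               else matrix(0, 0, edge_feature_width()),
       gid_nodes = gid_nodes, rid_graphs = rid_graphs,
       n_graphs = g_count, n_reactions = length(graph_lists))
}

# edge-conditioned message: for arc k, m_k = A(e_k) %*% h_src(k), with
# A(e) = reshape(e %*% We, h x h), column layout grouped by source dimension
.edge_messages <- function(tape, Hnode, Mflat, src, h) {
  Hsrc <- ad_index_rows(tape, Hnode, src)
  acc <- NULL
  for (l in seq_len(h)) {
    block <- ad_slice_cols(tape, Mflat, ((l - 1L) * h + 1L):(l * h))
    contrib <- ad_mul(tape, block, ad_slice_cols(tape, Hsrc, l))
    acc <- if (is.null(acc)) contrib else ad_add(tape, acc, contrib)
  }
  acc
}

.gru_update <- function(tape, pn, Hn, Mn) {
  z <- ad_sigmoid(tape, ad_add(tape, ad_add(tape,
         ad_matmul(tape, Mn, pn$Wz), ad_matmul(tape, Hn, pn$Uz)), pn$bz))
  r <- ad_sigmoid(tape, ad_add(tape, ad_add(tape,
         ad_matmul(tape, Mn, pn$Wr), ad_matmul(tape, Hn, pn$Ur)), pn$br))
  ht <- ad_tanh(tape, ad_add(tape, ad_add(tape,
         ad_matmul(tape, Mn, pn$Wh),
         ad_matmul(tape, ad_mul(tape, r, Hn), pn$Uh)), pn$bh))
  ad_add(tape, ad_mul(tape, ad_affine(tape, z, -1, 1), Hn),
         ad_mul(tape, z, ht))
}

.lstm_cell <- function(tape, pn, xn, hn, cn, h) {
  zs <- ad_add(tape, ad_matmul(tape, ad_concat_cols(tape, xn, hn), pn$Li),
               pn$Lb)
  i <- ad_sigmoid(tape, ad_slice_cols(tape, zs, 1:h))
  f <- ad_sigmoid(tape, ad_slice_cols(tape, zs, (h + 1):(2 * h)))
  o <- ad_sigmoid(tape, ad_slice_cols(tape, zs, (2 * h + 1):(3 * h)))
  g <- ad_tanh(tape, ad_slice_cols(tape, zs, (3 * h + 1):(4 * h)))
  cn2 <- ad_add(tape, ad_mul(tape, f, cn), ad_mul(tape, i, g))
  hn2 <- ad_mul(tape, o, ad_tanh(tape, cn2))
  list(h = hn2, c = cn2)
}

# set2set readout: M processing steps of attention driven by an LSTM query;
# returns [q, r] of width 2h per graph, invariant to node order
.set2set <- function(tape, pn, Hnode, gid, n_graphs, config) {
  h <- config$h
  qstar <- ad_input(tape, matrix(0, n_graphs, 2 * h))
  q <- ad_input(tape, matrix(0, n_graphs, h))
  cc <- ad_input(tape, matrix(0, n_graphs, h))
  ones <- ad_input(tape, matrix(1, h, 1))
  for (m in seq_len(config$M_s2s)) {
    st <- .lstm_cell(tape, pn, qstar, q, cc, h)
    q <- st$h; cc <- st$c
    e <- ad_matmul(tape, ad_mul(tape, Hnode, ad_index_rows(tape, q, gid)),
                   ones)
    a <- ad_segment_softmax(tape, e, gid, n_graphs)
    r <- ad_segment_sum(tape, ad_mul(tape, Hnode, a), gid, n_graphs)
    qstar <- ad_concat_cols(tape, q, r)
  }
  qstar
}

# full batched forward: graphs -> reaction embeddings (tape node)
mpnn_forward <- function(tape, params_nodes, batch, config,
                         mode = c("eval", "train")) {
  mode <- match.arg(mode)
  pn <- params_nodes
  Hn <- ad_matmul(tape, ad_input(tape, batch$X), pn$Win)
  if (length(batch$src)) {
    Mflat <- ad_matmul(tape, ad_input(tape, batch$eattr), pn$We)
    for (t in seq_len(config$T_mp)) {
      msg_arc <- .edge_messages(tape, Hn, Mflat, batch$src, config$h)
      msg <- ad_segment_sum(tape, msg_arc, batch$dst, nrow(batch$X))
      Hn <- .gru_update(tape, pn, Hn, msg)
    }
  }
  qstar <- .set2set(tape, pn, Hn, batch$gid_nodes, batch$n_graphs, config)
  rxn <- ad_segment_sum(tape, qstar, batch$rid_graphs, batch$n_reactions)
  head <- list(W1 = pn$head_W1, b1 = pn$head_b1, W2 = pn$head_W2,
               b2 = pn$head_b2)
  ffnn_forward(tape, head, rxn,
               ffnn_config(2 * config$h, config$hidden, config$d_emb,
                           config$dropout), mode)
}

#' Apply the message-passing extractor to one reaction's graphs
#'
#' Weights are shared across roles; the per-role set2set graph vectors are
#' summed, so the embedding is invariant to both atom order and role order.
#'
#' @param graphs named list role -> \code{molecular_graph}.
#' @param params weights from \code{mpnn_init} or a trained model.
#' @param config an \code{mpnn_config}.
#' @param mode \code{"eval"} or \code{"train"}.
#' @return embedding vector (length \code{config$d_emb}).
#' @export
mpnn_extract <- function(graphs, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  batch <- batch_graphs(list(graphs))
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_input(tape, p))
  drop(mpnn_forward(tape, pn, batch, config, mode)$value)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}
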