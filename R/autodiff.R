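# Minimal reverse-mode automatic differentiation over matrix operations.
#
# Internal machinery for the deep-kernel trainers: forward passes build a
# tape of coarse matrix ops (matmul, broadcast add, elementwise nonlinearity,
# row gather/scatter, per-segment softmax), and a single backward sweep
# accumulates gradients. The GP marginal-likelihood head is differentiated
# in closed form (see .lml_grad) and its gradient with respect to the
# embedding matrix is injected as the backward seed, so the tape never has
# to differentiate through a Cholesky factorization.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

.nd <- function(tape, value, parents = list(), back = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$back <- back
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- n
  n
}

.acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

ad_input <- function(tape, value) .nd(tape, as.matrix(value))

ad_backward <- function(tape, out, seed) {
  out$grad <- seed
  for (k in rev(seq_len(tape$n))) {
    n <- tape$nodes[[k]]
    if (is.null(n$grad) || is.null(n$back)) next
    gs <- n$back(n$grad, n)
    for (i in seq_along(n$parents))
      if (!is.null(gs[[i]])) .acc(n$parents[[i]], gs[[i]])
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  .nd(tape, a$value %*% b$value, list(a, b), function(g, n)
    list(g %*% t(n$parents[[2]]$value), t(n$parents[[1]]$value) %*% g))
}

# broadcast add: b may be a 1 x k bias row applied to every row of a
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    .nd(tape, sweep(av, 2, bv[1, ], "+"), list(a, b), function(g, n)
      list(g, matrix(colSums(g), 1)))
  } else {
    .nd(tape, av + bv, list(a, b), function(g, n) list(g, g))
  }
}

# elementwise product; b may be an n x 1 column broadcast across columns
ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (ncol(bv) == 1L && ncol(av) > 1L) {
    .nd(tape, av * bv[, 1], list(a, b), function(g, n)
      list(g * n$parents[[2]]$value[, 1],
           matrix(rowSums(g * n$parents[[1]]$value), ncol = 1)))
  } else {
    .nd(tape, av * bv, list(a, b), function(g, n)
      list(g * n$parents[[2]]$value, g * n$parents[[1]]$value))
  }
}

ad_affine <- function(tape, a, scale = 1, shift = 0) {
  .nd(tape, a$value * scale + shift, list(a),
      function(g, n) list(g * scale))
}

ad_relu <- function(tape, a) {
  .nd(tape, pmax(a$value, 0), list(a), function(g, n)
    list(g * (n$parents[[1]]$value > 0)))
}

ad_tanh <- function(tape, a) {
  .nd(tape, tanh(a$value), list(a), function(g, n)
    list(g * (1 - n$value^2)))
}

ad_sigmoid <- function(tape, a) {
  .nd(tape, 1 / (1 + exp(-a$value)), list(a), function(g, n)
    list(g * n$value * (1 - n$value)))
}

# inverted dropout with an externally supplied binary mask
ad_dropout <- function(tape, a, mask, rate) {
  .nd(tape, a$value * mask / (1 - rate), list(a), function(g, n)
    list(g * mask / (1 - rate)))
}

ad_index_rows <- function(tape, a, idx) {
  .nd(tape, a$value[idx, , drop = FALSE], list(a), function(g, n) {
    out <- matrix(0, nrow(n$parents[[1]]$value), ncol(g))
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

ad_segment_sum <- function(tape, a, seg, nseg) {
  .nd(tape, rowsum_segments(a$value, seg, nseg), list(a), function(g, n)
    list(g[seg, , drop = FALSE]))
}

rowsum_segments <- function(m, seg, nseg) {
  out <- matrix(0, nseg, ncol(m))
  rs <- rowsum(m, group = seg)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# softmax of an n x 1 logit column within segments
ad_segment_softmax <- function(tape, a, seg, nseg) {
  v <- a$value[, 1]
  mx <- tapply(v, seg, max)[as.character(seg)]
  e <- exp(v - mx)
  s <- tapply(e, seg, sum)[as.character(seg)]
  p <- matrix(e / s, ncol = 1)
  .nd(tape, p, list(a), function(g, n) {
    pv <- n$value[, 1]; gv <- g[, 1]
    dot <- tapply(pv * gv, seg, sum)[as.character(seg)]
    list(matrix(pv * (gv - dot), ncol = 1))
  })
}

ad_slice_cols <- function(tape, a, cols) {
  .nd(tape, a$value[, cols, drop = FALSE], list(a), function(g, n) {
    out <- matrix(0, nrow(n$parents[[1]]$value), ncol(n$parents[[1]]$value))
    out[, cols] <- g
    list(out)
  })
}

ad_concat_cols <- function(tape, a, b) {
  ka <- ncol(a$value)
  .nd(tape, cbind(a$value, b$value), list(a, b), function(g, n)
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE]))
}
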