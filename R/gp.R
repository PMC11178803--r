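# Exact GP regression with a Matern-5/2 kernel (no ARD).
#
# Hyperparameters are kept positive through a softplus reparameterization;
# the marginal likelihood and its analytic gradients are computed from a
# Cholesky factorization with an escalating jitter ladder.

#' Kernel hyperparameters
#' @param lengthscale shared lengthscale (> 0).
#' @param outputscale signal variance (>= 0).
#' @param noise observation noise variance (>= 0).
#' @return list of class \code{kernel_params}.
#' @export
kernel_params <- function(lengthscale = 1, outputscale = 1, noise = 0.1) {
  stopifnot(is.finite(lengthscale), lengthscale > 0,
            is.finite(outputscale), outputscale >= 0,
            is.finite(noise), noise >= 0)
  structure(list(lengthscale = lengthscale, outputscale = outputscale,
                 noise = noise), class = "kernel_params")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

.pdist <- function(A, B) {
  # Euclidean distances; clamp tiny negatives from cancellation
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Matern-5/2 Gram matrix
#'
#' Entry (i, j) is
#' \code{outputscale * (1 + sqrt(5) r / l + 5 r^2 / (3 l^2)) * exp(-sqrt(5) r / l)}
#' with \code{r} the Euclidean distance between row i of \code{A} and row j
#' of \code{B}.
#'
#' @param A,B point sets (matrices with equal width).
#' @param params a \code{kernel_params}.
#' @return \code{nrow(A)} x \code{nrow(B)} matrix; exactly symmetric when
#'   \code{A} and \code{B} are identical.
#' @export
matern52_gram <- function(A, B = A, params = kernel_params()) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("point sets have different widths", call. = FALSE)
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("non-finite input points", call. = FALSE)
  r <- .pdist(A, B)
  s5 <- sqrt(5) * r / params$lengthscale
  K <- params$outputscale * (1 + s5 + s5^2 / 3) * exp(-s5)
  if (identical(dim(A), dim(B)) && isTRUE(all.equal(A, B, check.attributes = FALSE)))
    K <- (K + t(K)) / 2
  K
}

# Cholesky of K + noise*I with jitter escalation 1e-8 -> 1e-4 (x10 steps)
.chol_jitter <- function(K, noise) {
  n <- nrow(K)
  Kn <- K + diag(noise, n)
  jit <- 0
  for (j in c(0, 10^seq(-8, -4))) {
    L <- tryCatch(chol(Kn + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) { jit <- j; return(list(L = L, jitter = jit)) }
  }
  stop("Gram factorization failed even at jitter 1e-4; condition estimate: ",
       format(kappa(Kn)), call. = FALSE)
}

#' Construct a GP state
#'
#' @param X training inputs (matrix).
#' @param y training targets (standardized by the caller).
#' @param params a \code{kernel_params}.
#' @param prior_mean constant prior mean (default 0 on the standardized scale).
#' @return list of class \code{gp_state} with a cached Cholesky factor.
#' @export
gp_state <- function(X, y, params = kernel_params(), prior_mean = 0) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1, all(is.finite(y)))
  K <- matern52_gram(X, X, params)
  cf <- .chol_jitter(K, params$noise)
  alpha <- backsolve(cf$L, backsolve(cf$L, y - prior_mean, transpose = TRUE))
  structure(list(X = X, y = as.numeric(y), params = params,
                 prior_mean = prior_mean, L = cf$L, jitter = cf$jitter,
                 alpha = alpha),
            class = "gp_state")
}

#' Log marginal likelihood of a GP state
#'
#' The complete Gaussian log density
#' \code{-0.5 * t(y) \%*\% solve(K + noise I, y) - 0.5 log|K + noise I| - n/2 log 2pi},
#' computed through the cached triangular factor so values are comparable
#' across data sizes.
#'
#' @param state a \code{gp_state}.
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(state) {
  yc <- state$y - state$prior_mean
  n <- length(yc)
  -0.5 * sum(yc * state$alpha) - sum(log(diag(state$L))) - n / 2 * log(2 * pi)
}

# LML and its gradient wrt (raw lengthscale, raw outputscale, raw noise)
# under the softplus reparameterization; used by both the L-BFGS-B fit and
# the deep-kernel trainer (which also needs dL/dZ).
.lml_grad <- function(X, y, raw, prior_mean = 0, want_dZ = FALSE) {
  l <- softplus(raw[1]); s <- softplus(raw[2]); noise <- softplus(raw[3])
  n <- nrow(X)
  r <- .pdist(X, X)
  c5 <- sqrt(5) / l
  E <- exp(-c5 * r)
  K <- s * (1 + c5 * r + (c5 * r)^2 / 3) * E
  cf <- .chol_jitter(K, noise)
  yc <- y - prior_mean
  alpha <- backsolve(cf$L, backsolve(cf$L, yc, transpose = TRUE))
  lml <- -0.5 * sum(yc * alpha) - sum(log(diag(cf$L))) - n / 2 * log(2 * pi)

  Kinv <- chol2inv(cf$L)
  G <- 0.5 * (tcrossprod(alpha) - Kinv)   # dLML/dK, elementwise over all i,j

  # dK/dc with c = sqrt(5)/l ; dc/dl = -sqrt(5)/l^2
  dK_dc <- -s * E * (c5 * r^2 / 3) * (1 + c5 * r)
  dl <- sum(G * dK_dc) * (-sqrt(5) / l^2)
  ds <- if (s > 0) sum(G * (K / s)) else sum(G * (1 + c5 * r + (c5 * r)^2 / 3) * E)
  dn <- sum(diag(G))

  sig <- function(x) 1 / (1 + exp(-x))   # d softplus / d raw
  grad <- c(dl * sig(raw[1]), ds * sig(raw[2]), dn * sig(raw[3]))

  out <- list(lml = lml, grad = grad, L = cf$L, alpha = alpha,
              params = kernel_params(l, s, noise), jitter = cf$jitter)
  if (want_dZ) {
    # dLML/dX through the pairwise distances: W_ij = (1/r) dk/dr, finite at 0
    W <- -(2 * G) * (s * c5^2 / 3) * (1 + c5 * r) * E
    out$dZ <- X * rowSums(W) - W %*% X
  }
  out
}

#' Fit GP hyperparameters by maximum marginal likelihood
#'
#' Optimizes lengthscale, outputscale and noise with L-BFGS-B in the
#' softplus-reparameterized (unconstrained) space, using analytic gradients.
#'
#' @param X training inputs (matrix, n >= 2 rows).
#' @param y training targets (standardized by the caller).
#' @param init initial \code{kernel_params} (default l=1, outputscale=1,
#'   noise=0.1, suited to standardized targets).
#' @param maxit L-BFGS-B iteration cap.
#' @return a fitted \code{gp_state}.
#' @export
fit_gp <- function(X, y, init = kernel_params(1, 1, 0.1), maxit = 200L) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training points", call. = FALSE)
  raw0 <- softplus_inv(c(init$lengthscale, max(init$outputscale, 1e-6),
                         max(init$noise, 1e-6)))
  fn <- function(raw) -.lml_grad(X, y, raw)$lml
  gr <- function(raw) -.lml_grad(X, y, raw)$grad
  opt <- tryCatch(
    stats::optim(raw0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit)),
    error = function(e) NULL
  )
  raw <- if (is.null(opt)) raw0 else opt$par
  # optimizer contract: never return a worse point than the initialization
  if (fn(raw) > fn(raw0) + 1e-9) {
    warning("L-BFGS-B did not improve on the initial hyperparameters; ",
            "returning the initial point")
    raw <- raw0
  }
  p <- kernel_params(softplus(raw[1]), softplus(raw[2]), softplus(raw[3]))
  gp_state(X, y, p)
}

#' GP posterior predictive distribution
#'
#' Mean \code{prior_mean + K_*x (K + noise I)^{-1} y} and the diagonal of
#' \code{K_** - K_*x (K + noise I)^{-1} K_x*}, plus observation noise if
#' requested.
#'
#' @param state a \code{gp_state}.
#' @param X_star query points (matrix, same width as training inputs).
#' @param include_noise add the noise variance to the predictive variance
#'   (default TRUE: predictions are for observed yields).
#' @return a \code{predictive_distribution}: list with \code{mean},
#'   \code{variance} (both per query point) and \code{scale_tag}.
#' @export
posterior_predict <- function(state, X_star, include_noise = TRUE) {
  X_star <- as.matrix(X_star)
  if (ncol(X_star) != ncol(state$X))
    stop("query width ", ncol(X_star), " != training width ", ncol(state$X),
         call. = FALSE)
  Ks <- matern52_gram(X_star, state$X, state$params)
  mu <- state$prior_mean + as.numeric(Ks %*% state$alpha)
  V <- backsolve(state$L, t(Ks), transpose = TRUE)
  var <- state$params$outputscale - colSums(V^2)
  if (include_noise) var <- var + state$params$noise
  var <- pmax(var, 1e-12)
  predictive_distribution(mu, var, "standardized")
}

#' Construct a predictive distribution
#' @param mean,variance per-point posterior mean and variance.
#' @param scale_tag \code{"standardized"} or \code{"original"}.
#' @return list of class \code{predictive_distribution}.
#' @export
predictive_distribution <- function(mean, variance,
                                    scale_tag = c("original", "standardized")) {
  scale_tag <- match.arg(scale_tag)
  stopifnot(length(mean) == length(variance), all(is.finite(mean)),
            all(is.finite(variance)))
  if (any(variance <= 0)) stop("non-positive predictive variance", call. = FALSE)
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance),
                 scale_tag = scale_tag), class = "predictive_distribution")
}

#' Negative log predictive density
#'
#' Mean over test points of the negative Gaussian log density of each target
#' under its predictive marginal; penalizes both over- and under-confident
#' uncertainty estimates. Set \code{aggregate = "sum"} for the summed form.
#'
#' @param pred a \code{predictive_distribution}.
#' @param targets observed values on the same scale as \code{pred}.
#' @param aggregate \code{"mean"} (default) or \code{"sum"}.
#' @return scalar NLPD.
#' @export
nlpd <- function(pred, targets, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(targets) == length(pred$mean))
  if (any(pred$variance <= 0)) stop("non-positive variance", call. = FALSE)
  ll <- stats::dnorm(targets, pred$mean, sqrt(pred$variance), log = TRUE)
  if (aggregate == "mean") -mean(ll) else -sum(ll)
}
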