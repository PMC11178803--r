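# Bayesian optimization over a discrete pool of candidate reactions with a
# GP or deep-kernel surrogate. Policies: expected improvement, greedy
# predictive mean, and uniform random selection.

#' Expected improvement
#'
#' \code{EI_i = sd_i * (z_i * pnorm(z_i) + dnorm(z_i))} with
#' \code{z_i = (mean_i - incumbent) / sd_i}; at \code{sd_i = 0} it collapses
#' to \code{max(mean_i - incumbent, 0)}, so EI is exactly zero when no
#' improvement is possible.
#'
#' @param pred a \code{predictive_distribution} on the same scale as
#'   \code{incumbent}.
#' @param incumbent best observed value so far, f(x+).
#' @return numeric vector of non-negative EI values.
#' @export
expected_improvement <- function(pred, incumbent) {
  if (any(pred$variance < 0)) stop("negative predictive variance",
                                   call. = FALSE)
  s <- sqrt(pred$variance)
  ei <- pmax(pred$mean - incumbent, 0)
  pos <- s > 0
  if (any(pos)) {
    z <- (pred$mean[pos] - incumbent) / s[pos]
    ei[pos] <- s[pos] * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  ei
}

#' Construct a candidate pool for benchmarking
#' @param reactions list of \code{reaction} objects with known yields (the
#'   lookup oracle).
#' @return list of class \code{candidate_pool}.
#' @export
candidate_pool <- function(reactions) {
  stopifnot(length(reactions) >= 2)
  structure(list(reactions = reactions, n = length(reactions)),
            class = "candidate_pool")
}

#' Run one Bayesian-optimization trial over a discrete pool
#'
#' A seeded random fraction of the pool initializes the surrogate; each
#' iteration refits the surrogate on the acquired set (yields
#' re-standardized on the acquired values), scores the held-out candidates
#' with the chosen policy, selects the argmax (lowest index on ties),
#' reveals that candidate's yield and moves it to the acquired set.
#'
#' @param pool a \code{candidate_pool}.
#' @param policy \code{"ei"}, \code{"greedy"} (predictive mean only) or
#'   \code{"random"}.
#' @param surrogate \code{"gp"} or \code{"dkl_ffnn"}.
#' @param featurizer featurizer spec for the surrogate.
#' @param config surrogate configuration; for deep-kernel surrogates the
#'   per-refit epoch count defaults to 100 (see \code{bo_config}).
#' @param init_fraction fraction of the pool used for initialization
#'   (default 0.05).
#' @param n_iterations acquisition steps (default 20).
#' @param seed trial seed (initial design and any stochastic surrogate).
#' @param features optional precomputed feature matrix for the whole pool.
#' @return a \code{bo_trace}: data.frame with one initialization row
#'   followed by one row per iteration (iteration, candidate id, revealed
#'   yield, incumbent best); the incumbent column is non-decreasing.
#' @export
run_bo <- function(pool, policy = c("ei", "greedy", "random"),
                   surrogate = c("gp", "dkl_ffnn"),
                   featurizer = list(type = "morgan"),
                   config = NULL, init_fraction = 0.05, n_iterations = 20L,
                   seed = 1L, features = NULL) {
  policy <- match.arg(policy)
  surrogate <- match.arg(surrogate)
  n <- pool$n
  n_init <- max(2L, floor(n * init_fraction))
  if (n < n_init + n_iterations)
    stop("pool smaller than initialization plus iterations", call. = FALSE)
  yields <- reaction_yields(pool$reactions)
  if (is.null(features) && policy != "random")
    features <- featurize_reactions(pool$reactions, featurizer)

  set.seed(seed)
  acquired <- sort(sample.int(n, n_init))
  heldout <- setdiff(seq_len(n), acquired)
  rows <- list(data.frame(iteration = 0L, candidate = NA_integer_,
                          yield = NA_real_,
                          incumbent = max(yields[acquired])))
  for (it in seq_len(n_iterations)) {
    incumbent <- max(yields[acquired])
    if (policy == "random") {
      pick <- heldout[sample.int(length(heldout), 1L)]
    } else {
      std <- standardizer(yields[acquired])
      if (surrogate == "gp") {
        gp <- fit_gp(features[acquired, , drop = FALSE],
                     std$transform(yields[acquired]))
        pr <- posterior_predict(gp, features[heldout, , drop = FALSE])
      } else {
        cfg <- config %||% dkl_config(extractor = "ffnn", epochs = 100L,
                                      seed = seed)
        cfg$extractor <- "ffnn"
        st <- train_dkl(pool$reactions[acquired], featurizer, cfg,
                        features = features[acquired, , drop = FALSE])
        pr_o <- dkl_predict(st, pool$reactions[heldout],
                            features = features[heldout, , drop = FALSE])
        pr <- predictive_distribution(std$transform(pr_o$mean),
                                      pr_o$variance / std$sd^2,
                                      "standardized")
      }
      score <- if (policy == "ei")
        expected_improvement(pr, std$transform(incumbent))
      else pr$mean
      pick <- heldout[which.max(score)]   # which.max: lowest index on ties
    }
    acquired <- c(acquired, pick)
    heldout <- setdiff(heldout, pick)
    rows[[it + 1L]] <- data.frame(iteration = it, candidate = pick,
                                  yield = yields[pick],
                                  incumbent = max(yields[acquired]))
  }
  trace <- do.call(rbind, rows)
  structure(list(trace = trace, seed = seed, policy = policy,
                 n_init = n_init), class = "bo_trace")
}

#' Aggregate incumbent curves across trials
#' @param traces list of \code{bo_trace} objects of equal length.
#' @return data.frame with per-iteration mean incumbent and standard error.
#' @export
aggregate_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  lens <- vapply(traces, function(t) nrow(t$trace), integer(1))
  if (length(unique(lens)) != 1) stop("ragged traces", call. = FALSE)
  inc <- vapply(traces, function(t) t$trace$incumbent, numeric(lens[1]))
  inc <- matrix(inc, nrow = lens[1])
  data.frame(
    iteration = traces[[1]]$trace$iteration,
    mean_incumbent = rowMeans(inc),
    se = apply(inc, 1, stats::sd) / sqrt(length(traces))
  )
}

#' Run repeated randomly initialized BO trials
#' @param pool a \code{candidate_pool}.
#' @param policy,surrogate,featurizer,config,init_fraction,n_iterations see
#'   \code{\link{run_bo}}.
#' @param n_trials number of trials (default 50, the policy-comparison
#'   protocol; acquisition ablations conventionally use 20).
#' @param base_seed trial t uses seed \code{base_seed + t}.
#' @return list with \code{traces} and the aggregated \code{curve}.
#' @export
run_bo_trials <- function(pool, policy = "ei", surrogate = "gp",
                          featurizer = list(type = "morgan"), config = NULL,
                          init_fraction = 0.05, n_iterations = 20L,
                          n_trials = 50L, base_seed = 1000L) {
  features <- if (policy == "random") NULL
              else featurize_reactions(pool$reactions, featurizer)
  traces <- lapply(seq_len(n_trials), function(t)
    run_bo(pool, policy, surrogate, featurizer, config, init_fraction,
           n_iterations, seed = base_seed + t, features = features))
  list(traces = traces, curve = aggregate_traces(traces))
}
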