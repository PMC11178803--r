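# Evaluation protocol: repeated random or leave-component-out splits,
# train-only target standardization, RMSE/MAE/R2/NLPD/Spearman metrics with
# standard errors across runs, learning curves, and embedding cluster
# summaries.

#' Train/validation/test split of a reaction list
#'
#' Random mode draws a seeded permutation and assigns
#' \code{floor(n f_train)} / \code{floor(n f_val)} / remainder. Leave-out
#' mode sends every reaction whose \code{role} component is in
#' \code{held_out} to the test set and splits the rest into train/val by the
#' same rule on the train:val proportions.
#'
#' @param reactions list of \code{reaction} objects.
#' @param fractions length-3 positive vector (train, val, test) summing to 1.
#' @param seed RNG seed; splits are deterministic per seed.
#' @param mode \code{"random"} or \code{"leave_component_out"}.
#' @param role,held_out for leave-out mode: role name and the component
#'   SMILES values to hold out.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test}; disjoint, exhaustive.
#' @export
make_splits <- function(reactions, fractions = c(0.7, 0.1, 0.2), seed = 1L,
                        mode = c("random", "leave_component_out"),
                        role = NULL, held_out = NULL) {
  mode <- match.arg(mode)
  n <- length(reactions)
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  if (mode == "random") {
    if (n < 10) stop("need at least 10 reactions for random splits",
                     call. = FALSE)
    set.seed(seed)
    perm <- sample.int(n)
    n_tr <- floor(n * fractions[1])
    n_va <- floor(n * fractions[2])
    out <- list(train = sort(perm[seq_len(n_tr)]),
                val = sort(perm[n_tr + seq_len(n_va)]),
                test = sort(perm[-seq_len(n_tr + n_va)]))
  } else {
    stopifnot(!is.null(role), !is.null(held_out))
    comp <- vapply(reactions, function(r) unname(r$components[[role]]),
                   character(1))
    if (!any(held_out %in% comp))
      stop("held-out value(s) not present for role '", role, "'",
           call. = FALSE)
    test <- which(comp %in% held_out)
    rest <- setdiff(seq_len(n), test)
    set.seed(seed)
    perm <- sample(rest)
    p_tr <- fractions[1] / (fractions[1] + fractions[2])
    n_tr <- floor(length(rest) * p_tr)
    out <- list(train = sort(perm[seq_len(n_tr)]),
                val = sort(perm[-seq_len(n_tr)]),
                test = sort(test))
  }
  if (!length(out$train) || !length(out$test))
    stop("empty train or test set", call. = FALSE)
  out
}

#' Target standardizer fit on training data
#'
#' @param train_y numeric vector with >= 2 distinct values.
#' @return list with \code{transform}, \code{inverse}, \code{mean},
#'   \code{sd}. \code{transform(train_y)} has zero mean and unit variance.
#' @export
standardizer <- function(train_y) {
  stopifnot(length(train_y) >= 2, all(is.finite(train_y)))
  m <- mean(train_y)
  s <- stats::sd(train_y)
  if (s == 0) stop("constant training targets cannot be standardized",
                   call. = FALSE)
  list(transform = function(y) (y - m) / s,
       inverse = function(z) z * s + m,
       mean = m, sd = s)
}

#' Regression metrics for one evaluation run
#'
#' @param pred a \code{predictive_distribution} (same scale as targets).
#' @param targets observed values.
#' @return one-row data.frame: \code{rmse}, \code{mae}, \code{r2},
#'   \code{nlpd}, \code{spearman_rho} (rank correlation between absolute
#'   error and predictive standard deviation, average ranks for ties).
#' @export
regression_metrics <- function(pred, targets) {
  stopifnot(length(pred$mean) == length(targets))
  err <- pred$mean - targets
  sst <- sum((targets - mean(targets))^2)
  if (sst == 0) stop("zero-variance targets: R^2 undefined", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(abs(err), sqrt(pred$variance), method = "spearman"))
  data.frame(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r2 = 1 - sum(err^2) / sst,
    nlpd = nlpd(pred, targets),
    spearman_rho = rho
  )
}

# fit + predict wrapper shared by repeated_evaluation and the BO surrogates.
# method: "gp" (fixed Matern-5/2 GP, L-BFGS-B), "dkl_ffnn", "dkl_mpnn", "gnn".
.fit_predict <- function(method, reactions, train_idx, test_idx, featurizer,
                         config, features = NULL, val_idx = integer(0)) {
  tr <- reactions[train_idx]
  te <- reactions[test_idx]
  if (method == "gp") {
    X <- if (is.null(features)) featurize_reactions(reactions, featurizer)
         else features
    y <- reaction_yields(reactions)
    std <- standardizer(y[train_idx])
    ini <- config$init
    if (!inherits(ini, "kernel_params")) ini <- kernel_params(1, 1, 0.1)
    gp <- fit_gp(X[train_idx, , drop = FALSE], std$transform(y[train_idx]),
                 init = ini)
    p <- posterior_predict(gp, X[test_idx, , drop = FALSE])
    predictive_distribution(std$inverse(p$mean), p$variance * std$sd^2,
                            "original")
  } else if (method %in% c("dkl_ffnn", "dkl_mpnn")) {
    config$extractor <- if (method == "dkl_ffnn") "ffnn" else "mpnn"
    feats_tr <- feats_te <- NULL
    if (!is.null(features)) {
      if (is.matrix(features)) {
        feats_tr <- features[train_idx, , drop = FALSE]
        feats_te <- features[test_idx, , drop = FALSE]
      } else {
        feats_tr <- features[train_idx]
        feats_te <- features[test_idx]
      }
    }
    val_rx <- if (length(val_idx)) reactions[val_idx] else NULL
    val_ft <- if (length(val_idx) && !is.null(features)) {
      if (is.matrix(features)) features[val_idx, , drop = FALSE]
      else features[val_idx]
    } else NULL
    st <- train_dkl(tr, featurizer, config, features = feats_tr,
                    val_reactions = val_rx, val_features = val_ft)
    dkl_predict(st, te, features = feats_te)
  } else if (method == "gnn") {
    gl <- if (is.null(features)) NULL else features
    model <- gnn_baseline(tr, config,
                          graphs = if (is.null(gl)) NULL else gl[train_idx])
    mu <- gnn_predict(model, te,
                      graphs = if (is.null(gl)) NULL else gl[test_idx])
    structure(list(mean = mu, variance = NULL, scale_tag = "original"),
              class = "point_prediction")
  } else stop("unknown method: ", method, call. = FALSE)
}

#' Repeated evaluation over splits and training fractions
#'
#' For each training fraction and run: split (run seed = \code{base_seed +}
#' run index), standardize on train, fit, predict the test set, compute
#' metrics; then aggregate mean and standard error per fraction.
#'
#' @param method \code{"gp"}, \code{"dkl_ffnn"}, \code{"dkl_mpnn"} or
#'   \code{"gnn"}.
#' @param reactions list of \code{reaction} objects.
#' @param featurizer featurizer spec (see \code{\link{featurize_reactions}}).
#' @param config method configuration (\code{dkl_config} for the neural
#'   methods; a list with \code{init} for the GP).
#' @param n_runs independent runs per fraction (default 10).
#' @param train_fractions training-set proportions; the remainder after the
#'   validation share is the test set. The default ladder spans 80:20 down
#'   to 5:95.
#' @param val_fraction validation share (default 0, i.e. two-way splits;
#'   use 0.1 for the 70:10:20 protocol).
#' @param base_seed run r of fraction f uses seed \code{base_seed + r}.
#' @return list with \code{runs} (one row per run) and \code{aggregate}
#'   (mean and standard error per fraction).
#' @export
repeated_evaluation <- function(method, reactions,
                                featurizer = list(type = "morgan"),
                                config = dkl_config(),
                                n_runs = 10L,
                                train_fractions = c(0.8, 0.7, 0.5, 0.3,
                                                    0.2, 0.1, 0.05),
                                val_fraction = 0,
                                base_seed = 100L) {
  stopifnot(n_runs >= 1)
  features <- featurize_reactions(reactions, featurizer)
  rows <- list()
  for (f in train_fractions) {
    for (r in seq_len(n_runs)) {
      seed <- base_seed + r
      res <- tryCatch({
        sp <- make_splits(reactions,
                          c(f, val_fraction, 1 - f - val_fraction), seed)
        if (method %in% c("dkl_ffnn", "dkl_mpnn", "gnn"))
          config$seed <- seed
        pred <- .fit_predict(method, reactions, sp$train, sp$test,
                             featurizer, config, features = features,
                             val_idx = sp$val)
        m <- if (inherits(pred, "point_prediction")) {
          err <- pred$mean - reaction_yields(reactions[sp$test])
          tg <- reaction_yields(reactions[sp$test])
          data.frame(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                     r2 = 1 - sum(err^2) / sum((tg - mean(tg))^2),
                     nlpd = NA_real_, spearman_rho = NA_real_)
        } else regression_metrics(pred, reaction_yields(reactions[sp$test]))
        cbind(data.frame(train_fraction = f, run = r, seed = seed), m)
      }, error = function(e) {
        warning("run failed (fraction ", f, ", run ", r, "): ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$train_fraction), function(d) {
    mets <- c("rmse", "mae", "r2", "nlpd", "spearman_rho")
    out <- data.frame(train_fraction = d$train_fraction[1], n_runs = nrow(d))
    for (m in mets) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_se")]] <- stats::sd(d[[m]]) / sqrt(nrow(d))
    }
    out
  }))
  rownames(agg) <- NULL
  list(runs = runs, aggregate = agg)
}

#' Cluster summary of learned reaction embeddings
#'
#' Reduces embeddings to 2-D with an injected reducer (default: first two
#' principal components), runs k-means (10 restarts, seeded), and reports
#' per-cluster sizes, median yields, and the distinct per-role component
#' values when reactions are supplied.
#'
#' @param embeddings n x d numeric matrix.
#' @param yields numeric vector of length n.
#' @param k number of clusters (default 4).
#' @param reducer function(matrix) -> n x 2 matrix; any 2-D reduction (UMAP,
#'   t-SNE, ...) can be plugged in.
#' @param reactions optional reaction list for component composition.
#' @param seed k-means seed.
#' @return list with \code{assignment}, \code{coords}, and \code{summary}
#'   (cluster, size, median_yield, plus per-role composition when available).
#' @export
cluster_summary <- function(embeddings, yields, k = 4L,
                            reducer = function(m) stats::prcomp(m)$x[, 1:2,
                                                                    drop = FALSE],
                            reactions = NULL, seed = 1L) {
  embeddings <- as.matrix(embeddings)
  stopifnot(nrow(embeddings) == length(yields), k >= 1)
  if (k > nrow(embeddings)) stop("k exceeds the number of points",
                                 call. = FALSE)
  coords <- if (ncol(embeddings) > 2) reducer(embeddings)
            else cbind(embeddings, matrix(0, nrow(embeddings),
                                          2 - ncol(embeddings)))
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = 10L)
  cl <- km$cluster
  summ <- data.frame(
    cluster = seq_len(k),
    size = as.integer(tabulate(cl, k)),
    median_yield = vapply(seq_len(k), function(i) stats::median(yields[cl == i]),
                          numeric(1))
  )
  composition <- NULL
  if (!is.null(reactions)) {
    roles <- reaction_roles(reactions)
    composition <- lapply(seq_len(k), function(i) {
      lapply(stats::setNames(roles, roles), function(role)
        sort(unique(vapply(reactions[cl == i],
                           function(r) unname(r$components[[role]]),
                           character(1)))))
    })
  }
  list(assignment = cl, coords = coords, summary = summ,
       composition = composition)
}
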