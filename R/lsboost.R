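# Least-squares gradient boosting with axis-aligned regression trees.
#
# The base learner is an exhaustive-search CART-style regression tree:
# at each node every feature's every admissible split point is scored by the
# exact SSE reduction, and the threshold is the midpoint between adjacent
# distinct values. Trees are grown depth-first to a maximum depth with a
# minimum leaf size. Boosting is stage-wise: tree m is fit to the residuals
# of the ensemble after m-1 rounds and added with shrinkage nu, which makes
# the training MSE non-increasing in the number of rounds for nu in (0, 2].

# Find the best split of rows `idx` of X: returns NULL or
# list(feature, threshold, score = SSE reduction)
best_split <- function(X, y, idx, min_leaf) {
  n <- length(idx)
  if (n < 2L * min_leaf) return(NULL)
  yi <- y[idx]
  tot <- sum(yi)
  base <- tot^2 / n
  best <- NULL
  best_score <- 1e-12
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    ord <- order(xv)
    xs <- xv[ord]
    cs <- cumsum(yi[ord])
    k <- seq_len(n - 1L)
    valid <- k >= min_leaf & (n - k) >= min_leaf & xs[k] < xs[k + 1L]
    if (!any(valid)) next
    red <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - base
    red[!valid] <- -Inf
    kb <- which.max(red)
    if (red[kb] > best_score) {
      best_score <- red[kb]
      best <- list(feature = j, threshold = (xs[kb] + xs[kb + 1L]) / 2,
                   score = red[kb])
    }
  }
  best
}

# Grow one regression tree; returns list(nodes = list of node lists)
grow_tree <- function(X, y, max_depth, min_leaf) {
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list()
    length(nodes)
  }
  build <- function(idx, depth) {
    id <- new_node()
    sp <- if (depth < max_depth) best_split(X, y, idx, min_leaf) else NULL
    if (is.null(sp)) {
      nodes[[id]] <<- list(leaf = TRUE, value = mean(y[idx]))
    } else {
      go_left <- X[idx, sp$feature] <= sp$threshold
      l <- build(idx[go_left], depth + 1L)
      r <- build(idx[!go_left], depth + 1L)
      nodes[[id]] <<- list(leaf = FALSE, feature = sp$feature,
                           threshold = sp$threshold, score = sp$score,
                           left = l, right = r)
    }
    id
  }
  build(seq_along(y), 0L)
  list(nodes = nodes)
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  recurse <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      out[rows] <<- nd$value
    } else {
      left <- X[rows, nd$feature] <= nd$threshold
      if (any(left)) recurse(nd$left, rows[left])
      if (any(!left)) recurse(nd$right, rows[!left])
    }
  }
  if (nrow(X) > 0) recurse(1L, seq_len(nrow(X)))
  out
}

#' Fit a least-squares boosted regression tree ensemble
#'
#' Stage-wise additive modelling: the fit starts from the response mean and
#' each round adds `shrinkage` times a regression tree fit to the current
#' residuals by exact exhaustive split search. Chosen because annual spread
#' rates follow no known parametric distribution and covariate effects are
#' expected to be non-linear.
#'
#' @param x feature data frame or matrix (numeric columns).
#' @param y numeric response, same length as `nrow(x)`.
#' @param n_rounds number of boosting rounds M.
#' @param shrinkage learning rate nu in (0, 1].
#' @param max_depth maximum tree depth (1 = stumps).
#' @param min_leaf minimum observations per leaf.
#' @param seed RNG seed (the fit itself is deterministic; kept for interface
#'   symmetry with stochastic variants).
#' @return object of class `lsboost` with elements `init` (mean response),
#'   `trees`, `shrinkage`, `feature_names`, `train_mse` (per-round vector),
#'   `importance` (named SSE-reduction totals) and `response_sd`.
#' @examples
#' x <- data.frame(u = runif(50))
#' fit <- fit_lsboost(x, as.numeric(x$u > 0.5), n_rounds = 1,
#'                    shrinkage = 1, max_depth = 1, min_leaf = 1)
#' @export
fit_lsboost <- function(x, y, n_rounds = 500, shrinkage = 0.05,
                        max_depth = 3, min_leaf = 5, seed = 1L) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  assert_that(nrow(X) == length(y), "features and response must align")
  assert_that(nrow(X) >= 2, "need at least 2 observations")
  assert_that(shrinkage > 0 && shrinkage <= 1, "shrinkage must be in (0,1]")
  const_feat <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (all(const_feat) && stats::sd(y) > 0) {
    warning("all features constant with non-constant response; ",
            "fit degenerates to the response mean")
  }
  init <- mean(y)
  f <- rep(init, length(y))
  trees <- vector("list", n_rounds)
  train_mse <- numeric(n_rounds)
  imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (m in seq_len(n_rounds)) {
    r <- y - f
    tr <- grow_tree(X, r, max_depth = max_depth, min_leaf = min_leaf)
    f <- f + shrinkage * predict_tree(tr, X)
    train_mse[m] <- mean((y - f)^2)
    for (nd in tr$nodes) {
      if (!nd$leaf) imp[nd$feature] <- imp[nd$feature] + nd$score
    }
    trees[[m]] <- tr
  }
  structure(list(init = init, trees = trees, shrinkage = shrinkage,
                 n_rounds = n_rounds, max_depth = max_depth,
                 min_leaf = min_leaf,
                 feature_names = colnames(X), train_mse = train_mse,
                 importance = imp, response_sd = stats::sd(y)),
            class = "lsboost")
}

#' Predict from a boosted ensemble
#'
#' @param object an `lsboost` fit.
#' @param newdata data frame or matrix with the training feature columns.
#' @param n_rounds optionally truncate the ensemble to its first rounds.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lsboost <- function(object, newdata, n_rounds = NULL, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  m <- if (is.null(n_rounds)) length(object$trees) else n_rounds
  out <- rep(object$init, nrow(X))
  for (i in seq_len(m)) {
    out <- out + object$shrinkage * predict_tree(object$trees[[i]], X)
  }
  out
}

#' @export
print.lsboost <- function(x, ...) {
  cat(sprintf("<lsboost> %d rounds, depth <= %d, nu = %g, final MSE %.4g\n",
              length(x$trees), x$max_depth, x$shrinkage,
              utils::tail(x$train_mse, 1)))
  invisible(x)
}

#' Feature importance of a boosted ensemble
#'
#' Total training SSE reduction attributed to each feature across all splits
#' of all trees, sorted decreasing.
#'
#' @param object an `lsboost` fit.
#' @return named numeric vector.
#' @export
lsboost_importance <- function(object) {
  sort(object$importance, decreasing = TRUE)
}
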