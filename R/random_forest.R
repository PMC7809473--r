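# Minimal CART + bagging forest for binary targets. No tree package ships in
# the target environment, so the one-vs-rest forest estimator is implemented
# here: gini splits, per-node feature subsampling (mtry), bootstrap bagging.
# Hyperparameters mirror the examined grid: max depth, min samples to split,
# min samples per leaf.

gini_split_search <- function(X, y, idx, mtry, minbucket) {
  p <- ncol(X)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  n <- length(idx)
  total1 <- sum(y[idx])
  best <- list(gain = -Inf)
  parent_imp <- 2 * (total1 / n) * (1 - total1 / n)
  for (j in feats) {
    x <- X[idx, j]
    o <- order(x)
    xs <- x[o]
    ys <- y[idx][o]
    cum1 <- cumsum(ys)
    i <- seq_len(n - 1L)
    valid <- which(xs[i] < xs[i + 1L] & i >= minbucket & (n - i) >= minbucket)
    if (!length(valid)) next
    nl <- valid
    nr <- n - nl
    p1l <- cum1[valid] / nl
    p1r <- (total1 - cum1[valid]) / nr
    imp <- (nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)) / n
    gain <- parent_imp - imp
    b <- which.max(gain)
    if (gain[b] > best$gain + 1e-12) {
      best <- list(gain = gain[b], feature = j,
                   threshold = (xs[valid[b]] + xs[valid[b] + 1L]) / 2)
    }
  }
  if (is.finite(best$gain) && best$gain > 0) best else NULL
}

grow_cart <- function(X, y, idx, depth, maxdepth, minsplit, minbucket, mtry) {
  n <- length(idx)
  prob1 <- mean(y[idx])
  if (depth >= maxdepth || n < minsplit || prob1 == 0 || prob1 == 1) {
    return(list(leaf = TRUE, prob = prob1))
  }
  sp <- gini_split_search(X, y, idx, mtry, minbucket)
  if (is.null(sp)) return(list(leaf = TRUE, prob = prob1))
  left <- idx[X[idx, sp$feature] <= sp$threshold]
  right <- setdiff(idx, left)
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_cart(X, y, left, depth + 1L, maxdepth, minsplit, minbucket, mtry),
       right = grow_cart(X, y, right, depth + 1L, maxdepth, minsplit, minbucket, mtry))
}

predict_cart <- function(tree, newdata) {
  out <- numeric(nrow(newdata))
  recurse <- function(node, rows) {
    if (!length(rows)) return(invisible())
    if (node$leaf) {
      out[rows] <<- node$prob
      return(invisible())
    }
    go_left <- newdata[rows, node$feature] <= node$threshold
    recurse(node$left, rows[go_left])
    recurse(node$right, rows[!go_left])
  }
  recurse(tree, seq_len(nrow(newdata)))
  out
}

#' Fit a bagged random forest for a binary target
#'
#' Bootstrap-aggregated CART trees with per-node feature subsampling
#' (`mtry = floor(sqrt(p))`), gini splits, and the depth/split/leaf
#' hyperparameters of the examined grid. Predicted probability is the mean of
#' the trees' leaf class-1 proportions.
#'
#' @param X numeric feature matrix.
#' @param y binary 0/1 target.
#' @param n_trees number of trees (default 100).
#' @param maxdepth,minsplit,minbucket tree growth control.
#' @param mtry features tried per split.
#' @param seed integer seed.
#' @return a `bagged_forest` object.
#' @export
fit_forest <- function(X, y, n_trees = 100, maxdepth = 6, minsplit = 2,
                       minbucket = 2, mtry = max(1L, floor(sqrt(ncol(X)))),
                       seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  set.seed(stage_seed(seed, 31L))
  trees <- lapply(seq_len(n_trees), function(t) {
    boot <- sample(nrow(X), nrow(X), replace = TRUE)
    grow_cart(X[boot, , drop = FALSE], y[boot], seq_along(boot), 0L,
              maxdepth, minsplit, minbucket, mtry)
  })
  structure(list(trees = trees, n_features = ncol(X),
                 params = list(n_trees = n_trees, maxdepth = maxdepth,
                               minsplit = minsplit, minbucket = minbucket,
                               mtry = mtry)),
            class = "bagged_forest")
}

#' Predict class-1 probability from a bagged forest
#' @param forest a `bagged_forest`.
#' @param newdata feature matrix.
#' @export
predict_forest <- function(forest, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != forest$n_features) {
    abort_on("shape_mismatch_error", "feature count differs from training")
  }
  probs <- vapply(forest$trees, function(tr) predict_cart(tr, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}
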