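#' Specify an autoencoder architecture
#'
#' Describes one member of the examined family: identity (linear) or ReLU
#' activations, one or more latent layers with a 15-unit bottleneck in the
#' canonical configurations, optional weight tying (decoder = transposed
#' encoder), and an optional penalty on the parameters (`l1`, `l2`) or on the
#' batch cross-covariance of the bottleneck activations (`xcov`, which
#' discourages correlated subnetworks). Training uses RMSprop at learning
#' rate 1e-3 by default.
#'
#' @param activation `"identity"` or `"relu"`.
#' @param latent_layers integer vector of latent layer widths, e.g. `15`,
#'   `c(25, 15, 25)`, `c(25, 20, 15, 20, 25)`.
#' @param tied_weights logical; requires a symmetric layer plan.
#' @param penalty `"none"`, `"l1"`, `"l2"` or `"xcov"`.
#' @param lambda penalty coefficient (ignored for `"none"`).
#' @param learning_rate RMSprop/SGD step size.
#' @param optimizer `"rmsprop"` or `"sgd"`.
#' @param max_epochs,batch_size,patience training control; early stopping
#'   monitors the validation loss with the given patience.
#' @param seed integer seed controlling initialization and batch order.
#' @param name optional label.
#' @return an `autoencoder_spec`.
#' @export
autoencoder_spec <- function(activation = c("identity", "relu"),
                             latent_layers = 15, tied_weights = FALSE,
                             penalty = c("none", "l1", "l2", "xcov"),
                             lambda = 0, learning_rate = 1e-3,
                             optimizer = c("rmsprop", "sgd"),
                             max_epochs = 500, batch_size = 128,
                             patience = 20, seed = 1, name = NULL) {
  activation <- match.arg(activation)
  penalty <- match.arg(penalty)
  optimizer <- match.arg(optimizer)
  latent_layers <- as.integer(latent_layers)
  if (any(latent_layers < 1L)) abort_on("spec_error", "latent layer widths must be >= 1")
  if (tied_weights && !identical(latent_layers, rev(latent_layers))) {
    abort_on("spec_error", "tied weights require a symmetric latent layer plan")
  }
  if (lambda < 0) abort_on("spec_error", "lambda must be nonnegative")
  if (is.null(name)) {
    name <- paste0(activation, "_", paste(latent_layers, collapse = "-"),
                   if (penalty != "none") paste0("_", penalty) else "",
                   if (tied_weights) "_tied" else "")
  }
  structure(list(activation = activation, latent_layers = latent_layers,
                 tied_weights = isTRUE(tied_weights), penalty = penalty,
                 lambda = lambda, learning_rate = learning_rate,
                 optimizer = optimizer, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed),
                 name = name),
            class = "autoencoder_spec")
}

#' The canonical family of examined architectures
#'
#' Seven configurations: linear baseline (one 15-unit latent layer, no
#' penalty), the same with l1, l2 and cross-covariance penalties, a tied
#' ReLU variant, and 3- and 5-latent-layer ReLU variants (25-15-25 and
#' 25-20-15-20-25).
#'
#' @param lambda penalty coefficient used for the penalized members when run
#'   outside a hyperparameter search.
#' @param ... passed to [autoencoder_spec()] (e.g. training control).
#' @return named list of `autoencoder_spec`s.
#' @export
table2_architectures <- function(lambda = 1e-3, ...) {
  list(
    baseline  = autoencoder_spec("identity", 15, name = "baseline", ...),
    l1        = autoencoder_spec("identity", 15, penalty = "l1", lambda = lambda,
                                 name = "l1", ...),
    l2        = autoencoder_spec("identity", 15, penalty = "l2", lambda = lambda,
                                 name = "l2", ...),
    xcov      = autoencoder_spec("identity", 15, penalty = "xcov", lambda = lambda,
                                 name = "xcov", ...),
    tied_relu = autoencoder_spec("relu", 15, tied_weights = TRUE,
                                 name = "tied_relu", ...),
    deep3     = autoencoder_spec("relu", c(25, 15, 25), name = "deep3", ...),
    deep5     = autoencoder_spec("relu", c(25, 20, 15, 20, 25), name = "deep5", ...)
  )
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else z
}
act_grad <- function(z, activation) {
  if (activation == "relu") (z > 0) * 1 else 1
}

tie_decoder <- function(model) {
  L <- length(model$weights)
  for (l in seq_len(L %/% 2L)) {
    model$weights[[L + 1L - l]] <- t(model$weights[[l]])
  }
  model
}

#' Initialize an autoencoder model
#'
#' Builds seeded Glorot-uniform weight matrices and zero biases for the layer
#' plan `R -> latent_layers -> R`. The bottleneck is the narrowest latent
#' layer; its activations are the participant-wise subnetwork expressions.
#'
#' @param spec an `autoencoder_spec`.
#' @param n_regions input/output dimension R.
#' @return an untrained `autoencoder_model`.
#' @export
build_autoencoder <- function(spec, n_regions) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  widths <- c(n_regions, spec$latent_layers, n_regions)
  L <- length(widths) - 1L
  set.seed(spec$seed)
  weights <- biases <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    weights[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_out, fan_in)
    biases[[l]] <- numeric(fan_out)
  }
  model <- structure(list(
    spec = spec, widths = widths, weights = weights, biases = biases,
    bottleneck_layer = which.min(widths[-c(1L, L + 1L)]),
    n_regions = n_regions, latent_means = NULL, log = NULL,
    trained = FALSE, method = "gradient"
  ), class = "autoencoder_model")
  if (spec$tied_weights) model <- tie_decoder(model)
  model
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat(sprintf("autoencoder (%s): layers %s%s%s, penalty %s%s\n",
              x$method, paste(x$widths, collapse = "-"),
              if (x$spec$tied_weights) ", tied" else "",
              if (x$trained) ", trained" else ", untrained",
              x$spec$penalty,
              if (x$spec$penalty != "none") sprintf(" (lambda=%g)", x$spec$lambda) else ""))
  invisible(x)
}

# forward pass keeping pre-activations and activations for backprop
ae_forward <- function(model, X) {
  L <- length(model$weights)
  A <- vector("list", L + 1L); Zs <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Zl <- sweep(A[[l]] %*% t(model$weights[[l]]), 2L, model$biases[[l]], "+")
    Zs[[l]] <- Zl
    A[[l + 1L]] <- if (l < L) act_fun(Zl, model$spec$activation) else Zl
  }
  list(A = A, Z = Zs)
}

#' Project volumes onto the latent subnetwork space
#'
#' Deterministic forward pass through the encoder half of the model,
#' returning the n x K matrix of participant-wise subnetwork expressions.
#'
#' @param model a (trained) `autoencoder_model`.
#' @param X standardized matrix or `volume_matrix`.
#' @return n x K latent embedding matrix.
#' @export
encode <- function(model, X) {
  X <- vm_values(X)
  if (ncol(X) != model$n_regions) {
    abort_on("shape_mismatch_error", "X has the wrong number of regions")
  }
  bl <- model$bottleneck_layer
  A <- X
  for (l in seq_len(bl)) {
    Zl <- sweep(A %*% t(model$weights[[l]]), 2L, model$biases[[l]], "+")
    A <- act_fun(Zl, model$spec$activation)
  }
  A
}

#' Reconstruct volumes from latent expressions
#'
#' @param model an `autoencoder_model`.
#' @param H n x K latent matrix.
#' @return n x R reconstruction.
#' @export
decode <- function(model, H) {
  L <- length(model$weights)
  bl <- model$bottleneck_layer
  if (ncol(H) != model$widths[bl + 1L]) {
    abort_on("shape_mismatch_error", "H has the wrong latent dimension")
  }
  A <- H
  for (l in seq(bl + 1L, L)) {
    Zl <- sweep(A %*% t(model$weights[[l]]), 2L, model$biases[[l]], "+")
    A <- if (l < L) act_fun(Zl, model$spec$activation) else Zl
  }
  A
}

#' Full encode-decode reconstruction
#' @inheritParams encode
#' @export
reconstruct <- function(model, X) decode(model, encode(model, X))

#' Mean absolute reconstruction error
#'
#' Mean over all entries of `|X - Xhat|`, the evaluation metric for all
#' architecture comparisons (computed on z-scored volumes).
#'
#' @param X,Xhat same-shape matrices or `volume_matrix` objects.
#' @return scalar MAE.
#' @export
reconstruction_mae <- function(X, Xhat) {
  X <- vm_values(X); Xhat <- vm_values(Xhat)
  if (!identical(dim(X), dim(Xhat))) {
    abort_on("shape_mismatch_error", "X and Xhat must have identical shape")
  }
  mean(abs(X - Xhat))
}

#' Explained-variance score
#'
#' `1 - reconstruction_mae(X, Xhat)` on z-scored volumes: 1 means perfect
#' encapsulation of the measured volumes, smaller values mean incomplete
#' recovery.
#'
#' @inheritParams reconstruction_mae
#' @return scalar score.
#' @export
explained_variance_score <- function(X, Xhat) 1 - reconstruction_mae(X, Xhat)

batch_xcov_penalty <- function(H) {
  n <- nrow(H)
  Hc <- sweep(H, 2L, colMeans(H))
  C <- crossprod(Hc) / n
  diag(C) <- 0
  0.5 * sum(C^2)
}

weight_penalty <- function(model) {
  switch(model$spec$penalty,
         none = 0,
         l1 = sum(vapply(model$weights, function(W) sum(abs(W)), numeric(1))),
         l2 = sum(vapply(model$weights, function(W) sum(W^2), numeric(1))),
         xcov = NA_real_)  # data-dependent; handled in training_loss
}

#' Training objective on a batch
#'
#' Mean squared reconstruction error plus `lambda` times the penalty:
#' `sum|w|` (l1), `sum w^2` (l2), or the cross-covariance term
#' `0.5 * sum_{k != l} Cov(h_k, h_l)^2` over the batch bottleneck activations
#' (xcov). The MAE metric is used for evaluation; squared error provides the
#' training gradients.
#'
#' @param model an `autoencoder_model`.
#' @param X standardized batch (matrix or `volume_matrix`).
#' @return scalar loss.
#' @export
training_loss <- function(model, X) {
  X <- vm_values(X)
  fw <- ae_forward(model, X)
  recon <- mean((X - fw$A[[length(fw$A)]])^2)
  pen <- switch(model$spec$penalty,
                none = 0,
                l1 = , l2 = weight_penalty(model),
                xcov = batch_xcov_penalty(fw$A[[model$bottleneck_layer + 1L]]))
  recon + model$spec$lambda * pen
}

# gradients of training_loss wrt weights and biases on batch X
ae_gradients <- function(model, X) {
  L <- length(model$weights)
  spec <- model$spec
  fw <- ae_forward(model, X)
  A <- fw$A; Zs <- fw$Z
  n <- nrow(X)
  dW <- vector("list", L); db <- vector("list", L)
  dA <- 2 * (A[[L + 1L]] - X) / (n * ncol(X))   # d recon_mse / d output
  bl <- model$bottleneck_layer
  for (l in L:1) {
    if (spec$penalty == "xcov" && l == bl) {
      H <- A[[bl + 1L]]
      Hc <- sweep(H, 2L, colMeans(H))
      C <- crossprod(Hc) / nrow(H)
      diag(C) <- 0
      dA <- dA + spec$lambda * (2 / nrow(H)) * (Hc %*% C)
    }
    dZ <- if (l < L) dA * act_grad(Zs[[l]], spec$activation) else dA
    dW[[l]] <- crossprod(dZ, A[[l]])
    db[[l]] <- colSums(dZ)
    if (spec$penalty == "l1") dW[[l]] <- dW[[l]] + spec$lambda * sign(model$weights[[l]])
    if (spec$penalty == "l2") dW[[l]] <- dW[[l]] + spec$lambda * 2 * model$weights[[l]]
    if (l > 1L) dA <- dZ %*% model$weights[[l]]
  }
  if (spec$tied_weights) {
    for (l in seq_len(L %/% 2L)) {
      g <- dW[[l]] + t(dW[[L + 1L - l]])
      dW[[l]] <- g
      dW[[L + 1L - l]] <- t(g)   # kept in sync; only encoder half is free
    }
  }
  list(dW = dW, db = db)
}

#' Train an autoencoder by backpropagation
#'
#' Mini-batch training with RMSprop (or plain SGD), early-stopped on the
#' validation loss; the best-validation weights are restored. Bit-reproducible
#' under a fixed spec seed. After training the model stores the mean
#' bottleneck activation over the training rows, needed for per-subnetwork
#' scoring.
#'
#' @param spec an `autoencoder_spec`.
#' @param X_train standardized training rows (matrix or `volume_matrix`).
#' @param X_val standardized validation rows; if `NULL`, a seeded 10% slice
#'   of `X_train` is held out.
#' @return a trained `autoencoder_model` with a `$log` data frame
#'   (epoch, train and validation loss).
#' @export
train_autoencoder <- function(spec, X_train, X_val = NULL) {
  X_train <- vm_values(X_train)
  if (is.null(X_val)) {
    set.seed(stage_seed(spec$seed, 97L))
    idx <- sample(nrow(X_train), max(1L, round(0.1 * nrow(X_train))))
    X_val <- X_train[idx, , drop = FALSE]
    X_train <- X_train[-idx, , drop = FALSE]
  } else {
    X_val <- vm_values(X_val)
  }
  model <- build_autoencoder(spec, ncol(X_train))
  L <- length(model$weights)
  cacheW <- lapply(model$weights, function(W) W * 0)
  cacheB <- lapply(model$biases, function(b) b * 0)
  lr <- spec$learning_rate; rho <- 0.9; eps <- 1e-8
  best_val <- Inf; best <- model; wait <- 0L
  log <- vector("list", spec$max_epochs)
  set.seed(stage_seed(spec$seed, 11L))
  n <- nrow(X_train)
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    for (s in starts) {
      rows <- ord[s:min(s + spec$batch_size - 1L, n)]
      g <- ae_gradients(model, X_train[rows, , drop = FALSE])
      for (l in seq_len(L)) {
        if (spec$optimizer == "rmsprop") {
          cacheW[[l]] <- rho * cacheW[[l]] + (1 - rho) * g$dW[[l]]^2
          cacheB[[l]] <- rho * cacheB[[l]] + (1 - rho) * g$db[[l]]^2
          model$weights[[l]] <- model$weights[[l]] -
            lr * g$dW[[l]] / (sqrt(cacheW[[l]]) + eps)
          model$biases[[l]] <- model$biases[[l]] -
            lr * g$db[[l]] / (sqrt(cacheB[[l]]) + eps)
        } else {
          model$weights[[l]] <- model$weights[[l]] - lr * g$dW[[l]]
          model$biases[[l]] <- model$biases[[l]] - lr * g$db[[l]]
        }
      }
      if (spec$tied_weights) model <- tie_decoder(model)
    }
    tr_loss <- training_loss(model, X_train)
    val_loss <- training_loss(model, X_val)
    if (!is.finite(tr_loss) || !is.finite(val_loss)) {
      abort_on("divergence_error", sprintf("loss became non-finite at epoch %d", epoch))
    }
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                               val_loss = val_loss)
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best <- model
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  model <- best
  model$log <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  model$trained <- TRUE
  model$latent_means <- colMeans(encode(model, X_train))
  model
}

#' Closed-form optimal linear autoencoder (PCA oracle)
#'
#' Builds the squared-error-optimal rank-k linear autoencoder from the top-k
#' eigenvectors `V` of the training covariance: `h = V'(x - mu)`,
#' `xhat = V h + mu`. Serves as the independent oracle every trained linear
#' autoencoder is checked against, and as a fast deterministic decomposition
#' backend.
#'
#' @param X standardized matrix or `volume_matrix` (n > k rows).
#' @param k bottleneck width.
#' @return a trained `autoencoder_model` with `method = "pca_oracle"`.
#' @export
closed_form_linear_ae <- function(X, k) {
  X <- vm_values(X)
  n <- nrow(X)
  if (n <= k) abort_on("rank_error", "need more rows than latent units")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / n
  e <- eigen(C, symmetric = TRUE)
  if (sum(e$values > max(e$values) * 1e-9) < k) {
    abort_on("rank_error", sprintf("covariance rank < k = %d", k))
  }
  V <- e$vectors[, seq_len(k), drop = FALSE]
  spec <- autoencoder_spec("identity", k, name = sprintf("pca_oracle_%d", k))
  model <- structure(list(
    spec = spec, widths = c(ncol(X), k, ncol(X)),
    weights = list(t(V), V),
    biases = list(drop(-t(V) %*% mu), mu),
    bottleneck_layer = 1L, n_regions = ncol(X),
    latent_means = NULL, log = NULL, trained = TRUE, method = "pca_oracle"
  ), class = "autoencoder_model")
  model$latent_means <- colMeans(encode(model, X))
  model
}

count_params <- function(model) {
  L <- length(model$weights)
  wfree <- if (model$spec$tied_weights) seq_len(ceiling(L / 2)) else seq_len(L)
  sum(vapply(model$weights[wfree], length, numeric(1))) +
    sum(vapply(model$biases, length, numeric(1)))
}

#' Compare autoencoder architectures by nested cross-validation
#'
#' Five (by default) outer repetitions split the rows 50/50 into train and
#' test; within each training half, inner 90/10 splits pick the penalty
#' coefficient from `lambda_grid` (for penalized specs). The winning
#' architecture has the best mean held-out explained-variance score, ties
#' broken toward fewer parameters.
#'
#' @param specs named list of `autoencoder_spec`s.
#' @param X standardized matrix or `volume_matrix`.
#' @param cv_plan list with `outer` (default 5) and `inner` (default 10).
#' @param lambda_grid candidate penalty coefficients.
#' @param seed integer controlling the splits and per-fold training seeds.
#' @return a `fit_report`: `$table` (per-spec mean/SD score, mean MAE,
#'   parameter count), `$winner`, `$chosen_lambda`, `$folds`.
#' @export
compare_architectures <- function(specs, X, cv_plan = list(outer = 5, inner = 10),
                                  lambda_grid = 10^seq(-4, -1), seed = 1) {
  X <- vm_values(X)
  if (cv_plan$outer < 2L) abort_on("spec_error", "need at least 2 outer splits")
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  }
  n <- nrow(X)
  scores <- matrix(NA_real_, cv_plan$outer, length(specs),
                   dimnames = list(NULL, names(specs)))
  maes <- scores
  chosen <- matrix(NA_real_, cv_plan$outer, length(specs),
                   dimnames = list(NULL, names(specs)))
  folds <- vector("list", cv_plan$outer)
  for (o in seq_len(cv_plan$outer)) {
    set.seed(stage_seed(seed, o))
    tr_idx <- sample(n, floor(n / 2))
    folds[[o]] <- tr_idx
    Xtr <- X[tr_idx, , drop = FALSE]
    Xte <- X[-tr_idx, , drop = FALSE]
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      spec$seed <- stage_seed(seed, 1000L + o)   # same for identical specs
      lam <- spec$lambda
      if (spec$penalty != "none" && length(lambda_grid) > 1L) {
        lam_scores <- vapply(lambda_grid, function(lambda) {
          s2 <- spec; s2$lambda <- lambda
          vals <- vapply(seq_len(cv_plan$inner), function(i) {
            set.seed(stage_seed(seed, 2000L + o * 100L + i))
            vi <- sample(nrow(Xtr), max(1L, round(0.1 * nrow(Xtr))))
            m <- train_autoencoder(s2, Xtr[-vi, , drop = FALSE],
                                   Xtr[vi, , drop = FALSE])
            explained_variance_score(Xtr[vi, , drop = FALSE],
                                     reconstruct(m, Xtr[vi, , drop = FALSE]))
          }, numeric(1))
          mean(vals)
        }, numeric(1))
        lam <- lambda_grid[which.max(lam_scores)]
      }
      spec$lambda <- lam
      chosen[o, si] <- lam
      model <- train_autoencoder(spec, Xtr)
      Xhat <- reconstruct(model, Xte)
      maes[o, si] <- reconstruction_mae(Xte, Xhat)
      scores[o, si] <- 1 - maes[o, si]
    }
  }
  nparams <- vapply(seq_along(specs), function(si) {
    count_params(build_autoencoder(specs[[si]], ncol(X)))
  }, numeric(1))
  tab <- data.frame(
    architecture = names(specs),
    mean_score = colMeans(scores),
    sd_score = apply(scores, 2L, stats::sd),
    mean_mae = colMeans(maes),
    sd_mae = apply(maes, 2L, stats::sd),
    n_params = nparams,
    row.names = NULL
  )
  winner <- tab$architecture[order(-tab$mean_score, tab$n_params)][1L]
  structure(list(table = tab, winner = winner, scores = scores, maes = maes,
                 chosen_lambda = chosen, folds = folds),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("architecture comparison (held-out explained-variance score):\n")
  print(x$table, digits = 4)
  cat("winner:", x$winner, "\n")
  invisible(x)
}
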