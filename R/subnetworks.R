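#' Per-subnetwork reconstruction importance
#'
#' One after another, each latent unit alone reconstructs the measured
#' volumes: the unit's activations are kept while all other units are fixed
#' at their training-set mean activation (not zero, since biases make zero
#' non-neutral), the result is decoded, and the explained-variance score is
#' computed. Units are ranked by descending score; the elbow is the position
#' of the largest drop between consecutive sorted scores.
#'
#' @param model trained `autoencoder_model` with stored `latent_means`.
#' @param X standardized matrix or `volume_matrix`.
#' @return a `subnetwork_ranking`: `$scores` (per unit), `$order` (descending),
#'   `$elbow`, `$full_model_score`, `$mean_predictor_score`.
#' @export
per_subnetwork_score <- function(model, X) {
  stopifnot(inherits(model, "autoencoder_model"))
  if (is.null(model$latent_means)) {
    abort_on("model_state_error", "model lacks training-set latent means")
  }
  X <- vm_values(X)
  H <- encode(model, X)
  K <- ncol(H)
  n <- nrow(H)
  base <- matrix(rep(model$latent_means, each = n), n, K)
  scores <- vapply(seq_len(K), function(k) {
    Hk <- base
    Hk[, k] <- H[, k]
    explained_variance_score(X, decode(model, Hk))
  }, numeric(1))
  names(scores) <- sprintf("unit_%02d", seq_len(K))
  ord <- order(scores, decreasing = TRUE)
  sorted <- scores[ord]
  drops <- sorted[-K] - sorted[-1L]
  elbow <- if (K > 1L) which.max(drops) else 1L
  full <- explained_variance_score(X, decode(model, H))
  mp <- explained_variance_score(X, decode(model, base))
  structure(list(scores = scores, order = ord, elbow = as.integer(elbow),
                 full_model_score = full, mean_predictor_score = mp),
            class = "subnetwork_ranking")
}

#' @export
print.subnetwork_ranking <- function(x, ...) {
  cat("per-subnetwork explained-variance scores (descending):\n")
  print(round(x$scores[x$order], 4))
  cat(sprintf("elbow after rank %d; full model %.4f\n", x$elbow, x$full_model_score))
  invisible(x)
}

# linear map from bottleneck to output: product of decoder weight matrices.
# Exact for identity activations; a linearization (ReLU gating ignored) for
# non-linear decoders.
decoder_map <- function(model) {
  L <- length(model$weights)
  M <- model$weights[[model$bottleneck_layer + 1L]]
  l <- model$bottleneck_layer + 2L
  while (l <= L) {
    M <- model$weights[[l]] %*% M
    l <- l + 1L
  }
  M  # R x K
}

encoder_map <- function(model) {
  M <- model$weights[[1L]]
  l <- 2L
  while (l <= model$bottleneck_layer) {
    M <- model$weights[[l]] %*% M
    l <- l + 1L
  }
  M  # K x R
}

#' Region-relevance matrix of a trained model
#'
#' Row k is the signed pattern of decoder weights mapping latent unit k back
#' to the atlas regions — the subnetwork attached to that unit. Signs are
#' aligned so each row's largest-magnitude entry is positive (latent signs are
#' arbitrary). `scale = "zscored"` additionally standardizes each row to mean
#' 0, SD 1. Encoder-side relevances are available via `side = "encoder"`.
#'
#' @param model trained `autoencoder_model`.
#' @param scale `"raw_decoder"` or `"zscored"`.
#' @param side `"decoder"` (default) or `"encoder"`.
#' @param region_names optional column names.
#' @return a `subnetwork_relevance`: `$matrix` (K x R), `$scale`, `$sign_convention`.
#' @export
relevance_matrix <- function(model, scale = c("raw_decoder", "zscored"),
                             side = c("decoder", "encoder"),
                             region_names = NULL) {
  scale <- match.arg(scale)
  side <- match.arg(side)
  M <- if (side == "decoder") t(decoder_map(model)) else encoder_map(model)
  for (k in seq_len(nrow(M))) {
    if (M[k, which.max(abs(M[k, ]))] < 0) M[k, ] <- -M[k, ]
  }
  if (scale == "zscored") {
    M <- t(apply(M, 1L, function(r) (r - mean(r)) / pop_sd(r)))
  }
  rownames(M) <- sprintf("unit_%02d", seq_len(nrow(M)))
  if (!is.null(region_names)) colnames(M) <- region_names
  structure(list(matrix = M, scale = scale,
                 sign_convention = "max-|weight| entry positive", side = side),
            class = "subnetwork_relevance")
}

rel_matrix <- function(x) {
  if (inherits(x, "subnetwork_relevance")) x$matrix else as.matrix(x)
}

#' Match subnetworks across two models and correlate them
#'
#' Latent units have arbitrary order and sign, so stability is assessed after
#' an optimal bijective matching: the assignment of rows of `A` to rows of `B`
#' maximizing the total absolute Pearson correlation across the region
#' profiles. Reports the mean and SD of matched `|rho|`. With `n_null > 0`,
#' a permutation null (region labels of `B` shuffled) quantifies how much the
#' matched mean is inflated by selection.
#'
#' @param A,B `subnetwork_relevance` objects (or K x R matrices) with equal
#'   dimensions.
#' @param n_null number of region-shuffling null replicates (0 = none).
#' @param seed seed for the null.
#' @return a `stability_report`: `$mean_abs_rho`, `$sd_abs_rho`, `$rhos`,
#'   `$matching` (columns of `B` assigned to rows of `A`), `$null_mean`.
#' @export
match_and_correlate <- function(A, B, n_null = 0, seed = 1) {
  A <- rel_matrix(A); B <- rel_matrix(B)
  if (!identical(dim(A), dim(B))) {
    abort_on("shape_mismatch_error", "relevance matrices must share dimensions")
  }
  matched_stats <- function(Bm) {
    cors <- abs(stats::cor(t(A), t(Bm)))
    perm <- solve_assignment(1 - cors)
    rhos <- cors[cbind(seq_len(nrow(A)), perm)]
    list(perm = perm, rhos = rhos)
  }
  m <- matched_stats(B)
  null_mean <- NA_real_
  if (n_null > 0) {
    set.seed(stage_seed(seed, 5L))
    null_mean <- mean(vapply(seq_len(n_null), function(b) {
      mean(matched_stats(B[, sample(ncol(B)), drop = FALSE])$rhos)
    }, numeric(1)))
  }
  structure(list(mean_abs_rho = mean(m$rhos), sd_abs_rho = stats::sd(m$rhos),
                 rhos = m$rhos, matching = m$perm, null_mean = null_mean),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("matched subnetworks: mean |rho| = %.3f (SD %.3f)\n",
              x$mean_abs_rho, x$sd_abs_rho))
  if (!is.na(x$null_mean)) cat(sprintf("permutation-null mean |rho| = %.3f\n", x$null_mean))
  invisible(x)
}

#' Cluster-level aggregate relevance
#'
#' Entry (c, k) is the average absolute relevance over all regions belonging
#' to cluster c for subnetwork k — the functional-cluster summary of each
#' subnetwork.
#'
#' @param rel a `subnetwork_relevance` (or K x R matrix) in atlas region order.
#' @param atlas the matching `social_brain_atlas`.
#' @return 4 x K matrix (clusters x subnetworks).
#' @export
cluster_relevance <- function(rel, atlas) {
  M <- rel_matrix(rel)
  if (ncol(M) != n_regions(atlas)) {
    abort_on("shape_mismatch_error", "relevance columns must match atlas regions")
  }
  G <- cluster_membership_matrix(atlas)
  out <- (G %*% t(abs(M))) / rowSums(G)
  colnames(out) <- rownames(M)
  out
}

#' Run one unsupervised decomposition (train + analytics)
#'
#' Convenience carrier for replication analyses: splits rows into train/test,
#' fits the given architecture (or the closed-form linear oracle when
#' `spec = "oracle"`), and computes the held-out score, region relevances and
#' per-subnetwork ranking.
#'
#' @param X standardized matrix or `volume_matrix`.
#' @param spec an `autoencoder_spec`, or `"oracle"` with `k` latent units.
#' @param k bottleneck width for the oracle backend.
#' @param holdout fraction of rows held out for scoring.
#' @param seed integer seed.
#' @return a `decomposition_run`: `$model`, `$score`, `$relevance`, `$ranking`.
#' @export
run_decomposition <- function(X, spec = "oracle", k = 15, holdout = 0.5, seed = 1) {
  X <- vm_values(X)
  set.seed(stage_seed(seed, 21L))
  te <- sample(nrow(X), max(1L, round(holdout * nrow(X))))
  Xtr <- X[-te, , drop = FALSE]
  Xte <- X[te, , drop = FALSE]
  if (identical(spec, "oracle")) {
    model <- closed_form_linear_ae(Xtr, k)
    arch <- list(activation = "identity", latent_layers = k, penalty = "none",
                 method = "pca_oracle")
  } else {
    spec$seed <- stage_seed(seed, 22L)
    model <- train_autoencoder(spec, Xtr)
    arch <- list(activation = spec$activation, latent_layers = spec$latent_layers,
                 penalty = spec$penalty, method = "gradient")
  }
  structure(list(
    model = model, architecture = arch,
    score = explained_variance_score(Xte, reconstruct(model, Xte)),
    relevance = relevance_matrix(model, region_names = colnames(X)),
    ranking = per_subnetwork_score(model, Xte)
  ), class = "decomposition_run")
}

#' Compare two decomposition runs
#'
#' For runs of the same architecture on (typically row-disjoint) data:
#' matches and correlates their relevance matrices and reports the held-out
#' score difference — the replication check that solutions agree across
#' independent splits.
#'
#' @param run_a,run_b `decomposition_run` objects.
#' @param ... passed to [match_and_correlate()].
#' @return list with `$stability` (a `stability_report`) and `$score_delta`.
#' @export
compare_runs <- function(run_a, run_b, ...) {
  stopifnot(inherits(run_a, "decomposition_run"),
            inherits(run_b, "decomposition_run"))
  if (!identical(run_a$architecture, run_b$architecture)) {
    abort_on("config_mismatch_error", "runs use different architectures")
  }
  if (!identical(dim(rel_matrix(run_a$relevance)), dim(rel_matrix(run_b$relevance)))) {
    abort_on("config_mismatch_error", "runs have different latent dimensions")
  }
  list(stability = match_and_correlate(run_a$relevance, run_b$relevance, ...),
       score_delta = run_a$score - run_b$score)
}
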