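test_that("assignment solver is optimal (brute-force oracle)", {
  set.seed(3)
  for (i in 1:15) {
    n <- sample(2:5, 1)
    C <- matrix(runif(n * n), n)
    p <- solve_assignment(C)
    expect_true(all(sort(p) == seq_len(n)))
    best <- min(vapply(all_perms(n), function(q) sum(C[cbind(1:n, q)]), numeric(1)))
    expect_equal(sum(C[cbind(1:n, p)]), best, tolerance = 1e-12)
  }
})

test_that("per-subnetwork scoring isolates the planted factor", {
  # single dominant factor: best unit carries (almost) the full model's score
  sp <- synthetic_spec(n_participants = 1000, n_factors = 1, support_size = 36,
                       variances = 4, noise_sd = 0.01, orthonormal = TRUE,
                       n_traits = 1, trait_effects = matrix(0, 1, 1),
                       sex_effects = 0, seed = 31)
  ds <- simulate_volumes(sp)
  # generative scale: z-scoring would inflate near-zero-loading regions to
  # unit variance and blur the planted rank-1 structure
  X <- ds$volumes$values
  m <- closed_form_linear_ae(X, 3)
  r <- per_subnetwork_score(m, X)
  best <- which.max(r$scores)
  expect_equal(unname(r$scores[best]), r$full_model_score, tolerance = 0.02)
  expect_equal(unname(r$scores[-best]),
               rep(r$mean_predictor_score, 2), tolerance = 0.02)
  expect_equal(r$order[1], as.integer(best))
  expect_true(r$elbow >= 1 && r$elbow <= 3)
  # keeping one unit never beats the full model
  expect_lte(max(r$scores), r$full_model_score + 1e-8)
  # missing training means is a model-state error
  m2 <- m; m2$latent_means <- NULL
  expect_error(per_subnetwork_score(m2, vz), class = "model_state_error")
})

test_that("relevance rows are sign-aligned and optionally z-scored", {
  out <- standardized_synthetic(n = 400, noise_sd = 0.2, seed = 32, K = 6)
  m <- closed_form_linear_ae(out$X, 6)
  rel <- relevance_matrix(m)
  # flipping a decoder column leaves the relevance row unchanged
  mf <- m
  mf$weights[[2]][, 3] <- -mf$weights[[2]][, 3]
  mf$weights[[1]][3, ] <- -mf$weights[[1]][3, ]
  expect_equal(relevance_matrix(mf)$matrix, rel$matrix, tolerance = 1e-12)
  # z-scored rows have mean 0, population SD 1
  relz <- relevance_matrix(m, scale = "zscored")
  expect_equal(unname(rowMeans(relz$matrix)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(relz$matrix, 1,
                            function(r) sqrt(mean((r - mean(r))^2)))),
               rep(1, 6), tolerance = 1e-10)
  # encoder-side variant has the same shape
  expect_equal(dim(relevance_matrix(m, side = "encoder")$matrix), c(6L, 36L))
})

test_that("matching undoes permutations and sign flips; noise stays near null", {
  set.seed(33)
  A <- matrix(rnorm(15 * 36), 15, 36)
  self <- match_and_correlate(A, A)
  expect_equal(self$mean_abs_rho, 1, tolerance = 1e-12)
  expect_equal(self$matching, 1:15)
  perm <- sample(15)
  B <- A[perm, ] * sample(c(-1, 1), 15, replace = TRUE)
  undone <- match_and_correlate(A, B)
  expect_equal(undone$mean_abs_rho, 1, tolerance = 1e-12)
  expect_equal(undone$matching, match(1:15, perm))
  # independent noise: matched mean is modest and a null mean is reported
  N <- matrix(rnorm(15 * 36), 15, 36)
  noisy <- match_and_correlate(A, N, n_null = 20, seed = 2)
  expect_lt(noisy$mean_abs_rho, 0.6)
  expect_true(is.finite(noisy$null_mean))
  expect_lt(abs(noisy$mean_abs_rho - noisy$null_mean), 0.15)
  expect_error(match_and_correlate(A, N[, 1:10]), class = "shape_mismatch_error")
})

test_that("cluster aggregation averages absolute relevances", {
  atlas <- load_atlas("default")
  K <- 5
  const <- matrix(0.1, K, 36)
  agg <- cluster_relevance(const, atlas)
  expect_equal(unname(agg), matrix(0.1, 4, K))
  # single relevant region in a cluster of size m -> 1/m, others 0
  sizes <- table(factor(atlas$regions$cluster, levels = ATLAS_CLUSTERS))
  single <- matrix(0, K, 36)
  single[1, 7] <- 1  # region 7 is in the limbic cluster of the default fixture
  agg2 <- cluster_relevance(single, atlas)
  expect_equal(as.numeric(agg2["limbic", 1]), 1 / as.numeric(sizes["limbic"]))
  expect_equal(sum(agg2[, 1] > 0), 1L)
  # invariant to sign flips
  flip <- single; flip[1, 7] <- -1
  expect_equal(cluster_relevance(flip, atlas), agg2)
  # aggregation consistency: size-weighted row sums recover the global mean
  set.seed(34)
  R <- matrix(rnorm(K * 36), K, 36)
  agg3 <- cluster_relevance(R, atlas)
  szs <- as.numeric(sizes[rownames(agg3)])
  expect_equal(drop(szs %*% agg3) / 36, rowMeans(abs(R)), tolerance = 1e-12)
})

test_that("compare_runs checks architecture compatibility and self-agrees", {
  out <- standardized_synthetic(n = 400, noise_sd = 0.3, seed = 35, K = 6)
  r1 <- run_decomposition(out$X, "oracle", k = 6, seed = 1)
  cmp <- compare_runs(r1, r1)
  expect_equal(cmp$stability$mean_abs_rho, 1, tolerance = 1e-12)
  expect_equal(cmp$score_delta, 0)
  r2 <- run_decomposition(out$X, "oracle", k = 4, seed = 1)
  expect_error(compare_runs(r1, r2), class = "config_mismatch_error")
})
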