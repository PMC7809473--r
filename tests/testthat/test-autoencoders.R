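test_that("spec validation and model shapes follow the architecture family", {
  expect_error(autoencoder_spec("relu", c(25, 15), tied_weights = TRUE),
               class = "spec_error")
  expect_error(autoencoder_spec(lambda = -1), class = "spec_error")
  m <- build_autoencoder(autoencoder_spec("identity", 15), 36)
  expect_equal(dim(m$weights[[1]]), c(15L, 36L))
  expect_equal(dim(m$weights[[2]]), c(36L, 15L))
  m5 <- build_autoencoder(autoencoder_spec("relu", c(25, 20, 15, 20, 25)), 36)
  expect_equal(m5$widths, c(36, 25, 20, 15, 20, 25, 36))
  expect_equal(m5$bottleneck_layer, 3L)
  # seeded initialization is reproducible
  s <- autoencoder_spec("relu", 15, seed = 42)
  expect_identical(build_autoencoder(s, 36)$weights,
                   build_autoencoder(s, 36)$weights)
  # tied models start with decoder = t(encoder)
  mt <- build_autoencoder(autoencoder_spec("relu", 15, tied_weights = TRUE), 12)
  expect_identical(mt$weights[[2]], t(mt$weights[[1]]))
})

test_that("MAE and score behave as defined", {
  set.seed(1)
  X <- matrix(rnorm(200), 20, 10)
  expect_equal(reconstruction_mae(X, X), 0)
  expect_equal(reconstruction_mae(X, X + 0.5), 0.5)
  expect_equal(explained_variance_score(X, X), 1)
  expect_equal(explained_variance_score(X, X + 0.5), 0.5)
  # score = 1 - MAE always
  for (i in 1:5) {
    Y <- X + matrix(rnorm(200, sd = i / 5), 20, 10)
    expect_equal(explained_variance_score(X, Y), 1 - reconstruction_mae(X, Y))
  }
  # E|Z| for the zero predictor on standard normal data
  Z <- matrix(rnorm(5000 * 36), 5000, 36)
  expect_equal(reconstruction_mae(Z, 0 * Z), sqrt(2 / pi), tolerance = 0.01)
  expect_error(reconstruction_mae(X, X[, 1:3]), class = "shape_mismatch_error")
})

test_that("training loss decomposes into reconstruction plus penalty", {
  set.seed(2)
  X <- matrix(rnorm(50 * 6), 50, 6)
  m <- build_autoencoder(autoencoder_spec("identity", 3, seed = 3), 6)
  fw_loss <- training_loss(m, X)
  expect_equal(fw_loss, mean((X - reconstruct(m, X))^2))
  # xcov hand value: two perfectly correlated unit-variance latents -> 1
  m2 <- build_autoencoder(autoencoder_spec("identity", 2, penalty = "xcov",
                                           lambda = 1, seed = 1), 2)
  m2$weights[[1]] <- diag(2)
  m2$biases[[1]] <- c(0, 0)
  z <- rnorm(200)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))  # population variance 1
  Xc <- cbind(z, z)
  m0 <- m2; m0$spec$lambda <- 0
  expect_equal(training_loss(m2, Xc) - training_loss(m0, Xc), 1,
               tolerance = 1e-10)
  # exactly uncorrelated latents give zero xcov penalty
  z2 <- rnorm(200)
  z2 <- residuals(lm(z2 ~ z))
  z2 <- (z2 - mean(z2)) / sqrt(mean((z2 - mean(z2))^2))
  Xu <- cbind(z, z2)
  expect_equal(training_loss(m2, Xu) - training_loss(m0, Xu), 0,
               tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(4)
  X <- matrix(rnorm(8 * 6), 8, 6)
  cases <- list(
    autoencoder_spec("relu", c(5, 3, 5), penalty = "xcov", lambda = 0.3, seed = 4),
    autoencoder_spec("identity", 3, penalty = "l1", lambda = 0.2, seed = 5),
    autoencoder_spec("relu", 3, tied_weights = TRUE, penalty = "l2",
                     lambda = 0.1, seed = 6)
  )
  eps <- 1e-6
  for (spec in cases) {
    m <- build_autoencoder(spec, 6)
    g <- overlapnet:::ae_gradients(m, X)
    L <- length(m$weights)
    free <- if (spec$tied_weights) seq_len(L %/% 2) else seq_len(L)
    for (l in free) {
      set.seed(l)
      for (i in sample(length(m$weights[[l]]), 3)) {
        bump <- function(h) {
          mm <- m
          mm$weights[[l]][i] <- mm$weights[[l]][i] + h
          if (spec$tied_weights) mm <- overlapnet:::tie_decoder(mm)
          training_loss(mm, X)
        }
        num <- (bump(eps) - bump(-eps)) / (2 * eps)
        expect_equal(g$dW[[l]][i], num, tolerance = 1e-5,
                     info = paste(spec$name, "layer", l))
      }
      num_b <- sapply(seq_along(m$biases[[l]]), function(i) {
        mm1 <- m; mm1$biases[[l]][i] <- mm1$biases[[l]][i] + eps
        mm2 <- m; mm2$biases[[l]][i] <- mm2$biases[[l]][i] - eps
        (training_loss(mm1, X) - training_loss(mm2, X)) / (2 * eps)
      })
      expect_equal(g$db[[l]], num_b, tolerance = 1e-5)
    }
  }
})

test_that("the baseline autoencoder learns noise-free rank-15 data", {
  out <- standardized_synthetic(n = 500, noise_sd = 0, seed = 7)
  spec <- autoencoder_spec("identity", 15, max_epochs = 2000, patience = 100,
                           seed = 2)
  m <- train_autoencoder(spec, out$X[1:400, ], out$X[401:500, ])
  score <- explained_variance_score(out$X[401:500, ],
                                    reconstruct(m, out$X[401:500, ]))
  expect_gte(score, 0.99)
  expect_true(m$trained)
  expect_equal(length(m$latent_means), 15L)
  # training log records both losses and the run is seed-reproducible
  expect_true(all(c("train_loss", "val_loss") %in% names(m$log)))
  m2 <- train_autoencoder(spec, out$X[1:400, ], out$X[401:500, ])
  expect_identical(m$weights, m2$weights)
})

test_that("an overwhelming l1 penalty collapses weights to the mean predictor", {
  out <- standardized_synthetic(n = 300, noise_sd = 0.5, seed = 8)
  spec <- autoencoder_spec("identity", 15, penalty = "l1", lambda = 1000,
                           max_epochs = 150, patience = 150, seed = 3)
  m <- train_autoencoder(spec, out$X[1:240, ], out$X[241:300, ])
  expect_lt(max(abs(unlist(m$weights))), 0.05)
  held <- out$X[241:300, ]
  score <- explained_variance_score(held, reconstruct(m, held))
  mean_pred <- explained_variance_score(
    held, matrix(rep(colMeans(out$X[1:240, ]), each = nrow(held)), nrow(held)))
  expect_equal(score, mean_pred, tolerance = 0.05)
})

test_that("tied ReLU training keeps decoder = t(encoder) exactly", {
  out <- standardized_synthetic(n = 200, noise_sd = 0.3, seed = 9, K = 5)
  spec <- autoencoder_spec("relu", 15, tied_weights = TRUE, max_epochs = 40,
                           patience = 40, seed = 4)
  m <- train_autoencoder(spec, out$X[1:160, ], out$X[161:200, ])
  expect_identical(m$weights[[2]], t(m$weights[[1]]))
})

test_that("the closed-form linear autoencoder is exact and dominant", {
  out <- standardized_synthetic(n = 300, noise_sd = 0, seed = 10, K = 8)
  m <- closed_form_linear_ae(out$X, 8)
  expect_equal(reconstruct(m, out$X), unname(out$X), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(explained_variance_score(out$X, reconstruct(m, out$X)), 1,
               tolerance = 1e-9)
  # k = R: identity map
  set.seed(5)
  X <- matrix(rnorm(100 * 6), 100, 6)
  mid <- closed_form_linear_ae(X, 6)
  expect_equal(reconstruct(mid, X), X, tolerance = 1e-10)
  # rank error when the covariance cannot support k
  low <- matrix(rnorm(50 * 2), 50, 2) %*% matrix(rnorm(2 * 6), 2, 6)
  expect_error(closed_form_linear_ae(low, 5), class = "rank_error")
  expect_error(closed_form_linear_ae(X[1:3, ], 5), class = "rank_error")
})

test_that("encoding is affine for identity models and respects degenerate weights", {
  m <- build_autoencoder(autoencoder_spec("identity", 4, seed = 11), 10)
  set.seed(6)
  X1 <- matrix(rnorm(50), 5, 10); X2 <- matrix(rnorm(50), 5, 10)
  a <- 0.3
  expect_equal(encode(m, a * X1 + (1 - a) * X2),
               a * encode(m, X1) + (1 - a) * encode(m, X2), tolerance = 1e-12)
  mz <- m
  mz$weights[[1]][] <- 0
  mz$biases[[1]] <- 1:4
  expect_equal(encode(mz, X1),
               matrix(rep(1:4, each = 5), 5, 4), tolerance = 1e-15)
})

test_that("architecture comparison reports deterministic per-spec results", {
  out <- standardized_synthetic(n = 200, noise_sd = 0.5, seed = 12, K = 5)
  fast <- function(...) autoencoder_spec(..., max_epochs = 30, patience = 30)
  specs <- list(baseline = fast("identity", 15),
                baseline_dup = fast("identity", 15))
  rep <- compare_architectures(specs, out$X, cv_plan = list(outer = 2, inner = 2),
                               seed = 5)
  expect_equal(nrow(rep$table), 2L)
  expect_true(all(rep$table$sd_score >= 0))
  # identical duplicated specs get identical seeds, hence identical rows
  expect_equal(rep$table$mean_score[1], rep$table$mean_score[2])
  expect_equal(rep$scores[, 1], rep$scores[, 2])
  expect_equal(rep$table$mean_mae, 1 - rep$table$mean_score)
  expect_error(compare_architectures(specs, out$X,
                                     cv_plan = list(outer = 1, inner = 2)),
               class = "spec_error")
})
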