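test_that("trait dichotomization follows the median-split and tie rules", {
  d <- dichotomize_trait(c(1, 2, 3, 4))
  expect_equal(d$median, 2.5)
  expect_equal(d$more, c(0L, 0L, 1L, 1L))
  d2 <- dichotomize_trait(c(1, 2, 2, 3))
  expect_equal(d2$median, 2)
  expect_equal(d2$more, c(0L, 0L, 0L, 1L))   # ties at the median fall to less
  d3 <- dichotomize_trait(c(0, 1, 1, 0))
  expect_true(d3$binary)
  expect_equal(d3$more, c(0L, 1L, 1L, 0L))
  d4 <- dichotomize_trait(c(0, 1, 0), already_binary = TRUE, positive_value = 0)
  expect_equal(d4$more, c(1L, 0L, 1L))
  expect_error(dichotomize_trait(rep(2, 5)), class = "constant_trait_error")
})

test_that("four-class labels cross sex with sociality and invert", {
  sex <- c(1, 1, 1, 1, 0, 0, 0, 0)
  more <- c(1, 1, 0, 0, 1, 1, 0, 0)
  lab <- make_four_class_labels(sex, more, "toy")
  expect_equal(unname(as.numeric(lab$counts)), rep(2, 4))
  back <- four_class_to_components(lab)
  expect_equal(back$sex, sex)
  expect_equal(back$more, more)
  expect_warning(make_four_class_labels(c(1, 1), c(0, 1)), "empty class")
  expect_error(make_four_class_labels(c(1, 0), c(1, 0, 1)),
               class = "length_mismatch_error")
})

test_that("nested CV classification is deterministic and beats chance when separable", {
  set.seed(8)
  n <- 400
  Z <- matrix(rnorm(n * 4), n, 4)
  lab <- make_four_class_labels(as.integer(Z[, 1] > 0), as.integer(Z[, 2] > 0),
                                "separable")
  age <- runif(n, 45, 80)
  plan <- list(outer = 2, inner = 2)
  r1 <- nested_cv_classify(Z, age, lab, cv_plan = plan, seed = 3)
  r2 <- nested_cv_classify(Z, age, lab, cv_plan = plan, seed = 3)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$weights, r2$weights)
  expect_gt(r1$mean_accuracy, 0.8)
  expect_equal(r1$chance, 0.25)
  expect_true(all(r1$accuracies >= 0 & r1$accuracies <= 1))
  expect_equal(dim(r1$weight_mean), c(4L, 6L))  # 4 classes x (intercept + 4 + age)
  # forest estimator on the same folds also finds the separable structure
  rf <- nested_cv_classify(Z, age, lab, estimator = "random_forest",
                           grids = list(random_forest =
                                          data.frame(maxdepth = 6, minsplit = 2,
                                                     minbucket = 2)),
                           cv_plan = plan, seed = 3, n_trees = 20)
  expect_gt(rf$mean_accuracy, 0.6)
  expect_null(rf$weights)
})

test_that("chance level is analytic 1/K and permutation-calibrated", {
  lab <- make_four_class_labels(rep(c(1, 0), each = 40),
                                rep(c(1, 0, 1, 0), each = 20), "toy")
  ch <- chance_level(lab)
  expect_equal(ch$chance, 0.25)
  expect_equal(ch$majority, 0.25)
  two <- factor(rep(c("a", "b"), 10))
  expect_equal(chance_level(two)$chance, 0.5)
  # permutation mode on null features covers the analytic value (scaled down:
  # 25 permutations, 2x2 CV, single-lambda grid)
  set.seed(9)
  n <- 240
  Z <- matrix(rnorm(n * 3), n, 3)
  lab2 <- make_four_class_labels(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), "null")
  perm <- chance_level(lab2, mode = "permutation", n_perm = 25, seed = 4,
                       embeddings = Z, age = runif(n, 45, 80),
                       cv_plan = list(outer = 2, inner = 2),
                       grids = list(logistic_l2 = 1))
  expect_true(perm$ci[1] <= 0.25 && 0.25 <= perm$ci[2])
})

test_that("weight summaries aggregate across traits and recover specificity", {
  set.seed(10)
  n <- 600
  wins <- 0L
  for (s in 1:5) {
    set.seed(s)
    Z <- matrix(rnorm(n * 4), n, 4)
    sex <- rbinom(n, 1, 0.5)
    age <- runif(n, 45, 80)
    yA <- rbinom(n, 1, plogis(2.5 * Z[, 1]))
    yB <- rbinom(n, 1, plogis(2.5 * Z[, 2]))
    reps <- list(
      A = nested_cv_classify(Z, age, make_four_class_labels(sex, yA, "A"),
                             cv_plan = list(outer = 2, inner = 2),
                             grids = list(logistic_l2 = 0.01), seed = s),
      B = nested_cv_classify(Z, age, make_four_class_labels(sex, yB, "B"),
                             cv_plan = list(outer = 2, inner = 2),
                             grids = list(logistic_l2 = 0.01), seed = s))
    sw <- summarize_weights(reps)
    pt <- sw$per_trait
    f1 <- pt[pt$feature == "unit_01", ]
    a1 <- mean(abs(f1$mean_weight[f1$trait == "A"]))
    b1 <- mean(abs(f1$mean_weight[f1$trait == "B"]))
    if (a1 > b1) wins <- wins + 1L
  }
  expect_gte(wins, 3L)  # factor-1 weight is specific to the factor-1 trait
  # degenerate single-trait summary has zero across-trait SD
  single <- summarize_weights(reps["A"])
  expect_true(all(single$across_traits$sd_weight == 0))
  # forests carry no linear weights
  Zs <- matrix(rnorm(200 * 3), 200, 3)
  labs <- make_four_class_labels(rbinom(200, 1, .5), rbinom(200, 1, .5), "f")
  rf <- nested_cv_classify(Zs, runif(200, 45, 80), labs,
                           estimator = "random_forest",
                           grids = list(random_forest =
                                          data.frame(maxdepth = 2, minsplit = 2,
                                                     minbucket = 2)),
                           cv_plan = list(outer = 2, inner = 2), seed = 1,
                           n_trees = 5)
  expect_error(summarize_weights(list(rf)), class = "estimator_error")
})

test_that("the bagged forest separates axis-aligned classes", {
  set.seed(11)
  X <- matrix(rnorm(300 * 3), 300, 3)
  y <- as.integer(X[, 2] > 0.2)
  f <- fit_forest(X, y, n_trees = 30, maxdepth = 6, seed = 2)
  p <- predict_forest(f, X)
  expect_gt(mean((p > 0.5) == (y == 1)), 0.9)
  expect_error(predict_forest(f, X[, 1:2]), class = "shape_mismatch_error")
})
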