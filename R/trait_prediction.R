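#' Dichotomize a social trait into more/less social
#'
#' Continuous traits are split at the full-sample median: strictly greater
#' than the median is "more social", ties at the median fall to "less".
#' Already-binary traits pass through with their stated polarity.
#'
#' @param values per-participant trait values.
#' @param already_binary force binary passthrough; `NULL` auto-detects values
#'   confined to \{0, 1\}.
#' @param positive_value for binary traits, the value meaning "more social".
#' @return list with `more` (0/1 integer vector), `median` (NA for binary),
#'   `tie_rule`, `binary`.
#' @export
dichotomize_trait <- function(values, already_binary = NULL, positive_value = 1) {
  if (length(unique(values)) < 2L) {
    abort_on("constant_trait_error", "trait has fewer than 2 distinct values")
  }
  if (is.null(already_binary)) already_binary <- all(values %in% c(0, 1))
  if (already_binary) {
    return(list(more = as.integer(values == positive_value), median = NA_real_,
                tie_rule = "binary_passthrough", binary = TRUE))
  }
  med <- stats::median(values)
  list(more = as.integer(values > med), median = med,
       tie_rule = "ties_less", binary = FALSE)
}

FOUR_CLASSES <- c("female_more", "female_less", "male_more", "male_less")

#' Build the four-class sex-by-sociality labels
#'
#' Crosses sex (1 = female, 0 = male) with the more/less-social
#' dichotomization into the four prediction targets. Empty classes are
#' tolerated with a warning (one-vs-rest training still proceeds).
#'
#' @param sex 0/1 vector, 1 = female.
#' @param more_less 0/1 vector (1 = more social) or the result of
#'   [dichotomize_trait()].
#' @param trait_id label for reports.
#' @return a `four_class_labels`: `$labels` (factor with the four levels),
#'   `$trait_id`, `$median`, `$tie_rule`, `$counts`.
#' @export
make_four_class_labels <- function(sex, more_less, trait_id = "trait") {
  med <- NA_real_; tie <- "unknown"
  if (is.list(more_less)) {
    med <- more_less$median; tie <- more_less$tie_rule
    more_less <- more_less$more
  }
  if (length(sex) != length(more_less)) {
    abort_on("length_mismatch_error", "sex and more_less lengths differ")
  }
  lab <- paste0(ifelse(sex == 1L, "female", "male"), "_",
                ifelse(more_less == 1L, "more", "less"))
  labels <- factor(lab, levels = FOUR_CLASSES)
  counts <- table(labels)
  if (any(counts == 0)) {
    warning("empty class(es): ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  structure(list(labels = labels, trait_id = trait_id, median = med,
                 tie_rule = tie, counts = counts),
            class = "four_class_labels")
}

#' Invert four-class labels back to (sex, more/less)
#' @param labels a `four_class_labels` or factor with the four levels.
#' @return data frame with `sex` and `more` 0/1 columns.
#' @export
four_class_to_components <- function(labels) {
  f <- if (inherits(labels, "four_class_labels")) labels$labels else labels
  data.frame(sex = as.integer(grepl("^female", f)),
             more = as.integer(grepl("_more$", f)))
}

labels_factor <- function(labels) {
  if (inherits(labels, "four_class_labels")) return(labels$labels)
  if (is.factor(labels)) return(labels)
  factor(labels, levels = FOUR_CLASSES)
}

# stratified repeated half-split indices (training rows) for outer folds
outer_half_split <- function(y, seed) {
  set.seed(seed)
  tr <- integer(0)
  for (cl in levels(y)) {
    rows <- which(y == cl)
    if (length(rows) >= 2L) {
      tr <- c(tr, sample(rows, floor(length(rows) / 2)))
    } else if (length(rows) == 1L) {
      tr <- c(tr, rows)
    }
  }
  sort(tr)
}

# one-vs-rest ridge-logistic fit across a lambda grid; returns per-class
# glmnet fits (x must already be standardized)
fit_ovr_logistic <- function(x, y, lambda_grid) {
  lam <- sort(lambda_grid, decreasing = TRUE)
  fits <- lapply(levels(y), function(cl) {
    yc <- as.integer(y == cl)
    glmnet::glmnet(x, yc, family = "binomial", alpha = 0, lambda = lam,
                   standardize = FALSE)
  })
  names(fits) <- levels(y)
  list(fits = fits, lambda = lam)
}

predict_ovr_logistic <- function(ovr, x, lambda) {
  scores <- vapply(ovr$fits, function(f) {
    drop(stats::predict(f, newx = x, s = lambda, type = "link", exact = FALSE))
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  factor(names(ovr$fits)[max.col(scores, ties.method = "first")],
         levels = names(ovr$fits))
}

fit_ovr_forest <- function(x, y, params, n_trees, seed) {
  fits <- lapply(seq_along(levels(y)), function(i) {
    cl <- levels(y)[i]
    fit_forest(x, as.integer(y == cl), n_trees = n_trees,
               maxdepth = params$maxdepth, minsplit = params$minsplit,
               minbucket = params$minbucket, seed = seed + i)
  })
  names(fits) <- levels(y)
  fits
}

predict_ovr_forest <- function(fits, x) {
  probs <- vapply(fits, function(f) predict_forest(f, x), numeric(nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  factor(names(fits)[max.col(probs, ties.method = "first")], levels = names(fits))
}

default_grids <- function() {
  list(logistic_l2 = 10^seq(-3, 3, length.out = 7),
       random_forest = expand.grid(maxdepth = c(2, 6), minsplit = c(2, 6),
                                   minbucket = c(2, 6)))
}

#' Nested cross-validated one-vs-rest trait classification
#'
#' Predicts the four sex-by-sociality classes from the 15 subnetwork
#' expressions plus standardized age. Outer folds are repeated stratified
#' 50/50 train/test splits; hyperparameters (the l2 penalty over
#' `10^-3..10^3` in 7 log steps for the logistic estimator; depth/split/leaf
#' in \{2, 6\} for the forest) are chosen on inner 90/10 splits of the
#' training half only. Features are standardized on the outer-training rows
#' (no leakage), so logistic coefficients are comparable across subnetworks.
#'
#' @param embeddings n x K latent expression matrix.
#' @param age per-participant age vector.
#' @param labels a `four_class_labels` (or factor with the four levels).
#' @param estimator `"logistic_l2"` or `"random_forest"`.
#' @param grids optional hyperparameter grids (see `default_grids`).
#' @param cv_plan list with `outer` (default 5) and `inner` (default 10).
#' @param seed integer seed; fold structure is shared between estimators at
#'   equal seeds, enabling paired comparison.
#' @param n_trees forest size (default 100).
#' @return a `trait_prediction_report`: per-split accuracies, analytic chance,
#'   per-class weight means/SDs across splits (logistic), chosen
#'   hyperparameters per fold.
#' @export
nested_cv_classify <- function(embeddings, age, labels,
                               estimator = c("logistic_l2", "random_forest"),
                               grids = NULL, cv_plan = list(outer = 5, inner = 10),
                               seed = 1, n_trees = 100) {
  estimator <- match.arg(estimator)
  y <- labels_factor(labels)
  X <- cbind(as.matrix(embeddings), age = as.numeric(age))
  if (is.null(colnames(X)) || anyNA(colnames(X)) || colnames(X)[1] == "") {
    colnames(X) <- c(sprintf("unit_%02d", seq_len(ncol(X) - 1L)), "age")
  }
  colnames(X)[ncol(X)] <- "age"
  if (nrow(X) != length(y)) {
    abort_on("length_mismatch_error", "features and labels lengths differ")
  }
  if (is.null(grids)) grids <- default_grids()
  feat_names <- colnames(X)
  n_out <- cv_plan$outer
  acc <- numeric(n_out)
  chosen <- vector("list", n_out)
  weights <- if (estimator == "logistic_l2") {
    array(NA_real_, dim = c(n_out, nlevels(y), ncol(X) + 1L),
          dimnames = list(NULL, levels(y), c("(Intercept)", feat_names)))
  } else NULL
  for (o in seq_len(n_out)) {
    tr <- outer_half_split(y, stage_seed(seed, 40L + o))
    te <- setdiff(seq_along(y), tr)
    if (any(table(y[tr])[table(y) > 0] == 0)) {
      abort_on("class_imbalance_error",
               sprintf("outer fold %d has an empty training class", o))
    }
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- col_pop_sd(X[tr, , drop = FALSE])
    sdv[sdv < 1e-12] <- 1
    std <- function(M) sweep(sweep(M, 2L, mu), 2L, sdv, "/")
    Xtr <- std(X[tr, , drop = FALSE])
    Xte <- std(X[te, , drop = FALSE])
    ytr <- droplevels(y[tr])
    # inner hyperparameter selection on the training half only
    inner_val_acc <- function(fit_fun, pred_fun, n_settings) {
      accs <- matrix(NA_real_, cv_plan$inner, n_settings)
      for (i in seq_len(cv_plan$inner)) {
        set.seed(stage_seed(seed, 500L + o * 50L + i))
        vi <- sample(nrow(Xtr), max(1L, round(0.1 * nrow(Xtr))))
        yt <- droplevels(ytr[-vi])
        ft <- fit_fun(Xtr[-vi, , drop = FALSE], yt, i)
        for (s in seq_len(n_settings)) {
          pred <- pred_fun(ft, Xtr[vi, , drop = FALSE], s)
          accs[i, s] <- mean(as.character(pred) == as.character(ytr[vi]))
        }
      }
      colMeans(accs)
    }
    if (estimator == "logistic_l2") {
      grid <- grids$logistic_l2
      mean_acc <- inner_val_acc(
        function(x, yy, i) fit_ovr_logistic(x, yy, grid),
        function(f, x, s) predict_ovr_logistic(f, x, sort(grid, decreasing = TRUE)[s]),
        length(grid))
      best_lam <- sort(grid, decreasing = TRUE)[which.max(mean_acc)]
      chosen[[o]] <- list(lambda = best_lam)
      fit <- fit_ovr_logistic(Xtr, ytr, grid)
      pred <- predict_ovr_logistic(fit, Xte, best_lam)
      for (ci in seq_along(levels(y))) {
        cl <- levels(y)[ci]
        if (cl %in% names(fit$fits)) {
          co <- as.numeric(stats::coef(fit$fits[[cl]], s = best_lam))
          weights[o, ci, ] <- co
        }
      }
    } else {
      grid <- grids$random_forest
      inner_trees <- min(n_trees, 25L)  # saturated forests are wasteful inside the inner loop
      mean_acc <- inner_val_acc(
        function(x, yy, i) lapply(seq_len(nrow(grid)), function(s) {
          fit_ovr_forest(x, yy, as.list(grid[s, ]), inner_trees,
                         stage_seed(seed, 700L + o * 100L + i * 10L + s))
        }),
        function(f, x, s) predict_ovr_forest(f[[s]], x),
        nrow(grid))
      best <- as.list(grid[which.max(mean_acc), ])
      chosen[[o]] <- best
      fit <- fit_ovr_forest(Xtr, ytr, best, n_trees, stage_seed(seed, 800L + o))
      pred <- predict_ovr_forest(fit, Xte)
    }
    acc[o] <- mean(as.character(pred) == as.character(y[te]))
  }
  wm <- ws <- NULL
  if (!is.null(weights)) {
    wm <- apply(weights, c(2L, 3L), mean)
    ws <- apply(weights, c(2L, 3L), stats::sd)
  }
  structure(list(
    trait_id = if (inherits(labels, "four_class_labels")) labels$trait_id else "trait",
    estimator = estimator, accuracies = acc,
    mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
    chance = 1 / nlevels(y),
    majority_freq = max(table(y)) / length(y),
    weights = weights, weight_mean = wm, weight_sd = ws,
    chosen = chosen, feature_names = feat_names,
    cv_plan = cv_plan, seed = seed
  ), class = "trait_prediction_report")
}

#' @export
print.trait_prediction_report <- function(x, ...) {
  cat(sprintf("trait '%s' (%s): accuracy %.3f (SD %.3f) vs chance %.2f\n",
              x$trait_id, x$estimator, x$mean_accuracy, x$sd_accuracy, x$chance))
  invisible(x)
}

#' Summarize classifier weights across traits
#'
#' For linear (logistic) reports: per class and subnetwork, the mean and SD of
#' the weight across traits (the cross-trait profile), in both signed and
#' absolute form; and per trait, the per-class weights with SD across CV
#' splits. The age weight is reported per trait but excluded from the
#' subnetwork summary.
#'
#' @param reports list of `trait_prediction_report`s from the linear estimator.
#' @return list with `$across_traits` and `$per_trait` tidy data frames.
#' @export
summarize_weights <- function(reports) {
  if (inherits(reports, "trait_prediction_report")) reports <- list(reports)
  if (!length(reports)) abort_on("spec_error", "no reports supplied")
  for (r in reports) {
    if (r$estimator != "logistic_l2" || is.null(r$weight_mean)) {
      abort_on("estimator_error", "weight summaries need linear (logistic) reports")
    }
  }
  per_trait <- do.call(rbind, lapply(reports, function(r) {
    grid <- expand.grid(class = rownames(r$weight_mean),
                        feature = colnames(r$weight_mean),
                        stringsAsFactors = FALSE)
    data.frame(trait = r$trait_id, grid,
               mean_weight = as.vector(r$weight_mean),
               sd_weight = as.vector(r$weight_sd), row.names = NULL)
  }))
  sub <- per_trait[!per_trait$feature %in% c("(Intercept)", "age"), ]
  mean_signed <- stats::aggregate(mean_weight ~ class + feature, data = sub, FUN = mean)
  sd_signed <- stats::aggregate(mean_weight ~ class + feature, data = sub,
                                FUN = function(v) if (length(v) > 1) stats::sd(v) else 0)
  sub_abs <- transform(sub, mean_weight = abs(mean_weight))
  mean_abs <- stats::aggregate(mean_weight ~ class + feature, data = sub_abs, FUN = mean)
  sd_abs <- stats::aggregate(mean_weight ~ class + feature, data = sub_abs,
                             FUN = function(v) if (length(v) > 1) stats::sd(v) else 0)
  across <- data.frame(mean_signed[, c("class", "feature")],
                       mean_weight = mean_signed$mean_weight,
                       sd_weight = sd_signed$mean_weight,
                       mean_abs_weight = mean_abs$mean_weight,
                       sd_abs_weight = sd_abs$mean_weight)
  list(across_traits = across, per_trait = per_trait)
}

#' Chance level of a multiclass problem
#'
#' Analytic mode: the expected accuracy of a uniform-random classifier,
#' `1 / number of classes` (0.25 for the four-class scheme), plus the majority
#' class frequency as the trivial baseline. Permutation mode: the mean
#' accuracy of the full nested-CV estimator on label-shuffled data, with a
#' Monte-Carlo confidence interval.
#'
#' @param labels a `four_class_labels` or factor.
#' @param mode `"analytic"` or `"permutation"`.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @param embeddings,age features, required for permutation mode.
#' @param ... passed to [nested_cv_classify()] in permutation mode.
#' @return list with `chance` (and `majority`; for permutation also `ci` and
#'   `perm_accuracies`).
#' @export
chance_level <- function(labels, mode = c("analytic", "permutation"),
                         n_perm = 200, seed = 1, embeddings = NULL, age = NULL, ...) {
  mode <- match.arg(mode)
  y <- labels_factor(labels)
  if (mode == "analytic") {
    return(list(chance = 1 / nlevels(y), majority = max(table(y)) / length(y)))
  }
  if (is.null(embeddings) || is.null(age)) {
    abort_on("spec_error", "permutation mode needs embeddings and age")
  }
  accs <- vapply(seq_len(n_perm), function(b) {
    set.seed(stage_seed(seed, 9000L + b))
    yp <- y[sample(length(y))]
    rep <- nested_cv_classify(embeddings, age, yp, seed = stage_seed(seed, b), ...)
    rep$mean_accuracy
  }, numeric(1))
  list(chance = mean(accs),
       ci = unname(stats::quantile(accs, c(0.025, 0.975))),
       majority = max(table(y)) / length(y),
       perm_accuracies = accs)
}
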