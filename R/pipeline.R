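#' Build a validated pipeline run configuration
#'
#' One config fully determines a run: data mode (synthetic generation or
#' precomputed volumes/covariates CSVs), atlas choice, extraction and
#' z-scoring settings, the architecture list, the nested CV plan, prediction
#' settings, master seed and output directory. Configs round-trip through
#' JSON ([save_config()] / [load_config()]).
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param synthetic a `synthetic_spec` (synthetic mode).
#' @param volumes_csv,covariates_csv input paths (real mode): volumes CSV with
#'   a `participant_id` column plus one column per region; covariates CSV with
#'   `participant_id`, `sex`, `age` and one 0/1 column per trait.
#' @param atlas `"default"` or path to an atlas file.
#' @param extraction list: `fwhm`, `diameter` (mm), `zscore_scope`
#'   (`"train_only"`, the leakage-safe default, or `"global"`).
#' @param architectures character vector of [table2_architectures()] names, or
#'   `"oracle"` for the closed-form linear decomposition backend.
#' @param cv_plan list with `outer` and `inner`.
#' @param prediction list: `estimator`, `traits` (`"all"` or names),
#'   `n_trees`.
#' @param latent_dim bottleneck width K (default 15) used by the oracle
#'   backend and the replication runs.
#' @param train_control list overriding autoencoder training control
#'   (`max_epochs`, `batch_size`, `patience`).
#' @param seed master seed; per-stage seeds fan out deterministically.
#' @param outdir output directory.
#' @return a `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       synthetic = synthetic_spec(),
                       volumes_csv = NULL, covariates_csv = NULL,
                       atlas = "default",
                       extraction = list(fwhm = 5, diameter = 5,
                                         zscore_scope = "train_only"),
                       architectures = "oracle",
                       cv_plan = list(outer = 5, inner = 10),
                       prediction = list(estimator = "logistic_l2",
                                         traits = "all", n_trees = 100),
                       train_control = list(),
                       latent_dim = 15,
                       seed = 1, outdir = tempfile("overlapnet_run_")) {
  mode <- match.arg(mode)
  if (mode == "real" && (is.null(volumes_csv) || is.null(covariates_csv))) {
    abort_on("spec_error", "real mode requires volumes_csv and covariates_csv")
  }
  if (!extraction$zscore_scope %in% c("train_only", "global")) {
    abort_on("spec_error", "zscore_scope must be 'train_only' or 'global'")
  }
  structure(list(mode = mode, synthetic = synthetic,
                 volumes_csv = volumes_csv, covariates_csv = covariates_csv,
                 atlas = atlas, extraction = extraction,
                 architectures = architectures, cv_plan = cv_plan,
                 prediction = prediction, train_control = train_control,
                 latent_dim = as.integer(latent_dim),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_on("missing_file", paste("config not found:", path))
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  syn <- x$synthetic
  synthetic <- synthetic_spec(
    n_participants = syn$n_participants, n_regions = syn$n_regions,
    n_factors = syn$n_factors, support_size = syn$support_size,
    overlap = syn$overlap, hubs = syn$hubs, hub_factors = syn$hub_factors,
    variances = syn$variances, noise_sd = syn$noise_sd,
    latent_dist = syn$latent_dist, n_traits = syn$n_traits,
    trait_effects = matrix(unlist(syn$trait_effects), syn$n_factors, syn$n_traits),
    sex_effects = syn$sex_effects, age_range = syn$age_range,
    orthonormal = syn$orthonormal, region_names = syn$region_names,
    seed = syn$seed)
  run_config(mode = x$mode, synthetic = synthetic,
             volumes_csv = x$volumes_csv, covariates_csv = x$covariates_csv,
             atlas = x$atlas, extraction = x$extraction,
             architectures = x$architectures, cv_plan = x$cv_plan,
             prediction = x$prediction,
             train_control = as.list(x$train_control),
             latent_dim = x$latent_dim %||% 15,
             seed = x$seed, outdir = x$outdir)
}

load_real_inputs <- function(config) {
  for (p in c(config$volumes_csv, config$covariates_csv)) {
    if (!file.exists(p)) abort_on("missing_file", paste("input not found:", p))
  }
  vol <- utils::read.csv(config$volumes_csv, stringsAsFactors = FALSE)
  cov <- utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE)
  ids <- vol$participant_id
  vol$participant_id <- NULL
  vm <- volume_matrix(as.matrix(vol), participant_ids = ids)
  cov <- cov[match(ids, cov$participant_id), , drop = FALSE]
  list(volumes = vm, covariates = cov)
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full two-arm pipeline
#'
#' Executes, in order: data acquisition (synthetic simulation or CSV load),
#' z-scoring, unsupervised decomposition (architecture training/selection or
#' the closed-form oracle), subnetwork analytics (ranking, relevances, cluster
#' aggregates), and supervised trait prediction from the latent expressions.
#' All tables are written as CSV/JSON under `config$outdir`, plus a manifest
#' with content hashes; identical configs yield identical hashes.
#'
#' @param config a `run_config`.
#' @return a `run_manifest` (list) with stage outputs, file hashes and
#'   wall-times; the in-memory results are attached as `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage_times <- c()
  tic <- function() proc.time()[["elapsed"]]
  files <- character(0)

  # stage 1: atlas + data
  t0 <- tic()
  atlas <- load_atlas(config$atlas)
  if (config$mode == "synthetic") {
    spec <- config$synthetic
    spec$seed <- stage_seed(config$seed, 1L)
    if (spec$n_regions == n_regions(atlas)) spec$region_names <- region_names(atlas)
    ds <- simulate_traits(simulate_volumes(spec))
    vm_raw <- ds$volumes
    covariates <- ds$covariates
  } else {
    inputs <- load_real_inputs(config)
    vm_raw <- inputs$volumes
    covariates <- inputs$covariates
    ds <- NULL
  }
  files <- c(files, write_stage_csv(
    data.frame(participant_id = vm_raw$participant_ids, vm_raw$values,
               check.names = FALSE),
    config$outdir, "volumes_raw.csv"))
  stage_times["data"] <- tic() - t0

  # stage 2: z-scoring + decomposition split
  t0 <- tic()
  n <- nrow(vm_raw$values)
  set.seed(stage_seed(config$seed, 2L))
  train_idx <- sort(sample(n, floor(n / 2)))
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_vm <- function(vm, idx) volume_matrix(
    vm$values[idx, , drop = FALSE], regions = vm$regions,
    participant_ids = vm$participant_ids[idx])
  if (config$extraction$zscore_scope == "global") {
    scaler <- zscore_fit(vm_raw)
  } else {
    scaler <- zscore_fit(subset_vm(vm_raw, train_idx))
  }
  vm_z <- zscore_apply(vm_raw, scaler)
  Xtr <- vm_z$values[train_idx, , drop = FALSE]
  Xte <- vm_z$values[test_idx, , drop = FALSE]
  stage_times["zscore"] <- tic() - t0

  # stage 3: decomposition
  t0 <- tic()
  if (identical(config$architectures, "oracle")) {
    model <- closed_form_linear_ae(Xtr, min(config$latent_dim, ncol(Xtr) - 1L))
    fit_rep <- NULL
    winner <- "oracle"
  } else {
    ctrl <- config$train_control
    specs <- table2_architectures(
      max_epochs = ctrl$max_epochs %||% 500,
      batch_size = ctrl$batch_size %||% 128,
      patience = ctrl$patience %||% 20)[config$architectures]
    fit_rep <- compare_architectures(specs, Xtr, cv_plan = config$cv_plan,
                                     seed = stage_seed(config$seed, 3L))
    winner <- fit_rep$winner
    wspec <- specs[[winner]]
    wspec$seed <- stage_seed(config$seed, 33L)
    model <- train_autoencoder(wspec, Xtr)
    files <- c(files, write_stage_csv(fit_rep$table, config$outdir, "fit_report.csv"))
  }
  score <- explained_variance_score(Xte, reconstruct(model, Xte))
  stage_times["train"] <- tic() - t0

  # stage 4: subnetwork analytics
  t0 <- tic()
  ranking <- per_subnetwork_score(model, Xte)
  rel <- relevance_matrix(model, region_names = vm_z$regions)
  files <- c(files, write_stage_csv(
    data.frame(unit = names(ranking$scores), score = unname(ranking$scores)),
    config$outdir, "subnetwork_ranking.csv"))
  files <- c(files, write_stage_csv(
    data.frame(unit = rownames(rel$matrix), rel$matrix, check.names = FALSE),
    config$outdir, "relevance_matrix.csv"))
  if (ncol(rel$matrix) == n_regions(atlas)) {
    cl_rel <- cluster_relevance(rel, atlas)
    files <- c(files, write_stage_csv(
      data.frame(cluster = rownames(cl_rel), cl_rel, check.names = FALSE),
      config$outdir, "cluster_relevance.csv"))
  } else {
    cl_rel <- NULL
  }
  stage_times["subnetworks"] <- tic() - t0

  # stage 5: trait prediction
  t0 <- tic()
  trait_cols <- setdiff(names(covariates), c("participant_id", "sex", "age"))
  if (!identical(config$prediction$traits, "all")) {
    trait_cols <- intersect(trait_cols, config$prediction$traits)
  }
  H <- encode(model, vm_z$values)
  colnames(H) <- sprintf("unit_%02d", seq_len(ncol(H)))
  trait_reports <- list()
  for (tc in trait_cols) {
    d <- dichotomize_trait(covariates[[tc]])
    labels <- make_four_class_labels(covariates$sex, d, trait_id = tc)
    trait_reports[[tc]] <- nested_cv_classify(
      H, covariates$age, labels,
      estimator = config$prediction$estimator,
      cv_plan = config$cv_plan,
      seed = stage_seed(config$seed, 4L),
      n_trees = config$prediction$n_trees %||% 100)
  }
  if (length(trait_reports)) {
    acc_tab <- data.frame(
      trait = names(trait_reports),
      mean_accuracy = vapply(trait_reports, function(r) r$mean_accuracy, numeric(1)),
      sd_accuracy = vapply(trait_reports, function(r) r$sd_accuracy, numeric(1)),
      chance = vapply(trait_reports, function(r) r$chance, numeric(1)),
      row.names = NULL)
    files <- c(files, write_stage_csv(acc_tab, config$outdir, "trait_accuracies.csv"))
    if (config$prediction$estimator == "logistic_l2") {
      ws <- summarize_weights(trait_reports)
      files <- c(files, write_stage_csv(ws$per_trait, config$outdir,
                                        "trait_weights_per_trait.csv"))
      files <- c(files, write_stage_csv(ws$across_traits, config$outdir,
                                        "trait_weights_across_traits.csv"))
    }
  }
  stage_times["predict"] <- tic() - t0

  cfg_path <- file.path(config$outdir, "config.json")
  save_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("overlapnet")),
    config_hash = unname(tools::md5sum(cfg_path)),
    winner = winner,
    heldout_score = score,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    stage_seconds = as.list(stage_times)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(manifest, list(results = list(
    atlas = atlas, dataset = ds, volumes_z = vm_z, model = model,
    fit_report = fit_rep, ranking = ranking, relevance = rel,
    cluster_relevance = cl_rel, trait_reports = trait_reports,
    train_idx = train_idx, test_idx = test_idx
  ))), class = "run_manifest")
}

#' Replication across row-disjoint splits
#'
#' Divides the population into `n_splits` disjoint, exhaustive splits, runs
#' the unsupervised decomposition independently on each, and correlates every
#' pair of solutions after optimal subnetwork matching.
#'
#' @param config a `run_config` (synthetic mode).
#' @param n_splits number of disjoint splits (1 gives a degenerate single run
#'   and an empty comparison set).
#' @return list with `$runs`, `$pairwise` (data frame of mean matched
#'   `|rho|` and score deltas per pair), `$rho_matrix`, `$splits`.
#' @export
replicate_runs <- function(config, n_splits) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$synthetic
  spec$seed <- stage_seed(config$seed, 1L)
  ds <- simulate_volumes(spec)
  n <- nrow(ds$volumes$values)
  if (n < 4L * n_splits) {
    abort_on("insufficient_data_error", "too few participants for the requested splits")
  }
  set.seed(stage_seed(config$seed, 6L))
  assignment <- sample(rep(seq_len(n_splits), length.out = n))
  k <- min(config$latent_dim, spec$n_regions - 1L)
  runs <- lapply(seq_len(n_splits), function(s) {
    rows <- which(assignment == s)
    vm_s <- volume_matrix(ds$volumes$values[rows, , drop = FALSE],
                          regions = ds$volumes$regions,
                          participant_ids = ds$volumes$participant_ids[rows])
    vm_z <- zscore_apply(vm_s, zscore_fit(vm_s))
    run_decomposition(vm_z, spec = "oracle", k = k,
                      seed = stage_seed(config$seed, 100L + s))
  })
  pairs <- if (n_splits > 1L) utils::combn(n_splits, 2L) else
    matrix(integer(0), nrow = 2L)
  rho_mat <- diag(1, n_splits)
  pw <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    cmp <- compare_runs(runs[[a]], runs[[b]])
    rho_mat[a, b] <- rho_mat[b, a] <- cmp$stability$mean_abs_rho
    pw[[p]] <- data.frame(split_a = a, split_b = b,
                          mean_abs_rho = cmp$stability$mean_abs_rho,
                          sd_abs_rho = cmp$stability$sd_abs_rho,
                          score_delta = cmp$score_delta)
  }
  list(runs = runs, pairwise = do.call(rbind, pw), rho_matrix = rho_mat,
       splits = assignment)
}
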