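DEFAULT_TRAITS <- c("loneliness", "friendship_satisfaction", "living_alone",
                    "sexual_partners", "social_job", "social_support")

#' Specify a synthetic population with planted overlapping subnetworks
#'
#' Defines the generative world used to validate every pipeline stage:
#' `n_participants x n_regions` volumes arise from `n_factors` latent factors
#' with sparse, partially overlapping loading supports (a few "hub" regions
#' load on three or more factors, mimicking the accumbens / temporo-parietal
#' junction / medial prefrontal overlap seen in population data), plus
#' isotropic Gaussian residual noise. Binary social-trait labels arise from
#' the latents through a logistic link with a sex offset.
#'
#' Defaults: a geometric factor-variance profile (ratio 0.8, leading variance
#' 4) so a clear dominance ordering with an elbow exists; Gaussian latents
#' (`latent_dist = "t5"` gives a heavy-tailed stress test); residual SD 0.5
#' (moderate noise); six traits, trait t loading on factor t with effect 1.5
#' and a sex effect of 0.5; age uniform on 45-80 years.
#'
#' @param n_participants number of participants n.
#' @param n_regions number of regions R (default 36).
#' @param n_factors number of latent factors K (default 15).
#' @param support_size nonzeros per factor loading (default 6).
#' @param overlap `"hubs"` (default) or `"disjoint"` (block supports, no
#'   region in two factors).
#' @param hubs region indices forced into `hub_factors` supports (default
#'   three regions spread over the atlas).
#' @param hub_factors factors receiving every hub (default `1:3`).
#' @param variances K descending positive factor variances.
#' @param noise_sd residual standard deviation.
#' @param latent_dist `"gaussian"` or `"t5"`.
#' @param n_traits number of binary social traits.
#' @param trait_effects K x n_traits matrix of logistic effects `beta`.
#' @param sex_effects length-`n_traits` logistic sex offsets `gamma`.
#' @param age_range length-2 years.
#' @param orthonormal if `TRUE`, loadings are symmetrically orthogonalized
#'   (exact supports are then only approximate) so individual factors are
#'   identifiable from second moments.
#' @param region_names optional column names for the volume matrix.
#' @param seed integer master seed.
#' @return a validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_participants = 2000, n_regions = 36, n_factors = 15,
                           support_size = 6, overlap = c("hubs", "disjoint"),
                           hubs = NULL, hub_factors = 1:3,
                           variances = 4 * 0.8^(seq_len(n_factors) - 1),
                           noise_sd = 0.5,
                           latent_dist = c("gaussian", "t5"),
                           n_traits = 6, trait_effects = NULL,
                           sex_effects = rep(0.5, n_traits),
                           age_range = c(45, 80),
                           orthonormal = FALSE,
                           region_names = NULL, seed = 1) {
  overlap <- match.arg(overlap)
  latent_dist <- match.arg(latent_dist)
  if (n_factors > n_regions) {
    abort_on("spec_error", "n_factors must not exceed n_regions")
  }
  if (length(variances) != n_factors || any(variances <= 0) ||
      is.unsorted(rev(variances))) {
    abort_on("spec_error", "variances must be K positive values in descending order")
  }
  if (noise_sd < 0) abort_on("spec_error", "noise_sd must be nonnegative")
  if (is.null(hubs)) {
    hubs <- unique(pmin(n_regions, c(
      max(1L, round(n_regions * 0.3)),
      max(1L, round(n_regions * 0.7)),
      n_regions)))
  }
  if (overlap == "hubs" && n_factors * support_size < n_regions) {
    abort_on("infeasible_support_error",
             "supports cannot cover all regions: K * support_size < R")
  }
  if (any(hubs < 1L | hubs > n_regions)) {
    abort_on("spec_error", "hub indices out of range")
  }
  if (is.null(trait_effects)) {
    trait_effects <- matrix(0, n_factors, n_traits)
    for (t in seq_len(n_traits)) {
      trait_effects[((t - 1L) %% n_factors) + 1L, t] <- 1.5
    }
  }
  trait_effects <- as.matrix(trait_effects)
  if (!identical(dim(trait_effects), c(as.integer(n_factors), as.integer(n_traits)))) {
    abort_on("spec_error", "trait_effects must be a K x n_traits matrix")
  }
  if (length(sex_effects) != n_traits) {
    abort_on("spec_error", "sex_effects must have one entry per trait")
  }
  if (is.null(region_names)) {
    region_names <- sprintf("region_%02d", seq_len(n_regions))
  }
  hub_factors <- intersect(as.integer(hub_factors), seq_len(n_factors))
  structure(list(
    n_participants = as.integer(n_participants), n_regions = as.integer(n_regions),
    n_factors = as.integer(n_factors), support_size = as.integer(support_size),
    overlap = overlap, hubs = as.integer(hubs), hub_factors = hub_factors,
    variances = as.numeric(variances), noise_sd = noise_sd,
    latent_dist = latent_dist, n_traits = as.integer(n_traits),
    trait_effects = trait_effects, sex_effects = as.numeric(sex_effects),
    age_range = as.numeric(age_range), orthonormal = isTRUE(orthonormal),
    region_names = region_names, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

plan_supports <- function(spec) {
  R <- spec$n_regions; K <- spec$n_factors; s <- spec$support_size
  supports <- vector("list", K)
  if (spec$overlap == "disjoint") {
    breaks <- floor(seq(0, R, length.out = K + 1))
    for (k in seq_len(K)) supports[[k]] <- seq(breaks[k] + 1L, breaks[k + 1L])
    return(supports)
  }
  # round-robin base assignment guarantees coverage of all R regions
  for (r in seq_len(R)) {
    k <- ((r - 1L) %% K) + 1L
    supports[[k]] <- c(supports[[k]], r)
  }
  # pad each support up to s with deterministic pseudo-random extras
  for (k in seq_len(K)) {
    pool <- setdiff(seq_len(R), supports[[k]])
    need <- s - length(supports[[k]])
    if (need > 0) supports[[k]] <- c(supports[[k]], sample(pool, need))
  }
  # hubs load on every hub factor; swap out a padded extra when possible so
  # support sizes stay at s, but never drop a base region (coverage)
  base_factor <- ((seq_len(R) - 1L) %% K) + 1L
  for (h in spec$hubs) {
    for (k in spec$hub_factors) {
      if (!h %in% supports[[k]]) {
        extras <- setdiff(supports[[k]][base_factor[supports[[k]]] != k], spec$hubs)
        if (length(extras)) {
          supports[[k]] <- setdiff(supports[[k]], extras[length(extras)])
        }
        supports[[k]] <- c(supports[[k]], h)
      }
    }
  }
  lapply(supports, sort)
}

inv_sqrt_sym <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(M)) %*% t(e$vectors)
}

#' Generate planted factor loadings
#'
#' Builds the R x K ground-truth loading matrix: each column has nonzeros
#' exactly on its planned support (unit-normalized), supports jointly cover
#' all regions, and hub regions appear in at least three factor supports under
#' the hub plan. With `spec$orthonormal`, columns are symmetrically
#' orthogonalized (`W (W'W)^{-1/2}`), preserving the support pattern only
#' approximately but making individual factors identifiable by PCA.
#'
#' @param spec a `synthetic_spec`.
#' @return R x K numeric loading matrix.
#' @export
generate_loadings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, 1L))
  supports <- plan_supports(spec)
  covered <- sort(unique(unlist(supports)))
  if (!identical(covered, seq_len(spec$n_regions))) {
    abort_on("infeasible_support_error", "supports do not cover all regions")
  }
  W <- matrix(0, spec$n_regions, spec$n_factors)
  for (k in seq_len(spec$n_factors)) {
    idx <- supports[[k]]
    v <- stats::rnorm(length(idx))
    # keep each factor's dominant region positive for a stable sign convention
    if (v[which.max(abs(v))] < 0) v <- -v
    W[idx, k] <- v / sqrt(sum(v^2))
  }
  if (spec$orthonormal) {
    W <- W %*% inv_sqrt_sym(crossprod(W))
  }
  rownames(W) <- spec$region_names
  colnames(W) <- sprintf("factor_%02d", seq_len(spec$n_factors))
  W
}

#' Simulate a synthetic volume matrix from planted subnetworks
#'
#' Draws latents `Z` (n x K, independent columns with the spec's variances),
#' forms `X = Z W' + E` with iid Gaussian residuals of SD `noise_sd`, and
#' packages the result with full ground truth. Bit-identical under a fixed
#' seed.
#'
#' @param spec a `synthetic_spec`.
#' @return a `synthetic_dataset`: `$volumes` (raw `volume_matrix`),
#'   `$latents`, `$loadings`, `$spec`, `$covariates` (NULL until
#'   [simulate_traits()]).
#' @export
simulate_volumes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  W <- generate_loadings(spec)
  n <- spec$n_participants; K <- spec$n_factors
  set.seed(stage_seed(spec$seed, 2L))
  Z <- matrix(0, n, K)
  for (k in seq_len(K)) {
    z <- switch(spec$latent_dist,
                gaussian = stats::rnorm(n),
                t5 = stats::rt(n, df = 5) / sqrt(5 / 3))
    Z[, k] <- z * sqrt(spec$variances[k])
  }
  set.seed(stage_seed(spec$seed, 3L))
  E <- matrix(stats::rnorm(n * spec$n_regions, sd = spec$noise_sd), n, spec$n_regions)
  X <- Z %*% t(W) + E
  ids <- sprintf("sub_%05d", seq_len(n))
  vm <- volume_matrix(X, regions = spec$region_names, participant_ids = ids)
  structure(list(volumes = vm, latents = Z, loadings = W,
                 covariates = NULL, spec = spec, seed = spec$seed),
            class = "synthetic_dataset")
}

#' Simulate sex, age and binary social-trait labels
#'
#' Per trait t, `P(more social) = plogis(beta_t' z_i + gamma_t * sex_i)` with
#' `sex ~ Bernoulli(0.5)` (1 = female) and `age ~ Uniform(age_range)`. Trait
#' labels depend on the volumes only through the latents, so a decomposition
#' that recovers the latents carries all available signal.
#'
#' @param ds a `synthetic_dataset` from [simulate_volumes()].
#' @param spec defaults to `ds$spec`.
#' @return `ds` with `$covariates` filled: data frame with `participant_id`,
#'   `sex` (0/1, 1 = female), `age`, and one 0/1 column per trait
#'   (1 = more social).
#' @export
simulate_traits <- function(ds, spec = ds$spec) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  n <- nrow(ds$latents)
  set.seed(stage_seed(spec$seed, 4L))
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  cov <- data.frame(participant_id = ds$volumes$participant_ids,
                    sex = sex, age = age, stringsAsFactors = FALSE)
  trait_names <- if (spec$n_traits <= length(DEFAULT_TRAITS)) {
    DEFAULT_TRAITS[seq_len(spec$n_traits)]
  } else {
    sprintf("trait_%02d", seq_len(spec$n_traits))
  }
  for (t in seq_len(spec$n_traits)) {
    eta <- drop(ds$latents %*% spec$trait_effects[, t]) + spec$sex_effects[t] * sex
    cov[[trait_names[t]]] <- stats::rbinom(n, 1L, stats::plogis(eta))
  }
  ds$covariates <- cov
  ds
}

#' Build phantom grey-matter images with known signals
#'
#' Constructs in-memory volumetric images whose extracted region volumes have
#' closed-form expectations, for exercising the extraction stage. The affine
#' is identity-scaled (1 mm voxels); when `center = TRUE` a translation is
#' added so the atlas bounding-box midpoint maps to the volume center.
#'
#' @param n number of participant images.
#' @param shape length-3 integer grid shape.
#' @param atlas a `social_brain_atlas`.
#' @param signal_plan list with `type` one of `"constant"` (field `value`,
#'   scalar or length-n), `"region_cubes"` (field `values`, length-R vector or
#'   n x R matrix, painted in cubes of `half_width_mm`, default 3), or
#'   `"point"` (field `value` placed at each region-center voxel).
#' @param center translate the affine to center the atlas in the grid.
#' @return list of `gm_image` objects.
#' @export
make_phantom_images <- function(n, shape, atlas,
                                signal_plan = list(type = "constant", value = 1),
                                center = TRUE) {
  stopifnot(inherits(atlas, "social_brain_atlas"), length(shape) == 3L)
  shape <- as.integer(shape)
  affine <- diag(4)
  coords <- as.matrix(atlas$regions[, c("x", "y", "z")])
  if (center) {
    bbox_mid <- (apply(coords, 2L, min) + apply(coords, 2L, max)) / 2
    affine[1:3, 4] <- round(bbox_mid - (shape - 1) / 2)
  }
  inv <- solve(affine)
  centers <- t(apply(coords, 1L, function(mm) round((inv %*% c(mm, 1))[1:3]) + 1L))
  if (any(centers < 1L) || any(sweep(centers, 2L, shape, ">"))) {
    abort_on("out_of_bounds_error",
             "atlas coordinates do not fit inside the phantom grid")
  }
  R <- nrow(centers)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    arr <- array(0, dim = shape)
    if (signal_plan$type == "constant") {
      val <- signal_plan$value
      arr[] <- if (length(val) >= i) val[i] else val[1]
    } else if (signal_plan$type == "region_cubes") {
      vals <- signal_plan$values
      vr <- if (is.matrix(vals)) vals[i, ] else vals
      hw <- as.integer(signal_plan$half_width_mm %||% 3L)
      for (r in seq_len(R)) {
        ix <- pmax(1L, centers[r, 1] - hw):pmin(shape[1], centers[r, 1] + hw)
        iy <- pmax(1L, centers[r, 2] - hw):pmin(shape[2], centers[r, 2] + hw)
        iz <- pmax(1L, centers[r, 3] - hw):pmin(shape[3], centers[r, 3] + hw)
        arr[ix, iy, iz] <- vr[r]
      }
    } else if (signal_plan$type == "point") {
      for (r in seq_len(R)) arr[centers[r, 1], centers[r, 2], centers[r, 3]] <-
          signal_plan$value
    } else {
      abort_on("spec_error", paste("unknown signal plan type:", signal_plan$type))
    }
    images[[i]] <- gm_image(arr, affine, sprintf("phantom_%03d", i))
  }
  images
}

`%||%` <- function(a, b) if (is.null(a)) b else a
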