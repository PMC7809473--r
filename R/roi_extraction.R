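#' Construct an in-memory grey-matter image
#'
#' A volumetric grey-matter map (already tissue-segmented and brain-size
#' adjusted upstream) with a voxel-to-millimeter affine. The affine maps
#' 0-based voxel indices `(i,j,k)` to millimeter coordinates via
#' `affine %*% c(i,j,k,1)`.
#'
#' @param data 3-D numeric array of grey-matter values, all finite.
#' @param affine 4x4 invertible voxel-to-mm matrix (default: identity, i.e.
#'   1 mm isotropic voxels anchored at the origin).
#' @param participant_id identifier string.
#' @return a `gm_image` object.
#' @export
gm_image <- function(data, affine = diag(4), participant_id = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_on("schema_error", "data must be a 3-D array")
  }
  if (!all(is.finite(data))) abort_on("schema_error", "image values must be finite")
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < 1e-12) {
    abort_on("affine_error", "affine must be an invertible 4x4 matrix")
  }
  structure(list(data = data, affine = affine,
                 participant_id = as.character(participant_id)),
            class = "gm_image")
}

voxel_sizes <- function(affine) {
  v <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(v <= 0) || any(!is.finite(v))) {
    abort_on("affine_error", "voxel sizes derived from affine must be positive")
  }
  v
}

#' Convert Gaussian FWHM to standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the standard relation for a
#' Gaussian kernel's full width at half maximum.
#'
#' @param fwhm_mm full width at half maximum, millimeters (> 0).
#' @return sigma in millimeters.
#' @examples
#' fwhm_to_sigma(5) # 2.1233...
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (!is_scalar_number(fwhm_mm) || fwhm_mm <= 0) {
    abort_on("non_positive_error", "fwhm_mm must be a positive scalar")
  }
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

# 1-D Gaussian kernel, truncated at 4 sigma, normalized to sum 1
gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution along one axis of a 3-D array with half-sample symmetric
# ("reflect") padding; the resulting linear operator is symmetric so the total
# image mass is conserved.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  # reflect-padded index sequence of length n + 2r (half-sample symmetric:
  # nearest-to-boundary samples mirror first, keeping the operator symmetric)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1L - seq_len(min(r, n)))
  while (length(idx) < n + 2L * r) idx <- c(idx[1L], idx, idx[length(idx)])
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  ap <- aperm(arr, perm)                        # axis of interest first
  m <- matrix(ap, nrow = n)                     # n x (prod of other dims)
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * padded[(t - 1L) + seq_len(n), , drop = FALSE]
  }
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

#' Smooth a grey-matter image with a Gaussian kernel
#'
#' Separable Gaussian convolution with per-axis sigma (in voxels) equal to
#' `fwhm_to_sigma(fwhm_mm) / voxel_size`, using reflect padding at the image
#' boundary so total image mass is conserved. `fwhm_mm = 0` is a no-op.
#'
#' @param img a `gm_image`.
#' @param fwhm_mm smoothing kernel full width at half maximum, mm (default 5,
#'   the standard homogenization choice for structural maps).
#' @return smoothed `gm_image`.
#' @export
smooth_image <- function(img, fwhm_mm = 5) {
  stopifnot(inherits(img, "gm_image"))
  if (identical(fwhm_mm, 0) || identical(fwhm_mm, 0L)) return(img)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  vs <- voxel_sizes(img$affine)
  out <- img$data
  for (axis in 1:3) {
    out <- conv_axis(out, gauss_kernel_1d(sigma_mm / vs[axis]), axis)
  }
  gm_image(out, img$affine, img$participant_id)
}

#' Integer voxel offsets inside a sphere
#'
#' All integer voxel offsets `v` whose center lies within a sphere of the
#' given diameter: `||v * voxel_size||_2 <= diameter/2`. Order is
#' deterministic (lexicographic in z, y, x).
#'
#' @param diameter_mm sphere diameter, mm (> 0). Note: diameter, not radius.
#' @param voxel_size_mm voxel edge length(s), mm; scalar or length-3 (> 0).
#' @return integer matrix with 3 columns (one offset per row).
#' @examples
#' nrow(sphere_voxel_offsets(5, 1)) # 81
#' @export
sphere_voxel_offsets <- function(diameter_mm, voxel_size_mm = 1) {
  if (!is_scalar_number(diameter_mm) || diameter_mm <= 0) {
    abort_on("non_positive_error", "diameter_mm must be a positive scalar")
  }
  if (!is.numeric(voxel_size_mm) || !length(voxel_size_mm) %in% c(1L, 3L) ||
      any(voxel_size_mm <= 0)) {
    abort_on("non_positive_error", "voxel_size_mm must be positive (length 1 or 3)")
  }
  vs <- if (length(voxel_size_mm) == 1L) rep(voxel_size_mm, 3L) else voxel_size_mm
  radius <- diameter_mm / 2
  m <- floor(radius / vs)
  g <- expand.grid(dx = -m[1]:m[1], dy = -m[2]:m[2], dz = -m[3]:m[3])
  keep <- (g$dx * vs[1])^2 + (g$dy * vs[2])^2 + (g$dz * vs[3])^2 <= radius^2
  out <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(out) <- "integer"
  dimnames(out) <- list(NULL, c("dx", "dy", "dz"))
  out
}

new_volume_matrix <- function(values, participant_ids, regions,
                              standardized = FALSE, scaler = NULL) {
  dimnames(values) <- list(participant_ids, regions)
  structure(list(values = values, participant_ids = participant_ids,
                 regions = regions, standardized = standardized,
                 scaler = scaler),
            class = "volume_matrix")
}

#' Assemble a volume matrix from a plain matrix
#'
#' @param values n x R numeric matrix (participants x regions).
#' @param regions region names in column order (default: existing colnames).
#' @param participant_ids row identifiers.
#' @param standardized whether values are already z-scored.
#' @param scaler optional scaler (see [zscore_fit()]).
#' @return a `volume_matrix`.
#' @export
volume_matrix <- function(values, regions = colnames(values),
                          participant_ids = rownames(values),
                          standardized = FALSE, scaler = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || !all(is.finite(values))) {
    abort_on("schema_error", "volume matrix must be finite with no missing values")
  }
  if (is.null(regions)) regions <- sprintf("region_%02d", seq_len(ncol(values)))
  if (is.null(participant_ids)) participant_ids <- sprintf("sub_%05d", seq_len(nrow(values)))
  new_volume_matrix(values, as.character(participant_ids), as.character(regions),
                    standardized, scaler)
}

#' @export
print.volume_matrix <- function(x, ...) {
  cat(sprintf("volume matrix: %d participants x %d regions (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) "z-scored" else "raw"))
  invisible(x)
}

#' Extract spherical region volumes from grey-matter images
#'
#' For each image: smooth at `fwhm_mm`, map each atlas coordinate to the
#' nearest voxel through the inverse affine, and average the smoothed signal
#' over all voxels within a sphere of `diameter_mm` around that center. This
#' yields one representative grey-matter volume per region per participant.
#'
#' @param images list of `gm_image` objects sharing grid shape and affine.
#' @param atlas a `social_brain_atlas`; its region order fixes column order.
#' @param diameter_mm sphere diameter, mm (default 5; 2.5 and 7.5 are
#'   supported sensitivity settings).
#' @param fwhm_mm smoothing FWHM, mm (default 5; 0 disables smoothing).
#' @return raw (unstandardized) `volume_matrix`.
#' @export
extract_region_volumes <- function(images, atlas, diameter_mm = 5, fwhm_mm = 5) {
  stopifnot(inherits(atlas, "social_brain_atlas"), length(images) >= 1L)
  ref <- images[[1L]]
  for (img in images) {
    stopifnot(inherits(img, "gm_image"))
    if (!identical(dim(img$data), dim(ref$data)) ||
        max(abs(img$affine - ref$affine)) > 1e-9) {
      abort_on("grid_mismatch_error", "all images must share grid shape and affine")
    }
  }
  inv <- solve(ref$affine)
  vs <- voxel_sizes(ref$affine)
  offsets <- sphere_voxel_offsets(diameter_mm, vs)
  dims <- dim(ref$data)
  R <- n_regions(atlas)
  centers <- matrix(0L, R, 3L)
  for (r in seq_len(R)) {
    mm <- c(atlas$regions$x[r], atlas$regions$y[r], atlas$regions$z[r], 1)
    vox <- round((inv %*% mm)[1:3]) + 1L  # 1-based array index
    sph <- sweep(offsets, 2L, as.integer(vox), "+")
    if (any(sph < 1L) || any(sph[, 1] > dims[1]) || any(sph[, 2] > dims[2]) ||
        any(sph[, 3] > dims[3])) {
      abort_on("out_of_bounds_error", sprintf(
        "sphere for region %s (participant %s) exceeds image bounds",
        atlas$regions$name[r], ref$participant_id))
    }
    centers[r, ] <- as.integer(vox)
  }
  vals <- matrix(NA_real_, length(images), R)
  for (i in seq_along(images)) {
    sm <- smooth_image(images[[i]], fwhm_mm)
    for (r in seq_len(R)) {
      sph <- sweep(offsets, 2L, centers[r, ], "+")
      vals[i, r] <- mean(sm$data[sph])
    }
  }
  ids <- vapply(images, function(im) im$participant_id, character(1))
  new_volume_matrix(vals, ids, atlas$regions$name)
}

#' Fit a per-region z-scoring scaler
#'
#' Centers each region's volumes to zero mean and scales to unit variance
#' across participants (population-SD convention). Fit on training rows only
#' to avoid leakage, or on the full sample to mirror a global-z-scoring
#' workflow; see `zscore_scope` in [run_config()].
#'
#' @param vm a `volume_matrix` (raw).
#' @return scaler: list with `center`, `scale`, `regions`.
#' @export
zscore_fit <- function(vm) {
  stopifnot(inherits(vm, "volume_matrix"))
  center <- colMeans(vm$values)
  scale <- col_pop_sd(vm$values)
  zero <- which(scale < 1e-12)
  if (length(zero)) {
    abort_on("zero_variance_error", paste(
      "zero variance in region(s):", paste(vm$regions[zero], collapse = ", ")))
  }
  list(center = center, scale = scale, regions = vm$regions)
}

#' Apply (or invert) a z-scoring scaler
#'
#' @param vm a `volume_matrix`.
#' @param scaler result of [zscore_fit()].
#' @return standardized `volume_matrix` carrying the scaler.
#' @export
zscore_apply <- function(vm, scaler) {
  stopifnot(inherits(vm, "volume_matrix"))
  if (!identical(scaler$regions, vm$regions)) {
    abort_on("schema_error", "scaler regions do not match volume matrix regions")
  }
  z <- sweep(sweep(vm$values, 2L, scaler$center), 2L, scaler$scale, "/")
  new_volume_matrix(z, vm$participant_ids, vm$regions,
                    standardized = TRUE, scaler = scaler)
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(vm, scaler = vm$scaler) {
  stopifnot(inherits(vm, "volume_matrix"), !is.null(scaler))
  x <- sweep(sweep(vm$values, 2L, scaler$scale, "*"), 2L, scaler$center, "+")
  new_volume_matrix(x, vm$participant_ids, vm$regions, standardized = FALSE)
}

# matrix view used throughout the modeling code
vm_values <- function(x) {
  if (inherits(x, "volume_matrix")) x$values else as.matrix(x)
}
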