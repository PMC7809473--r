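# shared fixtures, built in code

# tiny atlas written to a temp CSV and loaded through the public path
toy_atlas <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      name = c("A_L", "A_R", "B"),
      hemisphere = c("left", "right", "midline"),
      x = c(-4, 4, 0), y = c(0, 0, 2), z = c(1, 1, 3),
      cluster = c("limbic", "limbic", "intermediate"),
      stringsAsFactors = FALSE
    )
  }
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  load_atlas(path)
}

# standardized rank-K synthetic volumes (z-scored), with ground truth attached
standardized_synthetic <- function(n = 500, noise_sd = 0, seed = 7, K = 15,
                                   orthonormal = TRUE, ...) {
  spec <- synthetic_spec(n_participants = n, n_factors = K, noise_sd = noise_sd,
                         support_size = max(6L, ceiling(36 / K) + 2L),
                         orthonormal = orthonormal, seed = seed, ...)
  ds <- simulate_volumes(spec)
  vz <- zscore_apply(ds$volumes, zscore_fit(ds$volumes))
  list(X = vz$values, vm = vz, ds = ds, spec = spec)
}

# brute-force sphere membership oracle: loop over the whole grid, Euclidean
# test on voxel-center mm distances (independent of sphere_voxel_offsets)
brute_force_extract <- function(img_smoothed, atlas, diameter_mm) {
  inv <- solve(img_smoothed$affine)
  dims <- dim(img_smoothed$data)
  radius <- diameter_mm / 2
  out <- numeric(nrow(atlas$regions))
  for (r in seq_len(nrow(atlas$regions))) {
    mm <- c(atlas$regions$x[r], atlas$regions$y[r], atlas$regions$z[r], 1)
    ctr <- round((inv %*% mm)[1:3])  # 0-based voxel
    vals <- c()
    for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1)) for (k in 0:(dims[3] - 1)) {
      mm_v <- img_smoothed$affine %*% c(i, j, k, 1)
      mm_c <- img_smoothed$affine %*% c(ctr, 1)
      if (sqrt(sum((mm_v[1:3] - mm_c[1:3])^2)) <= radius) {
        vals <- c(vals, img_smoothed$data[i + 1, j + 1, k + 1])
      }
    }
    out[r] <- mean(vals)
  }
  out
}

# all permutations of 1..n (for brute-force assignment checks, n <= 5)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}
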