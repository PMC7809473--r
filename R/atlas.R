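#' Canonical social-brain cluster labels
#'
#' The four functional clusters of the social brain atlas: a visual-sensory
#' cluster, a limbic cluster, an intermediate cluster, and a
#' higher-associative cortical cluster.
#'
#' @export
ATLAS_CLUSTERS <- c("visual_sensory", "limbic", "intermediate", "higher_associative")

ATLAS_HEMISPHERES <- c("left", "right", "midline")

new_atlas <- function(regions, source) {
  structure(list(regions = regions, source = source),
            class = "social_brain_atlas")
}

validate_atlas_table <- function(df, source) {
  wanted <- c("name", "hemisphere", "x", "y", "z", "cluster")
  if (!identical(sort(names(df)), sort(wanted))) {
    abort_on("schema_error", sprintf(
      "atlas table must have columns %s; got %s",
      paste(wanted, collapse = ","), paste(names(df), collapse = ",")))
  }
  df <- df[, wanted]
  df$name <- as.character(df$name)
  df$hemisphere <- as.character(df$hemisphere)
  df$cluster <- as.character(df$cluster)
  for (cc in c("x", "y", "z")) df[[cc]] <- as.numeric(df[[cc]])
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) {
    abort_on("duplicate_region_error",
             paste("duplicate region names:", paste(unique(dup), collapse = ", ")))
  }
  bad_cluster <- which(!df$cluster %in% ATLAS_CLUSTERS)
  if (length(bad_cluster)) {
    abort_on("schema_error", sprintf(
      "unknown cluster label(s) in rows %s: %s",
      paste(bad_cluster, collapse = ","),
      paste(unique(df$cluster[bad_cluster]), collapse = ", ")))
  }
  bad_hemi <- which(!df$hemisphere %in% ATLAS_HEMISPHERES)
  if (length(bad_hemi)) {
    abort_on("schema_error", sprintf(
      "unknown hemisphere label(s) in rows %s", paste(bad_hemi, collapse = ",")))
  }
  bad_xyz <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad_xyz)) {
    abort_on("schema_error", sprintf(
      "non-finite coordinates in rows %s", paste(bad_xyz, collapse = ",")))
  }
  rownames(df) <- NULL
  new_atlas(df, source)
}

#' Load a social brain atlas
#'
#' Reads an atlas table (region name, hemisphere, millimeter coordinates in
#' the stereotaxic reference space, cluster membership) from CSV or JSON, or
#' the shipped 36-region default when `path = "default"`. The shipped default
#' is a synthetic stand-in with the structures named in the meta-analytic
#' social brain atlas but placeholder coordinates; substitute the published
#' table for real analyses. Region order in the file is preserved and defines
#' the column order of every downstream matrix.
#'
#' @param path file path (`.csv` or `.json`), or `"default"`.
#' @return a `social_brain_atlas` object: `$regions` data frame
#'   (`name, hemisphere, x, y, z, cluster`) and `$source` provenance string.
#' @examples
#' atlas <- load_atlas("default")
#' n_regions(atlas)
#' @export
load_atlas <- function(path = "default") {
  if (identical(path, "default")) {
    path <- system.file("extdata", "social_brain_atlas_synthetic.csv",
                        package = "overlapnet", mustWork = TRUE)
    source <- "shipped synthetic default (placeholder coordinates)"
  } else {
    source <- path
  }
  if (!file.exists(path)) {
    abort_on("missing_file", paste("atlas file not found:", path))
  }
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  validate_atlas_table(df, source)
}

#' Save an atlas to CSV or JSON
#'
#' @param atlas a `social_brain_atlas`.
#' @param path output path; format chosen by extension (`.json` else CSV).
#' @return `path`, invisibly.
#' @export
save_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "social_brain_atlas"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(atlas$regions, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(atlas$regions, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.social_brain_atlas <- function(x, ...) {
  cat(sprintf("social brain atlas: %d regions, %d clusters\n",
              nrow(x$regions), length(unique(x$regions$cluster))))
  cat("source:", x$source, "\n")
  print(table(factor(x$regions$cluster, levels = ATLAS_CLUSTERS)))
  invisible(x)
}

#' Number of regions in an atlas
#' @param atlas a `social_brain_atlas`.
#' @export
n_regions <- function(atlas) nrow(atlas$regions)

#' Region names, in atlas (column) order
#' @param atlas a `social_brain_atlas`.
#' @export
region_names <- function(atlas) atlas$regions$name

#' Cluster membership indicator matrix
#'
#' Binary 4 x R matrix with one row per canonical cluster and one column per
#' region; each column sums to 1 because the clusters partition the atlas.
#' Used to aggregate region relevances to cluster level.
#'
#' @param atlas a `social_brain_atlas`.
#' @return binary matrix, rows named by cluster, columns by region.
#' @export
cluster_membership_matrix <- function(atlas) {
  stopifnot(inherits(atlas, "social_brain_atlas"))
  clusters <- intersect(ATLAS_CLUSTERS, unique(atlas$regions$cluster))
  M <- vapply(seq_len(nrow(atlas$regions)),
              function(r) as.integer(clusters == atlas$regions$cluster[r]),
              integer(length(clusters)))
  dimnames(M) <- list(clusters, atlas$regions$name)
  M
}
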