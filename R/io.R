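#' Write and read a simulated cohort as delimited text
#'
#' A cohort on disk is a directory with `manifest.csv` (one row per trial:
#' `mouse_id`, `group`, `day`, `trial`, `label`, `escaped`, `latency_s`,
#' `file`) plus one trajectory CSV per trial with columns `time_s`, `x_m`,
#' `y_m`, and a `geometry.yaml` describing the pool. Writing then reading a
#' cohort round-trips the manifest and paths.
#'
#' @param cohort a `swim_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns the manifest invisibly; `read_cohort()`
#'   returns a `swim_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  geometry <- attr(cohort, "geometry")
  .check_geometry(geometry)
  dir.create(file.path(dir, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  df <- as_tibble(cohort)
  files <- sprintf("trajectories/%s_d%d_t%d.csv", df$mouse_id, df$day,
                   df$trial)
  for (i in seq_len(nrow(df))) {
    readr::write_csv(df$path[[i]], file.path(dir, files[i]),
                     progress = FALSE)
  }
  manifest <- df
  manifest$path <- NULL
  manifest$file <- files
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  yaml::write_yaml(
    list(pool_radius = geometry$pool_radius,
         platform_center = as.numeric(geometry$platform_center),
         platform_radius = geometry$platform_radius,
         start_points = lapply(geometry$start_points, as.numeric)),
    file.path(dir, "geometry.yaml"))
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  gy <- yaml::read_yaml(file.path(dir, "geometry.yaml"))
  geometry <- pool_geometry(
    pool_radius = gy$pool_radius,
    platform_center = unlist(gy$platform_center),
    platform_radius = gy$platform_radius,
    start_points = lapply(gy$start_points, unlist))
  paths <- lapply(manifest$file, function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                    progress = FALSE)
  })
  out <- manifest
  out$file <- NULL
  out$path <- paths
  structure(out, class = c("swim_cohort", class(out)), geometry = geometry)
}

#' Write a dataset's images and manifest to disk
#'
#' Saves every image of a `swim_dataset` as an 8-bit grayscale PNG plus a
#' manifest CSV (`file`, `label`, `class_index`, `mouse_id`, `day`,
#' `trial`). Byte-identical across runs for the same dataset.
#'
#' @param dataset a `swim_dataset`.
#' @param dir output directory.
#' @return the manifest tibble, invisibly.
#' @export
write_dataset_images <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$class_index)
  files <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[, , i], file.path(dir, files[i]))
  }
  manifest <- dataset$manifest
  manifest$file <- files
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}
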