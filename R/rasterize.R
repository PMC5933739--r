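#' Render a trajectory to an 8-bit grayscale raster
#'
#' Draws the swim path as a connected one-pixel polyline, dark on a light
#' background, mimicking a tracker's image export. The pool is inscribed in
#' the raster with a 2-pixel margin; raster x runs rightward and raster y
#' downward, with pixel centres at half-integer coordinates. The marked
#' pixels are exactly the cells the continuous polyline passes through
#' (4-connected grid traversal), so rendering is deterministic.
#'
#' @param traj a `swim_trajectory` (or tibble with `x_m`, `y_m` and a
#'   `geometry` attribute).
#' @param width,height raster size in pixels; the default matches a 140x120
#'   tracker export.
#' @return an integer matrix (`height` x `width`) with background 255 and
#'   path pixels 0.
#' @examples
#' img <- render_trajectory(simulate_trajectory("Scanning", seed = 4))
#' dim(img)
#' @export
render_trajectory <- function(traj, width = 140, height = 120) {
  if (min(width, height) <= 2) abort("raster size must exceed 2 pixels")
  if (min(width, height) < 6) abort("raster too small to inscribe the pool")
  geometry <- attr(traj, "geometry")
  .check_geometry(geometry)
  R <- geometry$pool_radius
  scale <- (min(width, height) - 4) / (2 * R)
  u <- width / 2 + traj$x_m * scale
  v <- height / 2 - traj$y_m * scale
  hits <- .rasterize_cells(cbind(u, v), as.integer(width), as.integer(height))
  255L - 255L * hits
}

# 1-D area-averaging resampling operator (dst x src); rows sum to 1 and
# every source pixel carries equal total weight, so the image mean is
# preserved exactly
.resample_matrix <- function(src, dst) {
  ratio <- src / dst
  L <- matrix(0, dst, src)
  for (t in seq_len(dst)) {
    lo <- (t - 1) * ratio
    hi <- t * ratio
    s0 <- floor(lo) + 1
    s1 <- ceiling(hi)
    for (s in s0:min(s1, src)) {
      overlap <- min(hi, s) - max(lo, s - 1)
      if (overlap > 0) L[t, s] <- overlap / ratio
    }
  }
  L / rowSums(L)
}

#' Preprocess a raster into a normalized model input
#'
#' Converts an 8-bit grayscale raster into the square, unit-intensity input
#' consumed by the network: the raster is padded to square with background
#' (preserving aspect ratio), downscaled by area averaging to one of the
#' three supported resolutions, and divided by 255 so intensities lie in
#' [0, 1].
#'
#' @param raster integer or numeric matrix with values in 0..255.
#' @param target_size one of 72, 48 or 24.
#' @return a `target_size` x `target_size` numeric matrix in [0, 1].
#' @examples
#' img <- render_trajectory(simulate_trajectory("Circling", seed = 5))
#' x <- preprocess_raster(img, 48)
#' range(x)
#' @export
preprocess_raster <- function(raster, target_size) {
  if (!target_size %in% c(72, 48, 24)) {
    abort("target_size must be one of 72, 48, 24")
  }
  raster <- as.matrix(raster)
  h <- nrow(raster)
  w <- ncol(raster)
  n <- max(h, w)
  sq <- matrix(255, n, n)
  r0 <- floor((n - h) / 2)
  c0 <- floor((n - w) / 2)
  sq[r0 + seq_len(h), c0 + seq_len(w)] <- raster
  L <- .resample_matrix(n, target_size)
  out <- L %*% sq %*% t(L) / 255
  pmin(pmax(out, 0), 1)
}

#' Build an image dataset from a labelled cohort
#'
#' Renders every trial of a (optionally stage-filtered) cohort, preprocesses
#' the rasters to the requested resolution, attaches the integer class
#' indices of the chosen recognition task, and shuffles the items
#' reproducibly.
#'
#' @param cohort a `swim_cohort` with labels.
#' @param target_size image side, one of 72, 48, 24.
#' @param classes recognition task: 2 (thigmotaxis vs other), 3 (adds direct
#'   swim) or 6 (all classes).
#' @param seed shuffle seed.
#' @param stage optional `"early"` (days 1-2) or `"late"` (days 4-5) filter.
#' @return a `swim_dataset`: list with `images` (array `size x size x n` in
#'   [0, 1]), `class_index` (0-based integer labels), `label` (strategy
#'   names), `class_map` (the label-to-index map) and `manifest`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_control = 2, n_lesion = 2, seed = 11))
#' ds <- build_dataset(co, 24, classes = 2, seed = 1)
#' dim(ds$images)
#' @export
build_dataset <- function(cohort, target_size, classes = 6, seed = 1,
                          stage = NULL) {
  geometry <- attr(cohort, "geometry")
  .check_geometry(geometry)
  df <- as_tibble(cohort)
  if (!is.null(stage)) df <- df[df$day %in% .stage_days(stage), ]
  if (any(is.na(df$label))) {
    bad <- df[is.na(df$label), ]
    abort(sprintf("unlabeled trial encountered: %s day %d trial %d",
                  bad$mouse_id[1], bad$day[1], bad$trial[1]))
  }
  n <- nrow(df)
  if (n < 10) abort("a dataset needs at least 10 labelled trials")
  cmap <- class_index_map(classes)
  images <- array(0, dim = c(target_size, target_size, n))
  for (i in seq_len(n)) {
    tr <- structure(df$path[[i]], geometry = geometry)
    images[, , i] <- preprocess_raster(render_trajectory(tr), target_size)
  }
  ord <- .with_seed(seed, sample.int(n))
  manifest <- df[ord, c("mouse_id", "group", "day", "trial", "label")]
  manifest$class_index <- unname(cmap[manifest$label])
  structure(
    list(images = images[, , ord, drop = FALSE],
         class_index = manifest$class_index,
         label = manifest$label,
         class_map = cmap,
         target_size = target_size,
         n_classes = length(unique(cmap)),
         manifest = manifest),
    class = "swim_dataset"
  )
}

#' @export
print.swim_dataset <- function(x, ...) {
  cat(sprintf("<swim_dataset> %d images %dx%d, %d classes\n",
              length(x$class_index), x$target_size, x$target_size,
              x$n_classes))
  invisible(x)
}

# subset a dataset by item indices (used by the holdout splitter)
.dataset_subset <- function(dataset, idx) {
  structure(
    list(images = dataset$images[, , idx, drop = FALSE],
         class_index = dataset$class_index[idx],
         label = dataset$label[idx],
         class_map = dataset$class_map,
         target_size = dataset$target_size,
         n_classes = dataset$n_classes,
         manifest = dataset$manifest[idx, ]),
    class = "swim_dataset"
  )
}
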