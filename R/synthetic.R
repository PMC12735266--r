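#' Synthetic scene configuration
#'
#' Describes desk-scale images of small quasi-circular objects with
#' known centers: soft-edged disks on a darker background with additive
#' Gaussian noise.  The defaults define the packaged benchmark regime:
#' 96 x 96 px scenes holding about 15 non-overlapping disks of radius
#' 4 px, of which a single one per image is annotated (under 10% of the
#' points), paired with a 7 px count-map kernel (slightly smaller than
#' the 8-9 px object diameter).
#'
#' @param height,width Image size in pixels.
#' @param n_objects Either a fixed count or `c(mean, sd)` for a
#'   per-image Gaussian draw (rounded, floored at 1).
#' @param object_radius Disk radius in pixels.
#' @param contrast Disk intensity above the background (images are
#'   clipped to \[0, 1\]).
#' @param background Background intensity.
#' @param noise_sd Additive Gaussian pixel noise, standard deviation.
#' @param labeled_count Annotations revealed to the learner per image
#'   (the rest of the centers stay hidden).
#' @param min_separation Minimum center-to-center distance in pixels;
#'   the default `2 * object_radius + 1` keeps disks disjoint.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 96L, width = 96L,
                         n_objects = c(15, 2), object_radius = 4,
                         contrast = 0.7, background = 0.1,
                         noise_sd = 0.02, labeled_count = 1L,
                         min_separation = 2 * object_radius + 1) {
  stopifnot(height > 0, width > 0, object_radius > 0,
            contrast > 0, noise_sd >= 0, labeled_count >= 0,
            min_separation > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_objects = n_objects, object_radius = object_radius,
                 contrast = contrast, background = background,
                 noise_sd = noise_sd, labeled_count = as.integer(labeled_count),
                 min_separation = min_separation),
            class = "scene_config")
}

#' Generate one annotated synthetic scene
#'
#' Places object centers by bounded rejection sampling (all centers at
#' least `object_radius + 1` px from the border and `min_separation`
#' apart), renders each object as a disk with a 1-pixel anti-aliased
#' edge, adds Gaussian noise, clips to \[0, 1\], and reveals
#' `labeled_count` randomly chosen centers as the labeled subset.
#' Deterministic given `seed`.
#'
#' @param cfg A [scene_config()].
#' @param seed Integer seed.
#' @return A list of class `annotated_image`: `image` (matrix),
#'   `centers` and `labeled` (data frames of 0-based `row`, `col`),
#'   `seed`, `config`.
#' @export
generate_scene <- function(cfg = scene_config(), seed = 1L) {
  withr_seed(seed, {
    n <- if (length(cfg$n_objects) == 2L)
      max(1L, round(rnorm(1, cfg$n_objects[1L], cfg$n_objects[2L])))
    else as.integer(cfg$n_objects)
    if (cfg$labeled_count > n)
      stop("labeled_count exceeds the number of objects", call. = FALSE)
    margin <- ceiling(cfg$object_radius) + 1L
    lo_r <- margin; hi_r <- cfg$height - 1L - margin
    lo_c <- margin; hi_c <- cfg$width - 1L - margin
    if (hi_r < lo_r || hi_c < lo_c)
      stop("image too small for the object radius", call. = FALSE)
    centers <- matrix(numeric(0), 0L, 2L)
    tries <- 0L; max_tries <- 400L * n
    while (nrow(centers) < n) {
      if ((tries <- tries + 1L) > max_tries)
        stop("could not pack ", n, " objects at min_separation = ",
             cfg$min_separation, call. = FALSE)
      cand <- c(sample(lo_r:hi_r, 1L), sample(lo_c:hi_c, 1L))
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) >=
              cfg$min_separation))
        centers <- rbind(centers, cand)
    }
    img <- matrix(cfg$background, cfg$height, cfg$width)
    rr <- row(img) - 1L; cc <- col(img) - 1L
    for (i in seq_len(nrow(centers))) {
      d <- sqrt((rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2)
      img <- img + cfg$contrast *
        pmin(pmax(cfg$object_radius + 0.5 - d, 0), 1)
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), sd = cfg$noise_sd),
                          nrow(img), ncol(img))
    img <- pmax(pmin(img, 1), 0)   # img first: pmin/pmax keep its dim
    centers_df <- data.frame(row = centers[, 1L], col = centers[, 2L])
    lab <- if (cfg$labeled_count > 0)
      centers_df[sort(sample.int(n, cfg$labeled_count)), , drop = FALSE]
    else centers_df[0L, ]
    rownames(centers_df) <- rownames(lab) <- NULL
    structure(list(image = img, centers = centers_df, labeled = lab,
                   seed = seed, config = cfg),
              class = "annotated_image")
  })
}

#' Generate a dataset of annotated scenes
#'
#' Per-image seeds are drawn once from `seed`, so any single scene can
#' be regenerated independently.
#'
#' @param n_images Number of scenes.
#' @param cfg A [scene_config()].
#' @param seed Master seed.
#' @return List of [generate_scene()] results.
#' @export
generate_dataset <- function(n_images, cfg = scene_config(), seed = 1L) {
  seeds <- withr_seed(seed, sample.int(.Machine$integer.max, n_images))
  lapply(seeds, function(s) generate_scene(cfg, s))
}

#' Subsample point annotations
#'
#' Draws \eqn{\lceil \mathrm{fraction} \cdot n \rceil} annotations
#' without replacement.  Used once per training epoch (keeping 2/3 of
#' the provided points) to regularize the ground-truth count map; a
#' fresh draw is taken on every call unless `seed` is given.
#'
#' @param points Data frame of annotations (>= 1 row).
#' @param fraction Keep fraction in (0, 1\].
#' @param seed Optional seed for a reproducible draw.
#' @return A subset of the rows of `points`.
#' @export
subsample_annotations <- function(points, fraction = 2 / 3, seed = NULL) {
  n <- NROW(points)
  if (n == 0L) stop("no annotations to subsample", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  k <- ceiling(fraction * n)
  idx <- if (is.null(seed)) sort(sample.int(n, k))
         else withr_seed(seed, sort(sample.int(n, k)))
  points[idx, , drop = FALSE]
}

#' Sample from a two-component beta mixture
#'
#' @param mix A [beta_mixture()].
#' @param n Number of draws (>= 1).
#' @param seed Optional seed.
#' @return Numeric vector of draws in (0, 1).
#' @export
sample_beta_mixture <- function(mix, n, seed = NULL) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  draw <- function() {
    k <- sample.int(2L, n, replace = TRUE, prob = mix$weights)
    rbeta(n, mix$alpha[k], mix$beta[k])
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Read or write point-annotation tables
#'
#' The on-disk format is a CSV with header `image,row,col`: an image
#' identifier and 0-based pixel coordinates.
#'
#' @param points Data frame with `image`, `row`, `col` columns.
#' @param path CSV file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_points_csv <- function(points, path) {
  stopifnot(all(c("image", "row", "col") %in% names(points)))
  write.csv(points[, c("image", "row", "col")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("image", "row", "col") %in% names(df)))
    stop("annotation CSV needs columns image,row,col", call. = FALSE)
  df
}

#' Persist a location or count map as single-channel TIFF
#'
#' @param map Numeric matrix.
#' @param path TIFF file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_map_tiff <- function(map, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF output", call. = FALSE)
  tiff::writeTIFF(map, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF input", call. = FALSE)
  tiff::readTIFF(path)
}
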