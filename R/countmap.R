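#' Count-map configuration
#'
#' The redundant count map is produced by summing a location map over an
#' \eqn{r \times r} square window centered at every pixel.  The kernel
#' size `r` should be slightly smaller than the diameter of the smallest
#' object so that a window never covers two objects, while still
#' spreading each point annotation over \eqn{r^2} entries (which is what
#' rebalances the positive rate for PU learning).
#'
#' @param r Odd positive integer, window side in pixels.
#' @param boundary_mode Only `"clip"` is supported: windows are clipped
#'   to the grid, so border entries sum fewer than \eqn{r^2} pixels.
#' @param min_object_diameter Optional declared diameter (pixels) of the
#'   smallest object; a warning (not an error) is raised when
#'   `r >= min_object_diameter`, since kernel choice is a user decision.
#' @return An object of class `countmap_config`.
#' @examples
#' cfg <- count_map_config(3)
#' @export
count_map_config <- function(r, boundary_mode = "clip",
                             min_object_diameter = NULL) {
  if (length(r) != 1L || !is.finite(r) || r < 1 || r %% 2 != 1)
    stop("kernel size `r` must be an odd positive integer", call. = FALSE)
  boundary_mode <- match.arg(boundary_mode, "clip")
  if (!is.null(min_object_diameter) && r >= min_object_diameter)
    warning("kernel size r = ", r, " is not smaller than the minimal ",
            "object diameter (", min_object_diameter, "); windows may ",
            "cover more than one object", call. = FALSE)
  structure(list(r = as.integer(r), boundary_mode = boundary_mode),
            class = "countmap_config")
}

as_countmap_config <- function(cfg) {
  if (inherits(cfg, "countmap_config")) return(cfg)
  if (is.numeric(cfg) && length(cfg) == 1L) return(count_map_config(cfg))
  stop("`cfg` must be a countmap_config or a single kernel size",
       call. = FALSE)
}

#' Redundant count map of a location map
#'
#' Every entry of the result is the sum of the location map inside the
#' boundary-clipped \eqn{r \times r} window centered at that pixel, so a
#' single point annotation contributes to \eqn{r^2} entries
#' ("redundancy").  The operator is linear, which also makes it the
#' gradient route from count-map losses back to the location map.
#'
#' Implemented with a summed-area table, so cost is independent of `r`.
#'
#' @param loc Non-negative numeric matrix (the location map); ground
#'   truth maps are binary with a 1 at each annotated center.
#' @param cfg A [count_map_config()] or a single odd kernel size.
#' @return Numeric matrix of the same shape as `loc`.
#' @examples
#' p <- matrix(0, 5, 5); p[3, 3] <- 1
#' make_count_map(p, 3)
#' @export
make_count_map <- function(loc, cfg) {
  cfg <- as_countmap_config(cfg)
  if (!is.matrix(loc) || nrow(loc) == 0L || ncol(loc) == 0L)
    stop("`loc` must be a non-empty matrix", call. = FALSE)
  if (any(loc < 0)) stop("location map must be non-negative", call. = FALSE)
  box_sum(loc, cfg$r)
}

# Clipped r x r box sum (integral image, compiled).
box_sum <- function(m, r) cpp_box_sum(m, as.integer(r))

#' Positive mask of a partially annotated count map
#'
#' Marks the count-map entries that are non-zero, i.e. the entries whose
#' window contains at least one provided annotation.  These are the
#' positive samples of the PU risk; the zero set is the unlabeled region.
#'
#' @param cmap Count map matrix (from [make_count_map()] applied to the
#'   partially annotated ground-truth location map).
#' @return A list of class `positive_mask` with elements `values`
#'   (binary matrix) and `n_positive`.
#' @export
positive_mask <- function(cmap) {
  if (!is.matrix(cmap)) stop("`cmap` must be a matrix", call. = FALSE)
  v <- (cmap != 0) * 1
  structure(list(values = v, n_positive = sum(v)), class = "positive_mask")
}

#' Estimate the positive class prior from scene statistics
#'
#' The prior is the expected proportion of non-zero entries in a fully
#' annotated count map: with `mu` objects per image on average, each
#' contributing a block of about \eqn{r^2} non-zero entries, the
#' proportion is \eqn{\mu r^2 / (\omega h)} (capped at 1).  In practice
#' a fixed prior of 0.1 is used for training (see [train_config()]);
#' this helper makes the scene-based estimate available for checking
#' that choice against a dataset.
#'
#' @param mu Average number of objects per image (>= 0).
#' @param cfg A [count_map_config()] or kernel size.
#' @param h,w Count-map height and width in pixels.
#' @return The estimated prior, a number in \[0, 1\].
#' @examples
#' estimate_class_prior(28, 7, 500, 500)
#' @export
estimate_class_prior <- function(mu, cfg, h, w) {
  cfg <- as_countmap_config(cfg)
  if (mu < 0) stop("`mu` must be non-negative", call. = FALSE)
  if (h <= 0 || w <= 0) stop("dimensions must be positive", call. = FALSE)
  min(1, mu * cfg$r^2 / (w * h))
}

#' Central response of a kernel-matched Gaussian
#'
#' Baseline for judging peak prominence: the density at the center of a
#' unit-mass isotropic 2-D Gaussian whose \eqn{3\sigma} radius equals
#' half the kernel (\eqn{\sigma = r/6}, so the kernel covers ~99.7% of
#' the mass), i.e. \eqn{1/(2\pi\sigma^2)}.  Peaks of a trained location
#' map are expected to exceed this value by a large margin, because the
#' count-map objective concentrates each object's unit mass at its
#' center instead of spreading it as a Gaussian.
#'
#' @param cfg A [count_map_config()] or kernel size.
#' @return The central density (location-map response units).
#' @examples
#' gaussian_center_response(7)   # ~0.117
#' @export
gaussian_center_response <- function(cfg) {
  cfg <- as_countmap_config(cfg)
  sigma <- cfg$r / 6
  1 / (2 * pi * sigma^2)
}

#' Rasterize point annotations into a binary location map
#'
#' @param points Data frame with 0-based `row` and `col` columns
#'   (pixels); fractional coordinates are rounded to the nearest pixel,
#'   ties toward the smaller index.
#' @param height,width Map dimensions in pixels.
#' @return Binary matrix with a 1 at each annotated pixel.
#' @export
location_map_from_points <- function(points, height, width) {
  m <- matrix(0, height, width)
  if (NROW(points) == 0L) return(m)
  ri <- ceiling(points$row - 0.5) + 1L   # 0-based -> 1-based, ties down
  ci <- ceiling(points$col - 0.5) + 1L
  if (any(ri < 1L | ri > height | ci < 1L | ci > width))
    stop("annotation outside the image", call. = FALSE)
  m[cbind(ri, ci)] <- 1
  m
}
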