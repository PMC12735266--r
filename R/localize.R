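#' Find object locations as prominent local maxima
#'
#' Detects pixels that are maxima of their \eqn{r \times r} Chebyshev
#' (square-window) neighborhood with value at least `min_value`.
#' Plateau ties resolve to the lexicographically smallest (row, col),
#' and no two reported peaks lie within \eqn{\lfloor r/2 \rfloor}
#' Chebyshev distance of one another (greedy suppression in decreasing
#' value order).  Square neighborhoods match the square summation
#' kernel that shapes the training objective.
#'
#' @param loc Non-negative location-map matrix.
#' @param cfg A [count_map_config()] or kernel size.
#' @param min_value Minimum peak value.  Default `0.1 * max(loc)`:
#'   scale-free, and removes the near-zero ripple a ReLU output floor
#'   leaves in flat regions.
#' @return A data frame of class `peak_set` with 0-based `row`, `col`,
#'   `value`, and `proportion` (peak value over its own r x r window
#'   sum).
#' @export
find_peaks <- function(loc, cfg, min_value = NULL) {
  cfg <- as_countmap_config(cfg)
  if (any(loc < 0)) stop("location map must be non-negative", call. = FALSE)
  r <- cfg$r; p <- (r - 1L) %/% 2L
  H <- nrow(loc); W <- ncol(loc)
  if (is.null(min_value)) min_value <- 0.1 * max(loc)
  # r x r maximum filter via shifted pmax
  mf <- loc
  for (du in -p:p) for (dv in -p:p) {
    if (du == 0 && dv == 0) next
    rs <- max(1, 1 - du):min(H, H - du)
    cs <- max(1, 1 - dv):min(W, W - dv)
    mf[rs, cs] <- pmax(mf[rs, cs], loc[rs + du, cs + dv])
  }
  cand <- which(loc >= mf & loc >= min_value & loc > 0, arr.ind = TRUE)
  out <- data.frame(row = integer(0), col = integer(0),
                    value = numeric(0), proportion = numeric(0))
  if (nrow(cand)) {
    vals <- loc[cand]
    ord <- order(-vals, cand[, 1L], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (any(keep &
              abs(cand[, 1L] - cand[i, 1L]) <= p &
              abs(cand[, 2L] - cand[i, 2L]) <= p)) next
      keep[i] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]
    wsum <- box_sum(loc, r)[cand]
    out <- data.frame(row = cand[, 1L] - 1L, col = cand[, 2L] - 1L,
                      value = vals, proportion = vals / wsum)
    out <- out[order(out$row, out$col), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("peak_set", class(out))
  attr(out, "r") <- r
  out
}

#' Summarize peak prominence
#'
#' Mean and standard deviation of the detected peak values and of their
#' proportions of the surrounding \eqn{r \times r} window sum, with the
#' kernel-matched Gaussian central density
#' ([gaussian_center_response()]) as the comparison baseline.  A
#' count-map-trained model concentrates each object's unit mass near
#' its center, so trained peaks exceed the Gaussian baseline (by how
#' much depends on how sharply training has concentrated the mass).
#'
#' @param detections A [find_peaks()] result (needs >= 1 peak).
#' @param cfg A [count_map_config()] or kernel size.
#' @return A list with `n`, `mean_value`, `sd_value`,
#'   `mean_proportion`, `sd_proportion`, `gaussian_center`.
#' @export
peak_prominence_stats <- function(detections, cfg) {
  cfg <- as_countmap_config(cfg)
  if (NROW(detections) == 0L)
    stop("no detections to summarize", call. = FALSE)
  list(n = nrow(detections),
       mean_value = mean(detections$value),
       sd_value = if (nrow(detections) > 1L) sd(detections$value) else 0,
       mean_proportion = mean(detections$proportion),
       sd_proportion = if (nrow(detections) > 1L) sd(detections$proportion) else 0,
       gaussian_center = gaussian_center_response(cfg))
}
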