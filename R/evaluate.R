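as_point_df <- function(x) {
  if (is.matrix(x)) x <- data.frame(row = x[, 1L], col = x[, 2L])
  if (NROW(x) && !all(c("row", "col") %in% names(x)))
    stop("points need `row` and `col` columns", call. = FALSE)
  x
}

#' Match predicted to ground-truth points at a distance threshold
#'
#' A prediction counts as a true positive when it can be paired
#' one-to-one with a ground-truth point at Euclidean distance at most
#' `threshold` pixels.  The default matcher is greedy
#' nearest-first: all within-threshold pairs are sorted by (distance,
#' gt index, pred index) and consumed while both endpoints are free,
#' which is deterministic and mirrors "nearest prediction" matching.
#' `method = "optimal"` instead computes, by exhaustive search over
#' injections (feasible for small point sets), a maximum-cardinality
#' matching of minimum total distance, for sensitivity checks.
#'
#' @param gt,pred Data frames (or 2-column matrices) of 0-based `row`,
#'   `col` coordinates in pixels.
#' @param threshold Matching radius in pixels (> 0).  Typical presets:
#'   6 px for histopathology nuclei, the minimal object radius for
#'   animal datasets (e.g. 12 px honeybee-like, 5 px fish-like).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A list of class `match_result`: `pairs` (data frame `gt`,
#'   `pred`, `distance`; indices 1-based into the inputs),
#'   `unmatched_gt`, `unmatched_pred`, `threshold`, `n_gt`, `n_pred`.
#' @export
match_points <- function(gt, pred, threshold,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  gt <- as_point_df(gt); pred <- as_point_df(pred)
  ng <- NROW(gt); np <- NROW(pred)
  D <- if (ng && np)
    sqrt(outer(gt$row, pred$row, "-")^2 + outer(gt$col, pred$col, "-")^2)
  else matrix(numeric(0), ng, np)
  pairs <- data.frame(gt = integer(0), pred = integer(0),
                      distance = numeric(0))
  if (ng && np) {
    if (method == "greedy") {
      cand <- which(D <= threshold, arr.ind = TRUE)
      if (nrow(cand)) {
        d <- D[cand]
        ord <- order(d, cand[, 1L], cand[, 2L])
        cand <- cand[ord, , drop = FALSE]; d <- d[ord]
        gfree <- rep(TRUE, ng); pfree <- rep(TRUE, np)
        for (i in seq_len(nrow(cand))) {
          g <- cand[i, 1L]; p <- cand[i, 2L]
          if (gfree[g] && pfree[p]) {
            gfree[g] <- FALSE; pfree[p] <- FALSE
            pairs <- rbind(pairs,
                           data.frame(gt = g, pred = p, distance = d[i]))
          }
        }
      }
    } else {
      pairs <- optimal_match(D, threshold)
    }
  }
  structure(list(pairs = pairs,
                 unmatched_gt = setdiff(seq_len(ng), pairs$gt),
                 unmatched_pred = setdiff(seq_len(np), pairs$pred),
                 threshold = threshold, n_gt = ng, n_pred = np),
            class = "match_result")
}

# Exhaustive maximum-cardinality, minimum-total-distance matching under
# a distance threshold.  Enumerates assignments of the smaller side;
# practical up to ~8 points per side.
optimal_match <- function(D, threshold) {
  ng <- nrow(D); np <- ncol(D)
  if (min(ng, np) > 8L)
    stop("optimal matching is exhaustive; limited to 8 points per side",
         call. = FALSE)
  A <- D; A[A > threshold] <- Inf
  best <- list(k = -1L, cost = Inf, gt = integer(0), pred = integer(0))
  gt_idx <- seq_len(ng)
  search <- function(g, used, cost, mg, mp) {
    # prune: even matching everything left cannot beat best cardinality
    remain <- ng - g + 1L
    if (length(mg) + remain < best$k) return()
    if (g > ng) {
      k <- length(mg)
      if (k > best$k || (k == best$k && cost < best$cost))
        best <<- list(k = k, cost = cost, gt = mg, pred = mp)
      return()
    }
    for (p in seq_len(np)) {
      if (!used[p] && is.finite(A[g, p])) {
        used[p] <- TRUE
        search(g + 1L, used, cost + A[g, p], c(mg, g), c(mp, p))
        used[p] <- FALSE
      }
    }
    search(g + 1L, used, cost, mg, mp)  # leave g unmatched
  }
  search(1L, rep(FALSE, np), 0, integer(0), integer(0))
  data.frame(gt = best$gt, pred = best$pred,
             distance = if (length(best$gt)) D[cbind(best$gt, best$pred)]
                        else numeric(0))
}

#' Detection precision, recall and F1
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1 = 2 p r / (p + r)`.  Empty-denominator conventions: with no
#' predictions, precision is 1 when there is also no ground truth and 0
#' otherwise; with no ground truth, recall is 1 when there are also no
#' predictions and 0 otherwise; F1 is 0 whenever `p + r = 0`.
#'
#' @param match A [match_points()] result.
#' @return A list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
detection_scores <- function(match) {
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  precision <- if (tp + fp == 0) as.numeric(match$n_gt == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) as.numeric(match$n_pred == 0) else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Mean localization error
#'
#' Mean Euclidean distance over matched gt-prediction pairs; every
#' unmatched ground-truth point (miss) and unmatched prediction (false
#' alarm) contributes a fixed penalty distance.  The penalty defaults
#' to the matching threshold; the convention is exposed because
#' published protocols differ on it.
#'
#' @param match A [match_points()] result.
#' @param penalty Distance (px) charged per unmatched point.
#' @return Mean localization error in pixels.
#' @export
mean_localization_error <- function(match, penalty = match$threshold) {
  n_un <- length(match$unmatched_gt) + length(match$unmatched_pred)
  n <- nrow(match$pairs) + n_un
  if (n == 0L)
    stop("mean localization error undefined: no points at all",
         call. = FALSE)
  (sum(match$pairs$distance) + penalty * n_un) / n
}

#' One-call evaluation of predicted against true centers
#'
#' @inheritParams match_points
#' @param mle_penalty Passed to [mean_localization_error()].
#' @return A list with `precision`, `recall`, `f1`, `mle`, `tp`, `fp`,
#'   `fn`.
#' @export
evaluate_detections <- function(gt, pred, threshold,
                                method = c("greedy", "optimal"),
                                mle_penalty = threshold) {
  m <- match_points(gt, pred, threshold, method)
  s <- detection_scores(m)
  s$mle <- if (m$n_gt + m$n_pred > 0)
    mean_localization_error(m, mle_penalty) else NA_real_
  s
}
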