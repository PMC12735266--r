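PART_LEVELS <- c("ignored", "provided_positive", "clear_negative",
                 "predicted_positive", "predicted_negative")

#' Partition the unlabeled count-map region with mixture posteriors
#'
#' Splits every count-map coordinate into the sets that drive the
#' positive-negative refinement stage:
#' * provided positives: non-zero entries of the partial ground-truth
#'   count map (the annotation mask always wins), plus predicted peaks
#'   within \eqn{\lceil r/2 \rceil} Chebyshev distance of one, which
#'   are absorbed rather than double-counted;
#' * clear negatives: unlabeled entries with raw loss below the
#'   clear-negative threshold;
#' * predicted positives: remaining peaks whose posterior probability
#'   of being a hidden object is at least `tau_pos`;
#' * predicted negatives: remaining peaks with posterior at most
#'   `tau_neg`, and every unlabeled non-peak coordinate;
#' * ignored: peaks with posterior strictly between the thresholds
#'   (too uncertain to risk a false label).
#'
#' @param peaks A [find_peaks()] data frame with an added `posterior`
#'   column (from [posterior_noisy()] on the raw loss at each peak).
#' @param losses An [unlabeled_losses()] object for the same image.
#' @param mask A [positive_mask()] of the partial ground-truth count
#'   map.
#' @param tau_pos,tau_neg Confidence thresholds,
#'   `0 <= tau_neg <= tau_pos <= 1`.  Defaults 0.95 / 0.05 leave an
#'   ignored band so uncertain peaks inject no false labels.
#' @return A list of class `pseudo_partition`: `codes` (matrix of the
#'   set name per coordinate), `counts` (named totals), and
#'   `peaks` (the input peaks with their assigned set).
#' @export
partition_unlabeled <- function(peaks, losses, mask,
                                tau_pos = 0.95, tau_neg = 0.05) {
  if (!(tau_neg >= 0 && tau_neg <= tau_pos && tau_pos <= 1))
    stop("need 0 <= tau_neg <= tau_pos <= 1", call. = FALSE)
  M <- mask$values
  H <- nrow(M); W <- ncol(M)
  codes <- matrix("predicted_negative", H, W)
  codes[M == 1] <- "provided_positive"
  if (nrow(losses$clear_coords))
    codes[cbind(losses$clear_coords$row + 1L,
                losses$clear_coords$col + 1L)] <- "clear_negative"
  # clear_negative never overrides a provided positive
  codes[M == 1] <- "provided_positive"
  peak_set <- character(nrow(peaks))
  if (nrow(peaks)) {
    if (is.null(peaks$posterior))
      stop("`peaks` must carry a `posterior` column", call. = FALSE)
    r <- attr(peaks, "r")
    if (is.null(r)) r <- 3L
    absorb <- ceiling(r / 2)
    pos_idx <- which(M == 1, arr.ind = TRUE)
    for (i in seq_len(nrow(peaks))) {
      ri <- peaks$row[i] + 1L; ci <- peaks$col[i] + 1L
      near_provided <- nrow(pos_idx) > 0 &&
        any(abs(pos_idx[, 1L] - ri) <= absorb &
            abs(pos_idx[, 2L] - ci) <= absorb)
      if (M[ri, ci] == 1 || near_provided) {
        peak_set[i] <- "provided_positive"
        codes[ri, ci] <- "provided_positive"
      } else if (codes[ri, ci] == "clear_negative") {
        peak_set[i] <- "clear_negative"
      } else if (peaks$posterior[i] >= tau_pos) {
        peak_set[i] <- "predicted_positive"
        codes[ri, ci] <- "predicted_positive"
      } else if (peaks$posterior[i] <= tau_neg) {
        peak_set[i] <- "predicted_negative"
      } else {
        peak_set[i] <- "ignored"
        codes[ri, ci] <- "ignored"
      }
    }
  }
  peaks$set <- peak_set
  counts <- vapply(PART_LEVELS, function(s) sum(codes == s), numeric(1))
  structure(list(codes = codes, counts = counts, peaks = peaks),
            class = "pseudo_partition")
}

#' Positive-negative refinement loss
#'
#' The L2-tanh loss of the refinement stage:
#' \deqn{L = \frac{1}{N}\Big(\sum_{\Phi^+} (C_{pre}-1)^2 +
#'   \sum_{\Phi^-} \tanh C_{pre}\Big),}
#' where \eqn{\Phi^+} is provided plus predicted positives (each
#' assumed to cover exactly one object, hence count target 1) and
#' \eqn{\Phi^-} is clear plus predicted negatives.  Ignored
#' coordinates contribute nothing; \eqn{N} is the total entry count.
#'
#' @param cpre Predicted count map.
#' @param part A [partition_unlabeled()] result of matching shape.
#' @return Scalar loss.
#' @export
pn_loss <- function(cpre, part) {
  check_same_shape(cpre, part$codes)
  pos <- part$codes %in% c("provided_positive", "predicted_positive")
  neg <- part$codes %in% c("clear_negative", "predicted_negative")
  if (!any(pos))
    stop_no_positives("refinement loss undefined: empty positive set")
  (sum((cpre[pos] - 1)^2) + sum(tanh(cpre[neg]))) / length(cpre)
}

# pn loss and its gradient wrt the predicted count map.
pn_loss_with_grad <- function(cpre, part) {
  pos <- part$codes %in% c("provided_positive", "predicted_positive")
  neg <- part$codes %in% c("clear_negative", "predicted_negative")
  if (!any(pos))
    stop_no_positives("refinement loss undefined: empty positive set")
  n <- length(cpre)
  g <- matrix(0, nrow(cpre), ncol(cpre))
  g[pos] <- 2 * (cpre[pos] - 1) / n
  g[neg] <- (1 / cosh(cpre[neg])^2) / n
  list(value = (sum((cpre[pos] - 1)^2) + sum(tanh(cpre[neg]))) / n,
       grad = g)
}

#' Dump a pseudo-label partition for audit
#'
#' Writes one `row,col,set` line (0-based coordinates) per non-default
#' coordinate: every provided/predicted positive and ignored
#' coordinate, plus peak rows; the ubiquitous negative sets are
#' summarized by the `counts` element instead of being enumerated.
#'
#' @param part A [partition_unlabeled()] result.
#' @param path CSV path.
#' @param all Write every coordinate (large!) instead of the compact
#'   form.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(part, path, all = FALSE) {
  keep <- if (all) part$codes != ""
          else !(part$codes %in% c("clear_negative", "predicted_negative"))
  dim(keep) <- dim(part$codes)   # %in% drops the matrix shape
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L,
                   set = part$codes[idx])
  write.csv(df[order(df$row, df$col), ], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
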