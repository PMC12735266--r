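#' PU risk configuration
#'
#' @param class_prior Positive class prior \eqn{\pi_p} in (0, 1): the
#'   marginal probability that a count-map entry is positive.  Default
#'   0.1, the fixed value used for training throughout; see
#'   [estimate_class_prior()] for the scene-based estimate.
#' @param kernel A [count_map_config()] or kernel size.
#' @return An object of class `pu_risk_config`.
#' @export
pu_risk_config <- function(class_prior = 0.1, kernel = count_map_config(7)) {
  if (class_prior <= 0 || class_prior >= 1)
    stop("`class_prior` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(class_prior = class_prior,
                 kernel = as_countmap_config(kernel)),
            class = "pu_risk_config")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("count map / mask shapes differ", call. = FALSE)
}

#' Positive-sample empirical risk
#'
#' Mean squared error between predicted and ground-truth count maps over
#' the positive (non-zero ground truth) entries only:
#' \eqn{\frac{1}{N_p}\lVert (C_{pre}-\tilde C_{gt})\odot M \rVert_F^2}.
#'
#' Maps from several images may be concatenated (e.g. with `cbind`)
#' into one matrix; the risk only involves entrywise sums, so batch
#' totals come out right.
#'
#' @param cpre Predicted count map.
#' @param cgt Ground-truth count map from the provided annotations.
#' @param mask A [positive_mask()] of `cgt`.
#' @return Non-negative scalar.
#' @export
positive_risk <- function(cpre, cgt, mask) {
  check_same_shape(cpre, cgt); check_same_shape(cpre, mask$values)
  if (mask$n_positive == 0)
    stop_no_positives("positive risk undefined: batch has no positive entries")
  sum(((cpre - cgt) * mask$values)^2) / mask$n_positive
}

stop_no_positives <- function(msg) {
  stop(structure(class = c("pulocalize_no_positives", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Debiased negative risk with tanh suppression
#'
#' The unlabeled-minus-positive negative risk
#' \eqn{\hat R_u^- - \pi_p \hat R_p^-} instantiated with a hyperbolic
#' tangent of the predicted counts, which saturates large responses and
#' suppresses background noise:
#' \deqn{\frac{1}{N}\sum_{ij} \tanh C_{pre}(i,j)
#'   - \frac{\pi_p}{N_p}\sum_{ij} \tanh C_{pre}(i,j)\, M(i,j).}
#' With no positive entries in the batch the subtracted term is defined
#' as 0.
#'
#' @inheritParams positive_risk
#' @param cfg A [pu_risk_config()].
#' @return Scalar (possibly negative; the clamp lives in
#'   [nonneg_pu_risk()]).
#' @export
negative_risk_tanh <- function(cpre, mask, cfg) {
  check_same_shape(cpre, mask$values)
  th <- tanh(cpre)
  pos <- if (mask$n_positive > 0)
    cfg$class_prior * sum(th * mask$values) / mask$n_positive
  else 0
  mean(th) - pos
}

#' Non-negative PU risk over count maps
#'
#' Combines the positive and debiased negative risks as
#' \deqn{\hat R_{pu} = \pi_p \hat R_p^+ +
#'   \max\big(0,\ \hat R_u^- - \pi_p \hat R_p^-\big).}
#' Clamping the negative part at zero is what keeps a flexible model
#' from driving the estimated negative risk below zero and overfitting
#' the unlabeled region.  When the clamp is active the subgradient of
#' the clamped term is taken as zero.
#'
#' @inheritParams positive_risk
#' @param cfg A [pu_risk_config()].
#' @return A list of class `pu_risk_value` with `total`,
#'   `positive_term` (\eqn{\hat R_p^+}, unweighted), `negative_term`,
#'   and `clamped`.
#' @export
nonneg_pu_risk <- function(cpre, cgt, mask, cfg) {
  rp <- positive_risk(cpre, cgt, mask)
  rn <- negative_risk_tanh(cpre, mask, cfg)
  clamped <- rn < 0
  structure(list(total = cfg$class_prior * rp + max(0, rn),
                 positive_term = rp, negative_term = rn,
                 clamped = clamped),
            class = "pu_risk_value")
}

# Risk and its gradient with respect to the predicted count map, for the
# trainer.  Returns list(value = pu_risk_value, grad = matrix).
pu_risk_with_grad <- function(cpre, cgt, mask, cfg) {
  val <- nonneg_pu_risk(cpre, cgt, mask, cfg)
  np <- mask$n_positive
  g <- cfg$class_prior * 2 * (cpre - cgt) * mask$values / np
  if (!val$clamped) {
    sech2 <- 1 / cosh(cpre)^2
    w <- 1 / length(cpre) -
      if (np > 0) cfg$class_prior * mask$values / np else 0
    g <- g + sech2 * w
  }
  list(value = val, grad = g)
}
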