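#' Two-component beta mixture
#'
#' Container for the label-noise model fitted to normalized
#' unlabeled-region losses.  Component 1 is the "clean" (low-loss,
#' truly negative) component, component 2 the "noisy" one (high loss,
#' i.e. a hidden positive the provided annotations missed); components
#' are kept sorted by mean \eqn{\alpha/(\alpha+\beta)}.
#'
#' @param weights Mixing weights, length 2, non-negative, summing to 1.
#' @param alpha,beta Shape parameters, length 2, strictly positive.
#' @param bounds Optional `c(lo, hi)` raw-loss normalization bounds
#'   (carried over from [unlabeled_losses()] so that posteriors can be
#'   queried for raw losses).
#' @param eps Normalization margin used with `bounds`.
#' @return An object of class `beta_mixture`.
#' @export
beta_mixture <- function(weights, alpha, beta, bounds = NULL, eps = 1e-4) {
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must be two non-negative values summing to 1",
         call. = FALSE)
  if (length(alpha) != 2L || length(beta) != 2L ||
      any(alpha <= 0) || any(beta <= 0))
    stop("shape parameters must be strictly positive", call. = FALSE)
  means <- alpha / (alpha + beta)
  ord <- order(means)
  structure(list(weights = weights[ord], alpha = alpha[ord],
                 beta = beta[ord], bounds = bounds, eps = eps),
            class = "beta_mixture")
}

#' Losses of the unlabeled count-map region
#'
#' For every coordinate where the (partial) ground-truth count map is
#' zero, the negative loss is the squared predicted count
#' \eqn{l_{ij} = C_{pre}(i,j)^2}.  Entries with \eqn{l < 0.01} are clear
#' negatives: they would dominate the mixture fit and are removed before
#' modeling.  Survivors are mapped affinely to \eqn{(\epsilon,
#' 1-\epsilon)} so a beta mixture has support over them; the bounds are
#' recorded so any raw loss can be normalized later.
#'
#' @param cpre Predicted count map.
#' @param cgt Partially annotated ground-truth count map (zeros define
#'   the unlabeled region).
#' @param clear_threshold Raw-loss threshold below which an entry is a
#'   clear negative (default 0.01).
#' @param eps Margin of the affine map into the open unit interval.
#' @return A list of class `unlabeled_losses` with a data frame `coords`
#'   (`row`, `col`, 0-based, survivors only), `raw`, `norm`, `bounds`,
#'   `eps`, `n_clear` and a data frame `clear_coords`.
#' @export
unlabeled_losses <- function(cpre, cgt, clear_threshold = 0.01,
                             eps = 1e-4) {
  check_same_shape(cpre, cgt)
  idx <- which(cgt == 0, arr.ind = TRUE)
  raw <- cpre[idx]^2
  keep <- raw >= clear_threshold
  coords <- data.frame(row = idx[keep, 1L] - 1L, col = idx[keep, 2L] - 1L)
  clear_coords <- data.frame(row = idx[!keep, 1L] - 1L,
                             col = idx[!keep, 2L] - 1L)
  raw <- raw[keep]
  bounds <- if (length(raw)) range(raw) else c(NA_real_, NA_real_)
  structure(list(coords = coords, raw = raw,
                 norm = normalize_raw_loss(raw, bounds, eps),
                 bounds = bounds, eps = eps,
                 n_clear = sum(!keep), clear_coords = clear_coords,
                 clear_threshold = clear_threshold),
            class = "unlabeled_losses")
}

normalize_raw_loss <- function(raw, bounds, eps) {
  if (!length(raw)) return(numeric(0))
  lo <- bounds[1L]; hi <- bounds[2L]
  if (!is.finite(lo) || hi - lo < .Machine$double.eps)
    return(rep(0.5, length(raw)))
  pmin(1 - eps, pmax(eps, eps + (1 - 2 * eps) * (raw - lo) / (hi - lo)))
}

stop_empty_losses <- function(msg) {
  stop(structure(class = c("pulocalize_empty_losses", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Weighted method-of-moments estimate of beta shapes.
beta_moments <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  v <- max(v, 1e-8)
  t0 <- max(m * (1 - m) / v - 1, 1e-3)
  c(alpha = clamp_shape(m * t0), beta = clamp_shape((1 - m) * t0))
}

clamp_shape <- function(s) min(max(s, 1e-3), 1e4)

# Weighted maximum-likelihood beta shapes (via optim on log-shapes),
# started from the moment estimates.  Returns whichever of {current
# shapes, moment start, optim result} has the best weighted likelihood,
# so an EM iteration using it can never decrease the Q-function — a
# generalized EM with monotone observed-data log-likelihood.
beta_wmle <- function(x, w, start, current = NULL) {
  nll <- function(p) {
    a <- exp(p[1L]); b <- exp(p[2L])
    -sum(w * dbeta(x, a, b, log = TRUE))
  }
  cand <- list(start)
  if (!is.null(current)) cand <- c(cand, list(current))
  fit <- try(optim(log(start), nll, method = "BFGS",
                   control = list(maxit = 50)), silent = TRUE)
  if (!inherits(fit, "try-error") && all(is.finite(fit$par)))
    cand <- c(cand, list(c(clamp_shape(exp(fit$par[1L])),
                           clamp_shape(exp(fit$par[2L])))))
  vals <- vapply(cand, function(p) nll(log(p)), numeric(1))
  best <- cand[[which.min(vals)]]
  c(alpha = best[1L], beta = best[2L])
}

mixture_logdens <- function(x, mix) {
  # columns: per-component log(lambda_k) + log Beta(x | a_k, b_k)
  sapply(1:2, function(k)
    log(mix$weights[k] + 1e-300) +
      dbeta(x, mix$alpha[k], mix$beta[k], log = TRUE))
}

log_sum_exp_rows <- function(m) {
  mx <- pmax(m[, 1L], m[, 2L])
  mx + log(exp(m[, 1L] - mx) + exp(m[, 2L] - mx))
}

#' Fit a two-component beta mixture by EM
#'
#' Models the normalized unlabeled losses as
#' \eqn{p(l) = \sum_k \lambda_k \mathrm{Beta}(l\,|\,\alpha_k,\beta_k)}.
#' The E-step computes responsibilities in log space; the M-step updates
#' the mixing weights as mean responsibilities and the shapes by
#' weighted maximum likelihood, started from weighted method-of-moments
#' estimates (a generalized EM step, so the observed-data log-likelihood
#' is non-decreasing).  `m_step = "moments"` uses the moment estimates
#' alone — faster, but it can overshoot the likelihood near convergence.
#' Initialization splits the data at its median and
#' moment-fits each half, so the fit is deterministic given the data;
#' `seed` only drives the single re-initialization attempted if a
#' component collapses onto fewer than two effective points.
#'
#' @param losses An [unlabeled_losses()] object, or a numeric vector of
#'   values in (0, 1).
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param seed Integer used only for the re-initialization fallback.
#' @param m_step `"mle"` (default) or `"moments"`.
#' @return A [beta_mixture()] with extra fields `loglik` (trace),
#'   `converged`, `iterations`, `n`.
#' @export
fit_bmm_em <- function(losses, max_iter = 100L, tol = 1e-6, seed = 1L,
                       m_step = c("mle", "moments")) {
  m_step <- match.arg(m_step)
  bounds <- NULL; eps <- 1e-4
  if (inherits(losses, "unlabeled_losses")) {
    bounds <- losses$bounds; eps <- losses$eps
    x <- losses$norm
  } else x <- losses
  if (length(x) < 10L)
    stop_empty_losses("too few unlabeled losses to fit a mixture (need >= 10)")
  if (any(x <= 0 | x >= 1))
    stop("losses must lie strictly inside (0, 1)", call. = FALSE)

  init_split <- function(q) {
    cut <- stats::quantile(x, q)
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (length(hi) < 2L) { lo <- x[x < cut]; hi <- x[x >= cut] }
    if (length(lo) < 2L || length(hi) < 2L) { lo <- hi <- x }
    s1 <- beta_moments(lo, rep(1, length(lo)))
    s2 <- beta_moments(hi, rep(1, length(hi)))
    list(weights = c(length(lo), length(hi)) / (length(lo) + length(hi)),
         alpha = c(s1[1L], s2[1L]), beta = c(s1[2L], s2[2L]))
  }

  run_em <- function(par) {
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      mix <- list(weights = par$weights, alpha = par$alpha, beta = par$beta)
      ld <- mixture_logdens(x, mix)
      ll <- sum(log_sum_exp_rows(ld))
      resp <- exp(ld - log_sum_exp_rows(ld))  # n x 2 responsibilities
      neff <- colSums(resp)
      if (any(neff < 2)) return(list(degenerate = TRUE))
      par$weights <- neff / length(x)
      for (k in 1:2) {
        est <- beta_moments(x, resp[, k])
        if (m_step == "mle")
          est <- beta_wmle(x, resp[, k], est,
                           current = c(par$alpha[k], par$beta[k]))
        par$alpha[k] <- est[1L]; par$beta[k] <- est[2L]
      }
      ll_trace <- c(ll_trace, ll)
      if (it > 1L && abs(ll - ll_trace[it - 1L]) < tol) break
    }
    list(degenerate = FALSE, par = par, loglik = ll_trace,
         converged = it < max_iter, iterations = it)
  }

  fit <- run_em(init_split(0.5))
  if (fit$degenerate) {
    q <- withr_seed(seed, runif(1, 0.25, 0.75))
    fit <- run_em(init_split(q))
    if (fit$degenerate)
      stop("beta mixture fit degenerated twice; not enough spread in losses",
           call. = FALSE)
  }
  out <- beta_mixture(fit$par$weights, fit$par$alpha, fit$par$beta,
                      bounds = bounds, eps = eps)
  out$loglik <- fit$loglik
  out$converged <- fit$converged
  out$iterations <- fit$iterations
  out$n <- length(x)
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Posterior probability that an unlabeled entry is a hidden positive
#'
#' Evaluates \eqn{p(k = 2 \mid l) = \lambda_2 \mathrm{Beta}(l |
#' \alpha_2, \beta_2) / \sum_k \lambda_k \mathrm{Beta}(l | \alpha_k,
#' \beta_k)} in log space (component 2 is the high-mean, "noisy label"
#' component, i.e. a true object the annotations missed).
#'
#' @param mix A [beta_mixture()].
#' @param l Loss values.  Normalized values in (0, 1) by default; with
#'   `raw = TRUE` they are raw squared counts, normalized with the
#'   bounds stored in `mix`.
#' @param raw Whether `l` is on the raw scale.
#' @return Posterior probabilities in \[0, 1\].
#' @export
posterior_noisy <- function(mix, l, raw = FALSE) {
  if (raw) {
    if (is.null(mix$bounds))
      stop("mixture carries no normalization bounds", call. = FALSE)
    l <- normalize_raw_loss(l, mix$bounds, mix$eps)
  }
  if (any(l <= 0 | l >= 1))
    stop("normalized losses must lie strictly inside (0, 1)", call. = FALSE)
  ld <- mixture_logdens(l, mix)
  if (length(l) == 1L) ld <- matrix(ld, nrow = 1L)
  exp(ld[, 2L] - log_sum_exp_rows(ld))
}

#' Serialize a fitted beta mixture to JSON
#'
#' @param mix A [beta_mixture()].
#' @param path File path; the mixture's weights, shapes and
#'   normalization bounds are written for inspection or reload.
#' @return `path`, invisibly.
#' @export
write_beta_mixture <- function(mix, path) {
  jsonlite::write_json(list(weights = mix$weights, alpha = mix$alpha,
                            beta = mix$beta, bounds = mix$bounds,
                            eps = mix$eps),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_beta_mixture
#' @export
read_beta_mixture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta_mixture(x$weights, x$alpha, x$beta,
               bounds = if (length(x$bounds)) x$bounds else NULL,
               eps = x$eps)
}
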