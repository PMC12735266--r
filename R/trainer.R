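#' Training configuration for the two-stage schedule
#'
#' Stage 1 trains the predictor under the non-negative PU risk from the
#' provided annotations only; stage 2 (pseudo-labeling) starts from the
#' best stage-1 weights, fits a beta mixture to the unlabeled-region
#' losses each epoch, partitions the unlabeled region, and minimizes
#' the positive-negative L2-tanh loss at a learning rate 100x smaller.
#'
#' @param kernel A [count_map_config()] or kernel size `r`.
#' @param class_prior Positive class prior (default 0.1).
#' @param lr_stage1,lr_stage2 Adam learning rates (defaults 1e-4 and
#'   1e-6).  The published rates assume batches larger than 8 images;
#'   with smaller batches the rates are scaled down linearly with the
#'   batch size (`scale_lr_small_batch`).
#' @param epochs_stage1,epochs_stage2 Epochs per stage (default 100).
#' @param batch_n Batch composition factor `n`: every stage-1 batch
#'   holds `n` positive images, `n` augmented copies of them, and `2n`
#'   unlabeled images (batch size `4n`).
#' @param keep_fraction Fraction of each image's annotations resampled
#'   every epoch (default 2/3) to regularize the ground-truth maps.
#' @param eval_delay Epochs before validation F1 is first computed and
#'   checkpoint selection starts (default 20): early maps are noisy and
#'   peak search on them is wasted work.
#' @param tau_pos,tau_neg Pseudo-label confidence thresholds.
#' @param val_threshold Matching radius (px) for validation/selection.
#' @param min_peak_frac Peak threshold as a fraction of the map
#'   maximum, passed to [find_peaks()].
#' @param base_channels Width of the predictor ([predictor_config()]).
#' @param augment Use random 90-degree rotations and flips for the
#'   enhanced copies (rotations are skipped for non-square images).
#' @param scale_lr_small_batch See learning rates above.
#' @param lr_halve_patience Epochs of no validation improvement before
#'   the learning rate is halved (plateau schedule).
#' @param seed Master seed; fans out to weight init, annotation
#'   resampling, augmentation and batch order.
#' @param verbose Print a line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(kernel = count_map_config(7), class_prior = 0.1,
                         lr_stage1 = 1e-4, lr_stage2 = 1e-6,
                         epochs_stage1 = 100L, epochs_stage2 = 100L,
                         batch_n = 1L, keep_fraction = 2 / 3,
                         eval_delay = 20L, tau_pos = 0.95, tau_neg = 0.05,
                         val_threshold = 6, min_peak_frac = 0.1,
                         base_channels = 8L, augment = TRUE,
                         scale_lr_small_batch = TRUE,
                         lr_halve_patience = 10L,
                         seed = 1L, verbose = FALSE) {
  stopifnot(lr_stage1 > 0, lr_stage2 > 0, batch_n >= 1,
            keep_fraction > 0, keep_fraction <= 1,
            eval_delay >= 0, eval_delay < epochs_stage1)
  structure(list(kernel = as_countmap_config(kernel),
                 class_prior = class_prior,
                 lr_stage1 = lr_stage1, lr_stage2 = lr_stage2,
                 epochs_stage1 = as.integer(epochs_stage1),
                 epochs_stage2 = as.integer(epochs_stage2),
                 batch_n = as.integer(batch_n),
                 keep_fraction = keep_fraction,
                 eval_delay = as.integer(eval_delay),
                 tau_pos = tau_pos, tau_neg = tau_neg,
                 val_threshold = val_threshold,
                 min_peak_frac = min_peak_frac,
                 base_channels = as.integer(base_channels),
                 augment = isTRUE(augment),
                 scale_lr_small_batch = isTRUE(scale_lr_small_batch),
                 lr_halve_patience = as.integer(lr_halve_patience),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

effective_lr <- function(lr, batch_size, cfg) {
  if (cfg$scale_lr_small_batch && batch_size <= 8)
    lr * batch_size / 8 else lr
}

# ---- augmentation ---------------------------------------------------

rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Rotate/flip a scene together with its annotations
#'
#' Applies `k` counter-clockwise quarter turns then an optional
#' left-right flip, transforming the point annotations consistently
#' with the image.
#'
#' @param image Matrix.
#' @param points Data frame of 0-based `row`, `col`.
#' @param k Quarter turns (0-3).
#' @param flip Flip columns after rotating.
#' @return List with transformed `image` and `points`.
#' @export
transform_scene <- function(image, points, k = 0L, flip = FALSE) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    W <- ncol(image)
    image <- rot90ccw(image)
    points <- data.frame(row = W - 1L - points$col, col = points$row)
  }
  if (flip) {
    W <- ncol(image)
    image <- image[, W:1, drop = FALSE]
    points$col <- W - 1L - points$col
  }
  list(image = image, points = points)
}

random_augment <- function(image, points, allow_rot = TRUE) {
  k <- if (allow_rot) sample(0:3, 1L) else sample(c(0L, 2L), 1L)
  transform_scene(image, points, k, flip = runif(1) < 0.5)
}

#' Compose a 4n-image PU training batch
#'
#' Draws `n` positive images, adds `n` randomly rotated/flipped copies
#' of those same images (annotations transformed along), and `2n`
#' images from the unlabeled pool; pools shorter than requested are
#' recycled.  Annotations of each positive image are first thinned to
#' `keep_fraction`.
#'
#' @param positives List of annotated scenes (each with `image` and a
#'   `labeled` point table).
#' @param unlabeled_pool List of scenes used unlabeled (typically the
#'   entire training set).
#' @param n Composition factor.
#' @param seed Optional seed for the draws.
#' @param keep_fraction Annotation keep fraction (default 1: keep all).
#' @param augment Augment the copies (otherwise they are verbatim).
#' @return List of `4n` elements, each `list(image, points, role)` with
#'   role `"positive"`, `"augmented"`, or `"unlabeled"` (unlabeled
#'   entries have `NULL` points).
#' @export
make_batch <- function(positives, unlabeled_pool, n = 1L, seed = NULL,
                       keep_fraction = 1, augment = TRUE) {
  if (!length(positives) || !length(unlabeled_pool))
    stop("empty image pool", call. = FALSE)
  build <- function() {
    draw <- function(pool, k)   # without replacement, recycling if short
      pool[sample.int(length(pool), k, replace = k > length(pool))]
    pos <- draw(positives, n)
    unl <- draw(unlabeled_pool, 2L * n)
    out <- list()
    for (sc in pos) {
      pts <- subsample_annotations(sc$labeled, keep_fraction)
      out <- c(out, list(list(image = sc$image, points = pts,
                              role = "positive")))
    }
    for (sc in pos) {
      pts <- subsample_annotations(sc$labeled, keep_fraction)
      a <- if (augment)
        random_augment(sc$image, pts, nrow(sc$image) == ncol(sc$image))
      else list(image = sc$image, points = pts)
      out <- c(out, list(list(image = a$image, points = a$points,
                              role = "augmented")))
    }
    for (sc in unl)
      out <- c(out, list(list(image = sc$image, points = NULL,
                              role = "unlabeled")))
    out
  }
  if (is.null(seed)) build() else withr_seed(seed, build())
}

# ---- Adam -----------------------------------------------------------

adam_init <- function(weights)
  list(t = 0L,
       m = lapply(weights, function(w) array(0, dim = if (is.null(dim(w))) length(w) else dim(w))),
       v = lapply(weights, function(w) array(0, dim = if (is.null(dim(w))) length(w) else dim(w))))

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(weights)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    weights[[k]] <- weights[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

zero_like <- function(weights) lapply(weights, function(w) w * 0)

add_grads <- function(a, b) {
  for (k in names(a)) a[[k]] <- a[[k]] + b[[k]]
  a
}

# ---- shared helpers -------------------------------------------------

scene_count_targets <- function(points, H, W, r) {
  loc <- location_map_from_points(points, H, W)
  cgt <- box_sum(loc, r)
  list(cgt = cgt, mask = positive_mask(cgt))
}

# Pooled validation F1 over a list of scenes with full annotations.
validation_f1 <- function(model, scenes, cfg) {
  tp <- fp <- fn <- 0L
  for (sc in scenes) {
    out <- model_forward(model, sc$image)$out
    pk <- find_peaks(out, cfg$kernel, min_value = cfg$min_peak_frac * max(out))
    s <- detection_scores(match_points(sc$centers, pk, cfg$val_threshold))
    tp <- tp + s$tp; fp <- fp + s$fp; fn <- fn + s$fn
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# ---- stage 1: PU learning -------------------------------------------

#' Stage 1: PU training from sparse annotations
#'
#' Per epoch, for every positive (annotated) image: resample
#' `keep_fraction` of its annotations, rebuild the partial ground-truth
#' count map and positive mask, compose a `4n` batch (positives,
#' augmented copies, unlabeled images drawn from the whole training
#' set), and take one Adam step on the non-negative PU risk
#' ([nonneg_pu_risk()]) computed over the pooled batch maps.  After
#' `eval_delay` epochs, pooled validation F1 is computed every epoch
#' and the best-scoring weights are kept; the learning rate halves
#' after `lr_halve_patience` evaluated epochs without improvement.
#'
#' @param train List of annotated scenes (`image` + `labeled`); the
#'   whole list also serves as the unlabeled pool.
#' @param validation List of scenes with full `centers` (model
#'   selection measures true F1).
#' @param cfg A [train_config()].
#' @param model Optional initial model (default fresh [init_model()]).
#' @return A checkpoint: `model` (best weights), `stage`, `val_f1`,
#'   `best_epoch`, `history` (per-epoch risk and validation F1).
#' @export
train_stage1_pu <- function(train, validation, cfg, model = NULL) {
  stopifnot(length(train) > 0, length(validation) > 0)
  if (!all(vapply(train, function(s) NROW(s$labeled) > 0, logical(1))))
    stop("every positive image needs at least one annotation", call. = FALSE)
  r <- cfg$kernel$r
  prcfg <- pu_risk_config(cfg$class_prior, cfg$kernel)
  set.seed(cfg$seed)
  # The clamped PU risk has a degenerate stationary point at the
  # all-zero location map (risk = pi_p exactly); some weight draws
  # fall into it within a few epochs and cannot escape.  Training
  # probes for that collapse early and restarts from a fresh init
  # (seeds drawn once from the master seed, so runs stay
  # deterministic).  A caller-supplied model is never restarted.
  init_seeds <- sample.int(2^30, 5L)
  user_model <- model
  probe_epochs <- unique(pmin(c(6L, 10L), cfg$epochs_stage1))
  attempt <- 1L
  repeat {
  model <- if (is.null(user_model))
    init_model(predictor_config(cfg$base_channels), init_seeds[attempt])
  else user_model
  st <- adam_init(model$weights)
  lr <- effective_lr(cfg$lr_stage1, 4L * cfg$batch_n, cfg)
  best <- list(f1 = -Inf, epoch = NA_integer_, weights = model$weights)
  hist <- data.frame(epoch = integer(0), risk = numeric(0),
                     val_f1 = numeric(0), lr = numeric(0))
  since_improve <- 0L
  collapsed <- FALSE
  for (epoch in seq_len(cfg$epochs_stage1)) {
    pos_order <- sample.int(length(train))
    unl_order <- sample.int(length(train))
    unl_ptr <- 0L
    next_unl <- function() {
      unl_ptr <<- unl_ptr + 1L
      if (unl_ptr > length(unl_order)) {
        unl_order <<- sample.int(length(train)); unl_ptr <<- 1L
      }
      train[[unl_order[unl_ptr]]]
    }
    epoch_risk <- 0; n_steps <- 0L
    for (step_start in seq(1L, length(pos_order), by = cfg$batch_n)) {
      idx <- pos_order[step_start:min(step_start + cfg$batch_n - 1L,
                                      length(pos_order))]
      batch <- list()
      for (i in idx) {
        sc <- train[[i]]
        pts <- subsample_annotations(sc$labeled, cfg$keep_fraction)
        batch <- c(batch, list(list(image = sc$image, points = pts)))
      }
      for (i in idx) {
        sc <- train[[i]]
        pts <- subsample_annotations(sc$labeled, cfg$keep_fraction)
        a <- if (cfg$augment)
          random_augment(sc$image, pts, nrow(sc$image) == ncol(sc$image))
        else list(image = sc$image, points = pts)
        batch <- c(batch, list(a))
      }
      for (i in seq_len(2L * length(idx))) {
        sc <- next_unl()
        batch <- c(batch, list(list(image = sc$image, points = NULL)))
      }
      fw <- lapply(batch, function(b) model_forward(model, b$image,
                                                    keep = TRUE))
      cpre <- lapply(fw, function(f) box_sum(f$out, r))
      tgt <- lapply(batch, function(b) {
        H <- nrow(b$image); W <- ncol(b$image)
        if (is.null(b$points))
          list(cgt = matrix(0, H, W),
               mask = structure(list(values = matrix(0, H, W),
                                     n_positive = 0),
                                class = "positive_mask"))
        else scene_count_targets(b$points, H, W, r)
      })
      CP <- do.call(cbind, cpre)
      CG <- do.call(cbind, lapply(tgt, `[[`, "cgt"))
      MMv <- do.call(cbind, lapply(tgt, function(t) t$mask$values))
      mask <- structure(list(values = MMv, n_positive = sum(MMv)),
                        class = "positive_mask")
      res <- tryCatch(pu_risk_with_grad(CP, CG, mask, prcfg),
                      pulocalize_no_positives = function(e) NULL)
      if (is.null(res)) next
      if (!is.finite(res$value$total))
        stop("PU risk diverged (non-finite) at epoch ", epoch, call. = FALSE)
      epoch_risk <- epoch_risk + res$value$total; n_steps <- n_steps + 1L
      grads <- zero_like(model$weights)
      col0 <- 0L
      for (b in seq_along(batch)) {
        W <- ncol(batch[[b]]$image)
        gC <- res$grad[, col0 + seq_len(W), drop = FALSE]
        col0 <- col0 + W
        gP <- box_sum(gC, r)
        grads <- add_grads(grads,
                           model_backward(model, fw[[b]]$cache, gP,
                                          out_leak = 0.01))
      }
      upd <- adam_step(model$weights, grads, st, lr)
      model$weights <- upd$weights; st <- upd$state
    }
    vf1 <- NA_real_
    if (epoch > cfg$eval_delay) {
      vf1 <- validation_f1(model, validation, cfg)
      if (vf1 > best$f1) {
        best <- list(f1 = vf1, epoch = epoch, weights = model$weights)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= cfg$lr_halve_patience) {
          lr <- lr / 2; since_improve <- 0L
        }
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   risk = epoch_risk / max(1L, n_steps),
                                   val_f1 = vf1, lr = lr))
    if (cfg$verbose)
      message(sprintf("stage1 epoch %3d  risk %.5f  val F1 %s",
                      epoch, epoch_risk / max(1L, n_steps),
                      ifelse(is.na(vf1), "-", sprintf("%.3f", vf1))))
    if (epoch %in% probe_epochs && is.null(user_model) &&
        attempt < length(init_seeds)) {
      probe <- model_forward(model, validation[[1L]]$image)$out
      if (max(probe) < 0.01) { collapsed <- TRUE; break }
    }
  }
  if (!collapsed) break
  attempt <- attempt + 1L
  if (cfg$verbose)
    message("stage1: output collapsed to zero; restarting (attempt ",
            attempt, ")")
  }
  if (!is.finite(best$f1)) best <- list(f1 = NA_real_, epoch = NA_integer_,
                                        weights = model$weights)
  model$weights <- best$weights
  list(model = model, stage = "stage1", val_f1 = best$f1,
       best_epoch = best$epoch, history = hist)
}

# ---- stage 2: pseudo-label refinement -------------------------------

# Fit one beta mixture to the pooled unlabeled losses of all images.
# Pooling across a training set can yield 10^5+ survivors; the fit is
# a 5-parameter model, so it is estimated on a seeded subsample (the
# normalization bounds still come from the full pool).
pooled_bmm <- function(raw_list, eps = 1e-4, seed = 1L, max_n = 4000L) {
  raw <- unlist(raw_list)
  if (length(raw) < 10L)
    stop_empty_losses("too few unlabeled losses pooled across images")
  bounds <- range(raw)
  sub <- if (length(raw) > max_n)
    withr_seed(seed, raw[sample.int(length(raw), max_n)])
  else raw
  mix <- fit_bmm_em(normalize_raw_loss(sub, bounds, eps), seed = seed)
  mix$bounds <- bounds; mix$eps <- eps
  mix
}

#' Stage 2: pseudo-label (positive-negative) refinement
#'
#' Starting from the best stage-1 weights, each epoch: run the model
#' over all training images, pool the unlabeled-region losses, fit the
#' two-component beta mixture, attach posterior probabilities to the
#' local maxima of every predicted location map, partition the
#' unlabeled region ([partition_unlabeled()]), and take Adam steps on
#' the positive-negative loss ([pn_loss()]) over image minibatches.
#' Validation F1 is tracked every epoch and the returned checkpoint is
#' the best seen, the stage-1 initialization included (so refinement
#' never hands back something worse than its starting point on the
#' validation data).
#'
#' @inheritParams train_stage1_pu
#' @param ckpt Stage-1 checkpoint (from [train_stage1_pu()]).
#' @return A checkpoint like [train_stage1_pu()]'s with
#'   `stage = "stage2"`.
#' @export
train_stage2_pseudo <- function(train, validation, ckpt, cfg) {
  model <- ckpt$model
  r <- cfg$kernel$r
  set.seed(cfg$seed + 1L)
  st <- adam_init(model$weights)
  lr <- effective_lr(cfg$lr_stage2, 4L * cfg$batch_n, cfg)
  init_f1 <- validation_f1(model, validation, cfg)
  best <- list(f1 = init_f1, epoch = 0L, weights = model$weights)
  hist <- data.frame(epoch = 0L, loss = NA_real_, val_f1 = init_f1)
  tgts <- lapply(train, function(sc)
    scene_count_targets(sc$labeled, nrow(sc$image), ncol(sc$image), r))
  for (epoch in seq_len(cfg$epochs_stage2)) {
    outs <- lapply(train, function(sc) model_forward(model, sc$image)$out)
    cpres <- lapply(outs, box_sum, r = r)
    losses <- mapply(function(cp, tg) unlabeled_losses(cp, tg$cgt),
                     cpres, tgts, SIMPLIFY = FALSE)
    mix <- tryCatch(pooled_bmm(lapply(losses, `[[`, "raw"),
                               seed = cfg$seed + epoch),
                    pulocalize_empty_losses = function(e) NULL)
    parts <- vector("list", length(train))
    for (i in seq_along(train)) {
      pk <- find_peaks(outs[[i]], cfg$kernel,
                       min_value = cfg$min_peak_frac * max(outs[[i]]))
      pk$posterior <- if (nrow(pk) == 0L) numeric(0)
      else if (is.null(mix)) rep(0, nrow(pk))
      else posterior_noisy(mix, cpres[[i]][cbind(pk$row + 1L,
                                                 pk$col + 1L)]^2,
                           raw = TRUE)
      parts[[i]] <- partition_unlabeled(pk, losses[[i]], tgts[[i]]$mask,
                                        cfg$tau_pos, cfg$tau_neg)
    }
    epoch_loss <- 0; n_steps <- 0L
    order_i <- sample.int(length(train))
    bs <- 4L * cfg$batch_n
    for (s0 in seq(1L, length(order_i), by = bs)) {
      idx <- order_i[s0:min(s0 + bs - 1L, length(order_i))]
      grads <- zero_like(model$weights)
      bl <- 0; ok <- 0L
      for (i in idx) {
        fw <- model_forward(model, train[[i]]$image, keep = TRUE)
        cp <- box_sum(fw$out, r)
        pg <- tryCatch(pn_loss_with_grad(cp, parts[[i]]),
                       pulocalize_no_positives = function(e) NULL)
        if (is.null(pg)) next
        ok <- ok + 1L; bl <- bl + pg$value
        grads <- add_grads(grads,
                           model_backward(model, fw$cache,
                                          box_sum(pg$grad, r),
                                          out_leak = 0.01))
      }
      if (ok == 0L) next
      grads <- lapply(grads, function(g) g / ok)
      upd <- adam_step(model$weights, grads, st, lr)
      model$weights <- upd$weights; st <- upd$state
      epoch_loss <- epoch_loss + bl / ok; n_steps <- n_steps + 1L
    }
    vf1 <- validation_f1(model, validation, cfg)
    if (vf1 > best$f1) best <- list(f1 = vf1, epoch = epoch,
                                    weights = model$weights)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   loss = epoch_loss / max(1L, n_steps),
                                   val_f1 = vf1))
    if (cfg$verbose)
      message(sprintf("stage2 epoch %3d  loss %.6f  val F1 %.3f",
                      epoch, epoch_loss / max(1L, n_steps), vf1))
  }
  model$weights <- best$weights
  list(model = model, stage = "stage2", val_f1 = best$f1,
       best_epoch = best$epoch, history = hist)
}

#' Run both training stages
#'
#' @inheritParams train_stage1_pu
#' @return A list with `stage1` and `stage2` checkpoints.
#' @export
train_two_stage <- function(train, validation, cfg) {
  s1 <- train_stage1_pu(train, validation, cfg)
  s2 <- train_stage2_pseudo(train, validation, s1, cfg)
  list(stage1 = s1, stage2 = s2)
}

#' Detect objects in an image with a trained model
#'
#' @param model A trained model (checkpoint `model` element).
#' @param image Numeric matrix in \[0, 1\].
#' @param kernel A [count_map_config()] or kernel size.
#' @param min_peak_frac Peak threshold as a fraction of the map max.
#' @return A [find_peaks()] data frame of detections.
#' @export
detect_objects <- function(model, image, kernel, min_peak_frac = 0.1) {
  out <- model_forward(model, image)$out
  find_peaks(out, kernel, min_value = min_peak_frac * max(out))
}

# Pooled test-set evaluation of a model.
evaluate_model <- function(model, scenes, cfg) {
  tp <- fp <- fn <- 0L; dist_sum <- 0; n_pts <- 0L
  for (sc in scenes) {
    pk <- detect_objects(model, sc$image, cfg$kernel, cfg$min_peak_frac)
    m <- match_points(sc$centers, pk, cfg$val_threshold)
    s <- detection_scores(m)
    tp <- tp + s$tp; fp <- fp + s$fp; fn <- fn + s$fn
    dist_sum <- dist_sum + sum(m$pairs$distance) +
      cfg$val_threshold * (s$fp + s$fn)
    n_pts <- n_pts + nrow(m$pairs) + s$fp + s$fn
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r),
       mle = if (n_pts > 0) dist_sum / n_pts else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Packaged synthetic sparse-annotation benchmark
#'
#' Generates the package's reference experiment — images of small
#' soft disks with a single annotated object per training image (under
#' 10% of all points) — trains both stages, and evaluates on held-out
#' test scenes.  All randomness derives from `seed`.
#'
#' @param seed Master seed.
#' @param n_train,n_val,n_test Dataset split sizes.
#' @param scene A [scene_config()]; the default is the benchmark
#'   regime (96 x 96 px, ~15 disks of radius 4, 1 label per image).
#' @param cfg A [train_config()]; the default uses the benchmark
#'   preset: kernel 7, prior 0.1, 4 px matching radius, and desk-scale
#'   epoch counts.
#' @return A list with `stage1`, `stage2` (checkpoints) and
#'   `test_stage1`, `test_stage2` (pooled test metrics).
#' @export
run_benchmark <- function(seed = 7L, n_train = 48L, n_val = 8L,
                          n_test = 16L, scene = scene_config(),
                          cfg = benchmark_train_config(seed)) {
  train <- generate_dataset(n_train, scene, seed = seed)
  val_scene <- scene; val_scene$labeled_count <- 0L
  validation <- generate_dataset(n_val, val_scene, seed = seed + 1L)
  test <- generate_dataset(n_test, val_scene, seed = seed + 2L)
  s1 <- train_stage1_pu(train, validation, cfg)
  t1 <- evaluate_model(s1$model, test, cfg)
  s2 <- train_stage2_pseudo(train, validation, s1, cfg)
  t2 <- evaluate_model(s2$model, test, cfg)
  list(stage1 = s1, stage2 = s2, test_stage1 = t1, test_stage2 = t2)
}

#' Benchmark training preset
#'
#' The [train_config()] used by [run_benchmark()]: kernel 7 px, prior
#' 0.1, 4 px validation/test matching radius, and epoch counts scaled
#' to the small synthetic datasets (the method needs far fewer passes
#' over 48 tiny images than over full microscopy datasets).
#'
#' @param seed Master seed.
#' @param epochs_stage1,epochs_stage2 Desk-scale epoch counts.
#' @param base_channels Predictor width for the benchmark scenes.
#' @param ... Further overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
benchmark_train_config <- function(seed = 7L, epochs_stage1 = 25L,
                                   epochs_stage2 = 5L,
                                   base_channels = 6L, ...) {
  train_config(kernel = count_map_config(7), class_prior = 0.1,
               epochs_stage1 = epochs_stage1,
               epochs_stage2 = epochs_stage2,
               base_channels = base_channels,
               eval_delay = 20L, val_threshold = 4,
               seed = seed, ...)
}
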