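#' Derive loss weights from per-class case counts
#'
#' Follows the four-step procedure: (1) take the benign and malignant case
#' counts in the training split, (2) normalize them to proportions, (3) take
#' reciprocals so the weights are inversely proportional to the case counts,
#' (4) renormalize the reciprocals to sum to one. Algebraically the result is
#' `w_b = n_m / (n_b + n_m)`, `w_m = n_b / (n_b + n_m)`. Weights are computed
#' from CASE counts, not image counts: cohorts often balance images per class
#' while the case counts stay heavily skewed.
#'
#' @param n_b,n_m benign / malignant case counts (positive integers).
#' @return a `class_weights` list: `n_b`, `n_m`, `w_b`, `w_m`.
#' @export
compute_class_weights <- function(n_b, n_m) {
  if (!is_count(n_b) || !is_count(n_m) || n_b < 1 || n_m < 1)
    abort_argument("case counts must be positive integers")
  n_b <- unname(n_b); n_m <- unname(n_m)
  total <- n_b + n_m
  n_b_norm <- n_b / total
  n_m_norm <- n_m / total
  r_b <- 1 / n_b_norm
  r_m <- 1 / n_m_norm
  w_b <- r_b / (r_b + r_m)
  w_m <- r_m / (r_b + r_m)
  structure(list(n_b = n_b, n_m = n_m, w_b = w_b, w_m = w_m),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("class weights from case counts (benign %d, malignant %d):\n", x$n_b, x$n_m))
  cat(sprintf("  w_benign = %.4f, w_malignant = %.4f\n", x$w_b, x$w_m))
  invisible(x)
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `w_class(y) * (-log softmax(logits)[y])` with
#' benign = 0 weighted by `w_b` and malignant = 1 by `w_m`. With equal
#' weights (0.5, 0.5) the loss is plain cross-entropy scaled by 0.5.
#'
#' @param logits `N x 2` matrix.
#' @param labels integer vector in `{0, 1}` (0 benign, 1 malignant).
#' @param weights a `class_weights` object, or `c(w_b, w_m)`.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(logits, labels, weights) {
  w <- as_weight_pair(weights)
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  if (ncol(logits) != 2) abort_shape("logits must have width 2")
  if (length(labels) != nrow(logits)) abort_argument("labels and logits disagree in length")
  if (!all(labels %in% c(0, 1))) abort_label("labels must lie in {0, 1}")
  p <- softmax_rows(logits)
  idx <- cbind(seq_along(labels), labels + 1)
  mean(w[labels + 1] * (-log(pmax(p[idx], 1e-300))))
}

# gradient of the weighted CE wrt logits (mean reduction)
weighted_ce_grad <- function(logits, labels, weights) {
  w <- as_weight_pair(weights)
  p <- softmax_rows(logits)
  onehot <- matrix(0, nrow(logits), 2)
  onehot[cbind(seq_along(labels), labels + 1)] <- 1
  (p - onehot) * w[labels + 1] / nrow(logits)
}

as_weight_pair <- function(weights) {
  if (inherits(weights, "class_weights")) c(weights$w_b, weights$w_m)
  else if (is.numeric(weights) && length(weights) == 2) weights
  else abort_argument("weights must be a class_weights object or a length-2 numeric")
}

#' Training hyperparameters
#'
#' Defaults follow the protocol this framework was tuned with: Adam with
#' weight decay 5e-4, initial learning rate 1e-3, batch size 32, up to 200
#' epochs with early stopping at patience 6 (monitoring validation loss and
#' restoring the best checkpoint), 224 x 224 inputs scaled from `[0, 255]`
#' to `[0, 1]`, and augmentation by horizontal/vertical flips, 90-degree
#' rotations and brightness/contrast/saturation jitter. `input_size` can be
#' lowered for desk-scale experiments.
#'
#' @param lr initial learning rate.
#' @param weight_decay Adam weight-decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param input_size branch image side in pixels.
#' @param augment logical; disable to train on the raw images.
#' @param jitter `(brightness, contrast, saturation)` maximum relative
#'   perturbations.
#' @param seed training seed (shuffling, augmentation draws, dropout).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 5e-4, batch_size = 32L,
                         max_epochs = 200L, early_stop_patience = 6L,
                         input_size = 224L, augment = TRUE,
                         jitter = c(0.2, 0.2, 0.2), seed = 0L) {
  if (lr <= 0 || weight_decay < 0 || batch_size < 1 || max_epochs < 1 || input_size < 8)
    abort_config("training hyperparameters must be positive")
  if (early_stop_patience >= max_epochs)
    abort_config("early_stop_patience must be smaller than max_epochs")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 input_size = as.integer(input_size), augment = isTRUE(augment),
                 jitter = jitter, seed = as.integer(seed)),
            class = "train_config")
}

#' Synchronized augmentation of a frame's branch images
#'
#' Draws one augmentation (flip decisions, a 90-degree rotation count and
#' brightness/contrast/saturation factors) from the current RNG stream and
#' applies it identically to every image in the group, so multi-branch
#' geometry stays aligned across branches.
#'
#' @param images list of `H x W x 3` arrays in `[0, 255]` (or a single
#'   array).
#' @param jitter `(brightness, contrast, saturation)` maximum relative
#'   perturbations; 0 disables jitter.
#' @param p_flip probability of each flip; 0 together with zero jitter makes
#'   the call a no-op.
#' @param rotate logical; draw a 90-degree rotation count from 0:3.
#' @return the augmented list (or single array).
#' @export
augment_group <- function(images, jitter = c(0.2, 0.2, 0.2), p_flip = 0.5, rotate = TRUE) {
  single <- !is.list(images)
  if (single) images <- list(images)
  hf <- runif(1) < p_flip
  vf <- runif(1) < p_flip
  k <- if (rotate) sample(0:3, 1) else 0L
  fb <- if (jitter[1] > 0) 1 + runif(1, -jitter[1], jitter[1]) else 1
  fc <- if (jitter[2] > 0) 1 + runif(1, -jitter[2], jitter[2]) else 1
  fs <- if (jitter[3] > 0) 1 + runif(1, -jitter[3], jitter[3]) else 1
  out <- lapply(images, function(img) {
    if (hf) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    if (vf) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
    if (k > 0) img <- rot90_image(img, k)
    if (fb != 1) img <- img * fb
    if (fc != 1) { mu <- mean(img); img <- (img - mu) * fc + mu }
    if (fs != 1) {
      gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * fs
    }
    clamp(img, 0, 255)
  })
  if (single) out[[1]] else out
}

# counter-clockwise rotation by k * 90 degrees
rot90_image <- function(img, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))
    img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  }
  img
}

## ---- dataset assembly -----------------------------------------------------

#' Load one branch's image tensor from a manifest
#'
#' Reads every frame, applies the branch preprocessing ([preprocess_frame()])
#' and stacks the result as an `(size, size, 3, N)` array of raw 8-bit
#' values, together with labels and case ids.
#'
#' @param manifest frame-level manifest tibble.
#' @param root directory frame paths are relative to.
#' @param image_type branch name (see [preprocess_frame()]).
#' @param size branch input side in pixels.
#' @param case_ids optional subset of cases to load.
#' @return list with `x`, `y` (0 benign / 1 malignant), `case_id`.
#' @export
load_branch_tensor <- function(manifest, root, image_type, size, case_ids = NULL) {
  if (!is.null(case_ids)) manifest <- manifest[manifest$case_id %in% case_ids, ]
  if (nrow(manifest) == 0) abort_data("no frames selected")
  x <- array(0, c(size, size, 3, nrow(manifest)))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    frame <- read_frame(file.path(root, m$frame_path))
    x[, , , i] <- preprocess_frame(frame, c(m$probe_row, m$probe_col),
                                   m$pixels_per_cm, image_type, size = size)
  }
  list(x = x, y = as.integer(manifest$label == "malignant"),
       case_id = manifest$case_id)
}

split_case_counts <- function(manifest, case_ids) {
  cases <- cohort_cases(manifest[manifest$case_id %in% case_ids, ])
  c(n_b = sum(cases$label == "benign"), n_m = sum(cases$label == "malignant"))
}

## ---- training loops -------------------------------------------------------

run_epochs <- function(step_fn, eval_fn, modules, config) {
  opt <- adam_new(modules, lr = config$lr, weight_decay = config$weight_decay)
  best <- list(loss = Inf, state = NULL, epoch = 0L)
  history <- list()
  bad <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    train_loss <- step_fn(opt, epoch)
    ev <- eval_fn()
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       valid_loss = ev$loss, valid_auc = ev$auc)
    if (ev$loss < best$loss - 1e-12) {
      best <- list(loss = ev$loss, state = lapply(modules, function(m)
        list(params = m$params, buffers = m$buffers)), epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$early_stop_patience) break
    }
  }
  if (!is.null(best$state)) {
    for (i in seq_along(modules)) {
      modules[[i]]$params <- best$state[[i]]$params
      modules[[i]]$buffers <- best$state[[i]]$buffers
    }
  }
  list(history = dplyr::bind_rows(history), best_epoch = best$epoch,
       best_valid_loss = best$loss)
}

#' Stage 1: fine-tune one encoder on one image type
#'
#' Trains the full encoder (backbone + head) with case-count-weighted
#' cross-entropy, synchronized augmentation, Adam, and early stopping on the
#' validation loss (patience per the config, best checkpoint restored).
#' Training and validation case lists must be disjoint.
#'
#' @param manifest frame-level manifest tibble.
#' @param root directory frame paths are relative to.
#' @param image_type branch name (see [preprocess_frame()]).
#' @param split list with `train` and `valid` case-id vectors.
#' @param encoder_cfg an [encoder_config()].
#' @param config a [train_config()].
#' @param weighted use case-count loss weights (`FALSE` trains with 0.5/0.5).
#' @return an `ebus_fit` list: `encoder`, `history`, `weights`, `best_epoch`.
#' @export
train_stage1 <- function(manifest, root, image_type, split,
                         encoder_cfg = encoder_config(), config = train_config(),
                         weighted = TRUE) {
  check_split(split)
  train <- load_branch_tensor(manifest, root, image_type, config$input_size, split$train)
  valid <- load_branch_tensor(manifest, root, image_type, config$input_size, split$valid)
  cnt <- split_case_counts(manifest, split$train)
  weights <- if (weighted) compute_class_weights(cnt["n_b"], cnt["n_m"])
             else structure(list(n_b = cnt[["n_b"]], n_m = cnt[["n_m"]],
                                 w_b = 0.5, w_m = 0.5), class = "class_weights")

  set.seed(derive_seed(config$seed, 1))
  encoder <- build_encoder(encoder_cfg, seed = derive_seed(config$seed, 2))
  modules <- encoder_modules(encoder)
  n <- dim(train$x)[4]
  vx <- valid$x / 255

  step_fn <- function(opt, epoch) {
    idx <- sample.int(n)
    total <- 0
    for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      xb <- train$x[, , , b, drop = FALSE]
      if (config$augment) {
        for (j in seq_along(b)) {
          xb[, , , j] <- augment_group(xb[, , , j], jitter = config$jitter)
        }
      }
      xb <- xb / 255
      yb <- train$y[b]
      zero_grads(modules)
      logits <- encoder_logits(encoder, xb, training = TRUE)
      total <- total + weighted_cross_entropy(logits, yb, weights) * length(b)
      dlog <- weighted_ce_grad(logits, yb, weights)
      encoder$backbone$bwd(encoder$pool$bwd(encoder$head$bwd(dlog)))
      adam_step(opt)
    }
    total / n
  }
  eval_fn <- function() {
    logits <- encoder_logits(encoder, vx, training = FALSE)
    scores <- softmax_rows(logits)[, 2]
    auc <- if (length(unique(valid$y)) == 2) compute_auc(scores, valid$y)$auc else NA_real_
    list(loss = weighted_cross_entropy(logits, valid$y, weights), auc = auc)
  }
  res <- run_epochs(step_fn, eval_fn, modules, config)
  structure(list(encoder = encoder, image_type = image_type, weights = weights,
                 history = res$history, best_epoch = res$best_epoch,
                 best_valid_loss = res$best_valid_loss, config = config),
            class = "ebus_fit")
}

check_split <- function(split) {
  if (is.null(split$train) || is.null(split$valid) ||
      length(split$train) == 0 || length(split$valid) == 0)
    abort_data("split must provide non-empty train and valid case lists")
  if (length(intersect(split$train, split$valid)))
    abort_data("train and valid case lists overlap")
  invisible(split)
}

#' Stage 2: train fusion + classifier on frozen encoders
#'
#' Branch features are extracted once from the frozen, evaluation-mode
#' encoders; only the fusion and classifier parameters are optimized
#' (same loss, optimizer and early-stopping rule as stage 1). Encoder
#' parameters are bit-identical before and after.
#'
#' @param encoders list of `ebus_fit` or `ebus_encoder` objects, one per
#'   branch (with matching `image_types`).
#' @param image_types per-branch image-type names.
#' @param variant fusion variant (`"ffm_v1"`, `"ffm_v2"`, `"ffm_v3"`).
#' @inheritParams train_stage1
#' @return an `ebus_fusion_fit` list: `fusion`, `history`, plus the frozen
#'   encoder list for prediction.
#' @export
train_stage2 <- function(encoders, image_types, manifest, root, split,
                         variant = "ffm_v2", config = train_config(),
                         weighted = TRUE) {
  check_split(split)
  encoders <- lapply(encoders, function(e) if (inherits(e, "ebus_fit")) e$encoder else e)
  nb <- length(encoders)
  if (nb != length(image_types)) abort_argument("one image type per encoder is required")
  pre_state <- lapply(encoders, encoder_parameters)

  feats <- function(case_ids) {
    per_branch <- lapply(seq_len(nb), function(k) {
      d <- load_branch_tensor(manifest, root, image_types[[k]], config$input_size, case_ids)
      list(map = extract_feature_map(encoders[[k]], d$x / 255),
           fc = extract_fc_feature(encoders[[k]], d$x / 255),
           y = d$y)
    })
    list(maps = lapply(per_branch, `[[`, "map"),
         fcs = lapply(per_branch, `[[`, "fc"),
         y = per_branch[[1]]$y)
  }
  tr <- feats(split$train)
  va <- feats(split$valid)

  cnt <- split_case_counts(manifest, split$train)
  weights <- if (weighted) compute_class_weights(cnt["n_b"], cnt["n_m"])
             else structure(list(n_b = cnt[["n_b"]], n_m = cnt[["n_m"]],
                                 w_b = 0.5, w_m = 0.5), class = "class_weights")

  fc_width <- ncol(tr$fcs[[1]])
  cfg <- fusion_config(variant,
                       channel_counts = vapply(tr$maps, function(m) dim(m)[3], numeric(1)),
                       fc_width = if (variant == "ffm_v3") fc_width else NULL)
  set.seed(derive_seed(config$seed, 3))
  fusion <- build_fusion(cfg, seed = derive_seed(config$seed, 4))
  n <- length(tr$y)

  subset_feats <- function(fs, b) {
    list(maps = lapply(fs$maps, function(m) m[, , , b, drop = FALSE]),
         fcs = lapply(fs$fcs, function(v) v[b, , drop = FALSE]))
  }
  step_fn <- function(opt, epoch) {
    idx <- sample.int(n)
    total <- 0
    for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      sb <- subset_feats(tr, b)
      zero_grads(fusion$modules)
      out <- fusion_forward(fusion, sb$maps, sb$fcs, training = TRUE)
      total <- total + weighted_cross_entropy(out$logits, tr$y[b], weights) * length(b)
      fusion_backward(fusion, weighted_ce_grad(out$logits, tr$y[b], weights))
      adam_step(opt)
    }
    total / n
  }
  eval_fn <- function() {
    out <- fusion_forward(fusion, va$maps, va$fcs, training = FALSE)
    scores <- softmax_rows(out$logits)[, 2]
    auc <- if (length(unique(va$y)) == 2) compute_auc(scores, va$y)$auc else NA_real_
    list(loss = weighted_cross_entropy(out$logits, va$y, weights), auc = auc)
  }
  res <- run_epochs(step_fn, eval_fn, fusion$modules, config)

  post_state <- lapply(encoders, encoder_parameters)
  if (!identical(pre_state, post_state))
    abort_numeric("frozen-encoder contract violated: encoder parameters changed")

  structure(list(fusion = fusion, encoders = encoders, image_types = image_types,
                 weights = weights, history = res$history,
                 best_epoch = res$best_epoch, best_valid_loss = res$best_valid_loss,
                 config = config),
            class = "ebus_fusion_fit")
}

#' Malignancy probabilities from a fused multi-branch model
#'
#' @param fit an `ebus_fusion_fit` from [train_stage2()].
#' @param manifest,root frames to score.
#' @param case_ids optional case subset.
#' @return tibble with `case_id`, `label`, `score`.
#' @export
predict_fusion <- function(fit, manifest, root, case_ids = NULL) {
  nb <- length(fit$encoders)
  per_branch <- lapply(seq_len(nb), function(k) {
    d <- load_branch_tensor(manifest, root, fit$image_types[[k]],
                            fit$config$input_size, case_ids)
    list(map = extract_feature_map(fit$encoders[[k]], d$x / 255),
         fc = extract_fc_feature(fit$encoders[[k]], d$x / 255),
         y = d$y, case_id = d$case_id)
  })
  out <- fusion_forward(fit$fusion, lapply(per_branch, `[[`, "map"),
                        lapply(per_branch, `[[`, "fc"), training = FALSE)
  tibble::tibble(case_id = per_branch[[1]]$case_id,
                 label = per_branch[[1]]$y,
                 score = softmax_rows(out$logits)[, 2])
}

#' @rdname predict_fusion
#' @param fit1 an `ebus_fit` from [train_stage1()] (single branch).
#' @export
predict_stage1 <- function(fit1, manifest, root, case_ids = NULL) {
  d <- load_branch_tensor(manifest, root, fit1$image_type,
                          fit1$config$input_size, case_ids)
  tibble::tibble(case_id = d$case_id, label = d$y,
                 score = predict_encoder(fit1$encoder, d$x / 255))
}

#' @method tidy ebus_fit
#' @export
tidy.ebus_fit <- function(x, ...) x$history

#' @method glance ebus_fit
#' @export
glance.ebus_fit <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 best_valid_loss = x$best_valid_loss,
                 w_benign = x$weights$w_b, w_malignant = x$weights$w_m)
}

#' @method tidy ebus_fusion_fit
#' @export
tidy.ebus_fusion_fit <- function(x, ...) x$history

#' @method glance ebus_fusion_fit
#' @export
glance.ebus_fusion_fit <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 best_valid_loss = x$best_valid_loss,
                 variant = x$fusion$config$variant,
                 n_branches = length(x$encoders))
}
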