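#' Confusion counts from malignancy scores
#'
#' Malignant is the positive class; a sample is predicted malignant iff its
#' score is at least `threshold` (default 0.5).
#'
#' @param scores per-image malignancy probabilities in `[0, 1]`.
#' @param labels integer labels in `{0, 1}` (1 = malignant).
#' @param threshold decision threshold.
#' @return a `confusion_counts` list: `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_from_scores <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    abort_argument("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1))) abort_label("labels must lie in {0, 1}")
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1 & labels == 1),
                 FP = sum(pred == 1 & labels == 0),
                 TN = sum(pred == 0 & labels == 0),
                 FN = sum(pred == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Accuracy, F1 (from precision = PPV and recall = sensitivity), PPV, NPV,
#' sensitivity and specificity. A ratio with a zero denominator is reported
#' as `NA` with a warning, never silently as zero.
#'
#' @param counts a `confusion_counts` list (or anything with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return a `metrics_report` list of the six threshold metrics plus the
#'   counts.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) abort_argument("confusion counts must be non-negative")
  if (TP + FP + TN + FN == 0) abort_argument("confusion counts are all zero")
  ratio <- function(num, den, what) {
    if (den == 0) { warn(paste0(what, " undefined: zero denominator")); return(NA_real_) }
    num / den
  }
  acc <- (TP + TN) / (TP + TN + FP + FN)
  ppv <- ratio(TP, TP + FP, "PPV")
  npv <- ratio(TN, TN + FN, "NPV")
  sen <- ratio(TP, TP + FN, "sensitivity")
  spec <- ratio(TN, TN + FP, "specificity")
  f1 <- if (is.na(ppv) || is.na(sen) || ppv + sen == 0) {
    warn("F1 undefined"); NA_real_
  } else 2 * ppv * sen / (ppv + sen)
  structure(list(acc = acc, f1 = f1, ppv = ppv, npv = npv, sen = sen,
                 spec = spec, counts = counts),
            class = "metrics_report")
}

#' ROC curve and AUC
#'
#' The ROC is built from every distinct score threshold; the AUC is its
#' trapezoidal area, identical to the Mann-Whitney statistic with ties
#' scored one half.
#'
#' @param scores malignancy scores.
#' @param labels labels in `{0, 1}`; both classes must be present.
#' @return list with `auc` and `roc` (tibble of `threshold`, `fpr`, `tpr`
#'   starting at (0, 0) and ending at (1, 1)).
#' @export
compute_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    abort_argument("scores and labels must have equal length")
  if (length(unique(labels)) < 2)
    abort_argument("AUC needs both classes present")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: each distinct value is one threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  roc <- tibble::tibble(threshold = c(Inf, s[last]),
                        fpr = c(0, fp[last] / nn),
                        tpr = c(0, tp[last] / np))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

#' Full metric panel from scores
#'
#' Combines the six threshold metrics (at `threshold`) with AUC and the ROC
#' curve — the seven-metric panel used throughout the package.
#'
#' @inheritParams confusion_from_scores
#' @return a `metrics_report` with `acc`, `f1`, `auc`, `ppv`, `npv`, `sen`,
#'   `spec`, `counts` and `roc`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  rep <- compute_metrics(confusion_from_scores(scores, labels, threshold))
  a <- compute_auc(scores, labels)
  rep$auc <- a$auc
  rep$roc <- a$roc
  rep
}

metric_names <- c("acc", "f1", "auc", "ppv", "npv", "sen", "spec")

#' @export
print.metrics_report <- function(x, ...) {
  for (m in metric_names) if (!is.null(x[[m]]))
    cat(sprintf("  %-5s %.4f\n", m, x[[m]]))
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN))
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(metric = metric_names,
                 value = vapply(metric_names, function(m) x[[m]] %||% NA_real_, numeric(1)))
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  vals <- lapply(metric_names, function(m) x[[m]] %||% NA_real_)
  names(vals) <- metric_names
  tibble::as_tibble(vals)
}

#' Stratified case-level cross-validation plan
#'
#' Cases (never images) are partitioned into `n_folds` test folds,
#' stratified by label. For each fold the remaining cases are split per
#' class into training and validation, with validation holding about
#' one-third of the non-test cases. No case ever contributes images to more
#' than one role within a fold.
#'
#' @param cases tibble with `case_id` and `label` (one row per case), or a
#'   frame-level manifest (summarized internally).
#' @param n_folds number of folds.
#' @param seed shuffling seed.
#' @param valid_frac fraction of non-test cases (per class) held out for
#'   validation.
#' @return a `fold_plan` tibble: `fold`, `case_id`, `label`, `role`.
#' @export
make_fold_plan <- function(cases, n_folds = 4L, seed = 0L, valid_frac = 1 / 3) {
  if ("frame_path" %in% names(cases)) cases <- cohort_cases(cases)
  per_class <- table(cases$label)
  if (!all(c("benign", "malignant") %in% names(per_class)))
    abort_data("fold plans need cases from both classes")
  if (any(per_class < n_folds))
    abort_data(paste0("need at least ", n_folds, " cases per class; got ",
                      paste(per_class, collapse = ", ")))
  assign_folds <- withr::with_seed(derive_seed(seed, 7), {
    out <- integer(nrow(cases))
    for (lb in unique(cases$label)) {
      i <- which(cases$label == lb)
      out[i] <- (sample(seq_along(i)) - 1L) %% n_folds + 1L
    }
    out
  })
  plan <- dplyr::bind_rows(lapply(seq_len(n_folds), function(f) {
    test_i <- which(assign_folds == f)
    rest_i <- which(assign_folds != f)
    roles <- withr::with_seed(derive_seed(seed, 11, f), {
      r <- rep("train", length(rest_i))
      for (lb in unique(cases$label[rest_i])) {
        j <- which(cases$label[rest_i] == lb)
        nv <- max(1L, round(valid_frac * length(j)))
        r[sample(j, nv)] <- "valid"
      }
      r
    })
    dplyr::bind_rows(
      tibble::tibble(fold = f, case_id = cases$case_id[test_i],
                     label = cases$label[test_i], role = "test"),
      tibble::tibble(fold = f, case_id = cases$case_id[rest_i],
                     label = cases$label[rest_i], role = roles))
  }))
  class(plan) <- c("fold_plan", class(plan))
  plan
}

fold_split <- function(plan, fold) {
  p <- plan[plan$fold == fold, ]
  list(train = p$case_id[p$role == "train"],
       valid = p$case_id[p$role == "valid"],
       test = p$case_id[p$role == "test"])
}

#' Evenly spaced frame subset of a case
#'
#' Picks `n_images` frames at evenly spaced positions across the case's
#' frame stack (`floor` of a linear spacing); if the case has fewer frames
#' than requested, all frames are returned.
#'
#' @param n_frames frame count of the case (or a vector of frame indices).
#' @param n_images number of frames to keep.
#' @return 0-based frame indices.
#' @export
sample_images_per_case <- function(n_frames, n_images) {
  if (length(n_frames) > 1) n_frames <- length(n_frames)
  if (n_images < 1) abort_argument("n_images must be at least 1")
  if (n_images >= n_frames) return(seq_len(n_frames) - 1L)
  as.integer(floor((seq_len(n_images) - 1L) * n_frames / n_images))
}

#' Cross-validated end-to-end evaluation
#'
#' Runs the two-stage protocol per fold — stage-1 fine-tuning of each branch
#' encoder, stage-2 fusion training on the frozen encoders (skipped for a
#' single branch, whose own logits are then evaluated) — and scores the
#' fold's held-out test images. Folds are case-disjoint by construction.
#'
#' @param manifest frame-level manifest tibble.
#' @param root directory frame paths are relative to.
#' @param image_types per-branch image-type names.
#' @param variant fusion variant when more than one branch is given.
#' @param encoder_cfg an [encoder_config()].
#' @param config a [train_config()].
#' @param n_folds,seed fold-plan parameters.
#' @return an `ebus_cv` list: `folds` (per-fold glance tibble), `mean`
#'   (unweighted mean of the per-fold metrics), `reports` (per-fold
#'   `metrics_report`s), `plan`.
#' @export
cross_validate <- function(manifest, root, image_types, variant = "ffm_v2",
                           encoder_cfg = encoder_config(),
                           config = train_config(), n_folds = 4L, seed = 0L) {
  plan <- make_fold_plan(manifest, n_folds = n_folds, seed = seed)
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sp <- fold_split(plan, f)
    cfg_f <- config
    cfg_f$seed <- derive_seed(seed, 100, f)
    fits <- lapply(image_types, function(ty)
      train_stage1(manifest, root, ty, sp, encoder_cfg, cfg_f))
    if (length(image_types) > 1) {
      fit2 <- train_stage2(fits, image_types, manifest, root, sp,
                           variant = variant, config = cfg_f)
      preds <- predict_fusion(fit2, manifest, root, sp$test)
    } else {
      preds <- predict_stage1(fits[[1]], manifest, root, sp$test)
    }
    reports[[f]] <- evaluate_scores(preds$score, preds$label)
  }
  per_fold <- dplyr::bind_rows(lapply(seq_len(n_folds), function(f)
    dplyr::mutate(glance(reports[[f]]), fold = f, .before = 1)))
  mean_rep <- dplyr::summarise(per_fold,
    dplyr::across(dplyr::all_of(metric_names), mean))
  structure(list(folds = per_fold, mean = mean_rep, reports = reports, plan = plan),
            class = "ebus_cv")
}

#' @export
print.ebus_cv <- function(x, ...) {
  cat("cross-validated metrics (mean over folds):\n")
  print(as.data.frame(x$mean), row.names = FALSE)
  invisible(x)
}
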