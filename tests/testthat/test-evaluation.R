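test_that("thresholding partitions samples into the four confusion cells", {
  cc <- confusion_from_scores(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  all_pos <- confusion_from_scores(rep(1, 7), rep(1, 7))
  expect_equal(all_pos$TP, 7L)
  expect_equal(all_pos$FP + all_pos$TN + all_pos$FN, 0L)
  t0 <- confusion_from_scores(runif(20), sample(0:1, 20, TRUE), threshold = 0)
  expect_equal(t0$FN + t0$TN, 0L)
  expect_error_class(confusion_from_scores(1, c(1, 0)), "ebusfusion_error_argument")
})

test_that("the six threshold metrics match their defining ratios", {
  r <- compute_metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(r$acc, 0.85)
  expect_equal(r$sen, 0.90)
  expect_equal(r$spec, 0.80)
  expect_equal(r$ppv, 9 / 11)
  expect_equal(r$npv, 8 / 9)
  expect_equal(r$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))
  perfect <- compute_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  for (m in c("acc", "f1", "ppv", "npv", "sen", "spec")) expect_equal(perfect[[m]], 1.0)
  expect_warning(
    expect_warning(deg <- compute_metrics(list(TP = 0, FP = 0, TN = 3, FN = 2)), "PPV"),
    "F1")
  expect_true(is.na(deg$ppv))
  expect_equal(deg$spec, 1)
  expect_equal(deg$npv, 0.6)
  expect_error_class(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
                     "ebusfusion_error_argument")
})

test_that("metric implementations agree with a hand-coded oracle on 1000 random tables", {
  set.seed(51)
  for (i in 1:1000) {
    k <- as.list(stats::rpois(4, 5) + c(1, 0, 1, 0))
    names(k) <- c("TP", "FP", "TN", "FN")
    r <- suppressWarnings(compute_metrics(k))
    expect_equal(r$acc, (k$TP + k$TN) / (k$TP + k$TN + k$FP + k$FN))
    sen <- k$TP / (k$TP + k$FN); ppv <- if (k$TP + k$FP > 0) k$TP / (k$TP + k$FP) else NA_real_
    expect_equal(r$sen, sen)
    expect_equal(r$ppv, ppv)
    expect_equal(r$spec, k$TN / (k$TN + k$FP))
    expect_equal(r$npv, if (k$TN + k$FN > 0) k$TN / (k$TN + k$FN) else NA_real_)
    f1 <- if (!is.na(ppv) && ppv + sen > 0) 2 * ppv * sen / (ppv + sen) else NA_real_
    expect_equal(r$f1, f1)
  }
})

test_that("trapezoidal AUC equals the pair-counting statistic on random score sets", {
  # the worked four-sample example: 3 wins out of 4 positive-negative pairs
  expect_equal(compute_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(compute_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(compute_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(52)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(compute_auc(s, y)$auc, pair_count_auc(s, y), tolerance = 1e-12)
  }
  expect_error_class(compute_auc(runif(5), rep(1, 5)), "ebusfusion_error_argument")
})

test_that("the ROC curve is monotone from (0,0) to (1,1) and agrees with pROC", {
  set.seed(53)
  y <- sample(0:1, 60, replace = TRUE, prob = c(0.3, 0.7))
  y[1:2] <- 0:1
  s <- round(runif(60), 2)
  a <- compute_auc(s, y)
  expect_equal(a$roc$fpr[1], 0); expect_equal(a$roc$tpr[1], 0)
  expect_equal(tail(a$roc$fpr, 1), 1); expect_equal(tail(a$roc$tpr, 1), 1)
  expect_true(all(diff(a$roc$fpr) >= 0))
  expect_true(all(diff(a$roc$tpr) >= 0))
  skip_if_not_installed("pROC")
  expect_equal(a$auc, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("fold plans are stratified, case-disjoint, exhaustive and seeded", {
  cases <- tibble::tibble(case_id = sprintf("C%02d", 1:16),
                          label = rep(c("benign", "malignant"), each = 8))
  plan <- make_fold_plan(cases, n_folds = 4L, seed = 2L)
  for (f in 1:4) {
    p <- plan[plan$fold == f, ]
    test <- p[p$role == "test", ]
    expect_equal(sum(test$label == "benign"), 2)
    expect_equal(sum(test$label == "malignant"), 2)
    expect_equal(sort(p$case_id), sort(cases$case_id))       # every case has a role
    expect_equal(anyDuplicated(p$case_id), 0)                # exactly one role each
    expect_true(all(c("train", "valid") %in% p$role))
  }
  tests <- lapply(1:4, function(f) plan$case_id[plan$fold == f & plan$role == "test"])
  expect_setequal(unlist(tests), cases$case_id)              # union = all cases
  expect_equal(anyDuplicated(unlist(tests)), 0)              # pairwise disjoint
  expect_identical(plan, make_fold_plan(cases, n_folds = 4L, seed = 2L))
  expect_false(identical(plan, make_fold_plan(cases, n_folds = 4L, seed = 3L)))
  # validation holds about one-third of the non-test cases per class
  p1 <- plan[plan$fold == 1 & plan$label == "benign", ]
  expect_equal(sum(p1$role == "valid"), 2)                   # round(6 / 3)
  expect_error_class(make_fold_plan(cases[1:6, ], n_folds = 4L), "ebusfusion_error_data")
})

test_that("even frame sampling covers the stack at linear spacing", {
  expect_equal(sample_images_per_case(10, 5), c(0L, 2L, 4L, 6L, 8L))
  expect_equal(sample_images_per_case(7, 3), floor((0:2) * 7 / 3))
  expect_equal(sample_images_per_case(4, 9), 0:3)
  expect_equal(sample_images_per_case(12, 1), 0L)
  expect_error_class(sample_images_per_case(5, 0), "ebusfusion_error_argument")
})

test_that("cross-validation aggregates per-fold metrics as their arithmetic mean", {
  sc <- small_cohort()
  tc <- train_config(input_size = 32L, max_epochs = 2L, early_stop_patience = 1L,
                     batch_size = 8L, seed = 4L)
  cv <- suppressWarnings(
    cross_validate(sc$manifest, sc$dir, "type4", config = tc, n_folds = 4L, seed = 6L))
  expect_equal(nrow(cv$folds), 4)
  expect_length(cv$reports, 4)
  for (m in c("acc", "auc", "sen", "spec")) {
    expect_equal(cv$mean[[m]], mean(cv$folds[[m]]))
  }
  # test cases of a fold never appear in that fold's training or validation
  for (f in 1:4) {
    p <- cv$plan[cv$plan$fold == f, ]
    expect_length(intersect(p$case_id[p$role == "test"],
                            p$case_id[p$role != "test"]), 0)
  }
})
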