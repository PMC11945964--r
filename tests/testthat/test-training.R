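test_that("class weights match the literal four-step derivation and the closed form", {
  set.seed(41)
  for (i in 1:100) {
    n_b <- sample(1:200, 1); n_m <- sample(1:200, 1)
    w <- compute_class_weights(n_b, n_m)
    oracle <- four_step_weights(n_b, n_m)
    expect_equal(c(w$w_b, w$w_m), oracle, tolerance = 1e-12)
    expect_equal(w$w_b, n_m / (n_b + n_m), tolerance = 1e-12)
    expect_equal(w$w_b + w$w_m, 1, tolerance = 1e-12)
    expect_equal(w$w_b / w$w_m, n_m / n_b, tolerance = 1e-9)
  }
  # the clinical training split: 6 benign vs 40 malignant cases
  w <- compute_class_weights(6, 40)
  expect_equal(w$w_b, 40 / 46, tolerance = 1e-12)
  expect_equal(w$w_m, 6 / 46, tolerance = 1e-12)
  expect_equal(round(c(w$w_b, w$w_m), 4), c(0.8696, 0.1304))
  expect_equal(unlist(compute_class_weights(7, 7)[c("w_b", "w_m")]),
               c(w_b = 0.5, w_m = 0.5))
  expect_equal(unlist(compute_class_weights(1, 3)[c("w_b", "w_m")]),
               c(w_b = 0.75, w_m = 0.25))
  expect_error_class(compute_class_weights(0, 5), "ebusfusion_error_argument")
  expect_error_class(compute_class_weights(2.5, 5), "ebusfusion_error_argument")
})

test_that("weighted cross-entropy has its closed-form values and limits", {
  expect_equal(weighted_cross_entropy(matrix(c(0, 0), 1, 2), 0L, c(0.5, 0.5)),
               0.5 * log(2), tolerance = 1e-12)
  # confident correct logits drive the loss to zero
  expect_lt(weighted_cross_entropy(matrix(c(50, -50), 1, 2), 0L, c(0.5, 0.5)), 1e-12)
  # a zero-weight class contributes nothing
  set.seed(42)
  lg <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0L, 1L), 5)
  expect_equal(weighted_cross_entropy(lg, y, c(1, 0)),
               weighted_cross_entropy(lg[y == 0, ], y[y == 0], c(1, 0)) * 0.5)
  expect_error_class(weighted_cross_entropy(lg, rep(2L, 10), c(0.5, 0.5)),
                     "ebusfusion_error_label")
})

test_that("equal weights reduce the loss to half the plain cross-entropy on random batches", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    lg <- matrix(rnorm(2 * n, sd = 2), n, 2)
    y <- sample(0:1, n, replace = TRUE)
    p <- exp(lg) / rowSums(exp(lg))
    plain <- mean(-log(p[cbind(seq_len(n), y + 1)]))
    expect_equal(weighted_cross_entropy(lg, y, c(0.5, 0.5)), 0.5 * plain,
                 tolerance = 1e-12)
  }
})

test_that("augmentation draws compose as a group and synchronize across branch images", {
  set.seed(44)
  img <- array(round(runif(8 * 8 * 3) * 255), c(8, 8, 3))
  r4 <- ebusfusion:::rot90_image(img, 4L)
  expect_identical(r4, img)
  hf <- img[, 8:1, , drop = FALSE]
  expect_identical(hf[, 8:1, , drop = FALSE], img)
  # no-op configuration returns the input unchanged
  expect_identical(augment_group(img, jitter = c(0, 0, 0), p_flip = 0, rotate = FALSE), img)
  # one draw, applied identically to every image of the group
  set.seed(10)
  out <- augment_group(list(img, img), jitter = c(0.2, 0.2, 0.2))
  expect_identical(out[[1]], out[[2]])
  # saturation jitter leaves R=G=B (gray) images gray
  gray <- array(rep(round(runif(16) * 255), 3), c(4, 4, 3))
  set.seed(11)
  g2 <- augment_group(gray, jitter = c(0, 0, 0.2), p_flip = 0, rotate = FALSE)
  expect_equal(g2[, , 1], g2[, , 2])
})

test_that("stage-1 training is reproducible and honors the early-stopping protocol", {
  sc <- small_cohort()
  split <- ebusfusion:::default_split(cohort_cases(sc$manifest), 1)
  tc <- train_config(input_size = 32L, max_epochs = 5L, early_stop_patience = 2L,
                     batch_size = 8L, seed = 3L)
  f1 <- train_stage1(sc$manifest, sc$dir, "type4", split, config = tc)
  f2 <- train_stage1(sc$manifest, sc$dir, "type4", split, config = tc)
  expect_identical(f1$history, f2$history)
  expect_identical(encoder_parameters(f1$encoder), encoder_parameters(f2$encoder))
  h <- f1$history
  expect_lte(nrow(h), tc$max_epochs)
  expect_equal(f1$best_valid_loss, min(h$valid_loss))
  expect_equal(f1$best_epoch, which.min(h$valid_loss))
  if (nrow(h) < tc$max_epochs) expect_gte(nrow(h), f1$best_epoch + tc$early_stop_patience)
  # weights derive from the training-split case counts
  cc <- table(cohort_cases(sc$manifest[sc$manifest$case_id %in% split$train, ])$label)
  expect_equal(f1$weights$w_b, cc[["malignant"]] / sum(cc))
  expect_error_class(train_stage1(sc$manifest, sc$dir, "type4",
                                  list(train = split$train, valid = split$train[1]),
                                  config = tc),
                     "ebusfusion_error_data")
  # tidiers expose the history and the fit summary
  expect_identical(tidy(f1), f1$history)
  expect_equal(glance(f1)$best_epoch, f1$best_epoch)
})

test_that("stage-2 training leaves the frozen encoders bit-identical", {
  sc <- small_cohort()
  split <- ebusfusion:::default_split(cohort_cases(sc$manifest), 1)
  tc <- train_config(input_size = 32L, max_epochs = 4L, early_stop_patience = 2L,
                     batch_size = 8L, seed = 5L)
  fits <- lapply(c("type4", "type3"), function(ty)
    train_stage1(sc$manifest, sc$dir, ty, split, config = tc))
  before <- lapply(fits, function(f) encoder_parameters(f$encoder))
  f2 <- train_stage2(fits, c("type4", "type3"), sc$manifest, sc$dir, split,
                     variant = "ffm_v2", config = tc)
  after <- lapply(f2$encoders, encoder_parameters)
  expect_identical(before, after)
  expect_lte(nrow(f2$history), tc$max_epochs)
  expect_equal(f2$best_valid_loss, min(f2$history$valid_loss))
  preds <- predict_fusion(f2, sc$manifest, sc$dir, split$test)
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_equal(glance(f2)$variant, "ffm_v2")
})
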