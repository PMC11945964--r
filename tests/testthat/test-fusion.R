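rand_map <- function(h, w, C, N, sd = 1) array(rnorm(h * w * C * N, sd = sd), c(h, w, C, N))

test_that("CBAM gating preserves shape, bounds magnitude and kills zero input", {
  set.seed(31)
  m <- cbam_module(6, reduction = 2)
  x <- rand_map(5, 5, 6, 3)
  y <- m$fwd(x, FALSE)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))      # both gates lie in (0, 1)
  z <- m$fwd(x * 0, FALSE)
  expect_true(all(z == 0))                        # zero-initialized biases
  expect_error_class(m$fwd(matrix(0, 3, 3), FALSE), "ebusfusion_error_shape")
})

test_that("attention rows sum to one in every head and a single token attends to itself", {
  set.seed(32)
  for (rep in 1:5) {
    C <- sample(c(4, 8, 12), 1)
    nh <- ebusfusion:::default_heads(C)
    m <- mhsa_module(C, nh)
    x <- array(rnorm(6 * C * 2), c(6, C, 2))
    m$fwd(x, FALSE)
    for (n in 1:2) for (h in seq_len(nh)) {
      expect_equal(rowSums(m$last_attention[[n]][[h]]), rep(1, 6), tolerance = 1e-6)
    }
  }
  # single token: softmax of a singleton is exactly 1, output = Wo(Wv x + bv) + bo
  m1 <- mhsa_module(4, 2)
  x1 <- array(rnorm(4), c(1, 4, 1))
  y1 <- m1$fwd(x1, FALSE)
  expect_equal(m1$last_attention[[1]][[1]], matrix(1, 1, 1))
  v <- as.vector(m1$params$Wv %*% x1[1, , 1] + m1$params$bv)
  expect_equal(as.vector(y1), as.vector(m1$params$Wo %*% v + m1$params$bo), tolerance = 1e-12)
  expect_error_class(mhsa_module(6, 4), "ebusfusion_error_config")
})

test_that("self-attention over spatial tokens is permutation-equivariant (no positional encoding)", {
  set.seed(33)
  m <- mhsa_module(4, 2)
  x <- array(rnorm(4 * 4 * 1), c(4, 4, 1))   # 4 tokens from a 2 x 2 map
  y <- m$fwd(x, FALSE)
  perm <- c(3, 1, 4, 2)
  yp <- m$fwd(x[perm, , , drop = FALSE], FALSE)
  expect_equal(yp[order(perm), , , drop = FALSE], y, tolerance = 1e-12)
})

test_that("FFM-v1 concatenates gated branches and zeroed attention output collapses to zero", {
  set.seed(34)
  cfg <- fusion_config("ffm_v1", channel_counts = c(3, 3, 2))
  fz <- build_fusion(cfg, seed = 1L)
  maps <- list(rand_map(4, 4, 3, 2), rand_map(4, 4, 3, 2), rand_map(4, 4, 2, 2))
  out <- fusion_forward(fz, maps)
  expect_equal(dim(out$fused), c(4, 4, 8, 2))   # C1 + C2 + C3 channels
  expect_equal(dim(out$logits), c(2L, 2L))
  # zero the MHSA output projection: F'' = 0 exactly
  fz$mhsa_map$params$Wo[] <- 0
  fz$mhsa_map$params$bo[] <- 0
  expect_true(all(fusion_forward(fz, maps)$fused == 0))
  # removing the CBAM residual changes the output
  cfg_nr <- fusion_config("ffm_v1", channel_counts = c(3, 3, 2), residual = FALSE)
  fz_nr <- build_fusion(cfg_nr, seed = 1L)
  fz_r <- build_fusion(fusion_config("ffm_v1", channel_counts = c(3, 3, 2)), seed = 1L)
  expect_false(isTRUE(all.equal(fusion_forward(fz_nr, maps)$fused,
                                fusion_forward(fz_r, maps)$fused)))
})

test_that("FFM-v2 is an additive residual around attention on the concatenated map", {
  set.seed(35)
  cfg <- fusion_config("ffm_v2", channel_counts = c(4, 4))
  fz <- build_fusion(cfg, seed = 2L)
  maps <- list(rand_map(3, 3, 4, 2), rand_map(3, 3, 4, 2))
  X <- ebusfusion:::concat_channels(maps)
  out <- fusion_forward(fz, maps)
  expect_equal(dim(out$fused), c(3, 3, 8, 2))
  # zeroed output projection leaves the identity path: F'' = X exactly
  fz$mhsa_map$params$Wo[] <- 0
  fz$mhsa_map$params$bo[] <- 0
  expect_identical(fusion_forward(fz, maps)$fused, X)
  # a two-branch call with identical inputs is well-defined and deterministic
  same <- list(maps[[1]], maps[[1]])
  expect_identical(fusion_forward(fz, same)$fused, fusion_forward(fz, same)$fused)
})

test_that("FFM-v3 fuses pooled map features with attended FC features", {
  set.seed(36)
  cfg <- fusion_config("ffm_v3", channel_counts = c(4, 4, 4), fc_width = 6)
  fz <- build_fusion(cfg, seed = 3L)
  maps <- replicate(3, rand_map(4, 4, 4, 2), simplify = FALSE)
  fcs <- replicate(3, matrix(rnorm(12), 2, 6), simplify = FALSE)
  out <- fusion_forward(fz, maps, fcs)
  expect_equal(dim(out$fused), c(2L, 12L + 18L))  # C_total + 3 * fc_width
  # zero both attention output projections: fused = concat(pooled Xm, flat Xv)
  for (mm in list(fz$mhsa_map, fz$mhsa_vec)) { mm$params$Wo[] <- 0; mm$params$bo[] <- 0 }
  out0 <- fusion_forward(fz, maps, fcs)
  Xm <- ebusfusion:::concat_channels(maps)
  pooled <- t(matrix(colMeans(matrix(Xm, 16, 12 * 2)), 12, 2))
  Xv <- array(0, c(3, 6, 2)); for (k in 1:3) Xv[k, , ] <- t(fcs[[k]])
  flat <- t(matrix(Xv, 18, 2))
  expect_equal(out0$fused, cbind(pooled, flat), tolerance = 1e-12)
  expect_error_class(fusion_forward(fz, maps, fcs[1:2]), "ebusfusion_error_shape")
  expect_error_class(fusion_forward(fz, maps, lapply(fcs, function(v) v[, 1:4])),
                     "ebusfusion_error_shape")
})

test_that("detaching the FFM-v3 vector path reproduces FFM-v2 followed by pooling", {
  set.seed(37)
  cfg3 <- fusion_config("ffm_v3", channel_counts = c(4, 4), fc_width = 5)
  fz3 <- build_fusion(cfg3, seed = 4L)
  cfg2 <- fusion_config("ffm_v2", channel_counts = c(4, 4))
  fz2 <- build_fusion(cfg2, seed = 9L)
  fz2$mhsa_map$params <- fz3$mhsa_map$params    # share the map-path attention
  maps <- list(rand_map(4, 4, 4, 3), rand_map(4, 4, 4, 3))
  fcs <- replicate(2, matrix(rnorm(15), 3, 5), simplify = FALSE)
  fused3 <- fusion_forward(fz3, maps, fcs)$fused
  fused2 <- fusion_forward(fz2, maps)$fused
  pooled2 <- t(matrix(colMeans(matrix(fused2, 16, 8 * 3)), 8, 3))
  expect_equal(fused3[, 1:8], pooled2, tolerance = 1e-12)
})

test_that("the classifier pools, normalizes and emits well-formed logits", {
  set.seed(38)
  fz <- build_fusion(fusion_config("ffm_v2", channel_counts = c(4, 4)), seed = 5L)
  fused <- rand_map(3, 3, 8, 8)
  lg <- classify(fz, fused)
  expect_equal(dim(lg), c(8L, 2L))
  expect_equal(rowSums(ebusfusion:::softmax_rows(lg)), rep(1, 8))
  const <- array(rep(as.vector(fused[, , , 1]), 8), dim(fused))
  lgc <- classify(fz, const)
  expect_true(all(abs(sweep(lgc, 2, lgc[1, ])) < 1e-9))
  bad <- fused; bad[1] <- NA
  expect_error_class(classify(fz, bad), "ebusfusion_error_numeric")
})

test_that("branch alignment pools to the smallest grid and preserves constants", {
  a <- rand_map(8, 8, 3, 2)
  b <- rand_map(4, 4, 5, 2)
  al <- align_branches(list(a, b))
  expect_equal(dim(al[[1]]), c(4, 4, 3, 2))
  expect_identical(al[[2]], b)                  # already on the common grid
  same <- align_branches(list(b, b))
  expect_identical(same[[1]], b)
  cst <- array(7, c(6, 6, 2, 1))
  expect_true(all(align_branches(list(cst, rand_map(3, 3, 1, 1)))[[1]] == 7))
  expect_error_class(align_branches(list()), "ebusfusion_error_argument")
})

test_that("fusion training gradients stay inside fusion + classifier parameters", {
  set.seed(39)
  fz <- build_fusion(fusion_config("ffm_v2", channel_counts = c(3, 3)), seed = 6L)
  maps <- list(rand_map(3, 3, 3, 4), rand_map(3, 3, 3, 4))
  out <- fusion_forward(fz, maps, training = TRUE)
  zero_grads(fz$modules)
  dlog <- matrix(rnorm(8), 4, 2)
  fusion_backward(fz, dlog)
  gnorm <- vapply(fz$modules, function(m)
    sum(vapply(m$grads, function(g) sum(abs(g)), numeric(1))), numeric(1))
  expect_true(sum(gnorm) > 0)
  has_params <- vapply(fz$modules, function(m) length(m$params) > 0, logical(1))
  expect_true(all(gnorm[has_params] > 0))
})
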