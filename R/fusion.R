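#' Configure a feature-fusion module
#'
#' Three attention-based fusion designs combine the per-branch feature maps
#' `F1..Fk` (2-4 branches):
#' * `ffm_v1`: each branch passes through CBAM with an additive residual
#'   (`Fk' = Fk + CBAM(Fk)`), the gated maps are channel-concatenated and the
#'   result passes through multi-head self-attention (MHSA) over spatial
#'   tokens: `F'' = MHSA(concat(F1', ..., Fk'))`.
#' * `ffm_v2`: concatenate first, then attention with an additive residual:
#'   `F'' = X + MHSA(X)` with `X = concat(F1, ..., Fk)`.
#' * `ffm_v3`: the `ffm_v2` map path runs alongside a vector path that fuses
#'   the per-branch FC-layer features as tokens (`F2' = Xv + MHSA(Xv)`); the
#'   pooled map path and the flattened vector path are concatenated into one
#'   fused vector.
#'
#' The classifier is adaptive-average-pool -> flatten -> BatchNorm -> FC for
#' map-shaped fusion output, and BatchNorm -> FC for the `ffm_v3` vector.
#'
#' @param variant `"ffm_v1"`, `"ffm_v2"` or `"ffm_v3"`.
#' @param channel_counts per-branch feature-map channel counts.
#' @param n_heads attention heads; default is the largest of 8, 4, 2, 1 that
#'   divides the concatenated channel count.
#' @param fc_width FC-feature width (required for `ffm_v3`).
#' @param residual logical ablation flag for the `ffm_v1` CBAM residual.
#' @param reduction CBAM channel-MLP reduction ratio.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(variant = c("ffm_v1", "ffm_v2", "ffm_v3"),
                          channel_counts, n_heads = NULL, fc_width = NULL,
                          residual = TRUE, reduction = 8) {
  variant <- match.arg(variant)
  if (length(channel_counts) < 1) abort_argument("at least one branch is required")
  channel_counts <- as.integer(channel_counts)
  C_total <- sum(channel_counts)
  if (is.null(n_heads)) n_heads <- default_heads(C_total)
  if (C_total %% n_heads != 0)
    abort_config(paste0("concatenated channel count ", C_total,
                        " is not divisible by n_heads = ", n_heads))
  if (variant == "ffm_v3") {
    if (is.null(fc_width)) abort_config("ffm_v3 requires fc_width")
    fc_width <- as.integer(fc_width)
  }
  structure(list(variant = variant, channel_counts = channel_counts,
                 C_total = C_total, n_heads = as.integer(n_heads),
                 fc_width = fc_width, residual = isTRUE(residual),
                 reduction = reduction),
            class = "fusion_config")
}

default_heads <- function(C) {
  for (h in c(8L, 4L, 2L)) if (C %% h == 0) return(h)
  1L
}

#' Align branch feature maps onto a common spatial grid
#'
#' Maps with differing spatial sizes are adaptively average-pooled down to
#' the smallest grid among the inputs; channel counts are untouched and maps
#' already on the common grid are returned unchanged.
#'
#' @param maps list of `(H, W, C, N)` arrays.
#' @return list of aligned arrays.
#' @export
align_branches <- function(maps) {
  if (length(maps) < 1) abort_argument("align_branches needs at least one map")
  hs <- vapply(maps, function(m) dim(m)[1], numeric(1))
  ws <- vapply(maps, function(m) dim(m)[2], numeric(1))
  th <- min(hs); tw <- min(ws)
  lapply(maps, function(m) {
    if (dim(m)[1] == th && dim(m)[2] == tw) m
    else nn_adaptive_avg_pool(th, tw)$fwd(m, FALSE)
  })
}

concat_channels <- function(maps) {
  d1 <- dim(maps[[1]])
  Cs <- vapply(maps, function(m) dim(m)[3], numeric(1))
  for (m in maps) {
    if (!all(dim(m)[c(1, 2, 4)] == d1[c(1, 2, 4)]))
      abort_shape(paste0("branch maps disagree in spatial/batch dims: ",
                         paste(vapply(maps, function(x) paste(dim(x), collapse = "x"),
                                      character(1)), collapse = " vs ")))
  }
  out <- array(0, c(d1[1], d1[2], sum(Cs), d1[4]))
  at <- 0
  for (m in maps) { out[, , at + seq_len(dim(m)[3]), ] <- m; at <- at + dim(m)[3] }
  out
}

split_channels <- function(x, Cs) {
  at <- 0
  lapply(Cs, function(C) { sl <- x[, , at + seq_len(C), , drop = FALSE]; at <<- at + C; sl })
}

#' Build a fusion module (fusion + classifier) from a configuration
#'
#' @param config a [fusion_config()].
#' @param seed initialization seed.
#' @return an `ebus_fusion` environment with `$fwd` / `$bwd`.
#' @export
build_fusion <- function(config, seed = 0L) {
  if (!inherits(config, "fusion_config")) abort_config("config must be a fusion_config")
  fz <- new.env(parent = emptyenv())
  fz$config <- config
  Ct <- config$C_total
  nb <- length(config$channel_counts)
  withr::with_seed(seed, {
    if (config$variant == "ffm_v1")
      fz$cbams <- lapply(config$channel_counts, cbam_module, reduction = config$reduction)
    if (config$variant %in% c("ffm_v1", "ffm_v2", "ffm_v3"))
      fz$mhsa_map <- mhsa_module(Ct, config$n_heads)
    if (config$variant == "ffm_v3") {
      fz$mhsa_vec <- mhsa_module(config$fc_width, default_heads(config$fc_width))
      cls_width <- Ct + nb * config$fc_width
    } else {
      cls_width <- Ct
    }
    fz$cls_bn <- nn_batchnorm(cls_width)
    fz$cls_fc <- nn_linear(cls_width, 2L)
  })
  fz$cls_width <- cls_width
  fz$modules <- c(
    if (!is.null(fz$cbams)) unlist(lapply(fz$cbams, collect_modules), recursive = FALSE),
    collect_modules(fz$mhsa_map),
    if (!is.null(fz$mhsa_vec)) collect_modules(fz$mhsa_vec),
    collect_modules(fz$cls_bn), collect_modules(fz$cls_fc)
  )

  fz$fwd <- function(maps, fcs = NULL, training = FALSE) fusion_forward(fz, maps, fcs, training)
  fz$bwd <- function(dlogits) fusion_backward(fz, dlogits)
  class(fz) <- "ebus_fusion"
  fz
}

#' Fuse branch features and classify
#'
#' @param fusion an `ebus_fusion` from [build_fusion()].
#' @param maps list of per-branch feature maps `(H, W, C_k, N)`.
#' @param fcs list of per-branch FC-feature matrices `N x fc_width`
#'   (`ffm_v3` only).
#' @param training logical.
#' @return list with `logits` (`N x 2`) and `fused` (the fused representation
#'   `F''`: a map for v1/v2, a vector matrix for v3).
#' @export
fusion_forward <- function(fusion, maps, fcs = NULL, training = FALSE) {
  cfg <- fusion$config
  if (length(maps) != length(cfg$channel_counts))
    abort_shape(paste0("expected ", length(cfg$channel_counts), " branch maps, got ", length(maps)))
  maps <- align_branches(maps)
  cache <- list(dims = lapply(maps, dim))
  H <- dim(maps[[1]])[1]; W <- dim(maps[[1]])[2]; N <- dim(maps[[1]])[4]

  if (cfg$variant == "ffm_v1") {
    gated <- vector("list", length(maps))
    for (k in seq_along(maps)) {
      g <- fusion$cbams[[k]]$fwd(maps[[k]], training)
      gated[[k]] <- if (cfg$residual) maps[[k]] + g else g
    }
    X <- concat_channels(gated)
    fused <- tokens_to_map(fusion$mhsa_map$fwd(map_to_tokens(X), training), H, W)
  } else if (cfg$variant == "ffm_v2") {
    X <- concat_channels(maps)
    fused <- X + tokens_to_map(fusion$mhsa_map$fwd(map_to_tokens(X), training), H, W)
  } else {
    X <- concat_channels(maps)
    F1p <- X + tokens_to_map(fusion$mhsa_map$fwd(map_to_tokens(X), training), H, W)
    if (is.null(fcs) || length(fcs) != length(maps))
      abort_shape("ffm_v3 needs one FC-feature matrix per branch")
    wds <- vapply(fcs, ncol, numeric(1))
    if (any(wds != cfg$fc_width))
      abort_shape(paste0("FC-feature widths (", paste(wds, collapse = ", "),
                         ") must all equal fc_width = ", cfg$fc_width))
    Xv <- array(0, c(length(fcs), cfg$fc_width, N))
    for (k in seq_along(fcs)) Xv[k, , ] <- t(fcs[[k]])
    F2p <- Xv + fusion$mhsa_vec$fwd(Xv, training)
    pooled <- t(matrix(colMeans(matrix(F1p, H * W, cfg$C_total * N)), cfg$C_total, N))
    flat <- t(matrix(F2p, length(fcs) * cfg$fc_width, N))
    fused <- cbind(pooled, flat)
    cache$v3 <- list(HW = H * W, nb = length(fcs))
  }

  # classifier
  if (cfg$variant == "ffm_v3") {
    vec <- fused
  } else {
    pm <- nn_adaptive_avg_pool(1L, 1L)
    pooled <- pm$fwd(fused, training)
    vec <- t(matrix(pooled, cfg$C_total, N))
    cache$cls_pool <- pm
  }
  z <- fusion$cls_bn$fwd(vec, training)
  logits <- fusion$cls_fc$fwd(z, training)
  cache$fused <- fused
  fusion$cache <- cache
  list(logits = logits, fused = fused)
}

#' Backward pass through fusion + classifier
#'
#' Accumulates parameter gradients inside the fusion's modules and returns
#' the gradient with respect to the branch feature maps (unused when the
#' encoders are frozen, but returned for completeness).
#'
#' @param fusion an `ebus_fusion` whose `fusion_forward()` cache is fresh.
#' @param dlogits gradient at the logits, `N x 2`.
#' @return list of gradients, one per branch map.
#' @export
fusion_backward <- function(fusion, dlogits) {
  cfg <- fusion$config
  cache <- fusion$cache
  dvec <- fusion$cls_bn$bwd(fusion$cls_fc$bwd(dlogits))
  H <- cache$dims[[1]][1]; W <- cache$dims[[1]][2]; N <- cache$dims[[1]][4]

  if (cfg$variant == "ffm_v3") {
    Ct <- cfg$C_total; nb <- cache$v3$nb; HW <- cache$v3$HW
    dpooled <- dvec[, seq_len(Ct), drop = FALSE]
    dflat <- dvec[, Ct + seq_len(nb * cfg$fc_width), drop = FALSE]
    dF1p <- array(rep(as.vector(t(dpooled)) / HW, each = HW), c(H, W, Ct, N))
    dF2p <- array(as.vector(t(dflat)), c(nb, cfg$fc_width, N))
    dXv <- dF2p + fusion$mhsa_vec$bwd(dF2p)
    dX <- dF1p + tokens_to_map(fusion$mhsa_map$bwd(map_to_tokens(dF1p)), H, W)
    dmaps <- split_channels(dX, cfg$channel_counts)
    dfcs <- lapply(seq_len(nb), function(k) t(matrix(dXv[k, , ], cfg$fc_width, N)))
    return(list(maps = dmaps, fcs = dfcs))
  }

  dfused <- cache$cls_pool$bwd(array(t(dvec), c(1, 1, cfg$C_total, N)))
  if (cfg$variant == "ffm_v2") {
    dX <- dfused + tokens_to_map(fusion$mhsa_map$bwd(map_to_tokens(dfused)), H, W)
    return(list(maps = split_channels(dX, cfg$channel_counts)))
  }
  # ffm_v1
  dXg <- tokens_to_map(fusion$mhsa_map$bwd(map_to_tokens(dfused)), H, W)
  dgated <- split_channels(dXg, cfg$channel_counts)
  dmaps <- vector("list", length(dgated))
  for (k in seq_along(dgated)) {
    dk <- fusion$cbams[[k]]$bwd(dgated[[k]])
    dmaps[[k]] <- if (cfg$residual) dgated[[k]] + dk else dk
  }
  list(maps = dmaps)
}

#' Classify a fused representation
#'
#' Map-shaped input is adaptively average-pooled to 1 x 1, flattened,
#' batch-normalized and passed through the final fully connected layer;
#' vector input skips the pooling. Probabilities are `softmax` of the
#' returned logits.
#'
#' @param fusion an `ebus_fusion` (provides the classifier parameters).
#' @param fused `(H, W, C, N)` array or `N x F` matrix of fused features.
#' @param training logical.
#' @return `N x 2` logit matrix.
#' @export
classify <- function(fusion, fused, training = FALSE) {
  if (any(!is.finite(fused))) abort_numeric("fused features contain non-finite values")
  if (!is.null(dim(fused)) && length(dim(fused)) == 4) {
    d <- dim(fused)
    pooled <- nn_adaptive_avg_pool(1L, 1L)$fwd(fused, training)
    vec <- t(matrix(pooled, d[3], d[4]))
  } else {
    vec <- fused
  }
  if (ncol(vec) != fusion$cls_width)
    abort_shape(paste0("classifier expects width ", fusion$cls_width, ", got ", ncol(vec)))
  fusion$cls_fc$fwd(fusion$cls_bn$fwd(vec, training), training)
}

fusion_parameters <- function(fusion) lapply(fusion$modules, function(m) list(params = m$params, buffers = m$buffers))
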