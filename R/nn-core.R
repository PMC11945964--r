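# Minimal neural-network core: forward/backward modules over plain R arrays,
# vectorized onto BLAS. Feature maps are 4-D arrays (H, W, C, N), vector
# features are N x F matrices, token stacks are (T, C, N). Every module is an
# environment with $fwd(x, training), $bwd(dy), $params, $grads, $buffers and
# $submodules; parameter gradients accumulate until zero_grads(). All random
# initialization draws from the caller's RNG stream, so seeding the stream
# makes construction fully reproducible.

new_module <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e$submodules <- list()
  class(e) <- "nn_module"
  e
}

# all module environments in a tree, depth-first
collect_modules <- function(module) {
  out <- list(module)
  for (s in module$submodules) out <- c(out, collect_modules(s))
  out
}

zero_grads <- function(modules) {
  for (m in modules) for (nm in names(m$params)) m$grads[[nm]] <- m$params[[nm]] * 0
  invisible(NULL)
}

# deep copy of every parameter and buffer, for checkpointing / restore
module_state <- function(module) {
  lapply(collect_modules(module), function(m) list(params = m$params, buffers = m$buffers))
}

restore_module_state <- function(module, state) {
  mods <- collect_modules(module)
  stopifnot(length(mods) == length(state))
  for (i in seq_along(mods)) {
    mods[[i]]$params <- state[[i]]$params
    mods[[i]]$buffers <- state[[i]]$buffers
  }
  invisible(module)
}

#' Apply a network module
#'
#' @param module an internal network module (e.g. from [cbam_module()]).
#' @param x input array.
#' @param training logical; enables dropout and batch statistics.
#' @return the module output.
#' @export
nn_forward <- function(module, x, training = FALSE) module$fwd(x, training)

n_parameters <- function(module) {
  sum(vapply(collect_modules(module),
             function(m) sum(vapply(m$params, length, numeric(1))), numeric(1)))
}

## ---- layers ---------------------------------------------------------------

nn_linear <- function(in_f, out_f) {
  m <- new_module("linear")
  sd <- sqrt(2 / in_f)
  m$params$W <- matrix(rnorm(out_f * in_f, sd = sd), out_f, in_f)
  m$params$b <- numeric(out_f)
  m$fwd <- function(x, training = FALSE) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    m$cache_x <- x
    sweep(tcrossprod(x, m$params$W), 2, m$params$b, "+")
  }
  m$bwd <- function(dy) {
    m$grads$W <- m$grads$W + crossprod(dy, m$cache_x)
    m$grads$b <- m$grads$b + colSums(dy)
    dy %*% m$params$W
  }
  m$grads <- lapply(m$params, function(p) p * 0)
  m
}

nn_relu <- function() {
  m <- new_module("relu")
  m$fwd <- function(x, training = FALSE) { m$cache_mask <- x > 0; x * m$cache_mask }
  m$bwd <- function(dy) dy * m$cache_mask
  m
}

nn_dropout <- function(p = 0.5) {
  m <- new_module("dropout")
  m$p <- p
  m$fwd <- function(x, training = FALSE) {
    if (!training || m$p <= 0) { m$cache_mask <- NULL; return(x) }
    mask <- (runif(length(x)) >= m$p) / (1 - m$p)
    dim(mask) <- dim(x)
    m$cache_mask <- mask
    x * mask
  }
  m$bwd <- function(dy) if (is.null(m$cache_mask)) dy else dy * m$cache_mask
  m
}

# Batch normalization over (H, W, N) per channel for 4-D inputs, over N per
# feature for matrix inputs. Running statistics follow the usual momentum
# update and are used in evaluation mode.
nn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- new_module("batchnorm")
  m$params$gamma <- rep(1, C)
  m$params$beta <- numeric(C)
  m$buffers$running_mean <- numeric(C)
  m$buffers$running_var <- rep(1, C)
  m$eps <- eps; m$momentum <- momentum

  to_mat <- function(x) {
    d <- dim(x)
    if (length(d) == 4) matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3]) else x
  }
  from_mat <- function(y, d) {
    if (length(d) == 4) aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    else y
  }
  m$fwd <- function(x, training = FALSE) {
    d <- dim(x); xr <- to_mat(x); M <- nrow(xr)
    if (training) {
      mu <- colMeans(xr)
      v <- colMeans(xr^2) - mu^2
      if (M > 1) {
        m$buffers$running_mean <- (1 - m$momentum) * m$buffers$running_mean + m$momentum * mu
        m$buffers$running_var <- (1 - m$momentum) * m$buffers$running_var +
          m$momentum * v * M / (M - 1)
      }
    } else {
      mu <- m$buffers$running_mean
      v <- m$buffers$running_var
    }
    s <- sqrt(v + m$eps)
    xhat <- sweep(sweep(xr, 2, mu, "-"), 2, s, "/")
    m$cache <- list(xhat = xhat, s = s, d = d, training = training, M = M)
    from_mat(sweep(sweep(xhat, 2, m$params$gamma, "*"), 2, m$params$beta, "+"), d)
  }
  m$bwd <- function(dy) {
    cc <- m$cache
    dyr <- to_mat(dy)
    m$grads$gamma <- m$grads$gamma + colSums(dyr * cc$xhat)
    m$grads$beta <- m$grads$beta + colSums(dyr)
    dxhat <- sweep(dyr, 2, m$params$gamma, "*")
    if (cc$training) {
      mh <- colMeans(dxhat)
      mhx <- colMeans(dxhat * cc$xhat)
      dxr <- sweep(sweep(dxhat, 2, mh, "-") - sweep(cc$xhat, 2, mhx, "*"), 2, cc$s, "/")
    } else {
      dxr <- sweep(dxhat, 2, cc$s, "/")
    }
    from_mat(dxr, cc$d)
  }
  m$grads <- lapply(m$params, function(p) p * 0)
  m
}

# 2-D convolution via im2col + GEMM. Weight matrix rows are output channels,
# columns follow patch order (kernel row fastest, then kernel col, then input
# channel) to match the gather index construction.
nn_conv2d <- function(in_c, out_c, k = 3, stride = 1, pad = 1) {
  m <- new_module("conv2d")
  kkC <- k * k * in_c
  m$params$W <- matrix(rnorm(out_c * kkC, sd = sqrt(2 / kkC)), out_c, kkC)
  m$params$b <- numeric(out_c)
  m$k <- k; m$stride <- stride; m$pad <- pad; m$in_c <- in_c; m$out_c <- out_c

  get_geom <- function(H, W) {
    key <- paste(H, W)
    if (!is.null(m$geom_cache[[key]])) return(m$geom_cache[[key]])
    Hp <- H + 2 * m$pad; Wp <- W + 2 * m$pad
    Ho <- (Hp - m$k) %/% m$stride + 1L
    Wo <- (Wp - m$k) %/% m$stride + 1L
    a <- rep(0:(m$k - 1), times = m$k * in_c)
    b <- rep(rep(0:(m$k - 1), each = m$k), times = in_c)
    cch <- rep(0:(in_c - 1), each = m$k * m$k)
    off <- a + Hp * b + Hp * Wp * cch
    oi <- rep(0:(Ho - 1), times = Wo)
    oj <- rep(0:(Wo - 1), each = Ho)
    base <- oi * m$stride + Hp * (oj * m$stride)
    idx <- outer(off, base, "+") + 1L
    g <- list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = as.vector(idx))
    if (is.null(m$geom_cache)) m$geom_cache <- list()
    m$geom_cache[[key]] <- g
    g
  }

  m$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    if (length(d) != 4 || d[3] != in_c)
      abort_shape(paste0("conv2d expects (H, W, ", in_c, ", N) input"))
    H <- d[1]; W <- d[2]; N <- d[4]
    g <- get_geom(H, W)
    if (m$pad > 0) {
      xp <- array(0, c(g$Hp, g$Wp, in_c, N))
      xp[m$pad + (1:H), m$pad + (1:W), , ] <- x
    } else xp <- x
    dim(xp) <- c(g$Hp * g$Wp * in_c, N)
    Xc <- xp[g$idx, , drop = FALSE]
    P <- g$Ho * g$Wo
    dim(Xc) <- c(kkC, P * N)
    Y <- m$params$W %*% Xc + m$params$b
    m$cache <- list(Xc = Xc, g = g, N = N, H = H, W = W)
    aperm(array(Y, c(out_c, g$Ho, g$Wo, N)), c(2, 3, 1, 4))
  }
  m$bwd <- function(dy) {
    cc <- m$cache; g <- cc$g; N <- cc$N
    P <- g$Ho * g$Wo
    dym <- matrix(aperm(dy, c(3, 1, 2, 4)), out_c, P * N)
    m$grads$W <- m$grads$W + tcrossprod(dym, cc$Xc)
    m$grads$b <- m$grads$b + rowSums(dym)
    dXc <- crossprod(m$params$W, dym)
    dim(dXc) <- c(kkC * P, N)
    rs <- rowsum(dXc, g$idx)
    dxp <- matrix(0, g$Hp * g$Wp * in_c, N)
    dxp[as.integer(rownames(rs)), ] <- rs
    dim(dxp) <- c(g$Hp, g$Wp, in_c, N)
    if (m$pad > 0) dxp[m$pad + (1:cc$H), m$pad + (1:cc$W), , , drop = FALSE] else dxp
  }
  m$grads <- lapply(m$params, function(p) p * 0)
  m
}

nn_global_avg_pool <- function() {
  m <- new_module("gap")
  m$fwd <- function(x, training = FALSE) {
    d <- dim(x); m$cache_d <- d
    t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  }
  m$bwd <- function(dy) {
    d <- m$cache_d
    array(rep(as.vector(t(dy)) / (d[1] * d[2]), each = d[1] * d[2]), d)
  }
  m
}

# Adaptive average pooling to a fixed output grid (torch-style binning).
nn_adaptive_avg_pool <- function(out_h, out_w) {
  m <- new_module("adaptive_pool")
  m$out_h <- out_h; m$out_w <- out_w
  bins <- function(n_in, n_out) {
    lapply(seq_len(n_out), function(i)
      (floor((i - 1) * n_in / n_out) + 1):ceiling(i * n_in / n_out))
  }
  m$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    m$cache <- list(d = d, rb = bins(d[1], out_h), cb = bins(d[2], out_w))
    if (d[1] == out_h && d[2] == out_w) { m$cache$identity <- TRUE; return(x) }
    y <- array(0, c(out_h, out_w, d[3], d[4]))
    for (i in seq_len(out_h)) for (j in seq_len(out_w)) {
      blk <- x[m$cache$rb[[i]], m$cache$cb[[j]], , , drop = FALSE]
      db <- dim(blk)
      y[i, j, , ] <- colMeans(matrix(blk, db[1] * db[2], db[3] * db[4]))
    }
    y
  }
  m$bwd <- function(dy) {
    cc <- m$cache
    if (isTRUE(cc$identity)) return(dy)
    dx <- array(0, cc$d)
    for (i in seq_len(out_h)) for (j in seq_len(out_w)) {
      nr <- length(cc$rb[[i]]); nc <- length(cc$cb[[j]])
      contrib <- dy[i, j, , ] / (nr * nc)
      add <- aperm(array(rep(as.vector(contrib), each = nr * nc),
                         c(nr, nc, cc$d[3], cc$d[4])), c(1, 2, 3, 4))
      dx[cc$rb[[i]], cc$cb[[j]], , ] <- dx[cc$rb[[i]], cc$cb[[j]], , ] + add
    }
    dx
  }
  m
}

nn_sequential <- function(...) {
  m <- new_module("sequential")
  m$submodules <- list(...)
  m$fwd <- function(x, training = FALSE) {
    for (s in m$submodules) x <- s$fwd(x, training)
    x
  }
  m$bwd <- function(dy) {
    for (s in rev(m$submodules)) dy <- s$bwd(dy)
    dy
  }
  m
}

## ---- attention modules ----------------------------------------------------

#' Multi-head self-attention module over token stacks
#'
#' Tokens are attended with standard scaled dot-product multi-head
#' self-attention (learned query/key/value projections, softmax over key
#' positions, output projection); no positional encoding is added, so the
#' operator is equivariant to token permutations. Input shape `(T, C, N)`.
#'
#' @param C embedding width; must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @return an attention module for [nn_forward()].
#' @export
mhsa_module <- function(C, n_heads) {
  if (C %% n_heads != 0)
    abort_config(paste0("embedding width ", C, " is not divisible by n_heads = ", n_heads))
  m <- new_module("mhsa")
  m$C <- C; m$n_heads <- n_heads; m$dh <- C %/% n_heads
  sd <- 1 / sqrt(C)
  for (nm in c("Wq", "Wk", "Wv", "Wo")) m$params[[nm]] <- matrix(rnorm(C * C, sd = sd), C, C)
  for (nm in c("bq", "bk", "bv", "bo")) m$params[[nm]] <- numeric(C)

  m$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    if (length(d) != 3 || d[2] != C) abort_shape("mhsa expects a (T, C, N) token array")
    Tn <- d[1]; N <- d[3]
    y <- array(0, d)
    cache <- vector("list", N)
    attn <- vector("list", N)
    hs <- split(seq_len(C), rep(seq_len(n_heads), each = m$dh))
    for (n in seq_len(N)) {
      X <- matrix(x[, , n], Tn, C)
      Q <- sweep(tcrossprod(X, m$params$Wq), 2, m$params$bq, "+")
      K <- sweep(tcrossprod(X, m$params$Wk), 2, m$params$bk, "+")
      V <- sweep(tcrossprod(X, m$params$Wv), 2, m$params$bv, "+")
      O <- matrix(0, Tn, C)
      A_list <- vector("list", n_heads)
      for (h in seq_len(n_heads)) {
        cols <- hs[[h]]
        S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(m$dh)
        S <- S - apply(S, 1, max)
        E <- exp(S)
        A <- E / rowSums(E)
        A_list[[h]] <- A
        O[, cols] <- A %*% V[, cols, drop = FALSE]
      }
      y[, , n] <- sweep(tcrossprod(O, m$params$Wo), 2, m$params$bo, "+")
      cache[[n]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = A_list)
      attn[[n]] <- A_list
    }
    m$cache <- list(per_sample = cache, d = d, hs = hs)
    m$last_attention <- attn
    y
  }
  m$bwd <- function(dy) {
    cc <- m$cache
    d <- cc$d; N <- d[3]
    dx <- array(0, d)
    for (n in seq_len(N)) {
      s <- cc$per_sample[[n]]
      dYn <- matrix(dy[, , n], d[1], C)
      m$grads$Wo <- m$grads$Wo + crossprod(dYn, s$O)
      m$grads$bo <- m$grads$bo + colSums(dYn)
      dO <- dYn %*% m$params$Wo
      dQ <- matrix(0, d[1], C); dK <- dQ; dV <- dQ
      for (h in seq_len(m$n_heads)) {
        cols <- cc$hs[[h]]
        A <- s$A[[h]]
        dOh <- dO[, cols, drop = FALSE]
        dA <- tcrossprod(dOh, s$V[, cols, drop = FALSE])
        dV[, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(m$dh)
        dQ[, cols] <- dS %*% s$K[, cols, drop = FALSE]
        dK[, cols] <- crossprod(dS, s$Q[, cols, drop = FALSE])
      }
      m$grads$Wq <- m$grads$Wq + crossprod(dQ, s$X)
      m$grads$bq <- m$grads$bq + colSums(dQ)
      m$grads$Wk <- m$grads$Wk + crossprod(dK, s$X)
      m$grads$bk <- m$grads$bk + colSums(dK)
      m$grads$Wv <- m$grads$Wv + crossprod(dV, s$X)
      m$grads$bv <- m$grads$bv + colSums(dV)
      dx[, , n] <- dQ %*% m$params$Wq + dK %*% m$params$Wk + dV %*% m$params$Wv
    }
    dx
  }
  m$grads <- lapply(m$params, function(p) p * 0)
  m
}

# feature map (H, W, C, N) <-> token stack (T = H * W, C, N)
map_to_tokens <- function(x) {
  d <- dim(x)
  array(x, c(d[1] * d[2], d[3], d[4]))
}
tokens_to_map <- function(x, h, w) {
  d <- dim(x)
  array(x, c(h, w, d[2], d[3]))
}

#' Convolutional block attention module (CBAM)
#'
#' Channel attention (shared two-layer MLP over global-average and global-max
#' channel descriptors, sigmoid-gated) followed by spatial attention (a 7 x 7
#' convolution over the stacked channel-mean and channel-max maps,
#' sigmoid-gated). Both gates lie in (0, 1), so the output magnitude never
#' exceeds the input's. Input shape `(H, W, C, N)`.
#'
#' @param C channel count.
#' @param reduction channel-MLP bottleneck ratio.
#' @param spatial_kernel spatial-attention kernel size (odd).
#' @return a CBAM module for [nn_forward()].
#' @export
cbam_module <- function(C, reduction = 8, spatial_kernel = 7) {
  m <- new_module("cbam")
  hidden <- max(1L, C %/% reduction)
  m$C <- C; m$hidden <- hidden
  m$params$W1 <- matrix(rnorm(hidden * C, sd = sqrt(2 / C)), hidden, C)
  m$params$b1 <- numeric(hidden)
  m$params$W2 <- matrix(rnorm(C * hidden, sd = sqrt(2 / hidden)), C, hidden)
  m$params$b2 <- numeric(C)
  m$conv_sp <- nn_conv2d(2, 1, k = spatial_kernel, stride = 1, pad = (spatial_kernel - 1) %/% 2)
  m$submodules <- list(m$conv_sp)

  mlp_fwd <- function(s) {
    pre <- sweep(tcrossprod(s, m$params$W1), 2, m$params$b1, "+")
    h <- pmax(pre, 0)
    list(out = sweep(tcrossprod(h, m$params$W2), 2, m$params$b2, "+"),
         h = h, mask = pre > 0)
  }
  mlp_bwd <- function(do, s, h, mask) {
    m$grads$W2 <- m$grads$W2 + crossprod(do, h)
    m$grads$b2 <- m$grads$b2 + colSums(do)
    dh <- (do %*% m$params$W2) * mask
    m$grads$W1 <- m$grads$W1 + crossprod(dh, s)
    m$grads$b1 <- m$grads$b1 + colSums(dh)
    dh %*% m$params$W1
  }

  m$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    if (length(d) != 4) abort_shape("cbam expects a (H, W, C, N) feature map")
    H <- d[1]; W <- d[2]; Cc <- d[3]; N <- d[4]
    if (Cc != C) abort_shape(paste0("cbam built for ", C, " channels, got ", Cc))
    HW <- H * W

    ## channel attention
    M1 <- matrix(x, HW, Cc * N)
    s_avg <- t(matrix(colMeans(M1), Cc, N))                 # N x C
    amax_sp <- max.col(t(M1), ties.method = "first")        # spatial argmax per (c, n)
    s_max <- t(matrix(M1[cbind(amax_sp, seq_len(Cc * N))], Cc, N))
    fa <- mlp_fwd(s_avg)
    fm <- mlp_fwd(s_max)
    gate_c <- 1 / (1 + exp(-(fa$out + fm$out)))             # N x C
    gc_big <- rep(as.vector(t(gate_c)), each = HW)
    x1 <- x * gc_big

    ## spatial attention
    M2 <- matrix(aperm(x1, c(1, 2, 4, 3)), ncol = Cc)       # (H*W*N) x C
    mu_sp <- rowMeans(M2)
    amax_ch <- max.col(M2, ties.method = "first")           # channel argmax per (h, w, n)
    mx_sp <- M2[cbind(seq_len(HW * N), amax_ch)]
    sa_in <- array(0, c(H, W, 2, N))
    sa_in[, , 1, ] <- array(mu_sp, c(H, W, N))
    sa_in[, , 2, ] <- array(mx_sp, c(H, W, N))
    conv_out <- m$conv_sp$fwd(sa_in, training)
    gs <- 1 / (1 + exp(-conv_out))                          # (H, W, 1, N)
    gs_big <- aperm(array(as.vector(gs), c(H, W, N, Cc)), c(1, 2, 4, 3))
    y <- x1 * gs_big

    m$cache <- list(d = d, x = x, x1 = x1, gate_c = gate_c, gc_big = gc_big,
                    gs = gs, gs_big = gs_big, s_avg = s_avg, s_max = s_max,
                    fa = fa, fm = fm, amax_sp = amax_sp, amax_ch = amax_ch)
    y
  }
  m$bwd <- function(dy) {
    cc <- m$cache
    d <- cc$d; H <- d[1]; W <- d[2]; Cc <- d[3]; N <- d[4]; HW <- H * W

    ## through spatial gate
    dx1 <- dy * cc$gs_big
    dgs_full <- dy * cc$x1
    dgs <- array(rowSums(matrix(aperm(dgs_full, c(1, 2, 4, 3)), ncol = Cc)), c(H, W, 1, N))
    dconv <- dgs * cc$gs * (1 - cc$gs)
    dsa <- m$conv_sp$bwd(dconv)
    davg <- dsa[, , 1, , drop = FALSE]                      # (H, W, 1, N)
    dmax <- dsa[, , 2, , drop = FALSE]
    dx1 <- dx1 + aperm(array(as.vector(davg) / Cc, c(H, W, N, Cc)), c(1, 2, 4, 3))
    Msc <- matrix(0, HW * N, Cc)
    Msc[cbind(seq_len(HW * N), cc$amax_ch)] <- as.vector(dmax)
    dx1 <- dx1 + aperm(array(Msc, c(H, W, N, Cc)), c(1, 2, 4, 3))

    ## through channel gate
    dx <- dx1 * cc$gc_big
    dgc <- t(matrix(colSums(matrix(dx1 * cc$x, HW, Cc * N)), Cc, N))  # N x C
    dpre <- dgc * cc$gate_c * (1 - cc$gate_c)
    ds_avg <- mlp_bwd(dpre, cc$s_avg, cc$fa$h, cc$fa$mask)
    ds_max <- mlp_bwd(dpre, cc$s_max, cc$fm$h, cc$fm$mask)
    dx <- dx + rep(as.vector(t(ds_avg)) / HW, each = HW)
    Msp <- matrix(0, HW, Cc * N)
    Msp[cbind(cc$amax_sp, seq_len(Cc * N))] <- as.vector(t(ds_max))
    dim(Msp) <- d
    dx + Msp
  }
  m$grads <- lapply(m$params, function(p) p * 0)
  m
}

## ---- optimizer ------------------------------------------------------------

# Adam with L2 weight decay folded into the gradient (the convention of the
# reference deep-learning stacks when weight_decay is passed to Adam).
adam_new <- function(modules, lr = 1e-3, weight_decay = 5e-4,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$modules <- modules
  st$lr <- lr; st$wd <- weight_decay
  st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0
  st$m <- list(); st$v <- list()
  for (i in seq_along(modules)) for (nm in names(modules[[i]]$params)) {
    key <- paste0(i, ".", nm)
    st$m[[key]] <- modules[[i]]$params[[nm]] * 0
    st$v[[key]] <- st$m[[key]]
  }
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(st$modules)) {
    mod <- st$modules[[i]]
    for (nm in names(mod$params)) {
      key <- paste0(i, ".", nm)
      g <- mod$grads[[nm]] + st$wd * mod$params[[nm]]
      st$m[[key]] <- st$b1 * st$m[[key]] + (1 - st$b1) * g
      st$v[[key]] <- st$b2 * st$v[[key]] + (1 - st$b2) * g^2
      mod$params[[nm]] <- mod$params[[nm]] -
        st$lr * (st$m[[key]] / bc1) / (sqrt(st$v[[key]] / bc2) + st$eps)
    }
  }
  invisible(st)
}
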