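# Minimal feed-forward / convolutional network engine.
#
# Activations are stored as (features x batch) matrices; images are
# flattened column-major as h + (w-1)*H + (c-1)*H*W, so a conv layer sees
# the same layout an R array(H, W, C) would produce. Convolutions are
# im2col gathers followed by BLAS matrix multiplication, with index maps
# precomputed once per layer at build time. Everything is deterministic
# under a fixed RNG seed.

# ---- layer constructors ----------------------------------------------------

.layer_dense <- function(n_in, n_out, l1 = 0, l2 = 0) {
  list(type = "dense", n_in = n_in, n_out = n_out, l1 = l1, l2 = l2,
       params = list(W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)),
                                n_out, n_in),
                     b = numeric(n_out)))
}

.layer_relu <- function() list(type = "relu", params = list())

.layer_softmax <- function() list(type = "softmax", params = list())

.layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate, params = list())
}

.layer_flatten <- function(n_out) list(type = "flatten", n_out = n_out,
                                       params = list())

# Batch normalization over the batch (dense: per feature row; conv:
# per channel, pooling over pixels and batch).
.layer_batchnorm <- function(n_feat, spatial = FALSE, hw = NULL,
                             momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", n_feat = n_feat, spatial = spatial, hw = hw,
       momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n_feat), beta = rep(0, n_feat)),
       rmean = rep(0, n_feat), rvar = rep(1, n_feat))
}

.layer_conv2d <- function(in_shape, filters, ksize = 5) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  oh <- H - ksize + 1L; ow <- W - ksize + 1L
  P <- oh * ow; K <- ksize * ksize * C
  # im2col index map: rows = output positions (oh-major), cols = kernel
  # elements ordered (kh, kw, c)
  pos <- expand.grid(r = seq_len(oh), cc = seq_len(ow))
  ker <- expand.grid(kh = seq_len(ksize), kw = seq_len(ksize), ch = seq_len(C))
  idx <- outer(seq_len(P), seq_len(K), function(p, k) {
    (pos$r[p] + ker$kh[k] - 1L) +
      (pos$cc[p] + ker$kw[k] - 2L) * H +
      (ker$ch[k] - 1L) * H * W
  })
  storage.mode(idx) <- "integer"
  list(type = "conv2d", in_shape = in_shape,
       out_shape = c(oh, ow, filters), ksize = ksize, filters = filters,
       P = P, K = K, idx = idx, n_in = H * W * C,
       params = list(W = matrix(stats::rnorm(K * filters, sd = sqrt(2 / K)),
                                K, filters),
                     b = numeric(filters)))
}

.layer_maxpool2 <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  oh <- H %/% 2L; ow <- W %/% 2L
  base <- expand.grid(r = seq(1L, H, by = 2L), cc = seq(1L, W, by = 2L),
                      ch = seq_len(C))
  flat <- function(dr, dc) (base$r + dr) + (base$cc + dc - 1L) * H +
    (base$ch - 1L) * H * W
  list(type = "maxpool2", in_shape = in_shape, out_shape = c(oh, ow, C),
       n_in = H * W * C,
       sel = list(flat(0L, 0L), flat(1L, 0L), flat(0L, 1L), flat(1L, 1L)),
       params = list())
}

# ---- forward / backward ----------------------------------------------------

.fwd_layer <- function(ly, X, training) {
  switch(ly$type,
    dense = {
      out <- ly$params$W %*% X + ly$params$b
      list(out = out, cache = list(X = X), layer = ly)
    },
    relu = list(out = pmax(X, 0), cache = list(X = X), layer = ly),
    softmax = {
      Z <- sweep(X, 2, apply(X, 2, max))
      E <- exp(Z)
      P <- sweep(E, 2, colSums(E), "/")
      list(out = P, cache = list(P = P), layer = ly)
    },
    dropout = {
      if (!training || ly$rate == 0)
        return(list(out = X, cache = list(mask = NULL), layer = ly))
      keep <- 1 - ly$rate
      mask <- matrix(stats::rbinom(length(X), 1L, keep), nrow(X)) / keep
      list(out = X * mask, cache = list(mask = mask), layer = ly)
    },
    flatten = list(out = X, cache = NULL, layer = ly),
    batchnorm = {
      eps <- ly$eps
      if (ly$spatial) {
        # channel blocks are contiguous rows; per-channel stats pool over
        # pixels and batch without any layout shuffle
        hw <- ly$hw; C <- ly$n_feat; B <- ncol(X)
        if (training) {
          s1 <- rowSums(matrix(.colSums(X, hw, C * B), C, B))
          s2 <- rowSums(matrix(.colSums(X * X, hw, C * B), C, B))
          nn <- hw * B
          mu <- s1 / nn
          v <- pmax(s2 / nn - mu^2, 0)
          ly$rmean <- ly$momentum * ly$rmean + (1 - ly$momentum) * mu
          ly$rvar <- ly$momentum * ly$rvar + (1 - ly$momentum) * v
        } else { mu <- ly$rmean; v <- ly$rvar }
        isd <- 1 / sqrt(v + eps)
        murow <- rep(mu, each = hw); isdrow <- rep(isd, each = hw)
        Xh <- (X - murow) * isdrow
        out <- Xh * rep(ly$params$gamma, each = hw) +
          rep(ly$params$beta, each = hw)
        list(out = out, cache = list(Xh = Xh, isdrow = isdrow, B = B),
             layer = ly)
      } else {
        if (training) {
          mu <- rowMeans(X); v <- pmax(rowMeans(X^2) - mu^2, 0)
          ly$rmean <- ly$momentum * ly$rmean + (1 - ly$momentum) * mu
          ly$rvar <- ly$momentum * ly$rvar + (1 - ly$momentum) * v
        } else { mu <- ly$rmean; v <- ly$rvar }
        isd <- 1 / sqrt(v + eps)
        Xh <- (X - mu) * isd
        out <- Xh * ly$params$gamma + ly$params$beta
        list(out = out, cache = list(Xh = Xh, isd = isd), layer = ly)
      }
    },
    conv2d = {
      out <- .conv_fwd_cpp(X, ly$idx, ly$params$W, ly$params$b)
      list(out = out, cache = list(X = X), layer = ly)
    },
    maxpool2 = {
      s <- ly$sel
      a1 <- X[s[[1]], , drop = FALSE]; a2 <- X[s[[2]], , drop = FALSE]
      a3 <- X[s[[3]], , drop = FALSE]; a4 <- X[s[[4]], , drop = FALSE]
      out <- pmax(pmax(a1, a2), pmax(a3, a4))
      list(out = out,
           cache = list(a = list(a1, a2, a3, a4), out = out, B = ncol(X)),
           layer = ly)
    },
    stop("unknown layer type: ", ly$type))
}

.bwd_layer <- function(ly, dY, cache) {
  switch(ly$type,
    dense = {
      dW <- dY %*% t(cache$X)
      if (ly$l1 > 0) dW <- dW + ly$l1 * sign(ly$params$W)
      if (ly$l2 > 0) dW <- dW + 2 * ly$l2 * ly$params$W
      list(dX = crossprod(ly$params$W, dY),
           grads = list(W = dW, b = rowSums(dY)))
    },
    relu = list(dX = dY * (cache$X > 0), grads = list()),
    softmax = {
      P <- cache$P
      list(dX = P * sweep(dY, 2, colSums(dY * P)), grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = list())
      else list(dX = dY * cache$mask, grads = list())
    },
    flatten = list(dX = dY, grads = list()),
    batchnorm = {
      g <- ly$params$gamma
      if (ly$spatial) {
        hw <- ly$hw; C <- ly$n_feat; B <- cache$B
        Xh <- cache$Xh; isdrow <- cache$isdrow
        nn <- hw * B
        chsum <- function(M) rowSums(matrix(.colSums(M, hw, C * B), C, B))
        dgamma <- chsum(dY * Xh)
        dbeta <- chsum(dY)
        dXh <- dY * rep(g, each = hw)
        m1 <- chsum(dXh) / nn
        m2 <- chsum(dXh * Xh) / nn
        dX <- (dXh - rep(m1, each = hw) - Xh * rep(m2, each = hw)) * isdrow
        list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
      } else {
        Xh <- cache$Xh; isd <- cache$isd
        dgamma <- rowSums(dY * Xh); dbeta <- rowSums(dY)
        dXh <- dY * g
        dX <- (dXh - rowMeans(dXh) - Xh * rowMeans(dXh * Xh)) * isd
        list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
      }
    },
    conv2d = {
      r <- .conv_bwd_cpp(cache$X, ly$idx, ly$params$W, dY)
      list(dX = r$dX, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    maxpool2 = {
      a <- cache$a; out <- cache$out
      m1 <- a[[1]] == out
      m2 <- (a[[2]] == out) & !m1
      m3 <- (a[[3]] == out) & !m1 & !m2
      m4 <- !m1 & !m2 & !m3
      dX <- matrix(0, ly$n_in, cache$B)
      s <- ly$sel
      dX[s[[1]], ] <- dY * m1; dX[s[[2]], ] <- dY * m2
      dX[s[[3]], ] <- dY * m3; dX[s[[4]], ] <- dY * m4
      list(dX = dX, grads = list())
    },
    stop("unknown layer type: ", ly$type))
}

# Forward a whole layer list. Returns output, caches and the (possibly
# state-updated) layers.
.fwd_chain <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- .fwd_layer(layers[[i]], X, training)
    X <- r$out; caches[[i]] <- r$cache; layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

# Backward a layer list from gradient dTop at its output. `from` allows
# skipping the terminal softmax when the cross-entropy gradient is fused.
.bwd_chain <- function(layers, caches, dTop, from = length(layers)) {
  grads <- vector("list", length(layers))
  dY <- dTop
  for (i in seq(from, 1L)) {
    r <- .bwd_layer(layers[[i]], dY, caches[[i]])
    grads[[i]] <- r$grads; dY <- r$dX
  }
  list(dX = dY, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(ly)
    lapply(ly$params, function(p) list(m = p * 0, v = p * 0)))
}

.adam_update <- function(layers, grads, state, lr, t, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-7) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (length(g) == 0) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mh / (sqrt(vh) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Regularization penalty of a layer list (L1/L2 on dense layers).
.reg_loss <- function(layers) {
  s <- 0
  for (ly in layers) if (ly$type == "dense" && (ly$l1 > 0 || ly$l2 > 0))
    s <- s + ly$l1 * sum(abs(ly$params$W)) + ly$l2 * sum(ly$params$W^2)
  s
}
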