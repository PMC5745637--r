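# Minimal feed-forward network engine used by the classifier: 3x3
# same-padded convolutions and 2x2 max pooling (compiled kernels), ReLU,
# dropout, dense layers, and a sigmoid (or identity) output.  Batches are
# matrices with one flattened W*H*C image per column.

glorot_matrix <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Forward pass.  When `training` is TRUE dropout masks are drawn from the
# current RNG stream and caches required by net_backward are collected.
net_forward <- function(net, X, training = FALSE) {
  caches <- if (training) vector("list", length(net$layers)) else NULL
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    switch(l$type,
      conv = {
        if (training) caches[[li]] <- list(input = X)
        X <- cpp_conv2d_fwd(X, l$W, l$H, l$Cin, l$K, l$b)
      },
      relu = {
        if (training) caches[[li]] <- list(mask = X > 0)
        X <- X * (X > 0)
      },
      pool = {
        r <- cpp_maxpool2_fwd(X, l$W, l$H, l$C)
        if (training) caches[[li]] <- list(idx = r$idx)
        X <- r$y
      },
      dropout = {
        if (training && l$rate > 0) {
          mask <- matrix(stats::runif(length(X)) >= l$rate,
                         nrow(X), ncol(X)) / (1 - l$rate)
          caches[[li]] <- list(mask = mask)
          X <- X * mask
        }
      },
      dense = {
        if (training) caches[[li]] <- list(input = X)
        X <- crossprod(l$Wt, X) + l$b
      },
      sigmoid = {
        if (training) caches[[li]] <- list(p = NULL)
        X <- stats::plogis(X)
      },
      identity = {},
      stop("unknown layer type: ", l$type))
  }
  list(out = X, caches = caches)
}

# Backward pass from the *pre-output-activation* gradient G (the training
# loop fuses sigmoid + cross-entropy, so the final activation layer is
# skipped).  Returns per-layer parameter gradients.
net_backward <- function(net, caches, G) {
  grads <- vector("list", length(net$layers))
  last <- length(net$layers)
  if (net$layers[[last]]$type %in% c("sigmoid", "identity"))
    last <- last - 1L
  for (li in rev(seq_len(last))) {
    l <- net$layers[[li]]
    switch(l$type,
      conv = {
        r <- cpp_conv2d_bwd(caches[[li]]$input, G, l$W, l$H, l$Cin, l$K,
                            need_dx = li > 1L, need_dw = TRUE)
        grads[[li]] <- list(K = r$dK, b = as.vector(r$db))
        if (li > 1L) G <- r$dX
      },
      relu = G <- G * caches[[li]]$mask,
      pool = G <- cpp_maxpool2_bwd(G, caches[[li]]$idx, l$W, l$H, l$C),
      dropout = if (!is.null(caches[[li]])) G <- G * caches[[li]]$mask,
      dense = {
        grads[[li]] <- list(Wt = caches[[li]]$input %*% t(G),
                            b = rowSums(G))
        G <- l$Wt %*% G
      })
  }
  grads
}

net_param_layers <- function(net)
  which(vapply(net$layers, function(l) l$type %in% c("conv", "dense"),
               logical(1L)))

net_param_count <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (l$type == "conv") length(l$K) + length(l$b)
    else if (l$type == "dense") length(l$Wt) + length(l$b)
    else 0L
  }, numeric(1L)))
}

# Inference forward in chunks to bound the im2col working memory.
net_predict_matrix <- function(net, X, batch_size = 512L) {
  n <- ncol(X)
  expected <- prod(net$input_shape)
  if (nrow(X) != expected)
    stop(sprintf("input shape mismatch: expected %d values per example (%s), got %d",
                 expected, paste(net$input_shape, collapse = "x"), nrow(X)),
         call. = FALSE)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    out[ix] <- as.vector(net_forward(net, X[, ix, drop = FALSE])$out)
  }
  out
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (l$type == "conv")
      list(mK = l$K * 0, vK = l$K * 0, mb = l$b * 0, vb = l$b * 0)
    else if (l$type == "dense")
      list(mW = l$Wt * 0, vW = l$Wt * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    list(p = p, m = m, v = v)
  }
  for (li in net_param_layers(net)) {
    l <- net$layers[[li]]; g <- grads[[li]]; s <- state[[li]]
    if (l$type == "conv") {
      r <- upd(l$K, g$K, s$mK, s$vK)
      l$K <- r$p; s$mK <- r$m; s$vK <- r$v
      r <- upd(l$b, g$b, s$mb, s$vb)
      l$b <- r$p; s$mb <- r$m; s$vb <- r$v
    } else {
      r <- upd(l$Wt, g$Wt, s$mW, s$vW)
      l$Wt <- r$p; s$mW <- r$m; s$vW <- r$v
      r <- upd(l$b, g$b, s$mb, s$vb)
      l$b <- r$p; s$mb <- r$m; s$vb <- r$v
    }
    net$layers[[li]] <- l; state[[li]] <- s
  }
  list(net = net, state = state)
}
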