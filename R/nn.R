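# Internal 1-D convolutional network engine.
#
# No deep-learning framework is part of this package's dependency set, and
# the convolutional architecture is the method's core, so a compact engine
# is implemented here directly: 1-D convolution (im2col as one matrix
# product), batch normalization, ReLU, global mean pooling, dense layers,
# manual reverse-mode gradients and Adam updates. Everything is driven by
# R's own RNG, so training is bit-reproducible under a fixed seed on a
# single device.
#
# Activations flow through the convolutional stage as plain matrices of
# shape [n*L, C] — sample index fastest, so matrix(x, n*L, C) of an
# array(n, L, C) is a free relayout — wrapped in a list(m, n, L) "feature
# map" container. That makes im2col a row-subset, channel concatenation a
# cbind, and avoids any aperm/array copies in the hot loop. After global
# pooling the container collapses to an ordinary [n, F] matrix. Layers are
# environments (mutable parameters + Adam state); a network is an ordered
# list of layers.

fm <- function(m, n, L) list(m = m, n = n, L = L)

fm_from_array <- function(x) {
  d <- dim(x)
  fm(matrix(x, d[1] * d[2], d[3]), d[1], d[2])
}

fm_to_array <- function(h) array(h$m, c(h$n, h$L, ncol(h$m)))

nn_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  l
}

nn_conv1d <- function(c_in, c_out, kernel = 3L, stride = 1L, lr_scale = 1) {
  sd <- sqrt(2 / (kernel * c_in))  # He initialization
  nn_layer("conv",
           W = matrix(stats::rnorm(c_in * kernel * c_out, sd = sd),
                      c_in * kernel, c_out),
           b = numeric(c_out),
           c_in = c_in, c_out = c_out, kernel = as.integer(kernel),
           stride = as.integer(stride), pad = kernel %/% 2L,
           lr_scale = lr_scale)
}

nn_bn <- function(c, momentum = 0.9, eps = 1e-5, lr_scale = 1) {
  nn_layer("bn", gamma = rep(1, c), beta = numeric(c),
           run_mean = numeric(c), run_var = rep(1, c),
           momentum = momentum, eps = eps, lr_scale = lr_scale)
}

nn_relu <- function() nn_layer("relu")
nn_pool <- function() nn_layer("pool")     # global mean pool over positions
nn_flatten <- function() nn_layer("flatten")

nn_dense <- function(f_in, f_out, lr_scale = 1) {
  sd <- sqrt(2 / f_in)
  nn_layer("dense", W = matrix(stats::rnorm(f_in * f_out, sd = sd), f_in, f_out),
           b = numeric(f_out), lr_scale = lr_scale)
}

conv_out_len <- function(L, kernel, stride) {
  (L + 2L * (kernel %/% 2L) - kernel) %/% stride + 1L
}

# Row-selection indices realizing im2col on the [n*L(+1), C] matrix with a
# trailing all-zero padding row; cached in the layer per (n, L).
.conv_indices <- function(l, n, L) {
  key <- paste0("idx_", n, "_", L)
  if (!is.null(l$.idx_key) && identical(l$.idx_key, key)) return(l$.idx)
  k <- l$kernel; s <- l$stride; p <- l$pad
  Lout <- conv_out_len(L, k, s)
  pad_row <- n * L + 1L
  idx <- vector("list", k)
  for (j in seq_len(k)) {
    lin <- (seq_len(Lout) - 1L) * s + j - p   # 1-based input positions
    block <- integer(n * Lout)
    for (t in seq_len(Lout)) {
      block[((t - 1L) * n + 1L):(t * n)] <-
        if (lin[t] >= 1L && lin[t] <= L) (n * (lin[t] - 1L) + 1L):(n * lin[t])
        else pad_row
    }
    idx[[j]] <- block
  }
  l$.idx <- list(blocks = idx, Lout = Lout, pad_row = pad_row)
  l$.idx_key <- key
  l$.idx
}

add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

layer_forward <- function(l, h, train = FALSE) {
  switch(l$type,
    conv = {
      n <- h$n; L <- h$L; C <- ncol(h$m)
      ii <- .conv_indices(l, n, L)
      k <- l$kernel
      m1 <- rbind(h$m, 0)
      M <- matrix(0, n * ii$Lout, C * k)
      for (j in seq_len(k)) {
        M[, ((j - 1L) * C + 1L):(j * C)] <- m1[ii$blocks[[j]], , drop = FALSE]
      }
      l$cache <- list(M = M, n = n, L = L, C = C, Lout = ii$Lout)
      fm(add_bias(M %*% l$W, l$b), n, ii$Lout)
    },
    bn = {
      xm <- h$m
      nr <- nrow(xm)
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
        l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
      } else {
        mu <- l$run_mean; v <- l$run_var
      }
      ivar <- 1 / sqrt(v + l$eps)
      xhat <- (xm - rep(mu, each = nr)) * rep(ivar, each = nr)
      ym <- xhat * rep(l$gamma, each = nr) + rep(l$beta, each = nr)
      l$cache <- list(xhat = xhat, ivar = ivar, train = train)
      fm(ym, h$n, h$L)
    },
    relu = {
      if (is.list(h)) {
        mask <- h$m > 0
        l$cache <- mask
        fm(h$m * mask, h$n, h$L)
      } else {
        mask <- h > 0
        l$cache <- mask
        h * mask
      }
    },
    pool = {
      n <- h$n; L <- h$L
      l$cache <- c(n, L)
      rowsum(h$m, group = rep_len(seq_len(n), n * L), reorder = TRUE) / L
    },
    flatten = {
      l$cache <- c(h$n, h$L, ncol(h$m))
      matrix(as.vector(h$m), h$n, h$L * ncol(h$m))
    },
    dense = {
      l$cache <- h
      add_bias(h %*% l$W, l$b)
    },
    stop("unknown layer type ", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      cc <- l$cache
      n <- cc$n; L <- cc$L; C <- cc$C
      dY <- dy$m
      l$dW <- crossprod(cc$M, dY)
      l$db <- colSums(dY)
      dM <- tcrossprod(dY, l$W)
      ii <- .conv_indices(l, n, L)
      dxm <- matrix(0, n * L + 1L, C)
      for (j in seq_len(l$kernel)) {
        rows <- ii$blocks[[j]]
        ok <- rows != ii$pad_row
        tgt <- rows[ok]
        dxm[tgt, ] <- dxm[tgt, , drop = FALSE] +
          dM[ok, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
      }
      fm(dxm[-(n * L + 1L), , drop = FALSE], n, L)
    },
    bn = {
      cc <- l$cache
      dym <- dy$m
      m <- nrow(dym)
      dxhat <- dym * rep(l$gamma, each = m)
      l$dgamma <- colSums(dym * cc$xhat)
      l$dbeta <- colSums(dym)
      if (cc$train) {
        t1 <- dxhat - rep(colSums(dxhat) / m, each = m)
        t2 <- cc$xhat * rep(colSums(dxhat * cc$xhat) / m, each = m)
        dxm <- (t1 - t2) * rep(cc$ivar, each = m)
      } else {
        dxm <- dxhat * rep(cc$ivar, each = m)
      }
      fm(dxm, dy$n, dy$L)
    },
    relu = if (is.list(dy)) fm(dy$m * l$cache, dy$n, dy$L) else dy * l$cache,
    pool = {
      n <- l$cache[1]; L <- l$cache[2]
      fm(dy[rep_len(seq_len(n), n * L), , drop = FALSE] / L, n, L)
    },
    flatten = {
      d <- l$cache
      fm(matrix(as.vector(dy), d[1] * d[2], d[3]), d[1], d[2])
    },
    dense = {
      l$dW <- crossprod(l$cache, dy)
      l$db <- colSums(dy)
      tcrossprod(dy, l$W)
    },
    stop("unknown layer type ", l$type))
}

# x may be an array c(n, L, C), a feature-map container, or (after the
# pooling/flatten stage) a plain matrix
net_forward <- function(layers, x, train = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) x <- fm_from_array(x)
  for (l in layers) x <- layer_forward(l, x, train)
  x
}

net_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

# ---- optimizer -------------------------------------------------------------

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (l in layers) {
    pnames <- switch(l$type, conv = , dense = c("W", "b"),
                     bn = c("gamma", "beta"), NULL)
    if (is.null(pnames)) next
    if (isTRUE(l$frozen)) next
    for (p in pnames) {
      g <- get(paste0("d", p), envir = l)
      mslot <- paste0(".m_", p); vslot <- paste0(".v_", p)
      if (!exists(mslot, envir = l, inherits = FALSE)) {
        assign(mslot, g * 0, envir = l)
        assign(vslot, g * 0, envir = l)
      }
      m <- beta1 * get(mslot, envir = l) + (1 - beta1) * g
      v <- beta2 * get(vslot, envir = l) + (1 - beta2) * g^2
      assign(mslot, m, envir = l)
      assign(vslot, v, envir = l)
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      val <- get(p, envir = l)
      upd <- lr * l$lr_scale * (mhat / (sqrt(vhat) + eps) +
                                  if (p == "W") weight_decay * val else 0)
      assign(p, val - upd, envir = l)
    }
  }
}

# ---- losses ----------------------------------------------------------------

# logits [n, K], y integer class in 0..K-1; returns loss and dlogits
softmax_ce <- function(logits, y) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  d <- probs
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / n, probs = probs)
}

mse_loss <- function(pred, y) {
  n <- length(y)
  r <- as.numeric(pred) - y
  list(loss = mean(r^2), dpred = matrix(2 * r / n, n, 1L))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# ---- parameter plumbing ----------------------------------------------------

layer_state <- function(l) {
  out <- list(type = l$type)
  for (p in c("W", "b", "gamma", "beta", "run_mean", "run_var", "c_in",
              "c_out", "kernel", "stride", "pad", "momentum", "eps",
              "lr_scale", "frozen")) {
    if (exists(p, envir = l, inherits = FALSE)) out[[p]] <- get(p, envir = l)
  }
  out
}

layer_from_state <- function(st) {
  l <- new.env(parent = emptyenv())
  for (nm in names(st)) assign(nm, st[[nm]], envir = l)
  l
}

net_state <- function(layers) lapply(layers, layer_state)
net_from_state <- function(states) lapply(states, layer_from_state)

# deep copy of a layer list; optimizer state is dropped so a clone starts
# training fresh from the copied parameters
clone_net <- function(layers) net_from_state(net_state(layers))

freeze_net <- function(layers) {
  for (l in layers) l$frozen <- TRUE
  invisible(layers)
}

set_lr_scale <- function(layers, scale) {
  for (l in layers) {
    if (exists("lr_scale", envir = l, inherits = FALSE)) l$lr_scale <- scale
  }
  invisible(layers)
}

# channel-wise concatenation of two feature maps (or plain matrices)
merge_channels <- function(a, b) {
  if (is.list(a)) {
    stopifnot(a$n == b$n, a$L == b$L)
    fm(cbind(a$m, b$m), a$n, a$L)
  } else cbind(a, b)
}

split_channels <- function(d, c1) {
  if (is.list(d)) {
    list(fm(d$m[, seq_len(c1), drop = FALSE], d$n, d$L),
         fm(d$m[, -seq_len(c1), drop = FALSE], d$n, d$L))
  } else {
    list(d[, seq_len(c1), drop = FALSE], d[, -seq_len(c1), drop = FALSE])
  }
}
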