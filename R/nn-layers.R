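# Low-level neural-network primitives: N-d convolution via im2col with
# BLAS-backed matrix products, batch normalization, ReLU, global average
# pooling, dense layers, and Adam. Tensor layout is column-major
# (spatial..., channel, batch); weights are plain numeric matrices/vectors so
# the whole parameter tree serializes as an R list.

.plan_cache <- new.env(parent = emptyenv())

# Index plan against the *unpadded* input; zero-padded positions carry the
# sentinel index 0, which the C++ gather reads as 0.0 and the scatter skips.

#' @noRd
conv_plan <- function(spatial, channels, k, stride, pad) {
  key <- paste(c(spatial, channels, k, stride, pad), collapse = "_")
  cached <- .plan_cache[[key]]
  if (!is.null(cached)) return(cached)

  nd <- length(spatial)
  out <- (spatial + 2L * pad - k) %/% stride + 1L
  if (any(out < 1L)) {
    stop("convolution output would be empty for input ", paste(spatial, collapse = "x"))
  }

  # channel-first layout (C, spatial...): channel stride 1
  dimstride <- channels * cumprod(c(1L, spatial))[seq_len(nd)]
  chanstride <- 1L

  offs <- do.call(expand.grid, c(list(0:(channels - 1L)), rep(list(0:(k - 1L)), nd)))
  pos <- do.call(expand.grid, lapply(out, function(n) seq(0L, by = stride, length.out = n)))

  krows <- as.integer(k^nd * channels)
  npos <- as.integer(prod(out))
  idx <- matrix(1L, krows, npos)
  valid <- matrix(TRUE, krows, npos)
  lin <- matrix(0, krows, npos)
  for (i in seq_len(nd)) {
    coord <- outer(offs[[i + 1L]], pos[[i]], `+`) - pad
    valid <- valid & coord >= 0L & coord < spatial[i]
    lin <- lin + coord * dimstride[i]
  }
  lin <- lin + offs[[1L]] * chanstride + 1
  idx[] <- as.integer(lin)
  idx[!valid] <- 0L

  plan <- list(
    spatial = spatial, out = out, channels = channels,
    k = k, stride = stride, pad = pad,
    krows = krows, npos = npos,
    idxvec = as.integer(idx),
    voxels = as.integer(prod(spatial) * channels)
  )
  .plan_cache[[key]] <- plan
  plan
}

#' @noRd
conv_init <- function(c_in, c_out, k, nd, stride = 1L, pad = (k - 1L) %/% 2L) {
  fan_in <- k^nd * c_in
  list(
    W = matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)), c_out, fan_in),
    b = numeric(c_out),
    c_in = c_in, c_out = c_out, k = as.integer(k), nd = as.integer(nd),
    stride = as.integer(stride), pad = as.integer(pad)
  )
}

#' @noRd
conv_forward <- function(layer, x) {
  d <- dim(x)
  nd <- layer$nd
  spatial <- d[1L + seq_len(nd)]
  B <- d[nd + 2L]
  plan <- conv_plan(spatial, layer$c_in, layer$k, layer$stride, layer$pad)
  y <- cpp_conv_forward(x, plan$idxvec, layer$W, plan$voxels, B,
                        plan$krows, plan$npos)
  y <- y + layer$b
  dim(y) <- c(layer$c_out, plan$out, B)
  list(out = y, cache = list(x = x, plan = plan, B = B))
}

#' @noRd
conv_backward <- function(layer, dout, cache, need_dx = TRUE) {
  plan <- cache$plan
  B <- cache$B
  dy <- dout
  dim(dy) <- c(layer$c_out, plan$npos * B)
  res <- cpp_conv_backward(cache$x, dy, plan$idxvec, layer$W, plan$voxels, B,
                           plan$krows, plan$npos, need_dx)
  grads <- list(W = res$dW, b = rowSums(dy))
  dx <- NULL
  if (need_dx) {
    dx <- res$dx
    dim(dx) <- c(plan$channels, plan$spatial, B)
  }
  list(dx = dx, grads = grads)
}

#' @noRd
bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels),
       momentum = 0.9, eps = 1e-5, channels = channels)
}

#' @noRd
bn_forward <- function(layer, x, training = TRUE) {
  d <- dim(x)   # (C, spatial..., B)
  xm <- x
  dim(xm) <- c(layer$channels, length(x) / layer$channels)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- xm - mu
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * invstd
  y <- xhat * layer$gamma + layer$beta
  dim(y) <- d
  list(out = y, layer = layer,
       cache = list(xhat = xhat, invstd = invstd, d = d))
}

#' @noRd
bn_backward <- function(layer, dout, cache) {
  dym <- dout
  dim(dym) <- dim(cache$xhat)
  xhat <- cache$xhat
  m <- ncol(dym)
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * layer$gamma
  dxm <- (dxhat - rowMeans(dxhat) - xhat * (rowSums(dxhat * xhat) / m)) *
    cache$invstd
  dim(dxm) <- cache$d
  list(dx = dxm, grads = list(gamma = dgamma, beta = dbeta))
}

#' @noRd
relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

#' @noRd
relu_backward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

#' @noRd
gap_forward <- function(x) {
  d <- dim(x)   # (C, spatial..., B)
  C <- d[1]
  B <- d[length(d)]
  nspat <- prod(d) / (C * B)
  xm <- x
  dim(xm) <- c(C * nspat, B)
  out <- rowsum(xm, rep(seq_len(C), nspat), reorder = TRUE) / nspat
  dimnames(out) <- NULL
  list(out = out, cache = list(d = d, nspat = nspat, C = C, B = B))
}

#' @noRd
gap_backward <- function(dout, cache) {
  dx <- dout[rep(seq_len(cache$C), cache$nspat), , drop = FALSE] / cache$nspat
  dim(dx) <- cache$d
  dx
}

#' @noRd
dense_init <- function(d_in, d_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (d_in + d_out))
  list(W = matrix(stats::rnorm(d_out * d_in, sd = scale), d_out, d_in),
       b = numeric(d_out))
}

#' @noRd
dense_forward <- function(layer, x) {
  list(out = layer$W %*% x + layer$b, cache = x)
}

#' @noRd
dense_backward <- function(layer, dout, x, need_dx = TRUE) {
  list(dx = if (need_dx) crossprod(layer$W, dout) else NULL,
       grads = list(W = dout %*% t(x), b = rowSums(dout)))
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# ---- Adam over a nested parameter tree --------------------------------------
# Layer lists mix metadata (c_in, stride, running stats, ...) with trainable
# arrays; only leaves named in .trainable_names are touched.

.trainable_names <- c("W", "b", "gamma", "beta", "emb", "phase", "rH", "rT",
                      "re", "im")

#' @noRd
is_param_leaf <- function(name, value) {
  !is.null(name) && name %in% .trainable_names && is.numeric(value)
}

#' @noRd
adam_init <- function(params) {
  walk <- function(p, nm) {
    if (is_param_leaf(nm, p)) return(list(m = p * 0, v = p * 0))
    if (is.list(p)) {
      nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
      return(lapply(seq_along(p), function(i) walk(p[[i]], nms[i])) |>
               stats::setNames(names(p)))
    }
    NULL
  }
  list(m = walk(params, ""), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, s, nm) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is_param_leaf(nm, p)) {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      p <- p - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      # decoupled weight decay on weight matrices only
      if (weight_decay > 0 && nm == "W") p <- p - lr * weight_decay * p
      return(list(p = p, s = s))
    }
    if (is.list(p)) {
      nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
      for (i in seq_along(p)) {
        gi <- if (nms[i] != "") g[[nms[i]]] else if (i <= length(g)) g[[i]] else NULL
        if (is.null(gi)) next
        si <- if (nms[i] != "") s[[nms[i]]] else s[[i]]
        r <- upd(p[[i]], gi, si, nms[i])
        p[[i]] <- r$p
        if (nms[i] != "") s[[nms[i]]] <- r$s else s[[i]] <- r$s
      }
    }
    list(p = p, s = s)
  }
  res <- upd(params, grads, state$m, "")
  list(params = res$p, state = list(m = res$s, t = state$t))
}

#' @noRd
zero_like <- function(params) {
  walk <- function(p, nm) {
    if (is_param_leaf(nm, p)) return(p * 0)
    if (is.list(p)) {
      nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
      return(lapply(seq_along(p), function(i) walk(p[[i]], nms[i])) |>
               stats::setNames(names(p)))
    }
    NULL
  }
  walk(params, "")
}

#' @noRd
accum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  if (is.null(names(b))) {
    for (i in seq_along(b)) a[[i]] <- accum_grads(a[[i]], b[[i]])
  } else {
    for (nm in names(b)) a[[nm]] <- accum_grads(a[[nm]], b[[nm]])
  }
  a
}
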