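# The dual-branch encoder: cascaded 3D residual blocks on the volume, the
# mirrored 2D residual stack on its z-projection, adaptive-gating fusion to a
# fused feature vector, the multi-label classification head over concatenated
# image + knowledge features, and the protein-ID head.

#' Encoder configuration
#'
#' @param n_classes,n_proteins Output sizes (C classes, N proteins).
#' @param n_blocks Residual blocks per branch (default 6, the
#'   full-resolution setting; inputs must satisfy every spatial dim >=
#'   2^n_blocks, so small volumes need fewer blocks).
#' @param base_channels First-block channel count; channels double per block,
#'   capped at 8x base.
#' @param channel_schedule Optional explicit per-block channel counts.
#' @param fused_dim Dimension of the fused image feature (default 768).
#' @param knowledge_dim Dimension the protein knowledge feature is adapted
#'   to before concatenation with the fused feature.
#' @param knowledge_input_dim Dimension of the incoming knowledge feature
#'   (the KGE entity dimension).
#' @param input_encoding `"raw"` (default) feeds the two recorded channels.
#'   `"nucleus_gated"` adds a third channel, protein x nucleus, grounding
#'   the protein signal relative to the nuclear reference.
#' @return A list of class `subloc3d_encoder_config`.
#' @export
encoder_config <- function(n_classes, n_proteins, n_blocks = 6L,
                           base_channels = 8L, channel_schedule = NULL,
                           fused_dim = 768L, knowledge_dim = 32L,
                           knowledge_input_dim = 32L,
                           input_encoding = c("raw", "nucleus_gated")) {
  stopifnot(n_blocks >= 1, base_channels >= 1, fused_dim > 0,
            n_classes >= 1, n_proteins >= 1)
  if (is.null(channel_schedule)) {
    channel_schedule <- pmin(base_channels * 2^(seq_len(n_blocks) - 1L),
                             8L * base_channels)
  }
  stopifnot(length(channel_schedule) == n_blocks)
  input_encoding <- match.arg(input_encoding)
  structure(
    list(input_encoding = input_encoding,
         n_blocks = as.integer(n_blocks),
         base_channels = as.integer(base_channels),
         channel_schedule = as.integer(channel_schedule),
         fused_dim = as.integer(fused_dim),
         knowledge_dim = as.integer(knowledge_dim),
         knowledge_input_dim = as.integer(knowledge_input_dim),
         n_classes = as.integer(n_classes),
         n_proteins = as.integer(n_proteins)),
    class = "subloc3d_encoder_config"
  )
}

#' @noRd
res_block_init <- function(c_in, c_out, nd) {
  list(conv1 = conv_init(c_in, c_out, 3L, nd, stride = 2L, pad = 1L),
       bn1 = bn_init(c_out),
       conv2 = conv_init(c_out, c_out, 3L, nd, stride = 1L, pad = 1L),
       bn2 = bn_init(c_out),
       skip = conv_init(c_in, c_out, 1L, nd, stride = 2L, pad = 0L))
}

#' Build an encoder network
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `subloc3d_net` holding all parameters.
#' @export
build_network <- function(config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ch <- config$channel_schedule
  c_in3 <- if (identical(config$input_encoding, "nucleus_gated")) 3L else 2L
  blocks3 <- list(); blocks2 <- list()
  prev <- c_in3
  for (i in seq_len(config$n_blocks)) {
    blocks3[[i]] <- res_block_init(prev, ch[i], nd = 3L)
    prev <- ch[i]
  }
  prev <- c_in3
  for (i in seq_len(config$n_blocks)) {
    blocks2[[i]] <- res_block_init(prev, ch[i], nd = 2L)
    prev <- ch[i]
  }
  fdim <- ch[config$n_blocks]
  net <- list(
    blocks3 = blocks3, blocks2 = blocks2,
    gate = dense_init(2L * fdim, fdim),
    fuse = dense_init(fdim, config$fused_dim),
    kadapt = dense_init(config$knowledge_input_dim, config$knowledge_dim),
    cls = dense_init(config$fused_dim + config$knowledge_dim,
                     config$n_classes),
    idh = dense_init(config$fused_dim, config$n_proteins),
    config = config
  )
  class(net) <- "subloc3d_net"
  net
}

#' Number of trainable parameters
#' @param net A `subloc3d_net`.
#' @return Integer count.
#' @export
count_parameters <- function(net) {
  n <- 0L
  walk <- function(p, nm) {
    if (is_param_leaf(nm, p)) n <<- n + length(p)
    else if (is.list(p)) {
      nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
      for (i in seq_along(p)) walk(p[[i]], nms[i])
    }
  }
  walk(net[c("blocks3", "blocks2", "gate", "fuse", "kadapt", "cls", "idh")], "")
  n
}

#' @noRd
res_block_forward <- function(bp, x, training) {
  c1 <- conv_forward(bp$conv1, x)
  n1 <- bn_forward(bp$bn1, c1$out, training)
  r1 <- relu_forward(n1$out)
  c2 <- conv_forward(bp$conv2, r1$out)
  n2 <- bn_forward(bp$bn2, c2$out, training)
  sk <- conv_forward(bp$skip, x)
  r2 <- relu_forward(n2$out + sk$out)
  list(out = r2$out,
       bp = list(bn1 = n1$layer, bn2 = n2$layer),   # updated running stats
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                    c2 = c2$cache, n2 = n2$cache, sk = sk$cache,
                    r2 = r2$cache))
}

#' @noRd
res_block_backward <- function(bp, dout, cache, need_dx = TRUE) {
  dsum <- relu_backward(dout, cache$r2)
  bsk <- conv_backward(bp$skip, dsum, cache$sk, need_dx)
  bn2 <- bn_backward(bp$bn2, dsum, cache$n2)
  bc2 <- conv_backward(bp$conv2, bn2$dx, cache$c2)
  dr1 <- relu_backward(bc2$dx, cache$r1)
  bn1 <- bn_backward(bp$bn1, dr1, cache$n1)
  bc1 <- conv_backward(bp$conv1, bn1$dx, cache$c1, need_dx)
  dx <- if (need_dx) bc1$dx + bsk$dx else NULL
  list(dx = dx,
       grads = list(conv1 = bc1$grads, bn1 = bn1$grads, conv2 = bc2$grads,
                    bn2 = bn2$grads, skip = bsk$grads))
}

# Max z-projection of a batch array (c, z, y, x, B) -> (c, y, x, B).
#' @noRd
project_z_batch <- function(x) {
  d <- dim(x)
  out <- array(-Inf, d[-2])
  for (z in seq_len(d[2])) {
    sl <- x[, z, , , , drop = FALSE]
    dim(sl) <- d[-2]
    out <- pmax(out, sl)
  }
  out
}

#' @noRd
check_spatial <- function(spatial, n_blocks) {
  if (any(spatial < 2^n_blocks)) {
    stop("input spatial size (", paste(spatial, collapse = "x"),
         ") too small for ", n_blocks,
         " downsampling blocks; use fewer blocks (n_blocks <= ",
         floor(log2(min(spatial))), ")")
  }
}

# Full forward pass on a batch. x: (z, y, x, 2, B); kraw: knowledge features
# (knowledge_input_dim x B), zeros when absent. Returns heads and a cache for
# the backward pass; `net` is returned with updated batch-norm running stats.
#' @noRd
forward_network <- function(net, x, kraw = NULL, training = FALSE) {
  cfg <- net$config
  d <- dim(x)   # (channels, z, y, x, B)
  B <- d[5]
  if (d[1] != net$blocks3[[1]]$conv1$c_in) {
    stop("input has ", d[1], " channels but the network expects ",
         net$blocks3[[1]]$conv1$c_in, " (input_encoding = '",
         cfg$input_encoding, "')")
  }
  check_spatial(d[2:4], cfg$n_blocks)
  if (is.null(kraw)) kraw <- matrix(0, cfg$knowledge_input_dim, B)

  caches3 <- list(); h <- x
  for (i in seq_along(net$blocks3)) {
    r <- res_block_forward(net$blocks3[[i]], h, training)
    net$blocks3[[i]]$bn1 <- r$bp$bn1
    net$blocks3[[i]]$bn2 <- r$bp$bn2
    caches3[[i]] <- r$cache
    h <- r$out
  }
  g3 <- gap_forward(h)
  f3d <- g3$out

  x2 <- project_z_batch(x)
  caches2 <- list(); h2 <- x2
  for (i in seq_along(net$blocks2)) {
    r <- res_block_forward(net$blocks2[[i]], h2, training)
    net$blocks2[[i]]$bn1 <- r$bp$bn1
    net$blocks2[[i]]$bn2 <- r$bp$bn2
    caches2[[i]] <- r$cache
    h2 <- r$out
  }
  g2 <- gap_forward(h2)
  f2d <- g2$out

  zcat <- rbind(f3d, f2d)
  zlin <- net$gate$W %*% zcat + net$gate$b
  g <- sigmoid(zlin)
  pre <- g * f3d + (1 - g) * f2d
  fused <- net$fuse$W %*% pre + net$fuse$b

  ka <- net$kadapt$W %*% kraw + net$kadapt$b
  cls_in <- rbind(fused, ka)
  logits_c <- net$cls$W %*% cls_in + net$cls$b
  class_probs <- sigmoid(logits_c)
  logits_id <- net$idh$W %*% fused + net$idh$b
  id_probs <- softmax_cols(logits_id)

  list(net = net, f3d = f3d, f2d = f2d, fused = fused,
       class_probs = class_probs, id_probs = id_probs,
       cache = list(caches3 = caches3, caches2 = caches2, g3 = g3$cache,
                    g2 = g2$cache, f3d = f3d, f2d = f2d, g = g, zcat = zcat,
                    pre = pre, fused = fused, kraw = kraw, ka = ka,
                    cls_in = cls_in, class_probs = class_probs,
                    id_probs = id_probs, B = B))
}

# Backward pass from head-logit gradients (and an optional extra gradient on
# the fused feature coming from the knowledge-embedding loss).
#' @noRd
backward_network <- function(net, cache, dlogits_c = NULL, dlogits_id = NULL,
                             dfused_extra = NULL) {
  cfg <- net$config
  fdim_b <- nrow(cache$f3d)
  grads <- list()
  dfused <- matrix(0, cfg$fused_dim, cache$B)

  if (!is.null(dlogits_c)) {
    bc <- dense_backward(net$cls, dlogits_c, cache$cls_in)
    grads$cls <- bc$grads
    dfused <- dfused + bc$dx[seq_len(cfg$fused_dim), , drop = FALSE]
    dka <- bc$dx[cfg$fused_dim + seq_len(cfg$knowledge_dim), , drop = FALSE]
    bk <- dense_backward(net$kadapt, dka, cache$kraw, need_dx = FALSE)
    grads$kadapt <- bk$grads
  }
  if (!is.null(dlogits_id)) {
    bi <- dense_backward(net$idh, dlogits_id, cache$fused)
    grads$idh <- bi$grads
    dfused <- dfused + bi$dx
  }
  if (!is.null(dfused_extra)) dfused <- dfused + dfused_extra

  bf <- dense_backward(net$fuse, dfused, cache$pre)
  grads$fuse <- bf$grads
  dpre <- bf$dx
  g <- cache$g
  dzlin <- dpre * (cache$f3d - cache$f2d) * g * (1 - g)
  bg <- dense_backward(net$gate, dzlin, cache$zcat)
  grads$gate <- bg$grads
  df3d <- dpre * g + bg$dx[seq_len(fdim_b), , drop = FALSE]
  df2d <- dpre * (1 - g) + bg$dx[fdim_b + seq_len(fdim_b), , drop = FALSE]

  dh3 <- gap_backward(df3d, cache$g3)
  grads$blocks3 <- vector("list", cfg$n_blocks)
  for (i in rev(seq_len(cfg$n_blocks))) {
    r <- res_block_backward(net$blocks3[[i]], dh3, cache$caches3[[i]],
                            need_dx = i > 1L)
    grads$blocks3[[i]] <- r$grads
    dh3 <- r$dx
  }
  dh2 <- gap_backward(df2d, cache$g2)
  grads$blocks2 <- vector("list", cfg$n_blocks)
  for (i in rev(seq_len(cfg$n_blocks))) {
    r <- res_block_backward(net$blocks2[[i]], dh2, cache$caches2[[i]],
                            need_dx = i > 1L)
    grads$blocks2[[i]] <- r$grads
    dh2 <- r$dx
  }
  grads
}

# ---- user-facing single-sample operations -----------------------------------

#' @noRd
batch_from_samples <- function(samples, normalize = TRUE,
                               encoding = "raw") {
  v1 <- samples[[1]]$volume
  d <- dim(v1)   # (2, z, y, x)
  gated <- identical(encoding, "nucleus_gated")
  x <- array(0, c(if (gated) 3L else 2L, d[2:4], length(samples)))
  for (i in seq_along(samples)) {
    v <- samples[[i]]$volume
    if (normalize) v <- normalize_minmax(v)
    x[1:2, , , , i] <- v
    if (gated) x[3, , , , i] <- v[1, , , ] * v[2, , , ]
  }
  x
}

#' Encode a single cell
#'
#' Runs the per-cell min-max normalized volume through both branches and the
#' fusion/heads in inference mode (batch-norm running statistics).
#'
#' @param net A `subloc3d_net`.
#' @param sample A [volume_sample()] with an in-memory volume, or a
#'   `(2, z, y, x)` array.
#' @param knowledge Optional knowledge feature vector
#'   (`knowledge_input_dim`); zeros when absent.
#' @return List with `f3d`, `f2d`, `fused`, `class_probs` (named by nothing;
#'   independent per-class probabilities) and `id_probs` (simplex over
#'   proteins).
#' @export
encode <- function(net, sample, knowledge = NULL) {
  vol <- if (inherits(sample, "subloc3d_sample")) sample$volume else sample
  if (is.null(vol)) stop("sample has no in-memory volume")
  s <- list(volume = vol)
  x <- batch_from_samples(list(s), encoding = net$config$input_encoding)
  kraw <- if (is.null(knowledge)) NULL else matrix(knowledge, ncol = 1)
  out <- forward_network(net, x, kraw, training = FALSE)
  list(f3d = drop(out$f3d), f2d = drop(out$f2d), fused = drop(out$fused),
       class_probs = drop(out$class_probs), id_probs = drop(out$id_probs))
}

#' Adaptive-gating fusion of two branch features
#'
#' `g = sigmoid(W_g [f3d; f2d] + b_g)` elementwise; the pre-fusion feature is
#' `g * f3d + (1-g) * f2d`, then a fully connected layer gives the
#' `fused_dim` output.
#'
#' @param net A `subloc3d_net`.
#' @param f3d,f2d Branch feature vectors of equal length.
#' @return List with `gate`, `pre` and `fused`.
#' @export
fuse_gated <- function(net, f3d, f2d) {
  if (length(f3d) != length(f2d)) stop("branch feature dimensions differ")
  zcat <- matrix(c(f3d, f2d), ncol = 1)
  g <- drop(sigmoid(net$gate$W %*% zcat + net$gate$b))
  pre <- g * f3d + (1 - g) * f2d
  fused <- drop(net$fuse$W %*% pre + net$fuse$b)
  list(gate = g, pre = pre, fused = fused)
}

#' Multi-label classification head
#'
#' Concatenates the fused image feature with the adapted knowledge feature
#' and applies the sigmoid output layer (independent per-class
#' probabilities). A missing knowledge feature is replaced by zeros.
#'
#' @param net A `subloc3d_net`.
#' @param fused Fused feature vector.
#' @param knowledge Optional raw knowledge feature (`knowledge_input_dim`).
#' @return Numeric vector of C probabilities in `[0,1]`.
#' @export
classify <- function(net, fused, knowledge = NULL) {
  cfg <- net$config
  if (is.null(knowledge)) knowledge <- numeric(cfg$knowledge_input_dim)
  ka <- drop(net$kadapt$W %*% knowledge + net$kadapt$b)
  drop(sigmoid(net$cls$W %*% c(fused, ka) + net$cls$b))
}

#' Protein-ID head
#' @param net A `subloc3d_net`.
#' @param fused Fused feature vector.
#' @return Softmax probabilities over the N training proteins (sums to 1).
#' @export
protein_id_head <- function(net, fused) {
  drop(softmax_cols(matrix(net$idh$W %*% fused + net$idh$b, ncol = 1)))
}

# ---- checkpoints -------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the network weights, encoder and loss
#' configuration, class vocabulary, protein index and (if present) the KGE
#' model, with a format version tag.
#'
#' @param fit A `subloc3d_fit` (from [train()]) or a compatible list.
#' @param path Destination file.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(format = "subloc3d-checkpoint-1",
              net = fit$net, encoder_config = fit$net$config,
              loss_config = fit$loss_config,
              class_vocabulary = fit$class_vocabulary,
              protein_index = fit$protein_index,
              kge = fit$kge)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return [load_checkpoint()] returns a `subloc3d_fit`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "subloc3d-checkpoint-1")) {
    stop("not a subloc3d checkpoint: ", path)
  }
  structure(list(net = obj$net, loss_config = obj$loss_config,
                 class_vocabulary = obj$class_vocabulary,
                 protein_index = obj$protein_index, kge = obj$kge,
                 history = NULL),
            class = "subloc3d_fit")
}
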