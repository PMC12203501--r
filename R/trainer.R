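# Joint optimization of the encoder, heads, and knowledge-graph embedding
# under the weighted three-part loss, and prediction for new cells.
#
# During training the protein entity of each sampled triple is represented by
# the current cell's adapted fused feature, so knowledge-embedding gradients
# reach the image encoder. At prediction time the protein knowledge feature
# is recovered from the protein's triples by head inversion (average pooled),
# which also works for proteins never seen in training.

#' Training configuration
#'
#' @param epochs Number of epochs (default 10).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param lr_schedule `"constant"` or `"cosine"` (cosine decay of `lr` to
#'   zero over the epochs).
#' @param seed Integer seed controlling shuffling, initialization and
#'   negative sampling.
#' @param triples_per_cell Protein-GO triples sampled per cell per step
#'   (k; 0 disables the knowledge-embedding loss).
#' @param kge_method Scoring function for the knowledge module.
#' @param entity_dim KGE entity dimension.
#' @param gamma,n_negatives Contrastive-loss margin and negatives per
#'   positive.
#' @param augment Random y/x flips of each training batch (off by default:
#'   on the synthetic benchmark flips did not improve held-out accuracy).
#' @param mixup Probability that a training batch is mixed with a shuffled
#'   copy of itself (volumes blended, labels united). Multi-label mixup
#'   teaches the classifier that patterns compose additively, instead of
#'   memorizing which label combinations co-occur in the few training
#'   proteins; the ID and knowledge losses are skipped on mixed batches
#'   because a blended cell has no single protein identity.
#' @param validate Compute validation macro-MCC each epoch and keep the
#'   best checkpoint?
#' @param log_path Optional CSV path for the per-epoch training log.
#' @param verbose Print per-epoch progress?
#' @return A list of class `subloc3d_train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L, lr = 1e-3,
                         lr_schedule = c("constant", "cosine"),
                         weight_decay = 0, seed = 1L, triples_per_cell = 4L,
                         kge_method = "pairre", entity_dim = 32L,
                         gamma = 6, n_negatives = 8L, augment = FALSE,
                         mixup = 0, validate = TRUE, log_path = NULL,
                         verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, triples_per_cell >= 0)
  lr_schedule <- match.arg(lr_schedule)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, lr_schedule = lr_schedule, weight_decay = weight_decay,
         seed = as.integer(seed),
         triples_per_cell = as.integer(triples_per_cell),
         kge_method = kge_method, entity_dim = as.integer(entity_dim),
         gamma = gamma, n_negatives = as.integer(n_negatives),
         augment = augment, mixup = mixup, validate = validate,
         log_path = log_path, verbose = verbose),
    class = "subloc3d_train_config"
  )
}

#' @noRd
knowledge_feature_matrix <- function(kge, proteins, graph) {
  kf <- matrix(0, kge$entity_dim, length(proteins),
               dimnames = list(NULL, proteins))
  present <- logical(length(proteins))
  for (i in seq_along(proteins)) {
    r <- knowledge_feature(kge, proteins[i], graph)
    kf[, i] <- r$feature
    present[i] <- r$present
  }
  attr(kf, "present") <- stats::setNames(present, proteins)
  kf
}

#' Train a localization model
#'
#' Optimizes the dual-branch encoder and heads with the asymmetric
#' confidence-weighted classification loss; when a knowledge graph is given,
#' jointly trains the knowledge-graph embedding through the contrastive loss
#' with category-aware negatives (the protein entity being the adapted fused
#' feature of the current cell), and adds the protein-ID aggregation loss on
#' cells whose labels intersect the low-variability class set.
#'
#' @param table A `subloc3d_table` with splits assigned and in-memory
#'   volumes.
#' @param graph A filtered [knowledge_graph()] or `NULL` for the image-only
#'   model.
#' @param config An [encoder_config()]; `NULL` builds a desk-scale default
#'   (3 blocks) from the table.
#' @param loss A [loss_config()].
#' @param control A [train_config()].
#' @return A `subloc3d_fit`: best network (by validation macro-MCC when
#'   validation cells exist), KGE model, per-epoch `history` tibble, and the
#'   configurations.
#' @export
train <- function(table, graph = NULL, config = NULL,
                  loss = loss_config(), control = train_config()) {
  splits <- vapply(table$samples, `[[`, character(1), "split")
  if (!any(splits == "train")) {
    stop("no training cells; assign splits first (split_by_protein + apply_split)")
  }
  C <- length(table$class_vocabulary)
  proteins <- names(table$protein_index)
  N <- length(proteins)
  if (is.null(config)) {
    config <- encoder_config(n_classes = C, n_proteins = N, n_blocks = 3L,
                             knowledge_input_dim = control$entity_dim)
  }
  stopifnot(config$n_classes == C, config$n_proteins == N)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(control$seed)

  net <- build_network(config, seed = control$seed)
  use_kg <- !is.null(graph) && control$triples_per_cell > 0L &&
    loss$weights["w_ke"] > 0
  kge <- NULL
  ptriples <- NULL
  # with the knowledge loss disabled the model is the exact image-only
  # ablation: no KGE parameters, no knowledge features into the classifier
  if (use_kg) {
    kge <- kge_model(control$kge_method, entity_dim = control$entity_dim,
                     relations = graph$relations, gamma = control$gamma,
                     n_negatives = control$n_negatives, seed = control$seed)
    kge <- embed_go_terms(kge, graph)
    kge$protein_adapter <- dense_init(config$fused_dim, kge$entity_dim)
    cat_of <- entity_categories(graph)
    pg <- graph$triples[cat_of[graph$triples$head] == "protein", ]
    # plain-vector views for the per-triple hot path
    ptriples <- lapply(split(seq_len(nrow(pg)), pg$head), function(ix) {
      list(relation = pg$relation[ix], tail = pg$tail[ix], n = length(ix))
    })
    # category-aware alternatives per observed tail (same order as
    # sample_negatives: entity-table order, true tail removed)
    alt_tails <- new.env(parent = emptyenv())
    for (tl in unique(pg$tail)) {
      members <- graph$entities$entity[graph$entities$category == cat_of[[tl]]]
      alt_tails[[tl]] <- setdiff(members, tl)
    }
  }

  train_ix <- which(splits == "train")
  val_ix <- which(splits == "val")
  y_all <- label_matrix(table)
  g_all <- grade_matrix(table)
  alpha_all <- alpha_from_grades(y_all, g_all, loss)
  prot_of <- vapply(table$samples, `[[`, character(1), "protein_id")
  pid_of <- table$protein_index[prot_of]   # 0-based
  labels_of <- lapply(table$samples, `[[`, "labels")
  pida_active <- vapply(labels_of, function(l) {
    length(intersect(l, loss$pida_classes)) > 0
  }, logical(1))

  params <- list(net = net[c("blocks3", "blocks2", "gate", "fuse",
                             "kadapt", "cls", "idh")])
  if (!is.null(kge)) {
    params$kge <- list(rel = kge$relation_parameters,
                       go = kge$go_embeddings,
                       padapt = kge$protein_adapter)
  }
  opt <- adam_init(params)
  sync_net <- function(net, params) {
    for (nm in names(params$net)) net[[nm]] <- params$net[[nm]]
    net
  }
  sync_kge <- function(kge, params) {
    if (is.null(kge)) return(kge)
    kge$relation_parameters <- params$kge$rel
    kge$go_embeddings <- params$kge$go
    kge$protein_adapter <- params$kge$padapt
    kge
  }
  # batch-norm running statistics live outside the optimizer; carry the
  # updates from the forward pass back into the parameter tree
  sync_bn_stats <- function(params, net) {
    for (br in c("blocks3", "blocks2")) {
      for (i in seq_along(net[[br]])) {
        for (bn in c("bn1", "bn2")) {
          params$net[[br]][[i]][[bn]][c("run_mean", "run_var")] <-
            net[[br]][[i]][[bn]][c("run_mean", "run_var")]
        }
      }
    }
    params
  }

  w <- loss$weights
  warned <- new.env(parent = emptyenv())
  history <- list()
  best <- list(mmcc = -Inf, net = net, kge = kge)

  for (epoch in seq_len(control$epochs)) {
    lr_now <- if (identical(control$lr_schedule, "cosine")) {
      control$lr * 0.5 * (1 + cos(pi * (epoch - 1) / control$epochs))
    } else {
      control$lr
    }
    order_ix <- sample(train_ix)
    nb <- ceiling(length(order_ix) / control$batch_size)
    ep_l <- c(slc = 0, ke = 0, id = 0, total = 0)
    # epoch-constant knowledge features (triple structure + current embeddings)
    kfeat <- if (use_kg) {
      knowledge_feature_matrix(sync_kge(kge, params), proteins, graph)
    } else NULL

    for (b in seq_len(nb)) {
      ix <- order_ix[((b - 1L) * control$batch_size + 1L):
                       min(b * control$batch_size, length(order_ix))]
      B <- length(ix)
      net <- sync_net(net, params)
      kge <- sync_kge(kge, params)
      x <- batch_from_samples(table$samples[ix],
                              encoding = config$input_encoding)
      if (isTRUE(control$augment)) {
        # random y/x flips; cells have no canonical lateral orientation
        if (stats::runif(1) < 0.5) x <- x[, , dim(x)[3]:1, , , drop = FALSE]
        if (stats::runif(1) < 0.5) x <- x[, , , dim(x)[4]:1, , drop = FALSE]
      }
      yb <- y_all[, ix, drop = FALSE]
      ab <- alpha_all[, ix, drop = FALSE]
      mixed <- B > 1 && control$mixup > 0 &&
        stats::runif(1) < control$mixup
      if (mixed) {
        perm <- sample.int(B)
        lam <- stats::runif(1, 0.35, 0.65)
        x <- lam * x + (1 - lam) * x[, , , , perm, drop = FALSE]
        yperm <- yb[, perm, drop = FALSE]
        aperm_ <- ab[, perm, drop = FALSE]
        anew <- pmax(ab * yb, aperm_ * yperm)   # positive-class weights
        yb <- pmax(yb, yperm)
        anew[anew == 0] <- 1                    # negatives keep weight 1
        ab <- anew
      }
      kraw <- if (!is.null(kfeat)) kfeat[, prot_of[ix], drop = FALSE] else NULL
      fw <- forward_network(net, x, kraw, training = TRUE)
      net <- fw$net   # running BN stats
      params <- sync_bn_stats(params, net)

      ## classification loss
      p <- fw$class_probs
      l_slc <- slc_loss(p, yb, ab, loss)
      dprob <- slc_loss_grad(p, yb, ab, loss)
      dlogits_c <- w["w_slc"] * dprob * p * (1 - p)

      ## protein-ID aggregation loss
      l_id <- 0
      dlogits_id <- NULL
      if (w["w_id"] > 0 && !mixed) {
        dlogits_id <- matrix(0, N, B)
        for (j in seq_len(B)) {
          i <- ix[j]
          if (!pida_active[i]) next
          pj <- fw$id_probs[, j]
          l_id <- l_id + pida_loss(pj, pid_of[i], labels_of[[i]], loss)
          gj <- pida_loss_grad(pj, pid_of[i], labels_of[[i]], loss)
          dlogits_id[, j] <- pj * (gj - sum(gj * pj))   # softmax jacobian
        }
        l_id <- l_id / B
        dlogits_id <- w["w_id"] * dlogits_id / B
      }

      ## knowledge-embedding loss (joint training)
      l_ke <- 0
      dfused_extra <- NULL
      kge_grads <- NULL
      if (use_kg && !mixed) {
        dfused_extra <- matrix(0, config$fused_dim, B)
        kge_grads <- list(rel = zero_like(params$kge$rel),
                          go = list(emb = params$kge$go$emb * 0),
                          padapt = list(W = kge$protein_adapter$W * 0,
                                        b = kge$protein_adapter$b * 0))
        emb <- kge$go_embeddings$emb
        n_triples_used <- 0L
        for (j in seq_len(B)) {
          i <- ix[j]
          tp <- ptriples[[prot_of[i]]]
          if (is.null(tp) || !tp$n) {
            if (is.null(warned[[prot_of[i]]])) {
              warned[[prot_of[i]]] <- TRUE
              warning("protein ", prot_of[i],
                      " has no knowledge triples; L_KE = 0 for its cells",
                      call. = FALSE)
            }
            next
          }
          sel <- if (tp$n > control$triples_per_cell) {
            sample.int(tp$n, control$triples_per_cell)
          } else {
            seq_len(tp$n)
          }
          h_raw <- drop(kge$protein_adapter$W %*% fw$fused[, j] +
                          kge$protein_adapter$b)
          if (kge$method == "pairre") {
            nh <- sqrt(sum(h_raw^2))
            h <- h_raw / max(nh, 1e-12)
          } else {
            h <- h_raw
          }
          dh_total <- numeric(kge$entity_dim)
          for (t in sel) {
            rel <- tp$relation[t]
            true_tail <- tp$tail[t]
            alts <- alt_tails[[true_tail]]
            if (is.null(alts) || !length(alts)) next
            tails <- if (length(alts) == 1L) rep(alts, kge$n_negatives) else
              sample(alts, kge$n_negatives, replace = TRUE)
            tails <- tails[tails %in% colnames(emb)]
            if (!length(tails)) next
            T_all <- emb[, c(true_tail, tails), drop = FALSE]
            d_all <- score_tails(kge, h, rel, T_all)
            lg <- ke_loss_grad(d_all[1], d_all[-1], kge$gamma)
            l_ke <- l_ke + ke_loss(d_all[1], d_all[-1], kge$gamma)
            n_triples_used <- n_triples_used + 1L
            sg <- score_tails_grad(kge, h, rel, T_all,
                                   c(lg$d_pos, lg$d_negs))
            dh_total <- dh_total + sg$dh
            kge_grads$rel[[rel]] <- accum_grads(kge_grads$rel[[rel]], sg$drel)
            cols <- c(true_tail, tails)
            for (cix in seq_along(cols)) {
              kge_grads$go$emb[, cols[cix]] <-
                kge_grads$go$emb[, cols[cix]] + sg$dT[, cix]
            }
          }
          if (kge$method == "pairre") {
            # chain through h = h_raw / ||h_raw||
            nh <- max(sqrt(sum(h_raw^2)), 1e-12)
            dh_total <- (dh_total - h * sum(dh_total * h)) / nh
          }
          kge_grads$padapt$W <- kge_grads$padapt$W +
            dh_total %*% t(fw$fused[, j, drop = FALSE])
          kge_grads$padapt$b <- kge_grads$padapt$b + dh_total
          dfused_extra[, j] <- crossprod(kge$protein_adapter$W, dh_total)
        }
        if (n_triples_used > 0L) {
          l_ke <- l_ke / n_triples_used
          sc <- unname(w["w_ke"]) / n_triples_used
          kge_grads <- rapply(kge_grads, function(v) v * sc, how = "replace")
          dfused_extra <- dfused_extra * sc
        } else {
          dfused_extra <- NULL
          kge_grads <- NULL
        }
      }

      grads <- list(net = backward_network(net, fw$cache, dlogits_c,
                                           dlogits_id, dfused_extra))
      if (!is.null(kge_grads)) grads$kge <- kge_grads
      st <- adam_step(params, grads, opt, lr = lr_now,
                      weight_decay = control$weight_decay)
      params <- st$params
      opt <- st$state
      if (!is.null(kge) && kge$method == "pairre" &&
          !is.null(params$kge$go$emb)) {
        nrm <- sqrt(colSums(params$kge$go$emb^2))
        params$kge$go$emb <- sweep(params$kge$go$emb, 2L, pmax(nrm, 1e-12), `/`)
      }

      lt <- total_loss(l_slc, l_ke, l_id, w)
      ep_l <- ep_l + c(l_slc, l_ke, l_id, lt) * B
    }
    ep_l <- ep_l / length(train_ix)

    val_mmcc <- NA_real_
    if (control$validate && length(val_ix)) {
      net <- sync_net(net, params)
      kge <- sync_kge(kge, params)
      fit_now <- structure(list(net = net, kge = kge, loss_config = loss,
                                class_vocabulary = table$class_vocabulary,
                                protein_index = table$protein_index),
                           class = "subloc3d_fit")
      sub <- table; sub$samples <- table$samples[val_ix]
      pr <- predict(fit_now, sub, graph = graph)
      val_mmcc <- evaluate(pr, sub)$macro[["mmcc"]]
      if (val_mmcc > best$mmcc) {
        best <- list(mmcc = val_mmcc, net = net, kge = kge)
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, l_slc = ep_l[1], l_ke = ep_l[2], l_id = ep_l[3],
      total = ep_l[4], val_mmcc = val_mmcc)
    if (control$verbose) {
      message(sprintf("epoch %d  slc %.4f  ke %.4f  id %.4f  total %.4f  val mMCC %s",
                      epoch, ep_l[1], ep_l[2], ep_l[3], ep_l[4],
                      ifelse(is.na(val_mmcc), "-", sprintf("%.3f", val_mmcc))))
    }
  }

  net <- sync_net(net, params)
  kge <- sync_kge(kge, params)
  if (is.finite(best$mmcc)) {
    net_best <- best$net; kge_best <- best$kge
  } else {
    net_best <- net; kge_best <- kge
  }
  history <- dplyr::bind_rows(history)
  if (!is.null(control$log_path)) {
    utils::write.csv(history, control$log_path, row.names = FALSE)
  }
  structure(list(net = net_best, final_net = net, kge = kge_best,
                 loss_config = loss, train_config = control,
                 class_vocabulary = table$class_vocabulary,
                 protein_index = table$protein_index,
                 history = history, seed = control$seed,
                 best_val_mmcc = if (is.finite(best$mmcc)) best$mmcc else NA_real_),
            class = "subloc3d_fit")
}

#' @export
print.subloc3d_fit <- function(x, ...) {
  cat("<subloc3d fit>", length(x$class_vocabulary), "classes,",
      length(x$protein_index), "proteins\n")
  if (!is.null(x$kge)) cat("  knowledge module:", x$kge$method, "\n")
  if (!is.null(x$history) && nrow(x$history)) {
    cat(sprintf("  %d epochs; final total loss %.4f; best val mMCC %s\n",
                nrow(x$history), x$history$total[nrow(x$history)],
                ifelse(is.na(x$best_val_mmcc), "-",
                       sprintf("%.3f", x$best_val_mmcc))))
  }
  invisible(x)
}

#' Per-epoch training history
#' @param x A `subloc3d_fit`.
#' @param ... Unused.
#' @method tidy subloc3d_fit
#' @export
tidy.subloc3d_fit <- function(x, ...) x$history

#' One-row fit summary
#' @param x A `subloc3d_fit`.
#' @param ... Unused.
#' @method glance subloc3d_fit
#' @export
glance.subloc3d_fit <- function(x, ...) {
  tibble::tibble(
    epochs = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    final_loss = if (is.null(x$history) || !nrow(x$history)) NA_real_
                 else x$history$total[nrow(x$history)],
    best_val_mmcc = x$best_val_mmcc,
    n_classes = length(x$class_vocabulary),
    n_proteins = length(x$protein_index),
    n_parameters = count_parameters(x$net),
    knowledge = if (is.null(x$kge)) "none" else x$kge$method
  )
}

#' Loss-curve plot of a fit
#' @param object A `subloc3d_fit`.
#' @param ... Unused.
#' @method autoplot subloc3d_fit
#' @export
autoplot.subloc3d_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("l_slc", "l_ke", "l_id", "total"),
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}

#' Predict localization for cells
#'
#' Computes per-protein knowledge features from the graph by head inversion
#' (usable for proteins unseen in training, since only their triples are
#' needed), runs the encoder in inference mode, and thresholds probabilities
#' at 0.5 for hard calls.
#'
#' @param object A `subloc3d_fit` (or [load_checkpoint()] result).
#' @param table A `subloc3d_table` (or list of samples) with in-memory
#'   volumes.
#' @param graph Optional knowledge graph; absent graph or absent triples
#'   fall back to a zero knowledge feature.
#' @param threshold Hard-call threshold.
#' @param batch_size Forward batch size.
#' @param ... Unused.
#' @return A `subloc3d_pred`: probability matrix `probs` (C x n), fused
#'   feature matrix `fused`, `meta` tibble (cell, protein, split,
#'   knowledge_used), and hard `calls`.
#' @export
predict.subloc3d_fit <- function(object, table, graph = NULL, threshold = 0.5,
                                 batch_size = 64L, ...) {
  samples <- if (inherits(table, "subloc3d_table")) table$samples else table
  if (!length(samples)) stop("no samples to predict")
  net <- object$net
  C <- net$config$n_classes
  voc <- object$class_vocabulary
  prot <- vapply(samples, `[[`, character(1), "protein_id")
  kused <- rep(FALSE, length(samples))
  kfeat <- NULL
  if (!is.null(graph) && !is.null(object$kge)) {
    up <- unique(prot)
    km <- knowledge_feature_matrix(object$kge, up, graph)
    kfeat <- km[, prot, drop = FALSE]
    kused <- unname(attr(km, "present")[prot])
  }
  n <- length(samples)
  probs <- matrix(0, C, n, dimnames = list(
    voc, vapply(samples, `[[`, character(1), "cell_id")))
  fused <- matrix(0, net$config$fused_dim, n,
                  dimnames = list(NULL, colnames(probs)))
  for (b in seq_len(ceiling(n / batch_size))) {
    ix <- (((b - 1L) * batch_size + 1L):min(b * batch_size, n))
    x <- batch_from_samples(samples[ix],
                            encoding = net$config$input_encoding)
    kraw <- if (!is.null(kfeat)) kfeat[, ix, drop = FALSE] else NULL
    fw <- forward_network(net, x, kraw, training = FALSE)
    probs[, ix] <- fw$class_probs
    fused[, ix] <- fw$fused
  }
  structure(list(
    probs = probs, fused = fused,
    calls = probs >= threshold, threshold = threshold,
    meta = tibble::tibble(cell_id = colnames(probs), protein_id = prot,
                          split = vapply(samples, `[[`, character(1), "split"),
                          knowledge_used = kused)),
    class = "subloc3d_pred")
}

#' @export
print.subloc3d_pred <- function(x, ...) {
  cat("<subloc3d predictions>", ncol(x$probs), "cells,",
      nrow(x$probs), "classes; knowledge used for",
      sum(x$meta$knowledge_used), "cells\n")
  invisible(x)
}

#' Predictions as a tibble (one row per cell, one probability column per class)
#' @param x A `subloc3d_pred`.
#' @param ... Unused.
#' @method as_tibble subloc3d_pred
#' @export
as_tibble.subloc3d_pred <- function(x, ...) {
  dplyr::bind_cols(x$meta,
                   tibble::as_tibble(t(x$probs), .name_repair = "minimal"))
}
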