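# Per-class and macro classification metrics (MCC, F1, Jaccard, average
# precision), cell- and image-level evaluation, and the clustering score used
# to judge feature separability.

#' Binary classification metrics for one class
#'
#' MCC, F1 and Jaccard are computed from the thresholded calls; average
#' precision uses the step (rectangle) estimator over the probability
#' ranking with stable tie-breaking. Degenerate conventions: an MCC
#' denominator of 0 gives 0; with no positives in truth and no positive
#' calls, F1 and Jaccard are 1 (vacuously correct) and AP is 0.
#'
#' @param y_true 0/1 vector.
#' @param y_prob Probabilities in `[0,1]`, same length.
#' @param threshold Call threshold (default 0.5, calls are `>=`).
#' @return Named numeric vector `c(mcc, f1, jaccard, ap)`.
#' @export
binary_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) stop("length mismatch")
  stopifnot(length(y_true) >= 1)
  call <- as.numeric(y_prob >= threshold)
  tp <- sum(y_true == 1 & call == 1)
  tn <- sum(y_true == 0 & call == 0)
  fp <- sum(y_true == 0 & call == 1)
  fn <- sum(y_true == 1 & call == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  jac <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  c(mcc = mcc, f1 = f1, jaccard = jac, ap = average_precision(y_true, y_prob))
}

#' @noRd
average_precision <- function(y_true, y_prob) {
  npos <- sum(y_true == 1)
  if (npos == 0) return(0)
  ord <- order(y_prob, decreasing = TRUE)   # stable for ties
  hits <- cumsum(y_true[ord] == 1)
  prec_at <- hits / seq_along(ord)
  sum(prec_at[y_true[ord] == 1]) / npos
}

#' Evaluate predictions against a dataset table
#'
#' Computes per-class MCC/F1/Jaccard/AP and their unweighted macro averages.
#' `level = "cell"` scores each cell; `level = "image"` averages the
#' per-cell probabilities of each source image before thresholding (the
#' aggregation used when annotation lives at the multicell-image level).
#'
#' @param predictions A `subloc3d_pred` from [predict.subloc3d_fit()], or a
#'   C x n probability matrix with rows named by class and columns by
#'   cell_id.
#' @param table The `subloc3d_table` holding labels (and `image_id`s for
#'   image-level evaluation).
#' @param level `"cell"` (default) or `"image"`.
#' @param threshold Call threshold.
#' @param split Optional split name to restrict evaluation to.
#' @return A `subloc3d_metrics` report.
#' @export
evaluate <- function(predictions, table, level = c("cell", "image"),
                     threshold = 0.5, split = NULL) {
  level <- match.arg(level)
  probs <- if (inherits(predictions, "subloc3d_pred")) predictions$probs
           else predictions
  samples <- table$samples
  ids <- vapply(samples, `[[`, character(1), "cell_id")
  keep <- ids %in% colnames(probs)
  if (!is.null(split)) {
    keep <- keep & vapply(samples, `[[`, character(1), "split") == split
  }
  samples <- samples[keep]
  if (!length(samples)) stop("no overlapping cells between predictions and table")
  ids <- ids[keep]
  probs <- probs[, ids, drop = FALSE]
  sub <- table; sub$samples <- samples
  y <- label_matrix(sub)[rownames(probs), , drop = FALSE]

  if (level == "image") {
    img <- vapply(samples, `[[`, character(1), "image_id")
    if (anyNA(img)) stop("image-level evaluation requires image_id on every sample")
    groups <- split(seq_along(img), img)
    cls <- rownames(probs)
    probs <- vapply(groups, function(ix) rowMeans(probs[, ix, drop = FALSE]),
                    numeric(nrow(probs)))
    y <- vapply(groups, function(ix) as.numeric(rowSums(y[, ix, drop = FALSE]) > 0),
                numeric(nrow(y)))
    if (is.null(dim(probs))) {   # single class: vapply dropped to vectors
      probs <- matrix(probs, nrow = 1)
      y <- matrix(y, nrow = 1)
    }
    rownames(probs) <- cls
    rownames(y) <- cls
  }

  per_class <- purrr::map_dfr(rownames(probs), function(cl) {
    m <- binary_metrics(y[cl, ], probs[cl, ], threshold)
    tibble::tibble(class = cl, mcc = m["mcc"], f1 = m["f1"],
                   jaccard = m["jaccard"], ap = m["ap"],
                   n_pos = sum(y[cl, ] == 1))
  })
  # macro averages run over classes that actually occur in the evaluated
  # units; classes with zero positives have no meaningful per-class score
  pc <- per_class[per_class$n_pos > 0, ]
  if (!nrow(pc)) pc <- per_class
  macro <- c(mmcc = mean(pc$mcc), mf1 = mean(pc$f1),
             mjs = mean(pc$jaccard), map = mean(pc$ap))
  structure(list(per_class = per_class, macro = macro, level = level,
                 threshold = threshold, n_units = ncol(probs)),
            class = "subloc3d_metrics")
}

#' @export
print.subloc3d_metrics <- function(x, ...) {
  cat("<subloc3d metrics>", x$level, "level,", x$n_units, "units\n")
  cat(sprintf("  mMCC %.4f  mF1 %.4f  mJS %.4f  mAP %.4f\n",
              x$macro["mmcc"], x$macro["mf1"], x$macro["mjs"], x$macro["map"]))
  invisible(x)
}

#' Tidy a metrics report (one row per class)
#' @param x A `subloc3d_metrics`.
#' @param ... Unused.
#' @method tidy subloc3d_metrics
#' @export
tidy.subloc3d_metrics <- function(x, ...) x$per_class

#' One-row macro summary of a metrics report
#' @param x A `subloc3d_metrics`.
#' @param ... Unused.
#' @method glance subloc3d_metrics
#' @export
glance.subloc3d_metrics <- function(x, ...) {
  tibble::tibble(mmcc = x$macro[["mmcc"]], mf1 = x$macro[["mf1"]],
                 mjs = x$macro[["mjs"]], map = x$macro[["map"]],
                 level = x$level, n_units = x$n_units)
}

#' Per-class metric bar chart
#' @param object A `subloc3d_metrics`.
#' @param ... Unused.
#' @method autoplot subloc3d_metrics
#' @export
autoplot.subloc3d_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, c("mcc", "f1", "jaccard", "ap"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Clustering score of a feature embedding
#'
#' Ratio of between-cluster dispersion to within-cluster compactness in the
#' Calinski-Harabasz form `[B/(k-1)] / [W/(n-k)]`, computed on cells of
#' single-location proteins to judge how well features separate
#' localization patterns.
#'
#' @param features n x d numeric matrix (one row per cell).
#' @param labels Vector of class labels, length n; at least 2 distinct.
#' @return Scalar score (larger = better separated).
#' @export
clustering_score <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  k <- length(unique(labels))
  if (k < 2) stop("clustering score needs at least 2 classes")
  n <- nrow(features)
  centroid <- colMeans(features)
  B <- 0; W <- 0
  for (cl in unique(labels)) {
    Xc <- features[labels == cl, , drop = FALSE]
    ck <- colMeans(Xc)
    B <- B + nrow(Xc) * sum((ck - centroid)^2)
    W <- W + sum(sweep(Xc, 2L, ck)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}
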