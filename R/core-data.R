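# Data model and I/O: single-cell volumes with multi-label annotations and
# confidence grades, dataset tables, cell cropping from multicell volumes,
# z-projection, and protein-level train/val/test splits.
#
# Conventions: volumes are numeric arrays with axis order (channel, z, y, x),
# channel 1 = nucleus reference, channel 2 = tagged protein; coordinates are
# 0-based with half-open crop windows.

#' Single-cell volume sample
#'
#' @param cell_id,protein_id Identifiers.
#' @param volume Numeric array (2, z, y, x), non-negative; channel 1 nucleus,
#'   channel 2 protein. May be `NULL` for annotation rows whose voxel data
#'   lives on disk.
#' @param labels Character vector of localization classes. May be empty only
#'   for freshly cropped, not-yet-annotated cells.
#' @param grades Named integer vector (names = labels) with confidence
#'   grades in {1, 2, 3}; 3 = prominent, 1 = subtle signal.
#' @param split One of `"train"`, `"val"`, `"test"`, `"unassigned"`.
#' @param image_id Source multicell image identifier (used by image-level
#'   evaluation); `NA` when unknown.
#' @param volume_path Optional path of the on-disk volume.
#' @return A list of class `subloc3d_sample`.
#' @export
volume_sample <- function(cell_id, protein_id, volume = NULL,
                          labels = character(), grades = integer(),
                          split = "unassigned", image_id = NA_character_,
                          volume_path = NA_character_) {
  if (!is.null(volume)) {
    d <- dim(volume)
    if (length(d) != 4L || d[1] != 2L) {
      stop("volume must be a (2, z, y, x) array; got dims ",
           paste(d, collapse = "x"))
    }
    if (min(volume) < 0) stop("volume intensities must be non-negative")
  }
  labels <- as.character(labels)
  if (length(labels)) {
    if (anyDuplicated(labels)) stop("duplicate labels")
    if (!setequal(names(grades), labels)) {
      stop("grades must be named by exactly the labels")
    }
    if (!all(grades %in% 1:3)) stop("confidence grades must be in {1,2,3}")
    grades <- grades[labels]
  }
  split <- match.arg(split, c("train", "val", "test", "unassigned"))
  structure(list(cell_id = cell_id, protein_id = protein_id, volume = volume,
                 labels = labels, grades = grades, split = split,
                 image_id = image_id, volume_path = volume_path),
            class = "subloc3d_sample")
}

#' @export
print.subloc3d_sample <- function(x, ...) {
  cat("<subloc3d sample>", x$cell_id, "protein", x$protein_id, "\n")
  cat("  labels:", paste(sprintf("%s(g%d)", x$labels, x$grades), collapse = ", "),
      " split:", x$split, "\n")
  if (!is.null(x$volume)) cat("  volume:", paste(dim(x$volume), collapse = "x"), "\n")
  invisible(x)
}

#' Dataset of annotated single-cell volumes
#'
#' @param samples List of [volume_sample()] objects (all with non-empty
#'   labels).
#' @param class_vocabulary Ordered class identifiers; default: sorted union
#'   of sample labels.
#' @param protein_index Named integer vector mapping protein_id to 0-based
#'   integer id; default: alphabetical.
#' @return A list of class `subloc3d_table`.
#' @export
dataset_table <- function(samples, class_vocabulary = NULL,
                          protein_index = NULL) {
  stopifnot(length(samples) >= 1)
  if (any(!vapply(samples, function(s) length(s$labels) > 0, logical(1)))) {
    stop("all samples in a dataset table must carry labels")
  }
  if (is.null(class_vocabulary)) {
    class_vocabulary <- sort(unique(unlist(lapply(samples, `[[`, "labels"))))
  }
  if (anyDuplicated(class_vocabulary)) stop("duplicate classes in vocabulary")
  proteins <- sort(unique(vapply(samples, `[[`, character(1), "protein_id")))
  if (is.null(protein_index)) {
    protein_index <- stats::setNames(seq_along(proteins) - 1L, proteins)
  }
  if (!setequal(names(protein_index), proteins) ||
      !setequal(protein_index, seq_along(protein_index) - 1L)) {
    stop("protein_index must be a bijection proteins -> 0..N-1")
  }
  unknown <- setdiff(unlist(lapply(samples, `[[`, "labels")), class_vocabulary)
  if (length(unknown)) stop("sample labels outside vocabulary: ",
                            paste(unknown, collapse = ", "))
  structure(list(samples = samples, class_vocabulary = class_vocabulary,
                 protein_index = protein_index),
            class = "subloc3d_table")
}

#' @export
print.subloc3d_table <- function(x, ...) {
  cat("<subloc3d dataset>", length(x$samples), "cells,",
      length(x$protein_index), "proteins,",
      length(x$class_vocabulary), "classes\n")
  spl <- table(vapply(x$samples, `[[`, character(1), "split"))
  cat("  splits:", paste(names(spl), spl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Annotation table as a tibble
#'
#' One row per cell with pipe-separated labels and grades, the
#' representation used by the annotation CSV.
#'
#' @param x A `subloc3d_table`.
#' @param ... Unused.
#' @method as_tibble subloc3d_table
#' @export
as_tibble.subloc3d_table <- function(x, ...) {
  tibble::tibble(
    cell_id = vapply(x$samples, `[[`, character(1), "cell_id"),
    protein_id = vapply(x$samples, `[[`, character(1), "protein_id"),
    volume_path = vapply(x$samples, `[[`, character(1), "volume_path"),
    labels = vapply(x$samples, function(s) paste(s$labels, collapse = "|"), character(1)),
    grades = vapply(x$samples, function(s) paste(s$grades, collapse = "|"), character(1)),
    split = vapply(x$samples, `[[`, character(1), "split"),
    image_id = vapply(x$samples, `[[`, character(1), "image_id")
  )
}

#' Label indicator matrix (C x n_cells) of a dataset
#' @param table A `subloc3d_table`.
#' @return 0/1 matrix, rows named by class, columns by cell id.
#' @export
label_matrix <- function(table) {
  C <- length(table$class_vocabulary)
  y <- matrix(0, C, length(table$samples),
              dimnames = list(table$class_vocabulary,
                              vapply(table$samples, `[[`, character(1), "cell_id")))
  for (i in seq_along(table$samples)) {
    y[table$samples[[i]]$labels, i] <- 1
  }
  y
}

#' @noRd
grade_matrix <- function(table) {
  C <- length(table$class_vocabulary)
  g <- matrix(3L, C, length(table$samples),
              dimnames = list(table$class_vocabulary, NULL))
  for (i in seq_along(table$samples)) {
    s <- table$samples[[i]]
    g[s$labels, i] <- s$grades
  }
  g
}

# ---- preprocessing -----------------------------------------------------------

#' Crop single cells from a multicell volume
#'
#' Takes a square (y, x) window of side `crop_xy` centered on each nucleus
#' center, keeps the full z extent, zero-pads windows that reach outside the
#' volume, and resizes the (y, x) plane to `out_xy` (bilinear; z untouched).
#'
#' @param multicell_volume Array (2, z, y, x).
#' @param nucleus_centers List of length-3 numeric vectors (z, y, x),
#'   0-based.
#' @param crop_xy Window side in voxels.
#' @param out_xy Output side (default 128, the standard single-cell size).
#' @param protein_id,labels,grades,image_id Annotation applied to every
#'   cropped cell (protein-level labels; may be left empty for later
#'   annotation).
#' @return List of [volume_sample()] objects, one per center.
#' @export
crop_single_cells <- function(multicell_volume, nucleus_centers, crop_xy,
                              out_xy = 128L, protein_id = "unknown",
                              labels = character(), grades = integer(),
                              image_id = NA_character_) {
  d <- dim(multicell_volume)
  if (length(d) != 4L || d[1] != 2L) stop("multicell_volume must be (2, z, y, x)")
  stopifnot(crop_xy > 0, out_xy > 0)
  lapply(seq_along(nucleus_centers), function(i) {
    ctr <- nucleus_centers[[i]]
    if (length(ctr) != 3L) stop("centers must be (z, y, x)")
    cy <- ctr[2]; cx <- ctr[3]
    if (cy < 0 || cy >= d[3] || cx < 0 || cx >= d[4]) {
      stop("nucleus center (", paste(ctr, collapse = ", "),
           ") lies outside the volume")
    }
    y0 <- floor(cy) - crop_xy %/% 2
    x0 <- floor(cx) - crop_xy %/% 2
    crop <- array(0, c(2L, d[2], crop_xy, crop_xy))
    ys <- (y0:(y0 + crop_xy - 1L))
    xs <- (x0:(x0 + crop_xy - 1L))
    yin <- which(ys >= 0 & ys < d[3])
    xin <- which(xs >= 0 & xs < d[4])
    crop[, , yin, xin] <- multicell_volume[, , ys[yin] + 1L, xs[xin] + 1L,
                                           drop = FALSE]
    if (out_xy != crop_xy) crop <- resize_yx(crop, out_xy)
    volume_sample(cell_id = sprintf("%s_cell%03d", protein_id, i),
                  protein_id = protein_id, volume = crop, labels = labels,
                  grades = grades, image_id = image_id)
  })
}

# Bilinear resize of the (y, x) plane of a (2, z, y, x) array; z untouched.
#' @noRd
resize_yx <- function(vol, out_xy) {
  d <- dim(vol)
  src <- function(n_out, n_in) {
    # align-corners-free mapping of output pixel centers into source coords
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- pmin(floor(pos), n_in - 1)
    list(lo = lo + 1L, hi = pmin(lo + 1, n_in - 1) + 1L, w = pos - lo)
  }
  sy <- src(out_xy, d[3]); sx <- src(out_xy, d[4])
  out <- array(0, c(d[1], d[2], out_xy, out_xy))
  for (ch in 1:d[1]) for (z in 1:d[2]) {
    sl <- vol[ch, z, , ]
    a <- sl[sy$lo, sx$lo]; b <- sl[sy$hi, sx$lo]
    cc <- sl[sy$lo, sx$hi]; dd <- sl[sy$hi, sx$hi]
    wy <- sy$w; wx <- sx$w
    top <- a * (1 - wy) + b * wy
    bot <- cc * (1 - wy) + dd * wy
    out[ch, z, , ] <- top * (1 - rep(wx, each = out_xy)) + bot * rep(wx, each = out_xy)
  }
  out
}

#' Project a volume along z
#'
#' @param volume Array (z, y, x) or (channel, z, y, x).
#' @param op `"max"` (default, maximum-intensity projection) or `"mean"`.
#' @return (y, x) matrix, or (channel, y, x) array for channel-first input.
#' @export
project_z <- function(volume, op = c("max", "mean")) {
  op <- match.arg(op)
  d <- dim(volume)
  if (is.null(d) || length(d) < 3L) stop("volume must be a 3D or 4D array")
  if (length(d) == 4L) {
    out <- array(0, c(d[1], d[3], d[4]))
    for (ch in seq_len(d[1])) out[ch, , ] <- project_z(volume[ch, , , ], op)
    return(out)
  }
  if (d[1] < 1L) stop("z axis has zero extent")
  f <- if (op == "max") max else mean
  apply(volume, c(2, 3), f)
}

#' Per-channel normalization of a cell volume
#'
#' Square-root variance-stabilizing transform (appropriate for
#' photon-limited intensities, where noise scales with signal) followed by
#' per-channel min-max scaling to `[0,1]`; constant channels map to 0.
#' Applied before the encoder so that per-cell intensity scale does not
#' affect predictions; the square root also keeps faint co-localized
#' patterns visible next to a dominant one.
#'
#' @param volume Array (2, z, y, x).
#' @param vst Apply the square-root transform before scaling? (default TRUE)
#' @return Array of the same shape.
#' @export
normalize_minmax <- function(volume, vst = TRUE) {
  for (ch in seq_len(dim(volume)[1])) {
    v <- volume[ch, , , ]
    if (vst) v <- sqrt(pmax(v, 0))
    rng <- range(v)
    volume[ch, , , ] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  }
  volume
}

# ---- splits ------------------------------------------------------------------

#' Protein-level (or cell-level) train/val/test split
#'
#' Proteins are shuffled with the seed and partitioned by the fractions
#' (floor + largest-remainder, so counts match the fractions within one);
#' every cell inherits its protein's split, which prevents protein leakage
#' across splits. `level = "cell"` shuffles cells instead (the mode for
#' datasets whose proteins map one-to-one to classes).
#'
#' @param table A `subloc3d_table`.
#' @param fractions Train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @param level `"protein"` (default) or `"cell"`.
#' @return A list of class `subloc3d_split`: fractions, seed, level, and
#'   `assignment` (named character vector unit -> split).
#' @export
split_by_protein <- function(table, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L, level = c("protein", "cell")) {
  level <- match.arg(level)
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  units <- if (level == "protein") names(table$protein_index) else
    vapply(table$samples, `[[`, character(1), "cell_id")
  n <- length(units)
  if (n < sum(fractions > 0)) {
    stop("need at least ", sum(fractions > 0), " ", level, "s for ",
         sum(fractions > 0), " nonzero fractions")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(units)
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  assignment <- stats::setNames(
    rep(c("train", "val", "test"), counts), shuffled)
  structure(list(fractions = fractions, seed = as.integer(seed),
                 level = level, assignment = assignment),
            class = "subloc3d_split")
}

#' Apply a split assignment to a dataset table
#' @param table A `subloc3d_table`.
#' @param split A `subloc3d_split` from [split_by_protein()].
#' @return The table with each sample's `split` field set.
#' @export
apply_split <- function(table, split) {
  key <- if (split$level == "protein") "protein_id" else "cell_id"
  table$samples <- lapply(table$samples, function(s) {
    sp <- split$assignment[[s[[key]]]]
    if (is.null(sp)) stop("no split assignment for ", s[[key]])
    s$split <- sp
    s
  })
  table
}

# ---- annotation CSV ----------------------------------------------------------

#' Read / write the annotation CSV
#'
#' Columns: `cell_id, protein_id, volume_path, labels, grades` plus optional
#' `split` and `image_id`; labels are pipe-separated, grades pipe-separated
#' integers aligned with the labels. Writing then reading reproduces the
#' table's annotation fields exactly. Volumes are not loaded; use
#' [read_volume()] on `volume_path` (or [attach_volumes()]).
#'
#' @param path CSV path.
#' @return A `subloc3d_table` (samples without in-memory volumes).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("cell_id", "protein_id", "volume_path", "labels", "grades")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation CSV lacks columns: ", paste(miss, collapse = ", "))
  samples <- lapply(seq_len(nrow(df)), function(i) {
    labels <- strsplit(df$labels[i], "|", fixed = TRUE)[[1]]
    grades_chr <- strsplit(df$grades[i], "|", fixed = TRUE)[[1]]
    if (length(labels) != length(grades_chr)) {
      stop("row ", i, ": labels and grades have different lengths")
    }
    grades <- suppressWarnings(as.integer(grades_chr))
    if (anyNA(grades) || !all(grades %in% 1:3)) {
      stop("row ", i, ": grades must be integers in {1,2,3}")
    }
    volume_sample(
      cell_id = df$cell_id[i], protein_id = df$protein_id[i],
      labels = labels, grades = stats::setNames(grades, labels),
      split = if ("split" %in% names(df)) df$split[i] else "unassigned",
      image_id = if ("image_id" %in% names(df)) df$image_id[i] else NA_character_,
      volume_path = df$volume_path[i]
    )
  })
  dataset_table(samples)
}

#' @rdname read_annotations
#' @param table A `subloc3d_table`.
#' @export
write_annotations <- function(table, path) {
  utils::write.csv(as_tibble.subloc3d_table(table), path, row.names = FALSE)
  invisible(table)
}

# ---- volume files ------------------------------------------------------------

#' Read / write a single-cell volume file
#'
#' TIFF stacks (`.tif`/`.tiff`) store 32-bit float pages in channel-major
#' order (all z of the nucleus channel, then all z of the protein channel);
#' `.rds` stores the array directly (channel-first `(2, z, y, x)` or
#' channel-last `(z, y, x, 2)`, autodetected from the dimensions).
#'
#' @param path File path; format chosen by extension.
#' @param n_channels Channel count for TIFF files (default 2).
#' @return [read_volume()]: a `(2, z, y, x)` array.
#' @export
read_volume <- function(path, n_channels = 2L) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    vol <- readRDS(path)
    d <- dim(vol)
    if (length(d) == 4L && d[4] == 2L && d[1] != 2L) {
      vol <- aperm(vol, c(4, 1, 2, 3))    # channel-last -> channel-first
    }
    return(vol)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages) %/% n_channels
  if (nz * n_channels != length(pages)) {
    stop("page count not divisible by n_channels in ", path)
  }
  dy <- nrow(pages[[1]]); dx <- ncol(pages[[1]])
  vol <- array(0, c(n_channels, nz, dy, dx))
  for (ch in seq_len(n_channels)) for (z in seq_len(nz)) {
    vol[ch, z, , ] <- pages[[(ch - 1L) * nz + z]]
  }
  vol
}

#' @rdname read_volume
#' @param volume A `(2, z, y, x)` array.
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(volume, path)
    return(invisible(path))
  }
  d <- dim(volume)
  mx <- max(volume)
  scale <- if (mx > 1) mx else 1   # writeTIFF float requires [0,1]
  pages <- list()
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[length(pages) + 1L]] <- volume[ch, z, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Load on-disk volumes into a dataset table
#' @param table A `subloc3d_table` read from an annotation CSV.
#' @param dir Base directory for relative `volume_path`s.
#' @return The table with `volume` arrays attached.
#' @export
attach_volumes <- function(table, dir = ".") {
  table$samples <- lapply(table$samples, function(s) {
    if (is.null(s$volume) && !is.na(s$volume_path)) {
      p <- if (file.exists(s$volume_path)) s$volume_path else
        file.path(dir, s$volume_path)
      s$volume <- read_volume(p)
    }
    s
  })
  table
}
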