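# Synthetic single-cell 3D volumes with known localization patterns, and a
# synthetic GO-style knowledge graph. The generator emulates the structure of
# endogenous-tagging screens: protein-level multi-label annotation applied to
# every cell of a protein (weak annotation), class imbalance, and confidence
# grades derived from how prominent each pattern is in the rendered cell.

#' Localization classes the simulator can render
#' @export
sim_classes <- c("nucleoplasm", "nucleolus", "cytoplasm", "membrane",
                 "vesicles", "er", "golgi", "focal_adhesions", "cell_contact")

#' Simulation configuration
#'
#' @param shape Volume shape (z, y, x); all dims >= 8. The default
#'   (12, 32, 32) is a desk-scale stand-in for full-resolution single cells;
#'   every size is configurable.
#' @param classes Class set drawn from [sim_classes].
#' @param n_proteins,cells_per_protein Dataset size.
#' @param class_frequencies Named non-negative weights over `classes` used
#'   to draw each protein's primary class (need not sum to 1); skewed
#'   weights reproduce class imbalance.
#' @param multilabel_rate Probability a protein carries 2 (or with prob.
#'   `multilabel_rate^2`, 3) classes.
#' @param weak_annotation_rate Probability that a labeled pattern is absent
#'   from a given cell while the label is kept (cellular heterogeneity).
#' @param grade_policy Mixing-weight cutpoints: weight >= `grade3` gives
#'   grade 3, weight >= `grade2` gives grade 2, else grade 1.
#' @param render_alias Named character vector mapping a class to the class
#'   whose renderer it should use (e.g. `c(er = "cytoplasm")` makes the two
#'   visually indistinguishable while their labels and knowledge-graph
#'   triples stay distinct) — the regime where knowledge enhancement has to
#'   carry the signal.
#' @param background Additive background level.
#' @param background_sd Gaussian jitter of the background.
#' @param shot_noise Apply Poisson shot noise to scaled intensities?
#' @param photons Poisson scaling (expected counts at unit intensity).
#' @param seed Integer seed.
#' @return A list of class `subloc3d_sim_config`.
#' @export
sim_config <- function(shape = c(12L, 32L, 32L),
                       classes = c("nucleoplasm", "nucleolus", "cytoplasm",
                                   "membrane", "vesicles", "er"),
                       n_proteins = 30L, cells_per_protein = 20L,
                       class_frequencies = NULL,
                       multilabel_rate = 0.3,
                       weak_annotation_rate = 0,
                       render_alias = character(),
                       grade_policy = c(grade3 = 0.7, grade2 = 0.3),
                       background = 0.02, background_sd = 0.005,
                       shot_noise = TRUE, photons = 200,
                       seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  unknown <- setdiff(classes, sim_classes)
  if (length(unknown)) {
    stop("unknown class(es) ", paste(unknown, collapse = ", "),
         "; available: ", paste(sim_classes, collapse = ", "))
  }
  if (is.null(class_frequencies)) {
    class_frequencies <- stats::setNames(rep(1, length(classes)), classes)
  }
  stopifnot(all(class_frequencies >= 0), sum(class_frequencies) > 0,
            multilabel_rate >= 0, multilabel_rate <= 1,
            weak_annotation_rate >= 0, weak_annotation_rate <= 1)
  structure(
    list(shape = as.integer(shape), classes = classes,
         n_proteins = as.integer(n_proteins),
         cells_per_protein = as.integer(cells_per_protein),
         class_frequencies = class_frequencies[classes],
         multilabel_rate = multilabel_rate,
         weak_annotation_rate = weak_annotation_rate,
         render_alias = render_alias,
         grade_policy = grade_policy, background = background,
         background_sd = background_sd, shot_noise = shot_noise,
         photons = photons, seed = as.integer(seed)),
    class = "subloc3d_sim_config"
  )
}

# Coordinate grids and the cell/nucleus geometry of one simulated cell.
#' @noRd
cell_geometry <- function(shape, rng_jitter = TRUE) {
  z <- shape[1]; y <- shape[2]; x <- shape[3]
  cz <- (z - 1) / 2; cy <- (y - 1) / 2; cx <- (x - 1) / 2
  jit <- function(f) if (rng_jitter) stats::runif(1, 1 - f, 1 + f) else 1
  # cell: ellipsoid filling most of the volume; nucleus: smaller, offset
  ax_c <- c(cz * 0.92 * jit(0.06), cy * 0.88 * jit(0.08), cx * 0.88 * jit(0.08))
  ax_n <- ax_c * c(0.62, 0.48, 0.48) * if (rng_jitter) stats::runif(1, 0.9, 1.1) else 1
  gz <- array(rep(0:(z - 1), times = y * x), c(z, y, x))
  gy <- array(rep(rep(0:(y - 1), each = z), times = x), c(z, y, x))
  gx <- array(rep(0:(x - 1), each = z * y), c(z, y, x))
  q <- function(ax, ctr) ((gz - ctr[1]) / ax[1])^2 + ((gy - ctr[2]) / ax[2])^2 +
    ((gx - ctr[3]) / ax[3])^2
  ctr <- c(cz, cy, cx)
  qc <- q(ax_c, ctr)
  qn <- q(ax_n, ctr)
  list(shape = shape, gz = gz, gy = gy, gx = gx, ctr = ctr,
       ax_c = ax_c, ax_n = ax_n,
       cell = qc <= 1, nucleus = qn <= 1, qc = qc, qn = qn)
}

# Per-class renderers: each returns a non-negative intensity field supported
# on the class's defining region; fields are normalized to unit mean over
# their support so mixing weights are comparable across classes.
#' @noRd
render_class <- function(class, geo) {
  msk <- switch(class,
    nucleoplasm = geo$nucleus,
    nucleolus = {
      m <- array(FALSE, geo$shape)
      k <- sample(1:3, 1)
      for (i in seq_len(k)) {
        # center well inside the nucleus
        u <- stats::runif(3, -0.4, 0.4)
        ctr <- geo$ctr + u * geo$ax_n
        rad <- max(1.2, 0.22 * min(geo$ax_n) * stats::runif(1, 0.8, 1.3))
        m <- m | (((geo$gz - ctr[1])^2 + (geo$gy - ctr[2])^2 +
                     (geo$gx - ctr[3])^2) <= rad^2)
      }
      m & geo$nucleus
    },
    cytoplasm = geo$cell & !geo$nucleus,
    membrane = geo$cell & geo$qc > 0.72,
    vesicles = {
      m <- array(FALSE, geo$shape)
      cyto <- which(geo$cell & !geo$nucleus)
      k <- sample(6:12, 1)
      pick <- sample(cyto, min(k, length(cyto)))
      for (p in pick) {
        pz <- (p - 1) %% geo$shape[1]
        py <- ((p - 1) %/% geo$shape[1]) %% geo$shape[2]
        px <- (p - 1) %/% (geo$shape[1] * geo$shape[2])
        m <- m | (((geo$gz - pz)^2 + (geo$gy - py)^2 + (geo$gx - px)^2) <= 1.3^2)
      }
      m & geo$cell
    },
    er = geo$cell & !geo$nucleus & geo$qn <= 1.9,
    golgi = {
      # one blob abutting the nucleus, random azimuth
      th <- stats::runif(1, 0, 2 * pi)
      ctr <- geo$ctr + c(0, sin(th), cos(th)) * geo$ax_n * 1.15
      rad <- 0.35 * min(geo$ax_n[2:3]) + 1
      (((geo$gz - ctr[1])^2 + (geo$gy - ctr[2])^2 +
          (geo$gx - ctr[3])^2) <= rad^2) & geo$cell & !geo$nucleus
    },
    focal_adhesions = {
      bottom <- geo$gz <= 1
      ring <- geo$cell & geo$qc > 0.5
      m <- array(FALSE, geo$shape)
      cand <- which(bottom & ring)
      if (length(cand)) {
        pick <- sample(cand, min(sample(4:8, 1), length(cand)))
        for (p in pick) {
          py <- ((p - 1) %/% geo$shape[1]) %% geo$shape[2]
          px <- (p - 1) %/% (geo$shape[1] * geo$shape[2])
          m <- m | (bottom & ((geo$gy - py)^2 + (geo$gx - px)^2) <= 1.1^2)
        }
      }
      m
    },
    cell_contact = {
      th <- stats::runif(1, 0, 2 * pi)
      dirv <- c(sin(th), cos(th))
      proj <- (geo$gy - geo$ctr[2]) * dirv[1] + (geo$gx - geo$ctr[3]) * dirv[2]
      geo$cell & geo$qc > 0.72 & proj > 0.55 * max(geo$ax_c[2:3])
    },
    stop("unknown class '", class, "'; vocabulary: ",
         paste(sim_classes, collapse = ", "))
  )
  field <- array(0, geo$shape)
  field[msk] <- 1
  field
}

#' Simulate one single-cell volume
#'
#' The nucleus channel is a filled ellipsoid; the protein channel is the
#' mixing-weighted sum of the renderers of the cell's realized classes, plus
#' background and optional Poisson shot noise. Weak annotation is emulated
#' by dropping a labeled pattern (weight 0) while keeping the label; grades
#' are derived from the realized mixing weights through the grade policy.
#'
#' @param protein_labels Character vector of the protein's classes.
#' @param config A [sim_config()].
#' @param seed Integer seed for this cell (bit-identical volumes for equal
#'   seeds).
#' @param cell_id,protein_id Identifiers stored in the sample.
#' @return `list(sample = volume_sample, truth = tibble)` where `truth` has
#'   one row per label with its realized mixing weight and whether it
#'   rendered.
#' @export
simulate_cell <- function(protein_labels, config = sim_config(), seed = 1L,
                          cell_id = "cell", protein_id = "protein") {
  unknown <- setdiff(protein_labels, sim_classes)
  if (length(unknown)) {
    stop("unknown class '", unknown[1], "'; vocabulary: ",
         paste(sim_classes, collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  geo <- cell_geometry(config$shape)
  L <- length(protein_labels)
  w <- if (L == 1L) 1 else {
    raw <- stats::rgamma(L, shape = 2)
    sort(raw / sum(raw), decreasing = TRUE)
  }
  realized <- stats::runif(L) >= config$weak_annotation_rate
  w_real <- w * realized
  protein <- array(0, config$shape)
  for (i in seq_len(L)) {
    if (w_real[i] > 0) {
      cls <- protein_labels[i]
      if (cls %in% names(config$render_alias)) cls <- config$render_alias[[cls]]
      protein <- protein + w_real[i] * render_class(cls, geo)
    }
  }
  nucleus <- array(0, config$shape)
  nucleus[geo$nucleus] <- 1
  add_noise <- function(v) {
    v <- v + config$background +
      stats::rnorm(length(v), sd = config$background_sd)
    v <- pmax(v, 0)
    if (config$shot_noise) {
      v <- stats::rpois(length(v), v * config$photons) / config$photons
    }
    array(v, config$shape)
  }
  vol <- array(0, c(2L, config$shape))
  vol[1, , , ] <- add_noise(nucleus)
  vol[2, , , ] <- add_noise(protein)
  grade_of <- function(wt) {
    if (wt >= config$grade_policy["grade3"]) 3L
    else if (wt >= config$grade_policy["grade2"]) 2L else 1L
  }
  grades <- stats::setNames(vapply(w_real, grade_of, integer(1)), protein_labels)
  sample <- volume_sample(cell_id = cell_id, protein_id = protein_id,
                          volume = vol, labels = protein_labels,
                          grades = grades)
  truth <- tibble::tibble(cell_id = cell_id, protein_id = protein_id,
                          class = protein_labels, weight = w_real,
                          rendered = realized)
  list(sample = sample, truth = truth)
}

#' Simulate a full annotated dataset
#'
#' Proteins receive label sets from the class frequencies and multilabel
#' rate; each protein gets `cells_per_protein` cells via [simulate_cell()].
#'
#' @param config A [sim_config()].
#' @return `list(table = subloc3d_table, truth = tibble)`; `truth` is the
#'   per-cell-per-label record of realized patterns and weights.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (sum(config$class_frequencies) <= 0) stop("class frequencies sum to zero")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  cls <- config$classes
  prob <- config$class_frequencies / sum(config$class_frequencies)
  protein_labels <- lapply(seq_len(config$n_proteins), function(i) {
    k <- 1L
    if (stats::runif(1) < config$multilabel_rate) {
      k <- if (stats::runif(1) < config$multilabel_rate) 3L else 2L
    }
    k <- min(k, length(cls))
    first <- sample(cls, 1, prob = prob)
    extra <- if (k > 1L) sample(setdiff(cls, first), k - 1L) else character()
    c(first, extra)
  })
  names(protein_labels) <- sprintf("prot%03d", seq_len(config$n_proteins))
  cell_seeds <- sample.int(2^31 - 2, config$n_proteins * config$cells_per_protein)
  samples <- vector("list", length(cell_seeds))
  truths <- vector("list", length(cell_seeds))
  k <- 0L
  for (p in names(protein_labels)) {
    for (j in seq_len(config$cells_per_protein)) {
      k <- k + 1L
      res <- simulate_cell(protein_labels[[p]], config, seed = cell_seeds[k],
                           cell_id = sprintf("%s_c%03d", p, j), protein_id = p)
      res$sample$image_id <- sprintf("%s_img%02d", p, (j - 1L) %/% 4L + 1L)
      samples[[k]] <- res$sample
      truths[[k]] <- res$truth
    }
  }
  list(table = dataset_table(samples, class_vocabulary = cls),
       truth = dplyr::bind_rows(truths))
}

#' Simulate a GO-style knowledge graph for a dataset
#'
#' One cellular-component (CC) term per localization class plus distractor
#' molecular-function (MF) and biological-process (BP) terms. Each protein
#' gets a `located_in` triple per labeled class (tail corrupted to a random
#' other CC term with probability `corruption`), plus random protein-MF/BP
#' triples; `is_a` triples form a small GO hierarchy. Every GO entity
#' carries a deterministic template annotation text.
#'
#' @param table A `subloc3d_table`.
#' @param corruption Probability a located_in tail is corrupted.
#' @param n_mf,n_bp Number of distractor MF/BP terms.
#' @param seed Integer seed.
#' @return A [knowledge_graph()].
#' @export
simulate_kg <- function(table, corruption = 0, n_mf = 4L, n_bp = 4L,
                        seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cls <- table$class_vocabulary
  cc <- stats::setNames(sprintf("GO:CC:%s", cls), cls)
  mf <- sprintf("GO:MF:%02d", seq_len(n_mf))
  bp <- sprintf("GO:BP:%02d", seq_len(n_bp))
  proteins <- names(table$protein_index)
  entities <- tibble::tibble(
    entity = c(proteins, unname(cc), "GO:CC:cellular_anatomical_entity", mf, bp),
    category = c(rep("protein", length(proteins)), rep("CC", length(cc) + 1L),
                 rep("MF", n_mf), rep("BP", n_bp))
  )
  labels_of <- list()
  for (s in table$samples) labels_of[[s$protein_id]] <- s$labels
  trip <- list()
  for (p in proteins) {
    for (cl in labels_of[[p]]) {
      tail <- cc[[cl]]
      if (corruption > 0 && stats::runif(1) < corruption) {
        tail <- sample(setdiff(unname(cc), tail), 1)
      }
      trip[[length(trip) + 1L]] <- c(p, "located_in", tail)
    }
    for (t in sample(c(mf, bp), sample(1:2, 1))) {
      rel <- if (t %in% mf) "enables" else "involved_in"
      trip[[length(trip) + 1L]] <- c(p, rel, t)
    }
  }
  for (g in unname(cc)) {
    trip[[length(trip) + 1L]] <- c(g, "is_a", "GO:CC:cellular_anatomical_entity")
  }
  if (n_bp >= 2L) {
    for (i in 2:n_bp) trip[[length(trip) + 1L]] <- c(bp[i], "is_a", bp[1])
  }
  triples <- unique(tibble::tibble(
    head = vapply(trip, `[`, character(1), 1),
    relation = vapply(trip, `[`, character(1), 2),
    tail = vapply(trip, `[`, character(1), 3)
  ))
  # definition-style annotation texts: like real GO definitions, terms share
  # some vocabulary but differ in their content words
  cc_defs <- c(
    nucleoplasm = "soluble phase of the nucleus excluding chromatin and nucleolus where splicing factors diffuse",
    nucleolus = "dense ribosome factory subcompartment around ribosomal dna repeats driving rrna synthesis",
    cytoplasm = "aqueous cytosol between plasma membrane and nucleus hosting translation and metabolism",
    membrane = "lipid bilayer delimiting the cell surface with integral transporters and receptors",
    vesicles = "small membrane bounded carriers trafficking cargo between endosomal and secretory compartments",
    er = "membranous network of tubules and sheets continuous with the nuclear envelope folding secreted proteins",
    golgi = "stacked flattened cisternae receiving vesicular traffic for glycosylation and sorting",
    focal_adhesions = "integrin based contact plaques anchoring actin stress fibers to the extracellular matrix",
    cell_contact = "junctional interface zone where neighboring cells adhere through cadherin complexes",
    cellular_anatomical_entity = "root anatomical structure term subsuming all cellular components"
  )
  go <- entities$entity[entities$category != "protein"]
  text_of <- function(e) {
    key <- sub("^GO:CC:", "", e)
    if (startsWith(e, "GO:CC:") && key %in% names(cc_defs)) {
      paste("cellular component:", cc_defs[[key]])
    } else if (startsWith(e, "GO:MF:")) {
      paste("molecular function: catalytic or binding activity number", sub("GO:MF:", "", e),
            "acting on", c("nucleotides", "lipids", "peptides", "ions", "sugars", "cofactors")[
              (as.integer(sub("GO:MF:", "", e)) - 1L) %% 6L + 1L])
    } else {
      paste("biological process: regulation pathway number", sub("GO:BP:", "", e),
            "controlling", c("division", "signaling", "transport", "adhesion", "stress response",
                             "differentiation")[(as.integer(sub("GO:BP:", "", e)) - 1L) %% 6L + 1L])
    }
  }
  go_texts <- tibble::tibble(entity = go,
                             text = vapply(go, text_of, character(1)))
  knowledge_graph(entities,
                  relations = unique(triples$relation),
                  triples = triples, go_texts = go_texts)
}
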