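# Knowledge-graph embedding: the four scoring functions (TransE, RotatE,
# PairRE, ComplEx) with analytic gradients, head inversion for pooled protein
# knowledge features, category-aware negative sampling, and a deterministic
# text-hashing embedder for GO annotation texts.
#
# Conventions: entity vectors of even length split into real/imaginary halves
# for RotatE and ComplEx. Lower score = more plausible triple (ComplEx's
# trilinear similarity is negated). PairRE follows its original formulation:
# entity embeddings are kept unit-norm where they are created or updated
# (a model-level constraint), and the score uses vectors as given, which
# makes exact head inversion possible.

#' Knowledge-graph embedding model
#'
#' Holds the scoring-function choice, relation parameters, GO-term
#' embeddings, the text adapter that maps annotation-text features to
#' `entity_dim`, and the contrastive-loss hyperparameters `gamma` (margin)
#' and `n_negatives`.
#'
#' @param method One of `"transe"`, `"rotate"`, `"pairre"`, `"complex"`.
#' @param entity_dim Embedding dimension; must be even for RotatE/ComplEx.
#' @param relations Character vector of relation identifiers.
#' @param gamma Margin of the contrastive loss (default 6).
#' @param n_negatives Negatives sampled per positive triple (default 8).
#' @param text_dim Dimension of the raw text features fed to the adapter.
#' @param transe_norm `"l2"` (default) or `"l1"`.
#' @param seed Integer seed for parameter initialization.
#' @return A list of class `subloc3d_kge`.
#' @export
kge_model <- function(method = c("pairre", "transe", "rotate", "complex"),
                      entity_dim = 32L, relations = character(),
                      gamma = 6, n_negatives = 8L, text_dim = 64L,
                      transe_norm = c("l2", "l1"), seed = 1L) {
  method <- match.arg(method)
  transe_norm <- match.arg(transe_norm)
  stopifnot(entity_dim >= 2, gamma > 0, n_negatives >= 1)
  if (method %in% c("rotate", "complex") && entity_dim %% 2 != 0) {
    stop("entity_dim must be even for ", method)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- entity_dim %/% 2L
  rel_par <- lapply(relations, function(r) {
    switch(method,
      transe = list(emb = stats::rnorm(entity_dim, sd = 0.5)),
      rotate = list(phase = stats::runif(half, -pi, pi)),
      pairre = list(rH = 1 + stats::rnorm(entity_dim, sd = 0.2),
                    rT = 1 + stats::rnorm(entity_dim, sd = 0.2)),
      complex = list(emb = stats::rnorm(entity_dim, sd = 0.5))
    )
  })
  names(rel_par) <- relations
  adapter <- dense_init(text_dim, entity_dim)
  structure(
    list(method = method, entity_dim = as.integer(entity_dim),
         relations = relations, relation_parameters = rel_par,
         go_embeddings = list(emb = NULL),   # entity_dim x n_go, named cols
         text_adapter = adapter, protein_adapter = NULL,
         gamma = gamma, n_negatives = as.integer(n_negatives),
         transe_norm = transe_norm, text_dim = as.integer(text_dim),
         seed = as.integer(seed)),
    class = "subloc3d_kge"
  )
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @noRd
rel_params <- function(model, r_id) {
  rp <- model$relation_parameters[[r_id]]
  if (is.null(rp)) stop("unknown relation: ", r_id)
  rp
}

#' Score a triple
#'
#' Returns the scoring-function value d(h, r, t); lower values indicate a
#' more plausible triple. TransE: `||h + r - t||`; RotatE: `||h o r - t||`
#' with unit-modulus complex rotations; PairRE: `||h o rH - t o rT||`
#' (entities maintained unit-norm by the model); ComplEx: negated real part
#' of the trilinear product `<h, r, conj(t)>`.
#'
#' @param model A [kge_model()].
#' @param h_vec,t_vec Entity vectors of length `entity_dim`.
#' @param r_id Relation identifier.
#' @return Scalar score.
#' @export
score_triple <- function(model, h_vec, r_id, t_vec) {
  if (length(h_vec) != model$entity_dim || length(t_vec) != model$entity_dim) {
    stop("entity vectors must have length entity_dim = ", model$entity_dim)
  }
  drop(score_tails(model, h_vec, r_id, matrix(t_vec, ncol = 1)))
}

#' @noRd
split_complex <- function(v) {
  m <- length(v) %/% 2L
  list(re = v[seq_len(m)], im = v[m + seq_len(m)])
}

#' Score one head against many candidate tails
#'
#' @param model A [kge_model()].
#' @param h_vec Head entity vector.
#' @param r_id Relation identifier.
#' @param t_mat Matrix with one candidate tail per column.
#' @return Numeric vector of scores, one per column of `t_mat`.
#' @export
score_tails <- function(model, h_vec, r_id, t_mat) {
  rp <- rel_params(model, r_id)
  if (nrow(t_mat) != model$entity_dim) stop("tail dimension mismatch")
  switch(model$method,
    transe = {
      e <- (h_vec + rp$emb) - t_mat
      if (model$transe_norm == "l1") colSums(abs(e)) else sqrt(colSums(e * e))
    },
    rotate = {
      h <- split_complex(h_vec)
      hr_re <- h$re * cos(rp$phase) - h$im * sin(rp$phase)
      hr_im <- h$re * sin(rp$phase) + h$im * cos(rp$phase)
      m <- length(rp$phase)
      er <- hr_re - t_mat[seq_len(m), , drop = FALSE]
      ei <- hr_im - t_mat[m + seq_len(m), , drop = FALSE]
      sqrt(colSums(er * er) + colSums(ei * ei))
    },
    pairre = {
      e <- h_vec * rp$rH - t_mat * rp$rT
      sqrt(colSums(e * e))
    },
    complex = {
      h <- split_complex(h_vec)
      r <- split_complex(rp$emb)
      m <- length(h$re)
      tr <- t_mat[seq_len(m), , drop = FALSE]
      ti <- t_mat[m + seq_len(m), , drop = FALSE]
      a <- h$re * r$re - h$im * r$im
      b <- h$re * r$im + h$im * r$re
      -(colSums(a * tr) + colSums(b * ti))
    }
  )
}

# Gradient of sum_k coef_k * d(h, r, t_k) w.r.t. h, the relation parameters,
# and each tail column. Used by the trainer; verified against finite
# differences in the tests.
#' @noRd
score_tails_grad <- function(model, h_vec, r_id, t_mat, coef) {
  rp <- rel_params(model, r_id)
  K <- ncol(t_mat)
  switch(model$method,
    transe = {
      e <- (h_vec + rp$emb) - t_mat
      if (model$transe_norm == "l1") {
        g <- sign(e)
      } else {
        d <- sqrt(colSums(e * e))
        g <- sweep(e, 2L, ifelse(d > 1e-12, 1 / d, 0), `*`)
      }
      gc_ <- sweep(g, 2L, coef, `*`)
      s <- rowSums(gc_)
      list(dh = s, drel = list(emb = s), dT = -gc_)
    },
    rotate = {
      h <- split_complex(h_vec)
      cth <- cos(rp$phase); sth <- sin(rp$phase)
      hr_re <- h$re * cth - h$im * sth
      hr_im <- h$re * sth + h$im * cth
      m <- length(rp$phase)
      er <- hr_re - t_mat[seq_len(m), , drop = FALSE]
      ei <- hr_im - t_mat[m + seq_len(m), , drop = FALSE]
      d <- sqrt(colSums(er * er) + colSums(ei * ei))
      w <- ifelse(d > 1e-12, coef / d, 0)
      erw <- sweep(er, 2L, w, `*`)
      eiw <- sweep(ei, 2L, w, `*`)
      sr <- rowSums(erw); si <- rowSums(eiw)
      dh_re <- sr * cth + si * sth
      dh_im <- -sr * sth + si * cth
      dphase <- -sr * hr_im + si * hr_re
      list(dh = c(dh_re, dh_im), drel = list(phase = dphase),
           dT = rbind(-erw, -eiw))
    },
    pairre = {
      e <- h_vec * rp$rH - t_mat * rp$rT
      d <- sqrt(colSums(e * e))
      w <- ifelse(d > 1e-12, coef / d, 0)
      ew <- sweep(e, 2L, w, `*`)
      s <- rowSums(ew)
      list(dh = s * rp$rH,
           drel = list(rH = s * h_vec, rT = -rowSums(ew * t_mat)),
           dT = -ew * rp$rT)
    },
    complex = {
      h <- split_complex(h_vec)
      r <- split_complex(rp$emb)
      m <- length(h$re)
      tr <- t_mat[seq_len(m), , drop = FALSE]
      ti <- t_mat[m + seq_len(m), , drop = FALSE]
      trc <- sweep(tr, 2L, coef, `*`)
      tic <- sweep(ti, 2L, coef, `*`)
      str_ <- rowSums(trc); sti <- rowSums(tic)
      a <- h$re * r$re - h$im * r$im
      b <- h$re * r$im + h$im * r$re
      dh_re <- -(r$re * str_ + r$im * sti)
      dh_im <- -(-r$im * str_ + r$re * sti)
      dr_re <- -(h$re * str_ + h$im * sti)
      dr_im <- -(-h$im * str_ + h$re * sti)
      dT <- rbind(sweep(matrix(-a, m, K), 2L, coef, `*`),
                  sweep(matrix(-b, m, K), 2L, coef, `*`))
      list(dh = c(dh_re, dh_im), drel = list(emb = c(dr_re, dr_im)), dT = dT)
    }
  )
}

#' Implied head of a (relation, tail) pair
#'
#' Solves d(h, r, t) = 0 for the head: `t - r` (TransE), the inverse rotation
#' of `t` (RotatE), `(t o rT) / rH` (PairRE). ComplEx has no exact inverse
#' and raises an error; see [knowledge_feature()] for its pooling surrogate.
#'
#' @param model A [kge_model()].
#' @param r_id Relation identifier.
#' @param t_vec Tail entity vector.
#' @return Head vector of length `entity_dim`.
#' @export
invert_head <- function(model, r_id, t_vec) {
  rp <- rel_params(model, r_id)
  switch(model$method,
    transe = t_vec - rp$emb,
    rotate = {
      t <- split_complex(t_vec)
      c(t$re * cos(rp$phase) + t$im * sin(rp$phase),
        -t$re * sin(rp$phase) + t$im * cos(rp$phase))
    },
    pairre = {
      bad <- which(abs(rp$rH) < 1e-8)
      if (length(bad)) {
        stop("PairRE head inversion undefined: |rH| ~ 0 at coordinate ", bad[1])
      }
      (t_vec * rp$rT) / rp$rH
    },
    complex = stop("ComplEx does not support exact head inversion; ",
                   "knowledge_feature() pools t o conj(r) instead")
  )
}

#' Pooled knowledge feature of a protein
#'
#' Averages the implied heads of the protein's protein-to-GO triples under
#' the current GO embeddings (for ComplEx, the rotated-back tails
#' `t o conj(r)` in real/imaginary layout). Proteins with no triples get a
#' zero vector and `present = FALSE`.
#'
#' @param model A [kge_model()] with GO embeddings set (see
#'   [embed_go_terms()]).
#' @param protein_id Protein entity identifier.
#' @param graph A filtered [knowledge_graph()].
#' @return `list(feature = numeric(entity_dim), present = logical(1))`.
#' @export
knowledge_feature <- function(model, protein_id, graph) {
  cat_of <- entity_categories(graph)
  tr <- graph$triples
  mine <- tr[tr$head == protein_id & cat_of[tr$tail] != "protein", ]
  emb <- model$go_embeddings$emb
  have <- mine$tail %in% colnames(emb) & mine$relation %in% names(model$relation_parameters)
  mine <- mine[have, ]
  if (!nrow(mine)) {
    return(list(feature = numeric(model$entity_dim), present = FALSE))
  }
  heads <- vapply(seq_len(nrow(mine)), function(i) {
    t_vec <- emb[, mine$tail[i]]
    if (model$method == "complex") {
      t <- split_complex(t_vec)
      r <- split_complex(rel_params(model, mine$relation[i])$emb)
      c(t$re * r$re + t$im * r$im, t$im * r$re - t$re * r$im)
    } else {
      invert_head(model, mine$relation[i], t_vec)
    }
  }, numeric(model$entity_dim))
  list(feature = rowMeans(heads), present = TRUE)
}

#' Category-aware negative sampling
#'
#' Corrupts the tail of a triple by sampling uniformly (with replacement)
#' from the other entities of the same category as the true tail; head and
#' relation are kept.
#'
#' @param graph A [knowledge_graph()].
#' @param triple List or one-row data frame with `head`, `relation`, `tail`.
#' @param n Number of negatives.
#' @return Tibble of `n` corrupted triples.
#' @export
sample_negatives <- function(graph, triple, n) {
  cat_of <- entity_categories(graph)
  tcat <- cat_of[[triple$tail]]
  members <- graph$entities$entity[graph$entities$category == tcat]
  alts <- setdiff(members, triple$tail)
  if (!length(alts)) {
    stop("cannot corrupt tail: category '", tcat, "' has a single member")
  }
  tails <- if (length(alts) == 1L) rep(alts, n) else sample(alts, n, replace = TRUE)
  tibble::tibble(head = triple$head, relation = triple$relation, tail = tails)
}

# ---- GO text embedding -------------------------------------------------------

#' Deterministic character n-gram hashing text embedder
#'
#' Feature-hashes lowercase character trigrams into `dim` signed buckets and
#' L2-normalizes; the same text always maps to the same vector. A pre-trained
#' biomedical text encoder can be plugged in through the same interface
#' (a list with `dim` and `embed(texts) -> dim x n matrix`).
#'
#' @param dim Output dimension (default 64).
#' @param seed Integer mixed into the hash.
#' @param n N-gram length (default 3).
#' @return A list of class `subloc3d_text_embedder`.
#' @export
hashing_text_embedder <- function(dim = 64L, seed = 1L, n = 3L) {
  dim <- as.integer(dim)
  mult <- 31 + 2 * (as.integer(seed) %% 1000L)
  embed_one <- function(text) {
    s <- tolower(text)
    codes <- utf8ToInt(paste0("^", s, "$"))
    v <- numeric(dim)
    if (length(codes) >= n) {
      for (i in seq_len(length(codes) - n + 1L)) {
        hsh <- 0
        for (j in 0:(n - 1L)) hsh <- (hsh * mult + codes[i + j]) %% 1048573
        bucket <- (hsh %% dim) + 1L
        sgn <- if ((hsh %/% dim) %% 2 == 0) 1 else -1
        v[bucket] <- v[bucket] + sgn
      }
    }
    nv <- sqrt(sum(v * v))
    if (nv > 0) v / nv else v
  }
  structure(
    list(dim = dim,
         embed = function(texts) vapply(texts, embed_one, numeric(dim))),
    class = "subloc3d_text_embedder"
  )
}

#' Initialize GO embeddings from annotation texts
#'
#' Runs every GO entity's annotation text through the embedder and the
#' model's linear text adapter; for PairRE the resulting embeddings are
#' projected to the unit sphere (the model's entity-norm constraint). GO
#' embeddings remain trainable afterwards.
#'
#' @param model A [kge_model()].
#' @param graph A [knowledge_graph()] whose GO entities all carry text.
#' @param embedder A text embedder; default [hashing_text_embedder()] with
#'   the model's seed.
#' @return The model with `go_embeddings` set (columns named by entity).
#' @export
embed_go_terms <- function(model, graph,
                           embedder = hashing_text_embedder(model$text_dim,
                                                            model$seed)) {
  if (embedder$dim != model$text_dim) {
    stop("embedder dimension must equal model$text_dim")
  }
  go <- graph$entities$entity[graph$entities$category != "protein"]
  txt <- stats::setNames(graph$go_texts$text, graph$go_texts$entity)
  miss <- go[!go %in% names(txt)]
  if (length(miss)) stop("missing GO annotation text for entity: ", miss[1])
  raw <- embedder$embed(unname(txt[go]))
  emb <- model$text_adapter$W %*% raw + model$text_adapter$b
  if (model$method == "pairre") {
    nrm <- sqrt(colSums(emb * emb))
    emb <- sweep(emb, 2L, pmax(nrm, 1e-12), `/`)
  }
  colnames(emb) <- go
  model$go_embeddings$emb <- emb
  model
}
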