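# Scoring functions against an independent complex-arithmetic oracle,
# head inversion, negative sampling, and the text embedder.

# Independent brute-force oracle using R's complex numbers.
oracle_score <- function(method, h, rp, t) {
  m <- length(h) / 2
  switch(method,
    transe = sqrt(sum((h + rp$emb - t)^2)),
    rotate = {
      hc <- complex(real = h[1:m], imaginary = h[m + 1:m])
      tc <- complex(real = t[1:m], imaginary = t[m + 1:m])
      rot <- exp(1i * rp$phase)
      sqrt(sum(Mod(hc * rot - tc)^2))
    },
    pairre = sqrt(sum((h * rp$rH - t * rp$rT)^2)),
    complex = {
      hc <- complex(real = h[1:m], imaginary = h[m + 1:m])
      tc <- complex(real = t[1:m], imaginary = t[m + 1:m])
      rc <- complex(real = rp$emb[1:m], imaginary = rp$emb[m + 1:m])
      -Re(sum(hc * rc * Conj(tc)))
    })
}

test_that("all four scoring functions agree with the brute-force oracle", {
  set.seed(21)
  for (method in c("transe", "rotate", "pairre", "complex")) {
    model <- kge_model(method, entity_dim = 4, relations = "r", seed = 5)
    for (i in 1:100) {
      h <- rnorm(4); t <- rnorm(4)
      if (method == "pairre") {
        h <- h / sqrt(sum(h^2)); t <- t / sqrt(sum(t^2))
      }
      d <- score_triple(model, h, "r", t)
      expect_equal(d, oracle_score(method, h, model$relation_parameters$r, t),
                   tolerance = 1e-8)
    }
  }
})

test_that("scoring special cases evaluate exactly", {
  mt <- kge_model("transe", entity_dim = 2, relations = "r")
  mt$relation_parameters$r$emb <- c(0, 1)
  expect_equal(score_triple(mt, c(1, 0), "r", c(1, 1)), 0, tolerance = 1e-12)
  expect_equal(invert_head(mt, "r", c(1, 1)), c(1, 0))

  mr <- kge_model("rotate", entity_dim = 4, relations = "r")
  mr$relation_parameters$r$phase <- c(0, 0)
  h <- rnorm(4); t <- rnorm(4)
  expect_equal(score_triple(mr, h, "r", t), sqrt(sum((h - t)^2)),
               tolerance = 1e-12)
  expect_equal(invert_head(mr, "r", t), t)

  mp <- kge_model("pairre", entity_dim = 3, relations = "r")
  mp$relation_parameters$r$rH <- rep(1, 3)
  mp$relation_parameters$r$rT <- rep(1, 3)
  hn <- c(1, 2, 2) / 3
  expect_equal(score_triple(mp, hn, "r", hn), 0, tolerance = 1e-12)

  mc <- kge_model("complex", entity_dim = 2, relations = "r")
  mc$relation_parameters$r$emb <- c(1, 0)
  expect_equal(score_triple(mc, c(1, 0), "r", c(1, 0)), -1, tolerance = 1e-12)
  expect_error(invert_head(mc, "r", c(1, 0)), "ComplEx")
})

test_that("head inversion is score-consistent for the invertible methods", {
  set.seed(9)
  for (method in c("transe", "rotate", "pairre")) {
    model <- kge_model(method, entity_dim = 8, relations = "r", seed = 2)
    for (i in 1:100) {
      t <- rnorm(8)
      if (method == "pairre") t <- t / sqrt(sum(t^2))
      h <- invert_head(model, "r", t)
      expect_lt(score_triple(model, h, "r", t), 1e-6)
    }
  }
  # PairRE refuses inversion when a relation coordinate vanishes
  mp <- kge_model("pairre", entity_dim = 4, relations = "r")
  mp$relation_parameters$r$rH[2] <- 0
  expect_error(invert_head(mp, "r", c(0.5, 0.5, 0.5, 0.5)), "coordinate 2")
})

test_that("rotations preserve the head norm and scores are permutation-invariant", {
  set.seed(4)
  mr <- kge_model("rotate", entity_dim = 8, relations = "r", seed = 3)
  h <- rnorm(8)
  ph <- mr$relation_parameters$r$phase
  hc <- complex(real = h[1:4], imaginary = h[5:8])
  expect_equal(sum(Mod(hc * exp(1i * ph))^2), sum(Mod(hc)^2), tolerance = 1e-10)

  # joint permutation of complex coordinates leaves every method invariant
  for (method in c("transe", "rotate", "pairre", "complex")) {
    model <- kge_model(method, entity_dim = 8, relations = "r", seed = 7)
    h <- rnorm(8); t <- rnorm(8)
    if (method == "pairre") { h <- h / sqrt(sum(h^2)); t <- t / sqrt(sum(t^2)) }
    d0 <- score_triple(model, h, "r", t)
    perm <- sample(4)   # permute complex pairs jointly (re and im together)
    pidx <- c(perm, 4 + perm)
    model2 <- model
    rp <- model$relation_parameters$r
    model2$relation_parameters$r <- switch(method,
      transe = list(emb = rp$emb[pidx]),
      rotate = list(phase = rp$phase[perm]),
      pairre = list(rH = rp$rH[pidx], rT = rp$rT[pidx]),
      complex = list(emb = rp$emb[pidx]))
    expect_equal(score_triple(model2, h[pidx], "r", t[pidx]), d0,
                 tolerance = 1e-10)
  }
})

test_that("score gradients match finite differences for every method", {
  set.seed(12)
  sg <- subloc3d:::score_tails_grad
  for (method in c("transe", "rotate", "pairre", "complex")) {
    model <- kge_model(method, entity_dim = 6, relations = "r", seed = 8)
    h <- rnorm(6); Tm <- matrix(rnorm(12), 6, 2); coef <- runif(2)
    g <- sg(model, h, "r", Tm, coef)
    eps <- 1e-6
    for (i in 1:6) {
      hp <- h; hp[i] <- hp[i] + eps
      hm <- h; hm[i] <- hm[i] - eps
      num <- sum(coef * (score_tails(model, hp, "r", Tm) -
                           score_tails(model, hm, "r", Tm))) / (2 * eps)
      expect_equal(g$dh[i], num, tolerance = 1e-4)
    }
  }
})

test_that("knowledge features pool implied heads with a zero-vector fallback", {
  g <- toy_graph()
  model <- kge_model("transe", entity_dim = 16, relations = g$relations,
                     seed = 1)
  model <- embed_go_terms(model, g)
  # p3 has exactly one triple (p3 -> g1): feature equals that implied head
  f3 <- knowledge_feature(model, "p3", g)
  expect_true(f3$present)
  expect_equal(f3$feature,
               invert_head(model, "located_in",
                           model$go_embeddings$emb[, "g1"]))
  # a protein with no triples gets zeros and the absent flag
  fx <- knowledge_feature(model, "p_absent", g)
  expect_false(fx$present)
  expect_equal(fx$feature, numeric(16))
  # identical implied heads average to themselves
  f1 <- knowledge_feature(model, "p1", g)
  heads <- sapply(c("g1", "g2", "g3"), function(gg) {
    invert_head(model, "located_in", model$go_embeddings$emb[, gg])
  })
  expect_equal(f1$feature, rowMeans(heads))
})

test_that("negative sampling respects the tail category and is uniform", {
  g <- toy_graph()
  trip <- list(head = "p1", relation = "located_in", tail = "g1")
  set.seed(5)
  negs <- sample_negatives(g, trip, 50)
  cat_of <- setNames(g$entities$category, g$entities$entity)
  expect_true(all(cat_of[negs$tail] == "CC"))
  expect_true(all(negs$tail != "g1"))
  # category of size 2: the single alternative is always drawn
  trip_mf <- list(head = "p1", relation = "enables", tail = "m1")
  negs_mf <- sample_negatives(g, trip_mf, 10)
  expect_true(all(negs_mf$tail == "m2"))
  # singleton category errors
  g1 <- g
  g1$entities <- g1$entities[g1$entities$entity != "m2", ]
  g1$triples <- g1$triples[g1$triples$tail != "m2" & g1$triples$head != "m2", ]
  expect_error(sample_negatives(g1, trip_mf, 3), "single member")
})

test_that("the hashing text embedder is deterministic with the right shape", {
  emb <- hashing_text_embedder(dim = 64, seed = 3)
  v1 <- emb$embed(c("membrane transporter activity", "nucleolar protein"))
  v2 <- emb$embed(c("membrane transporter activity", "nucleolar protein"))
  expect_identical(v1, v2)
  expect_equal(dim(v1), c(64L, 2L))
  expect_identical(v1[, 1], emb$embed("membrane transporter activity")[, 1])
  expect_false(isTRUE(all.equal(v1[, 1], v1[, 2])))
  # embeddings through the model adapter land in entity_dim, deterministically
  g <- toy_graph()
  m1 <- embed_go_terms(kge_model("transe", entity_dim = 12,
                                 relations = g$relations, seed = 2), g)
  m2 <- embed_go_terms(kge_model("transe", entity_dim = 12,
                                 relations = g$relations, seed = 2), g)
  expect_identical(m1$go_embeddings$emb, m2$go_embeddings$emb)
  expect_equal(nrow(m1$go_embeddings$emb), 12L)
  # missing text errors with the entity name
  gbad <- g
  gbad$go_texts <- gbad$go_texts[gbad$go_texts$entity != "g2", ]
  expect_error(embed_go_terms(kge_model("transe", entity_dim = 12,
                                        relations = g$relations), gbad), "g2")
})
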