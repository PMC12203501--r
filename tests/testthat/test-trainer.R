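# Training loop wiring: determinism, ablation equivalence, knowledge-path
# bookkeeping, and prediction contracts. All runs are deliberately tiny.

tiny_setup <- function(seed = 3, n_proteins = 6, cells = 4) {
  sim <- tiny_dataset(n_proteins = n_proteins, cells_per_protein = cells,
                      seed = seed, shape = c(8, 16, 16))
  table <- apply_split(sim$table, split_by_protein(sim$table, seed = seed))
  table
}

tiny_config <- function(table, entity_dim = 16L) {
  encoder_config(n_classes = length(table$class_vocabulary),
                 n_proteins = length(table$protein_index),
                 n_blocks = 2L, base_channels = 4L, fused_dim = 24L,
                 knowledge_dim = 8L, knowledge_input_dim = entity_dim)
}

test_that("training is deterministic under a fixed seed", {
  table <- tiny_setup()
  ctl <- train_config(epochs = 2, seed = 9, validate = FALSE, entity_dim = 16)
  f1 <- train(table, NULL, tiny_config(table), control = ctl)
  f2 <- train(table, NULL, tiny_config(table), control = ctl)
  expect_equal(f1$history$total, f2$history$total, tolerance = 1e-10)
  expect_identical(f1$net$cls$W, f2$net$cls$W)
  ctl2 <- train_config(epochs = 2, seed = 10, validate = FALSE, entity_dim = 16)
  f3 <- train(table, NULL, tiny_config(table), control = ctl2)
  expect_false(identical(f1$net$cls$W, f3$net$cls$W))
})

test_that("disabling the knowledge loss reproduces the image-only model", {
  table <- tiny_setup()
  graph <- filter_sproteinkg(simulate_kg(table, seed = 1),
                             names(table$protein_index))
  ctl <- train_config(epochs = 2, seed = 5, validate = FALSE, entity_dim = 16)
  f_img <- train(table, NULL, tiny_config(table),
                 loss = loss_config(w_ke = 0, w_id = 0), control = ctl)
  f_k0 <- train(table, graph, tiny_config(table),
                loss = loss_config(w_ke = 0, w_id = 0), control = ctl)
  expect_equal(f_img$history$total, f_k0$history$total, tolerance = 1e-12)
  expect_identical(f_img$net$cls$W, f_k0$net$cls$W)
  # k = 0 triples per cell behaves the same way
  ctl0 <- train_config(epochs = 2, seed = 5, validate = FALSE,
                       entity_dim = 16, triples_per_cell = 0)
  f_tk0 <- train(table, graph, tiny_config(table),
                 loss = loss_config(w_ke = 0, w_id = 0), control = ctl0)
  expect_identical(f_img$net$cls$W, f_tk0$net$cls$W)
})

test_that("joint knowledge training moves KGE parameters and logs components", {
  table <- tiny_setup()
  graph <- filter_sproteinkg(simulate_kg(table, seed = 1),
                             names(table$protein_index))
  ctl <- train_config(epochs = 2, seed = 5, validate = FALSE, entity_dim = 16)
  fit <- train(table, graph, tiny_config(table), control = ctl)
  expect_false(is.null(fit$kge))
  expect_true(all(fit$history$l_ke > 0))
  # GO embeddings and relation parameters were actually updated
  init <- embed_go_terms(kge_model("pairre", entity_dim = 16,
                                   relations = graph$relations, seed = 5,
                                   gamma = 6, n_negatives = 8), graph)
  expect_false(isTRUE(all.equal(init$go_embeddings$emb,
                                fit$kge$go_embeddings$emb)))
  # training log CSV on request
  d <- withr::local_tempdir()
  ctl_log <- train_config(epochs = 1, seed = 5, validate = FALSE,
                          entity_dim = 16,
                          log_path = file.path(d, "log.csv"))
  train(table, graph, tiny_config(table), control = ctl_log)
  logdf <- read.csv(file.path(d, "log.csv"))
  expect_setequal(names(logdf),
                  c("epoch", "l_slc", "l_ke", "l_id", "total", "val_mmcc"))
})

test_that("prediction is repeatable, flags knowledge use, and thresholds calls", {
  table <- tiny_setup()
  graph <- filter_sproteinkg(simulate_kg(table, seed = 1),
                             names(table$protein_index))
  ctl <- train_config(epochs = 1, seed = 5, validate = FALSE, entity_dim = 16)
  fit <- train(table, graph, tiny_config(table), control = ctl)
  test <- table
  test$samples <- Filter(function(s) s$split == "test", table$samples)
  p1 <- predict(fit, test, graph = graph)
  p2 <- predict(fit, test, graph = graph)
  expect_identical(p1$probs, p2$probs)
  # held-out proteins carry triples, so the knowledge path is active
  expect_true(all(p1$meta$knowledge_used))
  # absent graph falls back to the zero knowledge feature
  p0 <- predict(fit, test)
  expect_true(all(!p0$meta$knowledge_used))
  expect_identical(p1$calls, p1$probs >= 0.5)
  tb <- as_tibble(p1)
  expect_true(all(table$class_vocabulary %in% names(tb)))
  # validation bookkeeping recorded the best epoch when enabled
  ctl_v <- train_config(epochs = 2, seed = 5, entity_dim = 16)
  fv <- train(table, graph, tiny_config(table), control = ctl_v)
  expect_true(is.finite(fv$best_val_mmcc))
  expect_s3_class(glance(fv), "tbl_df")
  expect_identical(nrow(tidy(fv)), 2L)
})

test_that("a protein without triples contributes zero knowledge loss once-warned", {
  table <- tiny_setup()
  graph <- simulate_kg(table, seed = 1)
  # strip the triples of a protein that has training cells
  victim <- Filter(function(s) s$split == "train", table$samples)[[1]]$protein_id
  graph$triples <- graph$triples[graph$triples$head != victim, ]
  graph <- filter_sproteinkg(graph, names(table$protein_index))
  ctl <- train_config(epochs = 1, seed = 5, validate = FALSE, entity_dim = 16)
  expect_warning(
    fit <- train(table, graph, tiny_config(table), control = ctl),
    victim
  )
  expect_true(all(is.finite(fit$history$total)))
})
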