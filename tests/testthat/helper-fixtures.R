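# Shared fixtures, all generated in code.

# A tiny annotated dataset with in-memory volumes.
tiny_dataset <- function(n_proteins = 6, cells_per_protein = 4, seed = 11,
                         classes = c("nucleoplasm", "membrane", "cytoplasm"),
                         ...) {
  cfg <- sim_config(n_proteins = n_proteins,
                    cells_per_protein = cells_per_protein,
                    classes = classes, seed = seed, ...)
  simulate_dataset(cfg)
}

# Hand-enumerable knowledge graph: tagged proteins p1..p4 (p5 untagged in
# filter tests), GO terms g1..g3 with designed protein degrees.
toy_graph <- function() {
  entities <- tibble::tibble(
    entity = c("p1", "p2", "p3", "p4", "p5", "g1", "g2", "g3", "m1", "m2"),
    category = c(rep("protein", 5), "CC", "CC", "CC", "MF", "MF")
  )
  triples <- tibble::tibble(
    head = c("p1", "p2", "p3", "p1", "p2", "p4", "p5", "p1",
             "g1", "g1", "g3"),
    relation = c(rep("located_in", 8), "is_a", "is_a", "is_a"),
    tail = c("g1", "g1", "g1", "g2", "g2", "g2", "g3", "g3",
             "g2", "g3", "g2")
  )
  texts <- tibble::tibble(
    entity = c("g1", "g2", "g3", "m1", "m2"),
    text = paste("annotation text for term", c("g1", "g2", "g3", "m1", "m2"))
  )
  knowledge_graph(entities, unique(triples$relation), triples, texts)
}

# One-bright-voxel multicell volume for crop arithmetic.
point_volume <- function(z = 6, y = 16, x = 16, at = c(3, 8, 8)) {
  v <- array(0, c(2, z, y, x))
  v[2, at[1] + 1, at[2] + 1, at[3] + 1] <- 1
  v[1, , , ] <- 0.1
  v
}
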