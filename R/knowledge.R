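# Knowledge-graph container, TSV I/O, and the tagged-protein filtering rule
# that reduces a large protein/GO graph to the study-relevant subgraph.

#' Construct a knowledge graph
#'
#' Entities are categorized as `protein` or GO namespaces (`CC`, `MF`, `BP`);
#' triples are (head, relation, tail) rows; GO entities may carry annotation
#' text used to initialize their embeddings.
#'
#' @param entities Tibble/data.frame with columns `entity`, `category`.
#' @param relations Character vector of relation identifiers.
#' @param triples Tibble/data.frame with columns `head`, `relation`, `tail`.
#' @param go_texts Tibble/data.frame with columns `entity`, `text` (GO
#'   entities only); may be empty.
#' @return A list of class `subloc3d_kg`.
#' @export
knowledge_graph <- function(entities, relations, triples,
                            go_texts = tibble::tibble(entity = character(),
                                                      text = character())) {
  entities <- tibble::as_tibble(entities)
  triples <- tibble::as_tibble(triples)
  go_texts <- tibble::as_tibble(go_texts)
  stopifnot(all(c("entity", "category") %in% names(entities)),
            all(c("head", "relation", "tail") %in% names(triples)))
  if (anyDuplicated(entities$entity)) stop("duplicate entity ids")
  bad_cat <- setdiff(unique(entities$category), c("protein", "CC", "MF", "BP"))
  if (length(bad_cat)) stop("unknown entity categories: ", paste(bad_cat, collapse = ", "))
  known <- entities$entity
  miss <- setdiff(unique(c(triples$head, triples$tail)), known)
  if (length(miss)) stop("triples reference unknown entities: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (length(setdiff(unique(triples$relation), relations))) {
    stop("triples use relations not in the relation list")
  }
  if (anyDuplicated(triples[c("head", "relation", "tail")])) {
    stop("duplicate triples")
  }
  cat_of <- stats::setNames(entities$category, entities$entity)
  pg <- cat_of[triples$head] == "protein"
  if (any(pg & cat_of[triples$tail] == "protein")) {
    stop("protein entities must not appear as tails of protein-headed triples")
  }
  structure(list(entities = entities, relations = relations,
                 triples = triples, go_texts = go_texts),
            class = "subloc3d_kg")
}

#' @export
print.subloc3d_kg <- function(x, ...) {
  cat("<subloc3d knowledge graph>\n")
  cat("  entities:", nrow(x$entities),
      sprintf("(%s)", paste(names(table(x$entities$category)),
                            table(x$entities$category),
                            sep = "=", collapse = ", ")), "\n")
  cat("  relations:", length(x$relations), "\n")
  cat("  triples:", nrow(x$triples), "\n")
  invisible(x)
}

#' @noRd
entity_categories <- function(graph) {
  stats::setNames(graph$entities$category, graph$entities$entity)
}

#' Filter a protein/GO graph to the tagged-protein subgraph
#'
#' Protein-to-GO triples are kept only when their head is a tagged protein.
#' GO-to-GO triples are kept only when both GO entities are each related,
#' through the kept protein-to-GO triples, to strictly more than two tagged
#' proteins. Entities no longer touched by any kept triple are dropped.
#' The operation is idempotent.
#'
#' @param graph A [knowledge_graph()].
#' @param tagged_proteins Character vector of protein entity ids.
#' @return A filtered `subloc3d_kg`.
#' @export
filter_sproteinkg <- function(graph, tagged_proteins) {
  cat_of <- entity_categories(graph)
  tr <- graph$triples
  head_is_protein <- cat_of[tr$head] == "protein"
  if (!length(tagged_proteins)) {
    warning("empty tagged-protein set: no protein-GO triples survive")
  }
  pg_keep <- tr[head_is_protein & tr$head %in% tagged_proteins, ]
  deg <- if (nrow(pg_keep)) {
    tapply(pg_keep$head, pg_keep$tail, function(h) length(unique(h)))
  } else {
    stats::setNames(integer(0), character(0))
  }
  gg <- tr[!head_is_protein & cat_of[tr$head] != "protein" &
             cat_of[tr$tail] != "protein", ]
  ok <- function(e) !is.na(deg[e]) & deg[e] > 2
  gg_keep <- gg[ok(gg$head) & ok(gg$tail), ]
  kept <- dplyr::bind_rows(pg_keep, gg_keep)
  live <- unique(c(kept$head, kept$tail))
  knowledge_graph(
    entities = graph$entities[graph$entities$entity %in% live, ],
    relations = intersect(graph$relations, unique(kept$relation)),
    triples = kept,
    go_texts = graph$go_texts[graph$go_texts$entity %in% live, ]
  )
}

# ---- plain-text interchange --------------------------------------------------

#' Read/write knowledge-graph tables
#'
#' Triples are tab-separated `head<TAB>relation<TAB>tail` without a header;
#' entity categories and GO texts are two-column TSVs (`entity<TAB>category`,
#' `entity<TAB>text`), UTF-8.
#'
#' @param triples_path,categories_path,texts_path File paths; `texts_path`
#'   may be `NULL` when no annotation texts exist.
#' @return [read_knowledge_graph()] returns a `subloc3d_kg`.
#' @export
read_knowledge_graph <- function(triples_path, categories_path,
                                 texts_path = NULL) {
  tr <- utils::read.delim(triples_path, header = FALSE,
                          col.names = c("head", "relation", "tail"),
                          colClasses = "character", quote = "")
  ent <- utils::read.delim(categories_path, header = FALSE,
                           col.names = c("entity", "category"),
                           colClasses = "character", quote = "")
  texts <- if (!is.null(texts_path) && file.exists(texts_path)) {
    utils::read.delim(texts_path, header = FALSE,
                      col.names = c("entity", "text"),
                      colClasses = "character", quote = "")
  } else {
    data.frame(entity = character(), text = character())
  }
  knowledge_graph(ent, unique(tr$relation), tr, texts)
}

#' @rdname read_knowledge_graph
#' @param graph A `subloc3d_kg`.
#' @export
write_knowledge_graph <- function(graph, triples_path, categories_path,
                                  texts_path = NULL) {
  utils::write.table(graph$triples[c("head", "relation", "tail")],
                     triples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(graph$entities[c("entity", "category")],
                     categories_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(texts_path)) {
    utils::write.table(graph$go_texts[c("entity", "text")],
                       texts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(graph)
}
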