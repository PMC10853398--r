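test_that("graph construction validates endpoints and collapses duplicates", {
  g <- toy_kg()
  expect_identical(nrow(g$nodes), 6L)
  expect_identical(nrow(g$edges), 6L)
  # dangling endpoint
  expect_error(knowledge_graph(
    g$nodes, data.frame(source = "P1", target = "P9", type = "interacts")),
    "not in the node table")
  # duplicate triple collapses with a warning; distinct types may coexist
  ed <- rbind(g$edges, g$edges[1, ],
              data.frame(source = "P1", target = "P2", type = "binds",
                         directed = TRUE))
  expect_warning(g2 <- knowledge_graph(g$nodes, ed), "duplicate")
  expect_identical(nrow(g2$edges), 7L)
})

test_that("degree conservation holds on the undirected view", {
  gen <- generate_synthetic_kg(kg_config(n_proteins = 60, n_genes = 30,
                                         n_compounds = 40, n_diseases = 10,
                                         seed = 5))
  ig <- kg_as_igraph(gen$graph, simplify = FALSE)
  expect_identical(sum(igraph::degree(ig)), 2L * igraph::ecount(ig))
})

test_that("synthetic KG generation is deterministic with verifiable planted wiring", {
  cfg <- kg_config(n_proteins = 120, n_genes = 50, n_compounds = 80,
                   n_diseases = 20, n_seeds = 10, n_hidden = 5,
                   min_seed_links = 3, seed = 41)
  a <- generate_synthetic_kg(cfg)
  b <- generate_synthetic_kg(cfg)
  expect_identical(a$graph, b$graph)
  expect_identical(a$planted, b$planted)

  # planted sets disjoint; hidden wiring checked by direct adjacency count
  expect_length(intersect(a$planted$seed_proteins,
                          a$planted$hidden_proteins), 0)
  ed <- a$graph$edges
  for (h in a$planted$hidden_proteins) {
    nbr <- c(ed$target[ed$source == h & ed$type == "interacts"],
             ed$source[ed$target == h & ed$type == "interacts"])
    expect_gte(length(intersect(nbr, a$planted$seed_proteins)), 3)
    # within two hops of the disease node via a bridging compound
    compounds <- ed$source[ed$target == h & ed$type == "binds"]
    treats <- ed$source[ed$type == "treats" &
                          ed$target == a$planted$disease_node]
    expect_gte(length(intersect(compounds, treats)), 1)
  }

  # every seed protein reaches the disease node (BFS reachability)
  ig <- kg_as_igraph(a$graph)
  dist <- igraph::distances(ig, v = a$planted$seed_proteins,
                            to = a$planted$disease_node)
  expect_true(all(is.finite(dist)))
})

test_that("infeasible planted configurations are rejected", {
  expect_error(kg_config(n_proteins = 8, n_seeds = 6, n_hidden = 5),
               "not enough proteins")
  expect_error(kg_config(min_seed_links = 0), "min_seed_links")
  expect_error(kg_config(n_seeds = 2, min_seed_links = 3),
               "min_seed_links exceeds")
})

test_that("edge-list TSV round trip preserves node and edge sets", {
  gen <- generate_synthetic_kg(kg_config(n_proteins = 40, n_genes = 20,
                                         n_compounds = 25, n_diseases = 8,
                                         seed = 3))
  g <- gen$graph
  # add an isolated node to exercise node-only rows
  g <- knowledge_graph(rbind(g$nodes,
                             data.frame(id = "prot_lonely", type = "Protein",
                                        name = "prot_lonely")),
                       g$edges)
  path <- file.path(withr::local_tempdir(), "kg.tsv")
  write_graph_tsv(g, path)
  back <- load_graph(path)
  expect_setequal(back$nodes$id, g$nodes$id)
  node_key <- function(x) paste(x$id, x$type)[order(x$id)]
  expect_identical(node_key(back$nodes), node_key(g$nodes))
  key <- function(x) sort(paste(x$source, x$target, x$type, x$directed))
  expect_identical(key(back$edges), key(g$edges))

  # empty edge file loads as an empty graph
  empty <- file.path(withr::local_tempdir(), "empty.tsv")
  writeLines(paste("source_id", "source_type", "edge_type", "target_id",
                   "target_type", "directed", sep = "\t"), empty)
  g0 <- load_graph(empty)
  expect_identical(nrow(g0$nodes), 0L)
  expect_identical(nrow(g0$edges), 0L)
})

test_that("parse errors name the offending line", {
  path <- file.path(withr::local_tempdir(), "bad.tsv")
  hdr <- paste("source_id", "source_type", "edge_type", "target_id",
               "target_type", "directed", sep = "\t")
  # conflicting type declarations for one node id
  writeLines(c(hdr,
               paste("P1", "Protein", "interacts", "P2", "Protein", "false",
                     sep = "\t"),
               paste("P1", "Compound", "interacts", "P3", "Protein", "false",
                     sep = "\t")), path)
  expect_error(load_graph(path), "line 2.*conflicting types")
  # unknown type tag under a schema
  writeLines(c(hdr,
               paste("P1", "Protein", "interacts", "P2", "Protein", "false",
                     sep = "\t"),
               paste("X1", "Planet", "orbits", "P2", "Protein", "true",
                     sep = "\t")), path)
  expect_error(load_graph(path, schema = default_kg_schema()),
               "line 3.*unknown node type")
})

test_that("schema validation flags ill-typed edges and passes generated graphs", {
  gen <- generate_synthetic_kg(kg_config(n_proteins = 50, n_genes = 25,
                                         n_compounds = 30, n_diseases = 10,
                                         seed = 11))
  expect_identical(nrow(validate_schema(gen$graph)), 0L)

  bad <- knowledge_graph(
    data.frame(id = c("P1", "P2"), type = "Protein"),
    data.frame(source = "P1", target = "P2", type = "treats",
               directed = TRUE))
  v <- validate_schema(bad)
  expect_identical(nrow(v), 1L)
  expect_match(v$reason, "requires Compound-Disease")
  expect_identical(v$source, "P1")

  # a schema with no edge constraints flags nothing
  free <- list(node_types = character(),
               edge_types = data.frame(type = character(),
                                       source_type = character(),
                                       target_type = character(),
                                       directed = logical()))
  expect_identical(nrow(validate_schema(bad, free)), 0L)
})
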