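# shared generators and independent oracles for the test suite

# seeded Erdos-Renyi graph on named nodes; optionally resampled until
# connected
random_test_graph <- function(n, p, seed, connected = TRUE) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    el <- which(m, arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                 stringsAsFactors = FALSE),
      directed = FALSE, vertices = data.frame(name = ids))
    if (!connected || igraph::is_connected(g)) return(g)
  }
}

# direct linear-solve oracle for topic PageRank:
# (I - a (M' + r d')) p = (1 - a) r, M' = A D^{-1}, d = dangling indicator
pagerank_dense_oracle <- function(g, seeds, damping = 0.85) {
  nodes <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(A)
  dangling <- as.numeric(deg == 0)
  Mt <- sweep(A, 2, ifelse(deg == 0, 1, deg), `/`)
  n <- length(nodes)
  r <- numeric(n)
  r[match(seeds, nodes)] <- 1 / length(seeds)
  p <- solve(diag(n) - damping * (Mt + r %o% dangling), (1 - damping) * r)
  stats::setNames(p, nodes)
}

# tiny typed knowledge graph built by hand
toy_kg <- function() {
  nodes <- data.frame(
    id = c("P1", "P2", "P3", "C1", "G1", "D1"),
    type = c("Protein", "Protein", "Protein", "Compound", "Gene", "Disease"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("P1", "P2", "C1", "C1", "G1", "G1"),
    target = c("P2", "P3", "P1", "D1", "P3", "D1"),
    type = c("interacts", "interacts", "binds", "treats", "encodes",
             "associates"),
    directed = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges)
}

cascade_fixture_path <- function()
  system.file("extdata", "cascade_fixture.csv", package = "t2dtwin")

binarization_fixture <- function()
  utils::read.delim(system.file("extdata", "binarization_fixture.tsv",
                                package = "t2dtwin"),
                    stringsAsFactors = FALSE)

small_cohort_config <- function(seed = 11, ...)
  cohort_config(n_subjects = 80, n_proteins = 12, n_metabolites = 15,
                n_clinical = 8, seed = seed, ...)
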