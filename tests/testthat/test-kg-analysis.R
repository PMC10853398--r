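test_that("shortest paths match a unit-weight Dijkstra oracle on random graphs", {
  for (s in 1:5) {
    g <- random_test_graph(50, 0.08, seed = 600 + s)
    nodes <- igraph::V(g)$name
    target <- nodes[50]
    seeds <- nodes[1:8]
    ps <- shortest_paths_to_target(g, seeds, target)
    oracle <- igraph::distances(g, v = seeds, to = target,
                                weights = rep(1, igraph::ecount(g)),
                                algorithm = "dijkstra")
    for (sd_ in seeds) {
      p <- ps$paths[[sd_]]
      if (is.finite(oracle[sd_, 1])) {
        expect_identical(p$distance, as.integer(oracle[sd_, 1]))
        # every enumerated path has the stated length and correct endpoints
        for (pa in p$paths) {
          expect_identical(length(pa) - 1L, p$distance)
          expect_identical(pa[1], sd_)
          expect_identical(pa[length(pa)], target)
        }
      } else {
        expect_false(p$reachable)
      }
    }
  }
})

test_that("shortest-path base cases: adjacency, unreachable seeds, dropped seeds", {
  g <- toy_kg()
  ps <- shortest_paths_to_target(g, c("P1", "P2"), "D1")
  # P1 - C1 - D1: one 2-hop path
  expect_identical(ps$paths$P1$distance, 2L)
  expect_identical(ps$paths$P1$paths[[1]], c("P1", "C1", "D1"))
  # adjacency base case inside the typed graph
  ps2 <- shortest_paths_to_target(g, "C1", "D1")
  expect_identical(ps2$paths$C1$distance, 1L)
  # disconnected seed is flagged
  g2 <- knowledge_graph(rbind(g$nodes,
                              data.frame(id = "P9", type = "Protein",
                                         name = "P9")), g$edges)
  ps3 <- shortest_paths_to_target(g2, "P9", "D1")
  expect_false(ps3$paths$P9$reachable)
  # unknown seed dropped with a warning; none left is an error
  expect_warning(shortest_paths_to_target(g, c("P1", "nope"), "D1"),
                 "dropped")
  expect_error(suppressWarnings(shortest_paths_to_target(g, "nope", "D1")),
               "no seed")
})

test_that("Steiner base cases and the expansion invariant", {
  # path graph A-B-C with terminals {A, C}: the tree is the path itself
  path_g <- knowledge_graph(
    data.frame(id = c("A", "B", "C"), type = "Protein"),
    data.frame(source = c("A", "B"), target = c("B", "C"),
               type = "interacts", directed = FALSE))
  st <- steiner_takahashi(path_g, c("A", "C"))
  expect_identical(st$cost, 2L)
  expect_identical(st$tree_nodes, c("A", "B", "C"))
  # single terminal: trivial tree
  st1 <- steiner_takahashi(path_g, "B")
  expect_identical(st1$cost, 0L)
  expect_identical(st1$tree_nodes, "B")
  expect_error(steiner_takahashi(path_g, character()), "empty terminal")

  # star K_{1,3}, leaves as terminals: center forced in, cost 3
  star <- knowledge_graph(
    data.frame(id = c("hub", "l1", "l2", "l3"), type = "Protein"),
    data.frame(source = "hub", target = c("l1", "l2", "l3"),
               type = "interacts", directed = FALSE))
  st3 <- steiner_takahashi(star, c("l1", "l2", "l3"))
  expect_identical(st3$cost, 3L)
  expect_true("hub" %in% st3$tree_nodes)
  bf <- steiner_bruteforce(star, c("l1", "l2", "l3"))
  expect_identical(bf$cost, 3L)

  # expansion adds no nodes, and contains every tree edge
  gen <- generate_synthetic_kg(kg_config(n_proteins = 40, n_genes = 20,
                                         n_compounds = 25, n_diseases = 8,
                                         seed = 19))
  term <- c(gen$planted$seed_proteins[1:5], gen$planted$disease_node)
  st4 <- suppressWarnings(steiner_takahashi(gen$graph, term))
  expect_true(all(unique(c(st4$expanded_edges$source,
                           st4$expanded_edges$target)) %in% st4$tree_nodes))
  tree_keys <- paste(st4$tree_edges$from, st4$tree_edges$to)
  exp_keys <- paste(pmin(st4$expanded_edges$source, st4$expanded_edges$target),
                    pmax(st4$expanded_edges$source, st4$expanded_edges$target))
  expect_true(all(tree_keys %in% exp_keys))
  # the tree is connected and acyclic: |edges| = |nodes| - 1 and spans terminals
  sub <- igraph::graph_from_data_frame(st4$tree_edges, directed = FALSE)
  expect_true(igraph::is_connected(sub))
  expect_identical(st4$cost, length(st4$tree_nodes) - 1L)
  expect_true(all(term %in% st4$tree_nodes))
})

test_that("brute-force Steiner identities: 2 terminals and all-terminal MST", {
  for (s in 1:5) {
    g <- random_test_graph(9, 0.3, seed = 700 + s)
    nodes <- igraph::V(g)$name
    bf2 <- steiner_bruteforce(g, nodes[c(1, 9)])
    d <- igraph::distances(g, v = nodes[1], to = nodes[9])
    expect_identical(bf2$cost, as.integer(d[1, 1]))
    bf_all <- steiner_bruteforce(g, nodes)
    expect_identical(bf_all$cost, length(nodes) - 1L)  # unit-weight MST
  }
  expect_error(steiner_bruteforce(random_test_graph(17, 0.3, 1), "n001"),
               "more than 16")
})

test_that("the Takahashi heuristic respects the 2(1 - 1/t) bound and ties", {
  worst <- 0
  for (s in 1:40) {
    n <- 8 + (s %% 5)
    g <- random_test_graph(n, 0.28, seed = 800 + s)
    nodes <- igraph::V(g)$name
    t <- 3 + (s %% 2)
    set.seed(s)
    term <- sample(nodes, t)
    st <- steiner_takahashi(g, term)
    bf <- steiner_bruteforce(g, term)
    ratio <- st$cost / bf$cost
    worst <- max(worst, ratio)
    expect_lte(st$cost, 2 * (1 - 1 / t) * bf$cost)
    # union-of-paths upper bound
    d1 <- igraph::distances(g, v = sort(term)[1], to = term)
    expect_lte(st$cost, sum(d1))
    # 2-terminal identity: heuristic equals the shortest-path distance
    st2 <- steiner_takahashi(g, term[1:2])
    expect_identical(st2$cost,
                     as.integer(igraph::distances(g, v = term[1],
                                                  to = term[2])[1, 1]))
  }
  expect_lte(worst, 2)
  # deterministic output on repeated runs
  g <- random_test_graph(12, 0.25, seed = 999)
  t1 <- steiner_takahashi(g, c("n001", "n006", "n012"))
  t2 <- steiner_takahashi(g, c("n001", "n006", "n012"))
  expect_identical(t1$tree_edges, t2$tree_edges)
})

test_that("topic PageRank matches the dense linear-solve oracle", {
  for (s in 1:8) {
    g <- random_test_graph(60 + 10 * s, 0.04, seed = 300 + s,
                           connected = FALSE)
    nodes <- igraph::V(g)$name
    set.seed(s)
    seeds <- sample(nodes, 1 + (s %% 4))
    pr <- topic_pagerank(g, seeds)
    expect_true(pr$converged)
    expect_equal(sum(pr$scores), 1, tolerance = 1e-9)
    expect_true(all(pr$scores >= 0))
    oracle <- pagerank_dense_oracle(g, sort(seeds))
    expect_lt(max(abs(pr$scores - oracle[names(pr$scores)])), 1e-8)
  }
})

test_that("PageRank degenerate and symmetric cases behave as expected", {
  # isolated seed keeps all mass
  iso <- knowledge_graph(
    data.frame(id = c("A", "B", "C"), type = "Protein"),
    data.frame(source = "B", target = "C", type = "interacts",
               directed = FALSE))
  pr <- topic_pagerank(iso, "A")
  expect_equal(unname(pr$scores["A"]), 1, tolerance = 1e-9)
  # star graph with all leaves as seeds: leaf scores equal by symmetry
  star <- knowledge_graph(
    data.frame(id = c("hub", "l1", "l2", "l3"), type = "Protein"),
    data.frame(source = "hub", target = c("l1", "l2", "l3"),
               type = "interacts", directed = FALSE))
  prs <- topic_pagerank(star, c("l1", "l2", "l3"))
  leaf <- prs$scores[c("l1", "l2", "l3")]
  expect_lt(diff(range(leaf)), 1e-12)
  expect_error(suppressWarnings(topic_pagerank(star, "nope")), "no seed")
})

test_that("linking a node to a seed never lowers its score", {
  for (s in 1:5) {
    g <- random_test_graph(40, 0.06, seed = 500 + s)
    nodes <- igraph::V(g)$name
    seeds <- nodes[1:3]
    pr1 <- topic_pagerank(g, seeds)
    cand <- setdiff(nodes, c(seeds, names(igraph::neighbors(g, seeds[1]))))
    v <- cand[1]
    g2 <- igraph::add_edges(g, c(v, seeds[1]))
    pr2 <- topic_pagerank(g2, seeds)
    expect_gte(pr2$scores[v] + 1e-12, pr1$scores[v])
  }
})

test_that("prioritization filters, excludes seeds, and recovers planted proteins", {
  gen <- generate_synthetic_kg(kg_config(n_proteins = 200, n_genes = 80,
                                         n_compounds = 120, n_diseases = 30,
                                         seed = 27))
  pr <- topic_pagerank(gen$graph, gen$planted$seed_proteins)
  top <- prioritize_nodes(pr, node_type = "Protein", exclude_seeds = TRUE,
                          k = 20)
  expect_false(any(top$node %in% gen$planted$seed_proteins))
  expect_true(all(top$type == "Protein"))
  expect_true(all(diff(top$score) <= 0))

  # hidden proteins rank above the background median
  all_prot <- prioritize_nodes(pr, node_type = "Protein",
                               exclude_seeds = TRUE, k = 200)
  hidden_rank <- all_prot$rank[all_prot$node %in% gen$planted$hidden_proteins]
  background <- all_prot$rank[!(all_prot$node %in%
                                  gen$planted$hidden_proteins)]
  expect_lt(median(hidden_rank), median(background))
})

test_that("recovery metrics match hypergeometric expectations for random ranks", {
  expect_identical(
    recovery_metrics(c("h1", "h2", "x1", "x2"), c("h1", "h2"),
                     k_grid = 2)$recall[["recall_at_2"]], 1)
  none <- recovery_metrics(c("x1", "x2"), c("h1", "h2"), k_grid = 2)
  expect_identical(none$recall[["recall_at_2"]], 0)
  expect_identical(none$mrr, 0)

  set.seed(64)
  universe <- sprintf("p%03d", 1:100)
  hidden <- universe[1:5]
  rec <- replicate(1000,
    recovery_metrics(sample(universe), hidden,
                     k_grid = 20)$recall[["recall_at_20"]])
  # E[recall@20] = 20/100; 99% band from the hypergeometric null
  m <- mean(rec)
  p <- 20 / 100
  se <- sd(rec) / sqrt(1000)
  expect_lt(abs(m - p), 2.576 * se + 0.01)
})
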