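# All algorithms in this file operate on the simple undirected unit-weight
# view of the typed graph; distances are hop counts.
.kg_view <- function(graph) kg_as_igraph(graph, simplify = TRUE)

.node_types <- function(graph) {
  if (inherits(graph, "knowledge_graph")) {
    stats::setNames(graph$nodes$type, graph$nodes$id)
  } else {
    ty <- igraph::vertex_attr(graph, "type")
    if (is.null(ty)) ty <- rep(NA_character_, igraph::vcount(graph))
    stats::setNames(ty, igraph::V(graph)$name)
  }
}

#' Shortest paths from predictor seeds to a disease node
#'
#' Breadth-first shortest paths on the undirected unit-weight view, from each
#' seed node (typically a top-weighted predictor protein) to the target
#' (typically the disease node). With `all_paths = TRUE` every distinct
#' shortest path is enumerated. Seeds absent from the graph are dropped with
#' a warning; unreachable seeds are flagged with no path. The union of all
#' path edges is exported as a subgraph for visualization.
#'
#' @param graph A `knowledge_graph` or igraph.
#' @param seeds Character vector of seed node ids.
#' @param target Target node id.
#' @param all_paths Enumerate all distinct shortest paths per seed.
#' @return A `path_set`: per-seed list (`distance`, `paths` as node-id
#'   vectors, `reachable`), plus `subgraph_edges` (data.frame of consecutive
#'   path pairs, deduplicated).
#' @export
shortest_paths_to_target <- function(graph, seeds, target, all_paths = TRUE) {
  ig <- .kg_view(graph)
  nodes <- igraph::V(ig)$name
  if (!(target %in% nodes)) stop("target node not in graph: ", target)
  missing <- setdiff(seeds, nodes)
  if (length(missing)) {
    warning("seed(s) not in graph, dropped: ",
            paste(missing, collapse = ", "))
    seeds <- setdiff(seeds, missing)
  }
  if (!length(seeds)) stop("no seed present in the graph")
  res <- list()
  for (s in sort(seeds)) {
    if (all_paths) {
      sp <- igraph::all_shortest_paths(ig, from = s, to = target)$vpaths
    } else {
      one <- igraph::shortest_paths(ig, from = s, to = target)$vpath
      sp <- if (length(one[[1]]) > 0) one else list()
    }
    paths <- lapply(sp, function(p) igraph::V(ig)$name[as.integer(p)])
    paths <- paths[order(vapply(paths, paste, "", collapse = "\r"))]
    reachable <- length(paths) > 0 &&
      (length(paths[[1]]) > 1 || identical(s, target))
    res[[s]] <- list(
      distance = if (reachable) length(paths[[1]]) - 1L else NA_integer_,
      paths = if (reachable) paths else list(),
      reachable = reachable)
  }
  edge_list <- list()
  for (r in res) for (p in r$paths) {
    if (length(p) < 2) next
    a <- p[-length(p)]; b <- p[-1]
    lo <- pmin(a, b); hi <- pmax(a, b)
    edge_list[[length(edge_list) + 1]] <- data.frame(
      from = lo, to = hi, stringsAsFactors = FALSE)
  }
  sub <- if (length(edge_list)) unique(do.call(rbind, edge_list)) else
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  sub <- sub[order(sub$from, sub$to), , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(target = target, seeds = sort(seeds), paths = res,
                 subgraph_edges = sub),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  d <- vapply(x$paths, function(p)
    if (p$reachable) p$distance else NA_integer_, integer(1))
  cat("<path_set> target=", x$target, ", ", length(x$seeds), " seeds, ",
      "hop distances: [", paste(d, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# lexicographic comparison of node-id sequences
.lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Approximate Steiner tree by the Takahashi nearest-terminal heuristic
#'
#' Grows a tree from the lexicographically smallest terminal: at each step
#' the not-yet-connected terminal with minimum hop distance to the current
#' tree is attached along a shortest path. Ties on distance are broken by
#' smallest terminal id and, among equal-length attachment paths, by the
#' lexicographically smallest node-id sequence, so the output is
#' bit-reproducible. The tree is then *expanded* to the node-induced edge
#' set — every graph edge with both endpoints in the tree — giving the
#' (approximately) smallest subgraph containing all terminals. The heuristic
#' cost is within `2(1 - 1/t)` of the optimum for `t` terminals.
#'
#' @param graph A `knowledge_graph` or igraph.
#' @param terminals Node ids that must be spanned (e.g. top predictor
#'   proteins plus the disease node). Terminals absent from the graph are
#'   dropped with a warning; terminals in unreachable components are
#'   reported in `skipped`.
#' @return A `steiner_subgraph`: `terminals`, `skipped`, `tree_nodes`,
#'   `tree_edges` (data.frame `from`/`to`), `cost` (tree edge count), and
#'   `expanded_edges` (induced edge set, with edge types when the input was
#'   a typed graph).
#' @export
steiner_takahashi <- function(graph, terminals) {
  if (!length(terminals)) stop("empty terminal set")
  ig <- .kg_view(graph)
  nodes <- igraph::V(ig)$name
  missing <- setdiff(terminals, nodes)
  if (length(missing)) {
    warning("terminal(s) not in graph, dropped: ",
            paste(missing, collapse = ", "))
    terminals <- setdiff(terminals, missing)
  }
  if (!length(terminals)) stop("no terminal present in the graph")
  terminals <- sort(unique(terminals))

  tree_nodes <- terminals[1]
  tree_edges <- data.frame(from = character(), to = character(),
                           stringsAsFactors = FALSE)
  remaining <- setdiff(terminals, tree_nodes)
  skipped <- character()
  while (length(remaining)) {
    d <- igraph::distances(ig, v = remaining, to = tree_nodes)
    dmin_per <- apply(d, 1, min)
    dmin <- min(dmin_per)
    if (!is.finite(dmin)) { skipped <- remaining; break }
    cand <- sort(remaining[dmin_per == dmin])
    t_next <- cand[1]
    attach_to <- tree_nodes[d[t_next, ] == dmin]
    best <- NULL
    for (u in sort(attach_to)) {
      sps <- igraph::all_shortest_paths(ig, from = t_next, to = u)$vpaths
      for (p in sps) {
        seq_ids <- igraph::V(ig)$name[as.integer(p)]
        if (length(seq_ids) - 1 != dmin) next
        if (is.null(best) || .lex_less(seq_ids, best)) best <- seq_ids
      }
    }
    if (length(best) > 1) {
      a <- best[-length(best)]; b <- best[-1]
      tree_edges <- unique(rbind(tree_edges,
        data.frame(from = pmin(a, b), to = pmax(a, b),
                   stringsAsFactors = FALSE)))
    }
    tree_nodes <- union(tree_nodes, best)
    remaining <- setdiff(remaining, t_next)
  }
  tree_nodes <- sort(tree_nodes)
  tree_edges <- tree_edges[order(tree_edges$from, tree_edges$to), ,
                           drop = FALSE]
  rownames(tree_edges) <- NULL

  expanded <- induced_edge_set(graph, tree_nodes)
  structure(list(terminals = setdiff(terminals, skipped), skipped = skipped,
                 tree_nodes = tree_nodes, tree_edges = tree_edges,
                 cost = nrow(tree_edges), expanded_edges = expanded),
            class = "steiner_subgraph")
}

# every edge of the (typed or plain) graph whose both endpoints are in `nodes`
induced_edge_set <- function(graph, nodes) {
  if (inherits(graph, "knowledge_graph")) {
    keep <- graph$edges$source %in% nodes & graph$edges$target %in% nodes
    ed <- graph$edges[keep, , drop = FALSE]
    ed <- ed[order(ed$source, ed$target, ed$type), , drop = FALSE]
    rownames(ed) <- NULL
    ed
  } else {
    ig <- .kg_view(graph)
    sub <- igraph::induced_subgraph(ig, nodes)
    el <- igraph::as_edgelist(sub)
    ed <- data.frame(source = pmin(el[, 1], el[, 2]),
                     target = pmax(el[, 1], el[, 2]),
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$source, ed$target), , drop = FALSE]
    rownames(ed) <- NULL
    ed
  }
}

#' @export
print.steiner_subgraph <- function(x, ...) {
  cat("<steiner_subgraph> ", length(x$terminals), " terminals, tree: ",
      length(x$tree_nodes), " nodes / cost ", x$cost,
      ", expanded edges: ", nrow(x$expanded_edges), "\n", sep = "")
  if (length(x$skipped))
    cat("  skipped unreachable terminals: ",
        paste(x$skipped, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Exact minimum Steiner tree by exhaustive search (test oracle)
#'
#' Enumerates subsets of non-terminal nodes in increasing size; the first
#' size at which some candidate node set induces a connected subgraph
#' containing all terminals gives the optimum (with unit edge weights a
#' connected subgraph on `k` nodes always admits a spanning tree of `k - 1`
#' edges). Only feasible on tiny graphs; refuses more than 16 nodes.
#'
#' @param graph A `knowledge_graph` or igraph with at most 16 nodes.
#' @param terminals Node ids to span (must be mutually reachable).
#' @return List with `cost` and `nodes` (an optimal candidate node set).
#' @export
steiner_bruteforce <- function(graph, terminals) {
  ig <- .kg_view(graph)
  nodes <- igraph::V(ig)$name
  if (length(nodes) > 16)
    stop("steiner_bruteforce refuses graphs with more than 16 nodes")
  stopifnot(all(terminals %in% nodes))
  terminals <- sort(unique(terminals))
  nonterm <- setdiff(nodes, terminals)
  connected_on <- function(cand) {
    sub <- igraph::induced_subgraph(ig, cand)
    igraph::is_connected(sub)
  }
  for (s in 0:length(nonterm)) {
    subsets <- if (s == 0) list(character()) else
      utils::combn(nonterm, s, simplify = FALSE)
    for (extra in subsets) {
      cand <- c(terminals, extra)
      if (connected_on(cand))
        return(list(cost = length(cand) - 1L, nodes = sort(cand)))
    }
  }
  stop("terminals are not mutually reachable; no Steiner tree exists")
}

#' Topic (personalized) PageRank by power iteration
#'
#' Random walk with restart on the undirected unit-weight view: with
#' probability `damping` the walker follows a uniformly random incident
#' edge, otherwise it restarts at a uniformly random seed node. Degree-zero
#' nodes redistribute their mass to the restart set. Iteration
#' `p <- damping * (M'p + dangling_mass * r) + (1 - damping) * r` (M the
#' degree-normalized adjacency, r uniform over seeds) stops when the L1
#' residual falls below `tol`. Scores are a probability distribution — they
#' sum to one — and quantify graph proximity to the seeds, the basis of
#' gene/protein prioritization.
#'
#' @param graph A `knowledge_graph` or igraph.
#' @param seeds Seed (restart) node ids; seeds absent from the graph are
#'   dropped with a warning, and an error is raised if none remain.
#' @param damping Damping factor alpha (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap; non-convergence flags the result.
#' @return A `topic_pagerank_result`: named `scores`, `damping`, `seeds`,
#'   `tol`, `iterations`, `converged`, plus per-node `types` and
#'   `seed_adjacency` counts used by [prioritize_nodes()].
#' @export
topic_pagerank <- function(graph, seeds, damping = 0.85, tol = 1e-10,
                           max_iter = 1000L) {
  stopifnot(damping > 0, damping < 1)
  ig <- .kg_view(graph)
  nodes <- igraph::V(ig)$name
  missing <- setdiff(seeds, nodes)
  if (length(missing)) {
    warning("seed(s) not in graph, dropped: ",
            paste(missing, collapse = ", "))
    seeds <- setdiff(seeds, missing)
  }
  if (!length(seeds)) stop("no seed present in the graph")
  seeds <- sort(unique(seeds))
  n <- length(nodes)
  A <- igraph::as_adjacency_matrix(ig, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  dangling <- deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / deg)
  # M' = A D^{-1}: column j of A scaled by 1/deg(j); A symmetric here
  Mt <- A %*% Matrix::Diagonal(n, inv_deg)
  r <- numeric(n)
  r[match(seeds, nodes)] <- 1 / length(seeds)
  p <- r
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric(damping * (Mt %*% p + sum(p[dangling]) * r) +
                          (1 - damping) * r)
    resid <- sum(abs(p_new - p))
    p <- p_new
    iters <- it
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("topic_pagerank did not converge in ", max_iter, " iterations")
  scores <- stats::setNames(p, nodes)
  adj <- A[, match(seeds, nodes), drop = FALSE]
  structure(list(scores = scores, damping = damping, seeds = seeds,
                 tol = tol, iterations = iters, converged = converged,
                 types = .node_types(graph)[nodes],
                 seed_adjacency = stats::setNames(
                   as.integer(Matrix::rowSums(adj)), nodes)),
            class = "topic_pagerank_result")
}

#' @export
print.topic_pagerank_result <- function(x, ...) {
  cat("<topic_pagerank_result> ", length(x$scores), " nodes, ",
      length(x$seeds), " seeds, alpha=", x$damping, ", ",
      x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Prioritize graph nodes by topic PageRank score
#'
#' Ranks nodes of the requested type by score (descending, ties by node id),
#' optionally excluding the seed nodes themselves — the interesting output
#' is usually the *unmeasured* proteins that the walk concentrates on.
#'
#' @param result A converged `topic_pagerank_result`.
#' @param node_type Node type to rank (default `"Protein"`); `NULL` ranks
#'   all types.
#' @param exclude_seeds Drop the seed nodes from the ranking (default TRUE).
#' @param k Number of nodes to return.
#' @return Data.frame: `rank`, `node`, `type`, `score`, `seed_adjacency`.
#' @export
prioritize_nodes <- function(result, node_type = "Protein",
                             exclude_seeds = TRUE, k = 20L) {
  stopifnot(inherits(result, "topic_pagerank_result"))
  if (!result$converged)
    stop("prioritize_nodes requires a converged PageRank result")
  ids <- names(result$scores)
  keep <- rep(TRUE, length(ids))
  if (!is.null(node_type)) keep <- keep & result$types[ids] %in% node_type
  if (exclude_seeds) keep <- keep & !(ids %in% result$seeds)
  ids <- ids[keep]
  ord <- order(-result$scores[ids], ids)
  ids <- ids[ord][seq_len(min(k, length(ids)))]
  data.frame(rank = seq_along(ids), node = ids,
             type = unname(result$types[ids]),
             score = unname(result$scores[ids]),
             seed_adjacency = unname(result$seed_adjacency[ids]),
             stringsAsFactors = FALSE)
}

#' Recovery metrics of a planted node set in a ranking
#'
#' Quantifies how well a prioritized list recovers a known ("hidden
#' causal") node set: recall at each cutoff in `k_grid` and the mean
#' reciprocal rank (nodes absent from the list contribute 0).
#'
#' @param ranked Character vector of node ids in rank order (or a
#'   data.frame from [prioritize_nodes()] with a `node` column).
#' @param hidden Non-empty character vector of planted node ids.
#' @param k_grid Cutoffs for recall (default `c(5, 10, 20, 50)`).
#' @return List with `recall` (named by cutoff) and `mrr`.
#' @export
recovery_metrics <- function(ranked, hidden, k_grid = c(5, 10, 20, 50)) {
  if (is.data.frame(ranked)) ranked <- ranked$node
  if (!length(hidden)) stop("planted hidden set is empty")
  pos <- match(hidden, ranked)
  recall <- vapply(k_grid, function(k)
    sum(!is.na(pos) & pos <= k) / length(hidden), numeric(1))
  names(recall) <- paste0("recall_at_", k_grid)
  mrr <- mean(ifelse(is.na(pos), 0, 1 / pos))
  list(recall = recall, mrr = mrr)
}
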