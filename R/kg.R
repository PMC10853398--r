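#' Typed biomedical knowledge graph
#'
#' A lightweight container for a heterogeneous knowledge graph: a node table
#' (`id`, `type`, `name`) and an edge table (`source`, `target`, `type`,
#' `directed`). Edge endpoints must exist in the node table, node ids are
#' unique, and parallel edges are allowed only with distinct edge types —
#' duplicate (source, target, type) triples are collapsed with a warning.
#'
#' @param nodes Data.frame with columns `id`, `type`, `name` (name optional,
#'   defaults to the id).
#' @param edges Data.frame with columns `source`, `target`, `type`,
#'   `directed` (logical; optional, defaults per [default_kg_schema()] or
#'   `FALSE`).
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "type") %in% names(nodes)),
            all(c("source", "target", "type") %in% names(edges)))
  if (is.null(nodes$name)) nodes$name <- nodes$id
  if (is.null(edges$directed)) edges$directed <- FALSE
  nodes <- nodes[, c("id", "type", "name")]
  edges <- edges[, c("source", "target", "type", "directed")]
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(utils::head(nodes$id[duplicated(nodes$id)], 5), collapse = ", "))
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling))
    stop("edge endpoints not in the node table: ",
         paste(utils::head(dangling, 5), collapse = ", "))
  key <- paste(edges$source, edges$target, edges$type)
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)),
            " duplicate (source, target, type) edge(s)")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  nt <- table(x$nodes$type)
  et <- table(x$edges$type)
  cat("<knowledge_graph> ", nrow(x$nodes), " nodes [",
      paste(names(nt), nt, sep = ":", collapse = ", "), "], ",
      nrow(x$edges), " edges [",
      paste(names(et), et, sep = ":", collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Miniature biomedical knowledge-graph schema
#'
#' Node types Protein, Gene, Compound, Disease; edge types `interacts`
#' (protein-protein, undirected), `binds` and `downregulates`
#' (compound -> protein), `treats` (compound -> disease), `associates`
#' (gene -> disease) and `encodes` (gene -> protein). Note the schema has no
#' direct protein-disease edge: proteins reach diseases through compounds or
#' genes, which is what makes intermediate nodes on shortest paths
#' interpretable as candidate mechanisms.
#'
#' @return List with `node_types` and an `edge_types` data.frame
#'   (`type`, `source_type`, `target_type`, `directed`).
#' @export
default_kg_schema <- function() {
  list(
    node_types = c("Protein", "Gene", "Compound", "Disease"),
    edge_types = data.frame(
      type = c("interacts", "binds", "downregulates", "treats",
               "associates", "encodes"),
      source_type = c("Protein", "Compound", "Compound", "Compound",
                      "Gene", "Gene"),
      target_type = c("Protein", "Protein", "Protein", "Disease",
                      "Disease", "Protein"),
      directed = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  )
}

#' Configuration for the synthetic knowledge-graph generator
#'
#' Describes a random typed graph with *planted* disease-proximal structure:
#' a set of "measured seed" proteins that are densely interconnected by
#' protein-protein interaction edges (the analogue of top predictive
#' features), and a disjoint set of "hidden causal" proteins, each wired to
#' at least `min_seed_links` seeds and placed within two hops of the disease
#' node via a dedicated compound (binds the protein, treats the disease).
#'
#' @param n_proteins,n_genes,n_compounds,n_diseases Node counts per type.
#' @param disease_node Id of the focal disease node.
#' @param seed_proteins Ids of the measured seed proteins (default: the
#'   first `n_seeds` protein ids).
#' @param n_seeds,n_hidden Counts used when explicit ids are not given.
#' @param min_seed_links Minimum seed neighbors per hidden protein (m >= 1).
#' @param edge_probs Background wiring densities: `ppi` (protein-protein
#'   pair probability), `binds_per_compound`, `treats_prob`,
#'   `associates_prob`, `encodes_prob`, `downreg_per_compound`.
#' @param seed Integer seed.
#' @return A list of class `kg_config`.
#' @export
kg_config <- function(n_proteins = 800L, n_genes = 400L, n_compounds = 600L,
                      n_diseases = 200L,
                      disease_node = "dis_0001",
                      seed_proteins = NULL,
                      n_seeds = 10L, n_hidden = 5L,
                      min_seed_links = 3L,
                      edge_probs = list(ppi = 4 / n_proteins,
                                        binds_per_compound = 2,
                                        treats_prob = 0.10,
                                        associates_prob = 0.30,
                                        encodes_prob = 0.90,
                                        downreg_per_compound = 0.5),
                      seed = 1L) {
  if (min_seed_links < 1) stop("min_seed_links must be >= 1")
  prot_ids <- sprintf("prot_%04d", seq_len(n_proteins))
  if (is.null(seed_proteins)) seed_proteins <- utils::head(prot_ids, n_seeds)
  if (!all(seed_proteins %in% prot_ids))
    stop("seed_proteins must be among the generated protein ids")
  hidden <- utils::head(setdiff(prot_ids, seed_proteins), n_hidden)
  if (length(hidden) < n_hidden)
    stop("not enough proteins for ", n_hidden, " hidden causal proteins ",
         "disjoint from the seeds")
  if (length(seed_proteins) < min_seed_links)
    stop("min_seed_links exceeds the number of seed proteins")
  if (n_diseases < 1) stop("need at least one disease node")
  structure(list(
    n_proteins = as.integer(n_proteins), n_genes = as.integer(n_genes),
    n_compounds = as.integer(n_compounds), n_diseases = as.integer(n_diseases),
    disease_node = disease_node, seed_proteins = seed_proteins,
    hidden_proteins = hidden, min_seed_links = as.integer(min_seed_links),
    edge_probs = edge_probs, seed = as.integer(seed)
  ), class = "kg_config")
}

#' Generate a synthetic typed knowledge graph with planted structure
#'
#' Background edges are drawn independently per edge type at the configured
#' densities; the planted structure then adds dense seed-seed interaction
#' edges, `min_seed_links`-or-more seed links per hidden protein, and a
#' dedicated bridging compound per hidden protein (binds it, treats the
#' disease). Finally the protein-disease component is made connected by
#' bridging any leftover components to the disease node through a compound.
#' Deterministic given the config seed.
#'
#' @param config A [kg_config()].
#' @return List with `graph` (a `knowledge_graph`) and `planted` (list:
#'   `disease_node`, `seed_proteins`, `hidden_proteins`).
#' @export
generate_synthetic_kg <- function(config) {
  stopifnot(inherits(config, "kg_config"))
  set.seed(config$seed)
  prot <- sprintf("prot_%04d", seq_len(config$n_proteins))
  gene <- sprintf("gene_%04d", seq_len(config$n_genes))
  comp <- sprintf("comp_%04d", seq_len(config$n_compounds))
  dis <- sprintf("dis_%04d", seq_len(config$n_diseases))
  if (!(config$disease_node %in% dis))
    stop("disease_node must be among the generated disease ids")
  nodes <- data.frame(
    id = c(prot, gene, comp, dis),
    type = rep(c("Protein", "Gene", "Compound", "Disease"),
               c(length(prot), length(gene), length(comp), length(dis))),
    stringsAsFactors = FALSE)
  nodes$name <- nodes$id
  ep <- config$edge_probs
  edges <- list()
  add <- function(src, tgt, type, directed) {
    if (!length(src)) return()
    edges[[length(edges) + 1]] <<- data.frame(
      source = src, target = tgt, type = type, directed = directed,
      stringsAsFactors = FALSE)
  }

  # background PPI: Erdos-Renyi over protein pairs
  np <- length(prot)
  if (np >= 2) {
    ut <- which(upper.tri(matrix(FALSE, np, np)), arr.ind = TRUE)
    on <- stats::runif(nrow(ut)) < min(1, ep$ppi)
    if (any(on)) add(prot[ut[on, 1]], prot[ut[on, 2]], "interacts", FALSE)
  }
  # compound -> protein
  nb <- stats::rpois(length(comp), ep$binds_per_compound)
  src <- rep(comp, nb)
  if (length(src)) add(src, sample(prot, length(src), replace = TRUE),
                       "binds", TRUE)
  nd <- stats::rpois(length(comp), ep$downreg_per_compound)
  src <- rep(comp, nd)
  if (length(src)) add(src, sample(prot, length(src), replace = TRUE),
                       "downregulates", TRUE)
  # compound -> disease
  tr <- comp[stats::runif(length(comp)) < ep$treats_prob]
  if (length(tr)) add(tr, sample(dis, length(tr), replace = TRUE),
                      "treats", TRUE)
  # gene -> disease / gene -> protein
  as_g <- gene[stats::runif(length(gene)) < ep$associates_prob]
  if (length(as_g)) add(as_g, sample(dis, length(as_g), replace = TRUE),
                        "associates", TRUE)
  en <- gene[stats::runif(length(gene)) < ep$encodes_prob]
  if (length(en)) add(en, sample(prot, length(en), replace = TRUE),
                      "encodes", TRUE)

  # planted: dense seed-seed PPI
  seeds <- config$seed_proteins
  if (length(seeds) > 1) {
    pairs <- utils::combn(sort(seeds), 2)
    on <- stats::runif(ncol(pairs)) < 0.6
    # guarantee seed connectivity: chain consecutive seeds
    chain <- cbind(sort(seeds)[-length(seeds)], sort(seeds)[-1])
    add(c(pairs[1, on], chain[, 1]), c(pairs[2, on], chain[, 2]),
        "interacts", FALSE)
  }
  # planted: hidden causal proteins
  hid <- config$hidden_proteins
  m <- config$min_seed_links
  bridge <- utils::tail(comp, length(hid))  # dedicated bridging compounds
  for (h in seq_along(hid)) {
    k <- min(length(seeds), m + stats::rbinom(1, 2, 0.5))
    link <- sample(seeds, k)
    add(rep(hid[h], k), link, "interacts", FALSE)
    add(bridge[h], hid[h], "binds", TRUE)
    add(bridge[h], config$disease_node, "treats", TRUE)
  }

  ed_all <- do.call(rbind, edges)
  # undirected duplicates (a-b / b-a interacts) and repeated draws collapse
  # silently: they are an expected byproduct of independent sampling
  flip <- !ed_all$directed & ed_all$source > ed_all$target
  tmp <- ed_all$source[flip]
  ed_all$source[flip] <- ed_all$target[flip]
  ed_all$target[flip] <- tmp
  ed_all <- ed_all[!duplicated(paste(ed_all$source, ed_all$target,
                                     ed_all$type)), , drop = FALSE]
  g <- knowledge_graph(nodes, ed_all)

  # connect leftover components to the disease node
  ig <- kg_as_igraph(g)
  comp_id <- igraph::components(ig)$membership
  dis_comp <- comp_id[[config$disease_node]]
  extra <- list()
  for (cid in setdiff(unique(comp_id), dis_comp)) {
    members <- sort(names(comp_id)[comp_id == cid])
    anchor <- members[1]
    atype <- g$nodes$type[match(anchor, g$nodes$id)]
    link <- switch(atype,
      Protein = data.frame(source = c(comp[1], comp[1]),
                           target = c(anchor, config$disease_node),
                           type = c("binds", "treats"),
                           directed = TRUE, stringsAsFactors = FALSE),
      Gene = data.frame(source = anchor, target = config$disease_node,
                        type = "associates", directed = TRUE,
                        stringsAsFactors = FALSE),
      Compound = data.frame(source = anchor, target = config$disease_node,
                            type = "treats", directed = TRUE,
                            stringsAsFactors = FALSE),
      Disease = data.frame(source = comp[1], target = anchor,
                           type = "treats", directed = TRUE,
                           stringsAsFactors = FALSE))
    extra[[length(extra) + 1]] <- link
  }
  if (length(extra)) {
    ed <- rbind(g$edges, do.call(rbind, extra))
    key <- paste(ed$source, ed$target, ed$type)
    g <- knowledge_graph(g$nodes, ed[!duplicated(key), , drop = FALSE])
  }
  list(graph = g,
       planted = list(disease_node = config$disease_node,
                      seed_proteins = seeds, hidden_proteins = hid))
}

#' Convert a knowledge graph to an igraph object
#'
#' @param graph A `knowledge_graph` (or an igraph, returned as-is).
#' @param simplify Collapse parallel edges and loops, giving the simple
#'   undirected unit-weight view all graph algorithms in this package run on.
#' @return An undirected igraph with vertex attributes `type` and `name`.
#' @export
kg_as_igraph <- function(graph, simplify = TRUE) {
  if (igraph::is_igraph(graph)) return(graph)
  stopifnot(inherits(graph, "knowledge_graph"))
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("source", "target", "type")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$id, type = graph$nodes$type,
                          stringsAsFactors = FALSE))
  if (simplify)
    ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = TRUE,
                           edge.attr.comb = "first")
  ig
}

#' Read and write knowledge-graph edge lists
#'
#' TSV with columns `source_id`, `source_type`, `edge_type`, `target_id`,
#' `target_type`, `directed`. Nodes are declared by the edges that touch
#' them; isolated nodes are kept as rows with empty edge fields. Duplicate
#' (source, target, type) triples collapse with a warning; a node id
#' declared with two different types is a parse error naming the line.
#'
#' @param graph A `knowledge_graph`.
#' @param path TSV path.
#' @param schema Optional schema; when given, `load_graph()` rejects unknown
#'   node or edge type tags with a parse error naming the line.
#' @return `load_graph()` returns a `knowledge_graph`.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "knowledge_graph"))
  ntype <- stats::setNames(graph$nodes$type, graph$nodes$id)
  df <- data.frame(
    source_id = graph$edges$source,
    source_type = ntype[graph$edges$source],
    edge_type = graph$edges$type,
    target_id = graph$edges$target,
    target_type = ntype[graph$edges$target],
    directed = tolower(as.character(graph$edges$directed)),
    stringsAsFactors = FALSE)
  isolated <- setdiff(graph$nodes$id, c(graph$edges$source, graph$edges$target))
  if (length(isolated))
    df <- rbind(df, data.frame(source_id = isolated,
                               source_type = ntype[isolated],
                               edge_type = "", target_id = "",
                               target_type = "", directed = "",
                               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
load_graph <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  expected <- c("source_id", "source_type", "edge_type", "target_id",
                "target_type", "directed")
  if (!identical(names(raw), expected))
    stop("parse error in ", path, ": expected columns ",
         paste(expected, collapse = ", "))
  is_node_row <- raw$edge_type == "" & raw$target_id == ""
  decl <- rbind(
    data.frame(id = raw$source_id, type = raw$source_type, line = seq_len(nrow(raw)) + 1L,
               stringsAsFactors = FALSE),
    data.frame(id = raw$target_id[!is_node_row],
               type = raw$target_type[!is_node_row],
               line = which(!is_node_row) + 1L, stringsAsFactors = FALSE))
  bad <- if (nrow(decl)) {
    conf <- stats::aggregate(type ~ id, decl, function(t) length(unique(t)))
    conf$id[conf$type > 1]
  } else character()
  if (length(bad)) {
    ln <- min(decl$line[decl$id == bad[1]])
    stop("parse error in ", path, " line ", ln,
         ": node '", bad[1], "' declared with conflicting types")
  }
  if (!is.null(schema)) {
    bad_nt <- which(!(decl$type %in% schema$node_types))
    if (length(bad_nt))
      stop("parse error in ", path, " line ", decl$line[bad_nt[1]],
           ": unknown node type '", decl$type[bad_nt[1]], "'")
    bad_et <- which(!is_node_row &
                      !(raw$edge_type %in% schema$edge_types$type))
    if (length(bad_et))
      stop("parse error in ", path, " line ", bad_et[1] + 1,
           ": unknown edge type '", raw$edge_type[bad_et[1]], "'")
  }
  er <- raw[!is_node_row, , drop = FALSE]
  bad_dir <- which(!(er$directed %in% c("true", "false", "TRUE", "FALSE",
                                        "0", "1")))
  if (length(bad_dir))
    stop("parse error in ", path, " line ",
         which(!is_node_row)[bad_dir[1]] + 1,
         ": directed must be true/false")
  nodes <- unique(decl[, c("id", "type")])
  nodes$name <- nodes$id
  edges <- data.frame(source = er$source_id, target = er$target_id,
                      type = er$edge_type,
                      directed = er$directed %in% c("true", "TRUE", "1"),
                      stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges)
}

#' Check a knowledge graph against a typed schema
#'
#' @param graph A `knowledge_graph`.
#' @param schema A schema as returned by [default_kg_schema()]; an edge type
#'   absent from `schema$edge_types` or endpoint types not matching the
#'   allowed pair is a violation. Undirected edge types match in either
#'   orientation. An empty `edge_types` table constrains nothing.
#' @return Data.frame of violations (`edge_index`, `source`, `target`,
#'   `type`, `reason`); zero rows when the graph conforms.
#' @export
validate_schema <- function(graph, schema = default_kg_schema()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  ntype <- stats::setNames(graph$nodes$type, graph$nodes$id)
  viol <- list()
  flag <- function(i, reason)
    viol[[length(viol) + 1]] <<- data.frame(
      edge_index = i, source = graph$edges$source[i],
      target = graph$edges$target[i], type = graph$edges$type[i],
      reason = reason, stringsAsFactors = FALSE)
  unknown_nt <- length(schema$node_types) &&
    any(!(graph$nodes$type %in% schema$node_types))
  if (unknown_nt) {
    for (id in graph$nodes$id[!(graph$nodes$type %in% schema$node_types)])
      viol[[length(viol) + 1]] <- data.frame(
        edge_index = NA_integer_, source = id, target = NA_character_,
        type = ntype[[id]], reason = "unknown node type",
        stringsAsFactors = FALSE)
  }
  et <- schema$edge_types
  if (!is.null(et) && nrow(et)) {
    for (i in seq_len(nrow(graph$edges))) {
      ty <- graph$edges$type[i]
      row <- et[et$type == ty, , drop = FALSE]
      if (!nrow(row)) { flag(i, "unknown edge type"); next }
      st <- ntype[[graph$edges$source[i]]]
      tt <- ntype[[graph$edges$target[i]]]
      ok <- (st == row$source_type[1] && tt == row$target_type[1]) ||
        (!row$directed[1] && st == row$target_type[1] &&
           tt == row$source_type[1])
      if (!ok) flag(i, sprintf("edge type '%s' requires %s-%s, found %s-%s",
                               ty, row$source_type[1], row$target_type[1],
                               st, tt))
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(edge_index = integer(), source = character(),
               target = character(), type = character(),
               reason = character(), stringsAsFactors = FALSE)
}
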