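#' Build an unweighted module graph from the continuous adjacency
#'
#' Thresholds the soft adjacency: vertices are the given genes, with an
#' edge between `i` and `j` iff `a_ij >= tau`. Isolated vertices are
#' retained. The continuous adjacency values are carried along for
#' weighted-degree tie-breaking and export; path computations on the graph
#' are unweighted.
#'
#' @param a Adjacency matrix (e.g. from [adjacency_matrix()]).
#' @param genes Character vector of vertex gene ids (subset of
#'   `rownames(a)`).
#' @param tau Edge threshold in `(0, 1]`.
#' @param biotypes Optional named biotype vector for the vertices.
#' @return An object of class `ModuleGraph`: list with `vertices`, `edges`
#'   (logical adjacency matrix), `weights` (continuous sub-adjacency),
#'   `biotype`, `tau`.
#' @export
build_module_graph <- function(a, genes, tau, biotypes = NULL) {
  if (tau <= 0 || tau > 1) stopf("tau must lie in (0, 1]")
  missing <- setdiff(genes, rownames(a))
  if (length(missing)) stopf("genes absent from adjacency: %s",
                             paste(head(missing, 5), collapse = ", "))
  w <- unclass(a)[genes, genes, drop = FALSE]
  diag(w) <- 0
  edges <- w >= tau
  diag(edges) <- FALSE
  if (!any(edges)) warnf("module graph has no edges at tau = %g", tau)
  bt <- setNames(rep("unknown", length(genes)), genes)
  if (!is.null(biotypes)) {
    common <- intersect(genes, names(biotypes))
    bt[common] <- biotypes[common]
  }
  structure(list(vertices = genes, edges = edges, weights = w,
                 biotype = bt, tau = tau),
            class = "ModuleGraph")
}

#' @export
print.ModuleGraph <- function(x, ...) {
  cat(sprintf("ModuleGraph: %d vertices, %d edges (tau = %g)\n",
              length(x$vertices), sum(x$edges) / 2, x$tau))
  invisible(x)
}

#' Breadth-first shortest-path tree with deterministic tie-break
#'
#' Builds the BFS shortest-path tree rooted at `s` over the connected
#' component of `s`. When a vertex has several neighbors at the previous
#' depth, the lexicographically smallest gene id becomes its parent, so
#' the tree (and every statistic computed on it) is deterministic.
#'
#' @param g A [build_module_graph()] object.
#' @param s Root vertex id.
#' @return A list with `root`, `parent` (named character vector; `NA` for
#'   the root) and `depth` (named integer vector over the component).
#' @export
shortest_path_tree <- function(g, s) {
  stopifnot(inherits(g, "ModuleGraph"))
  if (!s %in% g$vertices) stopf("root '%s' is not a vertex", s)
  adj <- g$edges
  depth <- setNames(NA_integer_, s)
  parent <- setNames(NA_character_, s)
  depth[s] <- 0L
  frontier <- s
  d <- 0L
  visited <- s
  while (length(frontier)) {
    nb <- adj[frontier, , drop = FALSE]
    reach <- g$vertices[colSums(nb) > 0]
    new <- sort(setdiff(reach, visited))
    if (!length(new)) break
    d <- d + 1L
    for (v in new) {
      cands <- frontier[adj[frontier, v]]
      parent[v] <- min(cands)
      depth[v] <- d
    }
    visited <- c(visited, new)
    frontier <- new
  }
  list(root = s, parent = parent, depth = depth)
}

#' Shortest-path-tree hub centrality
#'
#' For every root `s`, the BFS shortest-path tree `T_s` is built
#' ([shortest_path_tree()]); a vertex `v != s` "meets" the tree path from
#' `s` to `t` when it lies on that path (as an intermediate vertex or as
#' the destination `t` itself). The per-root indicator is
#' `p_s(v) = 1` iff the number of destinations `t` in `V(T_s) \ {s}`
#' whose path meets `v` strictly exceeds `|V(T_s)| / 4`, and the hub score
#' of `v` is `sum_s p_s(v)` over all roots. Because the path from `s`
#' meets `v` exactly for the destinations in `v`'s subtree, the count
#' equals the subtree size of `v` in `T_s`. For disconnected graphs each
#' root's tree covers only its component and `|V(T_s)|` is that
#' component's size.
#'
#' @param g A [build_module_graph()] object.
#' @return Named integer vector of hub scores (one per vertex; each score
#'   lies in `[0, |V| - 1]`).
#' @export
hub_scores <- function(g) {
  stopifnot(inherits(g, "ModuleGraph"))
  score <- setNames(rep(0L, length(g$vertices)), g$vertices)
  for (s in g$vertices) {
    spt <- shortest_path_tree(g, s)
    comp <- names(spt$depth)
    n_tree <- length(comp)
    if (n_tree <= 1) next
    size <- setNames(rep(1L, n_tree), comp)
    for (v in comp[order(-spt$depth)]) {
      p <- spt$parent[[v]]
      if (!is.na(p)) size[p] <- size[p] + size[v]
    }
    meets <- setdiff(comp, s)
    hit <- meets[size[meets] > n_tree / 4]
    score[hit] <- score[hit] + 1L
  }
  score
}

#' Select top-k hub genes
#'
#' Ranks vertices by hub score; ties are broken by higher weighted degree
#' in the continuous adjacency, then by lexicographic gene id. Fewer than
#' `k` vertices returns all of them, ranked.
#'
#' @param g A [build_module_graph()] object.
#' @param scores Named score vector from [hub_scores()] (computed from `g`
#'   if omitted).
#' @param k Number of hubs (default 20).
#' @return Data frame `gene`, `score`, `weighted_degree`, `biotype`,
#'   `rank`.
#' @export
select_hubs <- function(g, scores = NULL, k = 20) {
  stopifnot(inherits(g, "ModuleGraph"))
  if (k < 1) stopf("k must be >= 1")
  scores <- scores %||% hub_scores(g)
  wdeg <- rowSums(g$weights)
  ord <- order(-scores[g$vertices], -wdeg[g$vertices], g$vertices, method = "radix")
  top <- head(g$vertices[ord], k)
  data.frame(gene = top,
             score = as.integer(scores[top]),
             weighted_degree = wdeg[top],
             biotype = g$biotype[top],
             rank = seq_along(top),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Coding/non-coding (CNC) co-expression network over hub genes
#'
#' Connects hub genes whose absolute pairwise correlation reaches
#' `cor_threshold`; nodes carry biotype and hub score, edges carry the
#' signed correlation. When a set of differentially expressed lncRNAs
#' (DELs) is supplied, the key-lncRNA report is the intersection of the
#' hub lncRNAs with that set.
#'
#' @param hubs Data frame from [select_hubs()] (columns `gene`, `score`,
#'   `biotype`).
#' @param S Correlation matrix covering the hub genes.
#' @param cor_threshold Minimum `|correlation|` for an edge (default 0.7).
#' @param dels Optional character vector of DEL gene ids.
#' @return A list of class `CncNetwork`: `nodes` (gene, biotype, score),
#'   `edges` (from, to, correlation), `key_lncrna` (character vector).
#' @export
cnc_network <- function(hubs, S, cor_threshold = 0.7, dels = NULL) {
  genes <- hubs$gene
  missing <- setdiff(genes, rownames(S))
  if (length(missing)) stopf("hub genes absent from correlation matrix: %s",
                             paste(head(missing, 5), collapse = ", "))
  sub <- S[genes, genes, drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0),
                      correlation = numeric(0), stringsAsFactors = FALSE)
  if (length(genes) > 1) {
    idx <- which(abs(sub) >= cor_threshold & upper.tri(sub), arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                          correlation = sub[idx], stringsAsFactors = FALSE)
    }
  }
  hub_lnc <- hubs$gene[hubs$biotype == "lncRNA"]
  key <- if (is.null(dels)) character(0) else sort(intersect(hub_lnc, dels))
  structure(list(nodes = data.frame(gene = genes,
                                    biotype = hubs$biotype,
                                    score = hubs$score,
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 key_lncrna = key),
            class = "CncNetwork")
}

#' Export a CNC network as GraphML
#'
#' Cytoscape-compatible GraphML with node attributes `biotype` and
#' `score` and edge attribute `correlation`.
#'
#' @param net A [cnc_network()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "CncNetwork"))
  ig <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                      vertices = net$nodes)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export a CNC network as SIF
#'
#' Cytoscape simple-interaction format: `gene <tab> co <tab> gene` lines;
#' isolated nodes are written as single-column lines.
#'
#' @param net A [cnc_network()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "CncNetwork"))
  lines <- character(0)
  if (nrow(net$edges))
    lines <- sprintf("%s\tco\t%s", net$edges$from, net$edges$to)
  touched <- unique(c(net$edges$from, net$edges$to))
  isolated <- setdiff(net$nodes$gene, touched)
  lines <- c(lines, isolated)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
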