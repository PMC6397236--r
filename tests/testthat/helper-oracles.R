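## Independent oracles and fixture builders used across the test files.

## Brute-force hub centrality: build the BFS tree with igraph distances and
## the lexicographic parent rule, then enumerate every tree path s -> t
## explicitly and count, for each vertex, the paths it lies on. Independent
## of the subtree-size computation used by the package.
oracle_hub_scores <- function(g) {
  ids <- g$vertices
  ig <- igraph::graph_from_adjacency_matrix(g$edges * 1, mode = "undirected")
  D <- igraph::distances(ig)
  dimnames(D) <- list(ids, ids)
  score <- setNames(rep(0L, length(ids)), ids)
  for (s in ids) {
    comp <- ids[is.finite(D[s, ])]
    if (length(comp) <= 1) next
    parent <- setNames(rep(NA_character_, length(comp)), comp)
    for (v in setdiff(comp, s)) {
      nb <- ids[g$edges[v, ]]
      parent[v] <- min(nb[D[s, nb] == D[s, v] - 1])
    }
    cnt <- setNames(rep(0L, length(comp)), comp)
    for (t in setdiff(comp, s)) {
      v <- t
      while (v != s) {
        cnt[v] <- cnt[v] + 1L
        v <- parent[v]
      }
    }
    hit <- setdiff(names(cnt)[cnt > length(comp) / 4], s)
    score[hit] <- score[hit] + 1L
  }
  score
}

## Unweighted random connected graph on n labeled vertices.
random_connected_graph <- function(n) {
  ids <- sprintf("v%02d", seq_len(n))
  repeat {
    p <- runif(1, 0.25, 0.9)
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
    a <- a + t(a)
    reach <- diag(n) + a
    for (i in seq_len(n)) reach <- sign(reach %*% (diag(n) + a))
    if (all(reach > 0)) break
  }
  dimnames(a) <- list(ids, ids)
  build_module_graph(a, ids, tau = 0.5)
}

## Graph from an explicit edge list (unit adjacency).
edge_graph <- function(edges, ids) {
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  build_module_graph(a, ids, tau = 0.5)
}

## Step-up Benjamini-Hochberg from the definition:
## q(i) = min_{j >= i} min(1, m * p_(j) / j) on sorted p-values.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * sorted[i:m] / (i:m))), numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## Exhaustive hypergeometric upper tail P(X >= k): enumerate all C(N, n)
## draws of n items from a population with K successes.
enum_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

## TOM from the elementwise definition (triple loop).
brute_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    den <- min(ki, kj) + 1 - a[i, j]
    tom[i, j] <- if (den > 0) (l + a[i, j]) / den else 0
  }
  dimnames(tom) <- dimnames(a)
  tom
}

## Small ExpressionDataset from a bare matrix.
toy_dataset <- function(values, condition = NULL, tissue = NULL, batch = NULL,
                        biotype = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  samples <- data.frame(
    sample_id = colnames(values),
    tissue = tissue %||% rep("glomeruli", n),
    condition = condition %||% rep(c("control", "diabetic"), length.out = n),
    batch = batch %||% rep("B1", n),
    stringsAsFactors = FALSE)
  features <- data.frame(feature_id = rownames(values),
                         symbol = rownames(values),
                         biotype = biotype %||% rep("coding", nrow(values)),
                         stringsAsFactors = FALSE)
  expression_dataset(values, samples, features)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Module-recovery study conditions: 5 planted modules of 60 genes,
## loading 0.8, 60 samples, no DE planting.
recovery_config <- function(seed) {
  simulation_config(
    n_genes = 300, n_lncrna = 0, module_sizes = rep(60L, 5),
    module_trait_cor = c(0.75, -0.75, 0.5, -0.5, 0),
    within_module_cor = 0.8, n_samples_per_group = 15,
    n_de_genes = 0, noise_sd = 0.6, seed = seed)
}
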