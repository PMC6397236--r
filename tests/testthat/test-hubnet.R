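test_that("module graph construction thresholds the adjacency", {
  a <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  g <- build_module_graph(a, letters[1:4], tau = 0.5)
  expect_equal(sum(g$edges) / 2, 6)            # complete graph

  a2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  a2["a", "b"] <- a2["b", "a"] <- 0.9
  a2["b", "c"] <- a2["c", "b"] <- 0.6
  a2["c", "d"] <- a2["d", "c"] <- 0.55
  a2["a", "d"] <- a2["d", "a"] <- 0.2
  g2 <- build_module_graph(a2, letters[1:4], tau = 0.5)
  expect_equal(sum(g2$edges) / 2, 3)
  expect_false(g2$edges["a", "d"])

  # tau = 1 keeps only unit-adjacency edges
  g3 <- suppressWarnings(build_module_graph(a2, letters[1:4], tau = 1))
  expect_equal(sum(g3$edges), 0)
  expect_error(build_module_graph(a2, letters[1:4], tau = 0), "tau")
  expect_warning(build_module_graph(a2, letters[1:2], tau = 1), "no edges")
})

test_that("shortest-path tree uses BFS depths and lexicographic parents", {
  g <- edge_graph(list(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  spt <- shortest_path_tree(g, "a")
  expect_equal(spt$parent[["b"]], "a")
  expect_equal(spt$parent[["c"]], "b")
  expect_equal(unname(spt$depth[c("a", "b", "c")]), c(0, 1, 2))

  # square a-b-c-d-a rooted at a: c reachable via b or d -> parent b
  sq <- edge_graph(list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")),
                   c("a", "b", "c", "d"))
  spt2 <- shortest_path_tree(sq, "a")
  expect_equal(spt2$parent[["c"]], "b")

  # isolated root spans only itself
  iso <- edge_graph(list(c("a", "b")), c("a", "b", "z"))
  spt3 <- shortest_path_tree(iso, "z")
  expect_equal(names(spt3$depth), "z")
  expect_error(shortest_path_tree(iso, "q"), "not a vertex")
})

test_that("hub scores match hand enumeration on canonical graphs", {
  # path a-b-c-d: all four roots enumerated by hand give (0, 3, 3, 0)
  path <- edge_graph(list(c("a", "b"), c("b", "c"), c("c", "d")),
                     c("a", "b", "c", "d"))
  expect_equal(unname(hub_scores(path)), c(0, 3, 3, 0))

  # star: center scores n - 1, leaves 0
  for (n in c(4, 7)) {
    ids <- c("c0", sprintf("l%d", seq_len(n - 1)))
    star <- edge_graph(lapply(ids[-1], function(l) c("c0", l)), ids)
    sc <- hub_scores(star)
    expect_equal(unname(sc["c0"]), n - 1)
    expect_true(all(sc[-1] == 0))
  }

  single <- suppressWarnings(edge_graph(list(), "a"))
  expect_equal(unname(hub_scores(single)), 0)
})

test_that("hub scores equal the brute-force path enumeration oracle", {
  set.seed(31)
  for (rep in 1:60) {
    g <- random_connected_graph(sample(3:7, 1))
    expect_identical(hub_scores(g), oracle_hub_scores(g))
  }
})

test_that("scores are bounded and equivariant under order-preserving relabeling", {
  ## The centrality depends on the BFS tree, which is made deterministic by
  ## the lexicographic parent rule; an order-preserving renaming therefore
  ## leaves every tree, and every score, unchanged.
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    g <- random_connected_graph(n)
    sc <- hub_scores(g)
    expect_true(all(sc >= 0 & sc <= n - 1))
    new_ids <- sprintf("w%03d", seq_len(n) * 2)  # same lexicographic order
    a2 <- g$weights
    rownames(a2) <- colnames(a2) <- new_ids
    g2 <- build_module_graph(a2, new_ids, tau = 0.5)
    expect_equal(unname(hub_scores(g2)), unname(sc))
  }
})

test_that("hub selection ranks by score, weighted degree, then id", {
  a <- matrix(0.1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(a) <- 0
  a["a", "b"] <- a["b", "a"] <- 0.9
  g <- build_module_graph(a, letters[1:5], tau = 0.05)
  sc <- setNames(c(3L, 3L, 1L, 0L, 0L), letters[1:5])
  hubs <- select_hubs(g, scores = sc, k = 3)
  # a and b tie at 3; both have the same weighted degree boost; id breaks it
  expect_equal(hubs$gene[1:2], c("a", "b"))
  expect_equal(hubs$gene[3], "c")
  expect_equal(hubs$rank, 1:3)

  # tie broken by weighted degree when degrees differ
  a2 <- a
  a2["b", "c"] <- a2["c", "b"] <- 0.95
  g2 <- build_module_graph(a2, letters[1:5], tau = 0.05)
  sc2 <- setNames(c(2L, 2L, 0L, 0L, 0L), letters[1:5])
  hubs2 <- select_hubs(g2, scores = sc2, k = 2)
  expect_equal(hubs2$gene[1], "b")

  # fewer vertices than k: all returned
  expect_equal(nrow(select_hubs(g, scores = sc, k = 20)), 5)
  expect_error(select_hubs(g, scores = sc, k = 0), "k must be")
})

test_that("CNC network edges, attributes and key-lncRNA report", {
  S <- diag(4)
  dimnames(S) <- list(c("h1", "h2", "h3", "h4"), c("h1", "h2", "h3", "h4"))
  S["h1", "h2"] <- S["h2", "h1"] <- 0.9
  S["h1", "h3"] <- S["h3", "h1"] <- -0.8
  S["h2", "h3"] <- S["h3", "h2"] <- 0.3
  hubs <- data.frame(gene = c("h1", "h2", "h3", "h4"),
                     score = c(3L, 2L, 1L, 0L),
                     biotype = c("coding", "lncRNA", "coding", "lncRNA"),
                     stringsAsFactors = FALSE)
  net <- cnc_network(hubs, S, cor_threshold = 0.7, dels = c("h2", "h9"))
  expect_equal(nrow(net$edges), 2)
  expect_true(any(net$edges$correlation < 0))
  expect_equal(net$key_lncrna, "h2")

  # no lncRNA among hubs -> empty report
  hubs2 <- hubs; hubs2$biotype <- "coding"
  expect_equal(cnc_network(hubs2, S, dels = c("h2"))$key_lncrna, character(0))
  # no DEL set -> empty report
  expect_equal(cnc_network(hubs, S)$key_lncrna, character(0))
})

test_that("GraphML and SIF exports round-trip through igraph", {
  S <- diag(3)
  dimnames(S) <- list(c("a", "b", "c"), c("a", "b", "c"))
  S["a", "b"] <- S["b", "a"] <- 0.85
  hubs <- data.frame(gene = c("a", "b", "c"), score = c(2L, 1L, 0L),
                     biotype = c("coding", "lncRNA", "coding"),
                     stringsAsFactors = FALSE)
  net <- cnc_network(hubs, S, cor_threshold = 0.7)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::V(back)$name), c("a", "b", "c"))
  expect_equal(igraph::ecount(back), 1)
  expect_equal(igraph::E(back)$correlation, 0.85, tolerance = 1e-12)
  expect_setequal(igraph::V(back)$biotype, c("coding", "lncRNA", "coding"))

  sif <- tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(lines[1], "a\tco\tb")
  expect_true("c" %in% lines)          # isolated vertex kept
})

test_that("planted high-connectivity lncRNAs surface as hubs", {
  cfg <- standard_preset(seed = 1)
  sim <- generate_dataset(cfg)
  ds <- sim$dataset
  m1 <- names(sim$truth$module)[sim$truth$module == "M1"]
  S <- correlation_matrix(subset_dataset(ds, features = m1))
  a <- adjacency_matrix(S, 6)
  bt <- setNames(ds$features$biotype, ds$features$feature_id)
  g <- build_module_graph(a, m1, tau = 0.02, biotypes = bt)
  hubs <- select_hubs(g, k = 20)
  expect_true(all(sim$truth$hub_lncrna %in% hubs$gene))
  net <- cnc_network(hubs, S, dels = sim$truth$hub_lncrna)
  expect_setequal(net$key_lncrna, sim$truth$hub_lncrna)
})
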