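test_that("variance filter keeps the top-variance genes with lexicographic ties", {
  v <- rbind(gB = c(0, 4, 0, 4),   # var 16/3
             gA = c(0, 2, 0, 2),   # var 4/3
             gC = c(0, 0, 0, 0.3),
             gD = c(4, 0, 4, 0),   # var 16/3 (tie with gB)
             gE = c(1, 1, 1, 1))
  ds <- toy_dataset(v)
  expect_equal(rownames(variance_filter(ds, 2)$values), c("gB", "gD"))
  expect_identical(variance_filter(ds, 5)$values, ds$values)
  # exact tie between gB and gD broken towards gB when only one fits
  expect_equal(rownames(variance_filter(ds, 1)$values), "gB")
  expect_error(variance_filter(ds, 0), "n_top")
  expect_error(variance_filter(ds, 9), "exceeds")
})

test_that("power adjacency follows |S|^beta", {
  S <- matrix(c(1, 0.5, -0.5,
                0.5, 1, 0.25,
                -0.5, 0.25, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  a <- adjacency_matrix(S, 6)
  expect_equal(a["a", "b"], 0.015625)
  expect_equal(a["a", "c"], 0.015625)   # absolute value first
  expect_equal(unname(diag(unclass(a))), c(0, 0, 0))
  a1 <- adjacency_matrix(S, 1)
  expect_equal(a1["a", "c"], 0.5)
  expect_error(adjacency_matrix(S, 0.5), "beta")
})

test_that("adjacency of correlation is permutation-equivariant", {
  cfg <- simulation_config(n_genes = 30, module_sizes = 15,
                           module_trait_cor = 0.4, n_samples_per_group = 5,
                           seed = 21)
  ds <- generate_dataset(cfg)$dataset
  a <- adjacency_matrix(correlation_matrix(ds), 6)
  perm <- sample(rownames(ds$values))
  ds2 <- subset_dataset(ds, features = perm)
  a2 <- adjacency_matrix(correlation_matrix(ds2), 6)
  expect_equal(unclass(a2), unclass(a)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("TOM matches hand values on 3-node graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  tom <- topological_overlap(tri)
  expect_equal(tom[1, 2], 1)           # (1 + 1) / (2 + 1 - 1)
  one <- matrix(0, 3, 3); one[1, 2] <- one[2, 1] <- 1
  tom1 <- topological_overlap(one)
  expect_equal(tom1[1, 2], 1)          # (0 + 1) / (1 + 1 - 1)
  expect_equal(tom1[1, 3], 0)
  zero <- matrix(0, 3, 3)
  expect_equal(unname(topological_overlap(zero)), diag(3))
})

test_that("TOM agrees with the elementwise definition on random graphs", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < 0.5)
    a <- a + t(a)
    tom <- topological_overlap(a)
    expect_equal(tom, brute_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom))
  }
  # and on weighted adjacencies
  for (i in 1:10) {
    n <- sample(3:6, 1)
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- runif(n * (n - 1) / 2)
    a <- a + t(a)
    expect_equal(topological_overlap(a), brute_tom(a), tolerance = 1e-12)
  }
})

test_that("soft threshold selection returns the target-reaching beta", {
  cfg <- simulation_config(n_genes = 500, module_sizes = rep(50L, 10),
                           module_trait_cor = rep(0, 10),
                           within_module_cor = 0.8, n_samples_per_group = 15,
                           seed = 7)
  S <- correlation_matrix(generate_dataset(cfg)$dataset)
  p <- pick_soft_threshold(S)
  expect_true(p$reached_target)
  expect_lte(p$beta, 12)
  expect_gte(p$fit_table$signed_r2[p$fit_table$beta == p$beta], 0.8)

  expect_equal(suppressWarnings(pick_soft_threshold(S, candidates = 6))$beta, 6)
})

test_that("independent noise falls back to the best-fit beta with a warning", {
  cfg <- simulation_config(n_genes = 200, n_samples_per_group = 15, seed = 3)
  S <- correlation_matrix(generate_dataset(cfg)$dataset)
  expect_warning(p <- pick_soft_threshold(S), "falling back")
  expect_false(p$reached_target)
})

test_that("planted modules are recovered with the right colors and sizes", {
  skip_if_not_installed("mclust")
  cfg <- simulation_config(n_genes = 120, module_sizes = c(50, 50),
                           module_trait_cor = c(0, 0), within_module_cor = 0.9,
                           n_samples_per_group = 15, seed = 23)
  sim <- generate_dataset(cfg)
  tom <- topological_overlap(adjacency_matrix(correlation_matrix(sim$dataset), 6))
  colors <- detect_modules(1 - tom, min_module_size = 30)
  expect_equal(length(setdiff(unique(colors), "grey")), 2)
  expect_gte(mclust::adjustedRandIndex(colors, sim$truth$module[names(colors)]),
             0.9)
  # determinism
  colors2 <- detect_modules(1 - tom, min_module_size = 30)
  expect_identical(unname(colors), unname(colors2))
  # canonical color order, largest first
  sizes <- table(colors[colors != "grey"])
  expect_true(all(names(sizes) %in% c("turquoise", "blue")))
})

test_that("undersized clusters go grey", {
  v <- matrix(rnorm(80), 8, 10)
  tom <- topological_overlap(adjacency_matrix(cor(t(v)), 6))
  expect_warning(colors <- detect_modules(1 - tom, min_module_size = 100),
                 "grey")
  expect_true(all(colors == "grey"))
})

test_that("eigengenes summarize, orient and recover the latent factor", {
  # identical genes -> eigengene correlates 1 with each member
  prof <- rnorm(12)
  v <- matrix(rep(prof, each = 4), 4, 12,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  ds <- toy_dataset(v + rnorm(48, sd = 1e-8))
  colors <- setNames(rep("turquoise", 4), rownames(v))
  me <- module_eigengenes(ds, colors)
  expect_equal(abs(cor(me["turquoise", ], prof)), 1, tolerance = 1e-6)
  expect_gt(cor(me["turquoise", ], as.numeric(ds$values[1, ])), 0)

  # negating the module flips the eigengene but orientation restores it
  ds_neg <- ds; ds_neg$values <- -ds_neg$values
  me_neg <- module_eigengenes(ds_neg, colors)
  expect_gt(mean(cor(me_neg["turquoise", ], t(ds_neg$values))), 0)

  # planted eigengene recovery
  cfg <- simulation_config(n_genes = 60, module_sizes = 60,
                           module_trait_cor = 0.5, within_module_cor = 0.8,
                           n_samples_per_group = 15, seed = 24)
  sim <- generate_dataset(cfg)
  col2 <- setNames(rep("blue", 60), rownames(sim$dataset$values))
  me2 <- module_eigengenes(sim$dataset, col2)
  expect_gte(abs(cor(me2["blue", ], sim$truth$eigengenes["M1", ])), 0.9)

  # single-gene module: z-scored profile
  col3 <- setNames(c("brown", rep("grey", 3)), rownames(v))
  me3 <- module_eigengenes(ds, col3)
  expect_equal(unname(me3["brown", ]),
               as.numeric(scale(as.numeric(ds$values[1, ]))), tolerance = 1e-6)
  expect_false("grey" %in% rownames(me3))
})

test_that("module-trait correlation uses the exact t transform", {
  z <- rep(c(0, 1), each = 6)
  me <- rbind(m1 = z, m2 = rnorm(12))
  me["m2", ] <- me["m2", ] - z * sum(me["m2", ] * z) / sum(z)  # roughly orthogonal
  mt <- module_trait_correlation(rbind(m1 = z), data.frame(trait = z))
  expect_equal(mt$correlation[1, 1], 1)
  expect_lt(mt$p[1, 1], 1e-12)

  # orthogonal constructed case
  e <- c(1, -1, 1, -1)
  tr <- c(1, 1, 0, 0) # cor(e, tr) = 0 exactly
  mt2 <- module_trait_correlation(rbind(m = e), data.frame(trait = tr))
  expect_equal(mt2$correlation[1, 1], 0, tolerance = 1e-9)
  expect_equal(mt2$p[1, 1], 1, tolerance = 1e-9)

  expect_error(module_trait_correlation(rbind(m = e), data.frame(t = rep(1, 4))),
               "zero variance")

  # agreement with cor.test on random data
  set.seed(25)
  e2 <- rnorm(20); t2 <- rnorm(20)
  mt3 <- module_trait_correlation(rbind(m = e2), data.frame(t = t2))
  ct <- cor.test(e2, t2)
  expect_equal(mt3$p[1, 1], ct$p.value, tolerance = 1e-9)
})

test_that("gene significance and per-module means exclude grey", {
  cfg <- simulation_config(n_genes = 40, module_sizes = 20,
                           module_trait_cor = 0.8, within_module_cor = 0.9,
                           n_samples_per_group = 10, seed = 26)
  sim <- generate_dataset(cfg)
  trait <- as.numeric(sim$dataset$samples$condition == "diabetic")
  gs <- gene_significance(sim$dataset, trait)
  expect_true(all(gs$gs >= 0 & gs$gs <= 1))
  in_mod <- sim$truth$module == "M1"
  expect_gt(mean(gs$gs[in_mod]), mean(gs$gs[!in_mod]))
  colors <- setNames(ifelse(in_mod, "turquoise", "grey"),
                     names(sim$truth$module))
  mgs <- module_gene_significance(sim$dataset, colors, trait)
  expect_equal(mgs$module, "turquoise")
  expect_equal(mgs$mean_gs, mean(gs$gs[in_mod]), tolerance = 1e-12)
})
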