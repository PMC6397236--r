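test_that("pure location batch effect is removed exactly", {
  set.seed(1)
  v <- matrix(rnorm(200), 20, 10)
  batch <- rep(c("A", "B"), each = 5)
  v[, batch == "B"] <- v[, batch == "B"] + 5
  ds <- toy_dataset(v, batch = batch)
  out <- remove_batch_effects(ds)
  mA <- rowMeans(out$values[, batch == "A"])
  mB <- rowMeans(out$values[, batch == "B"])
  expect_lt(max(abs(mA - mB)), 1e-9)
  # global gene means preserved
  expect_equal(unname(rowMeans(out$values)), unname(rowMeans(ds$values)),
               tolerance = 1e-9)
})

test_that("single batch is the identity; singleton batches error", {
  v <- matrix(rnorm(40), 4, 10)
  ds <- toy_dataset(v)
  expect_identical(remove_batch_effects(ds)$values, ds$values)
  ds2 <- toy_dataset(v, batch = c("A", rep("B", 9)))
  expect_error(remove_batch_effects(ds2), "single sample")
})

test_that("planted batch variance is removed from the generator output", {
  bl <- rep(c("A", "B"), 30)
  cfg <- simulation_config(n_genes = 150, n_samples_per_group = 15,
                           batch_labels = bl, batch_sd = 2, seed = 2)
  sim <- generate_dataset(cfg)
  clean <- remove_batch_effects(sim$dataset)
  fb <- factor(bl)
  r2 <- apply(clean$values, 1, function(x) summary(lm(x ~ fb))$r.squared)
  expect_lt(mean(r2), 0.02)
})

test_that("d0 = 0 recovers the ordinary pooled t-test", {
  set.seed(3)
  v <- matrix(rnorm(300), 30, 10)
  ds <- toy_dataset(v)
  v <- ds$values
  ga <- colnames(v)[1:5]; gb <- colnames(v)[6:10]
  res <- moderated_t_test(ds, ga, gb, d0 = 0)
  for (i in c(1, 7, 30)) {
    tt <- t.test(v[i, 1:5], v[i, 6:10], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("moderated test matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(4)
  v <- matrix(rnorm(2000), 200, 10)
  v[1:20, 1:5] <- v[1:20, 1:5] + 2
  ds <- toy_dataset(v)
  v <- ds$values
  ga <- colnames(v)[1:5]; gb <- colnames(v)[6:10]
  mine <- moderated_t_test(ds, ga, gb)
  grp <- rep(c("A", "B"), each = 5)
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- c("A", "B")
  fit <- limma::lmFit(v, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - B, levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0")^2, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(mine$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("degenerate constant genes are flagged with t = 0, p = 1", {
  v <- rbind(g1 = c(1, 1, 1, 2, 2, 2) * 0 + 5,  # constant and equal
             g2 = c(3, 3, 3, 9, 9, 9),           # constant, different means
             g3 = rnorm(6))
  ds <- toy_dataset(v)
  v <- ds$values
  res <- moderated_t_test(ds, colnames(v)[1:3], colnames(v)[4:6])
  expect_true(res$degenerate[1])
  expect_true(res$degenerate[2])
  expect_equal(res$t[1:2], c(0, 0))
  expect_equal(res$p[1:2], c(1, 1))
  expect_equal(res$call[1:2], c("ns", "ns"))
})

test_that("moderated test is invariant to sample order and per-gene shifts", {
  set.seed(5)
  v <- matrix(rnorm(500), 50, 10)
  ds <- toy_dataset(v)
  v <- ds$values
  ga <- colnames(v)[1:5]; gb <- colnames(v)[6:10]
  r1 <- moderated_t_test(ds, ga, gb)
  r2 <- moderated_t_test(ds, rev(ga), sample(gb))
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  v2 <- v
  v2[7, ] <- v2[7, ] + 100
  r3 <- moderated_t_test(toy_dataset(v2), ga, gb)
  expect_equal(r1$t[7], r3$t[7], tolerance = 1e-9)
  expect_equal(r1$p[7], r3$p[7], tolerance = 1e-9)
})

test_that("filter_degs applies inclusive thresholds on |log2fc| and p", {
  res <- data.frame(
    gene = paste0("g", 1:6),
    log2fc = c(1.0, 0.99, -1.4, 2.0, 0.5, -3.0),
    t = 0, p = c(0.05, 0.001, 0.04, 0.2, 0.01, 0.049),
    p_adj = c(0.3, 0.01, 0.06, 0.5, 0.02, 0.051),
    stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  out <- filter_degs(res)
  # g1 boundary-inclusive pass; g2 fails fc; g4 fails p; g5 fails fc
  expect_setequal(out$gene, c("g1", "g3", "g6"))
  expect_equal(out$sign[out$gene == "g3"], -1)
  out_adj <- filter_degs(res, use_adjusted = TRUE)
  expect_setequal(out_adj$gene, character(0))
  expect_error(filter_degs(res, fc_threshold = 0), "thresholds")
})

test_that("intersect_degs returns the intersection minus exclusions with Venn counts", {
  r <- intersect_degs(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(r$genes, c("B", "C"))
  expect_equal(unname(r$venn), c(1, 1, 2, 0))
  r2 <- intersect_degs(c("A", "B", "C"), c("B", "C", "D"), exclusion = "C")
  expect_equal(r2$genes, "B")
  expect_equal(r2$venn[["excluded"]], 1)
  r3 <- intersect_degs(c("A", "B"), c("X", "Y"))
  expect_equal(r3$genes, character(0))
  expect_equal(unname(r3$venn), c(2, 2, 0, 0))
})

test_that("BH adjustment equals the step-up definition on random vectors", {
  set.seed(6)
  for (i in 1:100) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
  # and the package's DEResult p_adj column agrees
  v <- matrix(rnorm(300), 30, 10)
  ds <- toy_dataset(v)
  v <- ds$values
  res <- moderated_t_test(ds, colnames(v)[1:5], colnames(v)[6:10])
  expect_equal(res$p_adj, brute_bh(res$p), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("PCA: rank-1 matrix, duplicated samples, sign convention, errors", {
  u <- rnorm(20); w <- rnorm(6)
  v <- outer(u, w)
  dimnames(v) <- list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6))
  pc <- pca_coordinates(toy_dataset(v), k = 2)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-9)

  v2 <- cbind(v, v[, 3, drop = FALSE])
  colnames(v2) <- c(colnames(v), "s3dup")
  pc2 <- pca_coordinates(toy_dataset(v2), k = 2)
  expect_equal(pc2$coordinates["s3", ], pc2$coordinates["s3dup", ],
               tolerance = 1e-9)

  # largest-magnitude loading positive
  for (j in 1:2) {
    l <- pc$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_error(pca_coordinates(toy_dataset(v), k = 10), "exceeds")
})

test_that("PCA separates strongly shifted condition groups", {
  cfg <- simulation_config(n_genes = 100, n_samples_per_group = 5,
                           n_de_genes = 50, de_log2fc = 4, seed = 7)
  sim <- generate_dataset(cfg)
  pc <- pca_coordinates(sim$dataset, k = 2)
  dis <- sim$dataset$samples$condition == "diabetic"
  x <- pc$coordinates[, 1]
  expect_true(max(x[dis]) < min(x[!dis]) || min(x[dis]) > max(x[!dis]))
})

test_that("outlier detection flags shifted samples and spares clean data", {
  flagged_none <- vapply(1:20, function(seed) {
    sim <- generate_dataset(simulation_config(n_genes = 100,
                                              n_samples_per_group = 5,
                                              seed = seed))
    length(detect_outlier_samples(sim$dataset)) == 0
  }, logical(1))
  expect_gte(mean(flagged_none), 0.95)

  sim <- generate_dataset(simulation_config(n_genes = 100,
                                            n_samples_per_group = 5, seed = 1))
  ds <- sim$dataset
  ds$values[, "GC_01"] <- ds$values[, "GC_01"] + 10
  expect_equal(detect_outlier_samples(ds), "GC_01")

  v <- matrix(1, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(detect_outlier_samples(toy_dataset(v)), character(0))
  expect_error(detect_outlier_samples(toy_dataset(v[, 1:3])), ">= 4 samples")
})
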