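#' Remove batch effects by per-batch location/scale adjustment
#'
#' Per gene and per batch, subtracts the batch mean and rescales the batch
#' standard deviation to the pooled within-batch standard deviation, then
#' restores the gene's global mean. Condition-group means are affected
#' only through the batch terms (pure location/scale adjustment, no
#' covariate modeling). With a single batch the transform is the identity.
#'
#' @param dataset An [expression_dataset()] whose `samples$batch` holds the
#'   batch labels. Every batch must contain at least 2 samples.
#' @return The adjusted `ExpressionDataset`.
#' @export
remove_batch_effects <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  batch <- as.character(dataset$samples$batch)
  batches <- unique(batch)
  if (length(batches) < 2) return(dataset)
  sizes <- table(batch)
  if (any(sizes < 2))
    stopf("batch(es) with a single sample (scale undefined): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  x <- dataset$values
  gmean <- rowMeans(x)
  bmean <- vapply(batches, function(b) rowMeans(x[, batch == b, drop = FALSE]),
                  numeric(nrow(x)))
  bvar <- vapply(batches, function(b) apply(x[, batch == b, drop = FALSE], 1, var),
                 numeric(nrow(x)))
  df <- as.numeric(sizes[batches]) - 1
  pooled_sd <- sqrt(as.vector(bvar %*% df) / sum(df))
  out <- x
  for (b in batches) {
    idx <- batch == b
    centered <- x[, idx, drop = FALSE] - bmean[, b]
    sdb <- sqrt(bvar[, b])
    scale <- ifelse(sdb > 0, pooled_sd / sdb, 1)
    out[, idx] <- centered * scale + gmean
  }
  dataset$values <- out
  dataset
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' For every gene, computes the two-sample mean difference on the log2
#' scale (`log2fc = mean(group_a) - mean(group_b)`), the pooled variance
#' `s^2` with `d = n_a + n_b - 2` residual degrees of freedom, and a
#' moderated t-statistic in which `s^2` is shrunk towards a prior variance
#' `s0^2` with `d0` prior degrees of freedom:
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`,
#' `t_mod = log2fc / (s_tilde * sqrt(1/n_a + 1/n_b))`, two-sided p-value
#' from the t distribution with `d0 + d` degrees of freedom. `(d0, s0^2)`
#' are estimated from the marginal distribution of the gene-wise `s^2` by
#' method of moments on `log(s^2)` (mean and variance of log-variances
#' matched to the scaled-F marginal; trigamma inversion). Benjamini-
#' Hochberg adjustment is applied across genes.
#'
#' Genes with zero variance in both groups are flagged degenerate and
#' reported with `t = 0`, `p = 1`.
#'
#' @param dataset An [expression_dataset()].
#' @param group_a,group_b Character vectors of sample ids (each of size
#'   >= 2); `group_a` is the case group (positive `log2fc` = higher in
#'   `group_a`).
#' @param d0,s0 Optional overrides of the prior degrees of freedom and
#'   prior standard deviation; `d0 = 0` gives the ordinary pooled t-test.
#' @param fc_threshold,p_threshold Thresholds used for the convenience
#'   `call` column (up/down/ns), on the fold-change scale and raw p scale.
#' @return A data frame of class `DEResult` with columns `gene`, `log2fc`,
#'   `t`, `p`, `p_adj`, `call`, `degenerate`, plus attributes `d0`, `s0`,
#'   `df_total`.
#' @export
moderated_t_test <- function(dataset, group_a, group_b,
                             d0 = NULL, s0 = NULL,
                             fc_threshold = 2, p_threshold = 0.05) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  x <- dataset$values
  miss <- setdiff(c(group_a, group_b), colnames(x))
  if (length(miss)) stopf("unknown sample id(s): %s", paste(miss, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    stopf("groups overlap: %s", paste(intersect(group_a, group_b), collapse = ", "))
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stopf("each group needs >= 2 samples (got %d and %d)", na, nb)

  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  log2fc <- ma - mb
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  d <- na + nb - 2
  s2 <- (ssa + ssb) / d
  degenerate <- s2 <= 0

  if (is.null(d0) || is.null(s0)) {
    eb <- fit_variance_prior(s2[!degenerate], d)
    if (is.null(d0)) d0 <- eb$d0
    if (is.null(s0)) s0 <- eb$s0
  }
  s02 <- s0^2
  if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
  } else {
    s2_tilde <- (d0 * s02 + d * s2) / (d0 + d)
  }
  ## total df capped at the pooled residual df across genes: the prior can
  ## never be more informative than the data it was estimated from
  df_total <- min(d0 + d, sum(!degenerate) * d)
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  t_mod[degenerate] <- 0
  p[degenerate] <- 1
  p_adj <- p.adjust(p, method = "BH")

  lfc_cut <- log2(fc_threshold)
  call <- ifelse(p <= p_threshold & log2fc >= lfc_cut, "up",
                 ifelse(p <= p_threshold & log2fc <= -lfc_cut, "down", "ns"))
  call[degenerate] <- "ns"
  res <- data.frame(gene = rownames(x), log2fc = log2fc, t = t_mod,
                    p = p, p_adj = p_adj, call = call,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0") <- s0
  attr(res, "df_total") <- df_total
  class(res) <- c("DEResult", "data.frame")
  res
}

## Method-of-moments fit of the variance prior (d0, s0^2) from gene-wise
## pooled variances s2 with d residual df each. Marginally s2 ~ s0^2 *
## F(d, d0); matching mean/variance of log(s2) gives
##   var(log s2) - trigamma(d/2) = trigamma(d0/2)
##   mean(log s2) = log(s0^2) + digamma(d/2) - digamma(d0/2) - log(d/d0)
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s0 = sqrt(mean(s2))))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    ## log-variances no more dispersed than a chi-square: infinite prior
    ## df, prior variance = plain mean of the sample variances
    d0 <- Inf
    s0 <- sqrt(mean(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- sqrt(exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
  }
  list(d0 = d0, s0 = s0)
}

#' Filter differentially expressed genes
#'
#' A gene passes iff `|log2fc| >= log2(fc_threshold)` and the chosen
#' p-value (raw by default, BH-adjusted with `use_adjusted = TRUE`) is
#' `<= p_threshold`; both boundaries inclusive. The sign of the log2 fold
#' change is reported per passing gene.
#'
#' @param result A `DEResult` from [moderated_t_test()].
#' @param fc_threshold Fold-change threshold (> 0, on the fold-change
#'   scale; default 2.0).
#' @param p_threshold P-value threshold (> 0; default 0.05).
#' @param use_adjusted Use BH-adjusted p-values instead of raw p-values.
#' @return Data frame with columns `gene`, `sign`, `log2fc`, `p_used`.
#' @export
filter_degs <- function(result, fc_threshold = 2.0, p_threshold = 0.05,
                        use_adjusted = FALSE) {
  stopifnot(inherits(result, "DEResult") || is.data.frame(result))
  if (fc_threshold <= 0 || p_threshold <= 0) stopf("thresholds must be > 0")
  p_used <- if (use_adjusted) result$p_adj else result$p
  pass <- abs(result$log2fc) >= log2(fc_threshold) & p_used <= p_threshold
  out <- data.frame(gene = result$gene[pass],
                    sign = sign(result$log2fc[pass]),
                    log2fc = result$log2fc[pass],
                    p_used = p_used[pass],
                    stringsAsFactors = FALSE)
  out[order(out$p_used, out$gene), , drop = FALSE]
}

#' Intersect two DEG lists with an optional exclusion set
#'
#' Returns `(a` \eqn{\cap} `b) \ exclusion` together with the Venn counts
#' (a-only, b-only, both, excluded-from-both).
#'
#' @param list_a,list_b Character vectors of gene ids (e.g. DEGs of the
#'   tubuli and glomeruli contrasts).
#' @param exclusion Optional character vector of genes to remove from the
#'   intersection (user-supplied irrelevant-gene list).
#' @return A list with `genes` (sorted character vector) and `venn`
#'   (named integer vector `a_only`, `b_only`, `both`, `excluded`).
#' @export
intersect_degs <- function(list_a, list_b, exclusion = NULL) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  both <- intersect(a, b)
  excluded <- intersect(both, exclusion %||% character(0))
  genes <- sort(setdiff(both, excluded))
  list(genes = genes,
       venn = c(a_only = length(setdiff(a, b)),
                b_only = length(setdiff(b, a)),
                both = length(both),
                excluded = length(excluded)))
}

#' Sample PCA coordinates
#'
#' Principal component analysis of the samples: singular value
#' decomposition of the gene-centered matrix (each gene centered across
#' samples). Sign convention: for each component the largest-magnitude
#' gene loading is made positive, so coordinates are reproducible.
#'
#' @param dataset An [expression_dataset()].
#' @param k Number of components (`k <= min(genes, samples)`).
#' @return A list with `coordinates` (samples x k), `explained_variance`
#'   (length-k fractions, summing to <= 1) and `loadings` (genes x k).
#' @export
pca_coordinates <- function(dataset, k = 3) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  x <- dataset$values
  if (k > min(dim(x))) stopf("k = %d exceeds min(genes, samples) = %d", k, min(dim(x)))
  xc <- t(x - rowMeans(x))           # samples x genes, gene-centered
  sv <- svd(xc, nu = k, nv = k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  dimnames(coords) <- list(colnames(x), paste0("PC", seq_len(k)))
  loadings <- sv$v
  dimnames(loadings) <- list(rownames(x), paste0("PC", seq_len(k)))
  list(coordinates = coords,
       explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       loadings = loadings)
}

#' Detect outlier samples by hierarchical clustering
#'
#' Average-linkage clustering of samples on Euclidean distance; a sample
#' is flagged when the height at which it first merges into the dendrogram
#' exceeds `mean + z_cut * sd` of all merge heights.
#'
#' @param dataset An [expression_dataset()] with >= 4 samples.
#' @param z_cut Robustness multiplier (default 2.5).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(dataset, z_cut = 2.5) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  x <- dataset$values
  if (ncol(x) < 4) stopf("need >= 4 samples")
  hc <- hclust(dist(t(x)), method = "average")
  h <- hc$height
  cutoff <- mean(h) + z_cut * sd(h)
  if (!is.finite(cutoff)) cutoff <- mean(h)
  merge_height <- vapply(seq_len(ncol(x)), function(i) {
    row <- which(hc$merge[, 1] == -i | hc$merge[, 2] == -i)
    hc$height[row]
  }, numeric(1))
  colnames(x)[merge_height > cutoff]
}
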