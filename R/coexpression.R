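#' Keep the most variable genes
#'
#' Retains the `n_top` genes with the highest across-sample variance
#' (ties broken by lexicographically smaller gene id). Gene order of the
#' retained set follows the input matrix.
#'
#' @param dataset An [expression_dataset()].
#' @param n_top Number of genes to keep (`0 < n_top <= n_genes`).
#' @return The filtered `ExpressionDataset`.
#' @export
variance_filter <- function(dataset, n_top) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (n_top <= 0) stopf("n_top must be > 0")
  if (n_top > nrow(dataset$values))
    stopf("n_top = %d exceeds the %d available genes", n_top, nrow(dataset$values))
  v <- apply(dataset$values, 1, var)
  ord <- order(-v, rownames(dataset$values), method = "radix")
  keep <- sort(ord[seq_len(n_top)])
  subset_dataset(dataset, features = rownames(dataset$values)[keep])
}

#' Pairwise Pearson correlation (similarity) matrix
#'
#' @param dataset An [expression_dataset()].
#' @return Symmetric genes-by-genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  S <- cor(t(dataset$values))
  diag(S) <- 1
  S
}

#' Choose a soft-threshold power by scale-free topology fit
#'
#' For each candidate power `beta`, connectivities
#' `k_i = sum_j |S_ij|^beta` (diagonal excluded) are binned, and
#' `log10 p(k)` is regressed on `log10 k`; the signed fit index is the
#' regression R-squared, negated when the slope is positive (a scale-free
#' network has a negative slope). The smallest `beta` reaching
#' `r2_target` is returned; if none does, the `beta` maximizing the signed
#' fit is returned with a warning.
#'
#' @param S Correlation matrix from [correlation_matrix()] (>= 30 genes).
#' @param candidates Candidate powers (default `1:20`).
#' @param r2_target Target signed R-squared (default 0.8).
#' @param n_bins Number of connectivity bins for the frequency fit.
#' @return A list with `beta` (chosen power), `fit_table` (data frame:
#'   `beta`, `signed_r2`, `slope`, `mean_k`, `max_k`) and `reached_target`
#'   (logical).
#' @export
pick_soft_threshold <- function(S, candidates = 1:20, r2_target = 0.8,
                                n_bins = 10) {
  if (nrow(S) < 30) stopf("need >= 30 genes for a meaningful scale-free fit")
  absS <- abs(S)
  diag(absS) <- 0
  fit <- data.frame(beta = candidates, signed_r2 = NA_real_,
                    slope = NA_real_, mean_k = NA_real_, max_k = NA_real_)
  for (i in seq_along(candidates)) {
    k <- rowSums(absS^candidates[i])
    fit$mean_k[i] <- mean(k)
    fit$max_k[i] <- max(k)
    if (max(k) - min(k) < .Machine$double.eps^0.5) {
      warnf("beta = %d skipped: degenerate connectivities (all equal)", candidates[i])
      next
    }
    ## frequency-vs-connectivity fit in the field's standard form: equal-
    ## width bins over k, empty bins kept at (near-)zero frequency with
    ## the bin midpoint as abscissa, small offset to keep logs finite
    breaks <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = breaks, include.lowest = TRUE)
    freq <- tabulate(bin, nbins = n_bins) / length(k)
    kmid <- as.numeric(tapply(k, bin, mean))
    mids <- (head(breaks, -1) + breaks[-1]) / 2
    kmid[is.na(kmid) | kmid == 0] <- mids[is.na(kmid) | kmid == 0]
    if (any(kmid <= 0)) next
    m <- lm(log10(freq + 1e-9) ~ log10(kmid))
    r2 <- summary(m)$r.squared
    slope <- coef(m)[2]
    fit$slope[i] <- slope
    fit$signed_r2[i] <- if (!is.na(slope) && slope > 0) -r2 else r2
  }
  reached <- which(!is.na(fit$signed_r2) & fit$signed_r2 >= r2_target)
  if (length(reached)) {
    beta <- candidates[reached[1]]
    hit <- TRUE
  } else {
    if (all(is.na(fit$signed_r2))) stopf("no candidate beta produced a valid fit")
    beta <- candidates[which.max(fit$signed_r2)]
    hit <- FALSE
    warnf("no beta reached signed R^2 >= %.2f; falling back to beta = %d (max fit %.3f)",
          r2_target, beta, max(fit$signed_r2, na.rm = TRUE))
  }
  list(beta = beta, fit_table = fit, reached_target = hit)
}

#' Soft-threshold power adjacency
#'
#' Unsigned weighted network: `a_ij = |S_ij|^beta`. The diagonal is set to
#' zero so that connectivity sums and topological overlap can be computed
#' directly from the matrix.
#'
#' @param S Correlation matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix with attribute `"beta"`, class
#'   `AdjacencyMatrix`.
#' @export
adjacency_matrix <- function(S, beta) {
  if (beta < 1) stopf("beta must be >= 1")
  a <- abs(S)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  class(a) <- c("AdjacencyMatrix", class(a))
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with `k_i = sum_u a_iu`; `TOM_ii = 1`. Values lie in
#' `[0, 1]`; `1 - TOM` is the clustering dissimilarity.
#'
#' @param a Adjacency from [adjacency_matrix()] (zero diagonal).
#' @return The TOM matrix.
#' @export
topological_overlap <- function(a) {
  a <- unclass(a)
  attr(a, "beta") <- NULL
  k <- rowSums(a)
  shared <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  tom[!is.finite(tom)] <- 0
  diag(tom) <- 1
  tom
}

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' Builds the average-linkage dendrogram on `1 - TOM`, cuts it at a static
#' height, discards clusters smaller than `min_module_size` (their genes
#' become `"grey"`), and labels surviving clusters by the canonical module
#' color order (turquoise, blue, brown, ...) in decreasing size (size
#' ties broken by smallest member gene id). Deterministic: identical
#' input gives identical colors.
#'
#' @param tom_dissim Square dissimilarity matrix (`1 - TOM`).
#' @param min_module_size Minimum cluster size to count as a module.
#' @param cut_height Static cut height; default is the midpoint of the
#'   largest gap in the upper half of the sorted merge heights, a
#'   deterministic rule that separates tight module subtrees from the
#'   near-one dissimilarity plateau where unrelated genes merge.
#' @return Named character vector gene -> color (`"grey"` = unassigned),
#'   with the dendrogram attached as attribute `"dendrogram"` and the cut
#'   height as `"cut_height"`.
#' @export
detect_modules <- function(tom_dissim, min_module_size = 30, cut_height = NULL) {
  if (nrow(tom_dissim) != ncol(tom_dissim)) stopf("dissimilarity must be square")
  genes <- rownames(tom_dissim)
  hc <- hclust(as.dist(tom_dissim), method = "average")
  if (is.null(cut_height)) {
    h <- sort(hc$height)
    upper <- h[h >= median(h)]
    if (length(upper) >= 2) {
      gaps <- diff(upper)
      i <- which.max(gaps)
      cut_height <- (upper[i] + upper[i + 1]) / 2
    } else {
      cut_height <- max(h)
    }
  }
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  colors <- setNames(rep("grey", length(genes)), genes)
  if (length(big)) {
    first_member <- vapply(big, function(b) min(genes[cl == as.integer(b)]), character(1))
    ord <- big[order(-as.integer(sizes[big]), first_member)]
    palette <- module_color_order()
    if (length(ord) > length(palette))
      palette <- c(palette, paste0("module", seq_len(length(ord) - length(palette))))
    for (i in seq_along(ord)) colors[cl == as.integer(ord[i])] <- palette[i]
  } else {
    warnf("no cluster reached min_module_size = %d; all genes grey", min_module_size)
  }
  attr(colors, "dendrogram") <- hc
  attr(colors, "cut_height") <- cut_height
  colors
}

#' Module eigengenes
#'
#' For every non-grey module, genes are z-scored across samples and the
#' first principal component's sample scores (unit norm) form the module
#' eigengene, sign-oriented so that the mean correlation with the module's
#' genes is non-negative. A single-gene module's eigengene is that gene's
#' z-scored profile.
#'
#' @param dataset An [expression_dataset()] containing the module genes.
#' @param colors Named gene -> color vector from [detect_modules()].
#' @return Eigengene matrix (modules x samples), row names are colors.
#' @export
module_eigengenes <- function(dataset, colors) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  mods <- setdiff(unique(colors), "grey")
  if (!length(mods)) stopf("no non-grey module")
  mods <- mods[order(match(mods, module_color_order()), mods)]
  x <- dataset$values
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(x),
               dimnames = list(mods, colnames(x)))
  for (m in mods) {
    genes <- names(colors)[colors == m]
    xm <- x[genes, , drop = FALSE]
    mu <- rowMeans(xm)
    sdv <- apply(xm, 1, sd)
    sdv[sdv == 0] <- 1
    z <- (xm - mu) / sdv
    if (length(genes) == 1) {
      e <- as.numeric(z)
    } else {
      sv <- svd(t(z), nu = 1, nv = 0)
      e <- sv$u[, 1]
    }
    cors <- suppressWarnings(cor(e, t(z)))
    if (mean(cors, na.rm = TRUE) < 0) e <- -e
    me[m, ] <- e
  }
  me
}

#' Module-trait correlations with exact-t p-values
#'
#' Pearson correlation of each module eigengene with each numerically
#' encoded trait, with the exact Student-t transform p-value
#' `p = 2 * (1 - F_t(|r| * sqrt((n - 2) / (1 - r^2)); df = n - 2))`.
#'
#' @param eigengenes Matrix from [module_eigengenes()] (modules x samples).
#' @param traits Data frame or matrix of numeric traits, one row per
#'   sample (binary traits as 0/1); zero-variance traits are an error.
#' @return A list with matrices `correlation` and `p` (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  if (nrow(traits) != ncol(eigengenes))
    stopf("traits have %d rows but eigengenes have %d samples",
          nrow(traits), ncol(eigengenes))
  if (nrow(traits) < 3) stopf("need >= 3 samples")
  for (nm in names(traits)) {
    if (!is.numeric(traits[[nm]])) stopf("trait '%s' is not numeric", nm)
    if (sd(traits[[nm]]) == 0) stopf("trait '%s' has zero variance", nm)
  }
  n <- nrow(traits)
  r <- cor(t(eigengenes), traits)
  p <- cor_pvalue(r, n)
  dimnames(p) <- dimnames(r)
  list(correlation = r, p = p)
}

cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.xmin))
  tstat[r2 >= 1] <- Inf
  2 * pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' Gene significance for a trait
#'
#' Per-gene absolute Pearson correlation with a numeric trait and its
#' exact-t p-value.
#'
#' @param dataset An [expression_dataset()].
#' @param trait Numeric vector, one value per sample (binary as 0/1).
#' @return Data frame `gene`, `gs` (absolute correlation), `cor` (signed),
#'   `p`.
#' @export
gene_significance <- function(dataset, trait) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  trait <- as.numeric(trait)
  if (length(trait) != ncol(dataset$values))
    stopf("trait length does not match sample count")
  if (sd(trait) == 0) stopf("trait has zero variance")
  r <- as.numeric(cor(t(dataset$values), trait))
  r[is.na(r)] <- 0
  data.frame(gene = rownames(dataset$values), gs = abs(r), cor = r,
             p = as.numeric(cor_pvalue(matrix(r), ncol(dataset$values))),
             stringsAsFactors = FALSE)
}

#' Mean gene significance per module
#'
#' @param dataset An [expression_dataset()].
#' @param colors Named gene -> color vector.
#' @param trait Numeric per-sample trait.
#' @return Data frame `module`, `mean_gs` (grey excluded).
#' @export
module_gene_significance <- function(dataset, colors, trait) {
  gs <- gene_significance(subset_dataset(dataset, features = names(colors)), trait)
  mods <- setdiff(unique(colors), "grey")
  data.frame(module = mods,
             mean_gs = vapply(mods, function(m)
               mean(gs$gs[match(names(colors)[colors == m], gs$gene)]), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene module membership (kME)
#'
#' Correlation of each gene's profile with each module eigengene.
#'
#' @param dataset An [expression_dataset()].
#' @param eigengenes Matrix from [module_eigengenes()].
#' @return Genes x modules matrix of correlations.
#' @export
module_membership <- function(dataset, eigengenes) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  kme <- cor(t(dataset$values), t(eigengenes))
  kme[is.na(kme)] <- 0
  kme
}
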