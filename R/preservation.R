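#' Permutation-based module preservation between two datasets
#'
#' Quantifies whether modules defined in a reference dataset recur in a
#' test dataset, against a permutation null of random gene sets of the
#' same size. Two statistics are computed per module on the soft-threshold
#' adjacency `|cor|^beta`:
#'
#' * **density**: mean within-module adjacency in the test network;
#' * **connectivity**: correlation between the within-module connectivity
#'   `kIM` (row sums of the module sub-adjacency) in the reference and in
#'   the test network.
#'
#' Each observed statistic is standardized against `n_permutations` random
#' gene sets drawn without replacement from the full shared gene universe
#' (nothing excluded), giving `Zdensity` and `Zconnectivity`;
#' `Zsummary = (Zdensity + Zconnectivity) / 2`. Modules are also ranked by
#' each observed statistic (1 = most preserved) and `medianRank` is the
#' median of the per-statistic ranks. Interpretation thresholds:
#' `Zsummary > 10` strong evidence of preservation, `Zsummary < 2` none.
#'
#' @param ref,test [expression_dataset()]s sharing the gene universe of
#'   `colors`.
#' @param colors Named gene -> color vector (from [detect_modules()] on
#'   the reference); grey genes belong to the universe but form no module.
#' @param beta Soft-threshold power for the adjacency.
#' @param n_permutations Number of null gene sets (>= 20; default 100).
#' @param seed Integer seed; fixed seed gives identical Z values.
#' @return Data frame of class `PreservationResult`: `module`,
#'   `module_size`, `density_obs`, `connectivity_obs`, `Zdensity`,
#'   `Zconnectivity`, `Zsummary`, `medianRank`; attributes
#'   `n_permutations`, `seed`.
#' @export
module_preservation <- function(ref, test, colors, beta,
                                n_permutations = 100, seed = 1) {
  stopifnot(inherits(ref, "ExpressionDataset"), inherits(test, "ExpressionDataset"))
  if (n_permutations < 20) stopf("n_permutations must be >= 20")
  universe <- names(colors)
  missing_ref <- setdiff(universe, rownames(ref$values))
  missing_test <- setdiff(universe, rownames(test$values))
  if (length(missing_ref) || length(missing_test))
    stopf("colors name genes absent from ref/test: %s",
          paste(head(c(missing_ref, missing_test), 5), collapse = ", "))
  mods <- setdiff(unique(colors), "grey")
  if (!length(mods)) stopf("no non-grey module to assess")
  sizes <- vapply(mods, function(m) sum(colors == m), integer(1))
  if (any(sizes > length(universe))) stopf("module size exceeds the gene universe")
  if (any(sizes < 2)) stopf("modules must have >= 2 genes")

  A_ref <- abs(cor(t(ref$values[universe, , drop = FALSE])))^beta
  A_test <- abs(cor(t(test$values[universe, , drop = FALSE])))^beta
  diag(A_ref) <- 0
  diag(A_test) <- 0

  stat_pair <- function(genes) {
    sub_ref <- A_ref[genes, genes, drop = FALSE]
    sub_test <- A_test[genes, genes, drop = FALSE]
    n <- length(genes)
    dens <- sum(sub_test) / (n * (n - 1))
    conn <- suppressWarnings(cor(rowSums(sub_ref), rowSums(sub_test)))
    c(density = dens, connectivity = if (is.na(conn)) 0 else conn)
  }

  obs <- t(vapply(mods, function(m) stat_pair(names(colors)[colors == m]),
                  numeric(2)))

  set.seed(seed)
  mods_sorted <- mods[order(mods)]
  null_stats <- lapply(setNames(mods_sorted, mods_sorted), function(m) {
    size <- sizes[[m]]
    t(vapply(seq_len(n_permutations),
             function(i) stat_pair(sample(universe, size)),
             numeric(2)))
  })

  z_of <- function(m, stat) {
    nulls <- null_stats[[m]][, stat]
    sdn <- sd(nulls)
    if (!is.finite(sdn) || sdn == 0) {
      warnf("null sd is zero for module '%s' (%s); Z undefined", m, stat)
      return(NA_real_)
    }
    (obs[m, stat] - mean(nulls)) / sdn
  }
  zd <- vapply(mods, z_of, numeric(1), stat = "density")
  zc <- vapply(mods, z_of, numeric(1), stat = "connectivity")
  zsum <- (zd + zc) / 2

  rank_d <- rank(-obs[, "density"], ties.method = "average")
  rank_c <- rank(-obs[, "connectivity"], ties.method = "average")
  median_rank <- (rank_d + rank_c) / 2

  out <- data.frame(module = mods,
                    module_size = as.integer(sizes),
                    density_obs = obs[, "density"],
                    connectivity_obs = obs[, "connectivity"],
                    Zdensity = zd,
                    Zconnectivity = zc,
                    Zsummary = zsum,
                    medianRank = median_rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("PreservationResult", "data.frame")
  out
}
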