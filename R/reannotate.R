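#' Reannotate probes to gene symbols with biotype tagging
#'
#' Replaces array probe-level annotation by a user-supplied probe-to-gene
#' table: every probe found in the table gets its gene symbol and biotype
#' (coding / lncRNA / unknown); probes absent from the table are dropped.
#' Sequence-level re-mapping against lncRNA reference databases is outside
#' the package — it is summarized by whatever table the user supplies.
#'
#' @param dataset An [expression_dataset()] whose feature ids are probe ids.
#' @param annotation A [gene_annotation()] table (probe_id unique).
#' @return The reannotated `ExpressionDataset` (feature ids still probe
#'   ids, `symbol`/`biotype` filled in), with a mapping report attached as
#'   attribute `"mapping_report"` (`n_mapped`, `n_lncrna`, `n_dropped`).
#' @export
reannotate <- function(dataset, annotation) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  annotation <- gene_annotation(annotation)
  probes <- rownames(dataset$values)
  hit <- probes %in% annotation$probe_id
  if (!any(hit)) stopf("annotation does not match platform: no probe id in common")
  keep <- probes[hit]
  idx <- match(keep, annotation$probe_id)
  out <- subset_dataset(dataset, features = keep)
  out$features$symbol <- annotation$gene_symbol[idx]
  out$features$biotype <- annotation$biotype[idx]
  report <- list(n_mapped = length(keep),
                 n_lncrna = sum(out$features$biotype == "lncRNA"),
                 n_dropped = sum(!hit))
  message(sprintf("reannotate: %d probes mapped (%d lncRNA), %d dropped",
                  report$n_mapped, report$n_lncrna, report$n_dropped))
  attr(out, "mapping_report") <- report
  out
}

#' Collapse duplicate gene symbols by expression variance
#'
#' When several probes map to the same gene symbol, only the probe with the
#' highest across-sample variance is kept. Exact variance ties are broken
#' by the lexicographically smallest probe id, so the result is
#' deterministic across platforms and runs. After collapsing, feature ids
#' are renamed to the (now unique) gene symbols.
#'
#' @param dataset A reannotated [expression_dataset()].
#' @return An `ExpressionDataset` with unique symbols as feature ids.
#'   Idempotent: applying it twice equals applying it once.
#' @export
collapse_duplicates <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- apply(dataset$values, 1, var)
  probe <- rownames(dataset$values)
  sym <- dataset$features$symbol
  ## order: by symbol, then decreasing variance, then probe id ascending;
  ## the first row per symbol wins
  ord <- order(sym, -v, probe, method = "radix")
  first <- ord[!duplicated(sym[ord])]
  keep <- sort(first)  # preserve original row order
  out <- subset_dataset(dataset, features = probe[keep])
  rownames(out$values) <- out$features$symbol
  out$features$feature_id <- out$features$symbol
  out
}
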