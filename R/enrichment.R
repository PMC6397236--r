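#' Read a GMT gene-set collection
#'
#' Standard GMT: one tab-separated line per gene set —
#' `name <tab> description <tab> member1 <tab> member2 ...`. Term names
#' must be unique; member ids are uppercased for case-insensitive
#' matching.
#'
#' @param path Path to the GMT file.
#' @return A named list of uppercase member-id character vectors, with the
#'   descriptions attached as attribute `"description"`; class
#'   `GmtCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stopf("GMT line %d has fewer than 3 fields", short[1])
  names_ <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names_))
    stopf("duplicate term name(s) in GMT: %s",
          paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- names_
  attr(sets, "description") <- setNames(vapply(parts, `[[`, character(1), 2), names_)
  class(sets) <- "GmtCollection"
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `GmtCollection` (or plain named list of character
#'   vectors).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description") %||%
    setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t"), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the gene list overlaps the term more than
#' expected under random draws from the universe: upper-tail
#' hypergeometric `P(X >= k)` with population `N = |universe|`, successes
#' `K = |term within universe|`, draws `n = |list|`, overlap `k`.
#' Benjamini-Hochberg adjustment across all terms of the collection;
#' significance at `q <= alpha`. With `ease = TRUE` the overlap is
#' reduced by one before the tail (the conservative EASE variant used by
#' DAVID-style tools). Matching is case-insensitive (ids uppercased).
#'
#' @param genes Character vector of query gene ids (non-empty). Genes
#'   outside the universe are dropped with a warning.
#' @param collection A [read_gmt()] collection (or named list).
#' @param universe Character vector: the background gene list (typically
#'   all genes expressed on the platform after reannotation).
#' @param alpha Significance level on the BH q-value (default 0.05).
#' @param ease Use the EASE-adjusted overlap `k - 1` (default `FALSE`).
#' @return Data frame of class `EnrichmentResult`, sorted by p: `term`,
#'   `k`, `n`, `K`, `N`, `p`, `q`, `significant`, `genes`
#'   (comma-separated overlap ids).
#' @export
enrich <- function(genes, collection, universe, alpha = 0.05, ease = FALSE) {
  if (!length(genes)) stopf("empty gene list")
  genes <- unique(toupper(genes))
  universe <- unique(toupper(universe))
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    genes <- intersect(genes, universe)
  }
  if (!length(genes)) stopf("no query gene lies in the universe")
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(toupper(collection[[term]]), universe)
    K <- length(members)
    ov <- intersect(genes, members)
    k <- length(ov)
    keff <- if (ease) max(k - 1L, 0L) else k
    p <- if (keff == 0) 1 else phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha
  out <- out[order(out$p, out$term), c("term", "k", "n", "K", "N", "p", "q",
                                       "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Compare two enrichment results
#'
#' Splits the significant terms of two [enrich()] results into shared and
#' unique sets and reports the Jaccard index of the significant-term sets
#' (defined as 0 when both are empty). Used e.g. to compare enriched
#' processes between species after ortholog mapping.
#'
#' @param res_a,res_b `EnrichmentResult` data frames over shared term ids.
#' @param alpha Significance level applied to both results' q-values.
#' @return List `a_only`, `b_only`, `both` (sorted term vectors) and
#'   `jaccard`.
#' @export
compare_enrichments <- function(res_a, res_b, alpha = 0.05) {
  sig <- function(res) sort(res$term[res$q <= alpha])
  a <- sig(res_a)
  b <- sig(res_b)
  un <- union(a, b)
  list(a_only = setdiff(a, b),
       b_only = setdiff(b, a),
       both = intersect(a, b),
       jaccard = if (length(un)) length(intersect(a, b)) / length(un) else 0)
}

#' Map genes through an ortholog table
#'
#' Expands one-to-many mappings, deduplicates the output and reports the
#' genes that could not be mapped.
#'
#' @param genes Character vector of source-species gene ids.
#' @param ortholog_table Two-column data frame (source id, target id);
#'   must be non-empty.
#' @return List `mapped` (sorted unique target ids) and `unmapped`
#'   (sorted source ids without a table entry).
#' @export
map_orthologs <- function(genes, ortholog_table) {
  tab <- as.data.frame(ortholog_table, stringsAsFactors = FALSE)
  if (!nrow(tab) || ncol(tab) < 2) stopf("empty ortholog table")
  src <- as.character(tab[[1]])
  dst <- as.character(tab[[2]])
  genes <- unique(as.character(genes))
  hit <- genes[genes %in% src]
  list(mapped = sort(unique(dst[src %in% hit])),
       unmapped = sort(setdiff(genes, src)))
}
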