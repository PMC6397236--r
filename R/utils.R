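`%||%` <- function(x, y) if (is.null(x)) y else x

## Full-precision number formatting so written tables round-trip exactly.
## %.17g is the shortest representation guaranteed to reproduce a double.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

## Write a data frame as a TSV with round-trip-safe numeric formatting:
## UTF-8, Unix newlines, no quoting, no row names.
write_tsv_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

## Inverse of trigamma() by Newton iteration on 1/trigamma (which is nearly
## linear), as used for method-of-moments fits of scaled inverse-chi-square
## variance priors.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

## Canonical module color order (grey reserved for unassigned genes).
module_color_order <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown",
    "steelblue", "paleturquoise", "violet", "darkolivegreen",
    "darkmagenta", "sienna3", "yellowgreen", "skyblue3", "plum1",
    "orangered4", "mediumpurple3", "lightsteelblue1", "lightcyan1",
    "ivory", "floralwhite", "darkorange2", "brown4", "bisque4")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
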