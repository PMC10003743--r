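## Expression screen for highly diverged Y genes: reads-per-kilobase-per-
## million (RPKM) normalization and a male:female median fold-change screen
## that retains sex-limited genes.

#' RPKM normalization
#'
#' `RPKM = count * 1e9 / (gene_length_bp * library_size)`.
#'
#' @param counts long-format count table with columns `gene`, `sample`,
#'   `sex`, `count`, `length`.
#' @param libsizes named numeric vector of per-sample library sizes; if
#'   NULL, per-sample count sums are used.
#' @return `counts` with an added `rpkm` column.
#' @export
rpkm <- function(counts, libsizes = NULL) {
  if (any(counts$length <= 0)) stop("gene lengths must be positive")
  if (is.null(libsizes))
    libsizes <- tapply(counts$count, counts$sample, sum)
  ls <- libsizes[counts$sample]
  if (any(is.na(ls) | ls <= 0)) stop("library sizes must be positive")
  counts$rpkm <- counts$count * 1e9 / (counts$length * as.numeric(ls))
  counts
}

## Median with the lower-interpolation convention for even counts
## (the lower of the two middle order statistics), for bit-stable output.
median_lower <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Screen for candidate highly diverged Y genes by expression
#'
#' Computes per-sex median RPKM for every gene; drops genes whose medians
#' are below `min_median_rpkm` in both sexes (genes sex-limited in
#' expression, i.e. median 0 in one sex with the other sex expressed, are
#' retained); flags as candidates the genes whose male:female median fold
#' change exceeds `fc_threshold`, with male-limited genes always
#' candidates. The reported log2 fold change uses a pseudocount (for
#' finite logs on sex-limited genes); the threshold test itself does not.
#'
#' @param rpkm_table output of [rpkm()].
#' @param fc_threshold male:female median fold-change threshold (default 2).
#' @param min_median_rpkm expression floor on the per-sex medians
#'   (default 2 RPKM).
#' @param pseudocount RPKM pseudocount for the reported log2 ratio only.
#' @return data frame gene / median_M / median_F / log2FC / sex_limited /
#'   candidate, one row per gene passing the expression floor.
#' @export
screen_candidates <- function(rpkm_table, fc_threshold = 2,
                              min_median_rpkm = 2, pseudocount = 0.1) {
  if (length(unique(rpkm_table$sex)) < 2)
    stop("need samples of both sexes")
  med <- function(sx) {
    d <- rpkm_table[rpkm_table$sex == sx, ]
    tapply(d$rpkm, d$gene, median_lower)
  }
  m <- med("M")
  f <- med("F")
  genes <- sort(unique(rpkm_table$gene))
  m <- m[genes]
  f <- f[genes]
  keep <- pmax(m, f, na.rm = TRUE) >= min_median_rpkm
  out <- data.frame(
    gene = genes, median_M = as.numeric(m), median_F = as.numeric(f),
    log2FC = log2((m + pseudocount) / (f + pseudocount)),
    sex_limited = (m == 0 & f > 0) | (f == 0 & m > 0),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$candidate <- (out$median_F == 0 & out$median_M > 0) |
    (out$median_F > 0 & out$median_M / out$median_F > fc_threshold)
  rownames(out) <- NULL
  out
}
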