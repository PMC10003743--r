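## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a global seed
#'
#' All simulator stages draw their randomness from sub-streams derived from
#' one global integer seed by fixed offsets, so that a scenario is
#' reproducible stage by stage.
#'
#' @param seed integer global seed.
#' @param offset fixed integer offset identifying the sub-stream.
#' @return an integer seed below `.Machine$integer.max`.
#' @keywords internal
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483587)
}

## Random DNA as an integer vector in 0:3 (A,C,G,T)
random_dna_int <- function(n) {
  sample.int(4L, n, replace = TRUE) - 1L
}

int_to_dna <- function(x) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[x + 1L]))
}

dna_to_int <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], BASES) - 1L
}

#' Evolve a sequence along a branch under an equal-rates substitution process
#'
#' Each site substitutes to one of the three other bases with total
#' probability `3/4 * (1 - exp(-4/3 * mu * myr))`, the Jukes-Cantor
#' transition probability for a branch of `mu * myr` expected substitutions
#' per site. Composing two branches reproduces the single-branch probability
#' for the summed length, so divergence accumulates exactly as under the
#' continuous-time model.
#'
#' @param x integer vector in 0:3.
#' @param myr branch length in Myr.
#' @param mu substitution rate per site per Myr.
#' @return mutated integer vector.
#' @keywords internal
evolve_seq <- function(x, myr, mu) {
  if (myr < 0) stop("negative branch length")
  if (myr == 0) return(x)
  p <- 0.75 * (1 - exp(-4 / 3 * mu * myr))
  n <- length(x)
  nmut <- rbinom(1L, n, p)
  if (nmut == 0L) return(x)
  idx <- sample.int(n, nmut)
  x[idx] <- (x[idx] + sample.int(3L, nmut, replace = TRUE)) %% 4L
  x
}

## Random in-frame coding sequence (sense codons of the standard code)
random_coding_int <- function(n_codons) {
  codons <- sense_codons_int()
  idx <- sample.int(nrow(codons), n_codons, replace = TRUE)
  as.integer(t(codons[idx, , drop = FALSE]))
}

## 61 sense codons of the standard code as an n x 3 integer matrix, cached
sense_codons_int <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      sense <- names(gc_tab)[gc_tab != "*"]
      cache <<- do.call(rbind, lapply(sense, dna_to_int))
    }
    cache
  }
})

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
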