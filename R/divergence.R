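## Pairwise synonymous divergence between X and Y gametologs: NG86-style
## codon counting (synonymous/nonsynonymous site fractions, equal-weight
## pathway averaging for multi-difference codons, stop-transiting paths
## excluded) with Jukes-Cantor correction and a codon-bootstrap standard
## error.

stop_codons <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  names(gc_tab)[gc_tab == "*"]
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

split_codons <- function(s) {
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

#' Filter a codon alignment of two sequences
#'
#' Drops codons containing gap or ambiguity characters in either sequence,
#' then drops codons that are stop codons in either sequence (counted).
#' Pairs retaining less than `min_bp` are flagged as failing the length
#' filter.
#'
#' @param x,y aligned coding sequences of equal length.
#' @param min_bp minimum retained length in bp (default 300).
#' @return list with codon vectors `x`, `y`, `n_codons`, `n_dropped_gap`,
#'   `n_dropped_stop`, and logical `passes_min`.
#' @export
codon_filter <- function(x, y, min_bp = 300) {
  if (nchar(x) != nchar(y)) stop("aligned sequences must have equal length")
  cx <- toupper(split_codons(x))
  cy <- toupper(split_codons(y))
  clean <- grepl("^[ACGT]{3}$", cx) & grepl("^[ACGT]{3}$", cy)
  n_gap <- sum(!clean)
  cx <- cx[clean]
  cy <- cy[clean]
  stops <- stop_codons()
  is_stop <- cx %in% stops | cy %in% stops
  n_stop <- sum(is_stop)
  cx <- cx[!is_stop]
  cy <- cy[!is_stop]
  list(x = cx, y = cy, n_codons = length(cx),
       n_dropped_gap = n_gap, n_dropped_stop = n_stop,
       passes_min = 3L * length(cx) >= min_bp)
}

## Cache of per-codon (S, N) site counts.
.ng86_sites_cache <- new.env(parent = emptyenv())

#' NG86 synonymous and nonsynonymous site counts of a codon
#'
#' At each codon position, the fraction of the three possible
#' single-nucleotide changes that preserve the amino acid contributes to
#' the synonymous site count; changes creating stop codons are excluded
#' from the denominator, so S + N = 3 per codon after renormalization.
#'
#' @param codon a sense codon string, e.g. `"GGT"`.
#' @return named numeric `c(S = , N = )`.
#' @export
ng86_sites <- function(codon) {
  hit <- .ng86_sites_cache[[codon]]
  if (!is.null(hit)) return(hit)
  aa <- translate_codon(codon)
  if (is.na(aa) || aa == "*") stop("stop or ambiguous codon: ", codon)
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    alts <- setdiff(BASES, base)
    syn <- 0L
    nonstop <- 0L
    for (b in alts) {
      alt <- codon
      substr(alt, pos, pos) <- b
      aa2 <- translate_codon(alt)
      if (aa2 == "*") next
      nonstop <- nonstop + 1L
      if (aa2 == aa) syn <- syn + 1L
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  out <- c(S = s, N = 3 - s)
  .ng86_sites_cache[[codon]] <- out
  out
}

## Orderings of 1..n for pathway enumeration.
perm_list <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.ng86_counts_cache <- new.env(parent = emptyenv())

#' NG86 synonymous and nonsynonymous difference counts for a codon pair
#'
#' For codons differing at several positions, substitution pathways are
#' averaged with equal weight; pathways passing through a stop codon are
#' excluded. Returns NA counts when every pathway transits a stop (the
#' codon pair is then dropped by the caller).
#'
#' @param c1,c2 sense codon strings.
#' @return named numeric `c(Sd = , Nd = )`, possibly NA.
#' @export
ng86_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_counts_cache[[key]]
  if (!is.null(hit)) return(hit)
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0L) {
    out <- c(Sd = 0, Nd = 0)
  } else {
    stops <- stop_codons()
    tot_s <- 0
    tot_n <- 0
    n_valid <- 0L
    for (ord in perm_list[[nd]]) {
      cur <- c1
      s <- 0L
      n <- 0L
      ok <- TRUE
      for (p in diff_pos[ord]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% stops) { ok <- FALSE; break }
        if (translate_codon(nxt) == translate_codon(cur)) s <- s + 1L
        else n <- n + 1L
        cur <- nxt
      }
      if (ok) {
        tot_s <- tot_s + s
        tot_n <- tot_n + n
        n_valid <- n_valid + 1L
      }
    }
    out <- if (n_valid == 0L) c(Sd = NA_real_, Nd = NA_real_)
           else c(Sd = tot_s / n_valid, Nd = tot_n / n_valid)
  }
  .ng86_counts_cache[[key]] <- out
  out
}

jc_correct <- function(p) -0.75 * log(1 - 4 / 3 * p)

#' Estimate dS and dN between a gametolog pair
#'
#' NG86 counting with sites averaged over the two sequences, equal-weight
#' pathway averaging, Jukes-Cantor distance correction, and a standard
#' error from codon-resampling bootstrap. Proportions at or beyond the
#' domain of the correction (p >= 3/4) yield a saturated flag instead of
#' an estimate.
#'
#' @param x,y aligned coding sequences (equal length, in frame).
#' @param n_boot bootstrap replicates for the dS standard error (0 skips
#'   the bootstrap; `se_dS` is then NA).
#' @param seed integer seed for the bootstrap.
#' @param min_bp minimum retained alignment length (see [codon_filter()]).
#' @return list with `dS`, `dN`, `se_dS`, `pS`, `pN`, `S`, `N`, `Sd`,
#'   `Nd`, `n_codons`, `n_dropped_stop`, `n_dropped_path`, `saturated`,
#'   `passes_min`.
#' @export
ds_estimate <- function(x, y, n_boot = 1000, seed = 1L, min_bp = 300) {
  flt <- codon_filter(x, y, min_bp = min_bp)
  if (flt$n_codons == 0) stop("no codons retained")
  cx <- flt$x
  cy <- flt$y
  sites_x <- vapply(cx, ng86_sites, numeric(2))
  sites_y <- vapply(cy, ng86_sites, numeric(2))
  s_i <- (sites_x[1, ] + sites_y[1, ]) / 2
  n_i <- (sites_x[2, ] + sites_y[2, ]) / 2
  cnt <- mapply(ng86_counts, cx, cy)
  keep <- !is.na(cnt[1, ])
  n_dropped_path <- sum(!keep)
  s_i <- s_i[keep]
  n_i <- n_i[keep]
  sd_i <- cnt[1, keep]
  nd_i <- cnt[2, keep]

  est <- function(idx) {
    S <- sum(s_i[idx])
    N <- sum(n_i[idx])
    pS <- if (S > 0) sum(sd_i[idx]) / S else NA_real_
    pN <- if (N > 0) sum(nd_i[idx]) / N else NA_real_
    c(pS = pS, pN = pN)
  }
  all_idx <- seq_along(s_i)
  p <- est(all_idx)
  saturated <- isTRUE(p[["pS"]] >= 0.75) || isTRUE(p[["pN"]] >= 0.75)
  S <- sum(s_i)
  if (S <= 0) stop("no synonymous sites")

  dS <- dN <- se <- NA_real_
  if (!saturated) {
    dS <- jc_correct(p[["pS"]])
    dN <- if (!is.na(p[["pN"]])) jc_correct(p[["pN"]]) else NA_real_
    if (n_boot > 0) {
      set.seed(seed)
      n <- length(all_idx)
      reps <- vapply(seq_len(n_boot), function(b) {
        pb <- est(sample.int(n, n, replace = TRUE))[["pS"]]
        if (is.na(pb) || pb >= 0.75) NA_real_ else jc_correct(pb)
      }, numeric(1))
      se <- stats::sd(reps[!is.na(reps)])
    }
  }
  list(dS = dS, dN = dN, se_dS = se,
       pS = unname(p[["pS"]]), pN = unname(p[["pN"]]),
       S = S, N = sum(n_i), Sd = sum(sd_i), Nd = sum(nd_i),
       n_codons = length(all_idx),
       n_dropped_stop = flt$n_dropped_stop,
       n_dropped_path = n_dropped_path,
       saturated = saturated, passes_min = flt$passes_min)
}

#' dS/dN table for a set of gametolog pairs
#'
#' @param pairs named list of pairs, each with elements `x`, `y` and
#'   optionally `position_bp` (as produced by [simulate_gametologs()]).
#' @inheritParams ds_estimate
#' @return data frame: gene, position_bp, dS, dN, se_dS, n_codons,
#'   saturated, passes_min.
#' @export
ds_table <- function(pairs, n_boot = 1000, seed = 1L, min_bp = 300) {
  rows <- lapply(names(pairs), function(g) {
    p <- pairs[[g]]
    e <- ds_estimate(p$x, p$y, n_boot = n_boot,
                     seed = substream_seed(seed, match(g, names(pairs))),
                     min_bp = min_bp)
    data.frame(gene = g, position_bp = p$position_bp %||% NA_real_,
               dS = e$dS, dN = e$dN, se_dS = e$se_dS,
               n_codons = e$n_codons, saturated = e$saturated,
               passes_min = e$passes_min, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
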