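## Canonical k-mer analysis: exact counting (compiled), depth-normalized
## spectra, sex-specific k-mer discovery (Y-mers and their female-specific
## false-positive control), cross-species sharing tables, and the shared-
## ancestry decision.

#' Count canonical k-mers of a sequence set
#'
#' Records every k-length window under its canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement); windows
#' containing non-ACGT characters are skipped. Counting is exact.
#'
#' @param x character vector of sequences, a `DNAStringSet`, or the path
#'   to a FASTA file.
#' @param k odd k-mer length between 3 and 63 (default 31).
#' @return object of class `kmer_spectrum`: list with `counts` (named
#'   integer vector), `k` and `total_bases`.
#' @export
count_kmers <- function(x, k = 31L) {
  if (k %% 2L == 0L || k < 3L || k > 63L)
    stop("k must be odd and between 3 and 63")
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (length(x) == 1 && nchar(x) < 1000 && file.exists(x)) x <- read_fasta(x)
  if (length(x) == 0 || all(nchar(x) == 0)) stop("empty input")
  x <- toupper(x)
  counts <- count_canonical_kmers_cpp(x, as.integer(k))
  structure(list(counts = counts, k = as.integer(k),
                 total_bases = sum(nchar(x))),
            class = "kmer_spectrum")
}

#' Depth-normalized k-mer count histogram
#'
#' Counts are rescaled so that the spectrum corresponds to a target
#' sequencing depth given the genome size: the multiplier is
#' `target_depth * genome_size_hint / total_bases`. Single-copy diploid
#' sequence then peaks near the target depth and Y-unique sequence in a
#' male sample near half of it.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param genome_size_hint genome size in bp.
#' @param target_depth normalization target (default 30).
#' @return data frame with `normalized_count` and `n_kmers`, plus the
#'   multiplier as an attribute.
#' @export
spectrum_histogram <- function(spectrum, genome_size_hint, target_depth = 30) {
  if (genome_size_hint <= 0) stop("genome_size_hint must be positive")
  if (spectrum$total_bases <= 0) stop("zero total bases")
  mult <- target_depth * genome_size_hint / spectrum$total_bases
  tab <- table(spectrum$counts)
  out <- data.frame(normalized_count = as.numeric(names(tab)) * mult,
                    n_kmers = as.integer(tab))
  attr(out, "multiplier") <- mult
  out
}

#' Sex-specific k-mers (Y-mers and the female-specific control)
#'
#' A Y-mer is a k-mer with count at least `min_count` in every male sample
#' and count zero in every female sample; the female-specific set is
#' defined symmetrically and, under XY heterogamety, estimates the
#' pipeline's false-positive rate.
#'
#' @param male_spectra,female_spectra lists of `kmer_spectrum` objects
#'   (at least one per sex).
#' @param min_count minimum per-sample count (default 2 for read data; use
#'   1 for assembled genomes, where every k-mer occurs once).
#' @return list with character vectors `male_specific` and
#'   `female_specific`.
#' @export
sex_specific <- function(male_spectra, female_spectra, min_count = 2) {
  if (length(male_spectra) == 0 || length(female_spectra) == 0)
    stop("need at least one sample per sex")
  present <- function(sp) names(sp$counts)[sp$counts >= min_count]
  any_present <- function(spectra)
    unique(unlist(lapply(spectra, function(sp) names(sp$counts))))
  core <- function(spectra) {
    sets <- lapply(spectra, present)
    out <- sets[[1]]
    for (s in sets[-1]) out <- out[out %in% s]
    out
  }
  mc <- core(male_spectra)
  fc <- core(female_spectra)
  list(male_specific = mc[!(mc %in% any_present(female_spectra))],
       female_specific = fc[!(fc %in% any_present(male_spectra))])
}

#' Exact-subset sharing table of sex-specific k-mers across species
#'
#' For every non-empty subset of species, counts the k-mers whose presence
#' pattern is exactly that subset, separately for the male-specific
#' (Y-mer) sets and the female-specific control sets. Exact-subset counts
#' over all subsets sum to the size of the union of the per-species sets.
#'
#' @param ymer_sets named list (per species) of Y-mer character vectors.
#' @param female_sets named list (per species) of female-specific k-mer
#'   vectors, same species order.
#' @return data frame with one row per non-empty subset: `subset` (species
#'   joined by `+`), `n_species`, one logical `has_<species>` column per
#'   species, `y_mer_count` and `female_specific_count`.
#' @export
sharing_table <- function(ymer_sets, female_sets) {
  species <- names(ymer_sets)
  if (length(species) < 2) stop("need at least two species")
  stopifnot(identical(species, names(female_sets)))
  n <- length(species)

  pattern_counts <- function(sets) {
    u <- unique(unlist(sets, use.names = FALSE))
    if (length(u) == 0) return(integer(2^n - 1))
    id <- integer(length(u))
    for (i in seq_len(n))
      id <- id + bitwShiftL(as.integer(u %in% sets[[i]]), i - 1L)
    tabulate(id, nbins = 2^n - 1)
  }
  yc <- pattern_counts(ymer_sets)
  fc <- pattern_counts(female_sets)

  ids <- seq_len(2^n - 1)
  membership <- vapply(seq_len(n),
                       function(i) bitwAnd(ids, bitwShiftL(1L, i - 1L)) > 0,
                       logical(length(ids)))
  colnames(membership) <- paste0("has_", species)
  out <- data.frame(
    subset = apply(membership, 1, function(r) paste(species[r], collapse = "+")),
    n_species = rowSums(membership), stringsAsFactors = FALSE)
  out <- cbind(out, membership)
  out$y_mer_count <- yc
  out$female_specific_count <- fc
  out
}

#' Shared-ancestry test on a k-mer sharing table
#'
#' Compares shared Y-mers against the female-specific false-positive
#' control for (i) all-species pooled sharing (k-mers in two or more
#' species), (ii) sharing within each clade (both clade members), and
#' (iii) cross-clade sharing (at least one member of each clade). Each
#' comparison reports `fold = shared_Ymers / max(shared_female, 1)` and a
#' verdict: `shared_ancestry` when the fold reaches `min_fold`,
#' `no_signal` when both counts are zero, otherwise
#' `consistent_with_independent_origins`. Because the evidence is an
#' order-of-magnitude argument rather than a sharp cutoff, the cross-clade
#' verdict is also reported across a sensitivity sweep of fold thresholds.
#'
#' @param table output of [sharing_table()].
#' @param clades list of two character vectors partitioning the species.
#' @param min_fold fold threshold (default 10).
#' @param sweep fold thresholds for the sensitivity report.
#' @return list with `comparisons` (data frame), `all_species_y_mers`,
#'   `sensitivity` (cross-clade verdict per swept threshold) and
#'   `min_fold`.
#' @export
ancestry_test <- function(table, clades, min_fold = 10,
                          sweep = c(2, 5, 10, 20)) {
  if (nrow(table) == 0) stop("empty sharing table")
  species <- sub("^has_", "", grep("^has_", names(table), value = TRUE))
  stopifnot(length(clades) == 2, all(unlist(clades) %in% species))
  in_clade <- function(cl) {
    cols <- paste0("has_", cl)
    rowSums(as.matrix(table[, cols, drop = FALSE]))
  }
  n1 <- in_clade(clades[[1]])
  n2 <- in_clade(clades[[2]])

  agg <- function(rows) c(y = sum(table$y_mer_count[rows]),
                          f = sum(table$female_specific_count[rows]))
  verdict_of <- function(cnt, fold_thr) {
    if (cnt[["y"]] == 0 && cnt[["f"]] == 0) return("no_signal")
    if (cnt[["y"]] / max(cnt[["f"]], 1) >= fold_thr) "shared_ancestry"
    else "consistent_with_independent_origins"
  }

  rows_list <- list(
    pooled = table$n_species >= 2,
    within_clade1 = n1 == length(clades[[1]]),
    within_clade2 = n2 == length(clades[[2]]),
    cross_clade = n1 >= 1 & n2 >= 1)
  comparisons <- do.call(rbind, lapply(names(rows_list), function(nmi) {
    cnt <- agg(rows_list[[nmi]])
    data.frame(comparison = nmi, y_mers = cnt[["y"]],
               female_specific = cnt[["f"]],
               fold = cnt[["y"]] / max(cnt[["f"]], 1),
               verdict = verdict_of(cnt, min_fold), stringsAsFactors = FALSE)
  }))
  cross_cnt <- agg(rows_list$cross_clade)
  sensitivity <- data.frame(
    min_fold = sweep,
    verdict = vapply(sweep, function(th) verdict_of(cross_cnt, th),
                     character(1)))
  list(comparisons = comparisons,
       all_species_y_mers = table$y_mer_count[table$n_species == length(species)],
       sensitivity = sensitivity, min_fold = min_fold)
}
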