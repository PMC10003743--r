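## Male:female read-depth analysis: log2 M:F ratios, the autosomal 95%
## confidence interval, PAR delineation from windowed coverage, and
## bootstrap-CI contig classification into Y / X / autosomal.

#' Log2 male:female depth ratio
#'
#' `log2((depth_M + pseudocount) / (depth_F + pseudocount))`. A window
#' with equal copy number in the sexes sits at 0; an X-like 1M:2F window
#' at -1; a male-enriched Y unit well above 0.
#'
#' @param depth_M,depth_F non-negative mean depths.
#' @param pseudocount small additive constant keeping the ratio finite.
#' @return numeric vector of log2 ratios.
#' @export
mf_ratio <- function(depth_M, depth_F, pseudocount = 0.3) {
  if (any(depth_M < 0) || any(depth_F < 0)) stop("negative depths")
  log2((depth_M + pseudocount) / (depth_F + pseudocount))
}

#' Empirical autosomal confidence interval
#'
#' The central `level` interval of autosomal unit ratios (2.5th and 97.5th
#' percentiles at the default level), computed with linear interpolation.
#'
#' @param ratios numeric vector of autosomal unit ratios (at least 20).
#' @param level confidence level, default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
autosomal_ci <- function(ratios, level = 0.95) {
  if (length(ratios) < 20) stop("need at least 20 autosomal units")
  a <- (1 - level) / 2
  unname(quantile(ratios, c(a, 1 - a), type = 7))
}

#' Delineate the pseudoautosomal region from windowed coverage
#'
#' The PAR is taken as the maximal contiguous run of windows, anchored at
#' the distal end of the chromosome, whose M:F ratios all fall inside the
#' autosomal confidence interval; its boundary is the proximal edge of the
#' first PAR window. An empty interval is returned when the distal window
#' itself falls outside the interval.
#'
#' @param windows data frame of sex-chromosome windows with columns
#'   `start`, `end` and `ratio` (log2 M:F), ordered by position.
#' @param ci numeric `c(lower, upper)` from [autosomal_ci()].
#' @return list with `start`, `end` (bp; NA when empty) and `n_windows`.
#' @export
delineate_par <- function(windows, ci) {
  if (is.unsorted(windows$start, strictly = TRUE)) stop("windows must be ordered")
  inside <- windows$ratio >= ci[[1]] & windows$ratio <= ci[[2]]
  n <- nrow(windows)
  run <- 0L
  for (i in rev(seq_len(n))) {
    if (!inside[i]) break
    run <- run + 1L
  }
  if (run == 0L)
    return(list(start = NA_real_, end = NA_real_, n_windows = 0L))
  list(start = windows$start[n - run + 1L], end = windows$end[n],
       n_windows = run)
}

#' Classify contigs as Y, X or autosomal by male:female depth
#'
#' Contigs shorter than `min_length` are excluded. Depths are normalized
#' per sex by the autosomal median so that autosomal contigs sit at a
#' plain-scale M:F ratio of 1. A bootstrap over the autosomal contigs
#' (resampling contigs) yields smoothed central-`level` percentile bounds
#' of the autosomal ratio distribution — the scale on which X and Y
#' contigs are outliers; contigs above the upper bound (with male depth at least
#' `y_min_male_frac` of the autosomal male median) are labelled Y, contigs
#' below the lower bound and within the X band (`x_band` to the lower
#' bound) are labelled X, everything else autosomal.
#'
#' @param contigs data frame with columns `unit_id`, `length`, `depth_M`,
#'   `depth_F`.
#' @param min_length minimum contig length retained (default 10 kb).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @param autosomal_ids optional character vector of known autosomal
#'   contigs to bootstrap; when NULL, contigs whose normalized ratio lies
#'   in (0.7, 1.3) serve as the provisional autosomal set.
#' @param x_band lower edge of the X ratio band (default 0.3).
#' @param y_min_male_frac minimum male depth for a Y label, as a fraction
#'   of the autosomal male median (default 0.25).
#' @param pseudocount_frac ratio pseudocount as a fraction of the
#'   normalized autosomal depth (default 0.01).
#' @return list with `records` (labelled contig table with `ratio` and
#'   `class`), `ci` (bootstrap CI of the autosomal median ratio),
#'   `totals` (summed lengths per class in bp), `y_fraction_pct` and
#'   `n_excluded`.
#' @export
classify_contigs <- function(contigs, min_length = 1e4, n_boot = 1000,
                             seed = 1L, level = 0.95, autosomal_ids = NULL,
                             x_band = 0.3, y_min_male_frac = 0.25,
                             pseudocount_frac = 0.01) {
  keep <- contigs$length >= min_length
  n_excluded <- sum(!keep)
  d <- contigs[keep, , drop = FALSE]
  if (nrow(d) == 0) stop("no contigs retained")

  norm_M <- d$depth_M / median(d$depth_M)
  norm_F <- d$depth_F / median(d$depth_F)
  pc <- pseudocount_frac
  ratio <- (norm_M + pc) / (norm_F + pc)

  if (is.null(autosomal_ids)) {
    auto_idx <- which(ratio > 0.7 & ratio < 1.3)
  } else {
    auto_idx <- which(d$unit_id %in% autosomal_ids)
  }
  if (length(auto_idx) < 2) stop("no autosomal contigs to bootstrap")

  ## renormalize by the autosomal medians so autosomal contigs sit at 1
  norm_M <- d$depth_M / median(d$depth_M[auto_idx])
  norm_F <- d$depth_F / median(d$depth_F[auto_idx])
  ratio <- (norm_M + pc) / (norm_F + pc)

  ## bootstrap-smoothed percentile bounds of the autosomal ratio
  ## distribution: each replicate resamples the autosomal contigs and
  ## takes its central-`level` percentiles; the CI is their average. The
  ## bounds therefore describe the spread of autosomal contig ratios (the
  ## scale on which X and Y contigs are outliers), not the sampling error
  ## of a location estimate.
  set.seed(seed)
  a <- (1 - level) / 2
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample(auto_idx, length(auto_idx), replace = TRUE)
    quantile(ratio[idx], c(a, 1 - a), type = 7, names = FALSE)
  }, numeric(2))
  ci <- rowMeans(boot)

  male_floor <- y_min_male_frac * median(norm_M[auto_idx])
  cls <- rep("autosomal", nrow(d))
  cls[ratio > ci[2] & norm_M >= male_floor] <- "Y"
  cls[ratio < ci[1] & ratio > x_band] <- "X"
  d$ratio <- ratio
  d$class <- cls

  totals <- vapply(c("Y", "X", "autosomal"),
                   function(k) sum(d$length[cls == k]), numeric(1))
  list(records = d, ci = ci, totals = totals,
       y_fraction_pct = y_fraction_pct(totals),
       n_excluded = n_excluded)
}

#' Y-limited fraction of the genome from class totals
#'
#' @param totals named numeric vector (or three numbers `y`, `x`, `auto`)
#'   of summed sequence per class, any consistent unit.
#' @return percentage of the assembly that is Y-limited.
#' @export
y_fraction_pct <- function(totals) {
  100 * totals[[1]] / sum(totals)
}
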