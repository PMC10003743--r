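## Pedigree-based segregation typing: per-gene posterior classification into
## autosomal / XY / X0 patterns from parent-offspring genotypes, with X/Y
## phasing. A transparent, fixed-error reimplementation of probabilistic
## segregation inference: per-site likelihoods are computed exactly by
## summing over every parental configuration consistent with a hypothesis,
## and genotyping error misassigns an observed genotype to each of the other
## two genotype states with probability error/2.

SEG_TYPES <- c("autosomal", "XY", "X0")

## Genotype observation-error matrix over the three states.
error_matrix <- function(error) {
  m <- matrix(error / 2, 3, 3)
  diag(m) <- 1 - error
  m
}

## P(observed state s) for each s, given a true-state distribution p.
obs_dist <- function(p, em) as.vector(p %*% em)

## Offspring term: product over observed-state counts n (length 3).
off_term <- function(p, em, n) {
  if (sum(n) == 0) return(1)
  prod(obs_dist(p, em)^n)
}

## Transmission distribution: one allele from a parent with genotype state
## g plus one fixed allele a (1 or 2) -> distribution over offspring states.
trans_one <- function(a, g) {
  pm <- c(0, 0.5, 1)[g]  # P(parent transmits allele 2)
  if (a == 1L) c(1 - pm, pm, 0) else c(0, 1 - pm, pm)
}

## Core per-site computation on genotype states. obs_f, obs_m: observed
## parental states (NA if missing); n_son, n_dau: counts of observed
## offspring states (length-3 integer vectors). Returns likelihood under
## each hypothesis plus the best-supported XY phase.
seg_site_core <- function(obs_f, obs_m, n_son, n_dau, error) {
  em <- error_matrix(error)
  pf <- function(state) if (is.na(obs_f)) 1 else em[state, obs_f]
  pm <- function(state) if (is.na(obs_m)) 1 else em[state, obs_m]

  l_auto <- 0
  for (f in 1:3) for (m in 1:3) {
    paf <- c(0, 0.5, 1)[f]
    pam <- c(0, 0.5, 1)[m]
    p <- c((1 - paf) * (1 - pam), paf * (1 - pam) + (1 - paf) * pam, paf * pam)
    l_auto <- l_auto + pf(f) * pm(m) *
      off_term(p, em, n_son + n_dau)
  }

  l_xy <- 0
  best <- c(NA_integer_, NA_integer_)
  best_val <- -1
  for (x in 1:2) for (y in 1:2) {
    f_state <- if (x == y) c(1L, 3L)[x] else 2L
    for (m in 1:3) {
      v <- pf(f_state) * pm(m) *
        off_term(trans_one(y, m), em, n_son) *
        off_term(trans_one(x, m), em, n_dau)
      l_xy <- l_xy + v
      if (v > best_val) { best_val <- v; best <- c(x, y) }
    }
  }

  l_x0 <- 0
  for (x in 1:2) {
    f_state <- c(1L, 3L)[x]
    for (m in 1:3) {
      pam <- c(0, 0.5, 1)[m]
      son_p <- c(1 - pam, 0, pam)  # hemizygous maternal allele, observed hom
      l_x0 <- l_x0 + pf(f_state) * pm(m) *
        off_term(son_p, em, n_son) *
        off_term(trans_one(x, m), em, n_dau)
    }
  }

  list(lik = c(autosomal = l_auto, XY = l_xy, X0 = l_x0),
       phase = best)
}

.seg_cache <- new.env(parent = emptyenv())

seg_site_cached <- function(obs_f, obs_m, n_son, n_dau, error) {
  key <- paste(obs_f, obs_m, paste(n_son, collapse = ""),
               paste(n_dau, collapse = ""), error, sep = "|")
  hit <- .seg_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- seg_site_core(obs_f, obs_m, n_son, n_dau, error)
  if (length(ls(.seg_cache)) < 250000) .seg_cache[[key]] <- res
  res
}

genotype_alleles <- function(genotypes) {
  sort(unique(unlist(strsplit(genotypes[!is.na(genotypes)], "/", fixed = TRUE))))
}

genotype_states <- function(genotypes, alleles) {
  parts <- strsplit(genotypes, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1L) p <- c(p, p)  # hemizygous observation
    i <- match(sort(p), alleles)
    if (anyNA(i)) return(NA_integer_)
    if (i[1] == 1L && i[2] == 1L) 1L else if (i[1] == 2L) 3L else 2L
  }, integer(1))
}

#' Per-site segregation likelihood
#'
#' Likelihood of one site's observed genotypes under a segregation
#' hypothesis, summing over every parental configuration consistent with
#' the hypothesis (including the unobservable paternal X/Y phase) and
#' applying the genotyping-error model to every individual.
#'
#' @param father,mother observed genotypes as `"A/G"` strings (a single
#'   allele denotes a hemizygous observation); NA if missing.
#' @param offspring_sex character vector, `"M"` or `"F"`.
#' @param offspring_genotype observed offspring genotypes.
#' @param hypothesis `"autosomal"`, `"XY"` or `"X0"`.
#' @param error genotyping error probability (misassignment to each of the
#'   other two genotype states with probability `error/2`).
#' @return the likelihood (a single non-negative number).
#' @export
site_likelihood <- function(father, mother, offspring_sex, offspring_genotype,
                            hypothesis, error = 0.01) {
  if (!hypothesis %in% SEG_TYPES) stop("unknown hypothesis: ", hypothesis)
  gts <- c(father, mother, offspring_genotype)
  alleles <- genotype_alleles(gts)
  if (length(alleles) > 2) stop("site is not biallelic")
  if (length(alleles) == 1) alleles <- c(alleles, ".")
  obs_f <- genotype_states(father, alleles)
  obs_m <- genotype_states(mother, alleles)
  off <- genotype_states(offspring_genotype, alleles)
  n_son <- tabulate(off[offspring_sex == "M"], 3L)
  n_dau <- tabulate(off[offspring_sex == "F"], 3L)
  seg_site_core(obs_f, obs_m, n_son, n_dau, error)$lik[[hypothesis]]
}

#' Classify one gene's segregation type within a family
#'
#' Combines exact per-site likelihoods into a posterior over
#' autosomal / XY / X0 and returns the argmax type when its posterior
#' reaches `threshold` (otherwise `"unassigned"`). For XY calls the X and
#' Y alleles are phased per site as the best-supported paternal phase: the
#' Y allele is the paternal allele transmitted to sons and withheld from
#' daughters.
#'
#' @param gene_df long-format genotype rows for one gene in one family,
#'   with columns `site`, `role` (`father`/`mother`/`offspring`), `sex` and
#'   `genotype`.
#' @param error genotyping error probability.
#' @param prior prior over the three types (autosomal, XY, X0).
#' @param threshold minimum posterior for an assignment (default 0.8).
#' @return list with `type`, `posterior` (named 3-vector summing to 1),
#'   `phase` (data frame site/x_allele/y_allele for divergent sites),
#'   `n_xy_snp_differences` and `n_sites_skipped` (sites with >2 alleles).
#' @export
call_gene <- function(gene_df, error = 0.01, prior = c(1, 1, 1) / 3,
                      threshold = 0.8) {
  if (nrow(gene_df) == 0) stop("empty gene")
  prior <- prior / sum(prior)
  loglik <- c(autosomal = 0, XY = 0, X0 = 0)
  phases <- list()
  skipped <- 0L
  for (site_df in split(gene_df, gene_df$site)) {
    alleles <- genotype_alleles(site_df$genotype)
    if (length(alleles) > 2) { skipped <- skipped + 1L; next }
    if (length(alleles) == 0) next
    if (length(alleles) == 1) alleles <- c(alleles, ".")
    st <- genotype_states(site_df$genotype, alleles)
    f <- st[site_df$role == "father"][1]
    m <- st[site_df$role == "mother"][1]
    off <- site_df$role == "offspring"
    n_son <- tabulate(st[off & site_df$sex == "M"], 3L)
    n_dau <- tabulate(st[off & site_df$sex == "F"], 3L)
    res <- seg_site_cached(f, m, n_son, n_dau, error)
    if (any(res$lik == 0) && error == 0) {
      ## structurally impossible hypotheses at error zero
      loglik <- loglik + log(res$lik)
    } else {
      loglik <- loglik + log(pmax(res$lik, .Machine$double.xmin))
    }
    if (!anyNA(res$phase) && res$phase[1] != res$phase[2]) {
      phases[[length(phases) + 1L]] <- data.frame(
        site = site_df$site[1],
        x_allele = alleles[res$phase[1]],
        y_allele = alleles[res$phase[2]],
        stringsAsFactors = FALSE)
    }
  }
  w <- log(prior) + loglik
  w <- exp(w - max(w[is.finite(w)]))
  w[!is.finite(w)] <- 0
  posterior <- w / sum(w)
  type <- names(posterior)[which.max(posterior)]
  if (max(posterior) < threshold) type <- "unassigned"
  phase <- if (type == "XY" && length(phases))
    do.call(rbind, phases) else NULL
  list(type = type, posterior = posterior,
       phase = phase,
       n_xy_snp_differences = if (!is.null(phase)) nrow(phase) else 0L,
       n_sites_skipped = skipped)
}

#' Call segregation types for all gene-family combinations
#'
#' @param genotypes long-format genotype table (columns gene, family, site,
#'   individual, sex, role, genotype), as produced by
#'   [simulate_pedigrees()] or read from a genotype TSV.
#' @inheritParams call_gene
#' @return list with `calls` (data frame gene/family/type/posterior/
#'   n_xy_snp_differences) and `phases` (per gene-family phase tables).
#' @export
call_genes <- function(genotypes, error = 0.01, prior = c(1, 1, 1) / 3,
                       threshold = 0.8) {
  gt <- genotypes
  prior <- prior / sum(prior)

  ## parse genotype strings through a lookup over the few unique values
  ug <- unique(gt$genotype)
  parts <- strsplit(ug, "/", fixed = TRUE)
  a1u <- vapply(parts, `[`, character(1), 1)
  a2u <- vapply(parts, function(p) p[length(p)], character(1))
  gi <- match(gt$genotype, ug)
  code1 <- match(a1u, BASES)[gi]
  code2 <- match(a2u, BASES)[gi]
  lo <- pmin(code1, code2)
  hi <- pmax(code1, code2)

  sk <- paste(gt$gene, gt$family, gt$site, sep = "\r")
  usk <- unique(sk)
  sid <- match(sk, usk)
  ns <- length(usk)

  ## per-site allele inventory (presence of each base code)
  pres <- matrix(0L, ns, 4)
  idx <- cbind(c(sid, sid), c(lo, hi))
  pres[idx] <- 1L
  n_alle <- rowSums(pres)
  a_min <- max.col(pres, ties.method = "first")
  a_max <- max.col(pres, ties.method = "last")

  state <- 1L + (lo != a_min[sid]) + (hi != a_min[sid])

  f_state <- m_state <- rep(NA_integer_, ns)
  fr <- gt$role == "father"
  mr <- gt$role == "mother"
  f_state[sid[fr]] <- state[fr]
  m_state[sid[mr]] <- state[mr]
  son <- gt$role == "offspring" & gt$sex == "M"
  dau <- gt$role == "offspring" & gt$sex == "F"
  n_son <- matrix(tabulate((sid[son] - 1L) * 3L + state[son], 3L * ns),
                  ns, 3, byrow = TRUE)
  n_dau <- matrix(tabulate((sid[dau] - 1L) * 3L + state[dau], 3L * ns),
                  ns, 3, byrow = TRUE)

  gfk <- sub("\r[0-9]+$", "", usk)
  ugf <- unique(gfk)
  gf <- match(gfk, ugf)
  ngf <- length(ugf)

  loglik <- matrix(0, ngf, 3)
  skipped <- integer(ngf)
  ph_gf <- integer(0)
  ph_site <- character(0)
  ph_x <- character(0)
  ph_y <- character(0)
  site_no <- sub("^.*\r", "", usk)
  for (s in seq_len(ns)) {
    if (n_alle[s] > 2L) { skipped[gf[s]] <- skipped[gf[s]] + 1L; next }
    res <- seg_site_cached(f_state[s], m_state[s], n_son[s, ], n_dau[s, ],
                           error)
    loglik[gf[s], ] <- loglik[gf[s], ] + log(res$lik)
    if (!anyNA(res$phase) && res$phase[1] != res$phase[2]) {
      ph_gf <- c(ph_gf, gf[s])
      ph_site <- c(ph_site, site_no[s])
      ph_x <- c(ph_x, BASES[c(a_min[s], a_max[s])[res$phase[1]]])
      ph_y <- c(ph_y, BASES[c(a_min[s], a_max[s])[res$phase[2]]])
    }
  }

  w <- sweep(loglik, 2, log(prior), `+`)
  w <- exp(w - apply(w, 1, function(r) max(r[is.finite(r)])))
  w[!is.finite(w)] <- 0
  post <- w / rowSums(w)
  type <- SEG_TYPES[max.col(post, ties.method = "first")]
  pmax_post <- apply(post, 1, max)
  type[pmax_post < threshold] <- "unassigned"

  gf_gene <- sub("\r.*$", "", ugf)
  gf_family <- sub("^.*\r", "", ugf)
  n_diff <- tabulate(ph_gf, ngf)
  calls <- data.frame(gene = gf_gene,
                      family = utils::type.convert(gf_family, as.is = TRUE),
                      type = type, posterior = pmax_post,
                      n_xy_snp_differences = ifelse(type == "XY", n_diff, 0L),
                      n_sites_skipped = skipped, stringsAsFactors = FALSE)
  rownames(calls) <- NULL

  phases <- rep(list(NULL), ngf)
  names(phases) <- paste(gf_gene, gf_family, sep = "|")
  if (length(ph_gf)) {
    ph <- data.frame(gf = ph_gf,
                     site = utils::type.convert(ph_site, as.is = TRUE),
                     x_allele = ph_x, y_allele = ph_y,
                     stringsAsFactors = FALSE)
    for (g in unique(ph$gf)) {
      if (type[g] != "XY") next
      d <- ph[ph$gf == g, c("site", "x_allele", "y_allele"), drop = FALSE]
      rownames(d) <- NULL
      phases[[g]] <- d
    }
  }
  list(calls = calls, phases = phases)
}

#' Pool per-family segregation calls to species level
#'
#' A gene is sex-linked if called XY or X0 in at least one family; a
#' detected Y copy dominates, so an XY call in any family overrides X0
#' calls elsewhere. The representative X/Y pair for an XY gene is taken
#' from the family with the highest number of X-Y SNP differences (ties
#' broken by lowest family id).
#'
#' @param family_calls output of [call_genes()].
#' @return data frame with one row per gene: `gene`, `type`, `posterior`,
#'   `family` (supporting family), `n_xy_snp_differences`, plus a
#'   `conflict` flag where families disagreed between XY and X0.
#' @export
pool_families <- function(family_calls) {
  calls <- family_calls$calls
  out <- lapply(split(calls, calls$gene), function(d) {
    d <- d[order(d$family), , drop = FALSE]
    has_xy <- any(d$type == "XY")
    has_x0 <- any(d$type == "X0")
    if (has_xy) {
      dx <- d[d$type == "XY", , drop = FALSE]
      pick <- dx[order(-dx$n_xy_snp_differences, dx$family), ][1, ]
      type <- "XY"
    } else if (has_x0) {
      dx <- d[d$type == "X0", , drop = FALSE]
      pick <- dx[order(-dx$posterior, dx$family), ][1, ]
      type <- "X0"
    } else if (any(d$type == "autosomal")) {
      dx <- d[d$type == "autosomal", , drop = FALSE]
      pick <- dx[order(-dx$posterior, dx$family), ][1, ]
      type <- "autosomal"
    } else {
      pick <- d[1, ]
      type <- "unassigned"
    }
    data.frame(gene = d$gene[1], type = type, posterior = pick$posterior,
               family = pick$family,
               n_xy_snp_differences = pick$n_xy_snp_differences,
               conflict = has_xy && has_x0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Drop sex-linked calls that fall inside the PAR (or off-chromosome)
#'
#' Post-filter in the spirit of mapping-based curation: sex-linked calls
#' are retained for downstream dS and phylogenetic work only when the gene
#' maps to the sex chromosome proximal to the PAR boundary.
#'
#' @param species_calls output of [pool_families()].
#' @param positions data frame with columns `gene`, `chrom`, `position_bp`.
#' @param par_interval numeric `c(start, end)` of the PAR in bp.
#' @param sex_chrom name of the sex chromosome in `positions`.
#' @return `species_calls` with added `chrom`, `position_bp` and logical
#'   `outside_par` columns.
#' @export
position_filter <- function(species_calls, positions, par_interval,
                            sex_chrom = "sexchr") {
  i <- match(species_calls$gene, positions$gene)
  species_calls$chrom <- positions$chrom[i]
  species_calls$position_bp <- positions$position_bp[i]
  species_calls$outside_par <- !is.na(i) &
    species_calls$chrom == sex_chrom &
    species_calls$position_bp < par_interval[[1]]
  species_calls
}
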