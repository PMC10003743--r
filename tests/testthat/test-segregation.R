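# Independent oracle for the three segregation likelihoods of a single
# site: explicit enumeration over parental configurations and offspring
# transmission, written against the model definition rather than the
# package internals.
oracle_site_lik <- function(father, mother, off_sex, off_gt, hyp, e) {
  states <- c("A/A", "A/B", "B/B")
  p_obs <- function(obs, true) if (obs == true) 1 - e else e / 2
  mendel <- function(fs, ms) {
    pa <- c("A/A" = 0, "A/B" = 0.5, "B/B" = 1)
    pf <- pa[[fs]]; pm <- pa[[ms]]
    c((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)
  }
  one_plus <- function(allele, ms) {
    pm <- c("A/A" = 0, "A/B" = 0.5, "B/B" = 1)[[ms]]
    if (allele == "A") c(1 - pm, pm, 0) else c(0, 1 - pm, pm)
  }
  total <- 0
  if (hyp == "autosomal") {
    for (fs in states) for (ms in states) {
      p <- mendel(fs, ms)
      term <- p_obs(father, fs) * p_obs(mother, ms)
      for (i in seq_along(off_gt))
        term <- term * sum(p * vapply(states, function(s)
          p_obs(off_gt[i], s), numeric(1)))
      total <- total + term
    }
  } else if (hyp == "XY") {
    for (x in c("A", "B")) for (y in c("A", "B")) for (ms in states) {
      fs <- paste(sort(c(x, y))[1], sort(c(x, y))[2], sep = "/")
      term <- p_obs(father, fs) * p_obs(mother, ms)
      for (i in seq_along(off_gt)) {
        p <- if (off_sex[i] == "M") one_plus(y, ms) else one_plus(x, ms)
        term <- term * sum(p * vapply(states, function(s)
          p_obs(off_gt[i], s), numeric(1)))
      }
      total <- total + term
    }
  } else {
    for (x in c("A", "B")) for (ms in states) {
      fs <- paste(x, x, sep = "/")
      term <- p_obs(father, fs) * p_obs(mother, ms)
      for (i in seq_along(off_gt)) {
        p <- if (off_sex[i] == "M") {
          pm <- c("A/A" = 0, "A/B" = 0.5, "B/B" = 1)[[ms]]
          c(1 - pm, 0, pm)
        } else one_plus(x, ms)
        term <- term * sum(p * vapply(states, function(s)
          p_obs(off_gt[i], s), numeric(1)))
      }
      total <- total + term
    }
  }
  total
}

test_that("site likelihoods match transmission-probability enumeration", {
  sexes <- c(rep("M", 5), rep("F", 5))
  xy_gt <- c(rep("A/B", 5), rep("A/A", 5))

  ## canonical XY pattern at error 0
  expect_gt(site_likelihood("A/G", "A/A", sexes,
                            sub("B", "G", xy_gt), "XY", 0), 0)
  expect_equal(site_likelihood("A/G", "A/A", sexes,
                               sub("B", "G", xy_gt), "autosomal", 0), 0.5^10)
  expect_equal(site_likelihood("A/G", "A/A", sexes,
                               sub("B", "G", xy_gt), "X0", 0), 0)

  ## monomorphic site: equally likely under every hypothesis
  mono <- rep("A/A", 10)
  l <- vapply(c("autosomal", "XY", "X0"), function(h)
    site_likelihood("A/A", "A/A", sexes, mono, h, 0), numeric(1))
  expect_true(all(l == l[1]))

  ## Mendelian impossibility at error 0
  expect_equal(site_likelihood("A/A", "A/A", sexes,
                               c("A/G", rep("A/A", 9)), "autosomal", 0), 0)

  ## full agreement with the oracle across random patterns and hypotheses
  set.seed(42)
  states <- c("A/A", "A/B", "B/B")
  for (rep_i in 1:25) {
    f <- sample(states, 1); m <- sample(states, 1)
    off <- sample(states, 10, replace = TRUE)
    e <- sample(c(0, 0.01, 0.1), 1)
    for (h in c("autosomal", "XY", "X0")) {
      expect_equal(site_likelihood(f, m, sexes, off, h, e),
                   oracle_site_lik(f, m, sexes, off, h, e),
                   tolerance = 1e-12)
    }
  }
})

test_that("gene calling matches the worked examples", {
  sexes <- c(rep("M", 5), rep("F", 5))
  mk_gene <- function(father, mother, off) {
    data.frame(site = 1, role = c("father", "mother", rep("offspring", 10)),
               sex = c("M", "F", sexes),
               genotype = c(father, mother, off), stringsAsFactors = FALSE)
  }

  ## XY: father A/G, sons A/G, daughters A/A
  g <- mk_gene("A/G", "A/A", c(rep("A/G", 5), rep("A/A", 5)))
  res <- call_gene(g, error = 0.01)
  expect_identical(res$type, "XY")
  expect_gt(max(res$posterior), 0.99)
  expect_identical(res$phase$x_allele, "A")
  expect_identical(res$phase$y_allele, "G")
  expect_identical(res$n_xy_snp_differences, 1L)

  ## X0: hemizygous father A, mother G/G, daughters A/G, sons G/G
  g <- mk_gene("A", "G/G", c(rep("G/G", 5), rep("A/G", 5)))
  res <- call_gene(g, error = 0.01)
  expect_identical(res$type, "X0")
  expect_gt(max(res$posterior), 0.9)

  ## autosomal: both parents het, offspring of both sexes mixed
  g <- mk_gene("A/B", "A/B", c("A/A", "A/B", "B/B", "A/B", "A/A",
                               "B/B", "A/B", "A/A", "B/B", "A/B"))
  res <- call_gene(g, error = 0.01)
  expect_identical(res$type, "autosomal")

  expect_error(call_gene(g[0, ], error = 0.01), "empty")

  ## sites with more than two alleles are skipped and counted
  g3 <- mk_gene("A/C", "G/T", rep("A/G", 10))
  res <- call_gene(g3, error = 0.01)
  expect_identical(res$n_sites_skipped, 1L)
})

test_that("allele relabelling leaves type calls unchanged", {
  cfg <- tiny_config("parsimony", seed = 31)
  g <- simulate_pedigrees(cfg)$genotypes
  keys <- unique(paste(g$gene, g$family))[1:12]
  for (key in keys) {
    d <- g[paste(g$gene, g$family) == key, ]
    r1 <- call_gene(d, error = 0.01)
    d2 <- d
    d2$genotype <- chartr("ACGT", "TGCA", d$genotype)  # bijective relabel
    r2 <- call_gene(d2, error = 0.01)
    expect_identical(r1$type, r2$type)
    expect_equal(unname(r1$posterior), unname(r2$posterior), tolerance = 1e-9)
  }
})

test_that("vectorized batch caller agrees with the per-gene caller", {
  cfg <- tiny_config("parsimony", seed = 8)
  g <- simulate_pedigrees(cfg)$genotypes
  batch <- call_genes(g, error = 0.01)
  for (i in sample(nrow(batch$calls), 30)) {
    row <- batch$calls[i, ]
    d <- g[g$gene == row$gene & g$family == row$family, ]
    single <- call_gene(d, error = 0.01)
    expect_identical(single$type, row$type)
    expect_equal(max(single$posterior), row$posterior, tolerance = 1e-9)
    expect_equal(single$n_xy_snp_differences, row$n_xy_snp_differences)
    key <- paste(row$gene, row$family, sep = "|")
    expect_equal(single$phase, batch$phases[[key]])
  }
})

test_that("calls are exact on error-free pedigrees and phased to truth", {
  cfg <- tiny_config("parsimony", seed = 77, genotyping_error = 0,
                     n_genes = c(autosomal = 40L, XY = 15L, X0 = 15L))
  ped <- simulate_pedigrees(cfg)
  g <- ped$genotypes
  batch <- call_genes(g, error = 0)
  truth <- ped$truth$genes

  for (i in seq_len(nrow(batch$calls))) {
    row <- batch$calls[i, ]
    d <- g[g$gene == row$gene & g$family == row$family, ]
    cls <- truth$class[truth$gene == row$gene]
    if (informative_site_count(d, cls) < 3) next
    expect_identical(row$type, cls)
  }

  ## phased Y alleles equal the planted phase exactly
  phase <- ped$truth$phase
  for (gene in unique(phase$gene)) {
    key <- paste(gene, 1, sep = "|")
    ph <- batch$phases[[key]]
    tr <- phase[phase$gene == gene, ]
    expect_identical(ph$x_allele, tr$x_allele[match(ph$site, tr$site)])
    expect_identical(ph$y_allele, tr$y_allele[match(ph$site, tr$site)])
  }
})

test_that("family pooling follows the max-SNP-difference rule", {
  calls <- data.frame(
    gene = c("g1", "g1", "g1", "g2", "g2", "g3", "g3", "g4", "g4"),
    family = c(1, 2, 3, 1, 2, 1, 2, 1, 2),
    type = c("XY", "autosomal", "XY", "X0", "unassigned",
             "autosomal", "autosomal", "XY", "X0"),
    posterior = c(0.95, 0.9, 0.99, 0.93, 0.5, 0.97, 0.98, 0.9, 0.96),
    n_xy_snp_differences = c(4, 0, 7, 0, 0, 0, 0, 3, 0),
    stringsAsFactors = FALSE)
  pooled <- pool_families(list(calls = calls, phases = list()))
  expect_identical(pooled$family[pooled$gene == "g1"], 3)
  expect_identical(pooled$type[pooled$gene == "g1"], "XY")
  expect_identical(pooled$type[pooled$gene == "g2"], "X0")
  expect_identical(pooled$type[pooled$gene == "g3"], "autosomal")
  expect_identical(pooled$type[pooled$gene == "g4"], "XY")  # Y copy dominates
  expect_true(pooled$conflict[pooled$gene == "g4"])
  expect_false(any(pooled$conflict[pooled$gene != "g4"]))
})

test_that("PAR position filter keeps only proximal sex-linked genes", {
  calls <- data.frame(gene = c("a", "b", "c"), type = "XY", posterior = 1,
                      family = 1, n_xy_snp_differences = 2,
                      conflict = FALSE, stringsAsFactors = FALSE)
  pos <- data.frame(gene = c("a", "b", "c"),
                    chrom = c("sexchr", "sexchr", "autosome1"),
                    position_bp = c(5e6, 3.2e7, 1e6))
  out <- position_filter(calls, pos, par_interval = c(3e7, 4.6e7))
  expect_identical(out$outside_par, c(TRUE, FALSE, FALSE))
})
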