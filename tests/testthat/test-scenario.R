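test_that("configuration invariants are enforced", {
  expect_error(scenario_config("parsimony", genotyping_error = 0.6),
               "genotyping_error")
  expect_error(scenario_config("parsimony", par_start_bp = 5e7,
                               chromosome_length_bp = 4.6e7),
               "par_start_bp")
  expect_error(scenario_config("homology",
                               suppression_times = list(
                                 ancestral_region = 20,
                                 clade_region = c(picta = 4, reticulata = 2))),
               "ancestral stratum")
  ## ancestral suppression older than the outgroup split is rejected
  expect_error(scenario_config("parsimony",
                               suppression_times = list(
                                 ancestral_region = 41,
                                 clade_region = c(picta = 4, reticulata = 2))),
               "ingroup stem")
  ## clade suppression predating the ingroup crown is rejected outside turnover
  expect_error(scenario_config("homology",
                               suppression_times = list(
                                 ancestral_region = NULL,
                                 clade_region = c(picta = 30, reticulata = 2))),
               "postdate")
  expect_silent(validate_scenario_config(scenario_config("turnover")))
})

test_that("gametolog X-Y divergence tracks 2*mu*t (binomial oracle)", {
  ## 10 kb genes, mu = 0.001, t = 10: raw divergence ~ 2*mu*t = 0.02
  cfg <- tiny_config("homology", seed = 7, gene_length_bp = 9999L,
                     suppression_times = list(
                       ancestral_region = NULL,
                       clade_region = c(picta = 10, reticulata = 2)))
  gam <- simulate_gametologs(cfg)
  p_exp <- 0.75 * (1 - exp(-8 / 3 * cfg$mu * 10))  # JC-exact pairwise
  divs <- vapply(gam$pairs, function(p) {
    a <- strsplit(p$x, "")[[1]]
    b <- strsplit(p$y, "")[[1]]
    mean(a != b)
  }, numeric(1))
  n_sites <- cfg$gene_length_bp
  for (d in divs) {
    expect_lt(abs(d - 0.02), 3 * sqrt(p_exp * (1 - p_exp) / n_sites) + 0.0003)
  }
  ## focal X and Y are mutually closest within the alignment when
  ## suppression postdates the focal clade's crown split
  gam <- simulate_gametologs(tiny_config("parsimony", seed = 7))
  clade_gene <- gam$genes$gene[gam$genes$region == "clade"][1]
  aln <- gam$alignments[[clade_gene]]
  dm <- outer(names(aln), names(aln), Vectorize(function(i, j) {
    mean(strsplit(aln[[i]], "")[[1]] != strsplit(aln[[j]], "")[[1]])
  }))
  dimnames(dm) <- list(names(aln), names(aln))
  others <- setdiff(names(aln), c("picta|X", "picta|Y"))
  expect_lt(dm["picta|X", "picta|Y"], min(dm["picta|X", others]))
  expect_lt(dm["picta|X", "picta|Y"], min(dm["picta|Y", others]))
})

test_that("turnover gametologs place the focal Y outside the ingroup X clade", {
  cfg <- tiny_config("turnover", seed = 11)
  gam <- simulate_gametologs(cfg)
  aln <- gam$alignments[[1]]
  d <- function(i, j) mean(strsplit(aln[[i]], "")[[1]] != strsplit(aln[[j]], "")[[1]])
  ## Y diverged before the outgroup: farther from focal X than the
  ## outgroup is, for every ingroup X
  for (x in c("picta|X", "parae|X", "reticulata|X", "wingei|X"))
    expect_gt(d("picta|Y", x), d("outgroup|X", x))
})

test_that("pedigree transmission follows the segregation class", {
  cfg <- tiny_config("parsimony", seed = 3, genotyping_error = 0)
  ped <- simulate_pedigrees(cfg)
  g <- ped$genotypes
  phase <- ped$truth$phase

  ## XY: every son carries the father's Y allele; no daughter does
  xy <- g[g$gene == "xy_001", ]
  for (fam in unique(xy$family)) {
    d <- xy[xy$family == fam, ]
    for (s in unique(d$site)) {
      y <- phase$y_allele[phase$gene == "xy_001" & phase$site == s]
      ds <- d[d$site == s & d$role == "offspring", ]
      has_y <- grepl(y, ds$genotype, fixed = TRUE)
      expect_true(all(has_y[ds$sex == "M"]))
      expect_false(any(has_y[ds$sex == "F"]))
    }
  }

  ## X0: sons carry only maternal alleles (observed as homozygotes)
  x0 <- g[g$gene == "x0_001" & g$family == 1, ]
  for (s in unique(x0$site)) {
    d <- x0[x0$site == s, ]
    mother <- strsplit(d$genotype[d$role == "mother"], "/")[[1]]
    sons <- d$genotype[d$role == "offspring" & d$sex == "M"]
    for (sg in strsplit(sons, "/")) {
      expect_length(unique(sg), 1)
      expect_in(unique(sg), mother)
    }
  }
})

test_that("autosomal transmission matches the binomial oracle", {
  ## father A/B x mother A/A style sites: heterozygous offspring ~ Bin(n, 1/2)
  cfg <- tiny_config("parsimony", seed = 5, genotyping_error = 0,
                     n_families = 1L, offspring_per_sex = 400L,
                     n_genes = c(autosomal = 30L, XY = 1L, X0 = 1L))
  g <- simulate_pedigrees(cfg)$genotypes
  aut <- g[grepl("^aut_", g$gene), ]
  checked <- 0L
  keys <- paste(aut$gene, aut$site)
  for (idx in split(seq_len(nrow(aut)), keys)) {
    d <- aut[idx, ]
    f <- strsplit(d$genotype[d$role == "father"], "/")[[1]]
    m <- strsplit(d$genotype[d$role == "mother"], "/")[[1]]
    if (length(unique(f)) == 2 && length(unique(m)) == 1) {
      off <- d$genotype[d$role == "offspring"]
      het <- vapply(strsplit(off, "/"), function(p) p[1] != p[2], logical(1))
      n <- length(het)
      expect_lt(abs(mean(het) - 0.5), 3 * sqrt(0.25 / n))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 5)
})

test_that("depth means follow copy number", {
  cfg <- tiny_config("parsimony", seed = 9, n_contigs = 600L)
  dep <- simulate_depth(cfg)
  ctg <- dep$contigs
  cls <- dep$truth$contig_class
  D <- cfg$read_depth_mean
  expect_lt(abs(mean(ctg$depth_M[cls == "Y"]) - D / 2), 0.5)
  expect_lt(mean(ctg$depth_F[cls == "Y"]), 0.05 * D)
  expect_lt(abs(mean(ctg$depth_M[cls == "X"]) / mean(ctg$depth_F[cls == "X"]) - 0.5), 0.05)
  win <- dep$windows
  wc <- dep$truth$window_class
  expect_lt(abs(mean(win$depth_M[wc == "PAR"] / win$depth_F[wc == "PAR"]) - 1), 0.05)
  expect_lt(abs(mean(win$depth_M[wc == "X"] / win$depth_F[wc == "X"]) - 0.5), 0.05)
})

test_that("female genomes contain no Y-limited sequence", {
  for (model in c("parsimony", "homology")) {
    cfg <- tiny_config(model, seed = 13)
    gen <- simulate_genomes(cfg)
    for (sp in names(gen$genomes)) {
      block <- gen$truth$blocks[[sp]]$clade
      probe <- substr(block, 1, 60)
      female <- paste(gen$genomes[[sp]]$female, collapse = "N")
      male <- paste(gen$genomes[[sp]]$male, collapse = "N")
      expect_false(grepl(probe, female, fixed = TRUE))
      expect_true(grepl(probe, male, fixed = TRUE))
    }
  }
  expect_identical(simulate_genomes(tiny_config("homology"))$truth$cross_clade_planted_bp, 0)
})

test_that("fixtures are deterministic and guarded against overwrite", {
  cfg <- tiny_config("parsimony", seed = 21)
  sc1 <- simulate_scenario(cfg)
  sc2 <- simulate_scenario(tiny_config("parsimony", seed = 21))
  d1 <- file.path(tempdir(), "fix_a")
  d2 <- file.path(tempdir(), "fix_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- write_fixture(sc1, d1)
  m2 <- write_fixture(sc2, d2)
  expect_identical(m1$md5, m2$md5)

  sc3 <- simulate_scenario(tiny_config("parsimony", seed = 22))
  d3 <- file.path(tempdir(), "fix_c")
  unlink(d3, recursive = TRUE)
  m3 <- write_fixture(sc3, d3)
  expect_false(identical(m1$md5[m1$file == "genotypes.tsv"],
                         m3$md5[m3$file == "genotypes.tsv"]))

  expect_error(write_fixture(sc1, d1), "overwrite")
  expect_silent(write_fixture(sc1, d1, overwrite = TRUE))
  expect_error(write_fixture(sc1, file.path(tempdir(), "nope", "deeper")),
               "parent directory")
  unlink(c(d1, d2, d3), recursive = TRUE)
})
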