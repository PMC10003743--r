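mk_spectrum <- function(counts, k = 31, total_bases = 1000) {
  structure(list(counts = counts, k = k, total_bases = total_bases),
            class = "kmer_spectrum")
}

test_that("canonical counting matches hand enumeration and the oracle", {
  sp <- count_kmers("ACGTA", k = 3)
  expect_equal(sp$counts[order(names(sp$counts))],
               c(ACG = 2L, GTA = 1L))
  expect_equal(count_kmers("ACNGT", k = 3)$counts, setNames(integer(0), character(0)))
  expect_error(count_kmers(character(0), k = 3), "empty")
  expect_error(count_kmers("ACGT", k = 4), "odd")

  set.seed(12)
  for (i in 1:12) {
    s <- random_dna(sample(50:150, 1))
    for (k in c(5L, 31L)) {
      got <- count_kmers(s, k)$counts
      want <- oracle_kmers(s, k)
      expect_equal(got[order(names(got))], want[order(names(want))])
    }
    ## reverse-complement invariance
    rcs <- count_kmers(revcomp(s), 7L)$counts
    fwd <- count_kmers(s, 7L)$counts
    expect_equal(fwd[order(names(fwd))], rcs[order(names(rcs))])
  }

  ## long-k string path agrees with the oracle too
  s <- random_dna(120)
  got <- count_kmers(s, 33L)$counts
  want <- oracle_kmers(s, 33L)
  expect_equal(got[order(names(got))], want[order(names(want))])
})

test_that("spectrum histogram normalizes to the target depth", {
  sp <- mk_spectrum(c(AAA = 1L), total_bases = 2 * 30 * 1e4)
  h <- spectrum_histogram(sp, genome_size_hint = 1e4)
  expect_equal(attr(h, "multiplier"), 0.5)

  ## diploid single-copy sequence at 30x peaks at 30; a haploid Y block
  ## in a male sample peaks near 15
  genome <- random_dna(4000)
  yblock <- random_dna(250)
  reads <- c(rep(genome, 30), rep(yblock, 15))
  sp <- count_kmers(reads, 31)
  h <- spectrum_histogram(sp, genome_size_hint = 4250)
  peaks <- sort(h$normalized_count[order(-h$n_kmers)][1:2])
  expect_lt(abs(peaks[1] - 15), 1)
  expect_lt(abs(peaks[2] - 30), 1.5)
  expect_error(spectrum_histogram(sp, 0), "positive")
})

test_that("sex-specific k-mers use strict presence/absence with min_count", {
  males <- list(mk_spectrum(c(AAA = 5L, CCC = 2L, GGG = 1L)),
                mk_spectrum(c(AAA = 7L, CCC = 9L, GGG = 3L)),
                mk_spectrum(c(AAA = 4L, GGG = 2L)))
  females <- list(mk_spectrum(c(TTT = 3L)), mk_spectrum(c(TTT = 2L, AGA = 2L)),
                  mk_spectrum(c(TTT = 4L, AGA = 5L)))
  ss <- sex_specific(males, females, min_count = 2)
  ## AAA: >= 2 in all males, absent in females -> Y-mer
  ## CCC: missing from male 3; GGG: count 1 in male 1 -> excluded
  expect_identical(ss$male_specific, "AAA")
  ## TTT in all females; AGA missing from female 1
  expect_identical(ss$female_specific, "TTT")
  expect_error(sex_specific(males, list()), "per sex")
})

test_that("fused genome path equals the spectrum path", {
  set.seed(31)
  male <- c(chr1 = random_dna(4000), chrY = random_dna(800))
  female <- c(chr1 = male[["chr1"]])
  fused <- ystrata:::sex_specific_genomes_cpp(male, female, 31L, 1L)
  ref <- sex_specific(list(count_kmers(male, 31)),
                      list(count_kmers(female, 31)), min_count = 1)
  expect_setequal(fused$male_specific, ref$male_specific)
  expect_setequal(fused$female_specific, ref$female_specific)
})

test_that("sharing table exact-subset counts and conservation", {
  y <- list(sp1 = c("a", "b"), sp2 = c("b", "c"), sp3 = "d")
  f <- list(sp1 = character(0), sp2 = character(0), sp3 = character(0))
  tab <- sharing_table(y, f)
  cnt <- setNames(tab$y_mer_count, tab$subset)
  expect_equal(cnt[["sp1"]], 1)
  expect_equal(cnt[["sp2"]], 1)
  expect_equal(cnt[["sp3"]], 1)
  expect_equal(cnt[["sp1+sp2"]], 1)
  expect_equal(sum(cnt), 4)  # |union|
  expect_true(all(cnt[!names(cnt) %in% c("sp1", "sp2", "sp3", "sp1+sp2")] == 0))

  ## disjoint and identical sets
  y2 <- list(sp1 = c("a", "b"), sp2 = c("c", "d"))
  t2 <- sharing_table(y2, list(sp1 = character(0), sp2 = character(0)))
  expect_equal(t2$y_mer_count[t2$n_species > 1], 0)
  y3 <- list(sp1 = c("a", "b"), sp2 = c("a", "b"))
  t3 <- sharing_table(y3, list(sp1 = character(0), sp2 = character(0)))
  expect_equal(t3$y_mer_count[t3$subset == "sp1+sp2"], 2)

  ## conservation over random set systems
  set.seed(77)
  universe <- replicate(60, random_dna(8))
  for (i in 1:20) {
    sets <- lapply(1:4, function(j) sample(universe, sample(0:40, 1)))
    names(sets) <- paste0("s", 1:4)
    fsets <- lapply(1:4, function(j) sample(universe, sample(0:40, 1)))
    names(fsets) <- names(sets)
    tab <- sharing_table(sets, fsets)
    expect_equal(sum(tab$y_mer_count), length(unique(unlist(sets))))
    expect_equal(sum(tab$female_specific_count), length(unique(unlist(fsets))))
  }
})

test_that("ancestry test reproduces the headline fold contrasts", {
  species <- c("picta", "parae", "reticulata", "wingei")
  clades <- list(c("picta", "parae"), c("reticulata", "wingei"))
  mk_tab <- function(y_cross, f_cross) {
    tab <- data.frame(subset = "picta+reticulata", n_species = 2,
                      has_picta = TRUE, has_parae = FALSE,
                      has_reticulata = TRUE, has_wingei = FALSE,
                      y_mer_count = y_cross, female_specific_count = f_cross)
    tab
  }
  ## pooled totals as printed: 142,047 shared Y-mers vs 1,029 female FP
  res <- ancestry_test(mk_tab(142047, 1029), clades)
  pooled <- res$comparisons[res$comparisons$comparison == "pooled", ]
  expect_gte(pooled$fold, 130)
  expect_identical(pooled$verdict, "shared_ancestry")

  ## cross-clade totals: 1,768 vs 220 -> fold ~8, threshold-sensitive
  res <- ancestry_test(mk_tab(1768, 220), clades, min_fold = 10)
  cross <- res$comparisons[res$comparisons$comparison == "cross_clade", ]
  expect_equal(cross$fold, 1768 / 220, tolerance = 1e-9)
  expect_identical(cross$verdict, "consistent_with_independent_origins")
  sens <- setNames(res$sensitivity$verdict, res$sensitivity$min_fold)
  expect_identical(sens[["5"]], "shared_ancestry")
  expect_identical(sens[["10"]], "consistent_with_independent_origins")

  ## no signal at all
  res0 <- ancestry_test(mk_tab(0, 0), clades)
  expect_identical(
    res0$comparisons$verdict[res0$comparisons$comparison == "cross_clade"],
    "no_signal")
})

test_that("planted cross-clade sharing separates parsimony from homology", {
  folds <- list(parsimony = numeric(0), homology = numeric(0))
  for (seed in 1:8) {
    for (model in names(folds)) {
      cfg <- tiny_config(model, seed = 1000 + seed)
      gen <- simulate_genomes(cfg)
      ym <- list(); fm <- list()
      for (sp in names(gen$genomes)) {
        g <- gen$genomes[[sp]]
        ss <- ystrata:::sex_specific_genomes_cpp(g$male, g$female, 31L, 1L)
        ym[[sp]] <- ss$male_specific
        fm[[sp]] <- ss$female_specific
      }
      res <- ancestry_test(sharing_table(ym, fm),
                           list(cfg$species[1:2], cfg$species[3:4]))
      cross <- res$comparisons[res$comparisons$comparison == "cross_clade", ]
      folds[[model]] <- c(folds[[model]],
                          ifelse(cross$verdict == "no_signal", 0, cross$fold))
    }
  }
  expect_gte(mean(folds$parsimony >= 10), 0.9)
  ## homology: cross-clade Y-mers are chance-level, like the female control
  expect_true(all(folds$homology < 10))
})
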