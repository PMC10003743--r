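# Small scenario configurations keep unit tests fast; the acceptance
# suite runs the full-size study conditions.

tiny_config <- function(model = "parsimony", seed = 1L, ...) {
  defaults <- list(n_genes = c(autosomal = 12L, XY = 6L, X0 = 6L),
                   n_contigs = 120L,
                   genome_autosome_bp = 4e4, genome_x_bp = 2e4,
                   ylim_ancestral_bp = 4e3, ylim_clade_bp = 6e3,
                   n_expr_genes = 40L, n_diverged_y = 4L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, c(list(model = model, seed = seed), args))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Sites that can discriminate the segregation hypotheses at error zero:
# a heterozygous father separates autosomal, XY and X0 transmission; for
# X0 genes (hemizygous father, observed homozygous) a son homozygous for
# a non-paternal allele is the discriminating signature. Sites with a
# homozygous father and heterozygous mother cannot separate XY from
# autosomal even in principle and are not counted.
informative_site_count <- function(gene_df, truth_class) {
  n <- 0L
  for (d in split(gene_df, gene_df$site)) {
    fa <- strsplit(d$genotype[d$role == "father"][1], "/", fixed = TRUE)[[1]]
    ok <- length(unique(fa)) > 1
    if (!ok && truth_class == "X0") {
      sons <- strsplit(d$genotype[d$role == "offspring" & d$sex == "M"],
                       "/", fixed = TRUE)
      ok <- any(vapply(sons, function(p)
        length(unique(p)) == 1 && !(p[1] %in% fa), logical(1)))
    }
    if (ok) n <- n + 1L
  }
  n
}
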