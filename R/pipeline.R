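## Pipeline orchestration: run every stage on a scenario (in memory) or on
## a fixture directory, aggregate the stage outputs, and synthesize an
## overall model verdict from the phylogenetic clustering pattern and the
## cross-clade Y-mer sharing test.

read_fixture <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("missing manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))

  maybe <- function(fn, reader) {
    p <- file.path(dir, fn)
    if (file.exists(p)) reader(p) else NULL
  }
  aln_dir <- file.path(dir, "alignments")
  alignments <- NULL
  if (dir.exists(aln_dir)) {
    files <- list.files(aln_dir, pattern = "\\.fasta$", full.names = TRUE)
    alignments <- lapply(files, read_fasta)
    names(alignments) <- sub("\\.fasta$", "", basename(files))
  }
  genome_dir <- file.path(dir, "genomes")
  genomes <- NULL
  if (dir.exists(genome_dir)) {
    genomes <- list()
    for (sp in cfg$species) {
      mf <- file.path(genome_dir, paste0(sp, "_M.fasta"))
      ff <- file.path(genome_dir, paste0(sp, "_F.fasta"))
      if (file.exists(mf) && file.exists(ff))
        genomes[[sp]] <- list(male = read_fasta(mf), female = read_fasta(ff))
    }
    if (length(genomes) == 0) genomes <- NULL
  }
  pairs <- NULL
  gam <- maybe("gametologs.fasta", read_fasta)
  if (!is.null(gam)) {
    genes <- unique(sub("\\|[XY]$", "", names(gam)))
    pairs <- lapply(genes, function(g)
      list(gene = g, x = gam[[paste0(g, "|X")]], y = gam[[paste0(g, "|Y")]],
           position_bp = NA_real_))
    names(pairs) <- genes
  }
  libs <- maybe("libsizes.tsv", read_tsv)
  list(config = cfg, manifest = manifest,
       genotypes = maybe("genotypes.tsv", read_tsv),
       positions = maybe("gene_positions.tsv", read_tsv),
       windows = maybe("depth_windows.tsv", read_tsv),
       contigs = maybe("depth_contigs.tsv", read_tsv),
       expression = maybe("expression.tsv", read_tsv),
       libsizes = if (!is.null(libs)) setNames(libs$libsize, libs$sample),
       pairs = pairs, alignments = alignments, genomes = genomes)
}

scenario_inputs <- function(scenario) {
  cfg <- scenario$config
  pairs <- scenario$gametologs$pairs
  list(config = unclass(cfg),
       genotypes = scenario$pedigrees$genotypes,
       positions = scenario$truth$genes,
       windows = scenario$depth$windows,
       contigs = scenario$depth$contigs,
       expression = scenario$expression$counts,
       libsizes = scenario$expression$libsizes,
       pairs = pairs,
       alignments = scenario$gametologs$alignments,
       genomes = scenario$genomes$genomes)
}

run_stage <- function(expr) {
  tryCatch(list(status = "ok", result = expr),
           error = function(e) list(status = "failed",
                                    error = conditionMessage(e)))
}

#' Run the full inference pipeline
#'
#' Executes, in dependency order: coverage (contig classification and PAR
#' delineation), pedigree segregation typing with pooling and PAR
#' filtering, the expression screen, dS estimation and gene trees for the
#' genes called XY, the k-mer sharing analysis on the per-sex genomes, and
#' the overall model verdict. A failing stage is recorded as failed in the
#' report; downstream stages run with whatever inputs remain.
#'
#' @param x a `ystrata_scenario` (in-memory) or the path to a fixture
#'   directory written by [write_fixture()].
#' @param error genotyping error rate used by the segregation caller;
#'   defaults to the value in the scenario configuration.
#' @param posterior_threshold minimum segregation posterior (default 0.8).
#' @param support_threshold minimum bootstrap support for a decisive
#'   branch (default 70).
#' @param min_fold cross-clade Y-mer fold threshold (default 10).
#' @param n_boot_trees bootstrap replicates per gene tree (default 100).
#' @param n_boot_ds codon-bootstrap replicates for dS (default 1000).
#' @param seed integer seed for all resampling in the analysis stages.
#' @return object of class `ystrata_report`: per-stage outputs and
#'   parameters, the overall verdict, and the configuration digest.
#' @export
run_pipeline <- function(x, error = NULL, posterior_threshold = 0.8,
                         support_threshold = 70, min_fold = 10,
                         n_boot_trees = 100, n_boot_ds = 1000, seed = 1L) {
  inputs <- if (inherits(x, "ystrata_scenario")) scenario_inputs(x)
            else read_fixture(x)
  cfg <- inputs$config
  if (is.null(error)) error <- cfg$genotyping_error %||% 0.01
  clades <- list(unlist(cfg$species)[1:2], unlist(cfg$species)[3:4])
  focal <- cfg$focal_species %||% unlist(cfg$species)[1]
  outgroup <- cfg$outgroup %||% "outgroup"

  ## coverage: contigs then PAR from windows
  coverage <- run_stage({
    if (is.null(inputs$contigs)) stop("missing contig depth table")
    cc <- classify_contigs(inputs$contigs, seed = substream_seed(seed, 11L))
    auto <- cc$records[cc$records$class == "autosomal", ]
    ci_log <- autosomal_ci(mf_ratio(auto$depth_M, auto$depth_F))
    win <- inputs$windows
    win$ratio <- mf_ratio(win$depth_M, win$depth_F)
    par <- delineate_par(win[order(win$start), ], ci_log)
    list(contigs = cc, window_ci = ci_log, par = par)
  })
  par_interval <- if (coverage$status == "ok" &&
                      !is.na(coverage$result$par$start))
    c(coverage$result$par$start, coverage$result$par$end)
  else c(cfg$par_start_bp %||% Inf, cfg$chromosome_length_bp %||% Inf)

  segregation <- run_stage({
    if (is.null(inputs$genotypes)) stop("missing genotype table")
    fam <- call_genes(inputs$genotypes, error = error,
                      threshold = posterior_threshold)
    species_calls <- pool_families(fam)
    if (!is.null(inputs$positions))
      species_calls <- position_filter(species_calls, inputs$positions,
                                       par_interval)
    list(family_calls = fam$calls, species_calls = species_calls)
  })

  expression <- run_stage({
    if (is.null(inputs$expression)) stop("missing expression table")
    screen_candidates(rpkm(inputs$expression, inputs$libsizes))
  })

  xy_genes <- character(0)
  if (segregation$status == "ok") {
    sc <- segregation$result$species_calls
    keep <- sc$type == "XY"
    if ("outside_par" %in% names(sc)) keep <- keep & sc$outside_par
    xy_genes <- sc$gene[keep]
  }

  divergence <- run_stage({
    if (is.null(inputs$pairs)) stop("missing gametolog pairs")
    genes <- intersect(xy_genes, names(inputs$pairs))
    if (length(genes) == 0) genes <- names(inputs$pairs)
    ds_table(inputs$pairs[genes], n_boot = n_boot_ds,
             seed = substream_seed(seed, 12L))
  })

  phylo <- run_stage({
    if (is.null(inputs$alignments)) stop("missing ortholog alignments")
    genes <- intersect(xy_genes, names(inputs$alignments))
    if (length(genes) == 0) genes <- names(inputs$alignments)
    calls <- lapply(seq_along(genes), function(i) {
      tr <- bootstrap_support(inputs$alignments[[genes[i]]],
                              n = n_boot_trees,
                              seed = substream_seed(seed, 13L + i))
      cl <- classify_topology(tr, focal, outgroup,
                              support_threshold = support_threshold)
      data.frame(gene = genes[i], verdict = cl$verdict,
                 support = cl$support,
                 newick = ape::write.tree(cl$tree),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, calls)
    rownames(out) <- NULL
    out
  })

  kmers <- run_stage({
    if (is.null(inputs$genomes)) stop("missing genome sequences")
    k <- cfg$k %||% 31L
    ym <- list()
    fm <- list()
    for (sp in names(inputs$genomes)) {
      g <- inputs$genomes[[sp]]
      ## assembled genomes: every true k-mer occurs once, so min_count = 1
      ss <- if (k <= 31) {
        sex_specific_genomes_cpp(toupper(g$male), toupper(g$female),
                                 as.integer(k), 1L)
      } else {
        sex_specific(list(count_kmers(g$male, k)),
                     list(count_kmers(g$female, k)), min_count = 1)
      }
      ym[[sp]] <- ss$male_specific
      fm[[sp]] <- ss$female_specific
    }
    tab <- sharing_table(ym, fm)
    list(table = tab,
         ancestry = ancestry_test(tab, clades, min_fold = min_fold))
  })

  verdict <- run_stage({
    if (phylo$status != "ok") stop("phylo stage failed")
    if (kmers$status != "ok") stop("kmer stage failed")
    model_verdict(phylo$result, kmers$result$ancestry)
  })

  report <- list(
    parameters = list(error = error,
                      posterior_threshold = posterior_threshold,
                      support_threshold = support_threshold,
                      min_fold = min_fold, n_boot_trees = n_boot_trees,
                      n_boot_ds = n_boot_ds, seed = seed),
    config_digest = digest_config(cfg),
    version = as.character(utils::packageVersion("ystrata")),
    stages = list(coverage = coverage, segregation = segregation,
                  expression = expression, divergence = divergence,
                  phylo = phylo, kmers = kmers),
    verdict = if (verdict$status == "ok") verdict$result
              else list(model = "inconclusive", reason = verdict$error))
  class(report) <- "ystrata_report"
  report
}

digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Overall model verdict from stage results
#'
#' Synthesizes the phylogenetic clustering pattern and the cross-clade
#' Y-mer sharing test into one label. With majorities computed over genes
#' with non-ambiguous topology calls: `turnover` when the majority verdict
#' is an ancient focal Y; `parsimony` when cross-clade Y-mer sharing shows
#' excess over the female-specific control and the majority verdict is a
#' single recent origin; `homology` when there is no cross-clade excess
#' but within-lineage clustering holds; `inconclusive` otherwise (ties
#' included). This decision rule is this package's synthesis of a
#' qualitative argument; its thresholds are parameters and are logged.
#'
#' @param phylo_calls data frame with a `verdict` column (per gene).
#' @param ancestry output of [ancestry_test()].
#' @return list with `model`, `n_single_recent`, `n_ancient`,
#'   `n_ambiguous`, `cross_clade_verdict` and `cross_clade_fold`.
#' @export
model_verdict <- function(phylo_calls, ancestry) {
  n_single <- sum(phylo_calls$verdict == "single_recent_origin")
  n_ancient <- sum(phylo_calls$verdict == "ancient_Y")
  n_amb <- sum(phylo_calls$verdict == "ambiguous")
  if (n_single + n_ancient == 0) stop("no non-ambiguous gene calls")
  cross <- ancestry$comparisons[
    ancestry$comparisons$comparison == "cross_clade", ]
  shared <- cross$verdict == "shared_ancestry"
  model <-
    if (n_ancient > n_single) "turnover"
    else if (n_single > n_ancient && shared) "parsimony"
    else if (n_single > n_ancient && !shared) "homology"
    else "inconclusive"
  list(model = model, n_single_recent = n_single, n_ancient = n_ancient,
       n_ambiguous = n_amb,
       cross_clade_verdict = cross$verdict,
       cross_clade_fold = cross$fold)
}

#' Write a pipeline report as JSON
#'
#' Serializes a report deterministically (trees as Newick strings, tables
#' as data frames); regenerating the report from the same fixture and
#' parameters reproduces the file byte for byte.
#'
#' @param report a `ystrata_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
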