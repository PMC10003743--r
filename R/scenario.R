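## Synthetic-data generator: complete scenarios (gametolog alignments,
## pedigree genotypes, depth tables, expression tables, sex-pooled genomes)
## under one of three models for the origin of the poeciliid XY system,
## with full planted ground truth.

#' Scenario configuration for the synthetic-data generator
#'
#' Defines the generative conditions of a simulated study: a four-species
#' ingroup (two clades of two species) plus an outgroup on a fixed dated
#' topology, one of three evolutionary-origin models for the sex
#' chromosomes, per-lineage recombination-suppression times, a molecular
#' clock, pedigree design, depth model and genome composition.
#'
#' The three models differ in which Y-limited sequence is shared across
#' lineages and in when the focal Y stopped recombining:
#' \describe{
#'   \item{parsimony}{a small ancestral stratum suppressed once on the
#'     ingroup stem (shared by all four species), plus younger
#'     clade/lineage-specific strata.}
#'   \item{turnover}{the focal clade retains a Y that pre-dates the
#'     outgroup split; the other clade carries a young, independent Y.}
#'   \item{homology}{each clade acquired its Y independently; no Y-limited
#'     sequence is shared across clades.}
#' }
#'
#' @param model one of `"parsimony"`, `"turnover"`, `"homology"`.
#' @param seed global integer seed; every stage derives a fixed sub-stream.
#' @param species four ingroup species, first two forming the focal clade;
#'   the first species is the focal species.
#' @param outgroup outgroup taxon name.
#' @param node_ages named vector of node ages in Myr: `root` (cap for
#'   pre-outgroup events), `outgroup_split`, `ingroup` crown, and the two
#'   clade crown ages `clade1`, `clade2`.
#' @param suppression_times list with `ancestral_region` (Myr, or NULL) and
#'   `clade_region` (named vector, per clade). Defaults are model-specific.
#' @param block_times ages (Myr) at which Y-limited insertion blocks arose:
#'   `ancestral` (parsimony only) and per-clade entries.
#' @param mu substitution rate per site per Myr.
#' @param n_families,offspring_per_sex pedigree design (default:
#'   4 families with 5 sons and 5 daughters each).
#' @param genotyping_error per-site per-individual probability that the
#'   observed genotype is misassigned to one of the other two states.
#' @param n_genes named integer vector of gene counts per segregation class
#'   (`autosomal`, `XY`, `X0`).
#' @param gene_length_bp coding-gene length (multiple of 3).
#' @param sites_per_gene mean number of informative polymorphic sites for
#'   autosomal and X0 genes (XY genes derive theirs from X-Y divergence).
#' @param chromosome_length_bp,par_start_bp,window_bp sex-chromosome window
#'   model; the PAR runs from `par_start_bp` to the distal end.
#' @param ancestral_fraction fraction of the non-PAR chromosome occupied by
#'   the ancestral stratum.
#' @param n_contigs,contig_class_props genome-wide contig depth model.
#' @param read_depth_mean target diploid depth.
#' @param mismap_floor female depth on Y contigs as a fraction of the
#'   diploid mean (homologous mismapping floor).
#' @param genome_autosome_bp,genome_x_bp sizes of the simulated genome
#'   components used for k-mer work.
#' @param ylim_ancestral_bp,ylim_clade_bp lengths of Y-limited insertion
#'   blocks.
#' @param n_expr_genes,n_diverged_y,expr_samples_per_sex,expr_fc expression
#'   screen design: background genes, planted male-limited diverged-Y genes,
#'   samples per sex, and the planted fold change of male-biased genes.
#' @param k k-mer length (odd).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(model = c("parsimony", "turnover", "homology"),
                            seed = 1L,
                            species = c("picta", "parae", "reticulata", "wingei"),
                            outgroup = "outgroup",
                            node_ages = c(root = 45, outgroup_split = 40,
                                          ingroup = 18, clade1 = 10, clade2 = 5),
                            suppression_times = NULL,
                            block_times = NULL,
                            mu = 1e-3,
                            n_families = 4L,
                            offspring_per_sex = 5L,
                            genotyping_error = 0.01,
                            n_genes = c(autosomal = 150L, XY = 20L, X0 = 30L),
                            gene_length_bp = 999L,
                            sites_per_gene = 8,
                            chromosome_length_bp = 46e6,
                            par_start_bp = 30e6,
                            window_bp = 1e6,
                            ancestral_fraction = 0.1,
                            n_contigs = 600L,
                            contig_class_props = c(autosomal = 0.79, X = 0.13, Y = 0.08),
                            read_depth_mean = 30,
                            mismap_floor = 0.02,
                            genome_autosome_bp = 5e5,
                            genome_x_bp = 3e5,
                            ylim_ancestral_bp = 2e4,
                            ylim_clade_bp = 3e4,
                            n_expr_genes = 300L,
                            n_diverged_y = 10L,
                            expr_samples_per_sex = 3L,
                            expr_fc = 8,
                            k = 31L) {
  model <- match.arg(model)
  stopifnot(length(species) == 4, length(outgroup) == 1)
  clades <- list(species[1:2], species[3:4])
  names(clades) <- c(species[1], species[3])

  if (is.null(suppression_times)) {
    suppression_times <- switch(model,
      parsimony = list(ancestral_region = 20,
                       clade_region = c(4, 2)),
      turnover  = list(ancestral_region = NULL,
                       clade_region = c(node_ages[["root"]], 2)),
      homology  = list(ancestral_region = NULL,
                       clade_region = c(4, 2)))
    names(suppression_times$clade_region) <- names(clades)
  }
  if (is.null(block_times)) {
    block_times <- switch(model,
      parsimony = list(ancestral = 20, clade = c(12, 12)),
      turnover  = list(ancestral = NULL, clade = c(node_ages[["root"]], 12)),
      homology  = list(ancestral = NULL, clade = c(12, 12)))
    if (!is.null(block_times$clade)) names(block_times$clade) <- names(clades)
  }

  cfg <- list(model = model, seed = as.integer(seed), species = species,
              outgroup = outgroup, focal_species = species[1],
              clades = clades, node_ages = node_ages,
              suppression_times = suppression_times, block_times = block_times,
              mu = mu, n_families = as.integer(n_families),
              offspring_per_sex = as.integer(offspring_per_sex),
              genotyping_error = genotyping_error,
              n_genes = n_genes, gene_length_bp = as.integer(gene_length_bp),
              sites_per_gene = sites_per_gene,
              chromosome_length_bp = chromosome_length_bp,
              par_start_bp = par_start_bp, window_bp = window_bp,
              ancestral_fraction = ancestral_fraction,
              n_contigs = as.integer(n_contigs),
              contig_class_props = contig_class_props,
              read_depth_mean = read_depth_mean, mismap_floor = mismap_floor,
              genome_autosome_bp = genome_autosome_bp, genome_x_bp = genome_x_bp,
              ylim_ancestral_bp = ylim_ancestral_bp, ylim_clade_bp = ylim_clade_bp,
              n_expr_genes = as.integer(n_expr_genes),
              n_diverged_y = as.integer(n_diverged_y),
              expr_samples_per_sex = as.integer(expr_samples_per_sex),
              expr_fc = expr_fc, k = as.integer(k))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  ages <- cfg$node_ages
  ts <- cfg$suppression_times
  all_t <- c(ts$ancestral_region, ts$clade_region)
  if (any(all_t < 0) || any(all_t > ages[["root"]]))
    stop("suppression times must lie in [0, root age]")
  if (cfg$model %in% c("parsimony", "homology")) {
    if (any(ts$clade_region >= ages[["ingroup"]]))
      stop("clade-region suppression must postdate the ingroup crown under ",
           cfg$model)
  }
  if (cfg$model == "parsimony") {
    ta <- ts$ancestral_region
    if (is.null(ta) || ta <= ages[["ingroup"]] || ta >= ages[["outgroup_split"]])
      stop("ancestral-region suppression must fall on the ingroup stem ",
           "(between the ingroup crown and the outgroup split)")
  } else if (!is.null(ts$ancestral_region)) {
    stop("only the parsimony model has a shared ancestral stratum")
  }
  if (cfg$genotyping_error < 0 || cfg$genotyping_error >= 0.5)
    stop("genotyping_error must lie in [0, 0.5)")
  if (cfg$par_start_bp >= cfg$chromosome_length_bp)
    stop("par_start_bp must be below chromosome_length_bp")
  if (cfg$gene_length_bp %% 3L != 0L || cfg$gene_length_bp <= 0L)
    stop("gene_length_bp must be a positive multiple of 3")
  if (cfg$k %% 2L == 0L || cfg$k < 3L || cfg$k > 63L)
    stop("k must be odd and between 3 and 63")
  if (cfg$read_depth_mean <= 0) stop("read_depth_mean must be positive")
  invisible(cfg)
}

#' Species tree of a scenario in Newick format
#' @param cfg a `scenario_config`.
#' @return single Newick string with branch lengths in Myr.
#' @export
species_tree_newick <- function(cfg) {
  a <- cfg$node_ages
  sp <- cfg$species
  sprintf("(((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g,%s:%g);",
          sp[1], a[["clade1"]], sp[2], a[["clade1"]],
          a[["ingroup"]] - a[["clade1"]],
          sp[3], a[["clade2"]], sp[4], a[["clade2"]],
          a[["ingroup"]] - a[["clade2"]],
          a[["outgroup_split"]] - a[["ingroup"]],
          cfg$outgroup, a[["outgroup_split"]])
}

## Deterministic per-gene plan: ids, classes, strata and chromosome
## positions. Both the gametolog and the pedigree simulators consume it,
## so the two views of a gene agree.
gene_plan <- function(cfg) {
  set.seed(substream_seed(cfg$seed, 1L))
  n <- cfg$n_genes
  nonpar <- cfg$par_start_bp
  anc_end <- round(cfg$ancestral_fraction * nonpar)
  focal_clade <- names(cfg$clades)[1]
  t_clade <- cfg$suppression_times$clade_region[[focal_clade]]

  xy_ids <- sprintf("xy_%03d", seq_len(n[["XY"]]))
  n_anc <- if (cfg$model == "parsimony")
    round(cfg$ancestral_fraction * n[["XY"]]) else 0L
  xy_region <- c(rep("ancestral", n_anc), rep("clade", n[["XY"]] - n_anc))
  xy_t <- ifelse(xy_region == "ancestral",
                 cfg$suppression_times$ancestral_region %||% NA_real_, t_clade)
  xy_pos <- ifelse(xy_region == "ancestral",
                   sample.int(anc_end, n[["XY"]], replace = TRUE),
                   anc_end + sample.int(nonpar - anc_end, n[["XY"]], replace = TRUE))

  x0_ids <- sprintf("x0_%03d", seq_len(n[["X0"]]))
  x0_pos <- anc_end + sample.int(nonpar - anc_end, n[["X0"]], replace = TRUE)

  aut_ids <- sprintf("aut_%03d", seq_len(n[["autosomal"]]))
  n_par <- round(0.2 * n[["autosomal"]])  # genes in the recombining PAR
  aut_chrom <- c(rep("sexchr", n_par), rep("autosome1", n[["autosomal"]] - n_par))
  aut_pos <- c(cfg$par_start_bp +
                 sample.int(cfg$chromosome_length_bp - cfg$par_start_bp,
                            n_par, replace = TRUE),
               sample.int(cfg$chromosome_length_bp,
                          n[["autosomal"]] - n_par, replace = TRUE))

  data.frame(
    gene = c(xy_ids, x0_ids, aut_ids),
    class = c(rep("XY", n[["XY"]]), rep("X0", n[["X0"]]),
              rep("autosomal", n[["autosomal"]])),
    chrom = c(rep("sexchr", n[["XY"]] + n[["X0"]]), aut_chrom),
    position_bp = c(xy_pos, x0_pos, aut_pos),
    region = c(xy_region, rep("clade", n[["X0"]]),
               rep(NA_character_, n[["autosomal"]])),
    t_suppression = c(xy_t, rep(NA_real_, n[["X0"]] + n[["autosomal"]])),
    stringsAsFactors = FALSE)
}

## Simulate one gene's ortholog alignment: X copies along the species tree,
## the focal Y grafted onto the focal X lineage at age t_y.
sim_gene_alignment <- function(cfg, t_y, n_codons) {
  a <- cfg$node_ages
  mu <- cfg$mu
  sp <- cfg$species
  t_y <- min(t_y, a[["root"]])

  anc <- random_coding_int(n_codons)
  path_ages <- sort(unique(c(a[["outgroup_split"]], a[["ingroup"]],
                             a[["clade1"]], 0, t_y)), decreasing = TRUE)
  seq_at <- vector("list", length(path_ages))
  names(seq_at) <- sprintf("%.6f", path_ages)
  cur <- anc
  cur_age <- a[["root"]]
  for (ag in path_ages) {
    cur <- evolve_seq(cur, cur_age - ag, mu)
    seq_at[[sprintf("%.6f", ag)]] <- cur
    cur_age <- ag
  }
  at <- function(ag) seq_at[[sprintf("%.6f", ag)]]

  out_tip <- evolve_seq(at(a[["outgroup_split"]]), a[["outgroup_split"]], mu)
  s5 <- evolve_seq(at(a[["ingroup"]]), a[["ingroup"]] - a[["clade2"]], mu)
  seqs <- c(
    setNames(list(at(0)), paste0(sp[1], "|X")),
    setNames(list(evolve_seq(at(a[["clade1"]]), a[["clade1"]], mu)),
             paste0(sp[2], "|X")),
    setNames(list(evolve_seq(s5, a[["clade2"]], mu)), paste0(sp[3], "|X")),
    setNames(list(evolve_seq(s5, a[["clade2"]], mu)), paste0(sp[4], "|X")),
    setNames(list(evolve_seq(at(t_y), t_y, mu)), paste0(sp[1], "|Y")),
    setNames(list(out_tip), paste0(cfg$outgroup, "|X")))
  vapply(seqs, int_to_dna, character(1))
}

#' Simulate gametolog alignments under a scenario
#'
#' For every XY-class gene, simulates a gap-free codon alignment containing
#' the X copies of the four ingroup species, the focal species' Y copy
#' (branching off the focal X lineage at the stratum-specific suppression
#' time) and the outgroup, under the equal-rates clock `mu`. The expected
#' raw X-Y divergence of a gene is approximately `2 * mu * t`.
#'
#' @param cfg a [scenario_config()].
#' @return list with `alignments` (named character-vector alignments),
#'   `pairs` (per-gene list with `x`, `y`, `position_bp`), and `genes`
#'   (the XY rows of the gene plan).
#' @export
simulate_gametologs <- function(cfg) {
  plan <- gene_plan(cfg)
  xy <- plan[plan$class == "XY", , drop = FALSE]
  set.seed(substream_seed(cfg$seed, 2L))
  n_codons <- cfg$gene_length_bp %/% 3L
  alignments <- vector("list", nrow(xy))
  pairs <- vector("list", nrow(xy))
  focal <- cfg$focal_species
  for (i in seq_len(nrow(xy))) {
    aln <- sim_gene_alignment(cfg, xy$t_suppression[i], n_codons)
    alignments[[i]] <- aln
    pairs[[i]] <- list(gene = xy$gene[i],
                       x = aln[[paste0(focal, "|X")]],
                       y = aln[[paste0(focal, "|Y")]],
                       position_bp = xy$position_bp[i])
  }
  names(alignments) <- xy$gene
  names(pairs) <- xy$gene
  list(alignments = alignments, pairs = pairs, genes = xy)
}

## --- pedigrees -----------------------------------------------------------

## Genotype states are coded 1 = a1/a1, 2 = a1/a2, 3 = a2/a2 with a1 < a2.
state_to_genotype <- function(state, a1, a2) {
  ifelse(state == 1L, paste0(a1, "/", a1),
         ifelse(state == 2L, paste0(a1, "/", a2), paste0(a2, "/", a2)))
}

corrupt_states <- function(states, error) {
  if (error <= 0) return(states)
  n <- length(states)
  hit <- runif(n) < error
  if (any(hit)) {
    shift <- sample.int(2L, sum(hit), replace = TRUE)
    states[hit] <- ((states[hit] - 1L + shift) %% 3L) + 1L
  }
  states
}

#' Simulate pedigree genotype tables under a scenario
#'
#' Emits observed genotypes for `n_families` families (father, mother, and
#' `offspring_per_sex` offspring of each sex) at informative sites of every
#' gene, under the gene's true segregation class: autosomal Mendelian
#' transmission, XY (the father's Y allele passes to all sons and no
#' daughter), or X0 (sons are hemizygous for a maternal allele). Observed
#' genotypes are corrupted uniformly to one of the other two genotype
#' states with probability `genotyping_error`.
#'
#' @param cfg a [scenario_config()].
#' @return list with `genotypes` (long-format data frame: gene, family,
#'   site, individual, sex, role, genotype), and `truth` (gene plan plus
#'   the planted X/Y phase for XY genes).
#' @export
simulate_pedigrees <- function(cfg) {
  plan <- gene_plan(cfg)
  set.seed(substream_seed(cfg$seed, 3L))
  nf <- cfg$n_families
  no <- cfg$offspring_per_sex
  err <- cfg$genotyping_error
  L <- cfg$gene_length_bp
  mu <- cfg$mu

  son_ids <- sprintf("son%02d", seq_len(no))
  dau_ids <- sprintf("dau%02d", seq_len(no))
  indiv <- c("father", "mother", son_ids, dau_ids)
  sexes <- c("M", "F", rep("M", no), rep("F", no))
  roles <- c("father", "mother", rep("offspring", 2L * no))
  n_ind <- length(indiv)

  n_chunks <- nrow(plan) * nf
  geno_chunks <- vector("list", n_chunks)
  chunk_gene <- character(n_chunks)
  chunk_family <- integer(n_chunks)
  chunk_ns <- integer(n_chunks)
  phase_chunks <- list()
  ci <- 0L
  for (g in seq_len(nrow(plan))) {
    cls <- plan$class[g]
    gene <- plan$gene[g]
    if (cls == "XY") {
      t_y <- plan$t_suppression[g]
      p_div <- 0.75 * (1 - exp(-8 / 3 * mu * t_y))
      n_s <- max(1L, rbinom(1L, L, p_div))
    } else {
      n_s <- max(1L, rpois(1L, cfg$sites_per_gene))
    }
    alle <- t(vapply(seq_len(n_s),
                     function(i) sort(sample(BASES, 2L)), character(2)))
    if (cls == "XY") {
      ## fixed X and Y alleles shared across families
      y_is_a2 <- runif(n_s) < 0.5
      x_state <- ifelse(y_is_a2, 1L, 3L)   # mothers and paternal X are hom X
      phase_chunks[[length(phase_chunks) + 1L]] <- data.frame(
        gene = gene, site = seq_len(n_s),
        x_allele = ifelse(y_is_a2, alle[, 1], alle[, 2]),
        y_allele = ifelse(y_is_a2, alle[, 2], alle[, 1]),
        stringsAsFactors = FALSE)
    } else if (cls == "X0") {
      pattern <- ifelse(runif(n_s) < 0.6, "mhet", "fdiff")
    }
    for (fam in seq_len(nf)) {
      G <- matrix(0L, nrow = n_s, ncol = n_ind)
      if (cls == "XY") {
        G[, 1] <- 2L                      # father heterozygous X/Y
        G[, 2] <- x_state                 # mother homozygous X
        G[, 3:(2 + no)] <- 2L             # sons: Y + maternal X
        G[, (3 + no):n_ind] <- x_state    # daughters: paternal X + maternal X
      } else if (cls == "X0") {
        mhet <- pattern == "mhet"
        G[, 1] <- ifelse(mhet, 1L, 3L)       # father hemizygous, observed hom
        G[, 2] <- ifelse(mhet, 2L, 1L)
        ## sons: one maternal allele, observed as a homozygote
        son_a2 <- matrix(rbinom(n_s * no, 1L, rep(ifelse(mhet, 0.5, 0), no)),
                         n_s, no)
        G[, 3:(2 + no)] <- 1L + 2L * son_a2
        ## daughters: paternal allele + one maternal allele
        dau_a2 <- matrix(rbinom(n_s * no, 1L, rep(ifelse(mhet, 0.5, 1), no)),
                         n_s, no)
        G[, (3 + no):n_ind] <- 1L + dau_a2
      } else {
        ## parental genotype pairs, excluding monomorphic hom x hom(same)
        combos <- cbind(rep(1:3, 3), rep(1:3, each = 3))
        combos <- combos[!(combos[, 1] == combos[, 2] & combos[, 1] != 2L), ,
                         drop = FALSE]
        pick <- sample.int(nrow(combos), n_s, replace = TRUE)
        fs <- combos[pick, 1]
        ms <- combos[pick, 2]
        G[, 1] <- fs
        G[, 2] <- ms
        K <- 2L * no
        pat <- matrix(rbinom(n_s * K, 1L, rep(c(0, 0.5, 1)[fs], K)), n_s, K)
        mat <- matrix(rbinom(n_s * K, 1L, rep(c(0, 0.5, 1)[ms], K)), n_s, K)
        G[, 3:n_ind] <- 1L + pat + mat
      }
      obs <- corrupt_states(as.integer(G), err)
      a1 <- rep(alle[, 1], times = n_ind)
      a2 <- rep(alle[, 2], times = n_ind)
      ci <- ci + 1L
      geno_chunks[[ci]] <- state_to_genotype(obs, a1, a2)
      chunk_gene[ci] <- gene
      chunk_family[ci] <- fam
      chunk_ns[ci] <- n_s
    }
  }
  lens <- chunk_ns * n_ind
  genotypes <- data.frame(
    gene = rep(chunk_gene, lens),
    family = rep(chunk_family, lens),
    site = unlist(lapply(chunk_ns, function(n) rep(seq_len(n), times = n_ind))),
    individual = rep(rep(indiv, times = n_chunks), rep(chunk_ns, each = n_ind)),
    sex = rep(rep(sexes, times = n_chunks), rep(chunk_ns, each = n_ind)),
    role = rep(rep(roles, times = n_chunks), rep(chunk_ns, each = n_ind)),
    genotype = unlist(geno_chunks),
    stringsAsFactors = FALSE)
  truth <- list(genes = plan,
                phase = if (length(phase_chunks))
                  do.call(rbind, phase_chunks) else NULL)
  list(genotypes = genotypes, truth = truth)
}

## --- depth ---------------------------------------------------------------

## Poisson depth averaged over 100-bp units, so noise shrinks with length.
rdepth <- function(n, mean_depth, length_bp) {
  units <- pmax(1, round(length_bp / 100))
  rpois(n, mean_depth * units) / units
}

#' Simulate read-depth tables under a scenario
#'
#' Produces per-window depth along the sex chromosome (X-class windows show
#' male depth D/2 vs female D; PAR windows D vs D) and genome-wide contig
#' depth with copy-number structure (Y contigs male-haploid with a small
#' female mismapping floor; X contigs 1M:2F; autosomes 2:2).
#'
#' @param cfg a [scenario_config()].
#' @return list with `windows`, `contigs` (data frames in the depth-table
#'   schema) and `truth` (planted class labels and the true PAR interval).
#' @export
simulate_depth <- function(cfg) {
  set.seed(substream_seed(cfg$seed, 4L))
  D <- cfg$read_depth_mean
  wb <- cfg$window_bp
  n_win <- cfg$chromosome_length_bp %/% wb
  start <- (seq_len(n_win) - 1) * wb
  w_class <- ifelse(start >= cfg$par_start_bp, "PAR", "X")
  windows <- data.frame(
    unit_id = sprintf("win_%03d", seq_len(n_win)), type = "window",
    chrom = "sexchr", start = start, end = start + wb, length = wb,
    depth_M = rdepth(n_win, ifelse(w_class == "PAR", D, D / 2), wb),
    depth_F = rdepth(n_win, D, wb), stringsAsFactors = FALSE)

  nc <- cfg$n_contigs
  cls <- sample(names(cfg$contig_class_props), nc, replace = TRUE,
                prob = cfg$contig_class_props)
  len <- pmin(pmax(round(rlnorm(nc, log(3e4), 0.8)), 2e3), 3e5)
  m_mean <- c(autosomal = D, X = D / 2, Y = D / 2)[cls]
  f_mean <- c(autosomal = D, X = D, Y = cfg$mismap_floor * D)[cls]
  contigs <- data.frame(
    unit_id = sprintf("contig_%04d", seq_len(nc)), type = "contig",
    chrom = sprintf("contig_%04d", seq_len(nc)), start = 0, end = len,
    length = len,
    depth_M = rdepth(nc, m_mean, len),
    depth_F = rdepth(nc, f_mean, len), stringsAsFactors = FALSE)

  list(windows = windows, contigs = contigs,
       truth = list(window_class = w_class, contig_class = cls,
                    par_interval = c(start = cfg$par_start_bp,
                                     end = cfg$chromosome_length_bp)))
}

## --- expression ----------------------------------------------------------

#' Simulate an expression count table under a scenario
#'
#' Background genes share expression between the sexes; planted diverged-Y
#' genes are male-limited (zero female expression) and planted male-biased
#' genes have fold change `expr_fc`. Counts are Poisson around
#' RPKM x length x library size / 1e9.
#'
#' @param cfg a [scenario_config()].
#' @return list with `counts` (long data frame: gene, sample, sex, count,
#'   length), `libsizes` (named numeric) and `truth` (planted gene sets).
#' @export
simulate_expression <- function(cfg) {
  set.seed(substream_seed(cfg$seed, 5L))
  ns <- cfg$expr_samples_per_sex
  samples <- c(sprintf("M%d", seq_len(ns)), sprintf("F%d", seq_len(ns)))
  sex <- c(rep("M", ns), rep("F", ns))
  libsizes <- setNames(round(runif(2 * ns, 2e7, 2.5e7)), samples)

  n_bg <- cfg$n_expr_genes
  n_dy <- cfg$n_diverged_y
  n_mb <- 10L
  genes <- c(sprintf("expr_%04d", seq_len(n_bg)),
             sprintf("divy_%03d", seq_len(n_dy)),
             sprintf("mbias_%03d", seq_len(n_mb)))
  lens <- pmax(300, round(rlnorm(length(genes), log(1500), 0.4)))
  base <- rlnorm(length(genes), log(15), 1)

  rpkm_m <- base
  rpkm_f <- base
  dy_idx <- n_bg + seq_len(n_dy)
  mb_idx <- n_bg + n_dy + seq_len(n_mb)
  rpkm_m[dy_idx] <- rlnorm(n_dy, log(10), 0.4)
  rpkm_f[dy_idx] <- 0
  rpkm_f[mb_idx] <- rlnorm(n_mb, log(5), 0.3)
  rpkm_m[mb_idx] <- rpkm_f[mb_idx] * cfg$expr_fc

  rows <- expand.grid(gi = seq_along(genes), si = seq_along(samples))
  lam <- ifelse(sex[rows$si] == "M", rpkm_m[rows$gi], rpkm_f[rows$gi]) *
    lens[rows$gi] * libsizes[rows$si] / 1e9
  counts <- data.frame(
    gene = genes[rows$gi], sample = samples[rows$si], sex = sex[rows$si],
    count = rpois(nrow(rows), lam), length = lens[rows$gi],
    stringsAsFactors = FALSE)
  list(counts = counts, libsizes = libsizes,
       truth = list(diverged_y = genes[dy_idx], male_biased = genes[mb_idx]))
}

## --- genomes -------------------------------------------------------------

## Evolve a sequence from a common ancestor at age t0 down the full ingroup
## species tree (t0 must predate the ingroup crown).
descend_ingroup <- function(seq0, t0, cfg) {
  a <- cfg$node_ages
  mu <- cfg$mu
  s_in <- evolve_seq(seq0, t0 - a[["ingroup"]], mu)
  s_c1 <- evolve_seq(s_in, a[["ingroup"]] - a[["clade1"]], mu)
  s_c2 <- evolve_seq(s_in, a[["ingroup"]] - a[["clade2"]], mu)
  out <- list(evolve_seq(s_c1, a[["clade1"]], mu),
              evolve_seq(s_c1, a[["clade1"]], mu),
              evolve_seq(s_c2, a[["clade2"]], mu),
              evolve_seq(s_c2, a[["clade2"]], mu))
  names(out) <- cfg$species
  out
}

## Evolve a sequence from a clade ancestor at age t0 (>= the clade crown)
## down to the clade's two species.
descend_clade <- function(seq0, t0, split_age, mu) {
  s <- evolve_seq(seq0, t0 - split_age, mu)
  list(evolve_seq(s, split_age, mu), evolve_seq(s, split_age, mu))
}

#' Simulate per-species, per-sex genome sequences under a scenario
#'
#' Builds, for each ingroup species, a female genome (autosomal block + X)
#' and a male genome (autosomal block + X + Y). The Y consists of
#' X-derived sequence diverged since the stratum-specific suppression time,
#' an identical-to-X PAR segment, and Y-limited insertion blocks whose
#' sharing across lineages is model-specific: a block inherited by all four
#' species under parsimony, clade-private blocks under homology, and a
#' pre-outgroup-aged focal-clade block under turnover. Under homology, no
#' planted Y-limited sequence is shared across clades.
#'
#' @param cfg a [scenario_config()].
#' @return list with `genomes` (per species: `male`/`female` named
#'   character vectors of sequences) and `truth` (per-species Y-limited
#'   block sequences and the amount of planted cross-clade-shared
#'   Y-limited sequence).
#' @export
simulate_genomes <- function(cfg) {
  set.seed(substream_seed(cfg$seed, 6L))
  a <- cfg$node_ages
  mu <- cfg$mu
  sp <- cfg$species
  nonpar <- round(cfg$genome_x_bp * cfg$par_start_bp / cfg$chromosome_length_bp)
  idx_par <- (nonpar + 1L):cfg$genome_x_bp

  ## autosomes
  auto0 <- random_dna_int(cfg$genome_autosome_bp)
  autos <- descend_ingroup(auto0, a[["outgroup_split"]], cfg)

  ## X chromosome along the species tree
  x45 <- random_dna_int(cfg$genome_x_bp)
  x_tip <- descend_ingroup(evolve_seq(x45, a[["root"]] - a[["outgroup_split"]], mu),
                           a[["outgroup_split"]], cfg)
  clade_of <- c(1L, 1L, 2L, 2L)

  ## Y-limited insertion blocks. The genome-scale Y is modelled as the
  ## recombining PAR (identical to the X) plus Y-limited sequence: on a
  ## heavily degenerate Y the X-derived regions recognizable at k-mer
  ## scale are gene-sized and negligible, while sequence diverged beyond
  ## recognition is statistically equivalent to Y-limited insertions.
  blocks <- lapply(1:4, function(i) list())
  if (!is.null(cfg$block_times$ancestral)) {
    b0 <- random_dna_int(cfg$ylim_ancestral_bp)
    banc <- descend_ingroup(b0, cfg$block_times$ancestral, cfg)
    for (i in 1:4) blocks[[i]]$ancestral <- banc[[i]]
  }
  for (cl in 1:2) {
    b0 <- random_dna_int(cfg$ylim_clade_bp)
    t_b <- cfg$block_times$clade[[cl]]
    bc <- descend_clade(b0, t_b, a[[paste0("clade", cl)]], mu)
    members <- which(clade_of == cl)
    for (j in 1:2) blocks[[members[j]]]$clade <- bc[[j]]
  }

  genomes <- vector("list", 4)
  names(genomes) <- sp
  for (i in 1:4) {
    x_seq <- int_to_dna(x_tip[[i]])
    y_seq <- int_to_dna(c(x_tip[[i]][idx_par],
                          unlist(blocks[[i]], use.names = FALSE)))
    auto_seq <- int_to_dna(autos[[i]])
    genomes[[i]] <- list(
      male = c(autosome1 = auto_seq, chrX = x_seq, chrY = y_seq),
      female = c(autosome1 = auto_seq, chrX = x_seq))
  }

  cross_clade_bp <- if (cfg$model == "parsimony") cfg$ylim_ancestral_bp else 0
  truth <- list(
    blocks = lapply(blocks, function(b) lapply(b, int_to_dna)),
    cross_clade_planted_bp = cross_clade_bp)
  names(truth$blocks) <- sp
  list(genomes = genomes, truth = truth)
}

## --- full scenario and fixtures ------------------------------------------

#' Simulate a complete scenario
#'
#' Runs every component simulator (gametologs, pedigrees, depth,
#' expression, genomes) under one configuration and collects the planted
#' ground truth. Identical `(config, seed)` pairs reproduce the scenario
#' exactly.
#'
#' @param cfg a [scenario_config()].
#' @return object of class `ystrata_scenario`.
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  gam <- simulate_gametologs(cfg)
  ped <- simulate_pedigrees(cfg)
  dep <- simulate_depth(cfg)
  expr <- simulate_expression(cfg)
  gen <- simulate_genomes(cfg)
  out <- list(config = cfg,
              gametologs = gam, pedigrees = ped, depth = dep,
              expression = expr, genomes = gen,
              truth = list(model = cfg$model,
                           genes = ped$truth$genes,
                           phase = ped$truth$phase,
                           par_interval = dep$truth$par_interval,
                           window_class = dep$truth$window_class,
                           contig_class = dep$truth$contig_class,
                           expression = expr$truth,
                           genomes = gen$truth))
  class(out) <- "ystrata_scenario"
  out
}

#' Write a scenario to disk as a fixture directory
#'
#' Serializes every component to plain-text formats (TSV tables, 60-column
#' FASTA, Newick, YAML config, JSON truth) and writes a `manifest.json`
#' listing each file with its MD5 digest. Re-running with the same
#' configuration and seed reproduces the digests exactly.
#'
#' @param scenario a `ystrata_scenario`.
#' @param dir output directory (must not exist unless `overwrite = TRUE`).
#' @param overwrite allow writing into an existing directory.
#' @return (invisibly) the manifest as a data frame.
#' @export
write_fixture <- function(scenario, dir, overwrite = FALSE) {
  stopifnot(inherits(scenario, "ystrata_scenario"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite)
    stop("directory exists and is not empty; use overwrite = TRUE")
  if (!dir.exists(dirname(dir)))
    stop("parent directory does not exist: ", dirname(dir))
  dir.create(dir, showWarnings = FALSE, recursive = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(dir, "genomes"), showWarnings = FALSE)
  cfg <- scenario$config

  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  writeLines(species_tree_newick(cfg), file.path(dir, "species_tree.nwk"))
  write_tsv(scenario$pedigrees$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv(scenario$truth$genes, file.path(dir, "gene_positions.tsv"))
  write_tsv(scenario$depth$windows, file.path(dir, "depth_windows.tsv"))
  write_tsv(scenario$depth$contigs, file.path(dir, "depth_contigs.tsv"))
  write_tsv(scenario$expression$counts, file.path(dir, "expression.tsv"))
  write_tsv(data.frame(sample = names(scenario$expression$libsizes),
                       libsize = unname(scenario$expression$libsizes)),
            file.path(dir, "libsizes.tsv"))

  pair_seqs <- unlist(lapply(scenario$gametologs$pairs, function(p)
    setNames(c(p$x, p$y), c(paste0(p$gene, "|X"), paste0(p$gene, "|Y")))))
  write_fasta(pair_seqs, file.path(dir, "gametologs.fasta"))
  for (g in names(scenario$gametologs$alignments))
    write_fasta(scenario$gametologs$alignments[[g]],
                file.path(dir, "alignments", paste0(g, ".fasta")))
  for (s in names(scenario$genomes$genomes)) {
    write_fasta(scenario$genomes$genomes[[s]]$male,
                file.path(dir, "genomes", paste0(s, "_M.fasta")))
    write_fasta(scenario$genomes$genomes[[s]]$female,
                file.path(dir, "genomes", paste0(s, "_F.fasta")))
  }
  truth <- scenario$truth
  truth$genomes$blocks <- NULL  # sequences live in the genome FASTAs
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
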