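## Distance-based gene trees for gametolog alignments: JC69 distances,
## neighbor-joining, column-bootstrap support, and classification of each
## gene's topology against the predictions of a single recent origin
## (focal X and Y are sisters) versus an ancient Y (the focal Y attaches
## outside the ingroup X clade).

aln_matrix <- function(aln) {
  stopifnot(length(unique(nchar(aln))) == 1)
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Remove gap/ambiguity columns alignment-wide
#' @param aln named character vector of equal-length aligned sequences.
#' @return the alignment with every column containing a non-ACGT character
#'   removed.
#' @export
drop_gap_columns <- function(aln) {
  m <- aln_matrix(aln)
  keep <- colSums(!(m == "A" | m == "C" | m == "G" | m == "T")) == 0
  apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
}

#' Jukes-Cantor (JC69) distance between two aligned sequences
#'
#' `d = -3/4 * log(1 - 4/3 * p)` with `p` the mismatch fraction over
#' compared sites.
#'
#' @param s1,s2 equal-length gap-filtered sequences.
#' @return substitutions per site.
#' @export
jc69_distance <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  p <- mean(a != b)
  if (p >= 0.75) stop("saturated: mismatch fraction >= 3/4")
  jc_correct(p)
}

jc_matrix <- function(aln) {
  m <- aln_matrix(aln)
  jc_int_matrix(matrix(match(m, BASES), nrow = nrow(m),
                       dimnames = dimnames(m)))
}

jc_int_matrix <- function(im) {
  n <- nrow(im)
  d <- matrix(0, n, n, dimnames = list(rownames(im), rownames(im)))
  for (i in seq_len(n - 1)) {
    xi <- im[i, ]
    for (j in (i + 1):n) {
      p <- mean(xi != im[j, ])
      if (p >= 0.75)
        stop("saturated pair: ", rownames(im)[i], " vs ", rownames(im)[j])
      d[i, j] <- d[j, i] <- jc_correct(p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; on an additive matrix it reproduces the
#' generating tree's topology and path lengths.
#'
#' @param d symmetric numeric matrix with zero diagonal and taxon
#'   dimnames, at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  ape::nj(stats::as.dist(d))
}

#' Column-bootstrap support for a neighbor-joining tree
#'
#' Builds the full-data NJ tree from JC69 distances, then `n`
#' column-resampled replicates; the support of each internal branch is the
#' percentage of replicate trees containing its bipartition, stored in
#' `node.label`.
#'
#' @param aln named character vector of aligned sequences (will be
#'   gap-column filtered).
#' @param n bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return a `phylo` tree with percentage supports as node labels; the
#'   attribute `degenerate` is TRUE when the alignment has no variable
#'   column.
#' @export
bootstrap_support <- function(aln, n = 100, seed = 1L) {
  aln <- drop_gap_columns(aln)
  if (any(nchar(aln) < 1)) stop("alignment has no columns")
  m <- aln_matrix(aln)
  im <- matrix(match(m, BASES), nrow = nrow(m),
               dimnames = dimnames(m))
  full <- nj_tree(jc_int_matrix(im))
  set.seed(seed)
  ncol_m <- ncol(m)
  boot_trees <- vector("list", n)
  for (b in seq_len(n)) {
    idx <- sample.int(ncol_m, ncol_m, replace = TRUE)
    boot_trees[[b]] <- nj_tree(jc_int_matrix(im[, idx, drop = FALSE]))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.character(round(100 * counts / n, 1))
  variable <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  attr(full, "degenerate") <- variable == 0
  full
}

node_support <- function(tree, node) {
  lab <- tree$node.label[node - length(tree$tip.label)]
  if (is.null(lab) || is.na(lab) || lab == "" || lab == "Root") return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

#' Classify a gene tree against the origin-model predictions
#'
#' Roots the tree at the outgroup and returns
#' `single_recent_origin` when the focal species' X and Y copies are
#' sisters (cherry support at or above `support_threshold`),
#' `ancient_Y` when the focal Y attaches outside the smallest rooted clade
#' containing every ingroup X/autosomal ortholog (decisive-branch support
#' at or above the threshold), and `ambiguous` otherwise.
#'
#' @param tree a `phylo` with bootstrap percentages as node labels (see
#'   [bootstrap_support()]); tip labels of the form `species|copy`.
#' @param focal focal species name.
#' @param outgroup outgroup species name.
#' @param support_threshold minimum decisive support (default 70).
#' @return list with `verdict`, `support`, and the rooted `tree`.
#' @export
classify_topology <- function(tree, focal, outgroup, support_threshold = 70) {
  tips <- tree$tip.label
  focal_x <- paste0(focal, "|X")
  focal_y <- paste0(focal, "|Y")
  out_tips <- tips[sub("\\|.*", "", tips) == outgroup]
  if (!all(c(focal_x, focal_y) %in% tips) || length(out_tips) == 0)
    stop("tree must contain focal X, focal Y and the outgroup")
  ## reroot only when needed: re-rooting an already outgroup-rooted tree
  ## shuffles node labels in ape
  already_rooted <- FALSE
  if (ape::is.rooted(tree)) {
    ntip0 <- length(tree$tip.label)
    root_children <- tree$edge[tree$edge[, 1] == ntip0 + 1L, 2]
    for (ch in root_children) {
      ch_tips <- if (ch <= ntip0) tree$tip.label[ch]
                 else ape::extract.clade(tree, ch)$tip.label
      if (setequal(ch_tips, out_tips)) already_rooted <- TRUE
    }
  }
  tr <- if (already_rooted) tree
        else ape::root(tree, outgroup = out_tips, resolve.root = TRUE,
                       edgelabel = TRUE)
  ntip <- length(tr$tip.label)

  species <- sub("\\|.*", "", tr$tip.label)
  copy <- sub(".*\\|", "", tr$tip.label)
  ingroup_x <- tr$tip.label[species != outgroup & copy != "Y"]
  if (length(ingroup_x) < 2) stop("need at least one other ingroup X")

  clade_tips <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    ape::extract.clade(tr, node)$tip.label
  }

  mrca_xy <- ape::getMRCA(tr, c(focal_x, focal_y))
  if (setequal(clade_tips(mrca_xy), c(focal_x, focal_y))) {
    sup <- node_support(tr, mrca_xy)
    if (!is.na(sup) && sup >= support_threshold)
      return(list(verdict = "single_recent_origin", support = sup, tree = tr))
    return(list(verdict = "ambiguous", support = sup, tree = tr))
  }

  mrca_in <- ape::getMRCA(tr, ingroup_x)
  if (!(focal_y %in% clade_tips(mrca_in))) {
    sup <- node_support(tr, mrca_in)
    if (!is.na(sup) && sup >= support_threshold)
      return(list(verdict = "ancient_Y", support = sup, tree = tr))
    return(list(verdict = "ambiguous", support = sup, tree = tr))
  }
  list(verdict = "ambiguous", support = NA_real_, tree = tr)
}
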