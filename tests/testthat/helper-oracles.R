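# Independent oracles shared by the unit and acceptance suites. Each is
# written against the mathematical definition (brute enumeration,
# closed form, or least squares) rather than the package internals.

# NG86 oracle: classify single-nucleotide changes by brute translation;
# enumerate substitution pathways recursively, skipping stop codons.
oracle_codon <- local({
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- function(c) gc_tab[[c]]
  list(
    sites = function(codon) {
      s <- 0
      for (pos in 1:3) {
        syn <- 0; ok <- 0
        for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
          alt <- codon; substr(alt, pos, pos) <- b
          if (aa(alt) == "*") next
          ok <- ok + 1
          if (aa(alt) == aa(codon)) syn <- syn + 1
        }
        if (ok > 0) s <- s + syn / ok
      }
      c(S = s, N = 3 - s)
    },
    counts = function(c1, c2) {
      paths <- function(cur, target) {
        dp <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
        if (length(dp) == 0) return(list(c(s = 0, n = 0)))
        out <- list()
        for (p in dp) {
          nxt <- cur; substr(nxt, p, p) <- substr(target, p, p)
          if (aa(nxt) == "*") next
          step <- if (aa(nxt) == aa(cur)) c(s = 1, n = 0) else c(s = 0, n = 1)
          for (tail in paths(nxt, target)) out <- c(out, list(step + tail))
        }
        out
      }
      pl <- paths(c1, c2)
      if (length(pl) == 0) return(c(Sd = NA_real_, Nd = NA_real_))
      m <- do.call(rbind, pl)
      c(Sd = mean(m[, "s"]), Nd = mean(m[, "n"]))
    })
})

all_near_codon_pairs <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  pairs <- expand.grid(c1 = sense, c2 = sense, stringsAsFactors = FALSE)
  nd <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               pairs$c1, pairs$c2)
  pairs[nd %in% 1:2, ]
}

# Brute-force least-squares oracle over all 15 unrooted 5-taxon
# topologies: OLS branch lengths on the path-edge incidence matrix,
# topology with minimal RSS wins.
ls_best_topology <- function(d) {
  taxa <- rownames(d)
  topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
  pair_idx <- t(combn(length(taxa), 2))
  best <- NULL
  best_rss <- Inf
  ## index with [[ so the multiPhylo method re-attaches tip labels
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]
    tr$edge.length <- rep(1, nrow(tr$edge))
    A <- matrix(0, nrow(pair_idx), nrow(tr$edge))
    for (r in seq_len(nrow(pair_idx))) {
      path_nodes <- ape::nodepath(tr, pair_idx[r, 1], pair_idx[r, 2])
      for (s in seq_len(length(path_nodes) - 1)) {
        e <- which((tr$edge[, 1] == path_nodes[s] & tr$edge[, 2] == path_nodes[s + 1]) |
                   (tr$edge[, 2] == path_nodes[s] & tr$edge[, 1] == path_nodes[s + 1]))
        A[r, e] <- 1
      }
    }
    rss <- sum(lm.fit(A, d[pair_idx])$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tr }
  }
  best
}

random_additive <- function(taxa) {
  tr <- ape::rtree(length(taxa), tip.label = taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  d <- cophenetic(tr)[taxa, taxa]
  list(tree = ape::unroot(tr), d = d)
}

# Plain-R canonical k-mer oracle (substring + reverse complement).
oracle_kmers <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(integer(0))
  km <- substring(s, 1:(n - k + 1), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0) return(integer(0))
  rc <- revcomp(km)
  canon <- pmin(km, rc)
  tab <- table(canon)
  setNames(as.integer(tab), names(tab))
}
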