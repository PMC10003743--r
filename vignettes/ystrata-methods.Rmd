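---
title: "Dating recombination suppression and testing sex-chromosome origin models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating recombination suppression and testing sex-chromosome origin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrata)
```

## The scientific question

Several poeciliid fishes — the guppy *Poecilia reticulata*, *P. wingei*,
*P. picta* and *P. parae* — carry XY sex chromosomes on the same linkage
group. Three histories can explain this:

* **Parsimony**: recombination between X and Y was suppressed once, over a
  small region, in the common ancestor of all four species, and the
  suppressed region later expanded independently in the *picta/parae* and
  *reticulata/wingei* clades.
* **Turnover**: an old sex chromosome (predating even the outgroup split)
  survives in one clade, while the other clade replaced it with a young
  system on the same linkage group.
* **Homology**: the two clades recruited the same linkage group as a sex
  chromosome independently; no Y-limited sequence is shared between them.

Three quantitative signals discriminate the models: the synonymous
divergence (dS) between X and Y gametologs, which dates when each stratum
stopped recombining; the placement of the focal species' Y in gene trees
containing the X orthologs of all species plus an outgroup; and the
sharing of male-specific k-mers (Y-mers) across species, read against the
female-specific k-mer count as a false-positive control.

`ystrata` implements the full inference pipeline and a synthetic-data
generator that plants each of the three histories with known truth, so
that every stage — segregation typing, expression screening, coverage
classification, dS dating, tree classification, Y-mer sharing, and the
combined verdict — can be verified end to end without external data.

## The synthetic-data generator

`scenario_config()` fixes the study conditions. The defaults mirror a
realistic poeciliid design:

* A dated species tree `(((picta, parae), (reticulata, wingei)), outgroup)`
  with clade crowns at 10 and 5 Myr, the ingroup crown at 18 Myr and the
  outgroup at 40 Myr. The exact ages are stylized but ordered like the
  accepted poeciliid phylogeny.
* A single-parameter equal-rates (JC-style) substitution clock,
  `mu = 1e-3` substitutions/site/Myr — a typical vertebrate nuclear rate.
  With the default focal suppression time of 4 Myr this yields expected
  X-Y dS near 0.008, matching the low divergence regime the method is
  designed for (observed gametolog dS of 0-0.02). Branch evolution uses
  the exact JC transition probability, so divergence composes correctly
  across branches and the expected raw X-Y divergence is `2*mu*t`.
* Four families with five sons and five daughters each — the minimal
  pedigree design for reliable segregation inference — and a genotyping
  error of 0.01 per site per individual, misassigned uniformly to the two
  other genotype states.
* A 46 Mb sex chromosome in 1 Mb windows with the pseudoautosomal region
  (PAR) from 30 Mb to the distal end; an ancestral stratum occupying 10%
  of the non-PAR chromosome (its true size is not known; 10% is a
  deliberately small "ancestral region" consistent with the argument that
  it predates the clade-specific strata, and it is configurable).
* Depth tables at a target diploid depth of 30: autosomes 2M:2F, X
  regions 1M:2F, Y contigs male-haploid with a 2% female mismapping
  floor so ratios stay finite.
* Per-species, per-sex genomes of about 1 Mb for k-mer work.

Sub-stream seeds are derived from one global seed by fixed offsets, so a
scenario is reproducible stage by stage and `write_fixture()` emits
byte-identical files for identical configurations.

### What the genome model plants, and why

The male genome is autosome + X + Y; the female genome is autosome + X.
The simulated Y consists of the recombining PAR (identical to the X) plus
Y-limited blocks whose inheritance carries the model signal: under
parsimony one block arose on the ingroup stem (20 Myr) and descends to
all four species, plus clade blocks (12 Myr) shared within each clade;
under homology only the clade blocks exist, drawn independently per
clade; under turnover the focal clade's block predates the outgroup split
while the other clade's is young. Mutation accumulates on each descending
branch, so cross-species k-mer sharing decays with block age exactly as
it would for real Y-limited sequence.

A design choice deserves emphasis: the genome-scale Y deliberately omits
a large "X-derived, recently diverged" segment. On a heavily degenerate Y
(the empirical motivation: ~2.6 Mb of Y-limited sequence against ~29.6 Mb
of X, and a handful of recognizable gametologs) the X-derived portion
that is still recognizable at k-mer scale is gene-sized, while older
X-derived sequence has diverged beyond 31-mer identity and is
statistically indistinguishable from Y-limited insertions. Including a
megabase-scale young X-derived segment would also create an artifact this
generator is designed to exclude: Y windows that retain the ancestral
state while the X fixes new substitutions become male-specific k-mers
that are *identical across species by descent through the X*, producing
cross-clade "sharing" of convergent origin even under homology. Real
read data hides this channel inside a large, repeat- and error-driven
false-positive floor; a clean genome-level simulation does not have that
floor, so the channel is excluded by construction and the planted
cross-clade Y-limited sequence is exactly zero under homology.
X-derived gametolog sequence is still simulated in full where it belongs:
in the codon alignments and pedigree genotypes used for dS and trees.

The generator does **not** emulate indels, rate heterogeneity across
sites, repeat families, within-population polymorphism, or sequencing
error. Two consequences matter for interpreting green tests: (i) the
female-specific k-mer control is structurally near zero here, whereas
real read data shows hundreds to thousands of female-specific k-mers —
passing tests show the decision logic is correct, not that the
false-positive floor of real data is modelled; (ii) segregation accuracy
on simulated pedigrees is an upper bound relative to real RNA-seq
genotypes, where allele-specific expression and coverage gaps add errors
beyond the uniform genotyping-error model.

## Segregation typing

For each gene and family the caller evaluates exact per-site likelihoods
under three hypotheses — autosomal, XY and X0 — by summing over every
parental configuration consistent with the hypothesis: parental genotype
states, and for XY the unobservable paternal phase (which allele rides
the Y). Offspring transmission follows Mendelian rules with
sex-dependence: sons receive the paternal Y allele (XY), only a maternal
allele (X0), or either paternal allele (autosomal). Observation error
misassigns a genotype to each of the other two states with probability
`error/2`; a heterozygote observed as homozygous (the RNA-seq
allele-imbalance failure mode) is thereby treated as a single error
event rather than modelled through expression ratios.

Configurations are weighted equally and summed (not averaged), which
makes a fully monomorphic site exactly equally likely under all three
hypotheses at error zero — uninformative sites then cancel in the
posterior. The full EM machinery of pedigree-based callers (error-rate
and allele-expression estimation) is intentionally replaced by a fixed,
user-set error rate (default 0.01): the acceptance surface is parameter
recovery on simulations, not output identity with any particular tool.

Posteriors combine site likelihoods with a uniform prior (configurable);
a call requires posterior ≥ 0.8, otherwise the gene is unassigned. Calls
are pooled across families: a gene is sex-linked if any family calls it
XY or X0; a detected Y copy dominates an X0 call (an explicit decision —
the pooling rule for XY/X0 conflicts is not specified by the original
procedure, and conflicts are flagged in the output); the representative
X/Y pair comes from the family with the most X-Y SNP differences, ties
to the lowest family id. A position post-filter drops sex-linked calls
inside the PAR or off the sex chromosome before dS and tree work.

## Expression screen

RPKM is `count * 1e9 / (length * library size)`. Per-sex medians use the
lower-interpolation convention for even sample counts so outputs are
bit-stable. Genes with both sex medians below 2 RPKM are dropped, except
genes sex-limited in expression (median 0 in one sex, expressed in the
other), which are retained; candidates are genes with male:female median
fold change above 2, with male-limited genes always candidates. The
2-RPKM floor is applied per sex (drop only when both sexes fall below) —
the source procedure does not state whether its median is pooled or
per-sex, and the per-sex rule is the one that cannot discard a
male-limited gene. The reported log2 fold change adds a 0.1 RPKM
pseudocount so sex-limited genes have finite logs; the threshold test
itself uses raw medians.

## Coverage: contig classes and the PAR

Window and contig ratios are computed as `log2((M + c) / (F + c))` — the
log2 of the M:F ratio. (The alternative literal reading "ratio of logs"
is undefined at depth 1 and inconsistent with published CI bounds near 1,
so it is not used.) Contig classification works on the plain ratio scale
after per-sex normalization by the autosomal median: the bootstrap over
autosomal contigs yields smoothed central 95% percentile bounds of the
autosomal ratio distribution. A contig above the upper bound is Y — with
the additional guard that its male depth reach 25% of the autosomal male
median, so near-zero-depth junk cannot become Y; a contig below the
lower bound and above 0.3 is X — the band excludes near-zero-male junk
from the X class; contigs under 10 kb are excluded outright. The PAR is
the maximal run of windows anchored at the distal chromosome end whose
ratios fall inside the autosomal interval; its boundary is the proximal
edge of the first such window.

## dS between gametologs

Codon alignments are filtered (gap/ambiguity codons dropped, stop codons
dropped with a logged count, pairs under 300 bp after filtering flagged);
the 300 bp rule is applied to X-Y pairs as well as multi-species
orthologs, configurable. Synonymous and nonsynonymous site counts follow
NG86: at each codon position the fraction of single-nucleotide changes
preserving the amino acid, with changes to stop codons excluded from the
denominator so S + N = 3 per codon. Differences are counted with
equal-weight averaging over substitution pathways; pathways through stop
codons are excluded, and codon pairs whose every pathway transits a stop
are dropped with a logged count. Proportions are corrected with the
Jukes-Cantor formula `d = -3/4 ln(1 - 4/3 p)`; `p >= 3/4` is flagged
saturated instead of extrapolated. The standard error is a codon
bootstrap (default 1000 replicates, seeded). At the divergence scale
this pipeline targets (dS ≤ 0.02) the NG86+JC estimator and the full
maximum-likelihood codon machinery agree closely, which is why the
simpler, exactly testable estimator is used; the acceptance surface is
recovery of planted `2*mu*t`, verified to within 10% at dS of
0.005-0.02 on 10 kb concatenations.

## Gene trees and topology classification

Distances are JC69 on gap-column-filtered alignments; trees are
neighbor-joining; support is a 100-replicate column bootstrap (percentage
of replicates containing each bipartition of the full-data tree).
Distance NJ replaces likelihood tree search deliberately: at these
divergences the topology is carried by a handful of shared derived
sites, NJ recovers every additive-distance topology exactly (verified
against a brute-force least-squares oracle over all 15 five-taxon
topologies), and the acceptance surface is the verdict, not likelihoods.
Trees are rooted strictly at the designated outgroup — no midpoint
fallback — and zero-length branches are retained, not collapsed.

A gene votes `single_recent_origin` when the focal X and Y are sisters
with cherry support ≥ 70 (a common support convention; none is inherited
from the source), `ancient_Y` when the focal Y attaches outside the
smallest rooted clade containing all ingroup X orthologs with decisive
support ≥ 70, and `ambiguous` otherwise. Under the default parsimony
configuration about 10% of gametologs sit in the ancestral stratum,
whose Y lineage predates the ingroup crown; those genes legitimately
vote `ancient_Y`, which is why the verdict below uses majorities.

## Y-mers and the ancestry test

Canonical k-mer counting (k = 31, lexicographic minimum of k-mer and
reverse complement, N-containing windows skipped) is exact and compiled.
A Y-mer must reach `min_count` in every male sample and be absent from
every female sample; the female-specific set is the symmetric control.
`min_count = 2` guards against read errors; for assembled genome input,
where every true k-mer occurs once, the pipeline uses `min_count = 1`.
The sharing table stores exact-subset counts (which sum to the union
size — a tested invariant); the ancestry test aggregates them into
pooled (≥ 2 species), within-clade and cross-clade (≥ 1 member of each
clade) comparisons, each reported as `fold = Ymers / max(female, 1)`
with a verdict at `min_fold = 10` and a mandatory sensitivity sweep over
{2, 5, 10, 20}, because the underlying evidence is an order-of-magnitude
argument, not a sharp cutoff. When both counts are zero the comparison
returns `no_signal`, which the verdict treats as absence of cross-clade
excess. The count of k-mers shared by all species is reported without
interpretation.

## The overall verdict

The combined rule is this package's synthesis of a qualitative argument,
and is labelled as such in the report: over genes with non-ambiguous
topology calls, a majority of `ancient_Y` gives **turnover**; a majority
of `single_recent_origin` gives **parsimony** when the cross-clade Y-mer
test shows excess, and **homology** when it does not (including
`no_signal`); ties or missing stages give **inconclusive**. All
thresholds (posterior 0.8, support 70, fold 10, majorities) are
parameters and are logged in the report, and the report is reproduced
byte-identically from the same fixture and seed.

## Numerical and testing choices

* Seeds: one global integer seed; each simulator stage and each
  resampling step derives a sub-stream by a fixed affine offset below
  2^31.
* Degenerate inputs: empty genes error; sites with more than two alleles
  are skipped and counted; constant alignments are flagged degenerate
  rather than resolved silently; saturated distances error (trees) or
  flag (dS).
* Tie-breaks: argmax type by fixed order autosomal/XY/X0; representative
  family by SNP count then lowest id; lower median for even counts.
* Problem sizes: the verification suite runs 30 full scenarios (10 per
  model) at 200 genes, 4 families and ~1 Mb genomes for model recovery;
  500 genes for segregation accuracy; 100 gametolog pairs per divergence
  level on 10 kb concatenations for dS recovery; 600 contigs and 20
  chromosomes for coverage; 112 genes of 1.2 kb per scenario for
  topology classification. Unit tests use miniature configurations of
  the same generator.

## Known limitations

* The female-specific false-positive floor of real read data is not
  reproduced (no sequencing error, repeats or polymorphism), so
  absolute fold values on simulations are much larger than on real data;
  only their contrast across models is meaningful.
* The segregation model fixes the genotyping error rather than
  estimating it, and handles allele-specific expression only as an error
  event.
* dS dating assumes a clock shared across lineages and strata; the
  JC-style generator cannot probe kappa or codon-usage biases that a
  full yn00-style estimator would absorb.
* The verdict rule weighs stages through fixed majorities and one fold
  threshold; it is transparent and configurable, but it is a synthesis,
  not an inherited, validated decision procedure.
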