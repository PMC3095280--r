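---
title: "Genome sequence tags for duplicated gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome sequence tags for duplicated gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phygst)
```

# The problem

Allopolyploid genomes carry two diverged parental subgenomes in one nucleus.
For a small gene family such as the phytochrome photoreceptors of cotton
(*Gossypium*), a full inventory must separate three kinds of relatives that
all look like "copies of the same gene": **paralogs** (duplicates predating
speciation, e.g. *PHYA1* vs *PHYA2*), **orthologs** (copies separated by
speciation, e.g. the A- and D-genome diploids), and **homeologs** (ortholog
pairs reunited by allopolyploidy in the AD tetraploids). A genome sequence
tag (GST) survey does this without genome assembly: degenerate PCR across a
variable marker region (the phytochrome "hinge"), cloning and sequencing of
many clones per amplicon, assembly of clones into per-locus contigs, and
phylogenetic + molecular-evolutionary analysis of the contig consensus
sequences. `phygst` implements that entire workflow as composable R
functions, together with a simulator that generates data of known truth for
validating every stage.

# Pipeline stages and their models

## Degenerate primers

A degenerate primer is an IUPAC string, optionally containing deoxyinosine
(`I`). Its **fold-degeneracy** is the product over positions of the base-set
size of each code; inosine multiplies the pool by
`inosine_multiplicity` (default 4), the only rule consistent with the
published panel values this package validates against (16,384-fold for the
universal reverse hinge primer; 64-fold for the PHYA reverse primer). Three
rows of that published panel disagree with their printed degeneracies under
*any* uniform counting rule (printed 768 vs computed 3,072; 64 vs 256; 2 vs
4); `gst_primers()` flags them (`consistent = FALSE`) and the package keeps
the rule validated by the two unambiguous rows. At annealing, inosine is
treated as matching every base (a universal-pairing analog), so degeneracy
counting and annealing follow deliberately different conventions.

`reverse_translate()` builds primers from conserved peptides by collapsing
the codon set column-wise to minimal IUPAC codes. For the 6-codon families
(Leu/Arg/Ser) the collapse is a strict superset of the true codon set — an
unavoidable property of box-shaped IUPAC codes that the tests document.
`in_silico_pcr()` enumerates every primer-site pair within a mismatch budget
and product-size window; it reproduces the mechanism by which a conserved
primer site with six mismatches fails to amplify one subfamily while others
amplify cleanly. No melting-temperature model is attempted: the failure
analysis in the underlying study is purely mismatch-count based.

## Clone assembly by diagnostic SNPs

The core assembly rule is the study's own: an alignment column is a
**diagnostic site** when at least two distinct alleles are each carried by at
least `min_support = 2` clones; a variant seen in a single clone is presumed
a *Taq* substitution error (the error rate of native *Taq*, with ~45 cycles,
makes sporadic singletons expected) and corrected toward the consensus.
Clones are grouped by their haplotype over diagnostic sites and merged by
single linkage whenever two haplotypes differ at fewer than
`min_shared_sites = 2` sites and share no supported indel difference; the
spec of how many sites separate *contigs* is genuinely open in the source
material, and 2 was chosen symmetrically with the clone-grouping rule and
exposed as a parameter. Consensus ties become IUPAC ambiguity codes and are
flagged.

## PCR-chimera screening

PCR-mediated recombination produces clones spliced from two template loci.
The screen scores each clone against each pair of candidate parent contigs
at their informative sites (1 = matches parent 1, 2 = matches parent 2) and
computes a **maximal chi-square breakpoint scan**: the best 2×2
(left/right × parent-1/parent-2) association over all ordered breakpoints,
compared with a site-permutation null (999 permutations, seeded; the null
depends only on the site count and match composition and is cached). The
breakpoint interval reported spans the two informative sites flanking the
best split.

Simulation exposed three ways a bare scan misbehaves on realistic data, and
the screen therefore adds three model-comparison rules, each a statement
about what a *PCR* recombinant is:

1. **Parents must be supported.** A parent contig needs ≥ 2 member clones
   and more members than the clone's own cluster. Chimeric clones form
   singleton or small co-breakpoint clusters; letting those act as parents
   makes every normal clone look recombinant (two opposite-orientation
   chimeras can jointly reconstruct any parent sequence).
2. **A recombinant is an exact splice.** The two-parent mosaic at the best
   breakpoint must reproduce the clone within `max_mosaic_mismatch = 2`
   mismatches (allowing for polymerase error) *and* fit at least two
   mismatches better than any single contig. Real loci whose
   lineage-specific substitutions happen to cluster positionally can pass
   the chi-square test, but they keep a residual mismatch load the splice
   model cannot remove.
3. **Two passes.** The pipeline removes first-pass calls, reassembles, and
   re-screens every clone against the cleaned contigs, so first-pass
   contamination of the parent set cannot propagate. Clusters left with a
   single member are reported as unassigned clones, not loci — a locus
   claim, like an allele claim, needs two independent clones.

With these rules the screen detects ≥ 80% of simulated recombinants
(misses are breakpoints so near an amplicon end that the clone is within
one diagnostic site of a real locus — such clones are silently and
harmlessly absorbed into the parent contig) with no false calls observed on
chimera-free simulations; the false-positive contract (≤ 10%) is defined on
chimera-free data, where "false positive" is well-posed.

## Alignment and trees

All amplicons in this setting are high-identity (> 94%) fragments, so the
multiple aligner is a star alignment around the sequence with the maximal
summed pairwise score, merged under "once a gap, always a gap". The pairwise
core is an exact Gotoh affine-gap DP (gap of length *g* costs
`gap_open + (g-1)*gap_extend`, defaults 1/−1/−5/−1 chosen for near-identity
DNA) with deterministic tie-breaking; a banded variant with adaptive band
doubling (accepted only when the score stabilizes) keeps long amplicons
cheap. A full progressive aligner with a guide tree would add nothing at
these identities and is deliberately out of scope. Clone sets of identical
length are taken as positionally homologous without realignment — correct
whenever amplicons are indel-free, which the per-set star fallback covers
otherwise.

Distances are uncorrected *p*, Jukes–Cantor, or Kimura two-parameter
(`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`), with gaps ignored
(complete deletion by default, matching the study's stated convention;
pairwise deletion available). Saturated corrections are flagged and carry a
finite lower-bound value (log arguments clamped at 1e-8). Trees are plain
Saitou–Nei neighbor joining — the "minimum evolution objective" mentioned
alongside NJ in the study is not separately specified and is identical in
effect at these sizes — with two documented determinism rules: ties in the
Q-criterion break toward the lexicographically lowest label pair, and
negative branch lengths are clamped to zero with the deficit moved to the
sibling branch so path lengths are preserved. Bootstrap resamples alignment
columns (not codons), is seeded, and writes supports as internal node
labels. Fitch parsimony and an exhaustive search over all (2n−5)!!
topologies (n ≤ 10) back the parsimony numbers; trees are reported
unrooted throughout, and midpoint rooting is used only transiently to
assign clade labels from the diploid anchor contigs (each non-anchor leaf
takes the genome of the anchors in its smallest anchor-containing clade,
`"unresolved"` on conflict). For a subfamily with a pre-speciation
duplication, the paralog split is recognized as the internal edge with
every taxon represented on both sides.

## Ka/Ks, Fisher tests and dating

`ng_sites()`/`ng_pairwise()` implement unweighted Nei–Gojobori counting:
fractional synonymous sites per codon position (changes to stop codons
excluded from the position's denominator), multi-difference codons averaged
over all orderings of single steps with pathways through stop codons
excluded, and Jukes–Cantor correction `K = -(3/4) ln(1 - 4p/3)`. A
proportion ≥ 3/4 is reported as the bound `">2.0"` with numeric floor 2.0,
and dating refuses saturated inputs.

The Fisher exact test for selection contrasts differences with sites:
`[[round(Sd), round(S)], [round(Nd), round(N)]]` (half-up rounding), with
the one-tailed p the hypergeometric probability of a synonymous count at
least as large as observed (the directional test for purifying selection).
This differences-vs-sites table was chosen because it reproduces the
published homeolog-table p-values to their printed precision (e.g. 0.010
for the 2.1 kb D-D comparison), which the alternative
differences-vs-remaining-sites construction does not; both tails are
available. Group comparisons (D-D, D-T, T-T) average the pair-level counts
and report mean(Ka)/mean(Ks) — the quotient-of-means convention matches the
published ratios more closely than averaging ratios. Cross-node summaries
take tabulated per-node Ka/Ks ratios as given when present (bounds at their
numeric value) and recompute them from Ka and Ks otherwise; population
(n-denominator) s.d. is reported.

The synonymous clock is bare arithmetic: `r = Ks_cal / (2 T_cal)` per
lineage and `T = Ks_node / (2 r)`, with range propagation when the
calibration age has an interval. The deep-eudicot default calibration
(Ks 1.82 at 85, range 68–96, MY) gives r ≈ 0.011 substitutions per
synonymous site per MY and dates a node at Ks 0.309 to ≈ 14.4 MY.

# The simulator: what it emulates and what it does not

`evolve_family()` runs a codon-level simulation along an event schedule of
duplications, speciations and allopolyploid mergers. Selection is
**rate-calibrated thinning**: synonymous changes arrive as a Poisson count
with mean `rate_syn × t × S` (S the current Nei–Gojobori synonymous site
count) and nonsynonymous changes with mean `omega × rate_syn × t × N`;
individual changes are placed with transition weight `kappa` and proposals
creating stops are excluded. This matches the study's summary level (Ka/Ks,
not a full codon rate matrix) and gives closed-form oracles the tests use
directly: realized pairwise Ks converges to `2 t rate_syn` and realized
Ka/Ks to `omega`. Truth output records each locus's genealogy and realized
pairwise Ks/Ka.

`sample_clones()` adds the experimental layer: clones drawn per taxon with
per-locus amplification weights, chimeras formed with a uniform random
breakpoint between two distinct loci of the taxon, and *Taq* errors applied
after chimera formation (errors arise throughout cycling), independently
per site at 2e-4 substitutions/site.

`preset_cotton_like()` fixes the study conditions: two diploids (A, D) and
two allotetraploids; a PHYA-like subfamily duplicated 14 MY ago plus
single-copy PHYB/C/E-like subfamilies; A/D speciation at 3.2 MY — chosen so
homeolog synonymous divergence is ≈ 0.070, the upper end of the observed
homeolog range (the PHYE hinge D-D value) and comfortably inside the 1–7 MY
A/D-split literature; polyploid merger at 1.5 MY and tetraploid speciation
at 1.0 MY; `omega = 0.1`, `kappa = 2` (a typical plant nuclear value),
`rate_syn = 0.011`. Amplicons are 360 bp (PHYA hinge), 2,061 bp (the long
PHYB composite), 1,020 bp (PHYC) and 330 bp (PHYE); clone numbers follow
the study's sequencing depth (50 per taxon for PHYA, 20 for PHYB/PHYC, 10
per diploid and 20 per tetraploid for PHYE); chimeras occur only on the
long amplicon in the tetraploids (rate 0.2), where the study observed them.

Features of real data the simulator deliberately omits — and which passing
tests therefore say nothing about: introns and indels (the preset's long
amplicon is modeled as coding sequence; the real composite spans an intron
with small indel polymorphisms), within-population polymorphism and
heterozygosity (the study used inbred/doubled-haploid lines), rate
heterogeneity among sites and lineages, gene conversion/concerted
evolution, base-composition bias, and sequencing (as opposed to
polymerase) error. The alignment and assembly code paths for gapped input
are exercised with constructed indel fixtures instead.

# Numerical and reproducibility choices

* Every stochastic stage takes a seed; the pipeline derives per-stage seeds
  from one master seed, so a run is reproducible byte for byte from its
  provenance block (config + seed + package version).
* Coordinates are 0-based half-open internally; user-facing reports
  (diagnostic sites, breakpoint intervals) are 1-based.
* The permutation null of the chimera scan uses `(1 + #{null ≥ obs}) / (n+1)`,
  so 999 permutations floor the p-value at 0.001.
* Degenerate/ambiguous bases: `N` never wins a consensus; clones with
  > 20% `N` are excluded and logged; translation renders N-containing
  codons as `X`.
* Problem sizes in the shipped tests: oracle suites use ≤ 8-leaf trees,
  ≤ 8-nt alignments and ≤ 6-taxon exhaustive searches; recovery suites use
  100 pipeline replicates of the preset (bootstrap off) and 20 replicates
  of a 1000-codon duplication — sizes at which the closed-form expectations
  are sharp while the full suite stays fast.

# A worked run

```{r pipeline, eval = FALSE}
rep <- run_pipeline(pipeline_config(seed = 1, bootstrap = 500))
xtabs(n_contigs ~ taxon + subfamily, rep$inventory)
rep$sets$PHYA$duplication_date   # ~14 MY at the default calibration
make_report_tables(rep)$divergence
```

The inventory table recovers two PHYA plus one each of PHYB/C/E per
diploid and four PHYA plus two each per tetraploid — ten distinct genes in
an allotetraploid; the divergence table mirrors the homeolog-comparison
layout (S dif / S pos / Ks / NS dif / NS pos / Ka / Ka/Ks / P) with
saturated entries rendered as bounds.

# Known limitations

The star aligner assumes high identity; the NJ/bootstrap machinery is not
meant for large trees; exhaustive parsimony is capped at 10 taxa;
`group_comparison()` presumes clade labels that distinguish A- from
D-origin copies; the chimera screen requires ≥ 4 informative sites between
candidate parents and cannot see breakpoints outside the informative-site
span; and the published alignment statistics that depend on the archived
GST sequences (GenBank HM143735–HM143763) are only reproducible after
downloading them — `inst/scripts/integration_genbank.R` does so on demand,
while the package itself never touches the network.
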