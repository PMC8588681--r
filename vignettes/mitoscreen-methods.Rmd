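---
title: "Interrogating plant mitochondrial genomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrogating plant mitochondrial genomes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## Scope

Plant mitochondrial genomes recombine across dispersed repeats, absorb
plastid DNA (MTPTs), occasionally acquire foreign tracts horizontally, and
carry genes that are fragmented, trans-spliced and heavily C-to-U edited.
`mitoscreen` bundles the screens needed to interrogate a new mitogenome
assembly for all of these phenomena, together with a ground-truthed
simulator so that every screen can be validated end to end on data where the
answer is known.  This vignette explains the models and procedures, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## The similarity-search engine

Every screen is driven by one local aligner (`local_search()`): exact-word
seeding (default word size 11), ungapped x-drop extension (drop-off 20), and
a gapped Smith--Waterman polish restricted to a window around each extended
segment (full dynamic programming for small windows, banded around the seed
diagonal for large ones).  Scoring is the common nucleotide convention
(+2/-3, affine gaps `-5 - 2k`); identity is computed over alignment columns
with gap columns counting as non-matches.

Two deliberate choices:

* **Raw-score threshold instead of E-values.**  An E-value needs a
  database-size context that a pairwise engine does not have.  The default
  `min_score = 50` was calibrated once so that self-contained searches of
  independent random 10 kb sequence pairs return no hits, which emulates a
  stringent E-value regime; it was then frozen.
* **Optimality is audited, not assumed.**  The test suite compares top hit
  scores against a full quadratic Smith--Waterman oracle (independently
  implemented in `Biostrings::pairwiseAlignment`): the seeded heuristic must
  reach the optimum on at least 95% of planted-homology pairs and may never
  exceed it.

The hit filters mirror the conventions of similarity-screen practice:
`filter_hits()` removes hits strictly below a length/identity floor (so a
hit exactly at the threshold is kept); `near_top_filter()` groups hits by
single-linkage overlap along the assembly and removes hits of equivalent
length (within 50 bp, or shorter) whose identity is more than 2 points below
the group's best; `coverage_fraction()` reports union coverage after
excluding designated features from numerator and denominator alike.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all stochastic stages derive
their streams from one root seed, so identical configurations reproduce
byte-identical bundles.  The generator emulates:

* **A reference panel**: a ladder-shaped order-level phylogeny (default 5
  orders, 3 taxa each, plus a 2-taxon outgroup clade) along which a random
  codon-structured gene set evolves under Jukes--Cantor substitution
  (default 0.03 expected substitutions/site per backbone branch,
  within-order branches 5x shorter).  No indels are simulated inside genes,
  which keeps codon structure intact for the phylogenetic stage; internal
  stop codons arising from substitution are repaired (third base set to C)
  and the terminal stop is restored, so every panel sequence remains
  translatable.  This repair perturbs the substitution process at a fraction
  of a percent of sites, which is visible only below the tolerance of any
  test used here.
* **A recipient mitogenome**: the focal order's gene set embedded in
  intergenic scaffold DNA (roughly evenly spaced, jittered), with planted
  dispersed repeats (copies diverged by an exact substitution count to hit a
  target identity within half a point), MTPT tracts cut from a simulated own
  or foreign plastome around a plastid gene, HGT tracts copied verbatim from
  a donor order's reference mitogenome, and optional nuclear copies of
  withheld genes at a configured identity.  Per-order reference mitogenomes
  are built alongside; the focal order's reference shares scaffold ancestry
  with the recipient (2% divergence), the others are independent.
* **Long reads** (default mean 3 kb, 2% substitution error, random strand):
  reads spanning a repeat copy with at least 100 bp of flank on both sides
  become crossover products with probability `recomb_fraction`, the
  crossover point uniform within the repeat (the least-informative choice;
  nothing in the underlying biology pins it down).
* **Transcript reads**: paired 150 bp reads from mature transcripts carrying
  C-to-T substitutions at the planted edit sites.  Edit sites are planted
  "in reverse": a T at codon position 2 (where the panel is conserved) is
  changed to C in the recipient's genomic copy, so that editing restores the
  conserved residue, exactly the configuration a conservation-based
  predictor is meant to detect.  The trans-spliced gene is split into
  exon1a / exon1b / exon2 loci pinned far apart (exon2 on the opposite
  strand); mature mRNA joins exon1b+exon2 while exon1a is emitted as a
  separate product, so no read pair ever joins the two portions of exon 1.

What the simulator does **not** emulate: realistic long-read error profiles
(indel-dominated in real data), expression-level variation, intragenomic
rearrangement beyond pairwise repeat crossovers, and compositional
heterogeneity of intergenic DNA.  Passing the recovery tests therefore shows
the inference logic is correct under substitution-type noise at the
configured rates; it does not certify performance on error profiles the
simulator does not model.

## Repeats and the recombination proxy

`dispersed_repeats()` self-searches the genome (the trivial self-match and
the artifacts of the doubled circular sequence are suppressed; symmetric
duplicates are collapsed with circle-aware overlap logic), applying the
conventional 50 bp / 90% identity floor.  `repeat_content()` is the union
of all copies as a percentage of genome length.  `long_repeats()` applies
the strict `> 500 bp and > 90%` rule and reduces overlapping qualifying
pairs to a non-overlapping set by descending length.

`tandem_repeats()` keeps the conventional parameter vector
(2 7 7 80 10 50 500) but scans **all** periods up to the maximum
exhaustively in compiled code, scoring each position against the position
one period back and keeping maximal positive segments; this subsumes the
usual k-mer-spacing candidate proposal and is fast at organellar scale.
The scan is substitution-only, so the indel penalties in the parameter
vector are carried for interface parity but unused; arrays whose copies
drift by indels would be found as shorter or split arrays.

`repeat_activity()` operationalizes recombinational activity as discordant
flank phasing: a read is *spanning* if it covers the whole repeat plus at
least 100 bp on both sides; each side is assigned to copy A or B by the
higher global-alignment identity of the read flank against each copy's
genomic flank, with sides differing by less than 2 identity points left
ambiguous; up to 50 spanning reads are sampled without replacement under a
recorded seed; the activity proxy is the percentage of incongruent reads
among classified reads (ambiguous reads never enter the denominator).  The
proxy is defined for direct repeat pairs; inverted pairs are flagged and
skipped.  Validation plants a known crossover fraction and requires
recovery within 3 binomial standard deviations per run and bias under 2
points across 20 seeded runs.

## Transfer screens

`plastid_hit_screen()` searches reference plastomes against the mitogenome,
excludes hits in ribosomal RNA genes and `atp1` (ancient
plastid--mitochondrial homologies, not transfers), and merges the remainder
into regions separated by less than 100 bp (the merge gap is a package
decision; published per-region tables report merged regions without stating
a rule).  `classify_transfer()` assigns each region one of four origins in
a fixed cascade: **mitogenome** (at least 98% identical to related
reference mitogenomes over most of its length --- a parameterized
generalization of "indistinguishable from relatives"), **homology** (region
overlaps a mitochondrial gene with a known plastid counterpart),
**intracellular** (phylogenetic placement with the own-lineage plastome),
**HGT candidate** (placement with a distant lineage, or the matched plastid
gene absent/pseudogenized in the own plastome).  Unresolved placements fall
back to the lowest-commitment applicable category (homology) with an
explicit evidence code; a missing placement withholds the category.  The
cascade is one consistent formalization of what is, in published practice,
a manual judgement; disagreements with manual calls on real data are
expected and should be reviewed, not treated as errors.

`intergenic_order_screen()` searches per-order reference mitogenomes
against the assembly, applies the 250 bp / 80% filter and the near-top
display filter, masks everything covered by the focal order, and flags any
non-focal hit with at least 500 contiguous bases outside that mask as an
HGT candidate tract, reporting the donor order and the cumulative candidate
percentage.  `nuclear_copy_search()` looks for copies of missing
mitochondrial genes at a 50% identity floor, extrapolates the best locus to
the full reference span (local alignment trims mismatching ends; gene
boundaries come from the reference, as in similarity-based annotation), and
assesses ORF intactness: start codon present, no internal stops, no net
frameshift.

## Annotation, gene structure and editing

`annotate_genome()` assigns genes by similarity: per reference CDS, the
best non-redundant hit chain becomes the exon model; completeness is
`intact` (one locus covering at least 95% of the reference), `fragmented`
(several loci, or a locus crossing a contig break), or `absent`.
`call_pseudogene()` downgrades models with a net frameshift or internal
stops; the frameshift test compares the genomic span against the aligned
*reference* span, so a few trimmed alignment ends (which shorten both spans
equally) never trigger a false call, and translation is taken in the
reference reading frame.

`detect_split_gene()` aligns an intron-less reference CDS and classifies
each junction between reference-ordered pieces: same strand, same contig
and within 5 kb is a cis intron; anything farther, strand-flipped or
contig-split is trans (the 5 kb default encodes "remotely located", which
published accounts leave unquantified; strand or contig changes force trans
regardless of distance).  Pieces that abut on the reference with no
reference gap indicate a split within an exon --- unless the junction
coincides with a known intron insertion site supplied from reference
annotations, where contiguity on a CDS reference is expected.
`junction_support()` quantifies transcript evidence per piece pair: read
pairs with mates anchored (at least 30 bp at 90% identity) in different
pieces, and single reads crossing a junction.

Editing-site prediction is deliberately **not** a reimplementation of any
published predictor: `predict_edit_sites()` is a conservation-restoration
scorer that shares only the 0.5 decision threshold.  For every genomic C,
the codon is edited in silico (C to T); if the edit changes the residue,
the site's score is the fraction of non-gap homologs whose aligned residue
matches the *edited* residue.  `observe_edit_sites()` maps transcript reads
(both orientations, 90% identity floor) and calls a site observed when the
genomic base is C, coverage is at least 5 and the T fraction at least 0.5;
`merge_edit_sites()` partitions sites into predicted-only / observed-only /
both.  On simulated data, sites missed by observation are those whose
transcript-end coverage falls below the minimum --- the caller finds every
adequately covered site, and the validation suite asserts exactly that.

## Phylogenetics and the grouping test

The alignment stage is protein-guided: translations are aligned and the
alignment is back-translated so gaps come in multiples of 3.  The protein
aligner is a center-star procedure against the longest translation
(BLOSUM62 pairwise alignments merged star-wise) rather than a guide-tree
progressive profile aligner: for organellar CDS panels, which are
substitution-dominated and nearly indel-free, center-star is exact enough,
and the contract (codon-aligned output, internal-stop sequences dropped
with a warning) is unchanged.  Columns with more than 50% missing data are
masked with the old-to-new coordinate map retained.

Trees are distance trees: Kimura two-parameter distances (own compiled
site-counting, pairwise deletion, saturated pairs flagged and set to a
ceiling --- cross-checked in the tests against an independent engine) and
neighbor joining via `ape`, with taxa processed in label order for
deterministic ties and negative branches clamped to zero with the deficit
moved to the sibling.  `bootstrap_support()` resamples columns, rebuilds
the tree per replicate and records percent bipartition support.  This
deliberately replaces full maximum-likelihood inference to stay
self-contained at desk scale; `read_support_tree()` is the adapter through
which externally computed ML trees (any Newick with support labels) can be
slotted into the same grouping test for full-scale work.

`grouping_test()` encodes the vertical-vs-horizontal decision: *vertical*
when the focal taxa are monophyletic and the focal+expected-sister clade
has support strictly above 80%, or when the smallest supported clade
containing the focal taxa lies within the expected group; *HGT candidate*
when that clade instead falls inside a single different labeled group;
*unresolved* otherwise --- low support for the expected sister with no
strong alternative is evidence of nothing, and stays unresolved.  The
taxonomic granularity of "grouped elsewhere" is supplied explicitly as a
label-to-taxon-set mapping rather than guessed.

`geneconv_scan()` detects conversion as improbably long runs of identity
across polymorphic (gap-free) columns between a sequence pair.  The null
distribution comes from global column permutations shared across pairs
(10,000 by default, seeded); per-pair p-values are Bonferroni-corrected
over pairs --- the simplest defensible multiplicity control, slightly
conservative relative to a dedicated global permutation statistic.  Known
co-conversion tracts can be masked out per gene via the `mask` argument
(default empty).  Validation shows a planted 40%-of-gene transfer is
flagged (and localized within the converted region) while clock-like
panels stay below a 5% family-wise false-positive rate across seeds.

## Problem sizes and numerical conventions

The validation suite and the reproduction script run at desk scale by
design: recipient genomes of 10--25 kb with 4--8 genes, panels of 4--5
orders with up to 3 taxa each, 600--1500 long reads, 1000 bootstrap
replicates for grouping tests and 2000 permutations for the conversion
scan.  These sizes were chosen so every recovery statistic has enough
events to be meaningful (for example, 150--250 repeat-spanning reads per
activity estimate) while a full run of suite plus script completes in
minutes on one CPU.

Conventions worth knowing when extending the package: all internal
coordinates are 0-based half-open, all file formats 1-based inclusive
(`coords_to_internal()` / `coords_to_external()` are mutual inverses);
circular genomes are stored linearized and doubled only inside the
operations that need origin-spanning matches; N bases never match anything
and are excluded from GC and identity denominators; an all-N sequence
yields an explicitly flagged undefined GC rather than NaN.

## Known limitations

* The aligner is heuristic: hits whose optimal alignment contains no exact
  seed word can be missed (the oracle tests bound this at 5% on
  planted-homology pairs).
* The recombination proxy requires distinct flanks; repeats whose flanks
  are themselves repeated give ambiguous reads, shrinking the effective
  sample rather than biasing the estimate.
* The tandem scan does not model indel drift between copies.
* Distance trees can be less resolving than ML trees at deep nodes; the
  grouping test consumes externally computed trees for that reason.
* The transfer-classification cascade formalizes judgements that are made
  manually in published practice; borderline regions deserve inspection.
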