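---
title: "anchorage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{anchorage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`anchorage` re-implements, as tested reusable components, the bespoke
computations that turn a fragmented draft plant genome into
chromosome-scale pseudomolecules and breeder-ready DNA markers: k-mer
genome-size estimation, two-stage scaffold anchoring (genetic map plus
synteny with a related reference genome), variant hard-filtering and
effect classification, and CAPS/indel/SSR/primer marker design.  Every
stage can be exercised on seeded synthetic data with a full truth table,
so the whole pipeline is testable offline.

This vignette records the models, the tunable parameters, the numerical
choices, and what the synthetic world does and does not establish.

## 1. Genome-size estimation from k-mer histograms

Reads are decomposed into canonical k-mers (the lexicographic minimum of
each window and its reverse complement; k = 17 by default, the classical
genome-survey choice).  The histogram of k-mer multiplicities from a
whole-genome read set shows an error spike at depth 1--2, optionally a
heterozygous peak near half coverage, and the homozygous peak at the
k-mer coverage \(c_k = c \cdot (L-k+1)/L\) for read length \(L\) and
base coverage \(c\).  Genome size is the total k-mer mass above the
error cutoff divided by the homozygous peak depth:

\[ \hat G = \frac{\sum_{d \ge d_0} d \cdot n(d)}{c_k}. \]

Numerical choices, all visible in `detect_peaks()`:

* smoothing: window-3 moving average before extremum detection;
* error cutoff \(d_0\): the first local minimum of smoothed counts as
  depth increases; if counts rise from the smallest depth there is no
  error component and the cutoff is that depth;
* peak candidates below 10% of the tallest peak are ignored
  (`min_peak_frac`); this keeps the two-copy-repeat shoulder at twice
  the coverage depth from being mistaken for the homozygous peak;
* the heterozygous peak is only called if its depth falls within
  0.4--0.6 of the homozygous depth (`het_band`), matching the roughly
  half-coverage position such a peak must occupy;
* the divisor \(c_k\) is a *half-height centroid* refinement of the
  integer modal depth: the count-weighted mean depth over the contiguous
  region where counts exceed half the peak count.  With 93-bp reads at
  30x, \(c_k = 24.8\); the integer mode (24) would bias \(\hat G\)
  upward by 3.3%, while the centroid estimator recovers a 1 Mb synthetic
  genome within 2%.  `estimate_genome_size(use_refined = FALSE)` gives
  the plain modal-depth estimator.

Counting is in-memory (Rcpp, 2-bit rolling encoding), sized for
desk-scale synthetic inputs, not for tens of gigabases of real reads.

## 2. Two-stage anchoring

### Map stage

Each scaffold is assigned to the linkage group holding a *strict
majority* of its mapped loci; ties leave it unassigned and logged.  The
ordering key is the median cM of its loci.  Orientation is the sign of
the least-squares slope of cM on scaffold bp, called when at least
`min_markers_to_orient = 2` loci with distinct cM and bp are available.
The source procedure's wording ("more than two marker loci") is
ambiguous between \(\ge 2\) and \(> 2\); two distinct loci already
define an order, so 2 is the default and the stricter reading is one
parameter away.

### Synteny stage

Protein-level best hits against the reference genome (E-value ceiling
1e-5; ties broken by bitscore, reference start, then gene id) are walked
along each scaffold in gene order.  A *collinear run* is a maximal block
of consecutive hit-bearing genes whose hits share one reference
chromosome.  Genes with no hit are transparent -- they do not break a
run -- because annotation density differs between genomes and a literal
reading of "continuous" would make the rule unimplementable; a
contradicting best hit does break the run.  Runs of at least
`min_genes = 5` genes are fitted by ordinary least squares of reference
midpoint on scaffold midpoint; a run is accepted iff \(R^2 > 0.6\)
(strict, matching the printed symbol), with orientation from the slope
sign and ordering key the median reference midpoint.  Regression is on
bp midpoints rather than gene ranks: bp is scale-aware and pins the same
orientation.

### Merge and layout

Map evidence outranks synteny (the procedure is stated as "first the
map, next similarity"): on a chromosome conflict the map wins and the
scaffold is flagged, never silently reassigned.  A scaffold with both
evidences on the same chromosome keeps the map's chromosome and
orientation but inherits the synteny bp key, putting it on the same
ordering scale as synteny-only scaffolds.

Scaffolds with only a cM key are projected to bp by linear interpolation
between dual-keyed anchor scaffolds bracketing them in cM, with linear
extrapolation at the ends clamped to the chromosome length.  A
chromosome with fewer than two anchors falls back to a *global* cM-to-bp
line fitted across all chromosomes' anchors (assuming roughly uniform
recombination density), and only as a last resort to scaling cM by
chromosome length.  The local-anchor rule alone mis-ordered chromosomes
that happened to have no map+synteny scaffold; the global fallback
restores exact ordering on noise-free synthetic data.

Pseudomolecules concatenate oriented scaffolds with exactly
`spacer_len = 10000` Ns, no leading or trailing spacer.  The AGP v2.1
uses `W` component rows and `U` gap rows (`gap_type contig`,
`linkage no`).  Unknown orientations are emitted as `+` and flagged in
the layout rather than dropped.

## 3. Variant filtering, summaries, effects

Two hard-filter presets mirror the reduced-representation and
resequencing criteria: `filter_params_ddrad()` (per-sample DP >= 5, site
quality strictly > 10, minor-allele frequency >= 0.2, missing rate
strictly < 0.5) and `filter_params_reseq()` (site quality >= 50, GQ >=
20, DP in [10, 100]).  The strict `>` on the ddRAD quality follows its
">10" phrasing; the resequencing bounds use `>=`, standard VCFtools
semantics.  Rejections are tallied against the first failing criterion
in the fixed order quality, depth, GQ, missing, MAF, so the counts are
reproducible.

Multi-allelic records are split before all downstream steps; genotype
codes for non-extracted alternates become missing.  The substitution
spectrum reports the six direction-collapsed classes (A/G and C/T
transitions; A/C, A/T, C/G, G/T transversions).  The source text's
"G/C to A/T transversions" conflicts with standard nomenclature
(G-to-A is a transition); the spectrum takes no side and reports neutral
classes.  Variant density divides by the assembly's **non-N** length;
this convention is pinned by the published indel density (65.8 per
100 kb), which reproduces with the non-N denominator and with no other.

The effect classifier applies feature precedence CDS > intron >
non-coding exon > intergenic.  Coding SNPs are resolved by strand-aware
codon translation (start-codon disruption, stop gain/loss, synonymous,
missense); coding indels are frameshift unless the length difference is
a multiple of three.  Impact follows the standard four-category mapping
(HIGH: stop/start/frameshift; MODERATE: missense and in-frame indels;
LOW: synonymous; MODIFIER: intron, intergenic and non-coding exon --
UTR classes are not distinguished, a simplification of full annotators).
Splice-site classes are omitted; a variant straddling an exon boundary
classifies by the CDS-first precedence.  The classifier is checked
against an oracle that rebuilds and translates the entire mutant CDS.

## 4. Marker design

**CAPS.**  For each of the 19 shipped enzymes (4--6 bp recognition
sites; palindromicity is asserted at load, which licenses
forward-strand-only counting) a window of length \(2(|site|-1)+1\)
centred on the SNP is digested in silico under both alleles; the enzyme
qualifies iff the allelic site counts differ.  IUPAC codes in sites are
expanded even though the shipped 19 need none.

**SSRs.**  Seeds are three consecutive perfect copies of a primitive
2--6 bp unit (mononucleotide runs excluded).  Seeds are extended in both
directions under +1 per matching base and -5 per interrupting base
(`mismatch_penalty`), and trimmed to the maximum-score extent; an
interrupting base leaves the repeat phase free, so a 1-bp interruption
does not desynchronise the downstream repeat.  Loci scoring >= 15 are
reported; overlapping reports resolve by highest score, then shortest
unit.  The scoring constants follow the documented defaults of the
mismatched-penalty school of SSR finders; the exact parameterisation
used in the source study is unstated, so genome-wide SSR counts are not
an acceptance surface.  An X-drop rule (`x_drop`, default
`4*penalty+4`) bounds how far a hopeless extension is explored; set it
to `Inf` for the exact dynamic-programming behaviour (the oracle tests
do).  Motifs are canonicalised as the lexicographic minimum over all
rotations of the unit and of its reverse complement.

**Primers.**  A deterministic, oracle-checkable simplification of a
full primer designer: exhaustive scan of 18--25-mers in the flanks; Tm
by unified nearest-neighbor thermodynamics (50 mM Na+, 50 nM oligo,
16.6 log10[Na+] salt correction) constrained to 55--62 C; GC 30--70%;
no homopolymer over 4; the 3'-terminal 5-mer must not be
self-complementary (outer bases antiparallel-paired, middle ignored --
an odd-length word cannot be a strict palindrome); product 80--300 bp
containing the target; pair dTm <= 3 C.  Among feasible pairs the
smallest |dTm| wins, then shortest product, then leftmost.  It is not a
clone of any published designer and makes no claim of equivalence.

## 5. The synthetic world

`generate_genome()` draws i.i.d. bases at a target GC of 0.38 (a typical
compact rosaceous genome) and writes real ATG...stop open reading frames
into 1--3-exon gene models at 400 genes/Mb, so the effect classifier and
the synteny stage operate on genuine coding sequence.
`fragment_scaffolds()` cuts chromosomes at breakpoints sampled outside
gene spans (gene models stay intact -- a deliberate simplification),
reverse-complements each scaffold with probability 0.5 and shuffles the
order.  `simulate_map()` places markers uniformly at 4 cM/Mb;
`simulate_hits()` hits each gene's true ortholog at E-value 1e-50 and
adds spurious hits at weaker scores, so spurious hits only surface as
best hits where true hits are missing (the >= 90%-recovery acceptance
test therefore combines 10% spurious with 10% missing hits to be
non-vacuous).  `simulate_variants()` draws substitutions at a target
Ts/Tv of 1.5 and indel lengths uniform on 1--15;
`simulate_reads()` draws uniform read starts on both strands with
optional per-base substitution errors.

What a green test establishes: the pipeline's algebra is correct --
placements, orientations, coordinates, scores and counts equal their
independently computed values.  What it does not establish: behaviour on
repeat-rich sequence (the base model has no repeat families), collapsed
assemblies, real error profiles, or map error from segregation
distortion.  The eliminated repeat fraction of real drafts is explicitly
out of the model: anchoring, not assembly, is the target.

## 6. Seeds and determinism

Every generator takes a mandatory seed and restores the caller's RNG
state, so runs are pure functions of (parameters, seed).  All tie-breaks
in the pipeline (best hits, layout ordering, primer ranking) are total
orders, so outputs are byte-reproducible; each CLI run writes a manifest
(parameters, input digests, package version) sufficient to reproduce its
outputs.

## 7. Known limitations

* In-memory k-mer counting only; no GC-bias or repeat-aware size model.
* One transcript per gene; no UTR-specific or splice-site effect terms.
* The genetic map is consumed, never computed; linkage-map construction
  and imputation are out of scope.
* Genome-wide marker counts from the source study are not reproducible
  at desk scale (they require the unreleased assembly and variant set)
  and are deliberately not asserted anywhere.
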