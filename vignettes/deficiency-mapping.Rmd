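---
title: "Deficiency mapping and sequence analysis of a supernumerary B chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deficiency mapping and sequence analysis of a supernumerary B chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bchrom)
library(dplyr)
```

## The problem

Supernumerary (B) chromosomes are dispensable chromosomes maintained in
populations by drive mechanisms rather than by necessity. Because they carry
no genetic landmarks usable for ordinary map-based assembly, a B-chromosome
pseudomolecule has to be built by *deficiency mapping*: lines carrying only a
portion of the chromosome (translocation, centromere-misdivision and breakage
derivatives) are sequenced at low coverage, the presence or absence of every
assembly scaffold is called per line, and the scaffolds are ordered by the
breakpoints those calls imply. `bchrom` implements that inference as a
reusable, testable pipeline, together with the companion analyses such a
project needs: k-mer classification of B-specific scaffolds against the
standard (A) complement, a read-depth dosage test, LTR retrotransposon
insertion-age dating, Ka/Ks selection analysis of genes transposed onto the
B, and nucleosome-midpoint profiling on centromeric tandem repeats.

Everything is exercised end to end on synthetic genomes generated by the
package itself, with ground truth retained, so no external download is ever
required and every claim the test suite makes is checkable against truth.

## The synthetic genome

`make_genome()` builds a small A complement plus one acrocentric B chromosome
following a segment blueprint (`default_blueprint()`): short arm (BS),
centromere (BC), proximal heterochromatin (PH) and euchromatin (PE), four
distal heterochromatin blocks (DH1-4) and distal euchromatin (DE), in that
fixed order. The construction mirrors the features that make the real
inference hard:

* a **B-specific tandem repeat** concentrated in and around the centromere,
  derived from the knob monomer at 50-80% identity, so the two are related
  but separable;
* a **180-bp knob repeat** present on both complements (shared repeats are
  exactly what host-read subtraction and repeat masking must cope with);
* a centromeric satellite and LTR retrotransposons drawn from shared
  templates, with insertion ages drawn from an exponential distribution
  (median 0.46 My by default, at a configurable clock rate of
  1.3e-8 substitutions/site/year) on both complements, so A and B copies of
  a family share an age distribution unless a divergent-age control is
  requested;
* TE occupancy tuned so TE features cover 60% of the B;
* **transposed genes**: each B gene is a mutated copy of a randomly chosen A
  gene, evolved with an elevated nonsynonymous acceptance (default 2x) so
  that relaxed purifying selection is recoverable by construction.

Coordinates are 0-based half-open throughout, and truth tables serialise to
BED. Read simulation (`simulate_reads()`) is substitution-only -- the
pipeline's matchers are exact or Hamming-verified by design, and indels would
add nothing the tests could detect -- with optional artificial 3' poly-G/N
tails to exercise trimming. Reads default to the low-pass design the method
is built around: single-end 75 bp at 6x per-copy depth.

What the simulator does *not* emulate: real maize k-mer spectra, indel and
quality-value error structure, GC bias, organellar insertions, or
chromosome-scale haplotype variation. Passing tests therefore demonstrate
the correctness of the inference machinery under the stated error model, not
robustness to every artefact of real sequencing data.

The A complement defaults to two chromosomes of 100-150 kb in the test
configurations -- a desk-scale stand-in that is deliberately rich (genes,
knob arrays, shared TEs at matching ages) so host subtraction, repeat
masking and the dosage test all face realistic confusion, while staying far
from the 2.1-Gb real complement that the package explicitly does not attempt
to model.

## Scaffold classification by k-mer profiling

`build_kmer_index()` counts canonical k-mers (lexicographic minimum of a
window and its reverse complement, so reads are unstranded); the default
`k = 49` follows the established tallymer-style profiling workflow.
`profile_scaffold()` reports, per position, the A-index occurrence count and
coverage by a B-enriched read index; positions with `a_count >=
repeat_threshold` (default 4) form the repetitive mask. `classify_scaffolds()`
then labels a scaffold `A` when at least half its nonrepetitive positions hit
the A index, else `B` when at least 80% are covered by B reads, else
`ambiguous`; scaffolds under 10 kb are excluded, and scaffolds with no
nonrepetitive positions are routed to a `repeat_only` report -- the analog of
satellite-only short-arm scaffolds that k-mer evidence cannot place. The
0.5/0.8/4 thresholds are declared defaults (no published values exist for
them) and are all exposed as arguments.

## The deficiency-mapping pipeline

`run_deficiency_pipeline()` chains the steps; each is also callable alone.

1. **Trimming** (`preprocess_reads()`): the maximal 3' run of Ns and/or
   artificial poly-G (>= 3 bp) is removed; reads shorter than 30 bp drop.
2. **Host subtraction** (`subtract_host_reads()`): a read is removed iff it
   has *exactly one* placement on the A complement with at most 2
   substitutions. The matcher anchors three disjoint exact seeds per read on
   a subject-side seed index and verifies candidates by Hamming comparison
   (pigeonhole: two mismatches cannot break all three seeds), so the rule is
   applied exactly, both strands, substitution-only.
3. **Unique placement** (`map_unique_reads()`): a read is kept iff it has
   exactly one zero-mismatch placement across all scaffolds.
4. **Repeat mask** (`repeat_mask()`): a scaffold position is masked when its
   49-mer either recurs within the scaffold set (self count >= 2) or occurs
   in the A complement at all (a_count >= 1). The second rule is what the
   host index is for: any host-shared position is exactly where retained
   multi-copy host reads, or reads whose sequencing errors turn them into a
   perfect copy of a paralogous locus, can cross-map. Placements whose span
   is more than half masked are dropped (`filter_masked_placements()`), and
   windows at least half masked are flagged out of the presence denominator.
5. **Window counts** (`coverage_windows()`): placements are counted in 1-kb
   windows by their start; a trailing window too short to host a read start
   is structurally uninformative and flagged.
6. **Presence calls** (`call_presence()`): the covered fraction over
   informative windows drives calls of present (>= 0.9), absent (<= 0.1) or
   partial. The pipeline sets the covered-depth threshold to 10% of the
   expected per-window read count (8 at the 6x/75-bp/1-kb defaults): genuine
   coverage sits far above it even after sequencing errors cost about half
   of the exactly-mappable reads (0.99^75 ~ 0.47), while residual
   cross-mapped noise arrives in clusters of a few reads at most. Windows
   caught in between (more than zero but below threshold) abstain from the
   denominator rather than voting either way.
7. **Ordering** (`order_scaffolds()`): terminal-deletion lines form a
   containment chain, verified *from the calls* (never from hidden truth);
   scaffolds group into bins by presence signature, bins order by the
   consecutive-ones condition, partial (breakpoint-spanning) scaffolds
   anchor bin boundaries, and any signature inconsistent with a chain order
   is surfaced as a conflict (the operation fails unless forced). Within-bin
   order is genuinely unresolved and flagged; descending length is used for
   determinism. Mini-chromosome lines carry interstitial information only,
   so they confirm centromere-proximal bins (`mini_support`) but never order
   distal ones.
8. **Orientation and AGP** (`orient_and_build()`): a spanning scaffold is
   oriented so its covered half (in the line defining the breakpoint) faces
   the retained, centromere-proximal side; halves within a 10% relative
   margin stay `unknown`. Scaffolds are joined with 100-N gaps (a declared
   default; none is published) into a pseudomolecule that begins at the
   centromere-proximal bin, serialised as AGP 2.1 with `map` gap evidence.
9. **Verification** (`verify_profile()`): the pseudomolecule is re-profiled
   with the same reads; each line must show a single contiguous covered
   block (a prefix for terminal lines). A shuffled layout fails.

The present/absent thresholds (0.9/0.1) have no published values -- the
original calls were read off coverage plots -- so they are declared defaults
with the whole sweep exposed through function arguments.

## Dosage (copy-number) testing

`dosage_profile()` counts uniquely placed reads in A-gene regions per
library, normalises by library size, forms per-region ratios against a
haploid control and re-centres them by a copy-neutral baseline before taking
per-segment medians. The re-centring matters: an extra (or missing) segment
copy inflates (deflates) the test library's total, which would otherwise
bias *every* ratio. The baseline is the median of per-segment median ratios
-- not the plain median over regions -- so that a CNV segment cannot drag
the baseline however many gene regions it happens to contain; this assumes
most *segments* are copy-neutral, which is the usual CNV-analysis premise.
Copy-neutral regions then sit at 1, a disomic segment reads ~2.0 and a
monosomic one ~0.5. Segments are called gain at >= 1.5 and loss at <= 0.66
(configurable).

## LTR insertion ages and Ka/Ks

An LTR element's two long terminal repeats are identical at insertion, so
their divergence dates it: `estimate_insertion_age()` aligns the 5' and 3'
LTRs globally, takes the p-distance over ungapped columns, corrects it
(JC69 by default; K2P available -- the literature rarely states which
correction underlies published LTR ages, so both are offered) and reports
`T = d / (2r)`. The default clock `r = 1.3e-8` substitutions/site/year is a
standard plant LTR rate supplied as a parameter, not derived from any one
dataset. JC69 saturates at p >= 0.74; such pairs are flagged, not silently
corrected. `cluster_ltr_families()` builds families by single-linkage on 5'
LTR identity (80% threshold, >= 10 members for summaries; both declared
defaults) and `summarize_ages()` compares A- and B-class member ages per
family under a 99th-percentile display cut.

`align_codon_pair()` produces protein-guided codon alignments (translate,
BLOSUM62 global alignment, back-thread nucleotides; all gaps are codon
multiples; trailing stops trimmed, internal stops are errors).
`compute_kaks()` implements NG86 counting: per-codon synonymous site
fractions averaged over the two sequences, substitutions averaged over all
shortest mutational paths with stop-traversing paths excluded when
avoidable, and Jukes-Cantor correction of the proportions. Two numerical
conventions are fixed explicitly because NG86 implementations differ:
mutations *to* stop codons count as nonsynonymous (so `N + S = 3 x codons`
exactly), and blocked paths are only used when every path is blocked. The
ratio is undefined when Ks = 0. `selection_comparison()` runs the three-way
contrast -- B vs A, B vs outgroup, A vs outgroup -- and tests for a global
Ka/Ks elevation in the B-involving comparison with a one-sided Wilcoxon
signed-rank test on the paired ratios, the signature of relaxed purifying
selection on a dispensable chromosome.

## Nucleosome midpoints on tandem repeats

`merge_read_pairs()` merges mates at the largest 3' overlap of at least
10 bp, allowing one mismatch per 10 bp of overlap. `midpoint_profile()`
places each merged read at its best location on a concatenated trimer of the
monomer consensus and folds the placement midpoint `floor((start + end)/2)`
onto the monomer modulo its length -- for tandem copies that offset is
invariant to which copy an ambiguous read is assigned to, which is exactly
why the trimer target works. `call_peaks()` smooths the ChIP/input ratio
with a circular 5-bp moving average, keeps local maxima with prominence at
least 10% of the maximum, and labels peaks major/minor by a two-means split
of their heights. The smoothing and prominence values are declared choices;
no published criteria exist for the corresponding peak sets.
`identity_stats()` supplies the per-group identity summaries and pairwise
two-sided Welch t tests used to compare repeat populations, with a guard for
zero-variance groups.

## Numerical choices and degenerate inputs

* Ties in the two-means peak split and equal-height peaks collapse to
  `major`; an all-zero input track receives a pseudocount of 1 with a
  warning.
* `scan_monomers()` accepts hits within `[0.5, 1.5]` monomer lengths at
  >= 70% identity (matches / alignment columns, stated explicitly because
  identity denominators vary between tools).
* Scaffolds with no informative windows are `uninformative` and reported,
  never silently dropped; repeat-only scaffolds stay unordered, like the
  satellite-only short-arm scaffolds they emulate.
* The orientation test refuses to guess within its tie margin; unknowns are
  emitted as `+` in AGP with orientation `?`.
* `fragment_scaffolds()` defaults to a gap-free partition so reconstruction
  is exact; recorded gap sequences make nonzero-gap round-trips exact too.

## Problem sizes used by the test suite

The acceptance checks run the full inference on a 2-Mb B chromosome in 20
scaffolds with 8 terminal + 2 mini lines at 6x, five seeds, error-free and
at 1% substitution error; presence-call accuracy uses 200 simulated
breakpoint-overlap cases on a 100-kb genome; LTR-age, Ka/Ks and midpoint
checks use 100-200 instances each. The dosage test sequences its three
libraries at 20x over ~24 gene regions per chromosome (8 per segment):
reading a two-fold ratio to within +-10% from a segment median needs
per-region counting error well under that, which low-pass 6x depth over a
handful of regions cannot deliver -- depth and cohort size here are the
power analysis of that comparison, while the deficiency-mapping reads stay
at their low-pass 6x design. For the same reason the LTR-age cohorts use
3-kb LTRs (realistic for gypsy elements): at the default 0.46-My median the
5'/3' divergence is only ~1.2%, and a shorter LTR simply cannot resolve a
cohort median to within 10%. These sizes were chosen as the
smallest at which the inference is genuinely nontrivial (hundreds of
thousands of reads per line, satellite arrays large enough to defeat naive
mapping) while a complete run stays comfortable on a laptop.

## Known limitations

* Substitution-only: indel sequencing errors or structurally variant lines
  are out of scope by design.
* Ordering requires a terminal-deletion chain; a panel of purely
  interstitial deletions cannot be ordered by this formulation and will be
  reported as conflicts.
* Scaffolds are oriented but never split: a chimeric scaffold spanning a
  misassembly will surface as a conflict rather than being repaired.
* The k-mer classifier decides from containment only; it cannot separate a
  true B scaffold from an A-complement segment absent from the provided A
  reference.
* NG86 is a counting method: it is directionally faithful for the
  relaxed-selection contrast but is not a maximum-likelihood estimate, and
  saturated pairs are reported, not rescued.
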