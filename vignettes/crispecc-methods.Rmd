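---
title: "Quantifying multiplexed CRISPR editing outcomes and small eccDNA junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multiplexed CRISPR editing outcomes and small eccDNA junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispecc)
library(tibble)
```

## The problem

Multiplexed CRISPR/Cas9 mutagenesis — for example, simultaneously targeting
a panel of tumor suppressor genes in mouse liver to induce tumors — leaves a
characteristic footprint at each sgRNA target site: a mixture of unedited
(wild-type) alleles and small insertion/deletion alleles anchored at the Cas9
double-strand break. Targeted amplicon deep sequencing of those sites gives,
per sample and per target, a spectrum of editing outcomes whose types and
frequencies carry the biology: how heterogeneous the editing is between tumor
nodules and clones, how allele frequencies oscillate as single-cell clones
proliferate, and whether extrachromosomal circular DNA (eccDNA) carrying
target-site fragments exists alongside the chromosomal copies.

`crispecc` implements this quantification as a reusable, tested pipeline:

1. a **target-site model** (protospacer, PAM, strand, derived cut coordinate);
2. an **amplicon read classifier** producing cut-anchored allele labels;
3. **allele tables** with frequencies, a true-mutation threshold, and
   library-normalized read ratios;
4. **lineage comparison** (parent vs. subclones, time courses, grafts) with
   discrete allele gain/loss events;
5. a **split-read eccDNA junction caller** with microhomology-aware
   canonical coordinates, genic annotation, size statistics, and
   junction-to-cut distances;
6. a **synthetic-data generator** that produces all of the above inputs with
   known ground truth.

## Coordinate and cut conventions

All internal coordinates are 0-based and half-open; BED exports keep that
convention, and human-readable outputs (SAM positions) are 1-based. SpCas9 is
modeled as cutting bluntly 3 bp 5' of the PAM, i.e. between protospacer bases
17 and 18 (1-based, protospacer strand). For a plus-strand protospacer
starting at genomic offset $p$ the cut coordinate is $p + 17$; for a
minus-strand protospacer occupying plus-strand bases $[p, p+20)$ it maps back
to $p + 3$. The inter-base cut coordinate is the anchor for everything
downstream.

For minus-strand targets every allele label is reported in
**protospacer-strand orientation**, so "left of the break" always means 5' on
the protospacer strand. This is a convention choice — the orientation of
published "a|b" labels for minus-strand guides is not standardized — and it
makes labels comparable across strands. Implementation-wise the amplicon
around the cut is extracted symmetrically and reverse-complemented for
minus-strand sites, after which plus- and minus-strand sites share one code
path (a property the test suite checks directly).

## Allele notation

An editing outcome is written:

* `WT` — no indel in the classification window;
* `Del a|b` — a deletion removing $a$ bases 5' and $b$ bases 3' of the cut;
* `Ins n SEQ` — an $n$-bp insertion at the break;
* `Del a|b Ins n SEQ` — a combined deletion plus insertion.

`format_allele_label()` and `parse_allele_label()` are exact inverses over
this grammar, and the grammar is strict: malformed variants (for instance an
insertion length that contradicts its sequence) are rejected rather than
guessed.

## Alignment and classification

Reads are aligned to their target amplicon with an affine-gap dynamic
program (compiled, in `src/`): the read aligns end-to-end, the amplicon
locally, under match $+2$, mismatch $-4$, gap open $-10$, gap extension $-1$
per base (a gap of length $L$ costs $10 + L$). The defaults are ordinary
DNA-resequencing scores; all four are configurable. A read whose optimal
score falls below $0.4 \times 2 \times \mathrm{length}$ is discarded as
`poor_alignment` — random 150-mers score far below this floor while reads
with several indels and sequencing errors stay well above it. Reads are
orientation-normalized: a read failing the floor is retried as its reverse
complement.

Classification looks only at a window of $\pm 25$ bp (configurable) around
the cut, wide enough to cover the longest deletion the package is designed to
label (a 27-bp `Del22|5` class) with margin. Within the window:

* **Placement ambiguity.** An indel inside a repeat has several
  score-equivalent placements. The classifier enumerates the equivalence
  class and picks the placement whose footprint is nearest the cut; residual
  ties assign bases to the 5' side. This makes the `a|b` label a
  deterministic function of the read, independent of aligner tie-breaking —
  the acceptance suite checks it against a brute-force enumeration oracle
  over all deletions with $a+b \le 10$ and insertions up to 6 bp.
* **Substitution-only reads count as `WT`** for all frequency computations;
  the substitution count is retained per read for QC. Sequencing
  substitutions would otherwise inflate mutation frequencies; indel classes
  are what the notation quantifies.
* **Combined deletion-insertion outcomes.** Under affine-gap scoring, a
  deletion of $d$ bases with $n \le 4$ inserted bases at the break aligns
  more cheaply as a deletion of $d-n$ with the inserted bases mismatched
  against adjacent reference bases (the representations differ by
  $10 - 2n$ in score), so the combined outcome never surfaces as literal
  del+ins alignment operations. The classifier therefore reinterprets that
  signature — a single deletion whose window substitutions cluster around
  the gap (at most 4 intervening matching bases) — as `Del a|b Ins n SEQ`,
  re-deriving the components by trimming the common ends of the reference
  and read segments over the spanned interval. Because a deletion read with
  a single adjacent sequencing error is indistinguishable at the read level
  from a genuine 1-bp-insert outcome, the reinterpretation requires at
  least 2 inserted bases by default (`min_promote_ins`); Sanger-clone
  classification, which sees effectively error-free consensus sequences,
  uses 1 and so also recovers 1-bp combined outcomes at junctions. When
  the inserted bases resemble the deleted sequence the alignment can
  fragment into several gaps instead, and the read is conservatively
  discarded as `complex`.
* **Multiple indels** (more than one disjoint deletion or more than one
  insertion in the window) discard the read as `complex` rather than
  receiving a guessed composite label. One deletion plus one insertion is the
  legitimate `DELINS` class.
* Reads whose aligned span does not cover the full window are discarded as
  `incomplete_window`.

Discarded reads are excluded from both numerator and denominator of every
frequency.

The `frameshift_phenotype()` helper implements the arithmetic of a
frame-shift reporter: an indel re-frames the downstream marker exactly when
its net length change is congruent to $1 \pmod 3$ ("3n+1" shifts).

## Allele tables and thresholds

Per sample and target, retained reads aggregate into an allele table with
frequencies in percent. The **gene-level mutation frequency** is the edited
read count over the retained read count, identically $100 - f_{WT}$. A
non-WT allele with frequency **at or above 5%** (inclusive; configurable
`tau`) is a **true mutation** — the noise filter that keeps
sequencing-error alleles (which sit orders of magnitude below 5% at
realistic error rates) out of downstream comparisons. The threshold applies
per sample per site, never across pooled samples.

Sites with fewer than 100 retained reads (configurable) become **no-call**
records rather than 0% rows: a poorly amplified site carries no frequency
information, and in the eccDNA context trace reads indicate absence of
circles harboring the site rather than a measured zero.

For eccDNA/gDNA comparisons, per-gene read counts are normalized to
percentages of each library's combined target reads; the **relative read
ratio** is the eccDNA percentage divided by the gDNA percentage. Sites with
reads below **0.1%** of a library's total (strict) are flagged invalid, and
the ratio is undefined where the gDNA side is invalid or zero (an eccDNA-side
zero yields a ratio of 0, which is informative). The ratio is invariant to
rescaling either library's counts, so sequencing depth differences cancel.

## Lineage profiles and oscillation events

Allele tables across related samples combine into a long frequency matrix
(union of labels per gene, zeros filled). Presence of an allele in a sample
reuses the 5% threshold. Between a parent and a child sample, a **loss**
event is parent $\ge \tau$, child $< \tau$; a **gain** event the reverse; WT
participates like any allele (loss of WT is how a fully edited site
manifests). Time courses chain consecutive samples as parent-child steps. An
optional hysteresis band suppresses events within a configurable margin of
the threshold; the default is 0 because a single threshold is what the
quantification defines.

**Allelic richness** — the number of alleles at or above threshold in one
sample at one site, WT included — flags richness above 2, which in a
single-cell clone indicates more allele types than one diploid locus can
carry (a copy-number signal). Heatmap rendering uses the square root of the
0-1 frequency, which spreads low frequencies visually; `sqrt_transform()`
validates its domain rather than silently clamping.

No statistical test is attached to events: they are descriptive threshold
crossings, and the generator-based tests check exact recovery rather than
power.

## The eccDNA junction caller

Circle-enrichment sequencing (exonuclease removal of linear DNA, rolling
circle amplification) yields reads from tandem concatemers of each circle, so
a fraction of reads span the **circularization junction**: their 5' part maps
at higher reference coordinates (suffix of the circle interval) and their 3'
part continues at lower coordinates (prefix). The caller:

1. seeds each read by an exact match of its first 20 bp (`min_seg`,
   configurable) against a k-mer index of the reference, requiring a unique
   hit;
2. extends the match maximally, and places the remainder (also at least
   `min_seg` bp) by exact match;
3. emits a candidate junction when the remainder maps strictly upstream on
   the same chromosome — the suffix-to-prefix signature of a simple circle;
4. canonicalizes each candidate under **microhomology**: when the sequences
   just inside the two junction boundaries share a k-mer, the coordinate pair
   can shift by up to k; the canonical placement is the leftmost, and the
   microhomology length and sequence are reported (capped at 20 bp for
   degenerate repeats, with a warning);
5. clusters candidates exactly by canonical coordinate pair and emits
   circles with at least `min_support = 2` junction reads.

Exact-match seeding is a deliberate desk-scale design: on the few-kb to
~100-kb synthetic references this package targets, unique exact seeds are the
norm, mapping is deterministic, and a read with a sequencing error in a seed
or remainder is simply not counted as junction support (support comes from
the error-free majority). Only same-chromosome, same-strand suffix-to-prefix
junctions are called; translocation-joined or inverted circles are out of
scope. Reads are tried in both orientations, and junction reads whose
junction sits within `min_seg` of either read end are undetectable by
construction — the generator's per-circle read depth is what makes recovery
reliable despite this geometric loss.

Detected circles are annotated by the genic feature at their **midpoint**
under the priority promoter > 5'UTR > exon > 3'UTR > intron, defaulting to
"distal intergenic" (an any-overlap mode is available). Size summaries
report the lower-middle median for even counts — a documented choice that
keeps the statistic an observed circle size. Junction-to-cut distances are
measured to the junction edges (proximal = nearer coordinate, distal =
farther); when the cut lies inside the circle the two distances sum to the
circle size, and log10 distances are reported only for distances of at
least 1 bp.

Target alleles harbored by a circle are classified by pooling reads anchored
to the site's flanking sequence and running the amplicon classifier against
the wild-type locus; the consensus (most frequent retained) label is
reported, or `"uncalled"` without classifiable coverage. Pooling is by locus,
not by circle: two overlapping circles carrying different alleles at the same
site would blend, which is the same limitation a PCR amplicon of the locus
has. Sanger-style junction clones — sequences spanning both the junction and
the target — are classified against a rotation of the circle sequence, giving
a (target label, junction label) pair under the same grammar.

## The synthetic-data generator

The generator stands in for the study data at desk scale and defines the
conditions the tests run under:

* **Amplicon read sets**: reads drawn multinomially from specified allele
  frequencies, each read a window of the edited amplicon guaranteed to cover
  the classification window, with uniform substitution errors (default
  0.3%/base, the magnitude motivating a 5% allele filter). Worked examples
  use a printed four-allele spectrum (41.88 / 28.12 / 16.13 / 13.87%) at
  depth 50,000.
* **Clonal lineages**: per subclone and target, each allele at or above
  threshold is lost with probability `p_loss` (frequency set to 0); with
  probability `p_gain` a new or dormant allele is raised to 25-40%; Gaussian
  drift (truncated at 0) jitters frequencies before renormalization; every
  gain/loss is logged. This is a phenomenological stand-in — the biology
  (eccDNA reintegration, hyperploidy) is not modeled, only the observable
  oscillation pattern. Event recovery is tested under a guard band keeping
  all frequencies at least 1 percentage point away from the threshold, since
  renormalization can otherwise move bystander alleles across it without an
  event.
* **eccDNA libraries**: each circle is concatemerized (at least 3 tandem
  copies), fragmented uniformly, and sequenced as read pairs; requested
  microhomology is planted by locally editing the reference so the junction
  flanks share an exact k-mer; circles containing a target site can carry a
  specified allele while the reference stays wild type. The truth table
  records per-read junction spanning (and multi-junction wrapping for
  circles shorter than the fragment), and per-circle canonical coordinates.
  `depth_per_copy` is per-copy fold fragment coverage, default 25 in the
  recovery experiments so that circles retain enough usable junction reads
  after the geometric and error losses described above.

FASTQ qualities are constant (Q30-equivalent) and never used downstream; the
error model is substitutions only, so classification ground truth stays
unambiguous. All generators take an explicit seed and restore the caller's
RNG state; fixed seeds give byte-identical FASTQ output.

What the generator does **not** emulate: PCR duplication and chimera
artifacts of rolling circle amplification, indel sequencing errors,
quality-score structure, real mouse-genome repeat content, and mappability
issues. Passing tests therefore demonstrate correctness of the
quantification logic under clean generative assumptions, not robustness to
every artifact of real libraries.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: depth 50,000 for frequency
recovery; an exhaustive single-indel grid (all 65 deletions with
$a+b \le 10$ plus 80 insertions up to 6 bp) on a 120-bp amplicon; lineages of
10 targets by 4 alleles by 4 subclones; 50 circles of 150-10,000 bp with
microhomology 0-5 bp at 0.3% error; and a 3-target, 250-read demonstration
pipeline run twice for byte-identity. These sizes exercise every code path
at full fidelity while keeping a complete run in minutes on one CPU.

## Known limitations

* The minus-strand label orientation and the blunt-cut offset are
  conventions; data produced under other conventions needs relabeling before
  comparison.
* The classifier treats reads as single-end fragments covering the window;
  there is no paired-end merging, UMI handling, or base-quality weighting.
* The junction caller requires exact unique seeds and is not suitable for
  repeat-rich or genome-scale references; SAM from an external mapper can be
  supplied for the classification steps, but junction calling itself is
  self-contained.
* Circle allele assignment pools reads per locus, not per circle.
* Copy number is not inferred beyond the richness > 2 flag; eccDNA
  abundance is compared only through library-fraction read ratios.
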