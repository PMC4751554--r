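---
title: "Methods: CGR discovery from read depth and split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGR discovery from read depth and split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

chromoscout characterizes a complex genomic rearrangement (CGR) confined to
one reference sequence, given coordinate-addressable alignments of a test
sample and a matched control.  The underlying model is a *derivative
chromosome*: an ordered concatenation of oriented reference segments,
possibly with short junctional insertions at the fusion points.  Everything
the pipeline reports is a view of that object:

* the **copy-number profile** is the per-base multiplicity of reference
  positions in the derivative, estimated from windowed read-depth ratios;
* **breakpoint junctions** are adjacencies in the derivative that do not
  exist in the reference, detected from soft-clipped split reads;
* **junction signatures** (microhomology, templated insertions) describe
  the bases at each fusion point and carry the mechanistic evidence;
* the **segment graph** ties both views together, and derivative
  reconstruction enumerates the walks that realize the observed copy
  numbers using the observed adjacencies;
* the **classification** maps the evidence onto the two canonical CGR
  classes: chromoanasynthesis-like (localized gains without losses,
  junctions bearing microhomology or templated inserts, pointing to
  replicative templated repair) versus chromothripsis-like (copy states
  oscillating between retained and lost segments with mostly blunt,
  end-joining junctions).

The package assumes a haploid comparison: the test sample carries the
derivative homozygously, the control carries the reference.  Copy "2" and
"3" therefore mean doubling and tripling of depth, which is also the
reading appropriate for a homozygous rearrangement in a diploid.
Heterozygosity, and hence loss-of-heterozygosity evidence, is outside the
model.

# The built-in scenario generator

The simulator exists so every stage is testable without external data; its
default scenario realizes the rearrangement geometry the package was built
around.  On a 5 Mb random reference (GC 0.36, the nucleotide composition of
the *C. elegans* genome), the default plan is the walk

```
[0, 3.028M)+   [3.0M, 3.528M)+   [1.0M, 3.787M)+   ins17
[3.778M, 3.78696M)-   [3.787M, 5M)+
```

whose coverage accounting yields two large doubled regions (2 Mb and
500 kb), one 28 kb triplicated segment between them, a 9 kb segment
duplicated as an inverted pair, and no deletions -- four novel junctions in
all, spanning 2.787 Mb between the outermost breakends.  The designed
junction signatures are: a 9-nt insertion templated from 50 bp beyond the
donor breakend, a 3-bp block (`AGT`) terminating both fusion-partner ends,
one blunt fusion, and a 17-nt insertion flanked by the two inverted copies
and templated from 25 bp beyond the fold-back breakend.  The two inverted
copies deliberately end 40 bp apart, so their fold-back junction has two
distinct breakend coordinates; the offset is a sequence-level feature and
is not scaled with the plan.

Two generator choices deserve justification:

* **Which small segment is triplicated.**  The triplicated segment must be
  visible in a 10 kb-window depth view, which requires roughly three
  windows (~30 kb).  The default therefore triplicates the 28 kb segment
  and uses the 9 kb segment as the inverted duplicated pair; the
  `triplicated =` argument flips this for users who want the alternative
  geometry, in which the tripled interval is invisible to the windowed
  view and is recovered only by the graph's interval re-estimation.
* **Engineered signature bases.**  A handful of reference bases are edited
  before the derivative is built (`engineer_reference()`): the shared
  triplet is written at both partner ends and capped at exactly 3 bp, the
  blunt junction is guaranteed zero ambiguity on both sides, and both
  insertions are made irreducible (their end bases cannot extend either
  partner flank).  Without the irreducibility edits the breakpoint
  representation -- and the reported insertion length -- is genuinely
  ambiguous, because an insertion base matching the flank can be shifted
  across the junction.

The read simulator draws a Poisson number of fragments (mean
`coverage * L / (2 * read_len)`), uniform fragment starts, Gaussian
fragment lengths (default 300 +- 50), FR orientation, constant Q40
qualities and uniform substitution errors (default 0.5%).  It does not
model indel errors, quality decay, GC-coverage bias, mappability, or
alignment ambiguity; truth alignments place every clip exactly at its
breakend.  Passing tests therefore demonstrate the pipeline's logic, not
robustness to aligner artifacts -- for external BAMs the clip clustering
offers a `merge_dist` tolerance, but real-data behavior is untested here.

# Depth ratios and copy states

Windowed counts use the leftmost aligned base of primary, non-duplicate,
MAPQ >= 1 records; supplementary and secondary records are excluded so a
split read is counted once.  The ratio track is
`r_i = (c_test_i / N_test) / (c_ctrl_i / N_ctrl)` with library totals as
the normalizers; windows with zero control reads are masked rather than
infinite, and are never interpolated.  This normalization forces the
count-weighted mean ratio to 1 -- which also means that when gained
sequence occupies a large fraction of the analyzed region (it is >50% of
the default 5 Mb scenario), *all* ratios are depressed by the mean copy
number and the copy-1 background sits well below 1.  Real whole-genome
libraries dilute this effect to a percent or two; a single-arm analysis
does not.  The state caller therefore estimates the *lattice unit* -- the
ratio corresponding to one copy -- by a grid search minimizing the
truncated distance of the smoothed ratios to an integer lattice, and
assigns `state = round(ratio / unit)`.  With a mostly copy-neutral region
the unit is ~1 and this reduces to plain rounding.  Noise measured in
lattice units shrinks as the unit grows, so the largest near-optimal unit
is preferred, which resolves the inherent unit/2 degeneracy.

Segmentation smooths with a running median (halfwidth 2 windows), merges
same-state runs, and absorbs segments shorter than 3 windows into the
flank with the closer mean ratio.  These two constants are the smallest
that survive isolated noisy windows while keeping a ~3-window triplicated
segment alive.  Masked windows do not break a run; a segment's interval
spans them, but they contribute nothing to its state.

**Boundary refinement** re-estimates each state-change coordinate at a
decreasing window schedule (default 10 kb, 1 kb, 200 bp).  At each scale
the boundary moves to the window edge with the largest local mean contrast
(two windows per flank), restricted to the expected transition direction
when the caller knows it; the transition itself is certified only at the
coarsest scale, where counts give high signal-to-noise.  A final unbinned
Poisson maximum-likelihood changepoint over test read starts within four
finest-scale windows gives base-pair-scale precision.  The returned
interval has width twice the finest window.  A local contrast (rather than
a global changepoint fit over the capture region) is used deliberately:
the triplicated segment is only ~3 windows wide, and a global fit centred
near one of its edges is hijacked by the other.

# Junction calling

Primary alignments with a soft clip of at least 15 bases are clustered by
exact clip coordinate and side; truth alignments place clips exactly, and
a +-2 bp merge is available for externally aligned data.  Each cluster's
clipped substrings are realigned against the reference in the
junction-outward direction (left clips are reverse complemented first):
a 12-nt exact seed, slid from the junction-proximal end to allow for
junctional insertions, is extended over the full clip with at most one
mismatch, on both strands.  Clusters vote; the majority partner
coordinate/orientation wins, and the unexplained clip prefix length is the
insertion hint.  Reciprocal clusters are paired into a junction when the
combined support reaches 3 reads -- the smallest count that is both plural
and above stray-noise level.  Junctions whose breakends carry clipped
support (>= 2 reads) in the control are suppressed.  At most 30 clips per
cluster are realigned (longest first); support is still counted over all.

The consensus lays all supporting reads out in a common junction frame
(partner A entering from the left; B-side reads are reverse complemented
into it, with insertion bases shifted across the junction point) and takes
a per-position majority; ties go to the alphabetically first base with a
warning, and a consensus where more than 20% of positions are contested is
refused as inconsistent.

**Signatures.**  Insertion bases are the consensus bases after the
junction that match neither partner: the partner-B continuation is scanned
for its exact onset (15-base probe, one mismatch tolerated).  When there
is no insertion, microhomology is measured in both shift directions --
a suffix of one partner's end equal to the sequence immediately preceding
the other partner's start -- and the total shift ambiguity is reported,
with the block printed from the direction in which it terminates a partner
end (so a shared triplet reads as it appears on the reference).
Microhomology and insertion are mutually exclusive by construction, which
keeps the accounting of junction bases single-valued.  An insertion of at
least 5 nt found (directly or reverse complemented) within 500 bp of
either breakend with at most one mismatch is labelled templated; shorter
insertions are never labelled, because chance matches at that length are
common in a 1 kb window.

# Reconstruction and classification

The reference is partitioned at every called breakend.  Copy numbers
transfer from the windowed segmentation by majority overlap, except that
segments below window resolution (but at least 500 bp) are re-estimated
from a direct test/control count ratio over the exact interval, divided by
the lattice unit -- the graph-level analog of shrinking the counting
interval, and the only way a 9 kb duplicated segment can be seen through a
10 kb windowed view.  Below 500 bp the interval counts are too noisy and
the overlap copy is inherited.  Each copy-state boundary must be explained
by a junction breakend within a tolerance of twice the finest refinement
window (400 bp); unexplained boundaries are reported as inconsistencies,
as data rather than errors.

Walk enumeration is a backtracking search over the segment graph: every
segment is traversed exactly its copy-number times (orientation-aware),
reference adjacencies may be reused freely, and every novel adjacency must
be used at least once -- a duplicated junction region legitimately
traverses the same adjacency twice, so "exactly once" would be wrong.
Any segment may start a walk (no telomere anchoring evidence exists in
this data), reference-collinear continuations are explored first so the
collinear walk heads the list, and a walk and its reverse complement are
reported once.  The search is capped (`max_walks`, plus a state budget)
and flags truncation; an exhausted search with no walk reports an
"unbalanced" diagnostic.

Classification is a pure function of the evidence, with the thresholds as
configuration: at most one junction is "simple"; gains without any lost
segment, with at least half the junctions carrying >= 2 bp microhomology
or a templated insertion, is "chromoanasynthesis-like"; lost segments
interleaved with retained ones (>= 2 alternations) with a feature fraction
below half is "chromothripsis-like"; anything else is "unclassified".
The class definitions are qualitative in the literature; these cutoffs are
this package's operationalization and are deliberately exposed as
parameters (`mh_min`, `feature_frac`, `min_alternations`).

# In silico PCR

The validation logic mirrors the bench experiment: a junction-specific
primer pair must amplify from the derivative and not from the reference.
Binding requires an exact 3'-terminal 3 nt (the polymerase-extension
convention) and otherwise tolerates a configurable mismatch count; a
product is any convergent site pairing within the size limit, and the
product set is invariant to swapping the primers.  Design picks 20-mers
from the derivative-oriented junction flanks with GC 40--60%, a unique
zero-mismatch site in the reference, exactly one derivative product of
150--1000 bp and zero reference products.  Melting-temperature
thermodynamics and dimer checks are intentionally absent: the target is
the asymmetry logic, not assay design.  When a junction's two flanks are
copies of each other no unique primer exists and the design reports
failure -- which is itself informative.

# Problem sizes, determinism, and what the tests show

All randomness flows from explicit integer seeds; a pipeline run is
bit-reproducible given its configuration.  The test suite exercises the
full-size scenario (5 Mb reference, 30x both samples, 10 kb windows) once
and shares that run across the end-to-end checks; unit tests use a 1/20
miniature (250 kb reference, 500 bp windows) whose window-boundary
geometry is identical.  Per-window counts in the miniature are ~20x
smaller, and mate-pair clumping roughly doubles the Poisson variance, so
windowed-depth tests in the miniature run at 100x coverage to restore the
rounding margins that 30x provides at full size; split-read and graph
tests keep 30x, where their evidence does not depend on per-window
rounding.  Known limitations worth restating: no GC or mappability
correction, no discordant-insert-pair evidence, single reference sequence
(no inter-chromosomal junctions), no LOH analysis, and no likelihood
scoring among enumerated walks.
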