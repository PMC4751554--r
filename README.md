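# chromoscout

Discovery and characterization of **complex genomic rearrangements (CGRs)**
from whole-genome sequencing alignments of a test sample against a matched
control — for geneticists who suspect that a mutant phenotype, a
recombination-suppressed interval, or an odd depth profile hides a
structural event that SNV-centric pipelines miss.

A CGR is a localized cluster of duplications, triplications, inversions
and/or deletions joined by novel breakpoint junctions. Two mechanistic
classes dominate the literature:

* **chromoanasynthesis** — localized copy-number *gains* (duplications and
  triplications, no deletions) whose junctions carry microhomology or
  short *templated insertions*, the signature of replication-based
  (template-switching) repair;
* **chromothripsis** — shattering followed by end-joining, leaving copy
  states that oscillate between retained and lost segments with mostly
  blunt junctions.

## What the package computes

Given coordinate-sorted SAM alignments (or its own simulated truth
alignments) for test and control:

1. **Depth ratios** — per-window counts are library-rescaled and divided,
   `r_i = (c_test_i / N_test) / (c_ctrl_i / N_ctrl)`; windows with zero
   control coverage are masked.
2. **Copy states** — running-median smoothing, calibration of the
   copy-lattice unit, integer state per window, merged into segments;
   state boundaries are refined through a multi-resolution window schedule
   (10 kb → 1 kb → 200 bp) finished by an exact Poisson changepoint on
   read starts.
3. **Junctions** — soft-clipped split reads are clustered by exact clip
   coordinate and side; clipped sequences are realigned (12-nt exact seed,
   ≤1-mismatch extension, both strands) to find the partner breakend;
   reciprocal clusters with ≥3 supporting reads become junctions, and any
   junction with clipped support in the control is suppressed.
4. **Signatures** — a per-junction consensus yields the microhomology
   (shared sequence terminating both fusion-partner ends), junctional
   insertion, and whether the insertion is templated from within 500 bp of
   a breakend (allowing reverse complement).
5. **Reconstruction** — copy segments and junctions combine into a segment
   graph; candidate derivative chromosomes are enumerated as walks that
   traverse every segment exactly its copy-number times and use every
   novel adjacency.
6. **Classification** — a deterministic rule table over the evidence
   labels the event chromoanasynthesis-like, chromothripsis-like, simple,
   or unclassified.
7. **In silico PCR** — junction-flanking primer pairs are designed and
   checked for the diagnostic asymmetry: a product from the derivative,
   none from the reference.

A built-in simulator generates the whole study system — reference,
derivative chromosome from a declarative segment plan, paired-end reads,
truth alignments, truth junctions and truth copy profile — so the entire
pipeline is testable offline. The default plan realizes a ~2.8 Mb
rearrangement with two doubled regions (≈2 Mb and ≈500 kb), one 28 kb
triplicated segment, a 9 kb inverted duplication flanking a 17-nt
templated insertion, an `AGT` triplet shared by both partner ends of one
junction, and no deletions.

## Worked example

```r
library(chromoscout)
rep <- run_all(chromo_config(seed = 1), outdir = "cgr_run")
print(rep)
```

On the default full-size scenario (5 Mb reference, 30× both samples) this
prints:

```
<run_report>
  junctions: 4 (span 2,787,000 bp)
  segments: 3 duplicated, 1 triplicated, 0 deleted
  classification: chromoanasynthesis-like
```

and `rep$junctions$table` holds the per-junction evidence:

```
  name coord_a orient_a coord_b orient_b support microhomology_len
1  jx1 1000000        - 3528000        +      18                 3
2  jx2 3000000        - 3028000        +      23                 0
3  jx3 3778000        - 3787000        -      26                 0
4  jx4 3786960        + 3787000        +      28                 0
  microhomology_seq insertion_len templated
1               AGT             0     FALSE
2                               9      TRUE
3                               0     FALSE
4                              17      TRUE
```

Reading this: four junctions were each supported by ≥18 split reads;
junction `jx1` fuses two loci whose ends share the triplet `AGT`;
junctions `jx2` and `jx4` carry 9-nt and 17-nt insertions copied from
sequence near their breakends (templated repair); `jx3` is blunt. The
10 kb depth view (`rep$depth`) shows two doubled segments of 2.0 Mb and
0.5 Mb and one tripled segment, the outermost breakends span 2.787 Mb,
and each designed primer pair (`rep$pcr`) amplifies exactly one 150–200 bp
product from the derivative and none from the reference. Three of four
junctions carrying homology or templated inserts, with gains and no
losses, drives the chromoanasynthesis-like label.

All intermediates are persisted in standard formats (FASTA, BEDPE, BED,
bedGraph, VCF 4.2 breakends, TSV) plus a JSON `report.json`.

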