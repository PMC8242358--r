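---
title: "Validating ATAC-seq peaks with histone-mark truth sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ATAC-seq peaks with histone-mark truth sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakproof)
```

## The validation model

ATAC-seq measures chromatin accessibility, but a called peak set mixes
genuine open-chromatin regions with artifacts, and the caller's own score
is only an internal confidence measure. Histone-mark ChIP-seq from the
same tissue provides an orthogonal reference grounded in chromatin
biology: regions carrying H3K4me1 (enhancers) or H3K4me3 (promoters)
*together with* H3K27ac are actively used regulatory elements and should
be accessible, while H3K27me3 marks Polycomb-repressed chromatin that
should not be. `peakproof` therefore builds

* a **real-positive set (RP)**: every H3K4me1 or H3K4me3 peak that shares
  at least `min_overlap` (default 1) bases with an H3K27ac peak, merged;
* a **real-negative set (RN)**: the merged H3K27me3 peaks,

and scores a peak set at a cutoff $c$ by base-level overlap of the
retained (score $\ge c$), merged peaks:

$$\mathrm{precision}(c) = \frac{TP(c)}{TP(c)+FP(c)}, \qquad
  \mathrm{recall}(c) = \frac{TP(c)}{|RP|}, \qquad
  \mathrm{FPR}(c) = \frac{FP(c)}{|RN|},$$

where $TP(c)$ and $FP(c)$ count distinct bases of the retained peaks
falling in RP and RN respectively. As $c$ increases the retained set
shrinks, so $TP$, $FP$, recall and FPR are non-increasing while precision
typically rises; the **filtering threshold** is the smallest evaluated
cutoff at which precision reaches recall (the intercept of the two
curves).

### Assumptions and caveats

The truth sets are trusted as ground truth, which they are not in a strict
sense: ChIP-seq peaks have their own false positives, some accessible
regions carry neither mark, and RP and RN may even overlap. The package
does not force RP and RN to be disjoint — bases in both count toward both
$TP$ and $FP$, exactly as the formulas dictate — but reports their shared
base count (`rp_rn_shared_bases`) so incoherent truth sets are visible.
Recall is measured against all of RP, so it conflates "the caller missed
it" with "it was not accessible in this sample"; it is a comparative
metric across libraries, not an absolute sensitivity.

## Design choices in the open corners

Several details of this validation scheme admit more than one reading;
the package fixes them as follows.

* **Whole-peak RP selection.** A K4 peak qualifying via H3K27ac enters RP
  in full, not clipped to the overlapping stretch — "peaks that overlap"
  reads as peak-level selection. `clip_to_k27ac = TRUE` gives the
  base-level alternative.
* **Merged overlap counting.** All base counting merges each side first,
  so a base is never counted twice even when raw peaks overlap; otherwise
  base-level precision could exceed 1.
* **Cutoff comparison is `>=`** (a peak scoring exactly the cutoff is
  kept), and the crossing is found on the raw evaluated grid without
  interpolation or smoothing; with ties, the smallest qualifying cutoff
  wins, keeping more peaks.
* **Default cutoff grid**: all distinct observed scores when there are at
  most 200 of them, otherwise 50 evenly spaced score quantiles.
* **Degenerate curves** are flagged, not hidden: precision at empty
  retention is undefined (`NA`), never 0; a curve where precision already
  dominates at the first point, or never crosses recall, returns the
  first/last cutoff with a `"note"` attribute.
* **Strand** is read and preserved but ignored by all overlap arithmetic;
  only promoter derivation uses it. Chromosome names are matched exactly
  (no `"chr"` aliasing); a warning fires when two inputs share no
  chromosome names.
* **Coordinates** are 0-based half-open everywhere, so `[a,b)` and
  `[b,c)` never overlap and a 1-bp overlap is the smallest possible.

## QC metrics

**FRiP** is the fraction of fragments (paired-end units, not read mates —
divide reported read-level FRiP by ~2 when comparing) overlapping the
merged peak set by ≥ 1 bp.

**Binned RPKM coverage** tiles the genome with fixed-size bins (default
1000 bp; the last bin of a chromosome may be short) and counts each
fragment once per overlapped bin; RPKM normalizes by the actual bin width
and library size, $C \cdot 10^9 / (n \cdot w)$. This is a per-bin count
approximation, not the per-base averaging of deepTools' `bamCoverage`, so
values are comparable across libraries here but not bit-identical to that
tool. Correlation (Pearson, with optional complete-linkage "farthest
point" display ordering) and PCA (all bins, centered per bin, no top-N
selection) operate on this matrix.

**Fingerprint curve**: bins sorted by ascending count, cumulative bin
fraction against cumulative count fraction, anchored at (0,0); AUC by the
trapezoid rule. Uniform counts give AUC exactly 0.5; a single-bin spike
among $B$ bins gives exactly $1/(2B)$; enrichment pushes the AUC toward 0.

**SJSD** compares the observed per-bin count histogram (integer count
bins from 0 to the joint maximum) against an equal-length sample drawn
from a Poisson law with the observed mean — the no-enrichment profile of
a library sequenced to the same depth — via the Jensen–Shannon distance
with base-2 logarithms (range [0,1]). The Poisson draw is seeded by a
mandatory argument, and the draw is made on a temporary RNG state so
calling `sjsd()` never perturbs the caller's random stream.

**Intersection patterns** (UpSet-style) are counted region-centrically:
the union of all peak sets is merged into disjoint regions and each region
is assigned the exact subset of libraries overlapping it. Peak-centric
counting would make pattern counts inconsistent between libraries;
region-centric counts are disjoint and sum to the number of union regions.

**Promoters** are the 1 kb upstream of the annotated gene start,
strand-aware (upstream of `end` for − genes) because "upstream" is
biologically strand-relative; `ignore_strand = TRUE` reproduces the
literal strand-blind reading. Promoters are clamped to the chromosome and
genes whose clamped promoter is empty are dropped with a warning.

## The synthetic data generator

`generate_dataset()` emulates the study conditions every test runs under:
a genome (default 2 × 5 Mb) with 300 planted active regions (carrying
H3K4me3 and H3K27ac, half also H3K4me1) and 100 repressed regions
(H3K27me3), all mutually disjoint with ≥ 1 kb gaps; region lengths
uniform on 1–5 kb. Peak calls are 300 true peaks inside active regions
with scores $\mathcal{N}(10, 1)$ and 100 decoys inside repressed regions
with scores $\mathcal{N}(3, 1)$ — score distributions separable but
overlapping in their tails, as a good caller on a decent library would
produce. Each call spans 90–100% of its region, reflecting that callers
approximately recover regulatory elements; this is what makes recall
start high (near the planted coverage fraction) while precision starts
low, so the precision–recall curves genuinely cross. 100,000 fragments
hit a true peak with probability 0.5 (the target FRiP; background
fragments are placed uniformly outside all calls, so the realized in-peak
fraction is exactly binomial) with lengths from the nucleosome ladder
mixture: 45% nucleosome-free (uniform 50–120 bp), 40% mono-nucleosomal
($\mathcal{N}(200, 20)$), 15% di-nucleosomal ($\mathcal{N}(400, 30)$).
500 genes are planted, half with a true peak under the promoter; the
expression table is $5 + 2 \cdot \mathrm{open} + \mathcal{N}(0,1)$ per
sample (a variance-stabilized-like scale) over 2 samples.

One master seed drives everything through per-stage derived seeds
(regions, histone placement, calls, fragments, genes, expression), so a
stage can be regenerated independently and the generator is
byte-reproducible: the same seed yields byte-identical output files.
Scores and expression values are rounded (4 and 6 decimals) at generation
so the text formats round-trip exactly. An optional `decoy_mode =
"neutral"` places decoys outside both truth sets, exercising the
undefined-precision path.

What the generator deliberately does **not** emulate: read-level
sequences and alignment error, PCR duplicates and mitochondrial
contamination, copy-number and mappability biases, ChIP-seq noise in the
histone truth sets (marks sit exactly on the planted regions), and
correlated expression structure beyond the single open-promoter shift.
Passing tests therefore demonstrate that the arithmetic, the threshold
rule and the estimators recover planted structure — not that any
particular real library is well calibrated.

## Numerical and testing notes

Interval arithmetic is delegated to IRanges/GenomicRanges per chromosome
(1-based closed internally, converted at the boundary); every
base-counting operation is checked in the test suite against an
independent per-base boolean-array oracle on toy genomes, across hundreds
of randomized instances. Test problem sizes are scaled down (1 Mb
single-chromosome configurations with 60 planted regions for the seeded
replicate studies; the full default dataset for the end-to-end recovery
test) so the whole suite runs in about a minute. The threshold-recovery
property — selected cutoff strictly between the decoy and true score
means — is checked over 100 seeded replicates, and the expression-shift
recovery over 20 seeds against its pooled standard error.

## Known limitations

* Peak-level RP selection can admit long K4 peaks on the strength of a
  1-bp H3K27ac touch; use `clip_to_k27ac` or a larger `min_overlap` for
  stricter truth sets.
* `confirmed_count(a, b)` is directional (counts peaks of `a`); report
  both directions for replicate pairs.
* FRiP, Jaccard and the validation metrics all depend on upstream peak
  calling and fragment filtering choices that this package deliberately
  does not re-do.
* The SJSD reference is a single Poisson draw, not an analytic mixture;
  with very few bins the statistic is noticeably seed-dependent.
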