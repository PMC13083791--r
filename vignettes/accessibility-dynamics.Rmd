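---
title: "Methods: state-transition modules, expression categories, and occupancy metrics"
author: "atacdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-transition modules, expression categories, and occupancy metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdyn)
```

# The problem

Reprogramming-type experiments follow cells from a somatic start state
(mouse embryonic fibroblasts, MEF) to a pluripotent endpoint (embryonic
stem cells, ESC) through an ordered series of intermediate timepoints
(D0, D3, D5, D7), usually in several parallel perturbation arms plus a
fluorescent-protein control. Three data layers are common: ATAC-seq peak
calls per (condition, timepoint), RNA-seq differential-expression tables
per arm versus the control, and binding peak sets for the perturbed factor.
This package implements the study-level integrative summaries over those
inputs, and a seeded generator of synthetic inputs with planted truth.

# Accessibility state-transition modules

## Union atlas and state calls

All samples' peaks (conditions x inner timepoints plus the two shared
anchor reference samples) are merged into a disjoint union set; every
analysis is carried out over these union intervals. Coordinates are 0-based
half-open (BED convention) at every file boundary; internally intervals are
`GRanges`. Bookended peaks merge by default, matching the behaviour of the
standard merge tooling; `merge_bookended = FALSE` is available.

A union interval is *open* in a sample when it overlaps that sample's peaks
by at least one base. One base is the most permissive reading of
"compared against the background"; since no minimum overlap is stated
anywhere upstream, we default to it and expose `min_overlap` (a fraction of
the union interval) for sensitivity analysis. Strand is ignored throughout:
accessibility and binding are unstranded signals.

## Classes and timing

Base classes come from the two shared anchors only: PO (open/open),
OC (open/closed), CO (closed/open). Intervals closed at both anchors do
occur in an atlas built from *all* samples (they are transiently accessible
somewhere mid-course); we label them NE rather than dropping them, so that
the module labels partition the atlas and every count table row sums to the
union size. NE is an artifact extension: it carries no timing submodule.

For OC/CO intervals the timing submodule over the inner trajectory
$x_1,\dots,x_{K-1}$ (inner timepoints) followed by the endpoint state $e$ is

$$ t^* \;=\; \min\{\,t : x_j = e \ \text{for all } j \ge t\,\}, $$

the earliest position from which the endpoint state is adopted *and
maintained*. We read this rule literally: a flicker (a reversion after
adopting the endpoint state) resets the clock and the latest maintained
suffix wins; no smoothing is applied. Equivalently $t^*$ is one past the
last mismatch, which is how the implementation computes it; the test suite
checks the equivalence against a brute-force suffix scan on all 64 anchor x
inner patterns. Within the 16 OC-consistent patterns the submodule
multiplicities are necessarily (1, 1, 2, 4, 8) for OC1..OC5, and
symmetrically for CO — a structural fact the acceptance suite pins down.

The axis generalises: any ordered timepoint vector with two distinct
anchors is accepted and $K$ (the number of submodules, inner count + 1)
adapts.

## Per-condition counting and Venn partitions

How the per-condition module counts relate to the control-anchored heatmap
ordering is genuinely open in the source material: counts could re-derive
everything from each condition, or reuse control-derived classes. We
resolve it as follows: *base classes* come from the shared anchors (hence
are condition-invariant, and PO/NE counts are identical across conditions
by construction — a tested invariant), while *timing* is recomputed from
each condition's own inner trajectory plus the shared endpoint anchor. The
fully control-anchored variant is simply `classify_condition(sm, "dsRed")`
reused for ordering. An optional `require_detection` filter forces
intervals never open in a condition's own samples nor anchors to NE; it is
off by default because nothing upstream states such a filter, but
near-identical (not identical) PO counts across published conditions
suggest one may have been applied.

`module_venn()` partitions intervals by the exact set of conditions in
which their label falls in a chosen class set (e.g. OC1..OC5).
"Shared by the treatment arms after excluding the control" is the
all-shared cell of the partition computed after dropping the excluded
condition entirely — membership in the excluded condition is ignored, not
required absent.

# Expression categories

Direction calls use raw p-values with p < 0.05 and |log2FC| > 1 by
default, because the stated gate is on *p*, not adjusted p; a
Benjamini-Hochberg mode (within system x timepoint) is available as a
flag. Within a system, a gene with significant calls in both directions at
different timepoints is `excluded` (inconsistent regulation); otherwise the
direction is whichever call was attained, or `ns`.

Across systems the categories form one exhaustive truth table:
all up → `common_up`; two or more (but not all) up with the rest `ns` →
`pair_up(...)`; exactly one up with the rest `ns` → `specific_up(...)`;
down analogues; any up/down mix or any `excluded` → `discordant`; all
`ns` → `none`. Two ambiguities had to be resolved: we require the
non-participating systems of pair/specific cells to be strictly `ns` (not
merely not-opposite), and genes absent from a system's table count as `ns`
rather than missing. The table is checked against an independently coded
oracle over all $4^3$ patterns. The published 15-cluster row labels (UC/DC)
derived partly from hierarchical clustering and are out of scope; the
package emits the composite sort (category x anchor bin x peak-timepoint
rank) that underlies such displays.

Anchor bins use $(\mathrm{ESC}+\varepsilon)/(\mathrm{MEF}+\varepsilon)$
with a two-fold cut and $\varepsilon = 1$: a pseudocount is needed for
zero RPKM-scale values and 1 is the conventional choice; none is stated
upstream. Ranking keys genes by their maximum- (up) or minimum- (down)
expression timepoint, ties to the earliest timepoint, then magnitude.

# Integration metrics

Feature annotation classifies each peak **by its midpoint** with precedence
promoter > exon > intron > distal. Midpoint assignment avoids multi-class
peaks; the ±3 kb promoter window is the stated annotation focus and the
default. Exon/intron calls require a declared exon table; without one,
gene bodies are unknown and non-promoter peaks fall to distal.

Peak-to-gene linking offers both plausible modes — TSS-window overlap
(default, ±3 kb) and nearest-TSS with distance ties contributing all tied
genes — because the upstream description does not disambiguate them.

Gene-set overlaps report the one-sided hypergeometric upper tail
$P(X \ge k)$ with the TSS table as the default universe, BH-adjusted when
several categories are tested. The p-values are auxiliary (the source
figures show Venn counts only).

Occupancy by class assigns each binding peak to the accessibility class it
overlaps most (ties to the earlier class in PO, OC, CO order) or to an
`outside` bin, and reports both the raw fraction of peaks per class and the
region-count-normalised metric `peaks / regions`, which is the right
comparison across classes of very different sizes. Class regions must not
overlap across classes (they are atlas subsets); this is validated.

# The synthetic world

`simulate_study()` generates every pipeline input from one seeded config.
Defaults state the world the analyses assume:

* axis MEF, D0, D3, D5, D7, ESC; four conditions (control + three arms);
* 5,000 union intervals over all 12 modules (PO 1,500; 300 per OC/CO
  submodule; NE 500) — thousands of dynamic loci per module, matching the
  scale at which such studies report counts;
* interval lengths uniform 200-1000 bases and gaps 200-2000 bases,
  typical ATAC peak widths and a genome large enough to hold them;
* per-(interval, sample) independent state-flip noise `flicker_noise`
  (default 0) — the simplest noise model consistent with
  threshold-crossing peak calls; correlated noise is deliberately not
  modelled;
* planted DE effects |log2FC| ~ N(2, 0.5) truncated below at the call gate
  (1), with p ~ U(0, 1e-4) at one active timepoint in the designated
  systems; null genes draw log2FC ~ N(0, 0.25), p ~ U(0, 1). Truncation is
  a logical requirement, not a convenience: "planted genes recovered at
  100%" is only satisfiable if planted effects clear the gate. For the same
  reason, planted genes' *inactive* cells are sampled from the null
  conditioned on non-significance; the unconditioned null block is what the
  closed-form false-call-rate check runs on.
* NE intervals are planted as transiently open (D3 and D5) in every
  condition: that is how an anchor-closed interval enters a union atlas
  built from sample peaks at all, and it keeps zero-noise recovery exact
  for all 12 modules;
* binding rates PO 0.30, OC 0.10, CO 0.05 per region — strong preference
  for constitutively open chromatin with measurable engagement of dynamic
  regions.

Determinism: one root seed; each stage derives a substream seed from a
stable label hash (kept far below $2^{31}$), so adding a stage never
perturbs earlier draws, and identical configs give byte-identical output
files (stage manifests carry a wall-clock timestamp and are excluded from
that guarantee).

What the generator does **not** emulate: read-level data, fragment-size or
transposase-bias structure, signal intensities (peaks are all-or-nothing),
correlated noise between neighbouring intervals or timepoints, and
peak-boundary jitter (emitted peaks cover their interval exactly). A green
recovery test therefore establishes that the classifiers invert the stated
generative model — not that they are robust to alignment- or
signal-level artefacts.

# Numerical choices and degenerate inputs

* Zero-length intervals are rejected at construction; adjacency in
  half-open coordinates is never overlap.
* An empty peak file yields an all-closed state-matrix column; an all-empty
  input set refuses to build an atlas.
* `which.max` tie-breaking (earliest class / earliest timepoint) is used
  everywhere a tie needs resolving, and is documented per function.
* The noisy-recovery acceptance check uses the exact per-label survival
  probability obtained by enumerating all $2^6$ flip patterns of the six
  label-determining calls — for every label this collapses to
  $(1-p)^d$ with $d$ the minimal determining set (e.g. $d = 3$ for CO5:
  the anchors and D7; $d = 6$ for CO1), and intervals that drop out of the
  union entirely (probability ~ $10^{-10}$ at the default noise) count as
  disagreements.

# Known limitations

Classification is binary per sample — no use of peak scores or signal
strength beyond the q-value filter at read time; no replicate handling
(peaks are assumed pre-consolidated per sample); no motif or GO analysis
(database-dependent); heatmap rendering and hierarchical clustering of
module rows are out of scope. Real-study headline counts depend on raw-read
reprocessing and are not reproduced here; the test suite instead pins the
machinery to oracles and planted truth.
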