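---
title: "Quantifying mosaic CRISPR editing from Sanger base-call exports"
author: "mosaicedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mosaic CRISPR editing from Sanger base-call exports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicedit)
```

## The problem

Co-injecting Cas9 mRNA and a single guide RNA into a fertilized egg edits
the genome after the first cell divisions, so each founder (F0) animal is
a genetic mosaic: its cells carry an assortment of NHEJ repair outcomes
at the cut site. In an allotetraploid genome the target gene additionally
exists as diverged paralogous copies, some of which a given guide may not
match. Direct Sanger sequencing of a PCR product from such an animal
reads a *mixture* of templates: clean, single-peak trace upstream of the
cut site, and a superposition of shifted registers downstream, where
deletions and insertions of different lengths put every template's bases
at different offsets.

`mosaicedit` turns that qualitative picture into numbers, at three
levels:

1. **Per-base sequence fidelity** of a direct (mixed-template) read
   against a wildtype control read — a fast, per-animal measure of
   editing extent.
2. **Per-clone indel calls** from sequenced plasmid clones of the PCR
   product — exact deletion/insertion coordinates, reading-frame
   consequence, and the altered residue run for frame-conserving
   events.
3. **Guide-level allele selectivity** — which paralogs a 20-nt
   protospacer + NGG PAM actually matches, at how many mismatches, and
   whether an HDR repair template is protected from re-cleavage.

A synthetic mosaic-editing simulator generates populations with known
ground truth so every stage can be validated in a closed loop.

## The fidelity score

Sanger base callers export, for every read position, a primary (most
probable) and a secondary (second most probable) base call. Each
position of the experimental read is compared with the primary call of
an aligned wildtype control read:

* primary call identical to the WT base: score **1**;
* primary mismatched but secondary identical: score **0.25**;
* neither call covering the WT base: score **0**.

Mixed templates also produce IUPAC-ambiguous calls (`R`, `Y`, ...).
These receive intermediate scores by dividing the anchor score by the
call's degeneracy $k$ (the size of its IUPAC expansion set):

$$ s = \max\left(\frac{1}{k_p}\,[\mathrm{WT} \in P],\;
   \frac{0.25}{k_s}\,[\mathrm{WT} \in S],\; 0\right) $$

where $P$ and $S$ are the expansion sets of the primary and secondary
calls. This rule reproduces the three anchors exactly, scores a two-base
code such as `R` against a covered WT base at 0.5, and is monotone in
call informativeness: a more ambiguous call never outscores a less
ambiguous one that also covers the WT base. The full 64-row score table
can be audited with `fidelity_score_table()`. A `-` no-call has an empty
expansion and scores 0 against every WT base — absence of signal is
treated as a complete mismatch.

Positions where the *control* read's own primary call is ambiguous or a
no-call are masked entirely (excluded from scores and from
moving-average denominators): the score is only defined relative to a
trusted WT base.

### Alignment

The experimental read is aligned to the control by a single rigid
offset — the integer shift maximizing exact primary-call identity over
the read's first 50 positions (the pre-cut region, assumed unedited),
ties broken toward the smallest absolute shift. Gapped alignment is
deliberately not used: downstream of the cut the read is a superposition
of registers and has no single correct gap structure. If the best shift
explains less than 80% of the anchor, alignment fails loudly rather than
returning a bad offset.

### Smoothing and summaries

Scores are smoothed with a moving average over 10 bases. The window is
centered (`[i - 5, i + 4]`) and shrinks at read ends, so no values are
fabricated beyond the read; masked positions drop out of both numerator
and denominator. Whether the original analysis centered or trailed its
window is not stated anywhere we could check; centering is this
package's choice and is symmetric around the cut, which keeps the onset
of the degraded region interpretable.

`summarize_editing()` reduces a profile to four numbers. Baseline
fidelity is the mean moving average over `[cut − 70, cut − 20)` — the
window deliberately ends 20 positions upstream of the cut so that short
deletions reaching a few bases upstream do not contaminate it. Post-cut
fidelity is the mean over `[cut, cut + 50)`; the fidelity drop is the
difference; and the onset is the most upstream position whose moving
average first falls below baseline − 3·SD(baseline window).

## Guide matching conventions

* **Protospacer numbering**: position 1 is the PAM-distal (5') end of
  the 20-nt protospacer. The numbering convention is stated in every
  output because the opposite (PAM-proximal) convention is also in use
  in the field; with the toy data here, a sibling locus built with
  substitutions at positions 1 and 6 reports `mismatch_positions`
  `[1, 6]`.
* **PAM**: NGG only, and mandatory — a destroyed PAM disqualifies a
  window at any mismatch tolerance. NAG and other alternative PAMs are
  out of scope.
* **Cut site**: the blunt cut is placed 3 nt 5' of the PAM, between
  protospacer positions 17 and 18, mapped to + strand coordinates for
  either orientation. Coordinates are 0-based half-open internally and
  1-based inclusive in human-facing tables; BED output stays 0-based.
* All overlapping matches are reported; paralog scans need completeness,
  so there is no greedy suppression.

`check_recleavage()` applies the same scan to an HDR repair template: a
template is *protected* when no window survives at the stated mismatch
tolerance (the standard design being two silent mutations inside the
recognition sequence), and residual near-matches are reported for audit.

## Indel calling

Each sequenced clone is assumed to carry one repair outcome: a deletion,
an insertion, or a simultaneous deletion + insertion at one site. The
caller extracts the *minimal changed interval* by trimming flanking
identity — maximally from the 3' side first, then from the 5' side —
which places any placement-degenerate event (a deletion inside a repeat,
say) at its 5'-most equivalent position. This is the VCF normalization
convention and makes deduplication of identical outcomes reliable;
recurrent identical clones are counted but never collapsed away, since
recurrence carries information about how early in development editing
occurred. A global affine-gap alignment (match +2, mismatch −3, gap open
−5, gap extend −1, all overridable) supplies the identity screen that
rejects clones below 70% identity to the locus.

Frame classification: loss of the start codon takes precedence whenever
the event removes or interrupts any base of the initiator ATG; otherwise
an event is a frameshift iff its net length change is not a multiple
of 3, else in-frame. For in-frame events inside the CDS the wildtype and
mutant CDS are translated and the minimal changed residue run is
reported as `WTRUN->MUTRUN` after trimming residues common to both
flanks — so a clean two-codon deletion reads like `SK->`, and a compound
event replacing 21 nt with 9 nt after the start codon reads as seven WT
residues replaced by three.

Paralog of origin is assigned by counting matches at registered
diagnostic positions (read through the clone's own indel register);
deleted or doubly-mismatching sites simply contribute no support, and
ties are reported as `ambiguous`, never silently broken.

## The simulator

The simulator emulates three things: a mosaic template population, the
mixed-template trace it produces, and clone sampling.

**Population.** `n_distinct_edits` distinct edited templates receive
symmetric Dirichlet(α = 1) weights rescaled to the editing fraction;
one wildtype template carries the remainder. α = 1 is an uninformative
default for unknown lineage proportions and is configurable. Each edit
is drawn from a configurable spectrum whose defaults are: 70%
deletions, 15% insertions, 15% compound (simultaneous
deletion + insertion); geometric lengths with mean 4 bp (deletions) and
2 bp (insertions), truncated at 30 bp; a 1% chance that a deletion is
instead drawn uniformly from 100–150 bp; and event midpoints jittered up
to ±5 bp around the cut. These defaults were chosen once to reproduce
the qualitative spectrum reported for this kind of experiment — small
deletions under 20 bp most common, occasional insertions and compound
events, rare deletions over 100 bp — and are declared assumptions, not
measured facts; no quantitative indel-length histogram was available to
fit.

**Trace rendering.** At read position $j$ every template contributes the
base at its own coordinate $j$ (templates and the read share their 5'
start, as with a common sequencing primer), so registers shift
downstream of each template's indel exactly as in a real mixed trace.
The weighted base distribution gives the primary (heaviest) and
secondary (runner-up) calls; when the runner-up carries at least
`ambiguity_ratio` of the top base's weight, the primary becomes the
two-base IUPAC code. The default ratio of 0.25 mirrors the secondary
peak threshold at which trace software typically flags heterozygous
positions (roughly 25–30% of the primary peak height). Independent
miscalls can be injected at a flat `noise_rate` (default 0). The
mixture is modeled at the base-call level, not the chromatogram-peak
level, because that is exactly what the pipeline consumes.

**What this does and does not show.** Closed-loop tests demonstrate that
the analysis recovers what the simulator put in: exact net-change and
frame-class recovery from clones, clean baselines upstream of bounded
indels, and a fidelity drop that increases with the editing fraction
(Spearman ρ > 0.9 across seeds). They do not demonstrate performance on
real chromatograms, which add dye blobs, polymerase slippage, quality
decay along the read, and base-caller idiosyncrasies that the flat noise
model does not emulate. One visible detection limit of the call-level
model: at low editing fractions (~0.2) with many distinct lineages, the
wildtype template dominates every position, the primary call stays
wildtype, and the fidelity drop is near zero — sensitivity at low
mosaicism comes from secondary-peak information that only degrades the
score once the minority coalition approaches the ambiguity threshold.

**Determinism.** Every stochastic operation takes an explicit seed, uses
one local RNG stream (the caller's RNG state is untouched), and records
the seed in its output headers; repeat runs are byte-identical.

## Problem sizes used in the validation suite

The test suite validates scoring on all 15 × 4 call/WT combinations,
profile self-identity on 1000 random reads, guide scanning against a
brute-force oracle on 50 random locus/guide pairs at mismatch tolerances
0–3, indel recovery on 1000 simulated clones over a 600-nt locus, and
fidelity monotonicity over 5 editing fractions × 20 seeds. The analysis
scripts use a 600-nt example paralog trio with 4 distinct edited
lineages and 24 clones per sample — the scale of a typical
cloning-and-sequencing experiment.

## Known limitations

* No indel-spectrum deconvolution from the trace itself (TIDE/ICE-style
  decomposition is a non-goal); the trace gives extent, clones give
  identity.
* One compound event per clone; multiple independent edits on one
  molecule are out of scope, as are PCR chimera detection and
  quality-value weighting.
* Binary chromatograms (.ab1) are not parsed; the package consumes
  tabular base-call exports, with a configurable dialect because export
  schemas vary between tools.
* The ambiguity scoring rule is a reconstruction that reproduces the
  published anchor scores and intermediate-score behavior; the full
  original score table was not available to compare against, which is
  why `fidelity_score_table()` exists.
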