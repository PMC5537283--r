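# mosaicedit

Quantify CRISPR/Cas9 editing of paralogous genes from Sanger sequencing
of mixed-template PCR products.

Founder animals generated by injecting Cas9 mRNA + sgRNA into fertilized
eggs are genetic mosaics: each carries a population of NHEJ repair
outcomes at the cut site, and in an allotetraploid genome the target
exists as several diverged paralogs that a guide may or may not match.
Enzyme-mismatch assays are unreliable in that setting, so editing is read
out directly from Sanger traces and cloned amplicons. `mosaicedit`
implements that workflow:

- **Sequence fidelity score** — each position of a direct
  (mixed-template) read is scored against the primary base call of an
  aligned wildtype control read:

  | call pattern | score |
  |---|---|
  | primary call matches WT | 1 |
  | primary mismatches, secondary matches | 0.25 |
  | ambiguous call of degeneracy *k* covering WT | 1/*k* (primary) or 0.25/*k* (secondary) |
  | no call covering WT | 0 |

  smoothed with a 10-base moving average and summarized as
  baseline/post-cut fidelity, fidelity drop, and onset position around
  the predicted cut site.
- **Indel calling** from cloned amplicon sequences: left-aligned minimal
  compound events (deletion + optional insertion), reading-frame
  classification (`in_frame` / `frameshift` / `start_loss`), altered
  residue runs for frame-conserving events, duplicate-clone counting,
  and paralog-of-origin assignment from diagnostic bases.
- **Guide targeting**: protospacer + NGG scans of both strands with
  per-position mismatch reports (position 1 = PAM-distal end), blunt-cut
  prediction between protospacer positions 17 and 18, and HDR-template
  re-cleavage checks.
- **A mosaic-editing simulator** (NHEJ-like indel spectrum,
  mixed-template trace rendering with IUPAC near-tie calls, clone
  sampling) that provides ground truth for closed-loop validation.

## Worked example

```r
library(mosaicedit)

ex    <- example_paralog_loci(20)        # three paralogs + two guides
locus <- ex$loci$rho.L
cut   <- ex$cut_sites[["universal"]]     # 277 (0-based)

# which paralogs does each guide hit?
run_guide_scan(ex$guides, ex$loci, max_mismatch = 2)[, c(1, 2, 6)]
#>  guide   locus_id n_mismatch
#>  sgUni   rho.L    0          # universal guide: exact in all three
#>  sgUni   rho.2.L  0
#>  sgUni   rho.S    0
#>  sgSel   rho.L    0          # selective guide: exact only in rho.L,
#>  sgSel   rho.2.L  2          # two mismatches (positions 1 and 6)
#>  sgSel   rho.S    2          # in the sibling copies

# simulate an 80%-edited mosaic animal, then analyze it end to end
res <- run_closed_loop(locus, cut, editing_fraction = 0.8, seed = 20)
res$summary
#> $baseline_fidelity 1        # clean trace upstream of the cut
#> $post_cut_fidelity 0.475    # heavily degraded after it
#> $fidelity_drop     0.525
#> $onset_position    276      # miscalling starts ~2 bp before the cut
res$recovery
#> $net_change_concordance  1  # all 24 clones recover the true indel size
#> $frame_class_concordance 1  # and the true frame consequence
table(res$calls$frame_class)
#> frameshift  in_frame  wildtype
#>         18         4         2
```

The fidelity drop is ~0 for an unedited sample and rises with the
editing fraction (0 / 0.004 / 0.39 / 0.49 / 0.71 at fractions
0 / 0.2 / 0.5 / 0.8 / 1.0, averaged over 10 seeds — see
`analysis/05_closed_loop.R`).

## Analysis workflow

The numbered scripts under `analysis/` run the whole study-style
workflow on the example paralog trio, writing tables under `results/`:

1. `01_simulate.R` — mosaic samples at editing fractions 0–0.8 (peak
   report CSVs, clone FASTA, ground-truth JSON)
2. `02_trace_fidelity.R` — fidelity profiles + cross-sample summary
3. `03_clone_indels.R` — clone indel calls, frame classes, paralog
   assignment
4. `04_guide_specificity.R` — guide × paralog match table, re-cleavage
   check of an HDR template carrying two silent mutations
5. `05_closed_loop.R` — ground-truth recovery and drop-vs-fraction
   monotonicity

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

## Not in scope

Binary `.ab1` chromatogram parsing (the package consumes tabular
base-call exports), TIDE/ICE-style trace deconvolution, genome-wide
off-target scoring, and any wet-lab statistics.
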