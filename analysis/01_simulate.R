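#!/usr/bin/env Rscript
# Stage 1: build the example paralog trio and simulate mosaic F0-style
# samples at a range of editing fractions with the universal guide.
# Writes, per sample: the mixed-template trace and WT control as
# peak-report CSVs, sampled clone sequences as FASTA, and the ground-truth
# sidecar JSON.

suppressMessages(library(mosaicedit))

out_root <- "results/simulated"
seed <- 20L

ex <- example_paralog_loci(seed)
locus <- ex$loci$rho.L
cut <- unname(ex$cut_sites["universal"])

dir.create("results", showWarnings = FALSE)
write_reference(ex$loci, "results/example_loci.fasta")

fractions <- c(0, 0.2, 0.5, 0.8)
for (f in fractions) {
  dir <- file.path(out_root, sprintf("fraction_%02d", round(100 * f)))
  sim <- run_simulation(locus, cut, f, dir, n_distinct_edits = 4L,
                        seed = seed, n_clones = 24L)
  n_edited <- sum(!sim$clones$is_wt)
  cat(sprintf(
    "editing fraction %.1f: %d templates, %d/%d sampled clones edited -> %s\n",
    f, length(sim$population$templates), n_edited, nrow(sim$clones), dir))
}
cat(sprintf("cut site (0-based, %s): %d; guide %s\n", locus$id, cut,
            ex$guides$universal$name))
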