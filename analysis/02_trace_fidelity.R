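#!/usr/bin/env Rscript
# Stage 2: per-base sequence fidelity profiling of each simulated sample
# against its WT control read, reading the peak-report CSVs back from
# disk exactly as an analysis of real exports would. Writes per-sample
# profile TSVs plus a cross-sample summary table.

suppressMessages(library(mosaicedit))

ex <- example_paralog_loci(20L)
cut <- unname(ex$cut_sites["universal"])
cut_read <- cut + 1L  # reads start at locus coordinate 0

dirs <- list.dirs("results/simulated", recursive = FALSE)
stopifnot(length(dirs) > 0)

rows <- lapply(dirs, function(d) {
  res <- run_profile(file.path(d, "sample_trace.csv"),
                     file.path(d, "wt_trace.csv"),
                     cut_site = cut_read, out_dir = d)
  s <- res$summary
  data.frame(sample = basename(d),
             baseline_fidelity = round(s$baseline_fidelity, 4),
             post_cut_fidelity = round(s$post_cut_fidelity, 4),
             fidelity_drop = round(s$fidelity_drop, 4),
             onset_position = s$onset_position)
})
summary_tab <- do.call(rbind, rows)
write.table(summary_tab, "results/fidelity_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("cut at read position %d; moving-average window 10\n", cut_read))
print(summary_tab, row.names = FALSE)
cat("fidelity stays ~1 upstream of the cut and falls after it in",
    "proportion to the editing fraction\n")
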