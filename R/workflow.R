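#' Workflow drivers
#'
#' One exported driver per analysis stage, mirroring the study's workflow:
#' simulate a mosaic population, profile a trace against the WT control,
#' call indels in clones, scan guides across paralogs, and run the whole
#' simulate-then-analyze loop with a recovery report. The numbered scripts
#' under \code{analysis/} are thin narrative wrappers over these.
#'
#' @name workflow
NULL

#' Simulate a mosaic sample and write its artifacts
#'
#' Writes the peak-report CSV of the mixed-template trace, the WT control
#' peak report, a clone multi-FASTA, and a ground-truth JSON sidecar.
#'
#' @param locus a \code{reference_locus}.
#' @param cut_site 0-based cut coordinate.
#' @param editing_fraction fraction of edited templates.
#' @param out_dir output directory (created if absent).
#' @param n_distinct_edits,spectrum,seed passed to
#'   [simulate_population()].
#' @param n_clones clones to sample.
#' @param read_start,read_len,ambiguity_ratio,noise_rate passed to
#'   [render_mixture_trace()].
#' @return invisible list with the population, trace, clones, and file
#'   paths.
#' @export
run_simulation <- function(locus, cut_site, editing_fraction, out_dir,
                           n_distinct_edits = 4L,
                           spectrum = indel_spectrum(), seed = 1L,
                           n_clones = 24L, read_start = 0L,
                           read_len = NULL, ambiguity_ratio = 0.25,
                           noise_rate = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(read_len)) read_len <- nchar(locus$seq) - read_start
  pop <- simulate_population(locus, cut_site, editing_fraction,
                             n_distinct_edits, spectrum, seed)
  trace <- render_mixture_trace(pop, read_start, read_len,
                                ambiguity_ratio, noise_rate, seed)
  wt_chars <- strsplit(locus$seq, "", fixed = TRUE)[[1]]
  wt_window <- wt_chars[seq.int(read_start + 1L,
                                min(read_start + read_len, nchar(locus$seq)))]
  wt_trace <- trace_read(paste0(locus$id, "_WT"), wt_window)
  clones <- sample_clones(pop, n_clones, seed)
  paths <- list(
    trace_csv = file.path(out_dir, "sample_trace.csv"),
    wt_csv = file.path(out_dir, "wt_trace.csv"),
    clones_fa = file.path(out_dir, "clones.fasta"),
    truth_json = file.path(out_dir, "truth.json"))
  write_peak_report(trace, paths$trace_csv, seed = seed)
  write_peak_report(wt_trace, paths$wt_csv, seed = seed)
  write_clone_fasta(clones, paths$clones_fa)
  write_truth_json(pop, paths$truth_json)
  invisible(list(population = pop, trace = trace, wt_trace = wt_trace,
                 clones = clones, paths = paths))
}

#' Profile an experimental trace against the WT control
#'
#' @param exp,wt \code{trace_read} objects (or paths to peak reports).
#' @param cut_site optional cut coordinate in WT read coordinates
#'   (1-based).
#' @param out_dir optional output directory for the score TSV and summary
#'   JSON.
#' @param rule,window passed to [compute_fidelity_profile()].
#' @return list with \code{profile} and (when a cut site is given)
#'   \code{summary}.
#' @export
run_profile <- function(exp, wt, cut_site = NULL, out_dir = NULL,
                        rule = scoring_rule(), window = 10L) {
  if (is.character(exp)) exp <- read_peak_report(exp)
  if (is.character(wt)) wt <- read_peak_report(wt)
  profile <- compute_fidelity_profile(exp, wt, rule, window, cut_site)
  summary <- NULL
  if (!is.null(cut_site)) summary <- summarize_editing(profile)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile_tsv(profile, file.path(out_dir, "fidelity_profile.tsv"))
    if (!is.null(summary)) {
      write_summary_json(c(list(sample_id = profile$sample_id,
                                cut_site = cut_site), summary),
                         file.path(out_dir, "editing_summary.json"))
    }
  }
  list(profile = profile, summary = summary)
}

#' Call indels in a clone set and write the call tables
#'
#' @param clones named character vector of clone sequences, a
#'   \code{DNAStringSet}, or a path to a multi-FASTA.
#' @param locus a \code{reference_locus}.
#' @param out_dir optional output directory for the TSV and VCF-flavored
#'   outputs.
#' @param ... passed to [call_indels()].
#' @return the calls data.frame.
#' @export
run_indel_analysis <- function(clones, locus, out_dir = NULL, ...) {
  if (is.character(clones) && length(clones) == 1L &&
      file.exists(clones)) {
    set <- Biostrings::readDNAStringSet(clones)
    names(set) <- sub("\\s.*$", "", names(set))
    clones <- set
  }
  calls <- call_indels(clones, locus, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_indel_tsv(calls, file.path(out_dir, "indel_calls.tsv"))
    write_indel_vcf(calls, locus, file.path(out_dir, "indel_calls.vcf"))
  }
  calls
}

#' Scan guides across loci and check HDR re-cleavage protection
#'
#' @param guides list of \code{guide_rna} (or a path to a guide table).
#' @param loci list of \code{reference_locus}.
#' @param max_mismatch mismatch tolerance.
#' @param out_dir optional output directory for match TSV/BED.
#' @return data.frame of matches across all guide x locus pairs.
#' @export
run_guide_scan <- function(guides, loci, max_mismatch = 3L,
                           out_dir = NULL) {
  if (is.character(guides)) guides <- read_guide_table(guides)
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  if (inherits(loci, "reference_locus")) loci <- list(loci)
  rows <- list()
  for (g in guides) {
    for (locus in loci) {
      m <- find_target_sites(g, locus, max_mismatch)
      if (nrow(m)) {
        m <- cbind(guide = g$name, m, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- m
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(guide = character(0), locus_id = character(0),
               strand = character(0), start = integer(0),
               end = integer(0), n_mismatch = integer(0),
               mismatch_positions = I(list()), cut = integer(0))
  rownames(matches) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_guide_matches(matches,
                        tsv_path = file.path(out_dir, "guide_matches.tsv"),
                        bed_path = file.path(out_dir, "guide_matches.bed"))
  }
  matches
}

#' Simulate then analyze: the full closed loop with a recovery report
#'
#' Simulates a mosaic sample, renders and profiles its trace, calls
#' indels on its sampled clones, and compares every result against the
#' simulator's ground truth.
#'
#' @inheritParams run_simulation
#' @param out_dir optional output directory; when given, all stage
#'   artifacts plus a \code{recovery_report.json} are written.
#' @return list with \code{summary} (editing summary), \code{calls}
#'   (clone indel calls), and \code{recovery} — a list with
#'   \code{net_change_concordance} and \code{frame_class_concordance}
#'   (fractions of clones whose called values equal ground truth).
#' @export
run_closed_loop <- function(locus, cut_site, editing_fraction,
                            out_dir = NULL, n_distinct_edits = 4L,
                            spectrum = indel_spectrum(), seed = 1L,
                            n_clones = 24L, noise_rate = 0) {
  sim_dir <- if (is.null(out_dir)) tempfile("mosaicedit_sim_") else
    file.path(out_dir, "simulated")
  sim <- run_simulation(locus, cut_site, editing_fraction, sim_dir,
                        n_distinct_edits = n_distinct_edits,
                        spectrum = spectrum, seed = seed,
                        n_clones = n_clones, noise_rate = noise_rate)
  # read starts at locus coordinate 0, so 0-based locus coordinate c is
  # 1-based read position c + 1: the first post-cleavage read position
  prof <- run_profile(sim$trace, sim$wt_trace, cut_site = cut_site + 1L,
                      out_dir = out_dir)
  calls <- run_indel_analysis(
    stats::setNames(sim$clones$seq, sim$clones$clone_id), locus,
    out_dir = out_dir)
  recovery <- list(
    n_clones = nrow(calls),
    net_change_concordance =
      mean(calls$net_change == sim$clones$true_net_change),
    frame_class_concordance =
      mean(calls$frame_class == sim$clones$true_frame_class))
  if (!is.null(out_dir)) {
    write_summary_json(recovery,
                       file.path(out_dir, "recovery_report.json"))
  }
  list(simulation = sim, profile = prof$profile, summary = prof$summary,
       calls = calls, recovery = recovery)
}
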