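#' Synthetic mosaic-editing simulator
#'
#' Injected embryos are genetic mosaics: each animal carries a population
#' of templates with different NHEJ repair outcomes at the Cas9 cut site.
#' The simulator generates such populations with a configurable indel
#' spectrum, renders the mixed-template Sanger read they would produce
#' (primary/secondary base calls, with IUPAC codes at near-ties), and
#' samples plasmid clones from the population — providing ground truth
#' for every stage of the analysis.
#'
#' @name synthetic_data
NULL

#' NHEJ indel spectrum configuration
#'
#' Defaults encode the qualitative spectrum seen in cloned amplicons:
#' small deletions under 20 bp dominate, insertions and simultaneous
#' deletion+insertions occur occasionally, and a rare deletion exceeds
#' 100 bp. Lengths are geometric (monotone decreasing, the simplest
#' family with that property), truncated at \code{max_len}; large
#' deletions are a separate uniform 100-150 bp component.
#'
#' @param p_deletion,p_insertion,p_compound event-type probabilities;
#'   must sum to 1.
#' @param del_mean,ins_mean geometric mean lengths (bp).
#' @param max_len truncation for the geometric components.
#' @param p_large_del probability a deletion event is drawn from the
#'   large-deletion component instead.
#' @param large_del_range inclusive bp range of large deletions.
#' @param placement_jitter maximum offset (bp) of the event midpoint from
#'   the cut site.
#' @return an object of class \code{indel_spectrum}.
#' @export
indel_spectrum <- function(p_deletion = 0.70, p_insertion = 0.15,
                           p_compound = 0.15, del_mean = 4, ins_mean = 2,
                           max_len = 30L, p_large_del = 0.01,
                           large_del_range = c(100L, 150L),
                           placement_jitter = 5L) {
  stopifnot(abs(p_deletion + p_insertion + p_compound - 1) < 1e-12,
            del_mean >= 1, ins_mean >= 1, max_len >= 1L,
            p_large_del >= 0, p_large_del <= 1,
            placement_jitter >= 0L)
  structure(list(p_deletion = p_deletion, p_insertion = p_insertion,
                 p_compound = p_compound, del_mean = del_mean,
                 ins_mean = ins_mean, max_len = as.integer(max_len),
                 p_large_del = p_large_del,
                 large_del_range = as.integer(large_del_range),
                 placement_jitter = as.integer(placement_jitter)),
            class = "indel_spectrum")
}

# geometric on {1, 2, ...} with the given mean, truncated by rejection
.rgeom_len <- function(mean_len, max_len) {
  repeat {
    x <- 1L + stats::rgeom(1L, prob = 1 / mean_len)
    if (x <= max_len) return(x)
  }
}

# draw one edit near the cut site; returns (del_start, del_end, ins_seq)
.draw_edit <- function(spectrum, cut_site, seq_len) {
  for (attempt in 1:100) {
    type <- sample(c("deletion", "insertion", "compound"), 1L,
                   prob = c(spectrum$p_deletion, spectrum$p_insertion,
                            spectrum$p_compound))
    jitter <- if (spectrum$placement_jitter > 0L) {
      sample(seq.int(-spectrum$placement_jitter,
                     spectrum$placement_jitter), 1L)
    } else 0L
    mid <- cut_site + jitter
    del_len <- 0L
    ins_seq <- ""
    if (type %in% c("deletion", "compound")) {
      del_len <- if (stats::runif(1) < spectrum$p_large_del) {
        sample(seq.int(spectrum$large_del_range[1],
                       spectrum$large_del_range[2]), 1L)
      } else {
        .rgeom_len(spectrum$del_mean, spectrum$max_len)
      }
    }
    if (type %in% c("insertion", "compound")) {
      ins_len <- .rgeom_len(spectrum$ins_mean, spectrum$max_len)
      ins_seq <- paste(sample(c("A", "C", "G", "T"), ins_len,
                              replace = TRUE), collapse = "")
    }
    d0 <- mid - del_len %/% 2L
    d1 <- d0 + del_len
    if (d0 >= 1L && d1 <= seq_len - 1L) {
      return(list(del_start = d0, del_end = d1, ins_seq = ins_seq))
    }
  }
  stop("could not place an edit inside the locus after 100 attempts",
       call. = FALSE)
}

#' Simulate a mosaic population of edited templates
#'
#' Produces \code{n_distinct_edits} distinct edited templates whose
#' weights are symmetric-Dirichlet(1) distributed and sum to
#' \code{editing_fraction}, plus one wildtype template carrying the
#' remaining weight. Every template records its ground-truth edit.
#' Deterministic given \code{seed}.
#'
#' @param locus a \code{reference_locus} with at least 200 nt on each
#'   side of the cut.
#' @param cut_site 0-based cut coordinate on the locus (cleavage between
#'   \code{cut_site - 1} and \code{cut_site}).
#' @param editing_fraction total weight of edited templates, in
#'   \code{[0, 1]}.
#' @param n_distinct_edits number of distinct edited lineages.
#' @param spectrum an \code{indel_spectrum}.
#' @param seed integer RNG seed.
#' @return an object of class \code{mosaic_population}: list with
#'   \code{locus_id}, \code{cut_site}, \code{editing_fraction},
#'   \code{seed}, and \code{templates} — a list of
#'   \code{list(seq, weight, truth)} where \code{truth} is an
#'   \code{indel_call} or \code{NULL} for wildtype.
#' @export
simulate_population <- function(locus, cut_site, editing_fraction,
                                n_distinct_edits = 4L,
                                spectrum = indel_spectrum(), seed = 1L) {
  stopifnot(inherits(locus, "reference_locus"),
            editing_fraction >= 0, editing_fraction <= 1,
            n_distinct_edits >= 1L)
  n <- nchar(locus$seq)
  if (cut_site < 200L || cut_site > n - 200L) {
    stop("cut site needs >= 200 nt flanks inside the locus", call. = FALSE)
  }
  templates <- with_local_seed(seed, {
    tpl <- list()
    if (editing_fraction > 0) {
      seqs_seen <- character(0)
      edits <- list()
      guard <- 0L
      while (length(edits) < n_distinct_edits) {
        guard <- guard + 1L
        if (guard > 100L * n_distinct_edits) {
          stop("could not draw distinct edits", call. = FALSE)
        }
        e <- .draw_edit(spectrum, cut_site, n)
        truth <- .indel_call(locus$id, e$del_start, e$del_end, e$ins_seq)
        truth$frame_class <- classify_frame(truth, locus)
        seq <- apply_indel(truth, locus)
        if (seq %in% seqs_seen || seq == locus$seq) next
        seqs_seen <- c(seqs_seen, seq)
        edits[[length(edits) + 1L]] <- list(seq = seq, truth = truth)
      }
      w <- stats::rgamma(n_distinct_edits, shape = 1)
      w <- w / sum(w) * editing_fraction
      tpl <- lapply(seq_along(edits), function(i) {
        list(seq = edits[[i]]$seq, weight = w[i], truth = edits[[i]]$truth)
      })
    }
    if (editing_fraction < 1) {
      tpl[[length(tpl) + 1L]] <- list(seq = locus$seq,
                                      weight = 1 - editing_fraction,
                                      truth = NULL)
    }
    tpl
  })
  structure(
    list(locus_id = locus$id, cut_site = as.integer(cut_site),
         editing_fraction = editing_fraction, seed = as.integer(seed),
         templates = templates),
    class = "mosaic_population"
  )
}

#' @export
print.mosaic_population <- function(x, ...) {
  cat(sprintf(
    "<mosaic_population> %s: %d template(s), editing fraction %.2f, cut at %d (seed %d)\n",
    x$locus_id, length(x$templates), x$editing_fraction, x$cut_site,
    x$seed))
  invisible(x)
}

#' Render the mixed-template Sanger read of a mosaic population
#'
#' Each template contributes, at read position j, the base at its own
#' coordinate \code{read_start + j} — so registers shift downstream of
#' each template's indel, exactly as a sequencing primer reading through
#' a template mixture would. The weighted base distribution at each
#' position yields the primary (heaviest) and secondary (runner-up)
#' calls; when the runner-up carries at least \code{ambiguity_ratio} of
#' the top base's weight the primary is emitted as the two-base IUPAC
#' code. Positions past a template's end contribute no signal. Flat
#' miscall noise replaces the primary call at rate \code{noise_rate}.
#' Deterministic given \code{seed}.
#'
#' @param pop a \code{mosaic_population}.
#' @param read_start 0-based coordinate where the read begins (common to
#'   all templates: the primer site is upstream of all edits).
#' @param read_len read length in positions.
#' @param ambiguity_ratio runner-up/top weight ratio at or above which an
#'   ambiguous IUPAC primary is called.
#' @param noise_rate per-position probability of an independent miscall.
#' @param seed integer RNG seed (used by the noise process).
#' @return a \code{trace_read}.
#' @export
render_mixture_trace <- function(pop, read_start = 0L,
                                 read_len = 400L, ambiguity_ratio = 0.25,
                                 noise_rate = 0, seed = 1L) {
  stopifnot(inherits(pop, "mosaic_population"), read_len >= 1L)
  bases <- c("A", "C", "G", "T")
  weights <- vapply(pop$templates, `[[`, numeric(1), "weight")
  seqs <- lapply(pop$templates, function(t) {
    strsplit(t$seq, "", fixed = TRUE)[[1]]
  })
  primary <- character(read_len)
  secondary <- character(read_len)
  with_local_seed(seed, {
    for (j in seq_len(read_len)) {
      pos <- read_start + j            # 1-based template index
      mass <- c(A = 0, C = 0, G = 0, T = 0)
      for (t in seq_along(seqs)) {
        if (pos <= length(seqs[[t]])) {
          b <- seqs[[t]][pos]
          mass[b] <- mass[b] + weights[t]
        }
      }
      if (sum(mass) == 0) {
        primary[j] <- "-"; secondary[j] <- "-"
        next
      }
      ord <- order(-mass, bases)       # weight desc, alphabetical ties
      top <- bases[ord[1]]; second <- bases[ord[2]]; third <- bases[ord[3]]
      if (mass[ord[2]] > 0 && mass[ord[2]] / mass[ord[1]] >= ambiguity_ratio) {
        primary[j] <- iupac_code(c(top, second))
        secondary[j] <- if (mass[ord[3]] > 0) third else "-"
      } else {
        primary[j] <- top
        secondary[j] <- if (mass[ord[2]] > 0) second else "-"
      }
      if (noise_rate > 0 && stats::runif(1) < noise_rate) {
        primary[j] <- sample(setdiff(bases, primary[j]), 1L)
      }
    }
  })
  trace_read(sprintf("%s_sim_seed%d", pop$locus_id, seed),
             primary, secondary)
}

#' Sample plasmid clones from a mosaic population
#'
#' Templates are drawn with replacement proportionally to their weights
#' (each cloned PCR molecule derives from one template). Deterministic
#' given \code{seed}.
#'
#' @param pop a \code{mosaic_population}.
#' @param n number of clones.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{clone_id}, \code{seq},
#'   \code{template_index}, \code{is_wt}, \code{true_net_change},
#'   \code{true_frame_class}.
#' @export
sample_clones <- function(pop, n, seed = 1L) {
  stopifnot(inherits(pop, "mosaic_population"), n >= 1L)
  weights <- vapply(pop$templates, `[[`, numeric(1), "weight")
  idx <- with_local_seed(seed, {
    sample.int(length(pop$templates), n, replace = TRUE, prob = weights)
  })
  truth_net <- vapply(pop$templates, function(t) {
    if (is.null(t$truth)) 0L else t$truth$net_change
  }, integer(1))
  truth_frame <- vapply(pop$templates, function(t) {
    if (is.null(t$truth)) "wildtype" else t$truth$frame_class
  }, character(1))
  data.frame(
    clone_id = sprintf("clone_%04d", seq_len(n)),
    seq = vapply(pop$templates[idx], `[[`, "", "seq"),
    template_index = idx,
    is_wt = vapply(pop$templates[idx], function(t) is.null(t$truth),
                   logical(1)),
    true_net_change = truth_net[idx],
    true_frame_class = truth_frame[idx],
    stringsAsFactors = FALSE
  )
}

#' Write sampled clones as multi-FASTA (ground truth in headers)
#' @param clones data.frame from [sample_clones()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clone_fasta <- function(clones, path) {
  seqs <- Biostrings::DNAStringSet(clones$seq)
  names(seqs) <- sprintf("%s template=%d net=%d frame=%s",
                         clones$clone_id, clones$template_index,
                         clones$true_net_change, clones$true_frame_class)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write the population's ground truth as JSON
#' @param pop a \code{mosaic_population}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_json <- function(pop, path) {
  truth <- lapply(pop$templates, function(t) {
    if (is.null(t$truth)) {
      list(type = "wildtype", weight = t$weight)
    } else {
      list(type = "edited", weight = t$weight,
           del_start = t$truth$del_start, del_end = t$truth$del_end,
           ins_seq = t$truth$ins_seq, net_change = t$truth$net_change,
           frame_class = t$truth$frame_class)
    }
  })
  jsonlite::write_json(
    list(locus_id = pop$locus_id, cut_site = pop$cut_site,
         editing_fraction = pop$editing_fraction, seed = pop$seed,
         templates = truth),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
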