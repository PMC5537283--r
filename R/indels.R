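#' Indel calling from cloned amplicon sequences
#'
#' Each sequenced plasmid clone carries one NHEJ repair outcome: a
#' deletion, an insertion, or a simultaneous deletion+insertion at the cut
#' site. The caller reports a single compound event per clone — the
#' minimal changed interval after maximal trimming of flanking identity —
#' left-aligned (shifted maximally 5'), the VCF normalization convention,
#' so identical outcomes from different clones deduplicate reliably.
#'
#' @name indel_calling
NULL

# longest common prefix / suffix lengths of two character strings
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

.lcs <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "", fixed = TRUE)[[1]])
  bv <- rev(strsplit(b, "", fixed = TRUE)[[1]])
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

#' Percent identity of a clone against a reference (affine-gap global)
#'
#' Global alignment with affine gap penalties; scoring favors one compact
#' indel over scattered mismatches. Parameters are overridable.
#'
#' @param clone_seq,ref_seq DNA strings.
#' @param match,mismatch,gap_open,gap_extend alignment scores (costs are
#'   positive for the gap parameters).
#' @return identity in \code{[0, 1]}: matched positions over alignment
#'   length.
#' @export
alignment_identity <- function(clone_seq, ref_seq, match = 2,
                               mismatch = -3, gap_open = 5,
                               gap_extend = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(clone_seq), Biostrings::DNAString(ref_seq),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Call the indel carried by one clone against a reference locus
#'
#' The event is the minimal changed interval: flanking identity is trimmed
#' maximally from the 3' end first, then from the 5' end, which places any
#' placement-degenerate indel (e.g. a deletion inside a repeat) at its
#' 5'-most equivalent position. A deletion and insertion at one site is
#' reported as a single compound call.
#'
#' @param clone_seq A/C/G/T DNA string covering the reference region.
#' @param locus a \code{reference_locus}.
#' @param min_identity clones below this affine-alignment identity are
#'   rejected as not matching the locus.
#' @param check_identity set \code{FALSE} to skip the alignment identity
#'   screen (e.g. for trusted simulated clones).
#' @return an object of class \code{indel_call}: list with
#'   \code{locus_id}, \code{del_start}, \code{del_end} (0-based half-open;
#'   equal for a pure insertion), \code{ins_seq}, \code{net_change},
#'   \code{frame_class}, \code{protein_consequence}.
#' @export
call_indel <- function(clone_seq, locus, min_identity = 0.7,
                       check_identity = TRUE) {
  stopifnot(inherits(locus, "reference_locus"))
  clone_seq <- toupper(clone_seq)
  if (!grepl("^[ACGT]+$", clone_seq)) {
    stop("clone sequence must be A/C/G/T only", call. = FALSE)
  }
  r <- locus$seq
  nr <- nchar(r); nc <- nchar(clone_seq)
  if (clone_seq == r) {
    call <- .indel_call(locus$id, 0L, 0L, "", frame_class = "wildtype")
    call$protein_consequence <- ""
    return(call)
  }
  if (check_identity) {
    ident <- alignment_identity(clone_seq, r)
    if (ident < min_identity) {
      stop(sprintf("clone does not match locus '%s' (identity %.2f < %.2f)",
                   locus$id, ident, min_identity), call. = FALSE)
    }
  }
  # maximal suffix first, then prefix capped so trims do not overlap:
  # this is the 5'-most (left-aligned) placement of the minimal event
  s <- .lcs(clone_seq, r)
  p <- min(.lcp(clone_seq, r), min(nr, nc) - s)
  del_start <- p
  del_end <- nr - s
  ins_seq <- if (nc - s >= p + 1L) substr(clone_seq, p + 1L, nc - s) else ""
  call <- .indel_call(locus$id, del_start, del_end, ins_seq)
  call$frame_class <- classify_frame(call, locus)
  call$protein_consequence <- protein_consequence(call, locus)
  call
}

.indel_call <- function(locus_id, del_start, del_end, ins_seq,
                        frame_class = NA_character_) {
  structure(
    list(locus_id = locus_id,
         del_start = as.integer(del_start), del_end = as.integer(del_end),
         ins_seq = ins_seq,
         net_change = nchar(ins_seq) - (as.integer(del_end) - as.integer(del_start)),
         frame_class = frame_class,
         protein_consequence = NA_character_),
    class = "indel_call"
  )
}

#' @export
print.indel_call <- function(x, ...) {
  cat(sprintf(
    "<indel_call> %s: del [%d,%d) ins '%s' (net %+d, %s)%s\n",
    x$locus_id, x$del_start, x$del_end, x$ins_seq, x$net_change,
    x$frame_class,
    if (is.na(x$protein_consequence) || x$protein_consequence == "") ""
    else paste0(" ", x$protein_consequence)))
  invisible(x)
}

#' Classify the reading-frame consequence of an indel call
#'
#' \code{start_loss} takes precedence whenever the event removes or
#' interrupts any base of the start ATG; otherwise \code{frameshift} iff
#' the net length change is not a codon multiple, else \code{in_frame}
#' (or \code{wildtype} for a no-op call).
#'
#' @param call an \code{indel_call}.
#' @param locus the \code{reference_locus} it was called against.
#' @return one of \code{"wildtype"}, \code{"in_frame"},
#'   \code{"frameshift"}, \code{"start_loss"}.
#' @export
classify_frame <- function(call, locus) {
  if (call$del_start == call$del_end && call$ins_seq == "") {
    return("wildtype")
  }
  atg0 <- locus$cds_start
  atg1 <- locus$cds_start + 3L
  deletes_atg <- call$del_start < atg1 && call$del_end > atg0
  interrupts_atg <- call$del_start == call$del_end &&
    call$del_start > atg0 && call$del_start < atg1
  if (deletes_atg || interrupts_atg) return("start_loss")
  if (call$net_change %% 3L != 0L) return("frameshift")
  "in_frame"
}

#' Reconstruct the mutant sequence described by an indel call
#' @param call an \code{indel_call}.
#' @param locus the matching \code{reference_locus}.
#' @return DNA string with the event applied.
#' @export
apply_indel <- function(call, locus) {
  r <- locus$seq
  paste0(substr(r, 1L, call$del_start), call$ins_seq,
         substr(r, call$del_end + 1L, nchar(r)))
}

#' Protein consequence of a frame-conserving indel
#'
#' Translates the wildtype and mutant CDS and reports the minimal changed
#' residue run, trimming residues common to both flanks, as
#' \code{"WTRESIDUES->MUTRESIDUES"} (empty side left blank, e.g.
#' \code{"SK->"} for a clean two-residue deletion). Frameshift and
#' start-loss calls return tagged markers rather than residue strings;
#' events wholly outside the CDS return an empty consequence.
#'
#' @param call an \code{indel_call}.
#' @param locus the matching \code{reference_locus}.
#' @return consequence string.
#' @export
protein_consequence <- function(call, locus) {
  fc <- call$frame_class
  if (is.na(fc)) fc <- classify_frame(call, locus)
  if (fc == "wildtype") return("")
  if (fc == "frameshift") return("[frameshift]")
  if (fc == "start_loss") return("[start_loss]")
  cds0 <- locus$cds_start
  cds1 <- locus$cds_start + locus$cds_frame_len
  ev0 <- call$del_start
  ev1 <- call$del_end
  pure_ins <- ev0 == ev1
  outside <- if (pure_ins) ev0 <= cds0 || ev0 >= cds1
             else ev1 <= cds0 || ev0 >= cds1
  if (outside) return("")  # frame-conserving event outside the CDS
  mut <- apply_indel(call, locus)
  wt_cds <- substr(locus$seq, cds0 + 1L, cds1)
  mut_cds <- substr(mut, cds0 + 1L, cds1 + call$net_change)
  wt_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(wt_cds), no.init.codon = TRUE))
  mut_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(mut_cds), no.init.codon = TRUE))
  p <- .lcp(wt_aa, mut_aa)
  s <- min(.lcs(wt_aa, mut_aa), min(nchar(wt_aa), nchar(mut_aa)) - p)
  wt_run <- substr(wt_aa, p + 1L, nchar(wt_aa) - s)
  mut_run <- substr(mut_aa, p + 1L, nchar(mut_aa) - s)
  if (wt_run == "" && mut_run == "") return("")  # synonymous at aa level
  paste0(wt_run, "->", mut_run)
}

#' Assign a clone to its paralog of origin via diagnostic bases
#'
#' Scores each candidate locus by the number of its paralog-diagnostic
#' positions at which the clone carries the expected base (reading through
#' the clone's own indel register). Sites deleted in the clone, or mutated
#' so they match no candidate, simply contribute no support. Ties are
#' reported as ambiguous, never silently broken.
#'
#' @param clone_seq A/C/G/T DNA string.
#' @param loci list of \code{reference_locus} objects, at least one with
#'   diagnostic positions.
#' @param min_identity passed to [call_indel()].
#' @return list with \code{locus_id} (or \code{"ambiguous"}),
#'   \code{support} (named integer vector of matching diagnostic counts),
#'   and \code{detail} (per-locus data.frame of position, expected,
#'   observed).
#' @export
assign_paralog <- function(clone_seq, loci, min_identity = 0.7) {
  has_diag <- vapply(loci, function(l) length(l$diagnostic_positions) > 0L,
                     logical(1))
  if (!any(has_diag)) {
    stop("no locus supplies diagnostic positions", call. = FALSE)
  }
  clone_seq <- toupper(clone_seq)
  support <- integer(0)
  detail <- list()
  for (locus in loci) {
    if (!length(locus$diagnostic_positions)) next
    call <- tryCatch(
      call_indel(clone_seq, locus, min_identity = min_identity),
      error = function(e) NULL)
    if (is.null(call)) {
      support[locus$id] <- 0L
      next
    }
    pos <- as.integer(names(locus$diagnostic_positions))
    expected <- unname(locus$diagnostic_positions)
    observed <- vapply(pos, function(pz) {
      if (pz >= call$del_start && pz < call$del_end) return("-")  # deleted
      cp <- if (pz < call$del_start) pz else pz + call$net_change
      if (cp < 0L || cp >= nchar(clone_seq)) return("-")
      substr(clone_seq, cp + 1L, cp + 1L)
    }, "")
    support[locus$id] <- sum(observed == expected)
    detail[[locus$id]] <- data.frame(
      position = pos, expected = expected, observed = observed,
      match = observed == expected, stringsAsFactors = FALSE)
  }
  top <- support == max(support)
  locus_id <- if (max(support) == 0L || sum(top) > 1L) "ambiguous"
              else names(support)[top]
  list(locus_id = locus_id, support = support, detail = detail)
}

#' Call indels for a set of clones with duplicate reporting
#'
#' Every clone is listed (recurrent identical outcomes carry information
#' about editing timing); identical sequences are additionally grouped and
#' counted.
#'
#' @param clones named character vector of clone sequences (names become
#'   clone ids) or a \code{Biostrings::DNAStringSet}.
#' @param locus a \code{reference_locus}.
#' @param ... passed to [call_indel()].
#' @return data.frame with one row per clone: \code{clone_id},
#'   \code{locus}, \code{del_start}, \code{del_end} (0-based half-open),
#'   \code{ins_seq}, \code{net_change}, \code{frame_class},
#'   \code{protein_consequence}, \code{identical_count} (number of clones
#'   sharing the sequence).
#' @export
call_indels <- function(clones, locus, ...) {
  if (inherits(clones, "DNAStringSet")) {
    clones <- stats::setNames(as.character(clones), names(clones))
  }
  if (is.null(names(clones))) {
    names(clones) <- sprintf("clone_%03d", seq_along(clones))
  }
  counts <- table(unname(clones))
  rows <- lapply(names(clones), function(id) {
    call <- call_indel(clones[[id]], locus, ...)
    data.frame(clone_id = id, locus = call$locus_id,
               del_start = call$del_start, del_end = call$del_end,
               ins_seq = call$ins_seq, net_change = call$net_change,
               frame_class = call$frame_class,
               protein_consequence = call$protein_consequence,
               identical_count = as.integer(counts[[clones[[id]]]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write indel calls as TSV (1-based inclusive coordinates)
#' @param calls data.frame from [call_indels()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_indel_tsv <- function(calls, path) {
  out <- calls
  # human-facing: 1-based inclusive deleted interval; 0-length -> NA
  out$del_first <- ifelse(out$del_end > out$del_start, out$del_start + 1L, NA)
  out$del_last <- ifelse(out$del_end > out$del_start, out$del_end, NA)
  out$del_start <- NULL; out$del_end <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mosaicedit %s indel calls (1-based inclusive)",
                     as.character(utils::packageVersion("mosaicedit"))), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write indel calls in a VCF-flavored format
#'
#' Minimal VCF 4.2: 1-based positions with an anchor base preceding the
#' event (or following it, when the event abuts the sequence start).
#'
#' @param calls data.frame from [call_indels()].
#' @param locus the \code{reference_locus} the calls were made against.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_indel_vcf <- function(calls, locus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=mosaicedit-%s",
            as.character(utils::packageVersion("mosaicedit"))),
    sprintf("##contig=<ID=%s,length=%d>", locus$id, nchar(locus$seq)),
    "##INFO=<ID=CLONE,Number=1,Type=String,Description=\"Clone id\">",
    "##INFO=<ID=FRAME,Number=1,Type=String,Description=\"Frame class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  r <- locus$seq
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (row$frame_class == "wildtype") next
    d0 <- row$del_start; d1 <- row$del_end
    if (d0 > 0L) {                                 # anchor before event
      pos <- d0                                     # 1-based anchor coord
      ref <- substr(r, d0, d1)
      alt <- paste0(substr(r, d0, d0), row$ins_seq)
    } else {                                        # event at position 1
      pos <- 1L
      ref <- substr(r, 1L, d1 + 1L)
      alt <- paste0(row$ins_seq, substr(r, d1 + 1L, d1 + 1L))
    }
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tCLONE=%s;FRAME=%s",
                       locus$id, pos, row$clone_id, ref, alt,
                       row$clone_id, row$frame_class), con)
  }
  invisible(path)
}
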