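#' Reference loci and trace reads
#'
#' A `reference_locus` is a wildtype gene sequence with the coordinates
#' needed to interpret edits: the 0-based offset of the start ATG, the
#' annotated CDS length, and (optionally) paralog-diagnostic positions —
#' bases that distinguish the locus from a named sibling gene copy.
#' Internal coordinates are 0-based half-open throughout the package;
#' human-facing tables are 1-based inclusive.
#'
#' @name reference
NULL

#' Construct a reference locus
#'
#' @param id locus name (e.g. \code{"rho.L"}).
#' @param seq wildtype DNA string, A/C/G/T only (lowercase tolerated).
#' @param cds_start 0-based offset of the A of the start ATG.
#' @param cds_frame_len length in nt of the annotated coding sequence;
#'   defaults to the remainder of the sequence truncated to a codon
#'   multiple.
#' @param diagnostic_positions named integer vector: names are 0-based
#'   positions, values the expected base distinguishing this locus from a
#'   sibling — or a list-like of \code{position = base}. May be empty.
#' @return an object of class \code{reference_locus}.
#' @export
reference_locus <- function(id, seq, cds_start = 0L, cds_frame_len = NULL,
                            diagnostic_positions = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
    stop("reference sequence for '", id,
         "' contains non-ACGT characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cds_start <- as.integer(cds_start)
  n <- nchar(seq)
  if (cds_start < 0L || cds_start >= n) {
    stop("cds_start out of range for '", id, "'", call. = FALSE)
  }
  if (substr(seq, cds_start + 1L, cds_start + 3L) != "ATG") {
    stop("cds_start of '", id, "' does not point at an ATG (found '",
         substr(seq, cds_start + 1L, cds_start + 3L), "')", call. = FALSE)
  }
  if (is.null(cds_frame_len)) {
    cds_frame_len <- ((n - cds_start) %/% 3L) * 3L
  }
  cds_frame_len <- as.integer(cds_frame_len)
  stopifnot(cds_frame_len >= 3L, cds_start + cds_frame_len <= n)
  diag <- character(0)
  if (!is.null(diagnostic_positions) && length(diagnostic_positions)) {
    diag <- vapply(diagnostic_positions, function(b) canonical_base(b), "")
    pos <- as.integer(names(diagnostic_positions))
    if (anyNA(pos) || any(pos < 0L) || any(pos >= n)) {
      stop("diagnostic positions must be 0-based offsets inside the sequence",
           call. = FALSE)
    }
    names(diag) <- pos
  }
  structure(
    list(id = id, seq = seq, cds_start = cds_start,
         cds_frame_len = cds_frame_len, diagnostic_positions = diag),
    class = "reference_locus"
  )
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf(
    "<reference_locus> %s: %d nt, CDS at %d (+%d nt), %d diagnostic base(s)\n",
    x$id, nchar(x$seq), x$cds_start, x$cds_frame_len,
    length(x$diagnostic_positions)))
  invisible(x)
}

#' Load reference loci from a FASTA file
#'
#' Each FASTA record becomes one locus, keyed by its header id. Per-locus
#' metadata (CDS start, diagnostic positions) comes from a metadata list
#' keyed the same way.
#'
#' @param fasta_path path to a (single-line or wrapped) FASTA file.
#' @param metadata named list; each element a list with \code{cds_start}
#'   and optionally \code{cds_frame_len} and \code{diagnostic_positions}.
#'   Loci absent from \code{metadata} get \code{cds_start = 0}.
#' @return named list of \code{reference_locus} objects.
#' @export
load_reference <- function(fasta_path, metadata = list()) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(set))
  loci <- lapply(seq_along(set), function(i) {
    md <- metadata[[ids[i]]]
    if (is.null(md)) md <- list()
    reference_locus(
      id = ids[i],
      seq = as.character(set[[i]]),
      cds_start = md$cds_start %||% 0L,
      cds_frame_len = md$cds_frame_len,
      diagnostic_positions = md$diagnostic_positions
    )
  })
  names(loci) <- ids
  loci
}

#' Write loci back to FASTA (round-trips the sequence byte-identically)
#' @param loci list of \code{reference_locus} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_reference <- function(loci, path) {
  if (inherits(loci, "reference_locus")) loci <- list(loci)
  seqs <- Biostrings::DNAStringSet(vapply(loci, `[[`, "", "seq"))
  names(seqs) <- vapply(loci, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a trace read from primary/secondary base calls
#'
#' A trace read is the per-position export of one Sanger sequencing
#' reaction: at each read position, the most probable (primary) and second
#' most probable (secondary) base call. Positions are 1-based read
#' coordinates and must be contiguous from 1 after loading; gaps are
#' represented by \code{"-"} records.
#'
#' @param sample_id sample label.
#' @param primary,secondary character vectors of equal length; IUPAC
#'   symbols and \code{"-"} allowed.
#' @return an object of class \code{trace_read}.
#' @export
trace_read <- function(sample_id, primary, secondary = NULL) {
  primary <- canonical_base(primary)
  if (is.null(secondary)) secondary <- rep("-", length(primary))
  secondary <- canonical_base(secondary)
  stopifnot(length(primary) == length(secondary), length(primary) > 0L)
  structure(
    list(sample_id = sample_id,
         calls = data.frame(position = seq_along(primary),
                            primary = primary, secondary = secondary,
                            stringsAsFactors = FALSE)),
    class = "trace_read"
  )
}

#' @export
print.trace_read <- function(x, ...) {
  cat(sprintf("<trace_read> %s: %d positions\n",
              x$sample_id, nrow(x$calls)))
  invisible(x)
}

#' @export
length.trace_read <- function(x) nrow(x$calls)
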