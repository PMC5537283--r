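#' sgRNA target-site scanning
#'
#' SpCas9 recognizes a 20-nt protospacer immediately 5' of an NGG PAM and
#' cleaves bluntly 3 nt 5' of the PAM (between protospacer positions 17 and
#' 18). Paralog selectivity in a duplicated genome comes down to counting
#' protospacer mismatches per gene copy: a guide with an exact match in one
#' paralog and two mismatches in its sibling cuts only the former.
#'
#' Protospacer positions are numbered 1..20 from the PAM-distal (5') end of
#' the guide; every report states this convention.
#'
#' @name guide_targeting
NULL

#' Construct a guide RNA
#'
#' @param name guide name (e.g. \code{"rhosg1"}).
#' @param protospacer 20-nt DNA string, A/C/G/T only.
#' @param pam_rule PAM pattern; only \code{"NGG"} is supported.
#' @return an object of class \code{guide_rna}.
#' @export
guide_rna <- function(name, protospacer, pam_rule = "NGG") {
  protospacer <- toupper(protospacer)
  chars <- strsplit(protospacer, "", fixed = TRUE)[[1]]
  if (length(chars) != 20L || !all(chars %in% c("A", "C", "G", "T"))) {
    stop("protospacer must be exactly 20 nt of A/C/G/T", call. = FALSE)
  }
  if (!identical(toupper(pam_rule), "NGG")) {
    stop("only the NGG PAM is supported", call. = FALSE)
  }
  structure(list(name = name, protospacer = protospacer, pam_rule = "NGG"),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s: %s-NGG\n", x$name, x$protospacer))
  invisible(x)
}

# scan one strand of a plain sequence; returns 0-based + strand intervals.
# `offset_map` converts a start index on the scanned string back to a
# + strand interval start (identity for + scans).
.scan_strand <- function(guide_chars, seq_chars, max_mismatch) {
  n <- length(seq_chars)
  if (n < 23L) {
    return(data.frame(start = integer(0),
                      mismatches = I(list()),
                      stringsAsFactors = FALSE))
  }
  starts <- seq_len(n - 22L)  # 1-based window starts, window = 20 + 3 PAM
  # PAM occupies window positions 21..23; N is free, 22 and 23 must be G
  pam_ok <- seq_chars[starts + 21L] == "G" & seq_chars[starts + 22L] == "G"
  starts <- starts[pam_ok]
  if (!length(starts)) {
    return(data.frame(start = integer(0), mismatches = I(list()),
                      stringsAsFactors = FALSE))
  }
  # mismatch count per candidate window, vectorized over windows
  mm_count <- integer(length(starts))
  mm_list <- vector("list", length(starts))
  win <- outer(starts - 1L, 1:20, `+`)        # index matrix [window, pos]
  hit <- matrix(seq_chars[win], nrow = length(starts)) !=
    matrix(guide_chars, nrow = length(starts), ncol = 20L, byrow = TRUE)
  mm_count <- rowSums(hit)
  keep <- which(mm_count <= max_mismatch)
  data.frame(
    start = starts[keep] - 1L,               # back to 0-based
    mismatches = I(lapply(keep, function(i) which(hit[i, ]))),
    stringsAsFactors = FALSE
  )
}

#' Find sgRNA target sites in a reference locus
#'
#' Scans every 23-nt window on both strands of the locus. A window
#' qualifies when its 3-nt PAM flank matches NGG (mandatory, regardless of
#' \code{max_mismatch}) and its 20-nt protospacer differs from the guide at
#' no more than \code{max_mismatch} positions.
#'
#' @param guide a \code{guide_rna}.
#' @param locus a \code{reference_locus}, or a plain DNA string.
#' @param max_mismatch maximum protospacer mismatches, 0..20.
#' @return data.frame with one row per match: \code{locus_id},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open protospacer
#'   interval on the + strand), \code{n_mismatch}, \code{mismatch_positions}
#'   (list column, 1-based from the PAM-distal end), and \code{cut}
#'   (0-based + strand coordinate; cleavage falls between \code{cut - 1}
#'   and \code{cut}). Sorted by position then strand.
#' @export
find_target_sites <- function(guide, locus, max_mismatch = 0L) {
  stopifnot(inherits(guide, "guide_rna"),
            max_mismatch >= 0L, max_mismatch <= 20L)
  if (inherits(locus, "reference_locus")) {
    locus_id <- locus$id
    seq <- locus$seq
  } else {
    locus_id <- "seq"
    seq <- toupper(as.character(locus))
  }
  n <- nchar(seq)
  g <- strsplit(guide$protospacer, "", fixed = TRUE)[[1]]
  fwd_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  rev_chars <- strsplit(revcomp(seq), "", fixed = TRUE)[[1]]

  fwd <- .scan_strand(g, fwd_chars, max_mismatch)
  rev <- .scan_strand(g, rev_chars, max_mismatch)

  rows <- list()
  if (nrow(fwd)) {
    rows[[1]] <- data.frame(
      locus_id = locus_id, strand = "+",
      start = fwd$start, end = fwd$start + 20L,
      n_mismatch = lengths(fwd$mismatches),
      mismatch_positions = I(fwd$mismatches),
      cut = fwd$start + 17L,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(rev)) {
    # a match starting at s (0-based) on the reverse strand occupies
    # + strand interval [n - s - 20, n - s); guide position 17/18 boundary
    # maps to + coordinate (n - s - 20) + 3
    start_plus <- n - rev$start - 20L
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = locus_id, strand = "-",
      start = start_plus, end = start_plus + 20L,
      n_mismatch = lengths(rev$mismatches),
      mismatch_positions = I(rev$mismatches),
      cut = start_plus + 3L,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(locus_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_mismatch = integer(0),
                      mismatch_positions = I(list()), cut = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predicted blunt-cut coordinate of a target-site match
#'
#' @param match one row of the data.frame returned by
#'   [find_target_sites()].
#' @return 0-based + strand coordinate; cleavage falls between
#'   \code{cut - 1} and \code{cut}.
#' @export
predict_cut_site <- function(match) {
  stopifnot(all(c("start", "strand") %in% names(match)))
  ifelse(match$strand == "+", match$start + 17L, match$start + 3L)
}

#' Check an HDR repair template for Cas9 re-cleavage
#'
#' An HDR template that still carries an intact (or near-intact) target
#' site is re-cleaved after integration; templates therefore carry silent
#' mutations in the recognition sequence. A template is \code{protected}
#' when the guide finds no site at \code{max_mismatch} or fewer
#' protospacer mismatches (a destroyed PAM protects regardless of
#' mismatch count).
#'
#' @param template_seq A/C/G/T DNA string of the repair template.
#' @param guide a \code{guide_rna}.
#' @param max_mismatch mismatch tolerance that still counts as cleavable.
#' @param report_max_mismatch mismatch radius for the residual near-match
#'   report (defaults to \code{max_mismatch + 3}, capped at 20).
#' @return list with \code{status} (\code{"cleavable"} or
#'   \code{"protected"}), \code{matches} (sites within
#'   \code{max_mismatch}), and \code{near_matches} (sites within
#'   \code{report_max_mismatch}, for audit).
#' @export
check_recleavage <- function(template_seq, guide, max_mismatch = 0L,
                             report_max_mismatch = min(max_mismatch + 3L, 20L)) {
  hits <- find_target_sites(guide, template_seq, max_mismatch)
  near <- find_target_sites(guide, template_seq, report_max_mismatch)
  list(
    status = if (nrow(hits)) "cleavable" else "protected",
    matches = hits,
    near_matches = near
  )
}

#' Read a guide table (name, protospacer)
#' @param path two-column delimited file with header columns \code{name}
#'   and \code{protospacer}.
#' @param sep field delimiter.
#' @return list of \code{guide_rna} objects, named.
#' @export
read_guide_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("name", "protospacer") %in% names(df))) {
    stop("guide table needs columns 'name' and 'protospacer'", call. = FALSE)
  }
  guides <- Map(guide_rna, df$name, df$protospacer)
  names(guides) <- df$name
  guides
}
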