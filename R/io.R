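#' Peak-report input and tabular output
#'
#' Trace reads enter the package as tabular base-call exports (one row per
#' read position with primary and secondary calls), the format produced by
#' chromatogram peak-reporting tools. The exact export schema varies, so
#' the reader takes a dialect describing column names and delimiter.
#'
#' @name cli_io
NULL

#' Peak-report dialect
#'
#' @param position,primary,secondary column names in the export.
#' @param sep field delimiter.
#' @param header whether the file carries a header row.
#' @return an object of class \code{peak_dialect}.
#' @export
peak_dialect <- function(position = "position", primary = "primary_call",
                         secondary = "secondary_call", sep = ",",
                         header = TRUE) {
  structure(list(position = position, primary = primary,
                 secondary = secondary, sep = sep, header = header),
            class = "peak_dialect")
}

#' Read a peak-report file into a trace read
#'
#' Rows are sorted by position; gaps in the position numbering are filled
#' with \code{"-"} no-call records (and reported via a warning, so masked
#' positions are auditable). Lines starting with \code{#} are skipped.
#'
#' @param path CSV/TSV path.
#' @param dialect a \code{peak_dialect}.
#' @param sample_id sample label; defaults to the file name.
#' @return a \code{trace_read}.
#' @export
read_peak_report <- function(path, dialect = peak_dialect(),
                             sample_id = NULL) {
  if (!file.exists(path)) stop("peak report not found: ", path,
                               call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.table(path, header = dialect$header,
                          sep = dialect$sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  for (col in c(dialect$position, dialect$primary, dialect$secondary)) {
    if (!col %in% names(df)) {
      stop("peak report is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  pos <- suppressWarnings(as.integer(df[[dialect$position]]))
  if (anyNA(pos) || any(pos < 1L)) {
    stop("positions must parse as positive integers (first bad row: ",
         which(is.na(pos) | pos < 1L)[1], ")", call. = FALSE)
  }
  prim <- as.character(df[[dialect$primary]])
  seco <- as.character(df[[dialect$secondary]])
  seco[is.na(seco) | seco == ""] <- "-"
  for (i in seq_along(prim)) {
    ok <- tryCatch({
      canonical_base(prim[i]); canonical_base(seco[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop(sprintf("unparseable base symbol at data row %d ('%s'/'%s')",
                   i, prim[i], seco[i]), call. = FALSE)
    }
  }
  ord <- order(pos)
  pos <- pos[ord]; prim <- prim[ord]; seco <- seco[ord]
  if (anyDuplicated(pos)) {
    stop("duplicate positions in peak report", call. = FALSE)
  }
  full <- seq_len(max(pos))
  missing_pos <- setdiff(full, pos)
  if (length(missing_pos)) {
    warning(sprintf(
      "peak report %s: %d position(s) absent, filled with '-' no-calls (%s)",
      basename(path), length(missing_pos),
      paste(utils::head(missing_pos, 10L), collapse = ",")),
      call. = FALSE)
  }
  p_full <- rep("-", length(full)); s_full <- rep("-", length(full))
  p_full[pos] <- prim; s_full[pos] <- seco
  trace_read(sample_id, p_full, s_full)
}

#' Write a trace read as a peak-report CSV
#'
#' Emits the same dialect the reader consumes (comment provenance header,
#' then position/primary_call/secondary_call), so simulated reads and
#' real exports flow through one path.
#'
#' @param read a \code{trace_read}.
#' @param path output path.
#' @param seed optional seed to record in the provenance header.
#' @return \code{path}, invisibly.
#' @export
write_peak_report <- function(read, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mosaicedit %s peak report sample=%s%s",
                     as.character(utils::packageVersion("mosaicedit")),
                     read$sample_id,
                     if (is.null(seed)) "" else sprintf(" seed=%d", seed)),
             con)
  df <- data.frame(position = read$calls$position,
                   primary_call = read$calls$primary,
                   secondary_call = read$calls$secondary)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write guide-scan matches as TSV (1-based inclusive) and BED
#'
#' @param matches data.frame from [find_target_sites()].
#' @param tsv_path,bed_path output paths (either may be \code{NULL}).
#' @return invisible list of written paths.
#' @export
write_guide_matches <- function(matches, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    out <- data.frame(
      locus_id = matches$locus_id, strand = matches$strand,
      start_1based = matches$start + 1L, end_1based = matches$end,
      n_mismatch = matches$n_mismatch,
      mismatch_positions = vapply(matches$mismatch_positions,
                                  paste, "", collapse = ","),
      cut_after_1based = matches$cut,   # cleavage after this 1-based base
      stringsAsFactors = FALSE)
    con <- file(tsv_path, "w")
    writeLines(c(
      sprintf("# mosaicedit %s guide matches",
              as.character(utils::packageVersion("mosaicedit"))),
      "# mismatch positions numbered 1..20 from the PAM-distal (5') protospacer end"),
      con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(matches$locus_id, matches$start, matches$end,
                      sprintf("mm%d", matches$n_mismatch), 0L,
                      matches$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(list(tsv = tsv_path, bed = bed_path))
}

#' Write an editing summary as JSON
#' @param summary list from [summarize_editing()] (extra fields allowed).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
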