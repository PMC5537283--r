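# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-window loops, exhaustive placement enumeration) so they share no
# code path with the implementation they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random locus with an ATG planted at cds_start (0-based)
make_random_locus <- function(len = 600L, cds_start = 49L, id = "toy") {
  seq <- random_dna(len)
  seq <- paste0(substr(seq, 1L, cds_start), "ATG",
                substr(seq, cds_start + 4L, len))
  reference_locus(id, seq, cds_start = cds_start)
}

# plant guide + AGG PAM at 0-based position site in a random background,
# avoiding accidental NGG second matches is not needed (oracle comparison)
make_locus_with_site <- function(guide_seq, site = 200L, len = 600L,
                                 id = "toy") {
  seq <- random_dna(len)
  seq <- paste0(substr(seq, 1L, site), guide_seq, "AGG",
                substr(seq, site + 24L, len))
  # keep a plantable ATG at 0 for reference_locus validity
  seq <- paste0("ATG", substr(seq, 4L, nchar(seq)))
  reference_locus(id, seq, cds_start = 0L)
}

# naive window-by-window scan of both strands; independent of .scan_strand
oracle_find_sites <- function(guide, seq, max_mismatch) {
  g <- strsplit(guide$protospacer, "", fixed = TRUE)[[1]]
  n <- nchar(seq)
  scan_one <- function(s_chars) {
    hits <- list()
    if (length(s_chars) < 23L) return(hits)
    for (s0 in 0:(length(s_chars) - 23L)) {
      if (s_chars[s0 + 22L] != "G" || s_chars[s0 + 23L] != "G") next
      mm <- which(s_chars[s0 + 1:20] != g)
      if (length(mm) <= max_mismatch) {
        hits[[length(hits) + 1L]] <- list(start = s0, mm = mm)
      }
    }
    hits
  }
  fwd <- scan_one(strsplit(seq, "", fixed = TRUE)[[1]])
  rev <- scan_one(strsplit(mosaicedit::revcomp(seq), "", fixed = TRUE)[[1]])
  rows <- list()
  for (h in fwd) {
    rows[[length(rows) + 1L]] <- data.frame(
      strand = "+", start = h$start, n_mismatch = length(h$mm),
      mm = paste(h$mm, collapse = ","), stringsAsFactors = FALSE)
  }
  for (h in rev) {
    rows[[length(rows) + 1L]] <- data.frame(
      strand = "-", start = n - h$start - 20L, n_mismatch = length(h$mm),
      mm = paste(h$mm, collapse = ","), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(strand = character(0), start = integer(0),
                      n_mismatch = integer(0), mm = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

as_oracle_frame <- function(matches) {
  df <- data.frame(strand = matches$strand, start = matches$start,
                   n_mismatch = matches$n_mismatch,
                   mm = vapply(matches$mismatch_positions, paste, "",
                               collapse = ","),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# every 0-based deletion start that turns ref into clone (pure deletions)
enumerate_deletion_placements <- function(ref, clone) {
  L <- nchar(ref) - nchar(clone)
  stopifnot(L > 0L)
  hits <- integer(0)
  for (d0 in 0:(nchar(ref) - L)) {
    cand <- paste0(substr(ref, 1L, d0), substr(ref, d0 + L + 1L, nchar(ref)))
    if (cand == clone) hits <- c(hits, d0)
  }
  hits
}

# minimal changed residue run by exhaustive (prefix, suffix) enumeration:
# the largest p with equal p-prefixes, then the largest compatible s with
# equal s-suffixes (prefix-first canonical form, as documented)
oracle_protein_diff <- function(wt_aa, mut_aa) {
  nw <- nchar(wt_aa); nm <- nchar(mut_aa)
  p_max <- 0L
  for (p in 0:min(nw, nm)) {
    if (substr(wt_aa, 1L, p) == substr(mut_aa, 1L, p)) p_max <- p
  }
  s_max <- 0L
  for (s in 0:(min(nw, nm) - p_max)) {
    if (substr(wt_aa, nw - s + 1L, nw) == substr(mut_aa, nm - s + 1L, nm)) {
      s_max <- s
    }
  }
  list(wt = substr(wt_aa, p_max + 1L, nw - s_max),
       mut = substr(mut_aa, p_max + 1L, nm - s_max))
}

# random trace read: ACGT primaries with occasional ambiguity codes
random_trace <- function(len = 60L, id = "r", p_ambig = 0.05) {
  prim <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  amb <- which(stats::runif(len) < p_ambig)
  if (length(amb)) {
    prim[amb] <- sample(c("R", "Y", "S", "W", "K", "M", "N"),
                        length(amb), replace = TRUE)
  }
  sec <- sample(c("A", "C", "G", "T", "-"), len, replace = TRUE)
  trace_read(id, prim, sec)
}
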