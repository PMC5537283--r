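#' Sequence fidelity scoring of mixed-template Sanger reads
#'
#' Direct Sanger sequencing of PCR products from a mosaic of edited
#' templates produces clean trace upstream of the Cas9 cut site and a
#' superposition of shifted registers downstream. The per-position
#' sequence fidelity score turns that qualitative picture into a number:
#' each position of an experimental read is scored against the primary
#' base call of an aligned wildtype control read — 1 for a primary-call
#' match, 0.25 for a secondary-call match, 0 for a complete mismatch, with
#' intermediate scores for IUPAC-ambiguous calls — and the scores are
#' smoothed with a 10-base moving average.
#'
#' @name fidelity
NULL

#' Scoring rule for per-position fidelity
#'
#' Ambiguous calls score proportionally to their informativeness: a call
#' with degeneracy k that covers the wildtype base contributes its anchor
#' score divided by k. This reproduces the three anchors exactly
#' (primary A vs WT A: 1; secondary match: 0.25; mismatch: 0) and gives
#' two-base codes such as R and Y an intermediate primary score of 0.5.
#'
#' @param primary_match_score score for an exact primary-call match.
#' @param secondary_match_score score for a secondary-call match.
#' @param complete_mismatch_score floor score.
#' @return an object of class \code{scoring_rule}.
#' @export
scoring_rule <- function(primary_match_score = 1.0,
                         secondary_match_score = 0.25,
                         complete_mismatch_score = 0.0) {
  stopifnot(primary_match_score > secondary_match_score,
            secondary_match_score > complete_mismatch_score,
            complete_mismatch_score >= 0)
  structure(list(primary_match_score = primary_match_score,
                 secondary_match_score = secondary_match_score,
                 complete_mismatch_score = complete_mismatch_score),
            class = "scoring_rule")
}

#' Score one position of an experimental read against the WT base
#'
#' The score is the maximum over: (a) WT base in the primary call's
#' expansion: \code{primary_match_score / degeneracy(primary)}; (b) WT
#' base in the secondary call's expansion:
#' \code{secondary_match_score / degeneracy(secondary)}; otherwise the
#' mismatch floor. A \code{"-"} no-call has empty expansion and can never
#' cover the WT base.
#'
#' @param primary,secondary experimental base calls (IUPAC or \code{"-"}).
#' @param wt wildtype control primary call; must be one of A/C/G/T.
#' @param rule a \code{scoring_rule}.
#' @return numeric score in \code{[0, 1]}.
#' @examples
#' score_position("A", "G", "A")  # 1
#' score_position("G", "A", "A")  # 0.25
#' score_position("G", "C", "A")  # 0
#' score_position("R", "-", "A")  # 0.5
#' @export
score_position <- function(primary, secondary, wt, rule = scoring_rule()) {
  wt <- canonical_base(wt)
  if (!wt %in% c("A", "C", "G", "T")) {
    stop("WT base must be unambiguous A/C/G/T, got '", wt, "'",
         call. = FALSE)
  }
  p_exp <- expand_iupac(primary)
  s_exp <- expand_iupac(secondary)
  score <- rule$complete_mismatch_score
  if (wt %in% p_exp) {
    score <- max(score, rule$primary_match_score / length(p_exp))
  }
  if (wt %in% s_exp) {
    score <- max(score, rule$secondary_match_score / length(s_exp))
  }
  score
}

#' Full fidelity score table for all call/WT combinations
#'
#' Enumerates the score of every primary call symbol (15 IUPAC codes plus
#' \code{"-"}) against each WT base, with no secondary call, so the
#' ambiguity rule can be audited against an external table.
#'
#' @param rule a \code{scoring_rule}.
#' @return data.frame with columns \code{primary_call}, \code{wt_base},
#'   \code{score}.
#' @export
fidelity_score_table <- function(rule = scoring_rule()) {
  syms <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-")
  grid <- expand.grid(primary_call = syms, wt_base = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid$score <- mapply(function(p, w) score_position(p, "-", w, rule),
                       grid$primary_call, grid$wt_base)
  grid
}

#' Align an experimental read to the WT control by rigid offset
#'
#' Mixed-template reads cannot be meaningfully gap-aligned past the cut
#' site, so alignment is a single rigid shift estimated from the pre-cut
#' region, which is assumed unedited: the integer offset maximizing exact
#' primary-call identity over the first \code{anchor_len} called positions
#' of the experimental read. Ties break toward the smallest absolute
#' shift. Offset k means experimental position i corresponds to WT
#' position i + k.
#'
#' @param exp,wt \code{trace_read} objects with at least 40 called
#'   positions each.
#' @param anchor_len number of leading experimental positions used for the
#'   identity search.
#' @param max_shift offsets searched are \code{-max_shift..max_shift}.
#' @param min_identity minimum identity of the best offset; below this the
#'   alignment fails with a diagnostic rather than returning a bad offset.
#' @return integer offset.
#' @export
align_read_to_control <- function(exp, wt, anchor_len = 50L,
                                  max_shift = 50L, min_identity = 0.8) {
  stopifnot(inherits(exp, "trace_read"), inherits(wt, "trace_read"))
  ep <- exp$calls$primary
  wp <- wt$calls$primary
  if (length(ep) < 40L || length(wp) < 40L) {
    stop("alignment needs >= 40 called positions in both reads",
         call. = FALSE)
  }
  shifts <- seq.int(-max_shift, max_shift)
  shifts <- shifts[order(abs(shifts), shifts)]  # smallest |shift| first
  best <- list(shift = NA_integer_, identity = -1)
  idx <- seq_len(min(anchor_len, length(ep)))
  for (k in shifts) {
    widx <- idx + k
    ok <- widx >= 1L & widx <= length(wp)
    if (sum(ok) < 20L) next
    ident <- mean(ep[idx[ok]] == wp[widx[ok]])
    if (ident > best$identity) best <- list(shift = k, identity = ident)
  }
  if (is.na(best$shift) || best$identity < min_identity) {
    stop(sprintf(
      "read alignment failed: best identity %.2f over anchor (< %.2f); %s vs %s",
      max(best$identity, 0), min_identity, exp$sample_id, wt$sample_id),
      call. = FALSE)
  }
  best$shift
}

#' Compute the fidelity profile of an experimental read
#'
#' One score per aligned WT position. Positions where the control read's
#' own primary call is ambiguous or a no-call are masked (NA): the score
#' is only defined relative to a trusted WT base. The moving average is a
#' centered window of \code{window} positions (\code{[i-5, i+4]} for
#' window 10) that shrinks at read ends and excludes masked positions from
#' both numerator and denominator.
#'
#' @param exp experimental \code{trace_read}.
#' @param wt wildtype control \code{trace_read}.
#' @param rule a \code{scoring_rule}.
#' @param window moving-average window size (default 10).
#' @param cut_site optional cut coordinate in WT read coordinates
#'   (1-based), stored for downstream summaries.
#' @param offset rigid alignment offset; estimated with
#'   [align_read_to_control()] when \code{NULL}.
#' @return an object of class \code{fidelity_profile}: a list with
#'   \code{sample_id}, \code{table} (data.frame of \code{wt_position},
#'   \code{read_position}, \code{score}, \code{moving_avg}),
#'   \code{alignment_offset}, \code{window}, \code{cut_site}.
#' @export
compute_fidelity_profile <- function(exp, wt, rule = scoring_rule(),
                                     window = 10L, cut_site = NULL,
                                     offset = NULL) {
  stopifnot(window >= 1L)
  if (is.null(offset)) offset <- align_read_to_control(exp, wt)
  ep <- exp$calls$primary
  es <- exp$calls$secondary
  wp <- wt$calls$primary
  ridx <- seq_along(ep)
  widx <- ridx + offset
  ok <- widx >= 1L & widx <= length(wp)
  ridx <- ridx[ok]; widx <- widx[ok]
  scores <- rep(NA_real_, length(ridx))
  unmasked <- wp[widx] %in% c("A", "C", "G", "T")
  for (j in which(unmasked)) {
    scores[j] <- score_position(ep[ridx[j]], es[ridx[j]], wp[widx[j]], rule)
  }
  mavg <- moving_average(scores, window)
  structure(
    list(sample_id = exp$sample_id,
         table = data.frame(wt_position = widx, read_position = ridx,
                            score = scores, moving_avg = mavg),
         alignment_offset = offset, window = as.integer(window),
         cut_site = cut_site),
    class = "fidelity_profile"
  )
}

#' @export
print.fidelity_profile <- function(x, ...) {
  cat(sprintf(
    "<fidelity_profile> %s: %d positions (offset %+d, window %d)%s\n",
    x$sample_id, nrow(x$table), x$alignment_offset, x$window,
    if (is.null(x$cut_site)) "" else sprintf(", cut at %d", x$cut_site)))
  invisible(x)
}

#' Centered shrinking moving average ignoring NA
#'
#' Window of size w covers positions \code{[i - floor(w/2), i + ceiling(w/2) - 1]},
#' truncated at the vector ends; NA entries are dropped from numerator and
#' denominator. A position whose window holds no finite value is NA.
#'
#' @param x numeric vector (may contain NA for masked positions).
#' @param window window size.
#' @return numeric vector, same length as \code{x}.
#' @export
moving_average <- function(x, window = 10L) {
  n <- length(x)
  lo <- pmax(seq_len(n) - window %/% 2L, 1L)
  hi <- pmin(seq_len(n) + (window - window %/% 2L) - 1L, n)
  vapply(seq_len(n), function(i) {
    w <- x[lo[i]:hi[i]]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Summarize editing extent around a cut site
#'
#' Baseline fidelity is the mean moving average over the window
#' \code{[cut - pre_flank - 20, cut - 20)} in WT coordinates — deliberately
#' ending 20 positions upstream of the cut so short deletions reaching a
#' few bases upstream do not contaminate it. Post-cut fidelity is the mean
#' over \code{[cut, cut + post_flank)}. The onset is the most upstream
#' position at which the moving average first falls below
#' \code{baseline - 3 * SD(baseline window)}.
#'
#' @param profile a \code{fidelity_profile}.
#' @param cut_site cut coordinate in WT read coordinates (1-based);
#'   defaults to the profile's stored cut site.
#' @param pre_flank,post_flank window lengths in positions.
#' @return list with \code{baseline_fidelity}, \code{post_cut_fidelity},
#'   \code{fidelity_drop}, \code{onset_position} (NA when the profile
#'   never leaves the baseline band).
#' @export
summarize_editing <- function(profile, cut_site = profile$cut_site,
                              pre_flank = 50L, post_flank = 50L) {
  stopifnot(inherits(profile, "fidelity_profile"))
  if (is.null(cut_site)) stop("no cut site supplied", call. = FALSE)
  tb <- profile$table
  pre_lo <- cut_site - pre_flank - 20L
  if (!any(tb$wt_position <= pre_lo)) {
    stop(sprintf(
      "insufficient upstream flank: need coverage down to WT position %d (pre_flank %d + 20)",
      pre_lo, pre_flank), call. = FALSE)
  }
  base_w <- tb$moving_avg[tb$wt_position >= pre_lo &
                            tb$wt_position < cut_site - 20L]
  post_w <- tb$moving_avg[tb$wt_position >= cut_site &
                            tb$wt_position < cut_site + post_flank]
  if (!length(post_w) || all(is.na(post_w))) {
    stop("insufficient downstream flank for post-cut window", call. = FALSE)
  }
  baseline <- mean(base_w, na.rm = TRUE)
  post <- mean(post_w, na.rm = TRUE)
  thr <- baseline - 3 * stats::sd(base_w, na.rm = TRUE)
  below <- which(tb$moving_avg < thr)
  onset <- if (length(below)) tb$wt_position[min(below)] else NA_integer_
  list(baseline_fidelity = baseline,
       post_cut_fidelity = post,
       fidelity_drop = baseline - post,
       onset_position = onset)
}

#' Write a fidelity profile as TSV (with provenance header)
#' @param profile a \code{fidelity_profile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mosaicedit %s fidelity profile",
            as.character(utils::packageVersion("mosaicedit"))),
    sprintf("# sample=%s offset=%d window=%d cut_site=%s",
            profile$sample_id, profile$alignment_offset, profile$window,
            if (is.null(profile$cut_site)) "NA" else profile$cut_site)
  ), con)
  utils::write.table(profile$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
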