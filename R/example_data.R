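#' Example paralog trio with allele-selective guides
#'
#' Builds a toy version of the study system this package is designed for:
#' three paralogous gene copies (as arise in an allotetraploid genome,
#' named here \code{rho.L}, \code{rho.2.L}, \code{rho.S} after the rod
#' opsin paralogs) plus two guide RNAs — a "universal" guide whose target
#' site is identical in all three copies, and a "selective" guide whose
#' protospacer matches \code{rho.L} exactly but carries two mismatches
#' (at protospacer positions 1 and 6, PAM-distal numbering) in the other
#' two copies, so it should cut only \code{rho.L}. Two diagnostic bases
#' distinguishing \code{rho.L} from \code{rho.2.L} are registered on both
#' loci.
#'
#' The sequences are synthetic: a random backbone with the guide sites,
#' paralog substitutions, and diagnostics planted at fixed offsets.
#' Deterministic given \code{seed}.
#'
#' @param seed integer RNG seed for the backbone sequence.
#' @return list with \code{loci} (named list of three
#'   \code{reference_locus}), \code{guides} (named list of two
#'   \code{guide_rna}), and \code{cut_sites} (0-based cut coordinates of
#'   the two guides on their matching loci).
#' @export
example_paralog_loci <- function(seed = 20L) {
  with_local_seed(seed, {
    n <- 600L
    backbone <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    backbone[1:3] <- c("A", "T", "G")
    # universal site at 0-based 260 (protospacer 260..279, PAM 280..282)
    uni_proto <- paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                       collapse = "")
    backbone[261:280] <- strsplit(uni_proto, "")[[1]]
    backbone[281:283] <- c("A", "G", "G")
    # selective site at 0-based 300
    sel_proto <- paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                       collapse = "")
    backbone[301:320] <- strsplit(sel_proto, "")[[1]]
    backbone[321:323] <- c("T", "G", "G")
    flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[[1]]
    rho_L <- backbone
    # siblings: mismatch the selective protospacer at positions 1 and 6
    sibling <- backbone
    sibling[301] <- flip(sibling[301])
    sibling[306] <- flip(sibling[306])
    # rho.L vs rho.2.L diagnostic bases at 0-based 100 and 150
    rho_2L <- sibling
    rho_2L[101] <- flip(rho_2L[101])
    rho_2L[151] <- flip(rho_2L[151])
    # rho.S: further scattered divergence away from both guide sites
    rho_S <- sibling
    for (p in c(60L, 130L, 200L, 420L, 500L)) {
      rho_S[p + 1L] <- flip(rho_S[p + 1L])
    }
    loci <- list(
      rho.L = reference_locus(
        "rho.L", paste(rho_L, collapse = ""), cds_start = 0L,
        diagnostic_positions = list(`100` = rho_L[101],
                                    `150` = rho_L[151])),
      rho.2.L = reference_locus(
        "rho.2.L", paste(rho_2L, collapse = ""), cds_start = 0L,
        diagnostic_positions = list(`100` = rho_2L[101],
                                    `150` = rho_2L[151])),
      rho.S = reference_locus("rho.S", paste(rho_S, collapse = ""),
                              cds_start = 0L))
    list(loci = loci,
         guides = list(universal = guide_rna("sgUni", uni_proto),
                       selective = guide_rna("sgSel", sel_proto)),
         cut_sites = c(universal = 260L + 17L, selective = 300L + 17L))
  })
}
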