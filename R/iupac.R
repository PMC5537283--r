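#' IUPAC nucleotide algebra
#'
#' Every base-call symbol handled by the package is one of the four
#' unambiguous DNA bases, one of the eleven IUPAC ambiguity codes, or the
#' gap/no-call symbol \code{"-"}. Lowercase input and the RNA letter
#' \code{"U"} are canonicalized (\code{U -> T}) so common FASTA and
#' peak-report dialects are tolerated.
#'
#' @name iupac
NULL

# symbol -> expansion over {A,C,G,T}; "-" expands to the empty set
.IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  `-` = character(0)
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Canonicalize a vector of base symbols
#'
#' Uppercases, maps \code{U} to \code{T}, and rejects anything outside the
#' 16-symbol alphabet (A/C/G/T, the 11 IUPAC ambiguity codes, and
#' \code{"-"}).
#'
#' @param x character vector of single-character base symbols.
#' @return character vector of canonical symbols.
#' @export
canonical_base <- function(x) {
  x <- toupper(as.character(x))
  x[x == "U"] <- "T"
  bad <- !(x %in% names(.IUPAC_EXPANSION))
  if (any(bad)) {
    stop("invalid base symbol(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Expand an IUPAC symbol to its set of unambiguous bases
#'
#' @param b a single base symbol (case-insensitive; \code{U} accepted).
#' @return character vector of bases from \code{A,C,G,T}; empty for
#'   \code{"-"} (no call carries no information).
#' @examples
#' expand_iupac("R")  # A G
#' expand_iupac("N")  # A C G T
#' @export
expand_iupac <- function(b) {
  stopifnot(length(b) == 1L)
  .IUPAC_EXPANSION[[canonical_base(b)]]
}

#' Degeneracy (expansion-set size) of a symbol, vectorized
#' @param x character vector of base symbols.
#' @return integer vector; 0 for \code{"-"}.
#' @export
iupac_degeneracy <- function(x) {
  lengths(.IUPAC_EXPANSION[canonical_base(x)])
}

#' Complement of base symbols (IUPAC-aware), vectorized
#' @param x character vector of base symbols.
#' @return character vector of complements; \code{"-"} maps to itself.
#' @export
complement_base <- function(x) {
  unname(.IUPAC_COMPLEMENT[canonical_base(x)])
}

#' IUPAC code for a set of unambiguous bases
#'
#' Inverse of [expand_iupac()] for non-empty subsets of \code{{A,C,G,T}}.
#'
#' @param bases character vector drawn from A/C/G/T.
#' @return the single symbol whose expansion equals \code{sort(unique(bases))}.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(canonical_base(bases)))
  if (length(bases) == 0L) return("-")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("iupac_code() takes unambiguous bases only", call. = FALSE)
  }
  for (sym in names(.IUPAC_EXPANSION)) {
    if (identical(.IUPAC_EXPANSION[[sym]], bases)) return(sym)
  }
  stop("no IUPAC code for base set: ", paste(bases, collapse = ""))
}

#' Reverse complement of a plain DNA string
#' @param seq single DNA string (IUPAC symbols allowed).
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(length(seq) == 1L)
  paste(rev(complement_base(strsplit(seq, "", fixed = TRUE)[[1]])),
        collapse = "")
}

# run set.seed() without clobbering the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
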