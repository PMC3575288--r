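# Low-level DNA string helpers shared across modules.
# Sequences are plain uppercase character scalars over {A,C,G,T,N};
# N is the placeholder for bases beyond a record boundary and never
# matches a template position or an enzyme recognition site.

DNA_BASES <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_BASES, "N")

# IUPAC degenerate nucleotide codes -> the set of bases each stands for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement (with `N` mapping to `N`), reversed.
#' The second TAL arm binds the reverse strand, so its binding sequence is
#' the reverse complement of the forward-strand slice.
#'
#' @param seq Character scalar over `{A,C,G,T,N}` (case-insensitive).
#' @return Uppercase character scalar, the reverse complement.
#' @examples
#' reverse_complement("ACGT")
#' reverse_complement("AAN")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), DNA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-IUPAC character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Reverse complement extended to degenerate IUPAC codes (for enzyme
# recognition sites, e.g. GANTC -> GANTC, CCANNNNNNTGG -> CCANNNNNNTGG).
iupac_reverse_complement <- function(seq) {
  seq <- toupper(seq)
  comp <- chartr("ACGTRYWSKMBDHVN", "TGCAYRWSMKVHDBN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

assert_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  chars <- unique(strsplit(toupper(seq), "")[[1]])
  ok <- if (allow_n) DNA_ALPHABET else DNA_BASES
  bad <- setdiff(chars, ok)
  if (length(bad) > 0) {
    stop("invalid character(s) in ", what, ": ", paste(bad, collapse = ", "))
  }
  invisible(toupper(seq))
}

assert_iupac <- function(seq, what = "recognition site") {
  chars <- unique(strsplit(toupper(seq), "")[[1]])
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  invisible(toupper(seq))
}

#' Sample a random DNA sequence at a given GC content
#'
#' Draws bases independently: G/C with total probability `gc_fraction`
#' (split equally), A/T with the remainder. Used by the fixture generator;
#' callers seed the RNG.
#'
#' @param n Sequence length in bp.
#' @param gc_fraction Number in `[0,1]`; fraction of G+C bases expected.
#' @return Character scalar of length `n`.
#' @export
random_dna <- function(n, gc_fraction = 0.5) {
  stopifnot(n >= 0, gc_fraction >= 0, gc_fraction <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
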