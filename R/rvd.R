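# The RVD cipher. Each 33-35 aa TAL repeat carries a repeat variable
# di-residue that determines the base it binds; artificial TAL effectors
# use the canonical four: NI=A, HD=C, NN=G, NG=T. The mapping is a
# bijection between {A,C,G,T}* and RVD strings, so round-trips are exact.

RVD_OF_BASE <- c(A = "NI", C = "HD", G = "NN", T = "NG")
BASE_OF_RVD <- setNames(names(RVD_OF_BASE), RVD_OF_BASE)

#' Encode a binding site as its RVD module string
#'
#' Maps each base of a TAL binding site to the repeat variable di-residue
#' of the module that binds it: A→NI, C→HD, G→NN, T→NG. Sites containing
#' the placeholder `N` (or any other character) are refused — they cannot
#' be assembled.
#'
#' @param site Character scalar over `{A,C,G,T}`.
#' @return Character vector of two-letter RVD codes, one per base.
#'   Serialize with `paste(..., collapse = "\t")` for the tab-delimited
#'   form used in reports.
#' @examples
#' rvd_encode("ACGT")  # NI HD NN NG
#' @export
rvd_encode <- function(site) {
  stopifnot(is.character(site), length(site) == 1L)
  if (nchar(site) == 0) return(character())
  bases <- strsplit(toupper(site), "")[[1]]
  bad <- setdiff(unique(bases), names(RVD_OF_BASE))
  if (length(bad) > 0) {
    stop("cannot RVD-encode character(s): ", paste(bad, collapse = ", "))
  }
  unname(RVD_OF_BASE[bases])
}

#' Decode an RVD module string back to DNA
#'
#' Inverse of [rvd_encode()].
#'
#' @param rvds Character vector of codes in `{NI, HD, NN, NG}`, or a
#'   single tab-delimited string of them.
#' @return The DNA sequence as a character scalar.
#' @examples
#' rvd_decode(c("NG", "NG"))  # "TT"
#' @export
rvd_decode <- function(rvds) {
  if (length(rvds) == 1L && grepl("\t", rvds)) {
    rvds <- strsplit(rvds, "\t", fixed = TRUE)[[1]]
  }
  if (length(rvds) == 0) return("")
  bad <- setdiff(unique(rvds), names(BASE_OF_RVD))
  if (length(bad) > 0) {
    stop("unknown RVD code(s): ", paste(bad, collapse = ", "))
  }
  paste(unname(BASE_OF_RVD[rvds]), collapse = "")
}
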