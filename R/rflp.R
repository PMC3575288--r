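# Restriction-site screening of candidate spacers for RFLP readout.
# After a TALEN cut is repaired by error-prone NHEJ, a recognition site
# in the spacer is usually destroyed; an enzyme that cuts exactly once
# in the PCR amplicon then gives a clean cut/uncut readout. Degenerate
# IUPAC matching is delegated to Biostrings.

#' Find all matches of a degenerate recognition site
#'
#' Scans the forward strand for the IUPAC pattern and for its reverse
#' complement (a reverse-strand hit). Overlapping occurrences are all
#' reported. For palindromic recognition sites the forward and reverse
#' match sets coincide and are collapsed to single `+` hits. Windows
#' containing the placeholder `N` never match.
#'
#' @param seq DNA sequence (may contain `N`).
#' @param recognition IUPAC degenerate recognition site.
#' @return Data frame with `pos` (1-based position of the first base of
#'   the recognition site on the forward strand) and `strand`
#'   (`"+"`/`"-"`), sorted by position.
#' @examples
#' match_recognition("GGATGCATGG", "ATGCAT")
#' @export
match_recognition <- function(seq, recognition) {
  seq <- assert_dna(seq, allow_n = TRUE)
  recognition <- assert_iupac(recognition)
  w <- nchar(recognition)
  empty <- data.frame(pos = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (w == 0 || nchar(seq) < w) return(empty)

  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(recognition)
  fwd <- Biostrings::start(
    Biostrings::matchPattern(pat, subj, fixed = "subject"))
  rc <- iupac_reverse_complement(recognition)
  if (rc == recognition) {
    hits <- data.frame(pos = fwd, strand = rep("+", length(fwd)),
                       stringsAsFactors = FALSE)
  } else {
    rev <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(rc), subj,
                               fixed = "subject"))
    hits <- rbind(
      data.frame(pos = fwd, strand = rep("+", length(fwd)),
                 stringsAsFactors = FALSE),
      data.frame(pos = rev, strand = rep("-", length(rev)),
                 stringsAsFactors = FALSE))
  }
  if (nrow(hits) == 0) return(empty)
  # Biostrings lets a literal N in the subject match a degenerate
  # pattern position; placeholder bases must never match, so drop any
  # window containing N.
  win_has_n <- vapply(hits$pos, function(p) {
    grepl("N", substr(seq, p, p + w - 1L), fixed = TRUE)
  }, logical(1))
  hits <- hits[!win_has_n, , drop = FALSE]
  hits <- hits[order(hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Screen one candidate pair for RFLP-suitable enzymes
#'
#' For every enzyme in the database whose recognition site occurs fully
#' inside the spacer, counts all occurrences across the amplicon window
#' (both binding sites extended by `long_flank` on each side, clipped to
#' the fragment). An enzyme cutting exactly once in the amplicon is
#' reported with the absolute position of the first base of its
#' recognition site. An enzyme with several amplicon matches is kept only
#' if the match nearest the (leftmost) spacer match is at least
#' `min_second_cut` bp away — far enough that the two restriction
#' fragments are distinguishable on a gel — and the second cut is then
#' reported relative to the first. Anything closer drops the enzyme.
#'
#' @param pair One row of [enumerate_pairs()] output (data frame row or
#'   list).
#' @param fragment The `tal_fragment` the pair was found in.
#' @param db An `enzyme_db`.
#' @param long_flank Amplicon flank width in bp (default 150).
#' @param min_second_cut Minimum separation of a tolerated second cut in
#'   bp (default 80).
#' @return Data frame of class `enzyme_hits`, sorted by enzyme name:
#'   `enzyme`, `prototype`, `recognition`, `strand`, `position`
#'   (fragment-absolute, 1-based, i.e. indexed from the start of the
#'   long-flanked fragment), `unique_in_amplicon`, `second_cut_rel`
#'   (NA when unique), and the buffer-score columns of `db`.
#' @export
analyze_pair <- function(pair, fragment, db, long_flank = 150L,
                         min_second_cut = 80L) {
  stopifnot(inherits(fragment, "tal_fragment"), inherits(db, "enzyme_db"))
  pair <- as.list(pair)
  sp_start <- pair$spacer_start
  sp_end <- pair$spacer_start + pair$spacer_len - 1L
  site2_end <- pair$site2_start + pair$site2_len - 1L
  n <- nchar(fragment$sequence)
  stopifnot(pair$site1_start >= 1, site2_end <= n)

  empty <- empty_hits(db)
  spacer_seq <- substr(fragment$sequence, sp_start, sp_end)
  if (grepl("N", spacer_seq, fixed = TRUE)) return(empty)

  amp_lo <- max(1L, pair$site1_start - long_flank)
  amp_hi <- min(n, site2_end + long_flank)

  rows <- list()
  for (i in seq_len(nrow(db))) {
    rec <- db$recognition[i]
    w <- nchar(rec)
    hits <- match_recognition(fragment$sequence, rec)
    if (nrow(hits) == 0) next
    in_spacer <- hits[hits$pos >= sp_start & hits$pos + w - 1L <= sp_end, ,
                      drop = FALSE]
    if (nrow(in_spacer) == 0) next
    primary <- in_spacer[1, ]  # leftmost spacer match
    in_amp <- hits[hits$pos >= amp_lo & hits$pos + w - 1L <= amp_hi, ,
                   drop = FALSE]
    others <- in_amp[!(in_amp$pos == primary$pos &
                         in_amp$strand == primary$strand), , drop = FALSE]
    if (nrow(others) == 0) {
      uniq <- TRUE
      second <- NA_integer_
    } else {
      d <- others$pos - primary$pos
      nearest <- d[order(abs(d), -sign(d))][1]  # tie: prefer downstream
      if (abs(nearest) < min_second_cut) next   # ambiguous gel — drop
      uniq <- FALSE
      second <- as.integer(nearest)
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(enzyme = db$name[i], prototype = db$prototype[i],
                 recognition = rec, strand = primary$strand,
                 position = as.integer(primary$pos),
                 unique_in_amplicon = uniq, second_cut_rel = second,
                 stringsAsFactors = FALSE),
      db[i, paste0("score_", BUFFER_NAMES), drop = FALSE])
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enzyme_hits", "data.frame")
  out
}

empty_hits <- function(db) {
  out <- cbind(
    data.frame(enzyme = character(), prototype = character(),
               recognition = character(), strand = character(),
               position = integer(), unique_in_amplicon = logical(),
               second_cut_rel = integer(), stringsAsFactors = FALSE),
    db[integer(), paste0("score_", BUFFER_NAMES), drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("enzyme_hits", "data.frame")
  out
}
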