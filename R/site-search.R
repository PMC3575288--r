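# Binding-site template compilation and candidate-pair enumeration.
#
# A template describes one TAL arm: an anchoring thymine immediately 5'
# of the site (`T` before the start marker `s`), optional per-position
# base sets for the first bases inside the site (e.g. `[ACG][CGT]`), a
# free interior (`.*`), and the end marker `e`. The same template is
# applied to both arms of a pair -- the second on the reverse strand, so
# on the forward strand the base immediately 3' of arm 2 must be an A.

#' Compile a binding-site consensus template
#'
#' Parses the template notation into its constraints. Supported tokens:
#' `T` (required thymine immediately before the site), `s`/`e` (site
#' start/end markers), bracketed base sets such as `[ACG]` (allowed bases
#' at successive positions just inside the site), and `.*` (free
#' interior). A trailing `T` before `e` is accepted as the mirror of the
#' 5' anchor (the thymine preceding the second arm on the reverse
#' strand); it adds no extra per-base constraint. The classical consensus
#' is `"Ts[ACG][CGT].*Te"`; the default used throughout the package is
#' the more permissive `"Ts.*e"`, since in practice only the 5' T is a
#' measurable constraint.
#'
#' @param notation Template string.
#' @return An object of class `tal_template` with `require_preceding_T`
#'   (logical) and `leading_sets` (list of character vectors of allowed
#'   bases, applied at site positions 1, 2, ...).
#' @examples
#' parse_template("Ts[ACG][CGT].*Te")
#' parse_template("Ts.*e")
#' @export
parse_template <- function(notation = "Ts.*e") {
  stopifnot(is.character(notation), length(notation) == 1L)
  chars <- strsplit(notation, "")[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("T", "s", "e")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) {
        stop("template parse error at position ", i, ": unclosed '['")
      }
      set <- chars[seq(i + 1L, j - 1L)]
      if (length(set) == 0 || !all(set %in% DNA_BASES)) {
        stop("template parse error at position ", i,
             ": base set must be a non-empty subset of ACGT")
      }
      tokens[[length(tokens) + 1L]] <- list(type = "set", set = set, pos = i)
      i <- j + 1L
    } else if (ch == ".") {
      if (i == length(chars) || chars[i + 1L] != "*") {
        stop("template parse error at position ", i, ": expected '.*'")
      }
      tokens[[length(tokens) + 1L]] <- list(type = "wild", pos = i)
      i <- i + 2L
    } else {
      stop("template parse error at position ", i,
           ": unknown token '", ch, "'")
    }
  }

  types <- vapply(tokens, `[[`, "", "type")
  s_at <- which(types == "s")
  e_at <- which(types == "e")
  if (length(s_at) != 1L) stop("template must contain exactly one 's'")
  if (length(e_at) != 1L) stop("template must contain exactly one 'e'")
  if (e_at < s_at) {
    stop("template parse error at position ", tokens[[e_at]]$pos,
         ": 'e' before 's'")
  }
  if (e_at != length(tokens)) {
    stop("template parse error: tokens after 'e'")
  }

  pre <- types[seq_len(s_at - 1L)]
  if (!all(pre == "T") || length(pre) > 1L) {
    stop("template parse error: only a single optional 'T' may precede 's'")
  }
  require_t <- length(pre) == 1L

  inner <- tokens[seq(s_at + 1L, e_at - 1L)]
  inner_types <- vapply(inner, `[[`, "", "type")
  # grammar inside the site: sets*, optional wildcard, optional mirror T
  k <- 1L
  leading_sets <- list()
  while (k <= length(inner) && inner_types[k] == "set") {
    leading_sets[[length(leading_sets) + 1L]] <- inner[[k]]$set
    k <- k + 1L
  }
  if (k <= length(inner) && inner_types[k] == "wild") k <- k + 1L
  if (k <= length(inner) && inner_types[k] == "T") {
    if (!require_t) {
      stop("template parse error: mirror 'T' anchor before 'e' requires ",
           "the 5' 'T' anchor before 's'")
    }
    k <- k + 1L
  }
  if (k <= length(inner)) {
    stop("template parse error at position ", inner[[k]]$pos,
         ": unexpected token inside site")
  }

  structure(list(
    notation = notation,
    require_preceding_T = require_t,
    leading_sets = leading_sets
  ), class = "tal_template")
}

#' @export
print.tal_template <- function(x, ...) {
  cat("<tal_template>", x$notation, "\n  preceding T:",
      x$require_preceding_T, "; leading sets:",
      if (length(x$leading_sets) == 0) "none" else
        paste(vapply(x$leading_sets, paste, "", collapse = ""),
              collapse = ", "), "\n")
  invisible(x)
}

#' Search configuration for pair enumeration
#'
#' @param site_len Length-2 integer vector, allowed binding-site lengths
#'   (default 15-17 bp).
#' @param spacer_len Length-2 integer vector, allowed spacer lengths
#'   (default 15-16 bp).
#' @param increment Optional integer overriding the automatic start-step
#'   rule of [increment_for_length()].
#' @param single_site If `TRUE`, enumerate single forward-strand sites and
#'   skip pairing and enzyme analysis.
#' @return A `search_config` list.
#' @export
search_config <- function(site_len = c(15L, 17L), spacer_len = c(15L, 16L),
                          increment = NULL, single_site = FALSE) {
  stopifnot(length(site_len) == 2, length(spacer_len) == 2,
            site_len[1] >= 1, spacer_len[1] >= 1,
            site_len[1] <= site_len[2], spacer_len[1] <= spacer_len[2])
  if (!is.null(increment)) stopifnot(increment >= 1)
  structure(list(site_len = as.integer(site_len),
                 spacer_len = as.integer(spacer_len),
                 increment = if (is.null(increment)) NULL
                             else as.integer(increment),
                 single_site = isTRUE(single_site)),
            class = "search_config")
}

#' Start-position step for long regions
#'
#' Enumeration over every start position is exhaustive for regions up to
#' 999 bp. Longer exons/introns would produce unusably many candidates,
#' so start positions are stepped: regions of 1000-4999 bp use an
#' increment of 10, regions of 5000 bp and more use 20. The step applies
#' to the core (exon/intron) length, not the flanked length. An explicit
#' override wins.
#'
#' @param fragment_core_length Core region length in bp.
#' @param override Optional positive integer.
#' @return The start-position increment.
#' @examples
#' increment_for_length(999)   # 1
#' increment_for_length(1500)  # 10
#' increment_for_length(6000)  # 20
#' @export
increment_for_length <- function(fragment_core_length, override = NULL) {
  stopifnot(fragment_core_length >= 0)
  if (!is.null(override)) {
    stopifnot(override >= 1)
    return(as.integer(override))
  }
  if (fragment_core_length >= 5000) 20L
  else if (fragment_core_length >= 1000) 10L
  else 1L
}

# Does the site frag[start..start+len-1] satisfy the template on the
# given strand? Arm 2 binds the reverse strand: its anchoring T precedes
# it on that strand (an A follows the site on the forward strand) and the
# leading base sets apply to the reverse complement's first positions.
site_satisfies <- function(chars, start, len, template, strand = "+") {
  end <- start + len - 1L
  if (start < 1L || end > length(chars)) return(FALSE)
  site <- chars[start:end]
  if (any(site == "N")) return(FALSE)
  nsets <- length(template$leading_sets)
  if (nsets > len) return(FALSE)
  if (strand == "+") {
    if (template$require_preceding_T &&
        (start < 2L || chars[start - 1L] != "T")) return(FALSE)
    for (j in seq_len(nsets)) {
      if (!(site[j] %in% template$leading_sets[[j]])) return(FALSE)
    }
  } else {
    if (template$require_preceding_T &&
        (end + 1L > length(chars) || chars[end + 1L] != "A")) return(FALSE)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (j in seq_len(nsets)) {
      if (!(unname(comp[site[len - j + 1L]]) %in%
            template$leading_sets[[j]])) return(FALSE)
    }
  }
  TRUE
}

# Window of admissible first-arm start positions: the core extended by
# the short flank on each side. Sites may extend rightwards into the long
# flank, but may not *start* in the long flank beyond the short-flanked
# window.
site1_window <- function(fragment) {
  core_len <- fragment$core_end - fragment$core_start + 1L
  ws <- max(1L, fragment$long_flank - fragment$short_flank + 1L)
  we <- min(nchar(fragment$sequence),
            fragment$long_flank + core_len + fragment$short_flank)
  c(ws, we)
}

#' Enumerate candidate TALEN binding-site pairs
#'
#' Scans the fragment for pairs of template-satisfying binding sites
#' separated by a spacer, iterating every combination of site-1 length,
#' spacer length and site-2 length in the configured ranges at every
#' admissible start position (stepped by [increment_for_length()] for
#' long cores). Site 1 is matched on the forward strand; site 2 must
#' satisfy the same template on the reverse strand, so an `A` follows it
#' on the forward strand. Sites containing the placeholder `N` are
#' rejected. Pairs are ordered by (site-1 start, site-1 length, spacer
#' length, site-2 length) and numbered from 1.
#'
#' @param fragment A `tal_fragment` from [extract_fragment()].
#' @param template A `tal_template` from [parse_template()].
#' @param config A [search_config()].
#' @return A data frame of class `talen_pairs`, one row per candidate:
#'   coordinates (fragment-local, 1-based inclusive), sequences, the
#'   reverse complement of site 2 (the strand the second TAL protein
#'   binds), and tab-delimited RVD strings for both arms.
#' @export
enumerate_pairs <- function(fragment, template = parse_template(),
                            config = search_config()) {
  stopifnot(inherits(fragment, "tal_fragment"),
            inherits(template, "tal_template"),
            inherits(config, "search_config"))
  chars <- strsplit(fragment$sequence, "")[[1]]
  core_len <- fragment$core_end - fragment$core_start + 1L
  inc <- increment_for_length(core_len, config$increment)
  win <- site1_window(fragment)

  rows <- list()
  if (win[1] <= win[2]) {
    for (s1 in seq(win[1], win[2], by = inc)) {
      for (l1 in seq(config$site_len[1], config$site_len[2])) {
        if (!site_satisfies(chars, s1, l1, template, "+")) next
        for (sp in seq(config$spacer_len[1], config$spacer_len[2])) {
          s2 <- s1 + l1 + sp
          for (l2 in seq(config$site_len[1], config$site_len[2])) {
            if (!site_satisfies(chars, s2, l2, template, "-")) next
            rows[[length(rows) + 1L]] <-
              c(s1 = s1, l1 = l1, sp_start = s1 + l1, sp = sp,
                s2 = s2, l2 = l2)
          }
        }
      }
    }
  }

  if (length(rows) == 0) return(empty_pairs())
  m <- do.call(rbind, rows)
  seq_at <- function(a, l) substr(fragment$sequence, a, a + l - 1L)
  site1_seq <- mapply(seq_at, m[, "s1"], m[, "l1"])
  site2_seq <- mapply(seq_at, m[, "s2"], m[, "l2"])
  res <- data.frame(
    index = seq_len(nrow(m)),
    site1_start = m[, "s1"], site1_len = m[, "l1"],
    spacer_start = m[, "sp_start"], spacer_len = m[, "sp"],
    site2_start = m[, "s2"], site2_len = m[, "l2"],
    site1_seq = site1_seq,
    spacer_seq = mapply(seq_at, m[, "sp_start"], m[, "sp"]),
    site2_seq = site2_seq,
    site2_revcomp = vapply(site2_seq, reverse_complement, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$rvd1 <- vapply(res$site1_seq,
                     function(s) paste(rvd_encode(s), collapse = "\t"), "")
  res$rvd2 <- vapply(res$site2_revcomp,
                     function(s) paste(rvd_encode(s), collapse = "\t"), "")
  class(res) <- c("talen_pairs", "data.frame")
  res
}

empty_pairs <- function() {
  res <- data.frame(index = integer(), site1_start = integer(),
                    site1_len = integer(), spacer_start = integer(),
                    spacer_len = integer(), site2_start = integer(),
                    site2_len = integer(), site1_seq = character(),
                    spacer_seq = character(), site2_seq = character(),
                    site2_revcomp = character(), rvd1 = character(),
                    rvd2 = character(), stringsAsFactors = FALSE)
  class(res) <- c("talen_pairs", "data.frame")
  res
}

#' Enumerate single TAL binding sites
#'
#' Forward-strand, single-arm variant of [enumerate_pairs()] for designs
#' that need one TAL protein only. The same template, length range,
#' windowing, stepping and ordering rules apply; downstream enzyme
#' analysis is skipped for single sites.
#'
#' @inheritParams enumerate_pairs
#' @return A data frame with `index`, `start`, `len`, `seq`, `rvd`.
#' @export
enumerate_single_sites <- function(fragment, template = parse_template(),
                                   config = search_config(single_site = TRUE)) {
  stopifnot(inherits(fragment, "tal_fragment"),
            inherits(template, "tal_template"))
  chars <- strsplit(fragment$sequence, "")[[1]]
  core_len <- fragment$core_end - fragment$core_start + 1L
  inc <- increment_for_length(core_len, config$increment)
  win <- site1_window(fragment)

  rows <- list()
  if (win[1] <= win[2]) {
    for (s1 in seq(win[1], win[2], by = inc)) {
      for (l1 in seq(config$site_len[1], config$site_len[2])) {
        if (!site_satisfies(chars, s1, l1, template, "+")) next
        rows[[length(rows) + 1L]] <- c(start = s1, len = l1)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(index = integer(), start = integer(), len = integer(),
                      seq = character(), rvd = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  seqs <- mapply(function(a, l) substr(fragment$sequence, a, a + l - 1L),
                 m[, "start"], m[, "len"])
  data.frame(index = seq_len(nrow(m)), start = m[, "start"], len = m[, "len"],
             seq = seqs,
             rvd = vapply(seqs,
                          function(s) paste(rvd_encode(s), collapse = "\t"),
                          ""),
             stringsAsFactors = FALSE, row.names = NULL)
}
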