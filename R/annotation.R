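# Gene-record parsing, feature prioritization and exon/intron fragment
# extraction. Internals use 1-based inclusive coordinates (R convention);
# reported positions follow the report conventions described in
# site_records(): binding-site spans are relative to the start of the
# short-flanked subsequence, enzyme positions to the start of the
# long-flanked fragment.

SUBSEQ_KINDS <- c("mRNA", "CDS", "miscRNA")

normalize_kind <- function(kind) {
  k <- sub("^misc[_ ]?RNA$", "miscRNA", kind, ignore.case = TRUE)
  k[k %in% c("mrna", "Mrna")] <- "mRNA"
  k
}

#' Parse a GenBank flat-file record
#'
#' Minimal offline reader for GenBank flat files: captures the accession,
#' the gene symbol and its aliases (from the first `gene` feature's
#' `/gene` and `/gene_synonym` qualifiers), the ORIGIN sequence
#' (upper-cased), and every `mRNA`, `CDS`, `misc_RNA` and `exon` feature
#' together with the `/gene` label it is annotated under. Locations of the
#' form `a..b`, `join(...)` and `complement(...)` are supported; partial
#' markers (`<`, `>`) are stripped.
#'
#' @param genbank_text Character: either a single string with embedded
#'   newlines, a character vector of lines, or a path to a file.
#' @return An object of class `gene_record`: a list with `accession`,
#'   `symbol`, `aliases`, `sequence`, `contig_span`, `strand` and
#'   `features` (each feature a list with `kind`, `label`,
#'   `transcript_id`, `intervals` — a two-column matrix of 1-based
#'   inclusive start/end pairs, sorted and non-overlapping).
#' @export
parse_gene_record <- function(genbank_text) {
  lines <- as_text_lines(genbank_text)
  if (length(lines) == 0) stop("empty GenBank record")

  accession <- NA_character_
  acc_line <- grep("^ACCESSION", lines)
  if (length(acc_line) > 0) {
    accession <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_line[1]])),
                          "\\s+")[[1]][1]
  } else {
    loc_line <- grep("^LOCUS", lines)
    if (length(loc_line) > 0) {
      accession <- strsplit(trimws(sub("^LOCUS", "", lines[loc_line[1]])),
                            "\\s+")[[1]][1]
    }
  }

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(origin_start) == 0) {
    stop("GenBank record has no ORIGIN sequence")
  }
  origin_start <- origin_start[1]

  # --- sequence ---
  end_line <- grep("^//", lines)
  end_line <- if (length(end_line) > 0) end_line[1] else length(lines) + 1L
  seq_lines <- lines[seq(origin_start + 1L, end_line - 1L)]
  seq_txt <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq_txt) == 0) stop("GenBank record has no ORIGIN sequence")
  assert_dna(seq_txt, allow_n = TRUE, what = "ORIGIN sequence")

  # --- features ---
  features <- list()
  gene_symbol <- ""
  aliases <- character()
  if (length(feat_start) > 0 && feat_start[1] < origin_start) {
    ftab <- lines[seq(feat_start[1] + 1L, origin_start - 1L)]
    # group lines into (key, location+qualifier) blocks: a new feature
    # starts when columns 6-20 hold a key (line begins with exactly 5
    # spaces then a word)
    is_key <- grepl("^     \\S", ftab)
    if (length(ftab) > 0 && !is_key[1]) {
      stop("malformed GenBank feature table at line: ", ftab[1])
    }
    idx <- cumsum(is_key)
    for (g in split(ftab, idx)) {
      key <- sub("^\\s+", "", substr(g[1], 1, 20))
      key <- sub("\\s.*$", "", key)
      body <- c(sub("^\\s*\\S+\\s*", "", g[1]), trimws(g[-1]))
      qual_at <- grep("^/", body)
      loc_txt <- paste(body[seq_len(if (length(qual_at)) qual_at[1] - 1L
                                    else length(body))], collapse = "")
      quals <- parse_qualifiers(body[qual_at])
      if (key == "gene") {
        if (gene_symbol == "" && !is.null(quals[["gene"]])) {
          gene_symbol <- quals[["gene"]]
        }
        if (!is.null(quals[["gene_synonym"]])) {
          aliases <- union(aliases,
                           trimws(strsplit(quals[["gene_synonym"]],
                                           "[;,]")[[1]]))
        }
      } else if (normalize_kind(key) %in% c(SUBSEQ_KINDS, "exon")) {
        iv <- parse_location(loc_txt, line = g[1])
        features[[length(features) + 1L]] <- list(
          kind = normalize_kind(key),
          label = if (is.null(quals[["gene"]])) "" else quals[["gene"]],
          transcript_id = quals[["transcript_id"]],
          intervals = iv
        )
      }
    }
  }

  n <- nchar(seq_txt)
  for (f in features) {
    if (any(f$intervals < 1) || any(f$intervals > n)) {
      stop("feature interval outside sequence for feature of kind ", f$kind)
    }
  }

  structure(list(
    accession = accession,
    symbol = gene_symbol,
    aliases = aliases,
    sequence = seq_txt,
    contig_span = c(1L, n),
    strand = "+",
    features = features
  ), class = "gene_record")
}

as_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

parse_qualifiers <- function(lines) {
  quals <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "/")) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        cur <- substr(ln, 2, eq - 1)
        quals[[cur]] <- gsub("\"", "", substr(ln, eq + 1, nchar(ln)))
      } else {
        cur <- substr(ln, 2, nchar(ln))
        quals[[cur]] <- ""
      }
    } else if (!is.null(cur)) {
      quals[[cur]] <- paste(quals[[cur]], gsub("\"", "", ln))
    }
  }
  quals
}

parse_location <- function(loc, line = loc) {
  loc <- gsub("\\s", "", loc)
  loc <- gsub("complement\\(|join\\(|order\\(", "", loc)
  loc <- gsub("\\)", "", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0) stop("malformed feature location at line: ", line)
  iv <- t(vapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", p))[[1]]
    if (length(m) == 0) stop("malformed feature location at line: ", line)
    a <- as.integer(m[2])
    b <- if (m[4] == "") a else as.integer(m[4])
    if (b < a) stop("malformed feature location (end < start) at line: ", line)
    c(a, b)
  }, integer(2)))
  dimnames(iv) <- list(NULL, c("start", "end"))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
    stop("overlapping intervals in feature location at line: ", line)
  }
  iv
}

#' Select the subsequence feature to design against
#'
#' Applies the feature-priority rule: `mRNA` features are preferred, then
#' `CDS`, then `miscRNA`. Within a kind, only features labeled with the
#' record's gene symbol or one of its aliases are considered (this keeps
#' overlapping genes in other reading frames from being picked up); when
#' the record carries no symbol every feature qualifies. If several
#' features remain the first is used and a warning is issued, unless the
#' caller states a preference by `index` or `transcript_id`. A `kind`
#' preference (e.g. `CDS`) skips the higher-priority kinds. When only
#' `exon` features exist they are pooled into a single exon-group feature;
#' with no subsequence features at all a whole-sequence sentinel (kind
#' `"whole"`) is returned.
#'
#' @param record A `gene_record`.
#' @param preference Optional list with any of `kind`, `index`,
#'   `transcript_id`.
#' @return A feature list (`kind`, `label`, `transcript_id`, `intervals`).
#' @export
select_feature <- function(record, preference = NULL) {
  stopifnot(inherits(record, "gene_record"))
  pref_kind <- preference$kind
  pref_index <- preference$index
  pref_tid <- preference$transcript_id

  label_ok <- function(f) {
    if (record$symbol == "") return(TRUE)
    f$label == "" ||
      tolower(f$label) %in% tolower(c(record$symbol, record$aliases))
  }

  kinds <- SUBSEQ_KINDS
  if (!is.null(pref_kind)) {
    pref_kind <- normalize_kind(pref_kind)
    if (!pref_kind %in% c(SUBSEQ_KINDS, "exon")) {
      stop("unknown feature kind preference: ", pref_kind)
    }
    kinds <- if (pref_kind == "exon") character() else pref_kind
  }

  for (k in kinds) {
    cand <- Filter(function(f) f$kind == k && label_ok(f), record$features)
    if (length(cand) == 0) next
    if (!is.null(pref_tid)) {
      hit <- Filter(function(f) identical(f$transcript_id, pref_tid), cand)
      if (length(hit) == 0) {
        stop("no ", k, " feature with transcript id ", pref_tid)
      }
      return(hit[[1]])
    }
    if (!is.null(pref_index)) {
      if (pref_index < 1 || pref_index > length(cand)) {
        stop("feature index ", pref_index, " out of range: ",
             length(cand), " ", k, " feature(s) available")
      }
      return(cand[[pref_index]])
    }
    if (length(cand) > 1) {
      warning("multiple ", k, " features found; using the first ",
              "(set a feature index or transcript id to override)")
    }
    return(cand[[1]])
  }

  exons <- Filter(function(f) f$kind == "exon" && label_ok(f),
                  record$features)
  if (length(exons) > 0) {
    iv <- do.call(rbind, lapply(exons, function(f) f$intervals))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    return(list(kind = "exon", label = exons[[1]]$label,
                transcript_id = NULL, intervals = iv))
  }

  # whole-sequence fallback
  list(kind = "whole", label = record$symbol, transcript_id = NULL,
       intervals = matrix(c(1L, nchar(record$sequence)), nrow = 1,
                          dimnames = list(NULL, c("start", "end"))))
}

#' Extract an exon, intron or whole-sequence fragment with flanks
#'
#' Slices the record around the requested region and attaches `long_flank`
#' bases of context on each side (short exons and edge-proximal binding
#' sites need flanking sequence; the long flank is what the amplicon
#' uniqueness screen looks at). Bases beyond the record boundary are
#' padded with the placeholder `N`, which never matches a template
#' position or an enzyme site. Intron `k` is the maximal gap between
#' exon blocks `k` and `k+1` of the selected feature.
#'
#' @param record A `gene_record`.
#' @param feature A feature from [select_feature()] (ignored for
#'   `region_kind = "A"`).
#' @param region_kind `"E"` (exon), `"I"` (intron) or `"A"` (whole
#'   sequence).
#' @param region_index 1-based exon/intron number.
#' @param short_flank,long_flank Flank widths in bp (see Details of the
#'   package vignette for the reporting conventions they induce).
#' @return An object of class `tal_fragment`: `region_kind`,
#'   `region_index`, `region_label`, `core_start`, `core_end` (record
#'   coords), `short_flank`, `long_flank`, `sequence`
#'   (length `core + 2*long_flank`), `offset_to_record`.
#' @export
extract_fragment <- function(record, feature = NULL,
                             region_kind = c("A", "E", "I"),
                             region_index = 1L,
                             short_flank = 25L, long_flank = 150L) {
  stopifnot(inherits(record, "gene_record"),
            short_flank >= 0, long_flank >= 0)
  region_kind <- match.arg(region_kind)
  n <- nchar(record$sequence)

  if (region_kind == "A") {
    core <- c(1L, n)
  } else {
    if (is.null(feature)) stop("a feature is required for exon/intron regions")
    iv <- feature$intervals
    if (region_kind == "E") {
      if (region_index < 1 || region_index > nrow(iv)) {
        stop("exon index ", region_index, " out of range: regions E1..E",
             nrow(iv), " available")
      }
      core <- c(iv[region_index, 1], iv[region_index, 2])
    } else {
      if (nrow(iv) < 2 || region_index < 1 || region_index > nrow(iv) - 1) {
        stop("intron index ", region_index, " out of range: ",
             if (nrow(iv) < 2) "no introns available" else
               paste0("regions I1..I", nrow(iv) - 1, " available"))
      }
      core <- c(iv[region_index, 2] + 1L, iv[region_index + 1, 1] - 1L)
      if (core[2] < core[1]) {
        stop("intron ", region_index, " is empty (adjacent exon blocks)")
      }
    }
  }

  lo <- core[1] - long_flank
  hi <- core[2] + long_flank
  chars <- rep("N", hi - lo + 1L)
  in_rec <- seq(max(lo, 1L), min(hi, n))
  if (length(in_rec) > 0) {
    chars[in_rec - lo + 1L] <- strsplit(record$sequence, "")[[1]][in_rec]
  }

  structure(list(
    region_kind = region_kind,
    region_index = as.integer(region_index),
    region_label = paste0(region_kind, region_index),
    core_start = as.integer(core[1]),
    core_end = as.integer(core[2]),
    short_flank = as.integer(short_flank),
    long_flank = as.integer(long_flank),
    sequence = paste(chars, collapse = ""),
    offset_to_record = as.integer(core[1] - long_flank - 1L)
  ), class = "tal_fragment")
}

#' Build an NCBI EFetch URL for a genomic span
#'
#' Pure string construction for the E-utilities EFetch endpoint, using a
#' RefSeq accession and 1-based inclusive start/stop coordinates. The URL
#' is never fetched by this package's tests; network retrieval is left to
#' the caller.
#'
#' @param accession RefSeq accession, e.g. `"NC_007118.5"`.
#' @param start,end 1-based inclusive span on the contig (`start <= end`).
#' @param strand `"+"` or `"-"` (encoded as `strand=1` / `strand=2`).
#' @return The EFetch URL as a character scalar.
#' @examples
#' build_efetch_request("NC_007118.5", 21501610, 21527471, "+")
#' @export
build_efetch_request <- function(accession, start, end, strand = "+") {
  if (!is.character(accession) || length(accession) != 1L ||
      !nzchar(accession)) {
    stop("accession must be a non-empty string")
  }
  stopifnot(start <= end, strand %in% c("+", "-"))
  sprintf(paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                 "efetch.fcgi?db=nuccore&id=%s&seq_start=%d&seq_stop=%d",
                 "&strand=%d&rettype=gb&retmode=text"),
          accession, as.integer(start), as.integer(end),
          if (strand == "+") 1L else 2L)
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record>", x$accession, if (nzchar(x$symbol)) x$symbol else NULL,
      "\n  sequence:", nchar(x$sequence), "bp;",
      length(x$features), "subsequence feature(s)\n")
  invisible(x)
}

#' @export
print.tal_fragment <- function(x, ...) {
  cat("<tal_fragment>", x$region_label,
      sprintf("core %d..%d (%d bp), flanks short=%d long=%d, seq %d bp\n",
              x$core_start, x$core_end, x$core_end - x$core_start + 1L,
              x$short_flank, x$long_flank, nchar(x$sequence)))
  invisible(x)
}
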