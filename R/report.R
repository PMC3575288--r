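# Report rendering and the end-to-end pipeline.
#
# Reporting conventions: binding-site spans use the "first-last(length)"
# notation, 1-based and relative to the start of the short-flanked
# subsequence (core minus short_flank); enzyme positions are 1-based from
# the start of the long-flanked fragment. Site 1 and the spacer define
# the forward direction regardless of source strand; the reverse
# complement of site 2 (the sequence the second TAL protein actually
# binds) is printed alongside.

#' Assemble per-site report records
#'
#' Joins enumerated pairs with their enzyme screens into the flat
#' structures the renderers consume.
#'
#' @param pairs Output of [enumerate_pairs()].
#' @param fragment The source `tal_fragment`.
#' @param hits_list List of `enzyme_hits`, parallel to rows of `pairs`
#'   (may be `NULL` for single-site style reports).
#' @param gene_symbol Symbol printed at the head of each site block.
#' @param buffer Which PCR-buffer score column to surface
#'   (`"standard"`, `"thermopol"`, `"phusion"` or `"crimson"`).
#' @return List of `site_record` lists.
#' @export
site_records <- function(pairs, fragment, hits_list = NULL,
                         gene_symbol = "", buffer = "standard") {
  stopifnot(inherits(fragment, "tal_fragment"))
  buffer <- match.arg(buffer, BUFFER_NAMES)
  # fragment coord -> reported (short-flank-relative) coord
  shift <- fragment$long_flank - fragment$short_flank
  lapply(seq_len(nrow(pairs)), function(i) {
    p <- as.list(pairs[i, ])
    hits <- if (is.null(hits_list)) NULL else hits_list[[i]]
    span <- function(start, len) {
      first <- start - shift
      sprintf("%d-%d(%d)", first, first + len - 1L, len)
    }
    structure(list(
      gene_symbol = gene_symbol,
      region_label = fragment$region_label,
      site_index = p$index,
      site1_span = span(p$site1_start, p$site1_len),
      site2_span = span(p$site2_start, p$site2_len),
      site1_seq = p$site1_seq,
      spacer_seq = p$spacer_seq,
      site2_seq = p$site2_seq,
      site2_revcomp_seq = p$site2_revcomp,
      rvd1 = p$rvd1,
      rvd2 = p$rvd2,
      buffer = buffer,
      hits = hits
    ), class = "site_record")
  })
}

#' Render site records as the flat-text report
#'
#' One block per candidate site: the header line
#' `<symbol> <region> Site <n>`, the two binding sites (`TAL1`, `TAL2`)
#' with their `first-last(length)` spans, the spacer, the reverse
#' complement of site 2, tab-delimited RVD strings, and one line per
#' suitable enzyme (name, prototype, buffer score 0-9, absolute position
#' — prefixed `-` for a reverse-strand recognition match — and the
#' relative second cut, left empty for enzymes unique in the amplicon).
#'
#' @param records List from [site_records()].
#' @return The report as a single string.
#' @export
render_text <- function(records) {
  out <- c("talenforge TALEN design report",
           paste0("sites: ", length(records)), "")
  for (r in records) {
    head <- trimws(paste(r$gene_symbol, r$region_label,
                         paste0("Site ", r$site_index)))
    out <- c(out,
      paste0("== ", head, " =="),
      paste0("TAL1    ", r$site1_span, "  ", r$site1_seq),
      paste0("Spacer  ", r$spacer_seq),
      paste0("TAL2    ", r$site2_span, "  ", r$site2_seq),
      paste0("TAL2rc  ", r$site2_revcomp_seq),
      paste0("RVD1    ", r$rvd1),
      paste0("RVD2    ", r$rvd2))
    if (!is.null(r$hits)) {
      out <- c(out, "Enzymes (name prototype score position second_cut):")
      if (nrow(r$hits) == 0) {
        out <- c(out, "  (none unique in amplicon)")
      } else {
        score <- r$hits[[paste0("score_", r$buffer)]]
        for (j in seq_len(nrow(r$hits))) {
          h <- r$hits[j, ]
          out <- c(out, sprintf("  %s\t%s\t%s\t%s%d\t%s",
            h$enzyme, h$prototype,
            ifelse(is.na(score[j]), "", as.character(score[j])),
            ifelse(h$strand == "-", "-", ""), h$position,
            ifelse(is.na(h$second_cut_rel), "",
                   as.character(h$second_cut_rel))))
        }
      }
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

CSV_COLUMNS <- c("gene", "region", "site", "site1_span", "site1_seq",
                 "rvd1", "spacer_seq", "site2_span", "site2_seq",
                 "site2_revcomp", "rvd2", "enzyme", "prototype", "buffer",
                 "buffer_score", "strand", "position", "second_cut_rel")

#' Render site records as CSV
#'
#' One row per (site, enzyme hit); a site with no suitable enzymes still
#' yields one row with the enzyme columns empty. Fields are RFC
#' 4180-quoted; the fixed column order is documented in the README. RVD
#' strings use `|` as the within-field separator (tabs do not survive
#' CSV round-trips in common spreadsheet tools).
#'
#' @param records List from [site_records()].
#' @return CSV text as a single string (header always present).
#' @export
render_csv <- function(records) {
  rows <- list()
  for (r in records) {
    base <- data.frame(
      gene = r$gene_symbol, region = r$region_label, site = r$site_index,
      site1_span = r$site1_span, site1_seq = r$site1_seq,
      rvd1 = gsub("\t", "|", r$rvd1, fixed = TRUE),
      spacer_seq = r$spacer_seq, site2_span = r$site2_span,
      site2_seq = r$site2_seq, site2_revcomp = r$site2_revcomp_seq,
      rvd2 = gsub("\t", "|", r$rvd2, fixed = TRUE),
      stringsAsFactors = FALSE)
    if (is.null(r$hits) || nrow(r$hits) == 0) {
      rows[[length(rows) + 1L]] <- cbind(base, data.frame(
        enzyme = "", prototype = "", buffer = "", buffer_score = NA_integer_,
        strand = "", position = NA_integer_, second_cut_rel = NA_integer_,
        stringsAsFactors = FALSE))
    } else {
      score <- r$hits[[paste0("score_", r$buffer)]]
      for (j in seq_len(nrow(r$hits))) {
        h <- r$hits[j, ]
        rows[[length(rows) + 1L]] <- cbind(base, data.frame(
          enzyme = h$enzyme, prototype = h$prototype, buffer = r$buffer,
          buffer_score = score[j], strand = h$strand,
          position = h$position, second_cut_rel = h$second_cut_rel,
          stringsAsFactors = FALSE))
      }
    }
  }
  df <- if (length(rows) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)),
                                        length(CSV_COLUMNS)), CSV_COLUMNS),
                           stringsAsFactors = FALSE)
    empty
  } else {
    do.call(rbind, rows)[, CSV_COLUMNS]
  }
  con <- textConnection("csv_out", "w", local = TRUE)
  write.csv(df, con, row.names = FALSE, na = "")
  close(con)
  paste0(paste(csv_out, collapse = "\n"), "\n")
}

#' Read the first (or a named) record from a FASTA file
#'
#' @param path FASTA file (multi-record permitted).
#' @param record Optional name or index of the record to use; default the
#'   first.
#' @return A `gene_record` with the FASTA name word as symbol and no
#'   subsequence features.
#' @export
read_fasta_record <- function(path, record = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no sequences in FASTA file: ", path)
  idx <- 1L
  if (!is.null(record)) {
    if (is.numeric(record)) {
      idx <- as.integer(record)
      if (idx < 1 || idx > length(set)) {
        stop("FASTA record index out of range: ", record)
      }
    } else {
      first_words <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
      idx <- match(record, first_words)
      if (is.na(idx)) stop("FASTA record not found: ", record)
    }
  }
  nm <- strsplit(names(set)[idx], "\\s+")[[1]][1]
  seq_txt <- toupper(as.character(set[[idx]]))
  assert_dna(seq_txt, allow_n = TRUE, what = "FASTA sequence")
  structure(list(
    accession = nm, symbol = nm, aliases = character(),
    sequence = seq_txt, contig_span = c(1L, nchar(seq_txt)),
    strand = "+", features = list()
  ), class = "gene_record")
}

#' Default pipeline configuration
#'
#' @param ... Overrides of any default (see [run_pipeline()]).
#' @return A named list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fasta = NULL, gene_file = NULL, record = NULL,
    region = "A", region_index = 1L,
    feature_kind = NULL, feature_index = NULL, transcript_id = NULL,
    short_flank = 25L, long_flank = 150L,
    template = "Ts.*e",
    site_len = c(15L, 17L), spacer_len = c(15L, 16L),
    increment = NULL, single_site = FALSE,
    rebase = NULL, prototypes = NULL, buffer_scores = NULL,
    vendors = NULL, buffer = "standard",
    min_second_cut = 80L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full design pipeline
#'
#' Sequence input (FASTA or GenBank flat file) → feature selection →
#' fragment extraction → pair enumeration → RVD encoding → spacer
#' restriction screen → report rendering. Exactly one of `fasta` /
#' `gene_file` must be given. FASTA input carries no subsequence
#' annotation, so the whole sequence is analyzed as region `A` with zero
#' flanks (the sequence supplied *is* the region of interest). In
#' single-site mode no enzyme analysis is performed.
#'
#' @param config A list from [pipeline_config()].
#' @return Invisible list with `records`, `pairs` (or `sites` in
#'   single-site mode), `fragment`, `text`, `csv` and `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.null(config$fasta) == is.null(config$gene_file)) {
    stop("exactly one input source (fasta or gene_file) must be given")
  }
  warns <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  if (!is.null(config$fasta)) {
    if (!file.exists(config$fasta)) stop("file not found: ", config$fasta)
    record <- read_fasta_record(config$fasta, config$record)
    region <- "A"
  } else {
    if (!file.exists(config$gene_file)) {
      stop("file not found: ", config$gene_file)
    }
    record <- parse_gene_record(config$gene_file)
    region <- config$region
  }

  pref <- NULL
  if (!is.null(config$feature_kind) || !is.null(config$feature_index) ||
      !is.null(config$transcript_id)) {
    pref <- list(kind = config$feature_kind, index = config$feature_index,
                 transcript_id = config$transcript_id)
  }
  feature <- wh(select_feature(record, pref))
  if (feature$kind == "whole") region <- "A"

  # an arbitrary sequence is the region of interest itself: no flanks
  sf <- if (region == "A") 0L else config$short_flank
  lf <- if (region == "A") 0L else config$long_flank
  fragment <- extract_fragment(record, feature, region,
                               config$region_index, sf, lf)

  template <- parse_template(config$template)
  sc <- search_config(config$site_len, config$spacer_len,
                      config$increment, config$single_site)

  db <- parse_rebase(
    if (is.null(config$rebase))
      system.file("extdata", "rebase_bairoch.txt", package = "talenforge")
    else config$rebase,
    prototype_table = if (is.null(config$prototypes))
      system.file("extdata", "prototypes.tsv", package = "talenforge")
    else config$prototypes,
    buffer_scores = if (is.null(config$buffer_scores))
      system.file("extdata", "synthetic_buffer_scores.tsv",
                  package = "talenforge")
    else config$buffer_scores)
  if (!is.null(config$vendors)) db <- filter_by_vendor(db, config$vendors)

  if (isTRUE(config$single_site)) {
    sites <- enumerate_single_sites(fragment, template, sc)
    shift <- fragment$long_flank - fragment$short_flank
    records <- lapply(seq_len(nrow(sites)), function(i) {
      s <- as.list(sites[i, ])
      first <- s$start - shift
      structure(list(
        gene_symbol = record$symbol, region_label = fragment$region_label,
        site_index = s$index,
        site1_span = sprintf("%d-%d(%d)", first, first + s$len - 1L, s$len),
        site2_span = "", site1_seq = s$seq, spacer_seq = "",
        site2_seq = "", site2_revcomp_seq = "", rvd1 = s$rvd,
        rvd2 = "", buffer = config$buffer, hits = NULL
      ), class = "site_record")
    })
    out <- list(records = records, sites = sites, fragment = fragment)
  } else {
    pairs <- enumerate_pairs(fragment, template, sc)
    hits_list <- lapply(seq_len(nrow(pairs)), function(i) {
      analyze_pair(pairs[i, ], fragment, db,
                   long_flank = config$long_flank,
                   min_second_cut = config$min_second_cut)
    })
    records <- site_records(pairs, fragment, hits_list,
                            gene_symbol = record$symbol,
                            buffer = config$buffer)
    out <- list(records = records, pairs = pairs, fragment = fragment)
  }
  out$text <- render_text(out$records)
  out$csv <- render_csv(out$records)
  out$warnings <- warns
  invisible(out)
}
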