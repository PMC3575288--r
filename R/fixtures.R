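# Deterministic synthetic-data generators. Everything the package needs
# for testing -- fragments with a planted TALEN pair and enzyme sites,
# and GenBank records with chosen feature combinations -- is built in
# code from an explicit seed, so no download or binary fixture is ever
# required.

#' Specification for a planted-pair test fragment
#'
#' Describes a designed test sequence carrying exactly one TALEN pair:
#' the construct `T + site1 + spacer + site2 + A` (the two thymine
#' anchors flank the arms; the one on the reverse strand appears as an A
#' on the forward strand) is embedded in the middle of a seeded random
#' background. The default background is pure G/C (`gc_fraction = 1`):
#' with the permissive default template any background A or T could seed
#' an accidental anchor pair, and a designed test sequence must contain
#' exactly one site. The default arm/spacer lengths are 15/15/15 bp, the
#' only geometry in the default length ranges whose anchor-to-anchor span
#' has a single (site1, spacer, site2) decomposition — wider spans are
#' re-segmentable and would legitimately enumerate as several candidate
#' pairs. The default spacer embeds an NsiI recognition site (`ATGCAT`).
#'
#' @param seed Integer seed for the background draw.
#' @param background_length Total fragment length in bp.
#' @param gc_fraction Background G+C fraction in `[0,1]`.
#' @param site1,site2 Arm sequences (forward strand).
#' @param spacer Spacer sequence.
#' @param enzyme_site Recognition site expected inside the spacer
#'   (recorded in the ground truth), or `NULL`.
#' @param decoy_sites List of `list(recognition =, position =)` sites to
#'   plant outside the spacer, `position` being the 1-based fragment
#'   coordinate of the first base.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(seed = 1L, background_length = 300L,
                       gc_fraction = 1.0,
                       site1 = "GCCGGCGCCGGCGCC",
                       spacer = "GCGGATGCATGGCGG",
                       site2 = "GGCGCCGGCGCCGGC",
                       enzyme_site = "ATGCAT",
                       decoy_sites = list()) {
  assert_dna(site1, allow_n = FALSE, what = "site1")
  assert_dna(site2, allow_n = FALSE, what = "site2")
  assert_dna(spacer, allow_n = FALSE, what = "spacer")
  construct_len <- nchar(site1) + nchar(spacer) + nchar(site2) + 2L
  stopifnot(background_length >= construct_len)
  structure(list(seed = as.integer(seed),
                 background_length = as.integer(background_length),
                 gc_fraction = gc_fraction,
                 site1 = toupper(site1), spacer = toupper(spacer),
                 site2 = toupper(site2), enzyme_site = enzyme_site,
                 decoy_sites = decoy_sites),
            class = "plant_spec")
}

#' Coordinates a plant_spec will occupy, without generating
#'
#' The construct is centered, so all planted coordinates are a pure
#' function of the spec; tests use this to place decoy sites at exact
#' distances from the spacer's enzyme site.
#'
#' @param spec A [plant_spec()].
#' @return List with `site1_start`, `site1_len`, `spacer_start`,
#'   `spacer_len`, `site2_start`, `site2_len`, `enzyme_pos` (fragment
#'   coordinate of the planted recognition site, or `NA`).
#' @export
planted_layout <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  l1 <- nchar(spec$site1); sp <- nchar(spec$spacer); l2 <- nchar(spec$site2)
  construct_len <- l1 + sp + l2 + 2L
  p0 <- (spec$background_length - construct_len) %/% 2L + 1L  # the 5' T
  site1_start <- p0 + 1L
  spacer_start <- site1_start + l1
  enzyme_pos <- NA_integer_
  if (!is.null(spec$enzyme_site)) {
    off <- regexpr(spec$enzyme_site, spec$spacer, fixed = TRUE)
    if (off > 0) enzyme_pos <- spacer_start + as.integer(off) - 1L
  }
  list(site1_start = site1_start, site1_len = l1,
       spacer_start = spacer_start, spacer_len = sp,
       site2_start = spacer_start + sp, site2_len = l2,
       enzyme_pos = enzyme_pos)
}

#' Generate a fragment with one planted TALEN pair
#'
#' Draws the background from a seeded generator at the requested GC
#' content, embeds the anchored construct and any decoy recognition
#' sites, and verifies by exhaustive enumeration that the planted pair is
#' the only candidate the template/length configuration admits. If an
#' accidental site appears the background is redrawn, up to
#' `max_attempts`; persistent failure raises an error suggesting a
#' longer or lower-complexity background.
#'
#' @param spec A [plant_spec()].
#' @param template,config Search settings the uniqueness guarantee is
#'   checked against.
#' @param max_attempts Background redraws before giving up.
#' @return List with `fragment` (a whole-sequence `tal_fragment`) and
#'   `truth` (the planted coordinates from [planted_layout()] plus
#'   `decoy_positions`).
#' @export
generate_planted_fragment <- function(spec,
                                      template = parse_template(),
                                      config = search_config(),
                                      max_attempts = 25L) {
  stopifnot(inherits(spec, "plant_spec"))
  layout <- planted_layout(spec)
  construct <- paste0("T", spec$site1, spec$spacer, spec$site2, "A")
  p0 <- layout$site1_start - 1L
  construct_span <- seq(p0, p0 + nchar(construct) - 1L)

  decoy_spans <- lapply(spec$decoy_sites, function(d) {
    assert_iupac(d$recognition, "decoy recognition site")
    span <- seq(d$position, d$position + nchar(d$recognition) - 1L)
    if (any(span < 1) || any(span > spec$background_length)) {
      stop("decoy site at position ", d$position, " falls outside the fragment")
    }
    if (any(span %in% c(construct_span,
                        seq(p0 - 1L, p0 + nchar(construct))))) {
      stop("decoy site at position ", d$position,
           " overlaps the planted construct")
    }
    span
  })

  set.seed(spec$seed)
  for (attempt in seq_len(max_attempts)) {
    chars <- strsplit(random_dna(spec$background_length, spec$gc_fraction),
                      "")[[1]]
    chars[construct_span] <- strsplit(construct, "")[[1]]
    for (i in seq_along(spec$decoy_sites)) {
      # degenerate decoy positions are instantiated with a concrete base
      rec <- strsplit(spec$decoy_sites[[i]]$recognition, "")[[1]]
      chars[decoy_spans[[i]]] <- vapply(rec, function(b) {
        sample(IUPAC_SETS[[b]], 1L)
      }, "")
    }
    seq_txt <- paste(chars, collapse = "")
    fragment <- structure(list(
      region_kind = "A", region_index = 1L, region_label = "A1",
      core_start = 1L, core_end = spec$background_length,
      short_flank = 0L, long_flank = 0L,
      sequence = seq_txt, offset_to_record = 0L
    ), class = "tal_fragment")

    pairs <- enumerate_pairs(fragment, template,
                             search_config(config$site_len,
                                           config$spacer_len,
                                           increment = 1L))
    ok <- nrow(pairs) == 1L &&
      pairs$site1_start == layout$site1_start &&
      pairs$site1_len == layout$site1_len &&
      pairs$spacer_len == layout$spacer_len &&
      pairs$site2_len == layout$site2_len
    if (ok) {
      truth <- layout
      truth$decoy_positions <- vapply(spec$decoy_sites,
                                      function(d) d$position, integer(1))
      return(list(fragment = fragment, truth = truth))
    }
  }
  stop("could not generate a fragment with a unique planted pair in ",
       max_attempts, " attempts; try a longer background or a lower ",
       "A/T content (gc_fraction closer to 1)")
}

#' Generate a synthetic GenBank flat-file record
#'
#' Writes a syntactically valid GenBank record with the requested exon
#' structure and subsequence features, for exercising the parser and the
#' feature-priority rules without any download.
#'
#' @param exon_lengths Integer vector of exon lengths (bp, 5'→3').
#' @param intron_lengths Integer vector of intron lengths
#'   (`length(exon_lengths) - 1` entries; ignored for a single exon).
#' @param features Character vector of feature kinds to annotate
#'   (`"mRNA"`, `"CDS"`, `"misc_RNA"`, `"exon"`), or a data frame with
#'   columns `kind` and `label` (and optionally `transcript_id`) for
#'   alias-labeled cases. mRNA/CDS/misc_RNA features span all exon
#'   blocks as a `join(...)`; `"exon"` emits one feature per block.
#' @param seed RNG seed for the sequence draw.
#' @param symbol Gene symbol (the `gene` feature's `/gene`).
#' @param aliases Alias symbols (the `/gene_synonym` qualifier).
#' @param pad Plain sequence padding before the first and after the last
#'   exon, bp.
#' @param accession Accession string for the LOCUS/ACCESSION lines.
#' @return The GenBank record as a single string.
#' @export
generate_gene_record <- function(exon_lengths, intron_lengths = integer(),
                                 features = "mRNA", seed = 1L,
                                 symbol = "genA", aliases = character(),
                                 pad = 50L, accession = "SYN000001") {
  stopifnot(all(exon_lengths > 0),
            length(intron_lengths) == max(0L, length(exon_lengths) - 1L),
            all(intron_lengths > 0) || length(intron_lengths) == 0)
  if (is.character(features)) {
    features <- data.frame(kind = features,
                           label = rep(symbol, length(features)),
                           stringsAsFactors = FALSE)
  }
  if (!"transcript_id" %in% names(features)) {
    features$transcript_id <- rep(NA_character_, nrow(features))
  }

  n_ex <- length(exon_lengths)
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- pad
  for (i in seq_len(n_ex)) {
    starts[i] <- pos + 1L
    ends[i] <- pos + exon_lengths[i]
    pos <- ends[i] + if (i < n_ex) intron_lengths[i] else 0L
  }
  total <- pos + pad
  set.seed(seed)
  seq_txt <- random_dna(total, 0.5)

  join_loc <- if (n_ex == 1L) sprintf("%d..%d", starts[1], ends[1]) else
    sprintf("join(%s)", paste(sprintf("%d..%d", starts, ends),
                              collapse = ","))

  lines <- c(
    sprintf("LOCUS       %s %16d bp    DNA     linear   SYN 01-JAN-2020",
            accession, total),
    sprintf("DEFINITION  synthetic record for %s.", symbol),
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", total),
    sprintf("     gene            %d..%d", starts[1], ends[n_ex]),
    sprintf("                     /gene=\"%s\"", symbol))
  if (length(aliases) > 0) {
    lines <- c(lines, sprintf("                     /gene_synonym=\"%s\"",
                              paste(aliases, collapse = "; ")))
  }
  tcount <- 0L
  for (i in seq_len(nrow(features))) {
    kind <- features$kind[i]
    label <- features$label[i]
    if (kind == "exon") {
      for (j in seq_len(n_ex)) {
        lines <- c(lines,
          sprintf("     exon            %d..%d", starts[j], ends[j]),
          sprintf("                     /gene=\"%s\"", label))
      }
    } else {
      lines <- c(lines,
        sprintf("     %-15s %s", kind, join_loc),
        sprintf("                     /gene=\"%s\"", label))
      if (kind == "mRNA") {
        tcount <- tcount + 1L
        tid <- features$transcript_id[i]
        if (is.na(tid)) tid <- sprintf("SYNT%04d.1", tcount)
        lines <- c(lines,
          sprintf("                     /transcript_id=\"%s\"", tid))
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  low <- tolower(seq_txt)
  for (off in seq(1L, total, by = 60L)) {
    chunk <- substr(low, off, min(off + 59L, total))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(groups, collapse = " ")))
  }
  lines <- c(lines, "//")
  paste(lines, collapse = "\n")
}
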