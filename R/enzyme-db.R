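# REBASE parsing and enzyme metadata. The canonical input is the
# Bairoch-style flat dialect (ID / RS / CR line records separated by
# "//"). Only commercially available enzymes (those with at least one
# supplier code on the CR line) are retained: RFLP screening is pointless
# for enzymes nobody can buy. Prototype names (the first-described enzyme
# of each isoschizomer family) come from a separate two-column table, and
# PCR-buffer compatibility scores from a three-column activity table,
# rescaled onto [0,9].

BUFFER_NAMES <- c("standard", "thermopol", "phusion", "crimson")

#' Parse a Bairoch-style REBASE enzyme database
#'
#' Reads `ID` (enzyme name), `RS` (recognition site, possibly carrying
#' cut-position annotation such as `^` or `(a/b)` offsets, which is
#' stripped for matching but kept as metadata) and `CR` (single-letter
#' commercial-supplier codes) lines. Records lacking any supplier code
#' are dropped. Recognition sites are upper-cased and validated against
#' the IUPAC degenerate alphabet.
#'
#' @param rebase_text REBASE file content (string, lines, or a path).
#' @param prototype_table Optional two-column TSV (`enzyme<TAB>prototype`)
#'   as text or path; unlisted enzymes get themselves as prototype.
#' @param buffer_scores Optional three-column TSV
#'   (`enzyme<TAB>buffer<TAB>raw`) of raw PCR-buffer activities; each
#'   buffer's scores are rescaled onto 0-9 with
#'   [rescale_buffer_score()] using that buffer's maximum raw value.
#' @return A data frame of class `enzyme_db` with columns `name`,
#'   `prototype`, `recognition`, `cut_annotation`, `vendor_codes` and one
#'   `score_<buffer>` column per buffer, plus a `source_version`
#'   attribute.
#' @export
parse_rebase <- function(rebase_text, prototype_table = NULL,
                         buffer_scores = NULL) {
  lines <- as_text_lines(rebase_text)
  lines <- lines[!grepl("^#", lines)]
  recs <- list()
  cur <- list()
  flush <- function(cur) {
    if (is.null(cur$ID)) {
      if (length(cur) > 0) stop("REBASE record without ID line")
      return(NULL)
    }
    if (is.null(cur$RS)) {
      stop("REBASE record ", cur$ID, " has no RS (recognition site) line")
    }
    cr <- if (is.null(cur$CR)) "" else cur$CR
    codes <- regmatches(cr, gregexpr("[A-Z]", cr))[[1]]
    raw_rs <- sub(";\\s*$", "", trimws(cur$RS))
    rs <- gsub("\\([0-9-]+/[0-9-]+\\)", "", raw_rs)
    rs <- gsub("\\^", "", rs)
    rs <- toupper(gsub("\\s", "", rs))
    if (grepl(",", rs)) {
      stop("REBASE record ", cur$ID,
           ": multiple recognition sites per record are not supported")
    }
    if (!nzchar(rs)) stop("REBASE record ", cur$ID, ": empty recognition site")
    assert_iupac(rs, what = paste0("recognition site of ", cur$ID))
    list(name = cur$ID, recognition = rs, cut_annotation = raw_rs,
         vendor_codes = paste(codes, collapse = ""))
  }
  for (ln in lines) {
    if (grepl("^//", ln)) {
      r <- flush(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- list()
    } else if (grepl("^(ID|RS|CR)\\b", ln)) {
      key <- substr(ln, 1, 2)
      val <- trimws(sub("^..\\s*", "", ln))
      cur[[key]] <- if (is.null(cur[[key]])) val else paste(cur[[key]], val)
    }
    # other Bairoch fields (ET, OS, PT, MS, ...) are ignored
  }
  r <- flush(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r

  keep <- Filter(function(r) nzchar(r$vendor_codes), recs)
  db <- if (length(keep) == 0) {
    data.frame(name = character(), recognition = character(),
               cut_annotation = character(), vendor_codes = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(keep, function(r) {
      data.frame(r, stringsAsFactors = FALSE)
    }))
  }

  # prototypes
  db$prototype <- db$name
  if (!is.null(prototype_table)) {
    pt <- read_two_col(prototype_table, c("enzyme", "prototype"))
    hit <- match(db$name, pt$enzyme)
    db$prototype[!is.na(hit)] <- pt$prototype[hit[!is.na(hit)]]
  }

  # buffer scores
  for (b in BUFFER_NAMES) {
    db[[paste0("score_", b)]] <- rep(NA_integer_, nrow(db))
  }
  if (!is.null(buffer_scores)) {
    bs <- read_buffer_table(buffer_scores)
    for (b in unique(bs$buffer)) {
      sub <- bs[bs$buffer == b, ]
      raw_max <- max(sub$raw)
      col <- paste0("score_", b)
      if (!col %in% names(db)) db[[col]] <- rep(NA_integer_, nrow(db))
      hit <- match(db$name, sub$enzyme)
      ok <- !is.na(hit)
      db[[col]][ok] <- vapply(sub$raw[hit[ok]], rescale_buffer_score,
                              integer(1), raw_max = raw_max)
    }
  }

  db <- db[order(db$name), c("name", "prototype", "recognition",
                             "cut_annotation", "vendor_codes",
                             paste0("score_", BUFFER_NAMES))]
  rownames(db) <- NULL
  attr(db, "source_version") <- source_version_of(lines)
  class(db) <- c("enzyme_db", "data.frame")
  db
}

source_version_of <- function(lines) {
  cc <- grep("^CC", lines, value = TRUE)
  v <- grep("version", cc, ignore.case = TRUE, value = TRUE)
  if (length(v) > 0) trimws(sub("^CC\\s*", "", v[1])) else "unversioned"
}

read_two_col <- function(x, col_names) {
  lines <- as_text_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop("malformed table line: ", lines[bad[1]])
  }
  df <- data.frame(do.call(rbind, lapply(parts, function(p) p[1:2])),
                   stringsAsFactors = FALSE)
  names(df) <- col_names
  df
}

read_buffer_table <- function(x) {
  lines <- as_text_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) stop("malformed buffer-score line: ", lines[bad[1]])
  df <- data.frame(do.call(rbind, lapply(parts, function(p) p[1:3])),
                   stringsAsFactors = FALSE)
  names(df) <- c("enzyme", "buffer", "raw")
  # tolerate a header row
  if (suppressWarnings(is.na(as.numeric(df$raw[1])))) df <- df[-1, ]
  df$buffer <- tolower(df$buffer)
  df$raw <- as.numeric(df$raw)
  if (anyNA(df$raw) || any(df$raw < 0)) {
    stop("buffer-score table has non-numeric or negative raw activities")
  }
  df
}

#' Restrict an enzyme database to selected vendors
#'
#' Keeps enzymes whose supplier codes intersect the requested set.
#' Narrowing the selection reduces the screening load downstream and
#' never adds enzymes; filtering by the intersection of two code sets
#' equals filtering twice.
#'
#' @param db An `enzyme_db`.
#' @param codes Character vector of single-letter supplier codes (or one
#'   string of them).
#' @return The filtered `enzyme_db`.
#' @export
filter_by_vendor <- function(db, codes) {
  stopifnot(inherits(db, "enzyme_db"))
  codes <- unique(unlist(strsplit(toupper(codes), "")))
  if (length(codes) == 0) stop("vendor code set must be non-empty")
  keep <- vapply(strsplit(db$vendor_codes, ""), function(v) {
    any(v %in% codes)
  }, logical(1))
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_version") <- attr(db, "source_version")
  class(out) <- class(db)
  out
}

#' Rescale a raw PCR-buffer activity onto 0-9
#'
#' Enzyme activities in each PCR buffer (standard, Thermopol, Phusion,
#' Crimson) are reported on an arbitrary raw scale; for display they are
#' rescaled onto the integer range 0-9, where 0 means no activity and the
#' raw maximum maps to 9. Rounding is half-up.
#'
#' @param raw Raw activity, `0 <= raw <= raw_max`.
#' @param raw_max The maximum raw activity on the source scale (> 0).
#' @return Integer score in `[0, 9]`.
#' @examples
#' rescale_buffer_score(0, 100)    # 0
#' rescale_buffer_score(50, 100)   # 5
#' rescale_buffer_score(100, 100)  # 9
#' @export
rescale_buffer_score <- function(raw, raw_max) {
  if (raw_max <= 0) stop("raw_max must be positive")
  stopifnot(raw >= 0, raw <= raw_max)
  as.integer(floor(9 * raw / raw_max + 0.5))
}

#' Load the packaged enzyme database
#'
#' Convenience loader for the REBASE-dialect fixture, prototype table and
#' synthetic buffer-score table shipped under `inst/extdata/`, or any
#' compatible user-supplied files.
#'
#' @param rebase,prototypes,buffer_scores Paths; defaults are the
#'   packaged files.
#' @return An `enzyme_db`.
#' @export
load_enzyme_db <- function(
    rebase = system.file("extdata", "rebase_bairoch.txt",
                         package = "talenforge"),
    prototypes = system.file("extdata", "prototypes.tsv",
                             package = "talenforge"),
    buffer_scores = system.file("extdata", "synthetic_buffer_scores.tsv",
                                package = "talenforge")) {
  parse_rebase(rebase, prototype_table = prototypes,
               buffer_scores = buffer_scores)
}
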