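# Independent brute-force oracles. These deliberately share no code with
# the package internals: complementation, template checking and IUPAC
# matching are re-derived from first principles so that agreement is
# meaningful.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(unname(oracle_comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Literal application of the binding-site consensus to every position and
# length triple: site 1 on the forward strand (T immediately 5', leading
# base sets just inside the site), site 2 on the reverse strand (so an A
# immediately 3' on the forward strand, leading sets on the reverse
# complement). Returns a data frame of (s1, l1, sp, l2).
oracle_pairs <- function(seq_txt, win_start, win_end,
                         site_len = c(15L, 17L), spacer_len = c(15L, 16L),
                         require_T = TRUE, leading = list(),
                         step = 1L) {
  chars <- strsplit(seq_txt, "")[[1]]
  n <- length(chars)
  out <- list()
  for (s1 in seq(win_start, min(win_end, n), by = step)) {
    for (l1 in site_len[1]:site_len[2]) {
      e1 <- s1 + l1 - 1L
      if (e1 > n) next
      site1 <- chars[s1:e1]
      if (any(site1 == "N")) next
      if (require_T && (s1 < 2 || chars[s1 - 1L] != "T")) next
      ok1 <- TRUE
      for (j in seq_along(leading)) {
        if (j > l1 || !(site1[j] %in% leading[[j]])) { ok1 <- FALSE; break }
      }
      if (!ok1) next
      for (sp in spacer_len[1]:spacer_len[2]) {
        for (l2 in site_len[1]:site_len[2]) {
          s2 <- s1 + l1 + sp
          e2 <- s2 + l2 - 1L
          if (e2 > n) next
          site2 <- chars[s2:e2]
          if (any(site2 == "N")) next
          if (require_T && (e2 + 1L > n || chars[e2 + 1L] != "A")) next
          rc2 <- rev(unname(oracle_comp[site2]))
          ok2 <- TRUE
          for (j in seq_along(leading)) {
            if (j > l2 || !(rc2[j] %in% leading[[j]])) { ok2 <- FALSE; break }
          }
          if (!ok2) next
          out[[length(out) + 1L]] <- c(s1 = s1, l1 = l1, sp = sp, l2 = l2)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(s1 = integer(), l1 = integer(), sp = integer(),
                      l2 = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_revcomp <- function(p) {
  pairs <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
             W = "W", S = "S", K = "M", M = "K", B = "V", V = "B",
             D = "H", H = "D", N = "N")
  paste(rev(unname(pairs[strsplit(p, "")[[1]]])), collapse = "")
}

# Position-by-position degenerate scan; a subject N matches nothing.
oracle_scan_one <- function(seq_txt, pattern) {
  sc <- strsplit(seq_txt, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  hits <- integer()
  if (length(sc) < w) return(hits)
  for (i in seq_len(length(sc) - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      b <- sc[i + j - 1L]
      if (b == "N" || !(b %in% oracle_iupac_sets[[pc[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_match_recognition <- function(seq_txt, recognition) {
  fwd <- oracle_scan_one(seq_txt, recognition)
  rc <- oracle_iupac_revcomp(recognition)
  if (rc == recognition) {
    df <- data.frame(pos = fwd, strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
  } else {
    rev <- oracle_scan_one(seq_txt, rc)
    df <- rbind(data.frame(pos = fwd, strand = rep("+", length(fwd)),
                           stringsAsFactors = FALSE),
                data.frame(pos = rev, strand = rep("-", length(rev)),
                           stringsAsFactors = FALSE))
  }
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Build a bare whole-sequence fragment around an explicit sequence.
make_fragment <- function(seq_txt, short_flank = 0L, long_flank = 0L,
                          core = NULL, label = "A1") {
  n <- nchar(seq_txt)
  if (is.null(core)) core <- c(1L + long_flank, n - long_flank)
  structure(list(
    region_kind = substr(label, 1, 1),
    region_index = as.integer(substr(label, 2, nchar(label))),
    region_label = label,
    core_start = as.integer(core[1]), core_end = as.integer(core[2]),
    short_flank = as.integer(short_flank),
    long_flank = as.integer(long_flank),
    sequence = seq_txt,
    offset_to_record = as.integer(core[1] - long_flank - 1L)
  ), class = "tal_fragment")
}

pair_coord_key <- function(df, cols = c("site1_start", "site1_len",
                                        "spacer_len", "site2_len")) {
  if (nrow(df) == 0) return(character())
  sort(do.call(paste, c(as.list(df[cols]), sep = ":")))
}

oracle_pair_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$s1, df$l1, df$sp, df$l2, sep = ":"))
}
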