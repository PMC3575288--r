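test_that("GenBank records parse with features, labels and sequence", {
  gb <- generate_gene_record(
    exon_lengths = c(100L, 80L, 120L), intron_lengths = c(150L, 90L),
    features = c("mRNA", "mRNA", "CDS"), seed = 11L,
    symbol = "genA", aliases = c("aliasB", "aliasC"))
  rec <- parse_gene_record(gb)

  expect_s3_class(rec, "gene_record")
  kinds <- vapply(rec$features, `[[`, "", "kind")
  expect_equal(sum(kinds == "mRNA"), 2L)
  expect_equal(sum(kinds == "CDS"), 1L)
  expect_identical(rec$symbol, "genA")
  expect_setequal(rec$aliases, c("aliasB", "aliasC"))
  expect_identical(rec$sequence, toupper(rec$sequence))
  expect_equal(nchar(rec$sequence), 100 + 80 + 120 + 150 + 90 + 2 * 50)
  for (f in rec$features) {
    expect_true(all(f$intervals >= 1 & f$intervals <= nchar(rec$sequence)))
    expect_true(all(diff(f$intervals[, "start"]) > 0))
  }
})

test_that("records without subsequence features parse to an empty list", {
  gb <- generate_gene_record(exon_lengths = 200L,
                             features = character(0), seed = 3L)
  rec <- parse_gene_record(gb)
  expect_length(rec$features, 0L)
  sel <- select_feature(rec)
  expect_identical(sel$kind, "whole")
})

test_that("malformed or sequence-free records are rejected", {
  gb <- generate_gene_record(exon_lengths = c(100L, 80L),
                             intron_lengths = 60L, seed = 1L)
  lines <- strsplit(gb, "\n")[[1]]
  no_origin <- lines[seq_len(grep("^ORIGIN", lines) - 1L)]
  expect_error(parse_gene_record(paste(no_origin, collapse = "\n")),
               "ORIGIN")
  broken <- sub("join\\(", "join(oops", gb)
  expect_error(parse_gene_record(broken), "malformed")
})

test_that("feature priority is mRNA > CDS > miscRNA with first-entry fallback", {
  # mRNA preferred over CDS
  rec <- parse_gene_record(generate_gene_record(
    exon_lengths = c(90L, 90L), intron_lengths = 100L,
    features = c("CDS", "mRNA"), seed = 5L))
  expect_identical(select_feature(rec)$kind, "mRNA")

  # CDS when no mRNA; miscRNA last
  rec2 <- parse_gene_record(generate_gene_record(
    exon_lengths = 150L, features = c("misc_RNA", "CDS"), seed = 6L))
  expect_identical(select_feature(rec2)$kind, "CDS")
  rec3 <- parse_gene_record(generate_gene_record(
    exon_lengths = 150L, features = "misc_RNA", seed = 7L))
  expect_identical(select_feature(rec3)$kind, "miscRNA")

  # multiple mRNAs: first wins, with a warning; index overrides
  gb <- generate_gene_record(
    exon_lengths = c(90L, 90L), intron_lengths = 100L,
    features = data.frame(kind = c("mRNA", "mRNA", "mRNA"),
                          label = "genA",
                          transcript_id = c("T1.1", "T2.1", "T3.1")),
    seed = 8L)
  rec4 <- parse_gene_record(gb)
  expect_warning(first <- select_feature(rec4), "first")
  expect_identical(first$transcript_id, "T1.1")
  expect_identical(select_feature(rec4, list(index = 2L))$transcript_id,
                   "T2.1")
  expect_identical(
    select_feature(rec4, list(transcript_id = "T3.1"))$transcript_id,
    "T3.1")
  expect_error(select_feature(rec4, list(index = 9L)), "out of range")

  # a kind preference skips mRNA
  rec5 <- parse_gene_record(generate_gene_record(
    exon_lengths = 150L, features = c("mRNA", "CDS"), seed = 9L))
  expect_identical(select_feature(rec5, list(kind = "CDS"))$kind, "CDS")
})

test_that("alias-labeled features are selected; foreign labels are not", {
  gb <- generate_gene_record(
    exon_lengths = 150L,
    features = data.frame(kind = c("mRNA", "mRNA"),
                          label = c("otherGene", "aliasB")),
    seed = 10L, symbol = "genA", aliases = "aliasB")
  rec <- parse_gene_record(gb)
  sel <- select_feature(rec)
  expect_identical(sel$label, "aliasB")
})

test_that("order of other-kind features does not disturb an index preference", {
  base <- data.frame(kind = c("mRNA", "CDS", "mRNA", "misc_RNA", "mRNA"),
                     label = "genA",
                     transcript_id = c("T1.1", NA, "T2.1", NA, "T3.1"))
  perm <- base[c(2, 1, 4, 3, 5), ]
  for (feats in list(base, perm)) {
    rec <- parse_gene_record(generate_gene_record(
      exon_lengths = 150L, features = feats, seed = 12L))
    expect_identical(select_feature(rec, list(index = 2L))$transcript_id,
                     "T2.1")
  }
})

test_that("fragment extraction slices, flanks and pads correctly", {
  gb <- generate_gene_record(
    exon_lengths = c(100L, 60L, 80L), intron_lengths = c(120L, 70L),
    features = "mRNA", seed = 13L, pad = 40L)
  rec <- parse_gene_record(gb)
  f <- select_feature(rec)

  # exon 2 with generous flanks
  fr <- extract_fragment(rec, f, "E", 2L, short_flank = 10L,
                         long_flank = 50L)
  expect_equal(nchar(fr$sequence), 60 + 2 * 50)
  core_seq <- substr(fr$sequence, 51, 110)
  expect_identical(core_seq,
                   substr(rec$sequence, fr$core_start, fr$core_end))

  # intron 2 is the gap between exon blocks 2 and 3
  fr_i <- extract_fragment(rec, f, "I", 2L, 10L, 20L)
  expect_equal(fr_i$core_start, unname(f$intervals[2, "end"]) + 1L)
  expect_equal(fr_i$core_end, unname(f$intervals[3, "start"]) - 1L)
  expect_equal(fr_i$core_end - fr_i$core_start + 1L, 70L)

  # whole-sequence mode with zero flanks is the identity
  fr_a <- extract_fragment(rec, NULL, "A", 1L, 0L, 0L)
  expect_identical(fr_a$sequence, rec$sequence)

  expect_error(extract_fragment(rec, f, "E", 9L), "E1..E3")
  expect_error(extract_fragment(rec, f, "I", 5L), "out of range")
})

test_that("flank windows beyond the record are N-padded, exactly", {
  gb <- generate_gene_record(exon_lengths = 100L, features = "mRNA",
                             seed = 14L, pad = 0L)
  rec <- parse_gene_record(gb)  # exon starts at base 1
  f <- select_feature(rec)
  fr <- extract_fragment(rec, f, "E", 1L, short_flank = 0L,
                         long_flank = 150L)
  expect_equal(nchar(fr$sequence), 100 + 300)
  expect_identical(substr(fr$sequence, 1, 150),
                   strrep("N", 150))
  # trailing side: record is exactly the exon, so 150 N's there too
  expect_identical(substr(fr$sequence, 251, 400), strrep("N", 150))
  n_count <- sum(strsplit(fr$sequence, "")[[1]] == "N")
  expect_equal(n_count, 300L)
})

test_that("fragment positions map back to the record through the offset", {
  set.seed(77)
  for (rep in 1:5) {
    gb <- generate_gene_record(
      exon_lengths = sample(60:200, 3), intron_lengths = sample(60:200, 2),
      features = "mRNA", seed = 100L + rep, pad = 30L)
    rec <- parse_gene_record(gb)
    f <- select_feature(rec)
    kind <- sample(c("E", "I"), 1)
    idx <- if (kind == "E") sample(3, 1) else sample(2, 1)
    fr <- extract_fragment(rec, f, kind, idx, 10L, 40L)
    chars <- strsplit(fr$sequence, "")[[1]]
    for (p in sample(nchar(fr$sequence), 25)) {
      rp <- p + fr$offset_to_record
      if (rp >= 1 && rp <= nchar(rec$sequence)) {
        expect_identical(chars[p], substr(rec$sequence, rp, rp))
      } else {
        expect_identical(chars[p], "N")
      }
    }
  }
})

test_that("EFetch URLs are deterministic strings with both indices", {
  url <- build_efetch_request("NC_007118.5", 21501610, 21527471, "+")
  expect_match(url, "NC_007118.5", fixed = TRUE)
  expect_match(url, "seq_start=21501610", fixed = TRUE)
  expect_match(url, "seq_stop=21527471", fixed = TRUE)
  expect_match(url, "strand=1", fixed = TRUE)

  expect_match(build_efetch_request("X1", 5, 5), "seq_start=5&seq_stop=5")
  expect_match(build_efetch_request("X1", 1, 10, "-"), "strand=2")
  expect_error(build_efetch_request("", 1, 10), "accession")
  expect_error(build_efetch_request("X1", 10, 1))
})
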