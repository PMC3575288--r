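test_that("template notation compiles to its constraints", {
  t1 <- parse_template("Ts[ACG][CGT].*Te")
  expect_true(t1$require_preceding_T)
  expect_equal(t1$leading_sets, list(c("A", "C", "G"), c("C", "G", "T")))

  t2 <- parse_template("Ts.*e")
  expect_true(t2$require_preceding_T)
  expect_length(t2$leading_sets, 0L)

  t3 <- parse_template("s.*e")
  expect_false(t3$require_preceding_T)

  expect_error(parse_template("Ts.*"), "'e'")
  expect_error(parse_template("Te.*s"), "before")
  expect_error(parse_template("Ts[AX].*e"), "subset of ACGT")
  expect_error(parse_template("Ts.*ez"), "unknown token")
  expect_error(parse_template("Ts.*eT"), "after 'e'")
  expect_error(parse_template("Tq.*e"), "unknown token")
})

test_that("start increment follows the long-region stepping rule", {
  expect_equal(increment_for_length(0), 1L)
  expect_equal(increment_for_length(999), 1L)
  expect_equal(increment_for_length(1000), 10L)
  expect_equal(increment_for_length(4999), 10L)
  expect_equal(increment_for_length(5000), 20L)
  expect_equal(increment_for_length(6000), 20L)
  expect_equal(increment_for_length(6000, override = 3L), 3L)
})

test_that("a planted pair is recovered with exact coordinates", {
  pf <- generate_planted_fragment(plant_spec(seed = 101L))
  pairs <- enumerate_pairs(pf$fragment)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$site1_start, pf$truth$site1_start)
  expect_equal(pairs$spacer_start, pf$truth$spacer_start)
  expect_equal(pairs$site2_start, pf$truth$site2_start)
  expect_identical(pairs$site2_revcomp,
                   reverse_complement(pairs$site2_seq))
  chars <- strsplit(pf$fragment$sequence, "")[[1]]
  expect_identical(chars[pairs$site1_start - 1L], "T")
  expect_identical(chars[pairs$site2_start + pairs$site2_len], "A")
})

test_that("a T-free sequence yields no pairs under the default template", {
  fr <- make_fragment(strrep("C", 120))
  expect_equal(nrow(enumerate_pairs(fr)), 0L)
  expect_equal(nrow(enumerate_single_sites(fr)), 0L)
})

test_that("enumeration equals the brute-force oracle on random fragments", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(80:200, 1)
    fr <- make_fragment(random_dna(n, runif(1, 0.3, 0.7)))
    for (tpl in list(parse_template("Ts.*e"),
                     parse_template("Ts[ACG][CGT].*Te"))) {
      got <- enumerate_pairs(fr, tpl, search_config())
      want <- oracle_pairs(fr$sequence, 1L, n,
                           require_T = tpl$require_preceding_T,
                           leading = tpl$leading_sets)
      expect_identical(pair_coord_key(got), oracle_pair_key(want))
    }
  }
})

test_that("single-site enumeration equals a brute-force forward scan", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(60:150, 1)
    fr <- make_fragment(random_dna(n, 0.5))
    got <- enumerate_single_sites(fr)
    chars <- strsplit(fr$sequence, "")[[1]]
    want <- list()
    for (s in seq_len(n)) for (l in 15:17) {
      if (s + l - 1L > n) next
      if (s < 2 || chars[s - 1L] != "T") next
      want[[length(want) + 1L]] <- c(s, l)
    }
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      wm <- do.call(rbind, want)
      expect_equal(got$start, wm[, 1])
      expect_equal(got$len, wm[, 2])
      expect_equal(got$index, seq_len(nrow(got)))
    }
  }
})

test_that("every emitted pair re-validates its own invariants", {
  set.seed(44)
  fr <- make_fragment(random_dna(250, 0.45))
  pairs <- enumerate_pairs(fr)
  expect_gt(nrow(pairs), 0)
  chars <- strsplit(fr$sequence, "")[[1]]
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    expect_equal(p$site1_start + p$site1_len, p$spacer_start)
    expect_equal(p$spacer_start + p$spacer_len, p$site2_start)
    expect_identical(chars[p$site1_start - 1L], "T")
    expect_identical(chars[p$site2_start + p$site2_len], "A")
    expect_true(p$site1_len >= 15 && p$site1_len <= 17)
    expect_true(p$site2_len >= 15 && p$site2_len <= 17)
    expect_true(p$spacer_len %in% 15:16)
    expect_identical(p$site1_seq,
                     substr(fr$sequence, p$site1_start,
                            p$site1_start + p$site1_len - 1L))
  }
  expect_equal(pairs$index, seq_len(nrow(pairs)))
})

test_that("widening length ranges never removes a reported pair", {
  set.seed(45)
  fr <- make_fragment(random_dna(220, 0.5))
  narrow <- enumerate_pairs(fr, config = search_config(c(15L, 16L),
                                                       c(15L, 15L)))
  wide <- enumerate_pairs(fr, config = search_config(c(14L, 18L),
                                                     c(14L, 17L)))
  expect_true(all(pair_coord_key(narrow) %in% pair_coord_key(wide)))
})

test_that("increment-k output is the increment-1 set restricted mod k", {
  set.seed(46)
  fr <- make_fragment(random_dna(300, 0.5))
  full <- enumerate_pairs(fr, config = search_config(increment = 1L))
  for (k in c(3L, 10L)) {
    stepped <- enumerate_pairs(fr, config = search_config(increment = k))
    keep <- full[(full$site1_start - 1L) %% k == 0L, ]
    expect_identical(pair_coord_key(stepped), pair_coord_key(keep))
  }
})

test_that("site 1 may not start in the long flank beyond the short window", {
  # the planted pair (arm 1 at fragment base 128) sits just inside the
  # long flank of a core declared at 151..250: invisible with a zero
  # short flank, recovered once the short flank reaches back to it
  pf <- generate_planted_fragment(plant_spec(seed = 47L))
  seq2 <- paste0(pf$fragment$sequence, strrep("G", 100))
  fr_tight <- make_fragment(seq2, short_flank = 0L, long_flank = 150L)
  expect_equal(nrow(enumerate_pairs(fr_tight)), 0L)
  fr_reach <- make_fragment(seq2, short_flank = 25L, long_flank = 150L)
  pairs <- enumerate_pairs(fr_reach)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$site1_start, pf$truth$site1_start)
})

test_that("sites containing placeholders are never emitted", {
  pf <- generate_planted_fragment(plant_spec(seed = 48L))
  seq_n <- pf$fragment$sequence
  # poison one base inside the planted first arm
  substr(seq_n, pf$truth$site1_start + 3L, pf$truth$site1_start + 3L) <- "N"
  fr <- make_fragment(seq_n)
  expect_equal(nrow(enumerate_pairs(fr)), 0L)
})

test_that("reverse complement is an involution with N fixed", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAN"), "NTT")
  expect_error(reverse_complement("ACGU"), "non-IUPAC")
  set.seed(49)
  for (i in 1:50) {
    s <- random_dna(sample(1:40, 1), runif(1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})
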