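---
title: "Designing TALEN pairs with restriction-site screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing TALEN pairs with restriction-site screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talenforge)
```

## The design problem

Transcription activator-like (TAL) effectors bind DNA through tandem
repeats of 33–35 amino acids, each repeat recognizing a single base
through its repeat variable di-residue (RVD). Fusing a TAL array to a
FokI-type nuclease domain gives a TALEN; a *pair* of TALENs binding
opposite strands, separated by a spacer, dimerizes the nuclease and cuts
inside the spacer. Error-prone repair of the break (NHEJ) leaves small
deletions. If the spacer contains a restriction-enzyme recognition site
that occurs nowhere else in the PCR amplicon, those deletions destroy
the site and TALEN activity can be scored as uncut PCR product — the
RFLP readout.

`talenforge` automates the design side of this workflow: given a target
sequence it enumerates all candidate binding-site pairs matching a
consensus template, encodes the arms as RVD module strings for Golden
Gate assembly, and screens each spacer for enzymes that give a clean
RFLP assay.

## The binding-site model

A candidate pair is defined on the forward strand as

```
... t [site1] [spacer] [site2] a ...
```

where a thymine must immediately precede each arm *on the strand that
arm binds*: a literal `T` before site 1, and — because site 2 binds the
reverse strand — an `A` immediately after site 2 on the forward strand.
Templates are written in a compact notation: `Ts[ACG][CGT].*Te` is the
classical consensus (required 5' T; first site base not T; second not
A; free interior), while the package default is the more permissive
`Ts.*e`, reflecting the observation that in practice only the 5' T is a
measurable constraint. The trailing `T` before `e` in the classical
notation is the mirror image of the 5' anchor as seen from the second
arm; the parser accepts it and it adds no per-base constraint beyond
the anchoring rule that is already applied to both arms.

Both arms are required to satisfy the *same* template (the second on
the reverse strand). Binding-site length excludes the anchoring
thymine: a "15 bp site" has 15 RVDs and a T immediately 5' of it.

### Enumeration and its parameters

Every combination of site-1 start position, site-1 length, spacer
length and site-2 length is tested. The defaults are the ranges a
practitioner would recognize: binding sites of 15–17 bp, spacers of
15–16 bp. Candidates are ordered by (site-1 start, site-1 length,
spacer length, site-2 length) and numbered from 1, which makes the
"Site N" ordinal reproducible across runs — the ordering is a package
convention, chosen so reports are stable.

For long regions exhaustive enumeration produces unusably many
candidates, so the start position is stepped: cores up to 999 bp are
scanned exhaustively (step 1), cores of 1000–4999 bp use step 10, and
5000 bp and above use step 20. The step applies to the *core*
(exon/intron) length, not the flanked length. The boundary semantics
(≥ 1000, ≥ 5000) were chosen so that the exhaustiveness guarantee for
999 bp inputs holds exactly; submitting a sub-1000 bp fragment always
yields every possible pair. An explicit `--increment` overrides the
rule.

### Fragments, flanks and coordinates

Designs target an exon (`E`), an intron (`I`, the gap between
consecutive exon blocks) or the whole sequence (`A`). Two flanks
surround the core region:

* **short flank** (default 25 bp): the window in which site 1 may
  *start* is the core extended by the short flank on each side, so
  sites overlapping an exon boundary are still found. The default is a
  package choice — it is just longer than the longest default binding
  site, so no edge site is missed.
* **long flank** (default 150 bp): the amplicon context. Enzyme-site
  uniqueness is judged on the span of both binding sites extended by
  the long flank on each side, emulating a PCR amplicon around the cut.

Internally all coordinates are 1-based inclusive. Reported binding-site
spans (`first-last(length)`) are relative to the start of the
short-flanked subsequence; reported enzyme positions are relative to
the start of the long-flanked fragment. These two origins differ by
`long_flank − short_flank`; both conventions are preserved in the text
and CSV reports. Bases requested beyond the record boundary are padded
with `N`, and `N` never matches a template position or an enzyme site,
so padded windows are inert rather than error-prone. For plain FASTA
input there is no annotation to extend into, so the whole sequence is
analyzed as region `A` with zero flanks: positions in the report then
index the input sequence directly.

## Feature selection from GenBank records

When the input is a GenBank flat file, the design region comes from its
annotation. `mRNA` features are preferred (they let the user pick any
exon), then `CDS`, then `misc_RNA`; when only `exon` features exist
they are pooled as one group, and with no subsequence features at all
the whole sequence is used. Features are filtered by the gene symbol
and its aliases so that overlapping genes in other reading frames are
not picked up. When several features of the winning kind remain there
is no principled way to choose, so the first is used and a warning
recorded; an explicit index or transcript identifier overrides this.
Network retrieval is deliberately out of the analysis path: the package
only *constructs* E-utilities EFetch URLs (`build_efetch_request()`),
and all parsing operates on local files.

## The RVD cipher

Arms are translated with the canonical artificial-TAL cipher A→NI,
C→HD, G→NN, T→NG — a bijection, so `rvd_decode(rvd_encode(x))` is
exact. Natural or alternative RVDs (NK, NH, N\*) and per-RVD efficiency
weighting are out of scope. RVD strings are serialized tab-delimited in
the text report (for pasting into assembly spreadsheets) and
`|`-separated in CSV, where embedded tabs would not survive round-trips.

## Restriction screening for RFLP

The enzyme catalogue is a Bairoch-style REBASE-dialect flat file; only
enzymes with at least one commercial supplier code are retained, and
screening can be narrowed by vendor. Recognition sites are degenerate
IUPAC patterns; matching (delegated to Biostrings, with a hand-rolled
naive scanner serving as the independent oracle in the test suite)
reports all overlapping occurrences on both strands and collapses the
double-counted hits of palindromic sites. The packaged database is a
hand-written fixture of ~40 well-known enzymes with their true
recognition sites; any file in the same dialect can be substituted.

An enzyme qualifies for a given pair when its site lies *entirely*
within the spacer (a site straddling an arm boundary would not be
reliably destroyed by spacer-centered deletions). Uniqueness is then
judged across the amplicon window:

* exactly one amplicon match → reported as unique, with the absolute
  position of the first base of the recognition site;
* two or more matches whose nearest pair is at least
  `min_second_cut` apart (default 80 bp — closer second cuts give
  fragments too similar to resolve on a gel) → reported with the second
  cut's position relative to the first;
* anything closer → the enzyme is dropped for that pair.

When several spacer matches exist the leftmost is the primary hit.
Enzymatic cut offsets within the recognition site are not modeled; the
recognition-site position is the reported quantity. PCR-buffer
compatibility scores (standard, Thermopol, Phusion, Crimson) are
rescaled onto the integer range 0–9 — 0 meaning no activity, the raw
maximum mapping to 9, rounding half-up — and displayed with each
enzyme. The shipped activity table is synthetic (its filename says so):
it exercises the rescaling and display machinery, not any vendor's
measured activities.

## Golden Gate recipes

For bench work each arm becomes a pick list: positions 1..n−1 map to
array-module plasmids (named by RVD and slot, slots cycling every 10
positions), the final RVD to a last-half-repeat plasmid. The layout
lives in an editable YAML file modeled on the widely used 10-slot
array kits, so a kit revision is a data edit, not a code change.
Volumes are `target_mass / stock_concentration`, rounded to 0.1 µL
with a 0.1 µL pipetting floor (a warning suggests diluting the stock).
The default target of 75 ng per module plasmid is a pragmatic package
default; the supported repeat range (12–31) comes from the kit layout
file and is enforced with an informative error.

## The synthetic-data generator

`plant_spec()` / `generate_planted_fragment()` produce designed test
sequences: the anchored construct `T + site1 + spacer + site2 + A`
embedded mid-background, with the ground-truth coordinates returned
alongside. Two deliberate defaults make the "exactly one candidate"
guarantee provable rather than probabilistic:

* the default background is pure G/C. Under the permissive default
  template any background `T ... A` at the right distance founds a
  valid candidate pair, so a realistic base composition would plant
  accidental sites with near-certainty. A designed all-G/C background
  contains no anchors other than the planted ones.
* the default geometry is 15 + 15 + 15 bp. The anchors fix the total
  arm-to-arm span, and a 45 bp span has exactly one decomposition into
  in-range (site1, spacer, site2) lengths. A 46 bp span (e.g. a 16 bp
  spacer) has three, all legitimately reported by an exhaustive
  enumerator — so a planted 16 bp spacer *cannot* yield exactly one
  candidate and is not the default.

The generator verifies uniqueness by exhaustive enumeration and redraws
the background a bounded number of times (relevant when `gc_fraction`
is lowered), then fails with advice. Decoy recognition sites can be
planted at exact distances for testing the second-cut rules;
`planted_layout()` exposes the planted coordinates as a pure function
of the spec so tests can compute those distances up front.

What these fixtures do *not* emulate: genomic base composition,
repeats, heterozygosity, or annotation errors. Passing the planted-pair
suite demonstrates coordinate and classification correctness, not
performance on real genomes; the brute-force equivalence suite on
random A/C/G/T fragments is the evidence that enumeration is exhaustive
on realistic composition.

## Numerical and degenerate-input choices

* Rounding: buffer-score rescaling and volumes round half-up
  (`floor(x + 0.5)`); R's banker's rounding is deliberately avoided so
  displayed scores are stable.
* Ties in the second-cut rule (equidistant up/downstream matches)
  resolve downstream (positive offset).
* Empty results are ordinary values everywhere: an unsatisfiable
  template yields an empty pair table, an empty record list renders a
  header-only report, an empty REBASE file parses to an empty database.
* Spacers containing `N` are never screened; sites containing `N` are
  never emitted or RVD-encoded.

## Problem sizes in the test suite

The test suite runs entirely from generated data: 200 random fragments
of 60–300 bp for the brute-force equivalence suite, 100 seeded planted
fragments of 300 bp for recovery, 1000 random draws each for the RVD
round-trip and degenerate-matching oracles. These sizes give full
coverage of the combinatorial space the algorithm iterates (every
length triple occurs thousands of times) while keeping the whole suite
under a couple of minutes on one core.

## Known limitations

* No off-target / genome-wide specificity scoring; candidate ranking is
  positional order, not predicted activity.
* One cipher, four RVDs; no modeling of NK/NH/N\* or context effects.
* Enzyme cut offsets, star activity and methylation sensitivity are not
  modeled; "cut site" means recognition-site position.
* GenBank parsing covers the flat-file subset the feature-priority
  logic needs (gene/mRNA/CDS/misc_RNA/exon, join/complement spans), not
  the full format.
* The reported candidate count explodes on long permissive regions by
  design; the stepping rule is a pragmatic thinning, not a ranking.
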