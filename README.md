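# talenforge

Design TALEN pairs against a DNA target, with restriction-site
screening of the spacer so nuclease activity can be read out by RFLP.

TAL effector repeats bind one base each through their repeat variable
di-residue (RVD: NI=A, HD=C, NN=G, NG=T). A TALEN pair binds opposite
strands around a spacer; the nuclease dimer cuts in the spacer, and
error-prone NHEJ repair leaves small deletions. If the spacer contains
a restriction site that is unique within the PCR amplicon, those
deletions destroy it — TALEN activity shows up as uncut PCR product.

`talenforge`:

* enumerates all candidate binding-site pairs matching a consensus
  template `Ts.*e` (required 5' thymine before each arm, free
  interior; the classical `Ts[ACG][CGT].*Te` is also supported) over
  configurable length ranges (sites 15–17 bp, spacer 15–16 bp by
  default), exhaustively for regions ≤ 999 bp and with start-position
  steps of 10 / 20 for regions ≥ 1000 / ≥ 5000 bp;
* extracts exons/introns (with short and long flanking sequence) from
  GenBank flat files, applying the mRNA > CDS > misc_RNA feature
  priority with gene-symbol/alias filtering, or takes plain FASTA;
* encodes each arm as its RVD module string;
* screens each spacer against a Bairoch-dialect REBASE enzyme database
  (commercial enzymes only, vendor-filterable), classifying each
  enzyme as unique-in-amplicon (binding region ± 150 bp) or reporting
  a second cut ≥ 80 bp away, and attaching PCR-buffer compatibility
  scores rescaled onto 0–9;
* renders flat-text and CSV reports, and turns RVD strings into Golden
  Gate pick lists with pipetting volumes from a local
  reagent-concentration table.

## Worked example

The packaged example FASTA carries a designed test sequence with one
planted TALEN pair whose 15 bp spacer contains an NsiI site:

```r
library(talenforge)
fa <- system.file("extdata", "example_planted.fasta", package = "talenforge")
res <- run_pipeline(pipeline_config(fasta = fa))
cat(res$text)
```

```
talenforge TALEN design report
sites: 1

== planted_example A1 Site 1 ==
TAL1    128-142(15)  GCCGGCGCCGGCGCC
Spacer  GCGGATGCATGGCGG
TAL2    158-172(15)  GGCGCCGGCGCCGGC
TAL2rc  GCCGGCGCCGGCGCC
RVD1    NN  HD  HD  NN  NN  HD  NN  HD  HD  NN  NN  HD  NN  HD  HD
RVD2    NN  HD  HD  NN  NN  HD  NN  HD  HD  NN  NN  HD  NN  HD  HD
Enzymes (name prototype score position second_cut):
  NsiI  NsiI  2  147
```

Reading the block: `128-142(15)` is the first arm's span in
`first-last(length)` notation (1-based, relative to the short-flanked
subsequence; for FASTA input that is simply the input sequence). A `T`
precedes base 128 and an `A` follows base 172 — the anchoring thymines
of the two arms on their respective strands. `TAL2rc` is the reverse
complement of site 2: the sequence the second TAL protein actually
binds. The RVD lines are the assembly modules for each arm
(tab-delimited for spreadsheet transfer). The enzyme line says NsiI
(its own prototype), standard-buffer compatibility score 2 of 9, cuts
the spacer with its recognition site starting at position 147, and the
empty final field means the site is unique in the amplicon — a clean
RFLP assay. `res$csv` holds the same content as CSV, one row per
(site, enzyme) with the fixed column order
`gene,region,site,site1_span,site1_seq,rvd1,spacer_seq,site2_span,
site2_seq,site2_revcomp,rvd2,enzyme,prototype,buffer,buffer_score,
strand,position,second_cut_rel`.

The same run from the shell, plus a recipe for the first arm:

```sh
talenforge design --fasta example_planted.fasta --out both --prefix out
talenforge recipe --rvds "NN,HD,HD,NN,NN,HD,NN,HD,HD,NN,NN,HD,NN,HD,HD" \
                  --reagents synthetic_reagents.tsv
```

The recipe CSV lists, per repeat position, the module plasmid (slot
cycling every 10 positions, last repeat from a `pLR_*` plasmid) and the
volume delivering 75 ng at the tabulated stock concentration.

## Layout

* `R/` — implementation; `exec/talenforge` — CLI wrapper.
* `inst/extdata/` — REBASE-dialect enzyme fixture, prototype table,
  synthetic buffer-activity table, kit layout, example inputs.
* `vignettes/talen-design.Rmd` — the model, parameter rationale and
  design decisions.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles.
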