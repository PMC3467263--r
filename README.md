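# ir1screen

Cross-species discovery screen for IR1-type nuclear receptor response
elements, for regulatory genomicists nominating direct target genes of the
farnesoid X receptor (FXR, NR1H4).

FXR/RXR heterodimers bind IR1 elements — two hexamer half-sites of
consensus `[GA]GGT[TC]A` arranged as an inverted repeat around a 1 bp
spacer:

```
[GA]GGT[TC]A - N - T[AG]ACC[TC]      (13 positions, 64 matching words)
```

The screen nominates candidate targets in three steps, each exposed as a
package function:

1. **Window extraction** — for every annotated gene, take the region
   −20,000 bp … +10,000 bp around the 5′ end of its first exon, oriented to
   the gene (`gene_anchors`, `extract_window`). Offsets use the +1
   convention (anchor base = +1, no position 0).
2. **Degenerate scanning** — match the compiled element under a mismatch
   budget on either strand (`compile_element`, `scan_motif`); the default
   budget is 0 (strict consensus). IR/DR/ER geometries and arbitrary
   half-sites/spacers are supported (`run_screen` for the per-species
   table).
3. **Conservation filter** — intersect per-species hit tables over an
   ortholog map (`conserved_candidates`): *presence* mode requires an
   element in every species; *positional* mode additionally bounds the
   spread of best-hit gene-relative offsets (default 2 kb).

A synthetic-data module (`generate_species_set`) builds multi-species
genomes with elements planted at known gene-relative offsets — including
exact corruption counts and an analytic background-hit expectation
(`expected_background_hits`) — so every stage is validated without any
download. The bench-side quantifications used to confirm a candidate are
included too: ΔΔCt expression folds (`ddct_fold`), relative luciferase
activity and fold induction (`rla_fold`), in-silico PCR product sizing
(`insilico_pcr`) and the unpaired t-test with significance stars
(`unpaired_t`).

## Worked example

The reporter insert from the human NDRG2 first intron carries two IR1
sites; the exact-consensus one is conserved in mouse and rat:

```r
library(ir1screen)
ir1 <- ir1_element()
scan_motif(ndrg2_re_wt, ir1, max_mm = 1)[, c("start", "start1", "mismatches", "matched")]
#>   start start1 mismatches       matched
#> 1    15     16          0 GGGTTAGTGACCC
#> 2    32     33          1 AGGTTGATGACCC
scan_motif(ndrg2_re_mut, ir1, max_mm = 1)   # mutated insert: zero hits
expected_background_hits(ir1, 30000)
#> [1] 0.02859879
```

The exact-consensus element `GGGTTAGTGACCC` starts at 0-based offset 15 of
the 66 bp insert; the second, human-specific element `AGGTTGATGACCC` (one
mismatch) starts at 32. In a random 30 kb window, ~0.029 chance consensus
matches are expected — conservation across species is what separates real
sites from that background.

The `analysis/` directory runs the whole screen as a numbered workflow on a
simulated three-species study set (`01_simulate.R` … `05_assays.R`),
writing hit tables and conserved-candidate tables under `results/`. On the
default bundle, 3 of 5 ortholog groups carry planted elements and all 3 —
and only those 3 — pass both conservation modes.

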