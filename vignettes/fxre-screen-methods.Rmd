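---
title: "Methods: the IR1 response-element screen and its validation"
author: "ir1screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the IR1 response-element screen and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ir1screen)
```

## The biological question

The farnesoid X receptor (FXR, NR1H4) binds DNA as a heterodimer with RXR,
predominantly at **IR1 elements**: two hexamer half-sites arranged as an
inverted repeat separated by a single spacer base. The half-site consensus
is `[GA]GGT[TC]A`, so the full IR1 site reads

```
[GA]GGT[TC]A - N - T[AG]ACC[TC]
```

where the right half is, by construction, the reverse complement of the
left. Candidate direct target genes of FXR can therefore be nominated
computationally: scan the neighbourhood of every annotated gene for IR1
matches, and keep genes whose orthologs in other species carry an element
at a comparable position — conservation being the evidence that the site is
functional rather than chance background. `ir1screen` implements that
screen end to end, together with the simulation machinery needed to
validate every stage, and the downstream bench quantifications (ΔΔCt
expression folds, reporter-assay fold induction, amplicon sizing, unpaired
t-tests) used to confirm a nominated target such as NDRG2.

## The pattern model

A half-site is an ordered list of allowed-base sets, parsed from bracket
text (`parse_halfsite`). `compile_element` arranges two copies into a full
site under one of three geometries — IR (inverted repeat, the FXR case), DR
(direct repeat) and ER (everted repeat) — with a configurable spacer whose
positions are fully degenerate. The IR1 full site spans 13 positions, of
which 12 are constrained; the product of allowed-set sizes gives exactly 64
distinct matching words.

```{r}
ir1 <- ir1_element()
bracket_form(ir1$full)
pattern_word_count(ir1)
```

Matching is mismatch-budgeted: a window matches at budget *k* if at most
*k* constrained positions hold a base outside their allowed set. Scoring
choices, fixed once:

* **Spacer positions never contribute**, whatever character they hold.
* **Ambiguity characters in the subject** (N and anything else outside
  A/C/G/T) count as mismatches at constrained positions. This is the
  conservative, deterministic reading: an N never creates a match for free,
  but a budget can absorb it.
* **Overlapping hits are all reported.** The wild-type NDRG2 insert itself
  carries two adjacent elements 4 bp apart; any greedy exclusion rule would
  be an unstated filter.
* **Strand handling.** The IR1 full pattern equals its own
  reverse-complement mirror (*self-RC*), so a match is one physical site
  regardless of strand; with `strands = "both"` such patterns are scanned
  once and every hit is canonicalised to the plus strand. Non-self-RC
  patterns (e.g. DR geometries) are scanned on both strands and minus-strand
  hits are reported with plus-strand coordinates and `strand == "-"`.

The default screen budget is **0 mismatches** — the screen is defined by
its consensus. The budget is exposed because the field's canonical positive
control, the IBABP element `GGGTGAATAACCT`, sits 1 mismatch off the
consensus and is only visible at budget ≥ 1:

```{r}
scan_motif(ibabp_re, ir1, max_mm = 1)[, c("start", "mismatches", "matched")]
```

## Window extraction and coordinates

The screen examines the region **−20,000 bp to +10,000 bp** around each
gene's anchor, defined as the 5′ end of its first exon. "First exon" is the
5′-most exon of the gene's 5′-most transcript; ties go to the longest exon,
then the lexicographically smallest transcript id — the annotation formats
do not define behaviour under alternative transcription starts, so the rule
is simply deterministic and documented.

Coordinates are 0-based half-open internally; reports carry 1-based
inclusive fields as well. Gene-relative offsets use the GenBank-like
convention: the anchor base is **+1**, the base immediately upstream is
**−1**, and there is no position 0. For a minus-strand gene the genomic
window is the strand mirror `[anchor − downstream + 1, anchor + upstream + 1)`
and the extracted sequence is reverse complemented, so that "upstream" and
"downstream" are biological and the planted-marker round trip (plant at
+*k*, re-extract, recover +*k*) is exact on both strands. The naive mirror
`[anchor − downstream, anchor + upstream)` is off by one under the +1
convention — it would make every unclipped minus-strand window report
extents 19,999/10,001 — and was rejected for that reason. Windows running
off a contig are clipped and flagged per side.

The historical screen reported 428/483/506 genes (human/mouse/rat) with at
least one consensus element, and NDRG2 first-intron elements at +1560, +757
and +1394. Those numbers are tied to circa-2012 assemblies and annotation
releases that are not identified and not bundled; they are retained as
reference constants (`ndrg2_ir1_offsets`) but are deliberately **not** test
expectations. Validation instead uses synthetic genomes where the truth is
known exactly (below).

## The conservation filter

"Elements at comparable positions in all species" needs an operational
definition; the package offers two, both over an explicit ortholog map
(orthology is an input, never inferred):

* **presence** (default, least assumptive): every species in the group has
  at least one hit anywhere in its window;
* **positional**: additionally, the per-species best hits (fewest
  mismatches, ties 5′-most) lie within a tolerance of each other on the
  gene-relative axis. The default tolerance of 2,000 bp is our
  interpretation of "comparable", chosen as roughly the scale of a first
  intron; it is a parameter, not a claim.

Positional-mode candidates are nested within presence-mode candidates and
grow monotonically with the tolerance; both properties are tested. Genic
compartment (promoter/first-intron/...) is not filtered on.

## The synthetic study set

`generate_species_set` builds what the screen needs and nothing more: per
species one contig of i.i.d. background (default uniform composition),
single-exon genes in alternating orientation spaced so their windows fit,
a slot-wise ortholog map, and IR1 elements planted at requested
gene-relative offsets with an exact corruption count (`sample_element`
draws a sequence scoring *exactly* n mismatches). The defaults — 3 species,
uniform base composition, full-width −20 kb/+10 kb windows — mirror the
three-species human/mouse/rat design. Deliberately not modelled: isochore
and repeat structure, higher-order composition, phylogenetic correlation
between species. Consequently a passing recovery test shows the pipeline's
bookkeeping (coordinates, strands, orientation, attribution) is exact, not
that real genomes are this clean; on real data the same scan simply
inherits the annotation's quality.

Because the background is i.i.d., the expected number of chance matches has
a closed form: per window of length *n*, the match probability at one start
is the product over positions of the summed allowed-base probabilities, and

```{r}
expected_background_hits(ir1, 30000)  # 64 * 29988 / 4^13
```

≈ 0.029 spurious hits are expected per 30 kb window under the uniform
composition. The generator pre-screens each contig and redraws the
background (from the ongoing RNG stream) if a chance exact match landed
outside the planted sites — at this rate a redraw is rare — so planted
bundles support precision = recall = 1 assertions. The Monte-Carlo
agreement test compares the mean hit count over 200 random 30 kb windows
with the analytic value within 3 standard errors (Poisson variance); the
acceptance script recomputes both sides.

## Assay quantifications

* **ΔΔCt**: per sample, ΔCt = Ct(target) − Ct(housekeeping, default TBP);
  ΔΔCt subtracts the *mean* control-group ΔCt; fold = 2^(−ΔΔCt). The
  reference is the control mean, so individual control folds are 1 only
  when all control ΔCts coincide. Group summaries are mean ± SEM with the
  n−1 variance.
* **Reporter assays**: RLA = firefly/Renilla per well; fold induction =
  mean RLA(agonist) / mean RLA(vehicle). Renilla must be positive — it is
  the normalisation denominator.
* **In-silico PCR**: exact primer matches only (forward primer, and the
  reverse complement of the reverse primer downstream of it), product
  length inclusive of both footprints; all products are reported, and no
  product is an empty result rather than an error. Exact matching suffices
  for fixture-scale checks and keeps the operation deterministic.
* **t-test**: classical pooled-variance Student form, since that is the
  named convention in this line of work; Welch is available behind a flag.
  Zero pooled variance with equal means yields t = 0, p = 1; with unequal
  means the statistic is undefined and an error is raised. Stars map at
  0.05/0.01/0.001. No multiple-testing correction is applied.

## Validation design and problem sizes

The scanner is validated against an independently written naive
per-position, per-strand oracle (and, separately, against
`Biostrings::matchPattern` ambiguity matching on the plus strand) over a
thousand-plus randomized sequence/pattern/budget instances, mostly 60–300 bp
with a tail of 2 kb cases; recovery uses 3-species bundles of 5 genes
(~170 kb per contig); the background calibration uses 200 independent 30 kb
windows. These sizes make the whole suite run in about a minute while
leaving every assertion at full strength; they are stated here so the
numbers in the test code read as choices, not accidents.

## Known limitations

* The screen is a consensus/mismatch model: no position weight matrices,
  no information-content or p-value scoring, by design.
* Plain GFF3 with gene → transcript → exon (or exon-under-gene) linkage is
  assumed; GTF dialects, trans-spliced and fusion annotations are out of
  scope.
* The historical gene counts and element offsets cannot be reproduced
  without the original assemblies, and the real ChIP amplicon check
  requires the human NDRG2 first-intron sequence, which is not deposited;
  the primer machinery is therefore exercised on a synthetic locus built to
  the reported 196 bp spacing.
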