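---
title: "Mapping triplo-insensitive pericentric territory on chromosome 11 from sSMC cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping triplo-insensitive pericentric territory on chromosome 11 from sSMC cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmc11)
```

## The problem

A small supernumerary marker chromosome (sSMC) is an extra, structurally
abnormal chromosome present alongside a normal 46,XX or 46,XY karyotype.
Markers derived from chromosome 11 carry pericentric material from 11p
and/or 11q in three copies. Whether a carrier shows clinical signs
depends on whether the trisomic segment contains *triplo-sensitive*
genes — genes that produce a phenotype at three copies. Territory
immediately flanking the centromere is largely triplo-*insensitive*:
carriers of small pericentric markers are often clinically normal.

Given a curated cohort of sSMC(11) carriers and sSMC-like interstitial
duplication cases, the package infers:

1. the **minimal triplo-insensitive pericentric span** — the outer
   envelope of the trisomic intervals of informative, clinically normal
   carriers;
2. a **refined span** after extending with benign population copy-number
   gains that overlap it;
3. per-arm **uncertainty windows** bracketing where triplo-sensitive
   territory must begin, from pathogenic-report flanks (fine windows)
   and from in-cohort abnormal carriers (coarse windows);
4. cohort descriptive statistics and an arm-wise sign-by-arm
   genotype–phenotype table.

## The two-zone model

Each arm is modelled as insensitive territory adjacent to the centromere
followed by sensitive territory distally, with one unknown changeover
point per arm. Under this model:

* a clinically **normal** carrier whose trisomy reaches coordinate $x$
  demonstrates that all territory between $x$ and the centromere is
  insensitive — so the span is $[\min_i s_i, \max_i e_i]$ over normal
  intervals $[s_i, e_i]$, provided their union is one centromere-anchored
  run (otherwise the anchored connected component is returned with a gap
  warning);
* a **benign population gain** overlapping the span extends it the same
  way, iterated to a fixed point so chained records propagate;
* coordinates covered by a **pathogenic** report are treated as at or
  beyond the changeover, so the nearest pathogenic coordinate on each
  side bounds the window from the telomere side, and the refined span
  boundary bounds it from the centromere side;
* an **abnormal** in-cohort carrier proves a sensitive locus somewhere in
  the part of its trisomy outside the span; only its telomere-ward
  extreme is informative, and the *least* telomere-ward such extreme
  (the maximum start on 11p, the minimum end on 11q) gives the tightest
  coarse bound.

Treating pathogenic coverage as sensitive-or-beyond is an operational
assumption, not a logical implication — a pathogenic report only proves
a sensitive locus *somewhere* in its interval. We state it explicitly
because the fine windows are only derivable under it; the packaged
pathogenic records are flank records whose pericentric-facing boundary
is the quantity used.

## Inputs and conventions

**Coordinates.** All case coordinates are stored 1-based inclusive on
GRCh37, exactly as printed in case tables, so every stored number can be
compared verbatim with a published one. Conversion to 0-based half-open
happens only at the BED boundary. Span lengths are reported as
`end − start` (the convention in which 47,675,469–60,516,539 is a
12,841,070 bp ≈ 12.84 Mb region); the +1 inclusive-length convention is
not used for reported lengths.

**Cytobands.** The packaged ideogram is the GRCh37 chromosome 11 band
table in cytoBand format. Band intervals keep the raw boundary numbers:
published pericentric coordinates quote these shared boundaries verbatim
(51,600,000 as a band start *and* 55,700,000 as a band end), so a strict
±1 conversion would make exact reproduction impossible. The p-arm acen
band is stored under the coarse label `p11.1` (51.6–53.7 Mb): ish
breakpoints written `:p11.1→…` in case tables denote the centromeric
band, and the resolved extents of the informative cases are only
reproducible under that reading.

**Extent resolution.** Per-case evidence is heterogeneous: cytoband
spans from banding, FISH probe calls, array intervals, and curated
table-transcribed coordinates. `resolve_extent()` applies a per-side
precision hierarchy: coordinate-level evidence (arrays, curated
intervals, gain-positive probe spans) supersedes the band-span endpoint
on an arm whenever it extends beyond the centromere anchor on that side;
bands are the fallback. A naïve union of all evidence would let a coarse
band claim (e.g. a `p11.12` breakpoint at 48.8 Mb) overrule a precise
array start at 51.1 Mb; the hierarchy reproduces all ten published
informative-case intervals exactly. A probe call counts as gain evidence
when it is `++`, or `+` on a marker-chromosome ish clause; on an
interstitial `dup` clause a single `+` is the undisturbed normal signal.
Negative probes validate but never truncate. When a curated coordinate
interval is present in a cohort table it is taken as authoritative for
that case, mirroring how the source tables treat aCGH values.

**Karyotype grammar.** The parser covers the permissive ISCN subset used
in sSMC case tables (mosaic clone lists, bracketed counts and
percentages, `.ish` clauses, `arr[...]` stanzas, inheritance tokens).
Anything outside the grammar degrades to a preserved remark, never a
crash, because published tables contain free-text rows; `seq[...]`
breakpoint notation is preserved verbatim and not modelled.

## Curation decisions in the packaged fixtures

* One case is counted clinically *unknown* although its table section
  header places it among cases with clinical findings; the running-text
  cohort counts (12 normal / 23 abnormal / 22 unknown) are followed, and
  the discrepancy is retained rather than resolved.
* Where a later table prints build-converted coordinates that conflict
  with an earlier hg18 value for the same case, the GRCh37 values are
  stored; the package performs no liftover.
* The benign population records are printed in the source only as the
  resulting outer boundaries (47,675,469 and 60,516,539). The fixture
  intervals are synthesized so that their pericentric-facing outer
  boundaries equal those numbers and they overlap the unrefined span;
  they are flagged `synthetic_interval`, as are the 1 Mb bodies attached
  to the two pathogenic flank coordinates (45,048,321 and 61,479,322).
* Shapes are curated one per case by the predominant-shape rule (largest
  clone cell count, first-listed on ties); multi-shape cases retain all
  shapes. Sex is curated from the first clone's sex token; `XN` and
  absent tokens are *unknown*.
* Mosaicism is defined structurally: a case is mosaic iff a clone
  without the marker (or, in duplication cases, without the aberration)
  is reported. Mosaic cases participate in inference regardless of
  fraction — mosaicism level is treated as having no major influence on
  phenotype — and a `min_mosaic_fraction` switch (default 0) allows a
  stricter filter.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the inference
assumes: pericentric gains spanning the centromere, a hidden two-zone
sensitivity layout, incomplete penetrance, status misclassification and
uninformative contamination. Defaults, chosen once to mimic the
chromosome 11 setting: anchor 51.6–55.7 Mb; true insensitive span
47.68–60.52 Mb; innermost sensitive loci at 45.05 Mb (11p) and 61.48 Mb
(11q); per-arm reach exponential with a 5 Mb scale truncated at the
chromosome ends, which yields the observed mixture of tiny
heterochromatic and larger euchromatic markers without fitting anything;
penetrance 0.9; misclassification 2%; uninformative fraction 0.39
(matching the 22/57 cases without usable clinical data); marker cell
fraction Beta(2, 2). All draws flow from a single seeded generator, so
identical seeds give byte-identical cohorts.

The generator also emits population evidence from its own truth: benign
records inside the true insensitive span and one pathogenic record per
arm whose pericentric-facing boundary sits exactly at the innermost
sensitive locus (a report whose proximal edge is the sensitive gene). In
the noise-free regime (penetrance 1, no misclassification, no
contamination) recovery is guaranteed by construction: no normal case
can cover a locus, so the inferred span excludes all loci and each arm's
window contains the innermost one. The tests assert exactly this over
20 seeds at n = 200, and that median window widths are non-increasing as
n grows 50 → 200 → 800 (more normal carriers push the refined boundary
toward the locus).

What the generator does **not** emulate — and hence what passing
recovery tests cannot show about real data: arm-specific attribution of
abnormality (a simulated abnormal case may owe its status to the other
arm's locus, which can bias coarse windows; the published analysis
avoids this by curating arm-assigned cases), uniparental disomy and
imprinting effects, tissue-specific mosaicism dynamics, and
ascertainment bias in which cases reach the literature.

## Numerical choices

* Overlap is inclusive and abutment counts as connected
  (`end + 1 ≥ start`): coverage is per-base, so \[10, 20\] and \[21, 30\]
  form one run. This makes the interval algebra match a per-position
  classifier exactly, which the property suite exploits: on ≥100 random
  block-aligned cohorts on a 10 kb grid, the span, the refinement and
  all four windows are compared against independent per-cell oracles.
* Ties among evidence boundaries resolve to the coordinate closest to
  the refined span; equal coordinates deduplicate trivially through
  min/max.
* Percentages round half-up to one decimal (8.8%, 17.5%, 38.6% style);
  Mb values round to two decimals. Shape percentages use the
  reported-shape denominator (43 in the packaged cohort), not the cohort
  size.
* An arm with no pathogenic evidence, or no span-exceeding abnormal
  carrier, yields an open-ended window flagged "not narrowable" rather
  than an error; a missing refined span is a contract violation.
* Degenerate inputs: an empty normal set is an inference error; a
  disconnected normal set reduces to the anchored component with a gap
  warning; evidence on another chromosome or build is skipped with a
  warning (benign) or rejected (case evidence).
* Problem sizes in the test suite — 100 oracle cohorts, 20 recovery
  seeds at n = 50/200/800, 2,000 cases for the penetrance calibration
  check — were chosen to give stable verdicts (binomial noise well below
  the asserted margins) while keeping the default run around a minute.

## A worked run

```{r, eval = FALSE}
map <- infer_dosage_map() # packaged fixtures throughout
map
#> Pericentric dosage map (chr11, GRCh37)
#>   triplo-insensitive span: 48,303,671-60,473,821 (12.17 Mb)
#>   refined span:            47,675,469-60,516,539 (12.84 Mb)
#>   11p sensitive-start window: 45,048,321-47,675,469 (2.63 Mb)
#>   11q sensitive-start window: 60,516,539-61,479,322 (0.96 Mb)
#>   coarse windows: p 42,922,228-48,303,671; q 60,473,821-79,072,352
tidy(map)
autoplot(map)

summarize_cohort(load_packaged_cohort("table1"))
tabulate_phenotypes(load_packaged_cohort("table5"), map)
```

## Known limitations

* The inference is deterministic interval algebra; no probabilistic or
  penetrance-weighted boundary estimation is attempted, and no
  confidence statement attaches to the windows beyond "the changeover
  lies inside".
* Gene-level annotation of the spans is out of scope (it depends on
  external database versions), as is liftover between genome builds and
  any live querying of population CNV services.
* The ISCN parser is deliberately partial: derivative-chromosome
  arithmetic and multi-chromosome rearrangement semantics are reduced to
  labelling a case *complex*; such cases are excluded from inference
  anyway.
* With only five informative normal and five informative abnormal cases,
  the packaged boundaries are envelopes of very few observations; the
  windows will tighten as informative cases accrue, which is exactly
  what the recovery experiments quantify on synthetic cohorts.
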