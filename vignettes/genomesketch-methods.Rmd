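---
title: "genomesketch: models, geometry and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genomesketch: models, geometry and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesketch)
```

`genomesketch` is a headless genome-browser engine: it parses standard
genomics formats, computes the geometry a browser would draw (pileups,
coverage, breakend adjacencies, synteny blocks, chord diagrams), and
serializes deterministic SVG. This vignette records the models it
implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## The coordinate model

All internal coordinates are 0-based half-open; 1-based inclusive
appears in exactly two places — locstrings (`"chr1:1,000-2,000"`) and
VCF I/O — and is converted at those boundaries. This matches the native
conventions of BED and BAM and avoids ±1 drift through the geometry
code.

A view is an ordered list of regions (`displayed_regions()`), possibly
discontiguous and possibly from the same chromosome twice; order is
significant. The forward transform is

$$\mathrm{px}(c) = \frac{\sum_{j<i} w_j + \delta_i(c)}{\text{bpPerPx}}
  + n_{\text{boundaries}} \cdot \text{interRegionPadding}$$

where $w_j$ are the widths of preceding regions and $\delta_i(c)$ is the
within-region offset, mirrored ($e_i - 1 - c$) in reversed regions. The
inverse `px_to_bp()` recovers the base by flooring the local offset, so
`px_to_bp(bp_to_px(x)) == x` for every displayed base — a property the
test suite checks on 10,000 random discontiguous/reversed stacks. A
pixel falling inside inter-region padding returns a gap marker, not an
error; a coordinate outside every displayed region maps to `NA`
(absence is a value).

Parameters: `interRegionPadding` defaults to 2 px (the upstream
browsers show a boundary but do not quantify it; 2 px reads as a hairline
separator at typical zooms). Alias matching is exact and case-sensitive
— equivalence between "1" and "chr1" is delegated entirely to the alias
list, with no heuristic "chr" stripping, so behavior is predictable.
Overlapping duplicate displayed regions are permitted (a browser user
can legitimately show an interval twice) and flagged with a message.

## Pileup layout and coverage

`assign_rows()` is the classic greedy first-fit interval coloring:
intervals arrive sorted by start (ties: longer first, then id) and each
takes the lowest row whose last occupied end plus `paddingBp` fits. For
interval graphs the left-endpoint greedy is optimal, so the row count
equals the maximum overlap depth — asserted against a brute-force
sweep-line oracle on 1,000 random intervals. Reads are keyed on their
padded extent *including soft clips* (`layout_reads()`), so clipped
reads never visually collide; the upstream behavior is unspecified here
and this is the conservative choice.

Coverage counts only reference-consuming aligned ops (`M/=/X`);
deletions and introns (`D/N`) consume reference but add no depth.
Binned values are per-base means, so `sum(depth * binSize)` equals the
total aligned-base mass whenever the bin width divides the region — the
conservation property in the acceptance suite.

Insert-size color bands default to the sample median of |TLEN| ± 3
standard deviations estimated from the loaded reads, overridable via
`colorSpec$insertLimits`; the upstream tool names the feature but not
the rule, so the rule is ours and configurable. Base-at-position sorting
orders A, C, G, T, deletion, reference-match, with reads not covering
the position last.

## MM/ML base modifications

The MM tag is walked per the SAM tags specification: within each
`base+code` group the delta values count *skipped* occurrences of the
canonical base along the original read as sequenced. For reverse-strand
alignments the stored sequence is the reverse complement, so occurrences
are enumerated as the complement base from the stored 3' end. Reported
positions are on the stored sequence (what a renderer needs); ML bytes
map to `(v + 0.5)/256`, the midpoint of the byte's probability bin.
`encode_modifications()` is the exact inverse, and 200 simulated reads
on both strands round-trip byte-identically in the acceptance suite.
Multi-code groups (`C+mh`) emit one call per code; numeric ChEBI codes
are kept as a unit.

## Breakends and split-read evidence

The four VCF 4.2 bracket forms map to which side of each position is
retained in the novel adjacency (`left_of_pos` / `right_of_pos`);
`format_breakend()` is the exact inverse of `parse_breakend_alt()`,
closed over all four forms × random coordinates in the tests. Pairing
uses `MATEID` when present, reciprocal coordinate matching otherwise;
unpaired ends survive as single-ended events with a warning rather than
being dropped. Symbolic `<DEL>/<DUP>/<INV>/<TRA>` records become
two-ended events from POS and INFO `END` (with `CHR2` honoured), since
Sniffles-style files encode translocations that way. One subtlety: for
`<TRA>` records `END` refers to a position on `CHR2`, so the
*record's* reference span stays `POS + len(REF)` while the *event's*
second end uses `END`.

Split evidence is geometric: a read's alignment segments are ordered by
their span on the original read (`query_span_on_read()`, where soft and
hard clips both count, mirrored for reverse-strand alignments), and each
adjacent pair contributes one connector between clip-boundary reference
coordinates — the query-later edge of one segment to the query-earlier
edge of the next. With the fixture generator's exact alignments, a
connector's endpoints land exactly on the simulated breakpoints.

The SV-inspector filter grammar is this package's own (the upstream
description is just "simple text expression filters"): whitespace-joined
clauses ANDed; `col=val` exact, `col~val` substring, numeric
comparisons, bare tokens as any-text-column substrings. Filtering is
associative with concatenation (`filter(e1 + " " + e2)` equals
sequential filtering), which the tests assert.

## Synteny blocks

All four input formats normalize to one block model with **query
coordinates on the forward strand** regardless of source convention
(PAF already is; chain's minus-strand query coordinates are converted
as `qSize − end, qSize − start`; delta's reversed ranges likewise).
CIGARs are validated at construction: target consumption must equal
`tEnd − tStart` and query consumption `qEnd − qStart`, so a parser bug
cannot produce a silently inconsistent block. Delta distances translate
as: positive `d` → `d−1` matches then one query deletion (`D`);
negative → one query insertion (`I`); the remainder after the `0`
terminator is matches. Chain triplets translate `size → M`, `dt → D`,
`dq → I`. MCScan anchors yield both per-gene-pair blocks and one merged
block per `###` group (the upstream figures show both), distinguished
by a `level` tag; group strand is the majority vote of its pairs, ties
`"+"`. mashmap-style output is accepted by `parse_paf(permissive =
TRUE)` as PAF-like with no CIGAR.

## SVG scenes

The renderer is the only module that knows pixels. Scenes are ordered
element trees with ids assigned depth-first at construction and numbers
formatted by one fixed rule, so identical inputs serialize to identical
bytes — no timestamps, no unordered traversal; the acceptance suite
runs every CLI render command twice and compares bytes. Geometry
invariants are spot-checked by parsing the SVG back with xml2.

Numerical and aesthetic choices, all defaults in one palette table:

* Ruler ticks at the largest power of ten ≤ viewWidth/5; labels with
  space-grouped thousands.
* Pileup rows 8 px + 1 px padding; coverage subpanel 28 px.
* Circular layouts: angle spans proportional to lengths, one `gapAngle`
  per boundary (n gaps for n regions); conservation
  $\sum \text{span} = 2\pi - n\,g$ holds to 1e−9. Chord endpoints sit
  exactly on the inner radius; the quadratic control point is pulled to
  20 % of the midpoint's distance from the center — an aesthetic
  choice, documented as such.
* Dotplots put the target on x and invert the query axis at render time
  so it reads bottom-up from a bottom-left origin.
* Breakpoint connectors are cubic curves in black; the variant call is
  a green line whose perpendicular "feet" point toward the retained
  side (`left_of_pos` → leftward), enumerated over all four breakend
  orientations in the tests.
* Soft clips render blue, large insertions purple — the conventional
  colors, overridable.

PNG rasterization is not provided: no rasterizer exists in the pinned
dependency set, and SVG is the deliverable format.

## The synthetic-data generator

`make_genome()` draws uniform A/C/G/T per chromosome (one `sample()`
call per chromosome, in order — the documented draw order that makes
outputs reproducible across versions). `apply_svs()` realizes
deletions, tandem duplications, inversions, insertions and reciprocal
translocations as segment chains over the reference; translocations are
applied to the *current* derived state by splitting two chains and
exchanging tails, so several translocations compose naturally. The
truth VCF is read off the derived adjacencies: cross-chromosome
junctions become breakend pairs with mutual `MATEID`s and bracket
orientations determined by the junction geometry; intra-chromosomal
events stay symbolic. `simulate_reads()` samples uniformly from the
derived genome and computes each read's reference alignment by lifting
its interval through the segment map — exact by construction, with
soft clips at junctions, one primary plus supplementaries, mutual SA
tags, and CpG-methylation MM/ML tags on a configurable fraction
(default ¼) of reads. Reads are error-free by default because the
evidence-geometry tests need exact coordinates; an error model is
deliberately out of scope.

The `sv-demo` preset (two 100 kb chromosomes, two reciprocal
translocations, one inversion, one deletion, 1 kb reads at 8×) is the
desk-scale stand-in for the rearranged cancer genomes such tools are
demonstrated on. What a green test does establish: parsing, pairing,
lifting, layout and rendering are exact on data whose truth is known to
the base pair. What it does not: robustness to sequencing error,
misalignment, multimapping, or caller noise — real data properties the
generator intentionally omits.

## Other design decisions

* GFF3 features naming several parents are duplicated under each parent
  (with a message); the tree model stays simple. GTF assembly is limited
  to gene/transcript/exon/CDS — what a feature track draws — and stop
  codons are taken literally from file content.
* The three-frame translation shows the forward strand's three frames
  only; ambiguity codes translate to `X` unless the codon resolves.
* BigBed is not supported; BED covers the need at this scale.
* CRAM is narrowed to the BAM/SAM path: reading CRAM requires reference
  registry plumbing irrelevant to an offline tool.
* The trix dialect (tokenization, 64-line `.ixx` stride, 5-char
  prefixes, 10-hex-digit offsets, the docId encoding
  `refName:start-end|trackId|displayName`) is self-defined and
  versioned in the `.ixx` header comment; byte compatibility with the
  UCSC ixIxx tool is explicitly not asserted — an explicit, testable
  spec beats silent incompatibility.
* The JSON config schema is a minimal dialect of our own with a
  `formatVersion` field; the CLI is a thin shell over exported
  functions, so every behavior is reachable as a library call.

## Known limitations

No interactivity, no Hi-C, no liftover between assemblies, no SV
calling or genotyping — the package consumes calls, it does not make
them. Region queries on plain-text files scan and filter; tabix indexes
are used when present but large-file performance is not a goal at this
scale.
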