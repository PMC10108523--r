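# genomesketch

A headless genome-browser engine for R. `genomesketch` does the
computational work of a modern genome browser — parsing the field's
standard file formats, computing track layouts and structural-variant /
synteny geometry — and emits deterministic, publication-quality SVG
scenes, with no GUI and no network. It is aimed at bioinformaticians who
need scripted, reproducible browser figures (pipelines, reports, CI) and
at tool authors who need the underlying geometry as a library.

## What it computes

**Genome model.** Assemblies from FASTA/`.fai` with chromosome-name
aliases ("chr1" and "1" treated identically) and UCSC cytobands for
ideograms. The view coordinate system is an ordered list of possibly
discontiguous, possibly reversed regions; the core transform maps a base
position to a horizontal pixel offset and back:

    px = (Σ widths of preceding regions + offset within region) / bpPerPx
         + padding per crossed boundary

**Tracks.** Feature trees from GFF3/GTF/BED (plain or tabix), per-sample
genotypes from VCF, binned signal from BigWig, GC content and a
three-frame translation from sequence. Alignments from BAM/SAM get the
classic pileup treatment: greedy first-fit row assignment (provably
optimal for interval graphs — row count equals the maximum overlap
depth), aligned-base coverage, soft-clip and insertion markup,
sort/filter/color policies, and MM/ML base-modification decoding per the
SAM tags specification (delta-encoded skips over a canonical base;
likelihood `(v + 0.5)/256`).

**Structural variation.** The four VCF breakend forms `t[p[`, `t]p]`,
`]p]t`, `[p[t` parse into join orientations and format back verbatim;
mates pair via `MATEID` or reciprocal coordinates; BEDPE and STAR-Fusion
tables are ingested into the same event model. An SV-inspector table
supports text-expression filtering (`type=BND refName~chr start>1000`),
and a breakpoint-split view gathers split-read evidence: segments
ordered along the original read, one connector per adjacent pair, drawn
between the clip-boundary coordinates.

**Synteny.** PAF (with `cg:Z` CIGARs), MUMmer `.delta`, UCSC `.chain`
and MCScan `.anchors` all normalize to one block model (query
coordinates always forward-strand), backing dotplot paths, ribbon
views, and Circos-style chord diagrams whose angle spans are
proportional to sequence lengths.

**Search.** A trix-style two-file prefix index (`.ix` sorted term lines,
`.ixx` sparse byte offsets) over feature names and descriptions, with
document ids that decode straight to genomic locations.

**Fixtures.** A first-class synthetic-data module: random genomes,
engineered SVs (deletion / duplication / inversion / insertion /
reciprocal translocation) realized in derived sequences with an exact
liftover map, truth VCFs with correct breakend brackets, and split
reads whose alignments are computed by lifting — exact by construction,
no aligner needed. Everything is testable offline.

## Worked example

Simulate a rearranged cancer-like genome (two 100 kb chromosomes, two
reciprocal translocations, an inversion, a deletion), then run the SV
inspector:

```r
library(genomesketch)

bundle <- make_fixture_bundle("fx", preset = "sv-demo", seed = 42)
length(bundle$sim$reads)
#> [1] 1641

events <- pair_mates(read_variants(bundle$paths$vcf))
filter_table(to_table(events), "type=BND")[,
  c("id", "refName", "start", "mateRef", "matePos", "type")]
#>        id refName start mateRef matePos type
#> 3 bnd_1_1    chr1 30000    chr2   40001  BND
#> 4 bnd_2_1    chr1 60001    chr2   70000  BND
#> 5 bnd_3_1    chr1 30001    chr2   40000  BND
#> 6 bnd_4_1    chr1 60000    chr2   70001  BND
```

Four breakend-pair events: the two junctions of each reciprocal
translocation, at exactly the engineered coordinates (1-based display).
The same workflow from the shell, producing the table, a chord-diagram
overview and a breakpoint-split evidence figure:

```sh
inst/cli/genomesketch sv-inspect --vcf fx/truth.vcf --filter "type=BND" \
    --out-table sv.tsv --out-circular sv.svg --config fx/config.json
inst/cli/genomesketch render breakpoint --config fx/config.json \
    --event bnd_1_1 --window 4000 --tracks truth-sv,reads --out bp.svg
```

`bp.svg` shows two stacked panels centered on the two breakpoints, one
curved black connector per junction-crossing read, and the variant call
as a green line whose directional "feet" indicate which side of each
breakpoint is retained. Rendering is byte-deterministic: the same
command always produces the same file.

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end workflow from
scratch — generating the fixture genome, simulating the SVs and reads,
running `sv-inspect`, and rendering the breakpoint-split and dotplot
scenes — and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
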