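Package: genomesketch
Title: Headless Genome-Browser Engine for Structural Variation and Synteny Graphics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A headless genome-browser engine: parses standard genomics
    formats (FASTA/fai, GFF3/GTF/BED, VCF including breakends, BAM/SAM with
    SA/MM/ML tags, BigWig, PAF, MUMmer delta, UCSC chain, MCScan anchors),
    computes track layouts (read pileups, coverage, base-modification calls)
    and structural-variant/synteny geometry (breakend pairing, dotplot paths,
    synteny ribbons, Circos-style chords), and emits deterministic
    publication-quality SVG scenes for linear, dotplot, circular,
    linear-synteny, breakpoint-split and SV-inspector views. Includes a
    synthetic-fixture generator (toy genomes, engineered SVs, split-aligned
    reads with exact truth) so everything is testable offline, a trix-style
    full-text index for feature-name search, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    VariantAnnotation,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
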