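write_test_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1;Name=G1",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t50\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tsrc\tgene\t201\t300\t.\t-\t.\tID=g2;Name=G2",
    "chr2\tsrc\tgene\t51\t80\t.\t+\t.\tID=g3;Name=G3"), path)
  path
}

test_that("GFF3 rows assemble into nested features, 0-based half-open", {
  td <- withr::local_tempdir()
  gff <- write_test_gff(file.path(td, "t.gff3"))
  fs <- read_features(gff)
  expect_length(fs, 3)
  g1 <- fs[[1]]
  expect_equal(g1$uniqueId, "g1")
  expect_equal(g1$start, 0)       # 1-based 1 -> 0-based 0
  expect_equal(g1$end, 100)
  expect_length(g1$subfeatures, 1)
  expect_length(g1$subfeatures[[1]]$subfeatures, 1)
  expect_equal(g1$subfeatures[[1]]$subfeatures[[1]]$type, "exon")
  expect_equal(fs[[2]]$strand, "-")
})

test_that("empty annotation files give an empty feature list", {
  td <- withr::local_tempdir()
  gff <- file.path(td, "empty.gff3")
  writeLines("##gff-version 3", gff)
  expect_length(read_features(gff), 0)
})

test_that("region queries equal full-scan-then-filter", {
  td <- withr::local_tempdir()
  gff <- write_test_gff(file.path(td, "t.gff3"))
  all_fs <- read_features(gff)
  reg <- region("chr1", 150, 250)
  got <- read_features(gff, region = reg)
  want <- Filter(function(f) f$refName == "chr1" && f$start < reg$end &&
                   f$end > reg$start, all_fs)
  expect_equal(vapply(got, `[[`, "", "uniqueId"),
               vapply(want, `[[`, "", "uniqueId"))
  expect_equal(vapply(got, `[[`, "", "uniqueId"), "g2")
})

test_that("tabix region query agrees with the plain-text scan", {
  td <- withr::local_tempdir()
  gff <- write_test_gff(file.path(td, "t.gff3"))
  bg <- Rsamtools::bgzip(gff, file.path(td, "t.gff3.gz"))
  Rsamtools::indexTabix(bg, format = "gff")
  reg <- region("chr1", 0, 120)
  plain <- read_features(gff, region = reg)
  tbx <- read_features(bg, format = "gff3", region = reg)
  expect_equal(vapply(tbx, `[[`, "", "uniqueId"),
               vapply(plain, `[[`, "", "uniqueId"))
})

test_that("GFF3 write/read round trip preserves the tree", {
  td <- withr::local_tempdir()
  gff <- write_test_gff(file.path(td, "t.gff3"))
  fs <- read_features(gff)
  out <- file.path(td, "rt.gff3")
  write_gff3(fs, out)
  fs2 <- read_features(out)
  strip <- function(f) {
    f$attributes <- f$attributes[order(names(f$attributes))]
    f$subfeatures <- lapply(f$subfeatures, strip)
    f
  }
  expect_equal(lapply(fs2, strip), lapply(fs, strip))
})

test_that("BED and GTF readers normalize into the same model", {
  td <- withr::local_tempdir()
  bed <- file.path(td, "t.bed")
  writeLines(c("chr1\t10\t20\tfeatA\t0\t+", "chr1\t30\t40\tfeatB\t0\t-"),
             bed)
  fs <- read_features(bed)
  expect_length(fs, 2)
  expect_equal(fs[[1]]$start, 10)   # BED is already 0-based
  expect_equal(fs[[1]]$end, 20)
  expect_equal(fs[[2]]$strand, "-")
  gtf <- file.path(td, "t.gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t1\t90\t.\t+\t.\t",
           'gene_id "gX"; transcript_id "tX";'),
    paste0("chr1\tsrc\texon\t1\t40\t.\t+\t.\t",
           'gene_id "gX"; transcript_id "tX";'),
    paste0("chr1\tsrc\texon\t61\t90\t.\t+\t.\t",
           'gene_id "gX"; transcript_id "tX";')), gtf)
  gf <- read_features(gtf)
  expect_length(gf, 1)
  expect_equal(gf[[1]]$type, "gene")
  tx <- gf[[1]]$subfeatures[[1]]
  expect_length(tx$subfeatures, 2)
  expect_equal(tx$subfeatures[[1]]$end, 40)
})

test_that("multi-sample VCF keeps genotypes in header order", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sampleA", "sampleB"), collapse = "\t"),
    paste(c("chr1", "101", "v1", "A", "G", "50", "PASS", "DP=10",
            "GT:DP", "0/1:7", "1/1:9"), collapse = "\t"),
    paste(c("chr1", "1001", "sv1", "T", "<DEL>", "30", "PASS",
            "SVTYPE=DEL;END=5000", "GT:DP", "0/1:5", "0/0:6"),
          collapse = "\t")), vcf)
  vs <- read_variants(vcf)
  expect_equal(vs[[1]]$samples, c("sampleA", "sampleB"))
  expect_equal(vs[[1]]$genotypes[[1]]$GT, "0/1")
  expect_equal(vs[[1]]$genotypes[[2]]$GT, "1/1")
  expect_equal(vs[[1]]$genotypes[[2]]$DP, "9")
  # symbolic <DEL> end comes from INFO END (1-based inclusive)
  expect_equal(vs[[2]]$start, 1000)
  expect_equal(vs[[2]]$end, 5000)
  # region query equals full-scan filter
  reg <- region("chr1", 0, 500)
  expect_equal(vapply(read_variants(vcf, region = reg), `[[`, "",
                      "uniqueId"), "v1")
  # cross-check the simple record against the independent VCF parser
  skip_if_not_installed("VariantAnnotation")
  vv <- suppressWarnings(VariantAnnotation::readVcf(vcf))
  expect_equal(unname(as.character(
    VariantAnnotation::geno(vv)$GT[1, ])), c("0/1", "1/1"))
  expect_equal(BiocGenerics::start(vv)[1], vs[[1]]$start + 1)
})

test_that("inconsistent sample columns raise an error", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "bad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("chr1", "101", "v1", "A", "G", "50", "PASS", ".", "GT",
            "0/1"), collapse = "\t")), vcf)
  expect_error(read_variants(vcf), "column count")
})

test_that("BigWig bins average per-base values; empty bins are NA", {
  td <- withr::local_tempdir()
  bw <- file.path(td, "t.bw")
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 51), c(50, 70)),
                               score = c(2, 6))
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = 200)
  rtracklayer::export.bw(gr, bw)
  sig <- read_quant(bw, region("chr1", 0, 100), binSizeBp = 10)
  expect_length(sig$values, 10)
  expect_equal(sig$values[1:5], rep(2, 5))
  expect_equal(sig$values[6:7], rep(6, 2))
  expect_true(all(is.na(sig$values[8:10])))
  # brute-force per-base oracle on a straddling bin size
  sig2 <- read_quant(bw, region("chr1", 45, 75), binSizeBp = 30)
  perBase <- c(rep(2, 5), rep(6, 20), rep(NA, 5))
  expect_equal(sig2$values, mean(perBase, na.rm = TRUE))
  expect_error(read_quant(bw, region("chr1", 0, 500)), "beyond chrom")
  expect_error(read_quant(bw, region("chrX", 0, 10)), "unknown chrom")
})

test_that("gc_content counts G/C per window, N excluded", {
  expect_equal(gc_content("GGCC", 4, 4)$values, 1.0)
  expect_equal(gc_content("ATAT", 2, 2)$values, c(0, 0))
  expect_true(is.na(gc_content("NNNN", 4, 4)$values))
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE),
             collapse = "")
  win <- 250
  got <- gc_content(s, win, win)$values
  chars <- strsplit(s, "")[[1]]
  want <- vapply(seq(1, 10000, by = win), function(i) {
    w <- chars[i:(i + win - 1)]
    sum(w %in% c("G", "C")) / sum(w %in% c("A", "C", "G", "T"))
  }, 0)
  expect_equal(got, want)
})

test_that("three-frame translation follows the standard code", {
  expect_equal(three_frame_translation("ATGAAA"), c("MK", "*", "E"))
  expect_equal(three_frame_translation(""), c("", "", ""))
  # ambiguity translates to X when the codon is ambiguous
  expect_equal(three_frame_translation("ATN")[1], "X")
  # cross-check one frame with Biostrings directly
  s <- "ATGGCCATTGTAATGGGCCGCTGAAAGGGTGCCCGATAG"
  expect_equal(three_frame_translation(s)[1],
               as.character(Biostrings::translate(Biostrings::DNAString(
                 substr(s, 1, nchar(s) - nchar(s) %% 3)))))
})
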