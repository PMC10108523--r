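test_that("the four breakend bracket forms map to join sides", {
  # enumeration of the VCF 4.2 breakend orientation table
  cases <- list(
    list(alt = "A[chr5:100[", join = "left_of_pos",
         mate = "right_of_pos"),
    list(alt = "A]chr5:100]", join = "left_of_pos", mate = "left_of_pos"),
    list(alt = "]chr5:100]A", join = "right_of_pos",
         mate = "left_of_pos"),
    list(alt = "[chr5:100[A", join = "right_of_pos",
         mate = "right_of_pos"))
  for (cs in cases) {
    b <- parse_breakend_alt(cs$alt, "chr1", 50)
    expect_equal(b$joinSide, cs$join)
    expect_equal(b$mateJoinSide, cs$mate)
    expect_equal(b$mateChrom, "chr5")
    expect_equal(b$matePos, 100)
    expect_equal(b$insertedSeq, "")
  }
  # inserted sequence is t minus the anchor base
  b <- parse_breakend_alt("ATTG[chr5:100[", "chr1", 50)
  expect_equal(b$anchorBase, "A")
  expect_equal(b$insertedSeq, "TTG")
  b2 <- parse_breakend_alt("]chr5:100]TTGA", "chr1", 50)
  expect_equal(b2$anchorBase, "A")
  expect_equal(b2$insertedSeq, "TTG")
  expect_error(parse_breakend_alt("A[chr5:100", "chr1", 50),
               "not a breakend")
})

test_that("format/parse breakend identity over random coordinates", {
  set.seed(31)
  forms <- c("t[p[", "t]p]", "]p]t", "[p[t")
  for (k in 1:200) {
    chrom <- sample(c("chr5", "17", "scaffold_2"), 1)
    pos <- sample.int(1e8, 1)
    t <- paste(sample(c("A", "C", "G", "T"),
                      sample(1:4, 1), replace = TRUE), collapse = "")
    p <- paste0(chrom, ":", pos)
    alt <- switch(sample(forms, 1),
                  "t[p[" = paste0(t, "[", p, "["),
                  "t]p]" = paste0(t, "]", p, "]"),
                  "]p]t" = paste0("]", p, "]", t),
                  "[p[t" = paste0("[", p, "[", t))
    expect_identical(format_breakend(parse_breakend_alt(alt, "chr1", 7)),
                     alt)
  }
})

make_bnd_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO"), collapse = "\t"),
    "chr1\t5000\tb1\tA\tA[chr5:7000[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr5\t7000\tb2\tG\t]chr1:5000]G\t.\tPASS\tSVTYPE=BND;MATEID=b1",
    # reciprocal pair without MATEID
    "chr2\t100\tx1\tC\tC[chr3:200[\t.\tPASS\tSVTYPE=BND",
    "chr3\t200\tx2\tT\t]chr2:100]T\t.\tPASS\tSVTYPE=BND",
    # lone breakend
    "chr4\t42\tlone\tG\tG[chr9:1[\t.\tPASS\tSVTYPE=BND")
}

test_that("pair_mates pairs by MATEID, reciprocity, and warns otherwise", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "bnd.vcf")
  writeLines(make_bnd_vcf_lines(), vcf)
  vars <- read_variants(vcf)
  expect_warning(evs <- pair_mates(vars), "no reciprocal mate")
  expect_length(evs, 3)
  kinds <- vapply(evs, `[[`, "", "kind")
  expect_true(all(kinds == "BND"))
  ids <- vapply(evs, `[[`, "", "id")
  expect_setequal(ids, c("b1", "x1", "lone"))
  paired <- evs[[which(ids == "b1")]]
  expect_equal(paired$end1$refName, "chr1")
  expect_equal(paired$end1$pos, 4999)      # 0-based internal
  expect_equal(paired$end2$refName, "chr5")
  lonee <- evs[[which(ids == "lone")]]
  expect_null(lonee$end2)
})

test_that("symbolic SV records become two-ended events", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "sym.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               "chr1\t1001\td1\tT\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5000",
               "chr1\t9000\ttr\tT\t<TRA>\t.\tPASS\tSVTYPE=TRA;END=77;CHR2=chr2"),
             vcf)
  evs <- pair_mates(read_variants(vcf))
  expect_length(evs, 2)
  expect_equal(evs[[1]]$kind, "DEL")
  expect_equal(evs[[1]]$end1$pos, 1000)
  expect_equal(evs[[1]]$end2$pos, 4999)
  expect_equal(evs[[2]]$kind, "TRA")
  expect_equal(evs[[2]]$end2$refName, "chr2")
})

test_that("BEDPE rows become midpoint events; bad arity errors", {
  td <- withr::local_tempdir()
  bedpe <- file.path(td, "t.bedpe")
  writeLines(c("chr1\t100\t200\tchr2\t1000\t1100\tevA\t5\t+\t-"), bedpe)
  evs <- read_bedpe(bedpe)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$end1$pos, 150)
  expect_equal(evs[[1]]$end2$pos, 1050)
  expect_equal(evs[[1]]$id, "evA")
  expect_equal(evs[[1]]$info$strand1, "+")
  writeLines(character(), bedpe)
  expect_length(read_bedpe(bedpe), 0)
  writeLines("chr1\t1\t2\tchr2\t3", bedpe)
  expect_error(read_bedpe(bedpe), ">= 6 columns")
})

test_that("STAR-fusion breakpoint strings are ingested", {
  td <- withr::local_tempdir()
  tsv <- file.path(td, "fus.tsv")
  writeLines(c(paste(c("#FusionName", "JunctionReadCount",
                       "LeftBreakpoint", "RightBreakpoint"),
                     collapse = "\t"),
               paste(c("AAA--BBB", "12", "chr1:500:+", "chr9:900:-"),
                     collapse = "\t")), tsv)
  evs <- read_starfusion(tsv)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$kind, "fusion")
  expect_equal(evs[[1]]$end1$pos, 499)
  expect_equal(evs[[1]]$end2$refName, "chr9")
})

sv_fixture_table <- function() {
  data.frame(id = c("a", "b", "c", "d", "e"),
             refName = c("chr1", "chr1", "chr2", "chr2", "chr3"),
             start = c(100, 2000, 300, 4000, 50),
             end = c(100, 2000, 300, 4000, 50),
             type = c("BND", "BND", "DEL", "BND", "INV"),
             stringsAsFactors = FALSE)
}

test_that("filter_table implements the clause grammar", {
  tab <- sv_fixture_table()
  expect_equal(filter_table(tab, "type=BND")$id, c("a", "b", "d"))
  expect_equal(nrow(filter_table(tab, "")), 5)
  expect_equal(filter_table(tab, "refName~chr start>1000")$id,
               c("b", "d"))
  expect_equal(filter_table(tab, "start<=100")$id, c("a", "e"))
  # bare token: substring over text columns
  expect_equal(filter_table(tab, "chr3")$id, "e")
  expect_error(filter_table(tab, "bogus=1"), "unknown column")
  expect_error(filter_table(tab, "start<abc"), "not a number")
  # conjunction == sequential filtering
  set.seed(32)
  e1 <- "type=BND"; e2 <- "start>500"
  expect_equal(filter_table(tab, paste(e1, e2)),
               filter_table(filter_table(tab, e1), e2))
})

test_that("breakpoint panels center on the ends and clamp", {
  asm <- assembly("t", data.frame(refName = c("chr1", "chr5"),
                                  length = c(1e5, 1e5)))
  ev <- genomesketch:::sv_event("e", "BND",
                                list(refName = "chr1", pos = 5000),
                                list(refName = "chr5", pos = 7000))
  p <- breakpoint_panels(ev, 1000, asm)
  expect_equal(p$panelA$regions[[1]]$start, 4500)
  expect_equal(p$panelA$regions[[1]]$end, 5500)
  expect_equal(p$panelB$regions[[1]]$start, 6500)
  expect_equal(p$panelB$regions[[1]]$end, 7500)
  near <- genomesketch:::sv_event("e2", "BND",
                                  list(refName = "chr1", pos = 100))
  p2 <- breakpoint_panels(near, 1000, asm)
  expect_equal(p2$panelA$regions[[1]]$start, 0)
  expect_null(p2$panelB)
})

test_that("split evidence yields one connector per adjacent segment pair", {
  asm <- assembly("t", data.frame(refName = c("chr1", "chr5"),
                                  length = c(1e5, 1e5)))
  ev <- genomesketch:::sv_event("e", "BND",
                                list(refName = "chr1", pos = 5000),
                                list(refName = "chr5", pos = 7000))
  panels <- breakpoint_panels(ev, 2000, asm)
  mkseg <- function(name, ref, pos, cigar, supp = FALSE) {
    sp <- cigar_spans(cigar)
    aligned_read(name, ref, pos, cigar,
                 flags = if (supp) 0x800L else 0L,
                 seq = strrep("A", sp$querySpan),
                 tags = list(SA = "x,1,+,1M,60,0;"))
  }
  # read split exactly at the simulated junction: 60 bases on chr1
  # ending at 5000, 40 bases on chr5 starting at 7000
  reads <- list(mkseg("sp1", "chr1", 4940, "60M40S"),
                mkseg("sp1", "chr5", 7000, "60S40M", supp = TRUE),
                mkseg("plain", "chr1", 4000, "100M"))
  reads[[3]]$tags$SA <- NULL
  conn <- gather_split_evidence(reads, ev,
                                list(panels$panelA, panels$panelB))
  expect_equal(nrow(conn), 1)
  expect_equal(conn$refPosA, 5000)   # clip boundary = breakpoint
  expect_equal(conn$refPosB, 7000)
  expect_equal(conn$panelA, 1L)
  expect_equal(conn$panelB, 2L)
  # three segments -> two connectors
  reads3 <- list(mkseg("m", "chr1", 4900, "30M70S"),
                 mkseg("m", "chr5", 7000, "30S40M30S", supp = TRUE),
                 mkseg("m", "chr1", 5100, "70S30M", supp = TRUE))
  conn3 <- gather_split_evidence(reads3, ev,
                                 list(panels$panelA, panels$panelB))
  expect_equal(nrow(conn3), 2)
})
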