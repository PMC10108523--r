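test_that("cigar_spans follows SAM consumption rules", {
  expect_equal(cigar_spans("10M"),
               list(refSpan = 10, querySpan = 10, clippedPrefix = 0,
                    clippedSuffix = 0))
  expect_equal(cigar_spans("5M2I3M"),
               list(refSpan = 8, querySpan = 10, clippedPrefix = 0,
                    clippedSuffix = 0))
  expect_equal(cigar_spans("10H20M5S"),
               list(refSpan = 20, querySpan = 25, clippedPrefix = 10,
                    clippedSuffix = 5))
  expect_error(parse_cigar("10Mx"), "invalid CIGAR")
  skip_if_not_installed("GenomicAlignments")
  set.seed(21)
  for (k in 1:50) {
    cg <- random_cigar()
    sp <- cigar_spans(cg)
    expect_equal(sp$refSpan,
                 GenomicAlignments::cigarWidthAlongReferenceSpace(cg))
    expect_equal(sp$querySpan,
                 GenomicAlignments::cigarWidthAlongQuerySpace(cg))
  }
})

test_that("assign_rows is first-fit and optimal on interval graphs", {
  empty <- assign_rows(data.frame(start = numeric(), end = numeric()))
  expect_equal(empty$rowCount, 0)
  lay <- assign_rows(data.frame(start = c(0, 5, 12), end = c(10, 15, 20)),
                     paddingBp = 0)
  expect_equal(unname(lay$rowOf), c(0, 1, 0))
  expect_equal(lay$rowCount, 2)
  expect_error(assign_rows(data.frame(start = c(5, 0), end = c(10, 10))),
               "not sorted")
  set.seed(22)
  for (rep in 1:10) {
    n <- 1000
    s <- sort(sample.int(5000, n, replace = TRUE))
    len <- sample.int(200, n, replace = TRUE)
    iv <- data.frame(start = s, end = s + len,
                     id = sprintf("i%04d", seq_len(n)))
    iv <- iv[order(iv$start, -iv$end, iv$id), ]
    lay <- assign_rows(iv, paddingBp = 0)
    # no same-row overlap
    for (r in unique(lay$rowOf)) {
      sub <- iv[lay$rowOf[iv$id] == r, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
    # left-endpoint greedy colors interval graphs optimally
    expect_equal(lay$rowCount, oracle_max_depth(iv$start, iv$end))
  }
})

test_that("coverage counts aligned bases only; conservation holds", {
  reg <- region("chr1", 0, 50)
  r1 <- read_from_cigar("10M", start = 0)
  cov <- compute_coverage(list(r1), reg, binSizeBp = 1)
  expect_equal(cov$values, c(rep(1, 10), rep(0, 40)))
  # deletions do not add depth
  r2 <- read_from_cigar("5M5D5M", start = 20)
  cov2 <- compute_coverage(list(r2), reg, binSizeBp = 1)
  expect_equal(cov2$values[21:35], c(rep(1, 5), rep(0, 5), rep(1, 5)))
  set.seed(23)
  reads <- lapply(1:200, function(i)
    read_from_cigar(random_cigar(), start = sample.int(400, 1) - 1,
                    name = paste0("r", i)))
  reg <- region("chr1", 0, 500)
  cov3 <- compute_coverage(reads, reg, binSizeBp = 1)
  expect_equal(cov3$values, oracle_coverage(reads, reg))
  # mass conservation at bin size 10 (500 divisible by 10)
  cov10 <- compute_coverage(reads, reg, binSizeBp = 10)
  expect_equal(sum(cov10$values * 10), sum(oracle_coverage(reads, reg)))
})

test_that("soft-clip markers anchor at the alignment edges", {
  expect_equal(find_softclip_markers(read_from_cigar("20S30M", 100)),
               data.frame(refPos = 100, clipLen = 20, side = "left"))
  expect_equal(find_softclip_markers(read_from_cigar("30M20S", 100)),
               data.frame(refPos = 130, clipLen = 20, side = "right"))
  both <- find_softclip_markers(read_from_cigar("5S10M5S", 100))
  expect_equal(both$side, c("left", "right"))
  expect_equal(both$refPos, c(100, 110))
})

test_that("find_insertions respects the length threshold and a walk oracle", {
  r <- read_from_cigar("5M3I5M", 0)
  expect_equal(find_insertions(r, 1), data.frame(refPos = 5, insLen = 3))
  expect_equal(nrow(find_insertions(r, 4)), 0)
  set.seed(24)
  for (k in 1:30) {
    cg <- random_cigar()
    r <- read_from_cigar(cg, start = 100)
    got <- find_insertions(r, 1)
    # independent walk
    ops <- parse_cigar(cg); pos <- 100; want <- list()
    for (i in seq_len(nrow(ops))) {
      if (ops$op[i] == "I")
        want[[length(want) + 1]] <- c(pos, ops$len[i])
      if (ops$op[i] %in% c("M", "D", "N", "=", "X")) pos <- pos + ops$len[i]
    }
    expect_equal(nrow(got), length(want))
    if (length(want))
      expect_equal(unname(as.matrix(got)),
                   matrix(unlist(want), ncol = 2, byrow = TRUE))
  }
})

test_that("read_to_ref_path consumes both spans exactly", {
  p <- read_to_ref_path(read_from_cigar("10M", 7))
  expect_equal(p, data.frame(qStart = 0, qEnd = 10, rStart = 7, rEnd = 17,
                             kind = "match"))
  p2 <- read_to_ref_path(read_from_cigar("5M3I5M", 0))
  expect_equal(p2$kind, c("match", "ins", "match"))
  expect_equal(sum(p2$qEnd - p2$qStart), 13)
  expect_equal(sum(p2$rEnd - p2$rStart), 10)
  set.seed(25)
  for (k in 1:30) {
    cg <- random_cigar()
    sp <- cigar_spans(cg)
    p <- read_to_ref_path(read_from_cigar(cg, 0))
    expect_equal(sum(p$rEnd[p$kind != "ins"] - p$rStart[p$kind != "ins"]),
                 sp$refSpan)
    expect_equal(sum(p$qEnd[p$kind != "del"] - p$qStart[p$kind != "del"]),
                 sp$querySpan - genomesketch:::soft_in_clips(cg))
  }
})

test_that("query_span_on_read places segments on the original read", {
  fwd <- aligned_read("r", "chr1", 0, "10H20M5S", strand = "+",
                      seq = strrep("A", 25))
  expect_equal(query_span_on_read(fwd), c(10, 30))
  rev <- aligned_read("r", "chr1", 0, "10H20M5S", strand = "-",
                      seq = strrep("A", 25))
  expect_equal(query_span_on_read(rev), c(5, 25))
  expect_equal(query_span_on_read(read_from_cigar("35M")), c(0, 35))
})

test_that("MM delta decoding walks forward and reverse strands", {
  r1 <- aligned_read("m1", "chr1", 0, "5M", seq = "CCCCC",
                     tags = list(MM = "C+m,2,0;"))
  expect_equal(decode_modifications(r1)$readPos, c(2L, 3L))
  # reverse: occurrences counted on the original read = complement base
  # walked from the stored sequence's 3' end
  r2 <- aligned_read("m2", "chr1", 0, "5M", strand = "-", seq = "GGGGG",
                     tags = list(MM = "C+m,0;"))
  expect_equal(decode_modifications(r2)$readPos, 4L)
  r3 <- aligned_read("m3", "chr1", 0, "1M", seq = "C",
                     tags = list(MM = "C+m,0;", ML = 255L))
  expect_equal(decode_modifications(r3)$likelihood, 255.5 / 256)
  # malformed: skips past the last occurrence
  bad <- aligned_read("m4", "chr1", 0, "3M", seq = "CAT",
                      tags = list(MM = "C+m,5;"))
  expect_error(decode_modifications(bad), "malformed MM")
})

test_that("decode/encode round trip reproduces the MM string", {
  set.seed(26)
  for (k in 1:50) {
    n <- sample(20:60, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    strand <- sample(c("+", "-"), 1)
    base <- "C"
    occBase <- if (strand == "+") base else "G"
    chars <- strsplit(seq, "")[[1]]
    occ <- if (strand == "+") which(chars == "C") else
      rev(which(chars == "G"))
    if (length(occ) < 2) next
    picks <- sort(sample(seq_along(occ), sample(1:min(4, length(occ)), 1)))
    deltas <- diff(c(0L, picks)) - 1L
    mm <- paste0("C+m,", paste(deltas, collapse = ","), ";")
    ml <- as.integer(sample(0:255, length(picks), replace = TRUE))
    r <- aligned_read("r", "chr1", 0, paste0(n, "M"), strand = strand,
                      seq = seq, tags = list(MM = mm, ML = ml))
    calls <- decode_modifications(r)
    expect_equal(nrow(calls), length(picks))
    enc <- encode_modifications(r, calls)
    expect_equal(enc$MM, mm)
    expect_equal(enc$ML, ml)
  }
})

test_that("read policies filter, sort and color deterministically", {
  mk <- function(name, flag, mapq, base, strand = "+", hp = NULL) {
    # 10M read over positions 100..110 with the probe base at 105
    seq <- paste0(strrep("A", 5), base, strrep("A", 4))
    tags <- list()
    if (!is.null(hp)) tags$HP <- hp
    aligned_read(name, "chr1", 100, "10M", strand = strand, flags = flag,
                 mapq = mapq, seq = seq, tags = tags)
  }
  reads <- list(mk("rT", 0L, 60, "T"), mk("rA", 0L, 60, "A"),
                mk("rG", 0L, 10, "G"), mk("rC", 0L, 60, "C"),
                mk("unmapped", 4L, 0, "A"),
                mk("rDel", 0L, 60, "A"))
  reads[[6]]$cigar <- "5M2D5M"
  reads[[6]]$seq <- strrep("A", 10)
  out <- apply_read_policies(reads,
                             filterSpec = list(flagsExclude = 0x4),
                             sortSpec = list(by = "base"), at = 105)
  expect_false("unmapped" %in% vapply(attr(out, "reads"), `[[`, "",
                                      "name"))
  bases <- vapply(attr(out, "reads"), genomesketch:::read_base_at, "", 105)
  expect_equal(bases, c("A", "C", "G", "T", "del"))
  # color by strand
  reads2 <- list(mk("f", 0L, 60, "A"), mk("r", 16L, 60, "A",
                                          strand = "-"))
  cc <- apply_read_policies(reads2, colorSpec = list(by = "strand"))
  expect_equal(cc$colorClass, c("strand_forward", "strand_reverse"))
  # tag filter
  reads3 <- list(mk("h1", 0L, 60, "A", hp = 1L), mk("h2", 0L, 60, "A",
                                                    hp = 2L))
  kept <- apply_read_policies(reads3,
                              filterSpec = list(tag = list(name = "HP",
                                                           value = 1)))
  expect_equal(kept$uniqueId, reads3[[1]]$uniqueId)
  expect_error(apply_read_policies(reads3, sortSpec = list(by = "zzz")),
               "unknown sort")
})

test_that("SAM text and BAM round trips agree", {
  td <- withr::local_tempdir()
  asm <- toy_assembly()
  r <- aligned_read("r1", "chr1", 99, "5S10M", seq = strrep("A", 15),
                    tags = list(NM = 0L, SA = "chr2,1,+,15M,60,0;",
                                MM = "A+a,0;", ML = c(10L, 20L)))
  sam <- file.path(td, "t.sam")
  write_sam(list(r), sam, asm)
  back <- read_alignments(sam)[[1]]
  expect_equal(back$start, 99)
  expect_equal(back$cigar, "5S10M")
  expect_equal(back$tags$SA, "chr2,1,+,15M,60,0;")
  expect_equal(back$tags$ML[1:2], c(10, 20))
  # through samtools-compatible BAM via Rsamtools
  bam <- Rsamtools::asBam(sam, file.path(td, "t"),
                          overwrite = TRUE)
  back2 <- read_alignments(bam)[[1]]
  expect_equal(back2$start, 99)
  expect_equal(back2$cigar, "5S10M")
  expect_equal(as.character(back2$tags$SA), "chr2,1,+,15M,60,0;")
  # region filter on SAM text path
  none <- read_alignments(sam, region = region("chr1", 200, 300))
  expect_length(none, 0)
  hit <- read_alignments(sam, region = region("chr1", 100, 105))
  expect_length(hit, 1)
})
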