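svg_xml <- function(scene) xml2::read_xml(svg_serialize(scene))

path_numbers <- function(d) {
  as.numeric(regmatches(d, gregexpr("-?[0-9.]+", d))[[1]])
}

test_that("rendering is deterministic and ids are unique", {
  d <- displayed_regions(list(region("chr1", 0, 500)))
  feats <- lapply(1:3, function(i)
    feature(paste0("f", i), "chr1", (i - 1) * 150, (i - 1) * 150 + 100,
            type = "gene"))
  mk <- function() svg_serialize(render_linear(
    d, list(list(trackId = "t", type = "feature", features = feats)),
    bpPerPx = 1))
  expect_identical(mk(), mk())
  x <- svg_xml(render_linear(
    d, list(list(trackId = "t", type = "feature", features = feats)),
    bpPerPx = 1))
  ids <- xml2::xml_attr(xml2::xml_find_all(x, "//*[@id]"), "id")
  expect_false(any(duplicated(ids)))
})

test_that("linear scene: ruler tick policy and feature geometry", {
  skip_if_not_installed("xml2")
  d <- displayed_regions(list(region("chr1", 0, 500)))
  # 0 tracks: ruler only; step = 10^floor(log10(500/5)) = 100 ->
  # ticks at 0,100,...,400 = 5 ticks (+5 labels)
  x <- svg_xml(render_linear(d, list(), bpPerPx = 1))
  expect_length(xml2::xml_find_all(x, "//*[@class='ruler-tick']"), 5)
  expect_length(xml2::xml_find_all(x, "//*[@class='ruler-label']"), 5)
  expect_equal(tick_step(500), 100)
  expect_equal(tick_step(5000), 1000)
  # 3 disjoint features -> exactly 3 feature rects, x == bp transform
  feats <- lapply(1:3, function(i)
    feature(paste0("f", i), "chr1", (i - 1) * 150, (i - 1) * 150 + 100,
            type = "gene"))
  x2 <- svg_xml(render_linear(
    d, list(list(trackId = "t", type = "feature", features = feats)),
    bpPerPx = 2))
  rects <- xml2::xml_find_all(x2, "//*[@class='feature feature-gene']")
  expect_length(rects, 3)
  xs <- as.numeric(xml2::xml_attr(rects, "x"))
  want <- vapply(feats, function(f) bp_to_px("chr1", f$start, d, 2), 0)
  expect_equal(xs, want)
  expect_error(render_linear(displayed_regions(list())), "zero-width")
})

test_that("region boundaries draw separators at the padding midline", {
  d <- displayed_regions(list(region("chr1", 0, 100),
                              region("chr2", 0, 100)),
                         interRegionPadding = 4)
  x <- svg_xml(render_linear(d, list(), bpPerPx = 1))
  sep <- xml2::xml_find_all(x, "//*[@class='separator']")
  expect_length(sep, 1)
  expect_equal(as.numeric(xml2::xml_attr(sep, "x1")), 102)
})

test_that("layout_circle spans are proportional and conserve the circle", {
  lay <- layout_circle(list(region("c1", 0, 100), region("c2", 0, 100)),
                       gapAngle = 0)
  spans <- lay$slices$angleEnd - lay$slices$angleStart
  expect_equal(spans, c(pi, pi))
  lay2 <- layout_circle(list(region("c1", 0, 300), region("c2", 0, 100)),
                        gapAngle = 0)
  spans2 <- lay2$slices$angleEnd - lay2$slices$angleStart
  expect_equal(spans2, c(3 * pi / 2, pi / 2))
  set.seed(41)
  for (k in 1:100) {
    n <- sample(1:8, 1)
    lens <- sample.int(1e6, n)
    gap <- stats::runif(1, 0, 2 * pi / (n + 1) * 0.5)
    regs <- lapply(seq_len(n), function(i)
      region(paste0("c", i), 0, lens[i]))
    lay <- layout_circle(regs, gapAngle = gap)
    spans <- lay$slices$angleEnd - lay$slices$angleStart
    expect_equal(sum(spans), 2 * pi - n * gap, tolerance = 1e-9)
    expect_equal(spans / sum(spans), lens / sum(lens))
  }
})

test_that("chords land on the inner radius; undisplayed events skipped", {
  skip_if_not_installed("xml2")
  lay <- layout_circle(list(region("chr1", 0, 1000),
                            region("chr2", 0, 1000)),
                       gapAngle = 0.05, radiusPx = 150)
  ev <- genomesketch:::sv_event("t1", "BND",
                                list(refName = "chr1", pos = 250),
                                list(refName = "chr2", pos = 750))
  sc <- render_circular(lay, list(ev), bandWidth = 12, marginPx = 20)
  x <- svg_xml(sc)
  chords <- xml2::xml_find_all(x, "//*[contains(@class,'chord ')]")
  expect_length(chords, 1)
  nums <- path_numbers(xml2::xml_attr(chords[[1]], "d"))
  ctr <- sc$widthPx / 2
  r1 <- sqrt((nums[1] - ctr)^2 + (nums[2] - ctr)^2)
  r2 <- sqrt((nums[5] - ctr)^2 + (nums[6] - ctr)^2)
  expect_lt(abs(r1 - 150), 0.5)
  expect_lt(abs(r2 - 150), 0.5)
  # endpoint angles equal bp_to_angle
  a1 <- bp_to_angle(lay, "chr1", 250)
  expect_equal(c(nums[1], nums[2]),
               c(ctr + 150 * cos(a1), ctr + 150 * sin(a1)),
               tolerance = 0.01)
  # zero events: arcs only
  x0 <- svg_xml(render_circular(lay, list()))
  expect_length(xml2::xml_find_all(x0, "//*[contains(@class,'chord ')]"),
                0)
  expect_length(xml2::xml_find_all(x0,
                                   "//*[contains(@class,'region-arc')]"),
                2)
  evbad <- genomesketch:::sv_event("t2", "BND",
                                   list(refName = "chrZ", pos = 1),
                                   list(refName = "chr1", pos = 1))
  expect_warning(render_circular(lay, list(evbad)), "undisplayed")
})

test_that("dotplot paths are the composed axis transforms", {
  skip_if_not_installed("xml2")
  dq <- displayed_regions(list(region("q1", 0, 1000)),
                          interRegionPadding = 0)
  dt <- displayed_regions(list(region("t1", 0, 2000)),
                          interRegionPadding = 0)
  blk <- synteny_block("q1", 1000, 0, 1000, "+", "t1", 2000, 0, 2000)
  sc <- render_dotplot(list(blk), dq, dt, sizePx = c(400, 400))
  x <- svg_xml(sc)
  p <- xml2::xml_find_all(x, "//*[contains(@class,'synteny-path')]")
  expect_length(p, 1)
  nums <- path_numbers(xml2::xml_attr(p[[1]], "d"))
  # full-span + block: corner to corner, query axis inverted
  expect_equal(nums, c(0, 400, 400, 0))
  blkm <- synteny_block("q1", 1000, 0, 1000, "-", "t1", 2000, 0, 2000)
  xm <- svg_xml(render_dotplot(list(blkm), dq, dt, sizePx = c(400, 400)))
  numsm <- path_numbers(xml2::xml_attr(
    xml2::xml_find_all(xm, "//*[contains(@class,'synteny-path')]")[[1]],
    "d"))
  expect_equal(numsm, c(0, 0, 400, 400))   # anti-diagonal
  # vertex coordinates = composed transforms for a CIGAR block
  blkc <- synteny_block("q1", 1000, 0, 500, "+", "t1", 2000, 0, 700,
                        cigar = "500M200D")
  xc <- svg_xml(render_dotplot(list(blkc), dq, dt, sizePx = c(400, 400)))
  numsc <- path_numbers(xml2::xml_attr(
    xml2::xml_find_all(xc, "//*[contains(@class,'synteny-path')]")[[1]],
    "d"))
  bppT <- 2000 / 400; bppQ <- 1000 / 400
  expect_equal(numsc, c(0 / bppT, 400 - 0 / bppQ,
                        500 / bppT, 400 - 500 / bppQ,
                        700 / bppT, 400 - 500 / bppQ))
})

test_that("synteny ribbons join the transformed spans, crossed for minus", {
  skip_if_not_installed("xml2")
  top <- displayed_regions(list(region("t1", 0, 800)),
                           interRegionPadding = 0)
  bot <- displayed_regions(list(region("q1", 0, 800)),
                           interRegionPadding = 0)
  blk <- synteny_block("q1", 800, 100, 300, "+", "t1", 800, 200, 400)
  sc <- render_synteny(top, bot, list(blk), widthPx = 800)
  x <- svg_xml(sc)
  rb <- xml2::xml_find_all(x, "//*[contains(@class,'ribbon ')]")
  expect_length(rb, 1)
  nums <- path_numbers(xml2::xml_attr(rb[[1]], "d"))
  xs <- nums[c(1, 3, 5, 7)]
  expect_equal(xs, c(200, 400, 300, 100))
  blkm <- synteny_block("q1", 800, 100, 300, "-", "t1", 800, 200, 400)
  xm <- svg_xml(render_synteny(top, bot, list(blkm), widthPx = 800))
  numsm <- path_numbers(xml2::xml_attr(
    xml2::xml_find_all(xm, "//*[contains(@class,'ribbon ')]")[[1]], "d"))
  expect_equal(numsm[c(1, 3, 5, 7)], c(200, 400, 100, 300))  # crossed
  # block outside both views -> no polygon
  far <- synteny_block("qZ", 800, 0, 10, "+", "tZ", 800, 0, 10)
  x0 <- svg_xml(render_synteny(top, bot, list(far)))
  expect_length(xml2::xml_find_all(x0, "//*[contains(@class,'ribbon ')]"),
                0)
  # cigar-level mode: one polygon per match segment
  blkc <- synteny_block("q1", 800, 0, 200, "+", "t1", 800, 0, 250,
                        cigar = "100M50D100M")
  xcg <- svg_xml(render_synteny(top, bot, list(blkc), detail = "cigar"))
  expect_length(xml2::xml_find_all(xcg, "//*[@class='cigar-match']"), 2)
})

test_that("breakpoint split view draws connectors and oriented feet", {
  skip_if_not_installed("xml2")
  asm <- assembly("t", data.frame(refName = c("chr1", "chr5"),
                                  length = c(1e5, 1e5)))
  mkev <- function(js1, js2)
    genomesketch:::sv_event("e", "BND",
                            list(refName = "chr1", pos = 5000),
                            list(refName = "chr5", pos = 7000),
                            info = list(joinSide1 = js1, joinSide2 = js2))
  ev <- mkev("left_of_pos", "right_of_pos")
  panels <- breakpoint_panels(ev, 2000, asm)
  conn <- data.frame(readName = c("r1", "r2"),
                     panelA = c(1L, 1L), refPosA = c(5000, 5000),
                     refA = "chr1",
                     panelB = c(2L, 2L), refPosB = c(7000, 7000),
                     refB = "chr5", stringsAsFactors = FALSE)
  sc <- render_breakpoint_split(panels, list(list(), list()), conn, ev)
  x <- svg_xml(sc)
  curves <- xml2::xml_find_all(x, "//*[contains(@class,'connector ')]")
  expect_length(curves, 2)
  expect_length(xml2::xml_find_all(x, "//*[@class='variant variant-line']"),
                1)
  feet <- xml2::xml_find_all(x, "//*[contains(@class,'variant-foot')]")
  expect_length(feet, 2)
  footdir <- function(node) {
    as.numeric(xml2::xml_attr(node, "x2")) -
      as.numeric(xml2::xml_attr(node, "x1"))
  }
  expect_lt(footdir(feet[[1]]), 0)   # left_of_pos points left
  expect_gt(footdir(feet[[2]]), 0)   # right_of_pos points right
  # flipping joinSides flips both feet
  ev2 <- mkev("right_of_pos", "left_of_pos")
  x2 <- svg_xml(render_breakpoint_split(panels, list(list(), list()),
                                        conn[0, ], ev2))
  feet2 <- xml2::xml_find_all(x2, "//*[contains(@class,'variant-foot')]")
  expect_gt(footdir(feet2[[1]]), 0)
  expect_lt(footdir(feet2[[2]]), 0)
  expect_length(xml2::xml_find_all(x2, "//*[contains(@class,'connector ')]"),
                0)
})

test_that("ideograms draw one proportional rect per band", {
  skip_if_not_installed("xml2")
  cy <- data.frame(refName = "chr1", start = c(0, 400, 700),
                   end = c(400, 700, 1000),
                   bandName = c("p12", "p11", "q11"),
                   stain = c("gneg", "gpos50", "acen"))
  asm <- assembly("t", data.frame(refName = "chr1", length = 1000),
                  cytobands = cy)
  x <- svg_xml(render_ideogram(asm, "chr1", widthPx = 500))
  bands <- xml2::xml_find_all(x, "//*[contains(@class,'band ')]")
  expect_length(bands, 3)
  w <- as.numeric(xml2::xml_attr(bands, "width"))
  expect_equal(w, c(400, 300, 300) / 1000 * 500)
  hl <- render_ideogram(asm, "chr1", highlight = region("chr1", 100, 200))
  xh <- svg_xml(hl)
  expect_length(xml2::xml_find_all(xh, "//*[@class='ideo-highlight']"), 1)
  # no cytobands: plain outline fallback
  asm0 <- assembly("t", data.frame(refName = "chr1", length = 1000))
  x0 <- svg_xml(render_ideogram(asm0, "chr1"))
  expect_length(xml2::xml_find_all(x0, "//*[@class='ideo-outline']"), 1)
})

test_that("alignments tracks mark soft clips and large insertions", {
  skip_if_not_installed("xml2")
  d <- displayed_regions(list(region("chr1", 0, 200)))
  reads <- list(
    aligned_read("a", "chr1", 50, "10S40M", seq = strrep("A", 50)),
    aligned_read("b", "chr1", 60, "20M5I20M", seq = strrep("A", 45)))
  x <- svg_xml(render_linear(
    d, list(list(trackId = "r", type = "alignments", reads = reads,
                 minInsertionBp = 3)), bpPerPx = 1))
  expect_length(xml2::xml_find_all(x, "//*[contains(@class,'read ')]"), 2)
  expect_length(xml2::xml_find_all(x, "//*[contains(@class,'softclip ')]"),
                1)
  expect_length(xml2::xml_find_all(x, "//*[@class='insertion']"), 1)
})
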