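# -- SVG scene primitives ------------------------------------------------

# default palette; Fig-style conventions (black connectors, green variant
# call, blue soft clips, purple insertions) kept as the defaults
SVG_PALETTE <- list(
  feature = "#4a7db8", featureStroke = "#2c4a70", quant = "#808080",
  read = "#b0b0b0", readStroke = "#888888", softclip = "#3a6bc6",
  insertion = "#800080", connector = "#000000", variant = "#00a000",
  ribbon = "#9fb8d8", chord = "#d04040", arc = "#606060",
  ruler = "#404040", separator = "#c0c0c0", gridline = "#d8d8d8",
  stains = c(gneg = "#ffffff", gpos25 = "#c0c0c0", gpos50 = "#808080",
             gpos75 = "#404040", gpos100 = "#000000", acen = "#b03030",
             gvar = "#d0d0e8", stalk = "#6080a0"))

fmt_px <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

svg_el <- function(tag, ..., children = NULL) {
  attrs <- list(...)
  structure(list(tag = tag, attrs = attrs, children = children),
            class = "SvgElement")
}

svg_rect <- function(x, y, w, h, class, fill = NULL, stroke = NULL,
                     extra = list()) {
  do.call(svg_el, c(list("rect", x = fmt_px(x), y = fmt_px(y),
                         width = fmt_px(w), height = fmt_px(h),
                         class = class),
                    if (!is.null(fill)) list(fill = fill),
                    if (!is.null(stroke)) list(stroke = stroke), extra))
}

svg_line <- function(x1, y1, x2, y2, class, stroke = "#000000",
                     extra = list()) {
  do.call(svg_el, c(list("line", x1 = fmt_px(x1), y1 = fmt_px(y1),
                         x2 = fmt_px(x2), y2 = fmt_px(y2), class = class,
                         stroke = stroke), extra))
}

svg_path <- function(d, class, stroke = NULL, fill = "none",
                     extra = list()) {
  do.call(svg_el, c(list("path", d = d, class = class, fill = fill),
                    if (!is.null(stroke)) list(stroke = stroke), extra))
}

svg_text <- function(x, y, content, class, size = 9) {
  svg_el("text", x = fmt_px(x), y = fmt_px(y), class = class,
         `font-size` = fmt_px(size), `font-family` = "sans-serif",
         children = content)
}

svg_group <- function(class, children, transform = NULL) {
  do.call(svg_el, c(list("g", class = class, children = children),
                    if (!is.null(transform)) list(transform = transform)))
}

#' Create an SVG scene
#'
#' A deterministic vector-graphics document: an ordered element tree with
#' unique ids assigned depth-first at construction, so identical inputs
#' serialize to identical bytes (no timestamps, no unordered traversal).
#'
#' @param widthPx,heightPx Document size.
#' @param elements Ordered list of elements (from the internal builders).
#' @return An object of class `SvgScene`.
#' @export
svg_scene <- function(widthPx, heightPx, elements) {
  counter <- new.env()
  counter$n <- 0L
  assign_ids <- function(el) {
    counter$n <- counter$n + 1L
    el$attrs$id <- paste0("e", counter$n)
    for (a in c("x", "y", "x1", "x2", "y1", "y2", "width", "height")) {
      v <- suppressWarnings(as.numeric(el$attrs[[a]]))
      if (length(v) && !is.na(v) && !is.finite(v))
        stop("non-finite coordinate in <", el$tag, ">")
    }
    if (!is.null(el$children) && is.list(el$children))
      el$children <- lapply(el$children, assign_ids)
    el
  }
  structure(list(widthPx = widthPx, heightPx = heightPx,
                 elements = lapply(elements, assign_ids)),
            class = "SvgScene")
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

serialize_el <- function(el, indent = "  ") {
  at <- vapply(names(el$attrs), function(k)
    sprintf('%s="%s"', k, xml_escape(as.character(el$attrs[[k]]))), "")
  open <- paste0(indent, "<", el$tag,
                 if (length(at)) paste0(" ", paste(at, collapse = " ")))
  if (is.null(el$children)) return(paste0(open, "/>"))
  if (is.character(el$children))
    return(paste0(open, ">", xml_escape(el$children), "</", el$tag, ">"))
  kids <- unlist(lapply(el$children, serialize_el,
                        indent = paste0(indent, "  ")))
  c(paste0(open, ">"), kids, paste0(indent, "</", el$tag, ">"))
}

#' Serialize an SVG scene to text
#'
#' Byte-stable for equal inputs: attribute order is insertion order and
#' all numbers are formatted with a fixed rule.
#'
#' @param scene An [svg_scene()].
#' @return A single character string (the SVG 1.1 document).
#' @export
svg_serialize <- function(scene) {
  lines <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'version="1.1" width="%s" height="%s" ',
                            'viewBox="0 0 %s %s">'),
                     fmt_px(scene$widthPx), fmt_px(scene$heightPx),
                     fmt_px(scene$widthPx), fmt_px(scene$heightPx)),
             unlist(lapply(scene$elements, serialize_el)),
             "</svg>")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write an SVG scene to a file
#'
#' @param scene An [svg_scene()].
#' @param path Output `.svg` path.
#' @return `path`, invisibly.
#' @export
svg_write <- function(scene, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(svg_serialize(scene)), con)
  invisible(path)
}

# -- Linear view ---------------------------------------------------------

# continuous bp->px transform used for drawing interval edges (end
# coordinates are valid input, unlike the bp-cell transform bp_to_px)
bp_edge_px <- function(refName, coord, displayed, bpPerPx) {
  off <- 0
  pad <- displayed$interRegionPadding
  for (i in seq_along(displayed$regions)) {
    r <- displayed$regions[[i]]
    if (i > 1) off <- off + pad
    if (r$refName == refName && coord >= r$start && coord <= r$end) {
      within <- if (r$reversed) r$end - coord else coord - r$start
      return(off + within / bpPerPx)
    }
    off <- off + region_width(r) / bpPerPx
  }
  NA_real_
}

#' Major-tick step for a view width
#'
#' Largest power of ten not exceeding a fifth of the view width.
#'
#' @param viewWidthBp View width in bp.
#' @return Tick step in bp.
#' @export
tick_step <- function(viewWidthBp) {
  stopifnot(viewWidthBp > 0)
  10^max(0, floor(log10(viewWidthBp / 5)))
}

# thousands grouping with thin spaces, the ruler label convention
format_bp_label <- function(x) {
  s <- format(x, big.mark = " ", scientific = FALSE, trim = TRUE)
  s
}

ruler_elements <- function(displayed, bpPerPx, heightPx = 20) {
  els <- list()
  step <- tick_step(total_bp(displayed))
  for (r in displayed$regions) {
    first <- ceiling(r$start / step) * step
    ticks <- if (first < r$end) seq(first, r$end - 1, by = step) else numeric()
    for (tk in ticks) {
      x <- bp_edge_px(r$refName, tk, displayed, bpPerPx)
      els <- c(els, list(
        svg_line(x, heightPx - 6, x, heightPx, "ruler-tick",
                 SVG_PALETTE$ruler),
        svg_text(x + 2, heightPx - 8, format_bp_label(tk + 1),
                 "ruler-label")))
    }
  }
  els
}

separator_elements <- function(displayed, bpPerPx, heightPx) {
  els <- list()
  if (length(displayed$regions) < 2) return(els)
  off <- 0
  pad <- displayed$interRegionPadding
  for (i in seq_along(displayed$regions)) {
    r <- displayed$regions[[i]]
    if (i > 1) {
      x <- off + pad / 2
      els <- c(els, list(svg_line(x, 0, x, heightPx, "separator",
                                  SVG_PALETTE$separator)))
      off <- off + pad
    }
    off <- off + region_width(r) / bpPerPx
  }
  els
}

track_height <- function(track) {
  switch(track$type,
         feature = 40, quantitative = 40, variant = 14, reference = 14,
         alignments = {
           lay <- layout_reads(track$reads,
                               paddingBp = track$paddingBp %||% 2)
           30 + lay$rowCount * 9
         },
         20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

render_feature_track <- function(track, displayed, bpPerPx) {
  feats <- track$features
  if (!length(feats)) return(list())
  iv <- data.frame(start = vapply(feats, `[[`, 0, "start"),
                   end = vapply(feats, `[[`, 0, "end"),
                   id = vapply(feats, `[[`, "", "uniqueId"),
                   stringsAsFactors = FALSE)
  o <- order(iv$start, -iv$end, iv$id)
  lay <- assign_rows(iv[o, , drop = FALSE], paddingBp = 1)
  els <- list()
  for (f in feats) {
    x1 <- bp_edge_px(f$refName, f$start, displayed, bpPerPx)
    x2 <- bp_edge_px(f$refName, f$end, displayed, bpPerPx)
    if (is.na(x1) || is.na(x2)) next
    row <- lay$rowOf[[f$uniqueId]]
    y <- 2 + row * 13
    els <- c(els, list(svg_rect(min(x1, x2), y, abs(x2 - x1), 10,
                                paste0("feature feature-", f$type),
                                fill = SVG_PALETTE$feature,
                                stroke = SVG_PALETTE$featureStroke)))
    if (f$strand %in% c("+", "-")) {
      tipx <- if (xor(f$strand == "-", isTRUE(displayed$regions[[1]]$reversed)))
        min(x1, x2) else max(x1, x2)
      els <- c(els, list(svg_line(tipx, y, tipx, y + 10, "feature-strand",
                                  SVG_PALETTE$featureStroke)))
    }
  }
  els
}

render_quant_track <- function(track, displayed, bpPerPx, heightPx = 40) {
  sig <- track$signal
  vals <- sig$values
  if (!length(vals) || all(is.na(vals))) return(list())
  vmax <- max(vals, na.rm = TRUE)
  if (vmax <= 0) vmax <- 1
  els <- list()
  for (i in seq_along(vals)) {
    if (is.na(vals[i])) next
    s <- sig$region$start + (i - 1) * sig$binSizeBp
    e <- min(sig$region$end, s + sig$binSizeBp)
    x1 <- bp_edge_px(sig$region$refName, s, displayed, bpPerPx)
    x2 <- bp_edge_px(sig$region$refName, e, displayed, bpPerPx)
    if (is.na(x1) || is.na(x2)) next
    h <- heightPx * vals[i] / vmax
    els <- c(els, list(svg_rect(min(x1, x2), heightPx - h,
                                max(abs(x2 - x1), 0.1), h, "quant-bar",
                                fill = SVG_PALETTE$quant)))
  }
  els
}

render_alignments_track <- function(track, displayed, bpPerPx) {
  reads <- track$reads
  if (!length(reads)) return(list())
  lay <- layout_reads(reads, paddingBp = track$paddingBp %||% 2)
  covH <- 28; rowH <- 8; rowPad <- 1
  region1 <- displayed$regions[[1]]
  cov <- compute_coverage(reads, region1,
                          binSizeBp = max(1, round(bpPerPx)))
  els <- render_quant_track(list(signal = cov), displayed, bpPerPx,
                            heightPx = covH)
  minIns <- track$minInsertionBp %||% 1
  for (r in reads) {
    sp <- cigar_spans(r$cigar)
    x1 <- bp_edge_px(r$refName, r$start, displayed, bpPerPx)
    x2 <- bp_edge_px(r$refName, min(r$start + sp$refSpan,
                                    max_end(displayed, r$refName)),
                     displayed, bpPerPx)
    if (is.na(x1) || is.na(x2)) next
    y <- covH + 2 + lay$rowOf[[r$uniqueId]] * (rowH + rowPad)
    cls <- paste0("read read-", if (r$strand == "+") "fwd" else "rev")
    els <- c(els, list(svg_rect(min(x1, x2), y, max(abs(x2 - x1), 0.5),
                                rowH, cls, fill = SVG_PALETTE$read,
                                stroke = SVG_PALETTE$readStroke)))
    sc <- find_softclip_markers(r)
    for (k in seq_len(nrow(sc))) {
      x <- bp_edge_px(r$refName, sc$refPos[k], displayed, bpPerPx)
      if (!is.na(x))
        els <- c(els, list(svg_rect(x - 1, y, 2, rowH,
                                    paste0("softclip softclip-", sc$side[k]),
                                    fill = SVG_PALETTE$softclip)))
    }
    ins <- find_insertions(r, minIns)
    for (k in seq_len(nrow(ins))) {
      x <- bp_edge_px(r$refName, ins$refPos[k], displayed, bpPerPx)
      if (!is.na(x))
        els <- c(els, list(svg_rect(x - 0.75, y, 1.5, rowH, "insertion",
                                    fill = SVG_PALETTE$insertion)))
    }
  }
  els
}

max_end <- function(displayed, refName) {
  ends <- vapply(displayed$regions,
                 function(r) if (r$refName == refName) r$end else -Inf, 0)
  max(ends)
}

render_variant_track <- function(track, displayed, bpPerPx) {
  els <- list()
  for (v in track$variants) {
    x1 <- bp_edge_px(v$refName, v$start, displayed, bpPerPx)
    x2 <- bp_edge_px(v$refName, max(v$start + 1, v$end), displayed, bpPerPx)
    if (is.na(x1)) next
    if (is.na(x2)) x2 <- x1 + 1 / bpPerPx
    els <- c(els, list(svg_rect(min(x1, x2), 2, max(abs(x2 - x1), 1), 10,
                                "variant-glyph",
                                fill = SVG_PALETTE$variant)))
  }
  els
}

#' Render a Linear Genome View scene
#'
#' One group per track, in order, under a ruler with major ticks at the
#' [tick_step()] policy and vertical separators at region boundaries.
#' All x coordinates agree with the genome-model transform.
#'
#' Track descriptors are lists with a `trackId`, a `type` and the
#' prepared data: `features` (feature), `signal` (quantitative),
#' `reads` (alignments), `variants` (variant).
#'
#' @param displayed A [displayed_regions()].
#' @param tracks List of track descriptors (may be empty).
#' @param bpPerPx Zoom level; when `NULL`, derived from `widthPx`.
#' @param widthPx Used when `bpPerPx` is `NULL` (default 800).
#' @return An [svg_scene()].
#' @export
render_linear <- function(displayed, tracks = list(), bpPerPx = NULL,
                          widthPx = 800) {
  tot <- total_bp(displayed)
  if (tot <= 0) stop("zero-width view")
  n <- length(displayed$regions)
  if (is.null(bpPerPx))
    bpPerPx <- tot / max(1, widthPx - (n - 1) * displayed$interRegionPadding)
  width <- view_width_px(displayed, bpPerPx)
  rulerH <- 20
  groups <- list(svg_group("ruler",
                           ruler_elements(displayed, bpPerPx, rulerH)))
  y <- rulerH + 4
  for (tr in tracks) {
    h <- track_height(tr)
    els <- switch(tr$type,
                  feature = render_feature_track(tr, displayed, bpPerPx),
                  quantitative = render_quant_track(tr, displayed, bpPerPx),
                  alignments = render_alignments_track(tr, displayed,
                                                       bpPerPx),
                  variant = render_variant_track(tr, displayed, bpPerPx),
                  reference = list(),
                  stop("unknown track type '", tr$type, "'"))
    groups <- c(groups, list(
      svg_group(paste0("track track-", tr$type, " track-id-", tr$trackId),
                els, transform = sprintf("translate(0 %s)", fmt_px(y)))))
    y <- y + h + 4
  }
  height <- y + 2
  groups <- c(groups,
              list(svg_group("separators",
                             separator_elements(displayed, bpPerPx,
                                                height))))
  svg_scene(width, height, groups)
}

# -- Circular view -------------------------------------------------------

#' Lay regions around a circle
#'
#' Angle spans are proportional to region lengths; one `gapAngle` sits at
#' each boundary (n gaps for n regions, the last closing the circle back
#' to the first). Angles grow clockwise (SVG y grows downward) starting at
#' `rotationOffset`.
#'
#' @param regions List of [region()]s (or a [displayed_regions()]).
#' @param gapAngle Gap at each boundary, radians.
#' @param rotationOffset Start angle, radians (default `-pi/2`, 12
#'   o'clock).
#' @param radiusPx Ring radius in px.
#' @return An object of class `CircleLayout`: data frame `slices` plus
#'   `radiusPx`, `gapAngle`.
#' @export
layout_circle <- function(regions, gapAngle = 0, rotationOffset = -pi / 2,
                          radiusPx = 200) {
  if (inherits(regions, "DisplayedRegions")) regions <- regions$regions
  n <- length(regions)
  lens <- vapply(regions, region_width, 0)
  tot <- sum(lens)
  if (tot <= 0) stop("total displayed length must be > 0")
  avail <- 2 * pi - n * gapAngle
  if (avail <= 0) stop("gapAngle too large for ", n, " regions")
  spans <- avail * lens / tot
  starts <- rotationOffset + cumsum(c(0, (spans + gapAngle)[-n]))
  slices <- data.frame(
    refName = vapply(regions, `[[`, "", "refName"),
    start = vapply(regions, `[[`, 0, "start"),
    end = vapply(regions, `[[`, 0, "end"),
    angleStart = starts, angleEnd = starts + spans,
    stringsAsFactors = FALSE)
  structure(list(slices = slices, radiusPx = radiusPx,
                 gapAngle = gapAngle),
            class = "CircleLayout")
}

#' Map a genomic position to its angle on a circular layout
#'
#' @param layout A [layout_circle()].
#' @param refName,pos Position to resolve (first matching slice wins).
#' @return Angle in radians, or `NA` if not displayed.
#' @export
bp_to_angle <- function(layout, refName, pos) {
  s <- layout$slices
  for (i in seq_len(nrow(s))) {
    if (s$refName[i] == refName && pos >= s$start[i] && pos <= s$end[i]) {
      frac <- (pos - s$start[i]) / max(1, s$end[i] - s$start[i])
      return(s$angleStart[i] + frac * (s$angleEnd[i] - s$angleStart[i]))
    }
  }
  NA_real_
}

polar_xy <- function(cx, cy, r, angle) {
  c(cx + r * cos(angle), cy + r * sin(angle))
}

#' Render a Circos-style circular scene
#'
#' One arc per displayed region and one quadratic chord per SV event,
#' drawn from the angle of `end1` to the angle of `end2` with the control
#' point pulled toward the circle center (factor 0.2 of the midpoint
#' radius — an aesthetic choice, documented). Chord endpoints lie exactly
#' on the inner radius. Events touching an undisplayed sequence are
#' skipped with a warning.
#'
#' @param layout A [layout_circle()].
#' @param events List of `SVEvent`s.
#' @param bandWidth Ring thickness in px.
#' @param marginPx Outer margin.
#' @return An [svg_scene()].
#' @export
render_circular <- function(layout, events = list(), bandWidth = 12,
                            marginPx = 20) {
  R <- layout$radiusPx
  size <- 2 * (R + bandWidth + marginPx)
  cx <- size / 2; cy <- size / 2
  els <- list()
  s <- layout$slices
  for (i in seq_len(nrow(s))) {
    a1 <- s$angleStart[i]; a2 <- s$angleEnd[i]
    rm <- R + bandWidth / 2
    p1 <- polar_xy(cx, cy, rm, a1); p2 <- polar_xy(cx, cy, rm, a2)
    large <- if ((a2 - a1) > pi) 1 else 0
    d <- sprintf("M %s %s A %s %s 0 %d 1 %s %s",
                 fmt_px(p1[1]), fmt_px(p1[2]), fmt_px(rm), fmt_px(rm),
                 large, fmt_px(p2[1]), fmt_px(p2[2]))
    els <- c(els, list(svg_path(d, paste0("region-arc arc-", s$refName[i]),
                                stroke = SVG_PALETTE$arc,
                                extra = list(`stroke-width` =
                                               fmt_px(bandWidth)))))
    lp <- polar_xy(cx, cy, R + bandWidth + 10, (a1 + a2) / 2)
    els <- c(els, list(svg_text(lp[1], lp[2], s$refName[i], "arc-label")))
  }
  for (ev in events) {
    if (is.null(ev$end2)) next
    a1 <- bp_to_angle(layout, ev$end1$refName, ev$end1$pos)
    a2 <- bp_to_angle(layout, ev$end2$refName, ev$end2$pos)
    if (is.na(a1) || is.na(a2)) {
      warning("event ", ev$id, " touches an undisplayed sequence; skipped")
      next
    }
    p1 <- polar_xy(cx, cy, R, a1)
    p2 <- polar_xy(cx, cy, R, a2)
    mid <- c((p1[1] + p2[1]) / 2, (p1[2] + p2[2]) / 2)
    ctrl <- c(cx + 0.2 * (mid[1] - cx), cy + 0.2 * (mid[2] - cy))
    d <- sprintf("M %s %s Q %s %s %s %s", fmt_px(p1[1]), fmt_px(p1[2]),
                 fmt_px(ctrl[1]), fmt_px(ctrl[2]), fmt_px(p2[1]),
                 fmt_px(p2[2]))
    els <- c(els, list(svg_path(d, paste0("chord chord-", ev$kind, " ev-",
                                          ev$id),
                                stroke = SVG_PALETTE$chord)))
  }
  svg_scene(size, size, list(svg_group("circular", els)))
}

# -- Dotplot view --------------------------------------------------------

#' Render a dotplot scene
#'
#' Target assembly on the x axis, query on the y axis with the origin at
#' the bottom-left (the query axis is inverted at render time so it reads
#' bottom-up). One path per block, scaled through each axis's coordinate
#' transform; gridlines at region boundaries.
#'
#' @param blocks List of [synteny_block()]s.
#' @param qDisplayed,tDisplayed [displayed_regions()] for each axis.
#' @param sizePx `c(width, height)` in px.
#' @return An [svg_scene()].
#' @export
render_dotplot <- function(blocks, qDisplayed, tDisplayed,
                           sizePx = c(600, 600)) {
  if (total_bp(qDisplayed) <= 0 || total_bp(tDisplayed) <= 0)
    stop("empty dotplot axis")
  W <- sizePx[1]; H <- sizePx[2]
  nT <- length(tDisplayed$regions); nQ <- length(qDisplayed$regions)
  bppT <- total_bp(tDisplayed) /
    max(1, W - (nT - 1) * tDisplayed$interRegionPadding)
  bppQ <- total_bp(qDisplayed) /
    max(1, H - (nQ - 1) * qDisplayed$interRegionPadding)
  els <- list(svg_rect(0, 0, W, H, "dotplot-frame", fill = "none",
                       stroke = "#404040"))
  # gridlines at internal region boundaries
  off <- 0
  for (i in seq_along(tDisplayed$regions)) {
    if (i > 1) {
      x <- off + tDisplayed$interRegionPadding / 2
      els <- c(els, list(svg_line(x, 0, x, H, "gridline gridline-t",
                                  SVG_PALETTE$gridline)))
      off <- off + tDisplayed$interRegionPadding
    }
    off <- off + region_width(tDisplayed$regions[[i]]) / bppT
  }
  off <- 0
  for (i in seq_along(qDisplayed$regions)) {
    if (i > 1) {
      yup <- off + qDisplayed$interRegionPadding / 2
      els <- c(els, list(svg_line(0, H - yup, W, H - yup,
                                  "gridline gridline-q",
                                  SVG_PALETTE$gridline)))
      off <- off + qDisplayed$interRegionPadding
    }
    off <- off + region_width(qDisplayed$regions[[i]]) / bppQ
  }
  for (b in blocks) {
    verts <- dotplot_path(b)
    xs <- vapply(verts$t, function(t)
      bp_edge_px(b$tName, t, tDisplayed, bppT), 0)
    ys <- vapply(verts$q, function(q)
      bp_edge_px(b$qName, q, qDisplayed, bppQ), 0)
    if (anyNA(xs) || anyNA(ys)) next
    d <- paste0("M ", paste(paste(vapply(xs, fmt_px, ""),
                                  vapply(H - ys, fmt_px, "")),
                            collapse = " L "))
    els <- c(els, list(svg_path(d, paste0("synteny-path strand-",
                                          if (b$strand == "+") "fwd"
                                          else "rev"),
                                stroke = if (b$strand == "+") "#3050b0"
                                         else "#b03050")))
  }
  svg_scene(W, H, list(svg_group("dotplot", els)))
}

# -- Linear synteny view -------------------------------------------------

cigar_match_segments <- function(block) {
  verts <- dotplot_path(block)
  ops <- if (is.null(block$cigar)) data.frame(op = "M", len = 1)
         else parse_cigar(block$cigar)
  segs <- list()
  if (is.null(block$cigar)) {
    segs[[1]] <- data.frame(tStart = block$tStart, tEnd = block$tEnd,
                            qStart = block$qStart, qEnd = block$qEnd)
    return(segs[[1]])
  }
  dir <- if (block$strand == "+") 1 else -1
  t <- block$tStart
  q <- if (block$strand == "+") block$qStart else block$qEnd
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      segs[[length(segs) + 1]] <-
        data.frame(tStart = t, tEnd = t + len,
                   qStart = min(q, q + dir * len),
                   qEnd = max(q, q + dir * len))
      t <- t + len; q <- q + dir * len
    } else if (op %in% c("D", "N")) t <- t + len
    else if (op == "I") q <- q + dir * len
  }
  do.call(rbind, segs)
}

#' Render a Linear Synteny View scene
#'
#' Two linear panels stacked vertically (target on top, query below). In
#' `"ribbon"` mode each block becomes one quadrilateral joining its
#' target span on the top panel's lower edge to its query span on the
#' bottom panel's upper edge, corners crossed for `-` strand blocks. In
#' `"cigar"` mode each match segment becomes its own polygon.
#'
#' @param topDisplayed,bottomDisplayed [displayed_regions()] for the
#'   target (top) and query (bottom) panels.
#' @param blocks List of [synteny_block()]s.
#' @param detail `"ribbon"` or `"cigar"`.
#' @param widthPx Scene width.
#' @return An [svg_scene()].
#' @export
render_synteny <- function(topDisplayed, bottomDisplayed, blocks,
                           detail = c("ribbon", "cigar"), widthPx = 800) {
  detail <- match.arg(detail)
  if (total_bp(topDisplayed) <= 0 || total_bp(bottomDisplayed) <= 0)
    stop("zero-width view")
  nT <- length(topDisplayed$regions)
  nB <- length(bottomDisplayed$regions)
  bppT <- total_bp(topDisplayed) /
    max(1, widthPx - (nT - 1) * topDisplayed$interRegionPadding)
  bppB <- total_bp(bottomDisplayed) /
    max(1, widthPx - (nB - 1) * bottomDisplayed$interRegionPadding)
  rulerH <- 20; ribbonH <- 120
  yTop <- rulerH          # lower edge of top panel
  yBot <- rulerH + ribbonH  # upper edge of bottom panel
  groups <- list(
    svg_group("panel-top", ruler_elements(topDisplayed, bppT, rulerH)),
    svg_group("panel-bottom",
              ruler_elements(bottomDisplayed, bppB, rulerH),
              transform = sprintf("translate(0 %s)", fmt_px(yBot))))
  els <- list()
  for (b in blocks) {
    t1 <- bp_edge_px(b$tName, b$tStart, topDisplayed, bppT)
    t2 <- bp_edge_px(b$tName, b$tEnd, topDisplayed, bppT)
    q1 <- bp_edge_px(b$qName, b$qStart, bottomDisplayed, bppB)
    q2 <- bp_edge_px(b$qName, b$qEnd, bottomDisplayed, bppB)
    if (is.na(t1) || is.na(t2) || is.na(q1) || is.na(q2)) next
    if (detail == "ribbon") {
      corners <- if (b$strand == "+") c(t1, t2, q2, q1) else c(t1, t2, q1, q2)
      d <- sprintf("M %s %s L %s %s L %s %s L %s %s Z",
                   fmt_px(corners[1]), fmt_px(yTop),
                   fmt_px(corners[2]), fmt_px(yTop),
                   fmt_px(corners[3]), fmt_px(yBot),
                   fmt_px(corners[4]), fmt_px(yBot))
      els <- c(els, list(svg_path(d, paste0("ribbon strand-",
                                            if (b$strand == "+") "fwd"
                                            else "rev"),
                                  fill = SVG_PALETTE$ribbon,
                                  extra = list(`fill-opacity` = "0.7"))))
    } else {
      segs <- cigar_match_segments(b)
      for (k in seq_len(nrow(segs))) {
        s1 <- bp_edge_px(b$tName, segs$tStart[k], topDisplayed, bppT)
        s2 <- bp_edge_px(b$tName, segs$tEnd[k], topDisplayed, bppT)
        u1 <- bp_edge_px(b$qName, segs$qStart[k], bottomDisplayed, bppB)
        u2 <- bp_edge_px(b$qName, segs$qEnd[k], bottomDisplayed, bppB)
        if (anyNA(c(s1, s2, u1, u2))) next
        crossed <- b$strand == "-"
        cor <- if (!crossed) c(s1, s2, u2, u1) else c(s1, s2, u1, u2)
        d <- sprintf("M %s %s L %s %s L %s %s L %s %s Z",
                     fmt_px(cor[1]), fmt_px(yTop), fmt_px(cor[2]),
                     fmt_px(yTop), fmt_px(cor[3]), fmt_px(yBot),
                     fmt_px(cor[4]), fmt_px(yBot))
        els <- c(els, list(svg_path(d, "cigar-match",
                                    fill = SVG_PALETTE$ribbon)))
      }
    }
  }
  groups <- append(groups, list(svg_group("ribbons", els)), after = 1)
  svg_scene(widthPx, yBot + rulerH, groups)
}

# -- Breakpoint split view -----------------------------------------------

#' Render a Breakpoint Split View scene
#'
#' Two stacked linear panels (one per event end). Split-read connectors
#' are drawn as cubic curves between their endpoint pixels; the variant
#' call itself is a distinguished (green) line between the two breakpoint
#' positions, with short perpendicular "feet" at each end pointing toward
#' the side of the breakpoint that is retained in the derived genome
#' (`left_of_pos` feet point left).
#'
#' @param panels List from [breakpoint_panels()].
#' @param tracks List of two track lists (one per panel), as for
#'   [render_linear()].
#' @param connectors Data frame from [gather_split_evidence()].
#' @param event The `SVEvent`.
#' @param widthPx Scene width.
#' @return An [svg_scene()].
#' @export
render_breakpoint_split <- function(panels, tracks, connectors, event,
                                    widthPx = 800) {
  pl <- list(panels$panelA, panels$panelB)
  scenes <- list()
  bpps <- numeric(2)
  for (i in 1:2) {
    if (is.null(pl[[i]])) next
    n <- length(pl[[i]]$regions)
    bpps[i] <- total_bp(pl[[i]]) /
      max(1, widthPx - (n - 1) * pl[[i]]$interRegionPadding)
    scenes[[i]] <- render_linear(pl[[i]],
                                 if (length(tracks) >= i) tracks[[i]]
                                 else list(),
                                 bpPerPx = bpps[i])
  }
  h1 <- scenes[[1]]$heightPx
  gap <- 60
  y2 <- h1 + gap
  groups <- list(svg_group("panel panel-1", scenes[[1]]$elements))
  if (length(scenes) > 1 && !is.null(scenes[[2]]))
    groups <- c(groups, list(
      svg_group("panel panel-2", scenes[[2]]$elements,
                transform = sprintf("translate(0 %s)", fmt_px(y2)))))
  conEls <- list()
  for (k in seq_len(nrow(connectors))) {
    cn <- connectors[k, ]
    if (is.na(cn$panelA) || is.na(cn$panelB)) next
    pA <- c(bp_edge_px(cn$refA, cn$refPosA, pl[[cn$panelA]],
                       bpps[cn$panelA]),
            if (cn$panelA == 2L) y2 else h1)
    pB <- c(bp_edge_px(cn$refB, cn$refPosB, pl[[cn$panelB]],
                       bpps[cn$panelB]),
            if (cn$panelB == 2L) y2 else h1)
    if (anyNA(c(pA, pB))) next
    pull <- 25
    d <- sprintf("M %s %s C %s %s %s %s %s %s",
                 fmt_px(pA[1]), fmt_px(pA[2]),
                 fmt_px(pA[1]), fmt_px(pA[2] + pull),
                 fmt_px(pB[1]), fmt_px(pB[2] - pull),
                 fmt_px(pB[1]), fmt_px(pB[2]))
    conEls <- c(conEls, list(svg_path(d, paste0("connector read-",
                                                cn$readName),
                                      stroke = SVG_PALETTE$connector)))
  }
  # the variant call line with orientation feet
  varEls <- list()
  if (!is.null(event$end2) && !is.null(pl[[2]])) {
    x1 <- bp_edge_px(event$end1$refName, event$end1$pos, pl[[1]], bpps[1])
    x2 <- bp_edge_px(event$end2$refName, event$end2$pos, pl[[2]], bpps[2])
    if (!anyNA(c(x1, x2))) {
      varEls <- c(varEls, list(
        svg_line(x1, h1, x2, y2, "variant variant-line",
                 SVG_PALETTE$variant,
                 extra = list(`stroke-width` = "2"))))
      foot <- 8
      js1 <- event$info$joinSide1 %||% "left_of_pos"
      js2 <- event$info$joinSide2 %||% "left_of_pos"
      dx1 <- if (js1 == "left_of_pos") -foot else foot
      dx2 <- if (js2 == "left_of_pos") -foot else foot
      varEls <- c(varEls, list(
        svg_line(x1, h1, x1 + dx1, h1,
                 paste0("variant-foot foot-", js1), SVG_PALETTE$variant,
                 extra = list(`stroke-width` = "2")),
        svg_line(x2, y2, x2 + dx2, y2,
                 paste0("variant-foot foot-", js2), SVG_PALETTE$variant,
                 extra = list(`stroke-width` = "2"))))
    }
  }
  groups <- c(groups, list(svg_group("connectors", conEls)),
              list(svg_group("variant-call", varEls)))
  h2 <- if (length(scenes) > 1 && !is.null(scenes[[2]]))
    scenes[[2]]$heightPx else 0
  svg_scene(widthPx, y2 + h2 + 10, groups)
}

# -- Ideogram ------------------------------------------------------------

#' Render a chromosome ideogram fragment
#'
#' One rect per cytoband, filled by stain class, with the optional
#' highlight drawn on top. Assemblies without cytobands fall back to a
#' plain outline ruler.
#'
#' @param assembly An [assembly()].
#' @param refName Chromosome to draw.
#' @param highlight Optional [region()] to mark.
#' @param widthPx,heightPx Fragment size.
#' @return An [svg_scene()].
#' @export
render_ideogram <- function(assembly, refName, highlight = NULL,
                            widthPx = 600, heightPx = 14) {
  refName <- canonical_refname(refName, assembly)
  len <- seq_length(assembly, refName)
  scale <- widthPx / len
  els <- list()
  bands <- assembly$cytobands
  if (!is.null(bands)) bands <- bands[bands$refName == refName, ,
                                      drop = FALSE]
  if (is.null(bands) || !nrow(bands)) {
    els <- c(els, list(svg_rect(0, 0, widthPx, heightPx, "ideo-outline",
                                fill = "none", stroke = "#404040")))
    step <- tick_step(len)
    for (tk in seq(0, len - 1, by = step))
      els <- c(els, list(svg_line(tk * scale, heightPx - 4, tk * scale,
                                  heightPx, "ideo-tick", "#404040")))
  } else {
    for (i in seq_len(nrow(bands))) {
      fill <- unname(SVG_PALETTE$stains[bands$stain[i]])
      if (is.na(fill)) fill <- "#e0e0e0"
      els <- c(els, list(
        svg_rect(bands$start[i] * scale, 0,
                 (bands$end[i] - bands$start[i]) * scale, heightPx,
                 paste0("band stain-", bands$stain[i]), fill = fill,
                 stroke = "#404040")))
    }
  }
  if (!is.null(highlight) && highlight$refName == refName)
    els <- c(els, list(svg_rect(highlight$start * scale, -2,
                                (highlight$end - highlight$start) * scale,
                                heightPx + 4, "ideo-highlight",
                                fill = "#ff000040", stroke = "#ff0000")))
  svg_scene(widthPx, heightPx + 4, list(svg_group("ideogram", els)))
}
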