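# -- Aligned reads -------------------------------------------------------

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")   # consume query
REF_OPS <- c("M", "D", "N", "=", "X")     # consume reference
DEPTH_OPS <- c("M", "=", "X")             # add pileup depth

#' Create an aligned read
#'
#' @param name Read (QNAME) name.
#' @param refName Reference sequence name.
#' @param start 0-based leftmost reference position.
#' @param cigar CIGAR string.
#' @param strand `"+"` or `"-"` (redundant with flag 0x10, kept explicit).
#' @param flags SAM flag bitfield.
#' @param mapq Mapping quality.
#' @param seq Read sequence as stored (reverse-complemented for `-`
#'   alignments, per SAM), or `NA` when absent (`*`).
#' @param quals Base qualities (character, as in SAM), or `NA`.
#' @param tags Named list of tag values (notably `SA`, `MM`, `ML`, `HP`).
#' @param mate Optional list `(refName, pos, reversed)` for paired reads.
#' @param uniqueId Identifier unique within a load; defaults to
#'   `name/start/cigar`.
#' @return An object of class `AlignedRead`.
#' @export
aligned_read <- function(name, refName, start, cigar, strand = "+",
                         flags = 0L, mapq = 60L, seq = NA_character_,
                         quals = NA_character_, tags = list(), mate = NULL,
                         uniqueId = NULL) {
  ops <- parse_cigar(cigar)
  if (!is.na(seq) && seq != "*") {
    qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
    if (qlen != nchar(seq))
      stop("read ", name, ": CIGAR consumes ", qlen,
           " query bases but SEQ has ", nchar(seq))
  }
  if (is.null(uniqueId)) uniqueId <- paste(name, refName, start, cigar,
                                           sep = "/")
  structure(list(name = name, refName = refName, start = as.numeric(start),
                 cigar = cigar, strand = strand, flags = as.integer(flags),
                 mapq = as.integer(mapq), seq = seq, quals = quals,
                 tags = tags, mate = mate, uniqueId = uniqueId),
            class = "AlignedRead")
}

#' Parse a CIGAR string into an op/length table
#'
#' @param cigar CIGAR string (`"*"` allowed, giving zero rows).
#' @return Data frame with columns `op` (character) and `len` (numeric).
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    return(data.frame(op = character(), len = numeric()))
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("invalid CIGAR '", cigar, "'")
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.numeric(substr(toks, 1, nchar(toks) - 1)),
             stringsAsFactors = FALSE)
}

format_cigar <- function(ops) {
  if (!nrow(ops)) return("*")
  paste0(ops$len, ops$op, collapse = "")
}

#' Reference/query consumption of a CIGAR
#'
#' Applies the SAM consumption rules: `M/D/N/=/X` advance the reference,
#' `M/I/S/=/X` advance the query; `H` counts only into the clipped lengths.
#'
#' @param cigar CIGAR string or parsed op table.
#' @return List with `refSpan`, `querySpan` (stored-sequence length,
#'   soft clips included), `clippedPrefix`, `clippedSuffix` (S and H both
#'   counted).
#' @export
cigar_spans <- function(cigar) {
  ops <- if (is.data.frame(cigar)) cigar else parse_cigar(cigar)
  n <- nrow(ops)
  pre <- 0; i <- 1
  while (i <= n && ops$op[i] %in% c("S", "H")) {
    pre <- pre + ops$len[i]; i <- i + 1
  }
  suf <- 0; j <- n
  while (j >= i && ops$op[j] %in% c("S", "H")) {
    suf <- suf + ops$len[j]; j <- j - 1
  }
  list(refSpan = sum(ops$len[ops$op %in% REF_OPS]),
       querySpan = sum(ops$len[ops$op %in% QUERY_OPS]),
       clippedPrefix = pre, clippedSuffix = suf)
}

# -- Pileup layout -------------------------------------------------------

#' Greedy first-fit pileup row assignment
#'
#' Stacks intervals (reads) into rows such that no two intervals in a row
#' overlap after padding. Intervals must arrive sorted by ascending start
#' (ties: longer first, then id); each takes the lowest row whose last
#' occupied end plus `paddingBp` does not exceed its start. For interval
#' graphs this left-endpoint greedy is optimal: `rowCount` equals the
#' maximum overlap depth.
#'
#' @param intervals Data frame with columns `start`, `end` (bp) and
#'   optionally `id`.
#' @param paddingBp Minimum bp gap between same-row neighbours.
#' @return An object of class `PileupLayout`: list with `rowOf` (named
#'   integer vector, 0-based row per id), `rowCount`, `paddingBp`.
#' @export
assign_rows <- function(intervals, paddingBp = 0) {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in%
                                            names(intervals)))
  n <- nrow(intervals)
  ids <- if ("id" %in% names(intervals)) as.character(intervals$id)
         else as.character(seq_len(n))
  if (n > 1) {
    s <- intervals$start; e <- intervals$end
    ok <- s[-1] > s[-n] |
      (s[-1] == s[-n] & (e[-1] < e[-n] |
                           (e[-1] == e[-n] & ids[-1] >= ids[-n])))
    if (!all(ok))
      stop("assign_rows: intervals not sorted (ascending start, ",
           "ties longer first then id); first violation at row ",
           which(!ok)[1] + 1)
  }
  rowEnd <- numeric(0)        # last occupied end per row
  rowOf <- integer(n)
  for (i in seq_len(n)) {
    fit <- which(rowEnd + paddingBp <= intervals$start[i])
    if (length(fit)) {
      r <- fit[1]
    } else {
      rowEnd <- c(rowEnd, -Inf)
      r <- length(rowEnd)
    }
    rowEnd[r] <- intervals$end[i]
    rowOf[i] <- r - 1L
  }
  structure(list(rowOf = stats::setNames(rowOf, ids),
                 rowCount = length(rowEnd), paddingBp = paddingBp),
            class = "PileupLayout")
}

#' Layout a list of reads into pileup rows
#'
#' Sorts reads by padded extent (soft clips included, so clipped reads do
#' not visually collide) and delegates to [assign_rows()].
#'
#' @param reads List of [aligned_read()]s.
#' @param paddingBp Same-row gap in bp.
#' @param includeClips Extend each read's interval by its soft-clip
#'   lengths (default `TRUE`).
#' @return A `PileupLayout` whose `rowOf` is keyed by read `uniqueId`.
#' @export
layout_reads <- function(reads, paddingBp = 2, includeClips = TRUE) {
  iv <- do.call(rbind, lapply(reads, function(r) {
    sp <- cigar_spans(r$cigar)
    s <- r$start; e <- r$start + sp$refSpan
    if (includeClips) { s <- s - sp$clippedPrefix; e <- e + sp$clippedSuffix }
    data.frame(start = s, end = e, id = r$uniqueId,
               stringsAsFactors = FALSE)
  }))
  if (is.null(iv)) return(assign_rows(data.frame(start = numeric(),
                                                 end = numeric())))
  o <- order(iv$start, -iv$end, iv$id)
  assign_rows(iv[o, , drop = FALSE], paddingBp)
}

#' Binned read-depth coverage
#'
#' Counts, per base, the reads whose reference-consuming aligned ops
#' (`M/=/X`) cover it — deletions and introns (`D/N`) do not add depth —
#' then averages per bin.
#'
#' @param reads List of [aligned_read()]s.
#' @param region A [region()].
#' @param binSizeBp Bin width in bp.
#' @return A [quant_signal()]; uncovered bins are 0.
#' @export
compute_coverage <- function(reads, region, binSizeBp = 1) {
  depth <- numeric(region_width(region))
  for (r in reads) {
    if (r$refName != region$refName) next
    pos <- r$start
    ops <- parse_cigar(r$cigar)
    for (i in seq_len(nrow(ops))) {
      op <- ops$op[i]; len <- ops$len[i]
      if (op %in% DEPTH_OPS) {
        s <- max(pos, region$start); e <- min(pos + len, region$end)
        if (s < e) {
          i1 <- s - region$start + 1; i2 <- e - region$start
          depth[i1:i2] <- depth[i1:i2] + 1
        }
      }
      if (op %in% REF_OPS) pos <- pos + len
    }
  }
  quant_signal(region, binSizeBp, bin_means(depth, binSizeBp))
}

# -- Read markup ---------------------------------------------------------

#' Soft-clip markers of a read
#'
#' Soft-clipped blocks are the visual signature of insertions and
#' breakpoints: the left clip anchors at the read's start, the right clip
#' at `start + refSpan`.
#'
#' @param read An [aligned_read()].
#' @return Data frame with columns `refPos`, `clipLen`, `side`.
#' @export
find_softclip_markers <- function(read) {
  ops <- parse_cigar(read$cigar)
  sp <- cigar_spans(ops)
  out <- data.frame(refPos = numeric(), clipLen = numeric(),
                    side = character(), stringsAsFactors = FALSE)
  aligned <- which(!ops$op %in% c("S", "H"))
  if (!length(aligned)) return(out)
  lead <- sum(ops$len[ops$op == "S" & seq_len(nrow(ops)) < min(aligned)])
  trail <- sum(ops$len[ops$op == "S" & seq_len(nrow(ops)) > max(aligned)])
  if (lead > 0)
    out <- rbind(out, data.frame(refPos = read$start, clipLen = lead,
                                 side = "left"))
  if (trail > 0)
    out <- rbind(out, data.frame(refPos = read$start + sp$refSpan,
                                 clipLen = trail, side = "right"))
  out
}

#' Insertions of at least a minimum length
#'
#' @param read An [aligned_read()].
#' @param minLenBp Minimum insertion length to report.
#' @return Data frame with columns `refPos` (position between the flanking
#'   aligned bases) and `insLen`.
#' @export
find_insertions <- function(read, minLenBp = 1) {
  ops <- parse_cigar(read$cigar)
  pos <- read$start
  out <- data.frame(refPos = numeric(), insLen = numeric())
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] == "I" && ops$len[i] >= minLenBp)
      out <- rbind(out, data.frame(refPos = pos, insLen = ops$len[i]))
    if (ops$op[i] %in% REF_OPS) pos <- pos + ops$len[i]
  }
  out
}

#' Decompose an alignment into match/insertion/deletion segments
#'
#' The read-vs-reference path drawn by the dotplot and synteny "read vs
#' ref" modes: match segments advance both axes, insertions the query
#' only, deletions the reference only. Query coordinates are on the stored
#' sequence (soft clips skipped).
#'
#' @param read An [aligned_read()].
#' @return Data frame with columns `qStart`, `qEnd`, `rStart`, `rEnd`,
#'   `kind` (`match`/`ins`/`del`).
#' @export
read_to_ref_path <- function(read) {
  ops <- parse_cigar(read$cigar)
  q <- 0; r <- read$start
  segs <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      segs[[length(segs) + 1]] <- data.frame(qStart = q, qEnd = q + len,
                                             rStart = r, rEnd = r + len,
                                             kind = "match")
      q <- q + len; r <- r + len
    } else if (op == "I") {
      segs[[length(segs) + 1]] <- data.frame(qStart = q, qEnd = q + len,
                                             rStart = r, rEnd = r,
                                             kind = "ins")
      q <- q + len
    } else if (op %in% c("D", "N")) {
      segs[[length(segs) + 1]] <- data.frame(qStart = q, qEnd = q,
                                             rStart = r, rEnd = r + len,
                                             kind = "del")
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  if (!length(segs))
    return(data.frame(qStart = numeric(), qEnd = numeric(),
                      rStart = numeric(), rEnd = numeric(),
                      kind = character()))
  do.call(rbind, segs)
}

#' Span of an alignment on the original full-length read
#'
#' Positions the aligned block on the as-sequenced read so that split-read
#' segments can be ordered by their query position. Both soft and hard
#' clips count toward the clip lengths; for a reverse-strand alignment the
#' clip roles swap.
#'
#' @param read An [aligned_read()].
#' @return Numeric vector `c(qStart, qEnd)`, 0-based half-open on the
#'   original read.
#' @export
query_span_on_read <- function(read) {
  sp <- cigar_spans(read$cigar)
  readLen <- sp$querySpan + sp$clippedPrefix + sp$clippedSuffix -
    soft_in_clips(read$cigar)
  if (read$strand == "+")
    c(sp$clippedPrefix, readLen - sp$clippedSuffix)
  else
    c(sp$clippedSuffix, readLen - sp$clippedPrefix)
}

# soft-clip bases appear in both querySpan and the clip totals; remove the
# double count when deriving the full read length
soft_in_clips <- function(cigar) {
  ops <- parse_cigar(cigar)
  n <- nrow(ops)
  tot <- 0; i <- 1
  while (i <= n && ops$op[i] %in% c("S", "H")) {
    if (ops$op[i] == "S") tot <- tot + ops$len[i]
    i <- i + 1
  }
  j <- n
  while (j >= i && ops$op[j] %in% c("S", "H")) {
    if (ops$op[j] == "S") tot <- tot + ops$len[j]
    j <- j - 1
  }
  tot
}

# -- Base modifications (MM/ML) ------------------------------------------

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                    a = "t", c = "g", g = "c", t = "a", n = "n")

revcomp_chr <- function(s) {
  paste(rev(DNA_COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]),
        collapse = "")
}

parse_mm_tag <- function(mm) {
  mm <- sub(";\\s*$", "", mm)
  groups <- strsplit(mm, ";", fixed = TRUE)[[1]]
  lapply(groups[nzchar(groups)], function(g) {
    m <- regexec("^([ACGTUN])([-+])([a-z]+|[0-9]+)([.?]?)((,[0-9]+)*)$", g)
    p <- regmatches(g, m)[[1]]
    if (!length(p)) stop("malformed MM group '", g, "'")
    deltas <- if (nzchar(p[6]))
      as.integer(strsplit(sub("^,", "", p[6]), ",", fixed = TRUE)[[1]])
    else integer()
    list(base = p[2], mmStrand = p[3], codes = p[4], flag = p[5],
         deltas = deltas)
  })
}

#' Decode MM/ML base-modification tags
#'
#' Walks the MM delta encoding per the SAM tags specification: within each
#' `base+code,counts` group, skip `count` occurrences of the base then
#' mark the next. Occurrences are counted along the original read as
#' sequenced, so for a reverse-strand alignment the walk runs from the
#' stored sequence's 3' end over the complement base. ML bytes map to
#' likelihood `(v + 0.5)/256`.
#'
#' @param read An [aligned_read()] whose tags include `MM` (and optionally
#'   `ML`, an integer vector).
#' @return Data frame of modification calls: `readPos` (0-based on the
#'   stored sequence), `canonicalBase`, `modCode`, `likelihood` (`NA`
#'   when ML absent).
#' @export
decode_modifications <- function(read) {
  mm <- read$tags$MM
  if (is.null(mm)) stop("read ", read$name, " has no MM tag")
  if (is.na(read$seq) || read$seq == "*")
    stop("read ", read$name, ": MM decoding requires SEQ")
  ml <- read$tags$ML
  groups <- parse_mm_tag(mm)
  seqChars <- strsplit(read$seq, "", fixed = TRUE)[[1]]
  reverse <- read$strand == "-"
  out <- list(); mli <- 0L
  for (g in groups) {
    # positions of the canonical base along the original read, expressed
    # as stored-sequence indices
    if (!reverse) {
      occ <- which(seqChars == g$base)
    } else {
      occ <- rev(which(seqChars == DNA_COMPLEMENT[[g$base]]))
    }
    codes <- strsplit(g$codes, "", fixed = TRUE)[[1]]
    if (grepl("^[0-9]+$", g$codes)) codes <- g$codes   # numeric ChEBI code
    cursor <- 0L
    for (d in g$deltas) {
      cursor <- cursor + d + 1L
      if (cursor > length(occ))
        stop("malformed MM tag on read ", read$name, ": group ", g$base,
             g$mmStrand, g$codes, " skips past the last ", g$base)
      pos <- occ[cursor] - 1L
      for (code in codes) {
        mli <- mli + 1L
        lik <- if (!is.null(ml)) {
          if (mli > length(ml))
            stop("ML tag shorter than MM calls on read ", read$name)
          (ml[mli] + 0.5) / 256
        } else NA_real_
        out[[length(out) + 1]] <- data.frame(readPos = pos,
                                             canonicalBase = g$base,
                                             modCode = code,
                                             likelihood = lik,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(readPos = integer(), canonicalBase = character(),
                      modCode = character(), likelihood = numeric()))
  do.call(rbind, out)
}

#' Re-encode modification calls into an MM (+ML) tag
#'
#' Inverse of [decode_modifications()]; groups calls by canonical base and
#' modification code in order of first appearance.
#'
#' @param read The [aligned_read()] the calls belong to.
#' @param calls Data frame from [decode_modifications()].
#' @return List with `MM` (string) and `ML` (integer vector or `NULL`).
#' @export
encode_modifications <- function(read, calls) {
  seqChars <- strsplit(read$seq, "", fixed = TRUE)[[1]]
  reverse <- read$strand == "-"
  key <- paste0(calls$canonicalBase, "+", calls$modCode)
  mm <- character(); ml <- integer()
  for (k in unique(key)) {
    sub <- calls[key == k, , drop = FALSE]
    base <- sub$canonicalBase[1]
    occ <- if (!reverse) which(seqChars == base)
           else rev(which(seqChars == DNA_COMPLEMENT[[base]]))
    idx <- match(sub$readPos + 1L, occ)
    if (anyNA(idx)) stop("call position not on canonical base")
    idx <- sort(idx)
    deltas <- diff(c(0L, idx)) - 1L
    mm <- c(mm, paste0(base, "+", sub$modCode[1], ",",
                       paste(deltas, collapse = ","), ";"))
    if (!all(is.na(sub$likelihood)))
      ml <- c(ml, as.integer(round(sub$likelihood[order(idx)] * 256 - 0.5)))
  }
  list(MM = paste(mm, collapse = ""), ML = if (length(ml)) ml else NULL)
}

# -- Sort / filter / color policies --------------------------------------

read_base_at <- function(read, refPos) {
  if (is.na(read$seq) || read$seq == "*") return(NA_character_)
  ops <- parse_cigar(read$cigar)
  q <- 0; r <- read$start
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (refPos >= r && refPos < r + len) {
        b <- substr(read$seq, q + (refPos - r) + 1, q + (refPos - r) + 1)
        return(if (op == "=") "ref" else toupper(b))
      }
      q <- q + len; r <- r + len
    } else if (op %in% c("D", "N")) {
      if (refPos >= r && refPos < r + len) return("del")
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    }
  }
  NA_character_
}

#' Filter, sort and color a set of reads
#'
#' The alignments-track policy engine. Filters by flag masks, minimum
#' MAPQ, or tag equality; sorts (stably) by start, by the observed base at
#' a position (order A, C, G, T, deletion, reference match), or by a tag
#' value; assigns a color class by strand, MAPQ band, insert-size band,
#' tag value, or presence of base modifications.
#'
#' @param reads List of [aligned_read()]s.
#' @param filterSpec Optional list with any of `flagsExclude`,
#'   `flagsRequire` (bit masks), `minMapq`, `tag` (list `name`, `value`).
#' @param sortSpec Optional list with `by` in `"start"`, `"base"`, `"tag"`
#'   plus `tag` name for the latter; base sorting uses `at`.
#' @param colorSpec Optional list with `by` in `"strand"`, `"mapq"`,
#'   `"insertSize"`, `"tag"`, `"modification"`, plus `tag` name and
#'   optional `insertLimits = c(lo, hi)` (defaults: sample median TLEN
#'   +/- 3 sd of the loaded reads).
#' @param at Optional reference bp for base-at-position sorting.
#' @return Data frame with columns `uniqueId`, `colorClass` and the order
#'   of the surviving reads; the reads themselves in `attr(, "reads")`.
#' @export
apply_read_policies <- function(reads, filterSpec = NULL, sortSpec = NULL,
                                colorSpec = NULL, at = NULL) {
  keep <- rep(TRUE, length(reads))
  if (!is.null(filterSpec)) {
    bad <- setdiff(names(filterSpec),
                   c("flagsExclude", "flagsRequire", "minMapq", "tag"))
    if (length(bad)) stop("unknown filter policy: ", paste(bad, collapse = ","))
    for (i in seq_along(reads)) {
      r <- reads[[i]]
      if (!is.null(filterSpec$flagsExclude) &&
          bitwAnd(r$flags, filterSpec$flagsExclude) != 0) keep[i] <- FALSE
      if (!is.null(filterSpec$flagsRequire) &&
          bitwAnd(r$flags, filterSpec$flagsRequire) !=
            filterSpec$flagsRequire) keep[i] <- FALSE
      if (!is.null(filterSpec$minMapq) && r$mapq < filterSpec$minMapq)
        keep[i] <- FALSE
      if (!is.null(filterSpec$tag)) {
        v <- r$tags[[filterSpec$tag$name]]
        if (is.null(v) || !identical(as.character(v),
                                     as.character(filterSpec$tag$value)))
          keep[i] <- FALSE
      }
    }
  }
  reads <- reads[keep]
  ord <- seq_along(reads)
  if (!is.null(sortSpec)) {
    by <- sortSpec$by
    if (!by %in% c("start", "base", "tag"))
      stop("unknown sort policy '", by, "'")
    key <- switch(by,
      start = vapply(reads, `[[`, 0, "start"),
      base = {
        if (is.null(at)) stop("base sort needs `at`")
        levels <- c("A", "C", "G", "T", "del", "ref")
        b <- vapply(reads, read_base_at, "", at)
        match(b, levels, nomatch = length(levels) + 1L)
      },
      tag = {
        v <- lapply(reads, function(r) r$tags[[sortSpec$tag]])
        vapply(v, function(x) if (is.null(x)) Inf else as.numeric(x), 0)
      })
    ord <- order(key)            # stable in R
    reads <- reads[ord]
  }
  colorClass <- rep("default", length(reads))
  if (!is.null(colorSpec)) {
    by <- colorSpec$by
    if (!by %in% c("strand", "mapq", "insertSize", "tag", "modification"))
      stop("unknown color policy '", by, "'")
    colorClass <- vapply(reads, function(r) switch(by,
      strand = if (r$strand == "+") "strand_forward" else "strand_reverse",
      mapq = {
        q <- r$mapq
        if (q == 0) "mapq_0" else if (q < 10) "mapq_1_9"
        else if (q < 30) "mapq_10_29" else if (q < 60) "mapq_30_59"
        else "mapq_60plus"
      },
      insertSize = {
        lim <- colorSpec$insertLimits
        if (is.null(lim)) lim <- insert_size_limits(reads)
        tl <- abs(if (is.null(r$tags$TLEN)) NA_real_
                  else as.numeric(r$tags$TLEN))
        if (is.na(tl)) "insert_unknown"
        else if (tl < lim[1]) "insert_short"
        else if (tl > lim[2]) "insert_long" else "insert_normal"
      },
      tag = {
        v <- r$tags[[colorSpec$tag]]
        if (is.null(v)) "tag_missing" else paste0("tag_", v)
      },
      modification = if (!is.null(r$tags$MM)) "mod_present" else "mod_none"),
      "")
  }
  out <- data.frame(uniqueId = vapply(reads, `[[`, "", "uniqueId"),
                    colorClass = colorClass, stringsAsFactors = FALSE)
  attr(out, "reads") <- reads
  out
}

#' Default insert-size color band limits
#'
#' Median absolute TLEN of the loaded reads +/- 3 standard deviations,
#' the package default where the upstream behavior names the feature but
#' not the rule.
#'
#' @param reads List of [aligned_read()]s carrying `TLEN` tags.
#' @return Numeric `c(lo, hi)`.
#' @export
insert_size_limits <- function(reads) {
  tl <- abs(vapply(reads, function(r)
    if (is.null(r$tags$TLEN)) NA_real_ else as.numeric(r$tags$TLEN), 0))
  tl <- tl[!is.na(tl) & tl > 0]
  if (!length(tl)) return(c(0, Inf))
  c(max(0, stats::median(tl) - 3 * stats::sd(tl)),
    stats::median(tl) + 3 * stats::sd(tl))
}

# -- SAM/BAM I/O ---------------------------------------------------------

parse_sam_tag <- function(tok) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  name <- parts[1]; type <- parts[2]
  val <- paste(parts[-(1:2)], collapse = ":")
  v <- switch(type,
              i = as.integer(val), f = as.numeric(val),
              B = {
                xs <- strsplit(val, ",", fixed = TRUE)[[1]]
                as.numeric(xs[-1])
              },
              val)
  stats::setNames(list(v), name)
}

parse_sam_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11) stop("SAM record with fewer than 11 fields")
  flags <- as.integer(f[2])
  tags <- list()
  if (length(f) > 11)
    for (tok in f[12:length(f)]) tags <- c(tags, parse_sam_tag(tok))
  if (!is.null(tags$TLEN)) tags$TLEN <- NULL
  tags$TLEN <- as.numeric(f[9])
  mate <- NULL
  if (bitwAnd(flags, 0x1) && f[7] != "*")
    mate <- list(refName = if (f[7] == "=") f[3] else f[7],
                 pos = as.numeric(f[8]) - 1,
                 reversed = bitwAnd(flags, 0x20) != 0)
  aligned_read(f[1], f[3], as.numeric(f[4]) - 1, f[6],
               strand = if (bitwAnd(flags, 0x10)) "-" else "+",
               flags = flags, mapq = as.integer(f[5]),
               seq = if (f[10] == "*") NA_character_ else f[10],
               quals = if (f[11] == "*") NA_character_ else f[11],
               tags = tags, mate = mate)
}

#' Read alignments from a SAM or BAM file
#'
#' SAM text is parsed directly (the fixture path); BAM goes through
#' [Rsamtools::scanBam()], with `SA`/`MM`/`ML`/`HP`/`NM` tags retained.
#'
#' @param path `.sam` or `.bam` path.
#' @param region Optional [region()]; for BAM an index is used, for SAM
#'   records are scanned and filtered by reference span overlap.
#' @return List of [aligned_read()]s.
#' @export
read_alignments <- function(path, region = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE))
    return(read_bam(path, region))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  reads <- lapply(lines, parse_sam_line)
  if (!is.null(region)) {
    keep <- vapply(reads, function(r) {
      sp <- cigar_spans(r$cigar)
      r$refName == region$refName &&
        overlaps_region(r$start, r$start + sp$refSpan, region)
    }, TRUE)
    reads <- reads[keep]
  }
  reads
}

read_bam <- function(path, region = NULL) {
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
            "mpos", "isize", "seq", "qual")
  param <- Rsamtools::ScanBamParam(
    what = what, tag = c("SA", "MM", "ML", "HP", "NM"),
    which = if (is.null(region)) GenomicRanges::GRanges() else
      GenomicRanges::GRanges(region$refName,
                             IRanges::IRanges(region$start + 1, region$end)),
    flag = Rsamtools::scanBamFlag())
  if (is.null(region))
    param <- Rsamtools::ScanBamParam(what = what,
                                     tag = c("SA", "MM", "ML", "HP", "NM"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(res$qname)
  lapply(seq_len(n), function(i) {
    tags <- list()
    for (tg in names(res$tag)) {
      v <- res$tag[[tg]][[i]]
      if (!is.null(v) && !all(is.na(v))) tags[[tg]] <- v
    }
    tags$TLEN <- res$isize[i]
    flags <- res$flag[i]
    mate <- NULL
    if (!is.na(res$mrnm[i]) && bitwAnd(flags, 0x1))
      mate <- list(refName = as.character(res$mrnm[i]),
                   pos = res$mpos[i] - 1,
                   reversed = bitwAnd(flags, 0x20) != 0)
    aligned_read(res$qname[i], as.character(res$rname[i]), res$pos[i] - 1,
                 res$cigar[i],
                 strand = if (bitwAnd(flags, 0x10)) "-" else "+",
                 flags = flags, mapq = res$mapq[i],
                 seq = as.character(res$seq[i]),
                 quals = as.character(res$qual[i]), tags = tags,
                 mate = mate)
  })
}

#' Write reads as SAM text
#'
#' @param reads List of [aligned_read()]s.
#' @param path Output `.sam` path.
#' @param assembly Optional [assembly()] for `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, assembly = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  if (!is.null(assembly))
    for (i in seq_len(nrow(assembly$sequences)))
      writeLines(sprintf("@SQ\tSN:%s\tLN:%d", assembly$sequences$refName[i],
                         as.integer(assembly$sequences$length[i])), con)
  fmt_tag <- function(name, v) {
    if (name == "TLEN") return(NULL)
    if (is.integer(v) && length(v) == 1) return(sprintf("%s:i:%d", name, v))
    if (is.numeric(v) && length(v) > 1)
      return(paste0(name, ":B:C,", paste(as.integer(v), collapse = ",")))
    if (is.numeric(v)) return(sprintf("%s:i:%d", name, as.integer(v)))
    sprintf("%s:Z:%s", name, as.character(v))
  }
  for (r in reads) {
    tags <- unlist(lapply(names(r$tags), function(n) fmt_tag(n, r$tags[[n]])))
    tlen <- if (!is.null(r$tags$TLEN)) as.integer(r$tags$TLEN) else 0L
    mrnm <- "*"; mpos <- 0L
    if (!is.null(r$mate)) {
      mrnm <- if (r$mate$refName == r$refName) "=" else r$mate$refName
      mpos <- as.integer(r$mate$pos + 1)
    }
    writeLines(paste(c(r$name, r$flags, r$refName, format(r$start + 1,
                                                          scientific = FALSE),
                       r$mapq, r$cigar, mrnm, mpos, tlen,
                       if (is.na(r$seq)) "*" else r$seq,
                       if (is.na(r$quals)) "*" else r$quals, tags),
                     collapse = "\t"), con)
  }
  invisible(path)
}
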