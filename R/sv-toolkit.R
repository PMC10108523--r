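# -- Breakends -----------------------------------------------------------

#' Parse a VCF breakend ALT allele
#'
#' Handles the four bracket forms of the VCF 4.2 breakend grammar —
#' `t[p[`, `t]p]`, `]p]t`, `[p[t` — mapping bracket orientation and the
#' side of `t` to which side of each position is retained in the novel
#' adjacency:
#'
#' * `t[p[` — current keeps the piece left of (and including) `pos`,
#'   joined to the piece extending right of the mate.
#' * `t]p]` — current keeps left of `pos`, mate keeps left of its pos.
#' * `]p]t` — current keeps right of `pos`, mate keeps left.
#' * `[p[t` — current keeps right of `pos`, mate keeps right.
#'
#' `insertedSeq` is `t` minus the anchoring reference base.
#'
#' @param altText The ALT string.
#' @param chrom,pos The record's CHROM and 1-based POS.
#' @param mateId Optional INFO `MATEID`.
#' @return An object of class `Breakend` with fields `chrom`, `pos`
#'   (1-based, VCF-facing), `anchorBase`, `insertedSeq`, `mateChrom`,
#'   `matePos`, `joinSide`, `mateJoinSide`, `mateId`.
#' @export
parse_breakend_alt <- function(altText, chrom, pos, mateId = NULL) {
  pat_t_first <- "^([A-Za-z.*]+)(\\[|\\])([^:\\[\\]]+):([0-9]+)(\\[|\\])$"
  pat_t_last <- "^(\\[|\\])([^:\\[\\]]+):([0-9]+)(\\[|\\])([A-Za-z.*]+)$"
  m1 <- regmatches(altText, regexec(pat_t_first, altText, perl = TRUE))[[1]]
  m2 <- regmatches(altText, regexec(pat_t_last, altText, perl = TRUE))[[1]]
  if (length(m1)) {
    t <- m1[2]; br <- m1[3]; mateChrom <- m1[4]; matePos <- as.numeric(m1[5])
    if (m1[6] != br) stop("mismatched brackets in breakend ALT '",
                          altText, "'")
    joinSide <- "left_of_pos"
    mateJoinSide <- if (br == "[") "right_of_pos" else "left_of_pos"
    anchor <- substr(t, 1, 1)
    ins <- substr(t, 2, nchar(t))
  } else if (length(m2)) {
    br <- m2[2]; mateChrom <- m2[3]; matePos <- as.numeric(m2[4]); t <- m2[6]
    if (m2[5] != br) stop("mismatched brackets in breakend ALT '",
                          altText, "'")
    joinSide <- "right_of_pos"
    mateJoinSide <- if (br == "[") "right_of_pos" else "left_of_pos"
    anchor <- substr(t, nchar(t), nchar(t))
    ins <- substr(t, 1, nchar(t) - 1)
  } else {
    stop("ALT '", altText, "' is not a breakend")
  }
  structure(list(chrom = chrom, pos = as.numeric(pos), anchorBase = anchor,
                 insertedSeq = ins, mateChrom = mateChrom, matePos = matePos,
                 joinSide = joinSide, mateJoinSide = mateJoinSide,
                 mateId = mateId),
            class = "Breakend")
}

#' Format a breakend back into its ALT string
#'
#' Exact inverse of [parse_breakend_alt()]:
#' `format_breakend(parse_breakend_alt(x, ...)) == x`.
#'
#' @param bnd A `Breakend`.
#' @return The ALT string.
#' @export
format_breakend <- function(bnd) {
  p <- paste0(bnd$mateChrom, ":", format(bnd$matePos, scientific = FALSE))
  if (bnd$joinSide == "left_of_pos") {
    t <- paste0(bnd$anchorBase, bnd$insertedSeq)
    if (bnd$mateJoinSide == "right_of_pos") paste0(t, "[", p, "[")
    else paste0(t, "]", p, "]")
  } else {
    t <- paste0(bnd$insertedSeq, bnd$anchorBase)
    if (bnd$mateJoinSide == "left_of_pos") paste0("]", p, "]", t)
    else paste0("[", p, "[", t)
  }
}

is_bnd_alt <- function(alt) grepl("\\[|\\]", alt)

# -- SV events -----------------------------------------------------------

sv_event <- function(id, kind, end1, end2 = NULL, info = list(),
                     sourceRow = NA) {
  if (!is.null(end2)) {
    swap <- end2$refName < end1$refName ||
      (end2$refName == end1$refName && end2$pos < end1$pos)
    if (swap) {
      tmp <- end1; end1 <- end2; end2 <- tmp
      if (!is.null(info$joinSide1)) {
        j <- info$joinSide1; info$joinSide1 <- info$joinSide2
        info$joinSide2 <- j
      }
    }
  }
  structure(list(id = id, kind = kind, end1 = end1, end2 = end2,
                 info = info, sourceRow = sourceRow),
            class = "SVEvent")
}

#' Pair breakend records into structural-variant events
#'
#' BND records are paired via `MATEID` when present, otherwise by
#' reciprocal coordinates (record A's mate position equals record B's
#' position and vice versa). Unpaired breakends become single-ended
#' events with a warning; a `MATEID` referencing a missing record
#' likewise.
#'
#' Symbolic `<DEL>/<DUP>/<INV>/<TRA>` records become two-ended events
#' using POS and INFO `END` (and `CHR2` when present).
#'
#' @param variants List of [variant_feature()]s.
#' @return List of `SVEvent`s (ends hold 0-based positions).
#' @export
pair_mates <- function(variants) {
  events <- list()
  bnds <- list()
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    alt <- v$alts[1]
    if (is_bnd_alt(alt)) {
      bnd <- parse_breakend_alt(alt, v$refName, v$start + 1,
                                mateId = v$info$MATEID)
      bnds[[length(bnds) + 1]] <- list(v = v, bnd = bnd, row = i)
    } else if (grepl("^<(DEL|DUP|INV|TRA)>$", alt)) {
      kind <- sub("^<(.*)>$", "\\1", alt)
      endPos <- if (!is.null(v$info$END)) as.numeric(v$info$END) else v$end
      chr2 <- if (!is.null(v$info$CHR2)) v$info$CHR2 else v$refName
      events[[length(events) + 1]] <-
        sv_event(v$uniqueId, kind,
                 end1 = list(refName = v$refName, pos = v$start),
                 end2 = list(refName = chr2, pos = endPos - 1),
                 info = v$info, sourceRow = i)
    }
  }
  used <- rep(FALSE, length(bnds))
  ids <- vapply(bnds, function(b) b$v$uniqueId, "")
  for (i in seq_along(bnds)) {
    if (used[i]) next
    a <- bnds[[i]]
    j <- NA
    if (!is.null(a$bnd$mateId)) {
      j <- which(!used & ids == a$bnd$mateId & seq_along(bnds) != i)
      j <- if (length(j)) j[1] else NA
      if (is.na(j))
        warning("MATEID '", a$bnd$mateId, "' of ", a$v$uniqueId,
                " not found; keeping single-ended")
    }
    if (is.na(j) && is.null(a$bnd$mateId)) {
      # reciprocal coordinate match
      for (k in seq_along(bnds)) {
        if (k == i || used[k]) next
        b <- bnds[[k]]$bnd
        if (b$chrom == a$bnd$mateChrom && b$pos == a$bnd$matePos &&
            b$mateChrom == a$bnd$chrom && b$matePos == a$bnd$pos) {
          j <- k; break
        }
      }
    }
    used[i] <- TRUE
    if (!is.na(j)) {
      used[j] <- TRUE
      b <- bnds[[j]]
      events[[length(events) + 1]] <-
        sv_event(a$v$uniqueId, "BND",
                 end1 = list(refName = a$bnd$chrom, pos = a$bnd$pos - 1),
                 end2 = list(refName = b$bnd$chrom, pos = b$bnd$pos - 1),
                 info = c(a$v$info,
                          list(joinSide1 = a$bnd$joinSide,
                               joinSide2 = b$bnd$joinSide,
                               mateId2 = b$v$uniqueId)),
                 sourceRow = a$row)
    } else {
      if (is.null(a$bnd$mateId))
        warning("breakend ", a$v$uniqueId,
                " has no reciprocal mate; keeping single-ended")
      events[[length(events) + 1]] <-
        sv_event(a$v$uniqueId, "BND",
                 end1 = list(refName = a$bnd$chrom, pos = a$bnd$pos - 1),
                 end2 = NULL,
                 info = c(a$v$info, list(joinSide1 = a$bnd$joinSide,
                                         mateRef = a$bnd$mateChrom,
                                         matePos0 = a$bnd$matePos - 1)),
                 sourceRow = a$row)
    }
  }
  events
}

# -- BEDPE / fusion ingestion -------------------------------------------

#' Read paired-interval SV calls from a BEDPE file
#'
#' Requires at least the six standard columns (two 0-based half-open
#' intervals); the midpoints of the intervals become the event ends.
#' Columns 7+ (name, score, strands, ...) are retained in `info`.
#'
#' @param path BEDPE path.
#' @return List of `SVEvent`s (kind `"BEDPE"`).
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6)
      stop("BEDPE '", path, "' line ", i, ": expected >= 6 columns, got ",
           length(f))
    mid1 <- floor((as.numeric(f[2]) + as.numeric(f[3])) / 2)
    mid2 <- floor((as.numeric(f[5]) + as.numeric(f[6])) / 2)
    info <- list()
    if (length(f) >= 7 && f[7] != ".") info$name <- f[7]
    if (length(f) >= 8) info$score <- f[8]
    if (length(f) >= 10) { info$strand1 <- f[9]; info$strand2 <- f[10] }
    if (length(f) > 10) info$extra <- paste(f[11:length(f)], collapse = "\t")
    id <- if (!is.null(info$name)) info$name else paste0("bedpe", i)
    out[[i]] <- sv_event(id, "BEDPE",
                         end1 = list(refName = f[1], pos = mid1),
                         end2 = list(refName = f[4], pos = mid2),
                         info = info, sourceRow = i)
  }
  out
}

#' Read gene-fusion predictions from a STAR-Fusion table
#'
#' Reads the default tab-separated output columns, using the
#' `LeftBreakpoint`/`RightBreakpoint` strings (`chr:pos:strand`, 1-based).
#'
#' @param path `star-fusion.fusion_predictions.tsv` path.
#' @return List of `SVEvent`s (kind `"fusion"`).
#' @export
read_starfusion <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(list())
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  li <- match("LeftBreakpoint", hdr)
  ri <- match("RightBreakpoint", hdr)
  ni <- match("FusionName", hdr)
  if (is.na(li) || is.na(ri))
    stop("STAR-fusion file '", path,
         "': missing LeftBreakpoint/RightBreakpoint columns")
  out <- list()
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    pl <- strsplit(f[li], ":", fixed = TRUE)[[1]]
    pr <- strsplit(f[ri], ":", fixed = TRUE)[[1]]
    out[[length(out) + 1]] <-
      sv_event(if (!is.na(ni)) f[ni] else paste0("fusion", i - 1), "fusion",
               end1 = list(refName = pl[1], pos = as.numeric(pl[2]) - 1),
               end2 = list(refName = pr[1], pos = as.numeric(pr[2]) - 1),
               info = list(leftStrand = pl[3], rightStrand = pr[3]),
               sourceRow = i - 1)
  }
  out
}

# -- Text-expression filtering ------------------------------------------

#' Filter a feature table with a simple text expression
#'
#' The expression is a whitespace-joined conjunction of clauses. Each
#' clause is one of:
#'
#' * `column=value` — exact match (numbers compared numerically);
#' * `column~value` — substring match;
#' * `column<n`, `column>n`, `column<=n`, `column>=n` — numeric compare;
#' * a bare token — substring match against any text column.
#'
#' Column names come from the table header (see [to_table()]), e.g.
#' `id`, `refName`, `start`, `end`, `mateRef`, `matePos`, `type`,
#' `info.*`. An empty expression keeps every row.
#'
#' @param rows A data frame (typically a `FeatureTable`).
#' @param expression Filter text.
#' @return The filtered data frame (row order preserved).
#' @export
filter_table <- function(rows, expression) {
  stopifnot(is.data.frame(rows))
  expression <- trimws(expression)
  if (!nzchar(expression)) return(rows)
  keep <- rep(TRUE, nrow(rows))
  for (clause in strsplit(expression, "\\s+")[[1]]) {
    m <- regmatches(clause,
                    regexec("^([A-Za-z_][A-Za-z0-9_.]*)(<=|>=|=|~|<|>)(.*)$",
                            clause))[[1]]
    if (length(m)) {
      col <- m[2]; op <- m[3]; val <- m[4]
      if (!col %in% names(rows))
        stop("unknown column '", col, "' in filter expression")
      x <- rows[[col]]
      hit <- switch(op,
        "=" = if (is.numeric(x)) x == suppressWarnings(as.numeric(val))
              else as.character(x) == val,
        "~" = grepl(val, as.character(x), fixed = TRUE),
        {
          num <- suppressWarnings(as.numeric(val))
          if (is.na(num))
            stop("clause '", clause, "': '", val, "' is not a number")
          xn <- suppressWarnings(as.numeric(x))
          switch(op, "<" = xn < num, ">" = xn > num,
                 "<=" = xn <= num, ">=" = xn >= num)
        })
      hit[is.na(hit)] <- FALSE
    } else {
      if (grepl("[<>=~]", clause))
        stop("unparsable filter clause '", clause, "'")
      textCols <- names(rows)[vapply(rows, is.character, TRUE)]
      hit <- rep(FALSE, nrow(rows))
      for (tc in textCols)
        hit <- hit | grepl(clause, rows[[tc]], fixed = TRUE)
    }
    keep <- keep & hit
  }
  rows[keep, , drop = FALSE]
}

# -- Breakpoint evidence -------------------------------------------------

#' Displayed regions for the two sides of an SV event
#'
#' Each panel is a window centered on one event end, clamped to the
#' sequence bounds.
#'
#' @param event An `SVEvent`.
#' @param windowBp Window width in bp (> 0).
#' @param assembly An [assembly()] used for clamping.
#' @return List with `panelA` and `panelB` ([displayed_regions()];
#'   `panelB` is `NULL` for single-ended events).
#' @export
breakpoint_panels <- function(event, windowBp, assembly) {
  stopifnot(windowBp > 0)
  panel <- function(end) {
    len <- seq_length(assembly, canonical_refname(end$refName, assembly))
    s <- max(0, end$pos - windowBp / 2)
    e <- min(len, end$pos + windowBp / 2)
    displayed_regions(list(region(end$refName, s, e)), assembly)
  }
  list(panelA = panel(event$end1),
       panelB = if (is.null(event$end2)) NULL else panel(event$end2))
}

locate_panel <- function(refName, pos, panels) {
  for (pi in seq_along(panels)) {
    p <- panels[[pi]]
    if (is.null(p)) next
    for (r in p$regions)
      if (r$refName == refName && pos >= r$start && pos <= r$end)
        return(pi)
  }
  NA_integer_
}

#' Collect split-read and paired-end connectors for a breakpoint view
#'
#' Groups alignments by read name and orders each read's segments along
#' the original read (via [query_span_on_read()]). For each adjacent pair
#' of segments a connector is emitted from the query-later edge of the
#' first segment (the reference coordinate at its clip boundary) to the
#' query-earlier edge of the next. Paired-end (non-split) evidence
#' connects the mates' outer ends.
#'
#' @param reads List of [aligned_read()]s fetched from both panels
#'   (primary + supplementary records).
#' @param event The `SVEvent` under inspection (unused for geometry,
#'   recorded for provenance).
#' @param panels List of the two panels from [breakpoint_panels()].
#' @return Data frame with columns `readName`, `panelA`, `refPosA`,
#'   `refA`, `panelB`, `refPosB`, `refB`.
#' @export
gather_split_evidence <- function(reads, event, panels) {
  out <- list()
  names_ <- vapply(reads, `[[`, "", "name")
  for (nm in unique(names_)) {
    segs <- reads[names_ == nm]
    if (length(segs) < 2) next
    split_like <- any(vapply(segs, function(r)
      !is.null(r$tags$SA) || bitwAnd(r$flags, 0x800) != 0, TRUE))
    if (split_like) {
      qs <- t(vapply(segs, query_span_on_read, c(0, 0)))
      o <- order(qs[, 1])
      segs <- segs[o]
      for (i in seq_len(length(segs) - 1)) {
        a <- segs[[i]]; b <- segs[[i + 1]]
        spA <- cigar_spans(a$cigar); spB <- cigar_spans(b$cigar)
        posA <- if (a$strand == "+") a$start + spA$refSpan else a$start
        posB <- if (b$strand == "+") b$start else b$start + spB$refSpan
        out[[length(out) + 1]] <- data.frame(
          readName = nm,
          panelA = locate_panel(a$refName, posA, panels), refPosA = posA,
          refA = a$refName,
          panelB = locate_panel(b$refName, posB, panels), refPosB = posB,
          refB = b$refName, stringsAsFactors = FALSE)
      }
    } else if (length(segs) == 2) {
      # discordant mate pair: connect the outer ends
      a <- segs[[1]]; b <- segs[[2]]
      spA <- cigar_spans(a$cigar); spB <- cigar_spans(b$cigar)
      posA <- if (a$strand == "+") a$start else a$start + spA$refSpan
      posB <- if (b$strand == "+") b$start else b$start + spB$refSpan
      out[[length(out) + 1]] <- data.frame(
        readName = nm,
        panelA = locate_panel(a$refName, posA, panels), refPosA = posA,
        refA = a$refName,
        panelB = locate_panel(b$refName, posB, panels), refPosB = posB,
        refB = b$refName, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(readName = character(), panelA = integer(),
                      refPosA = numeric(), refA = character(),
                      panelB = integer(), refPosB = numeric(),
                      refB = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
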