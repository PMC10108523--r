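# -- Synteny blocks ------------------------------------------------------

CIGAR_T_OPS <- c("M", "D", "N", "=", "X")  # consume target
CIGAR_Q_OPS <- c("M", "I", "=", "X")       # consume query

#' Create a pairwise synteny block
#'
#' One alignment block between a query and a target assembly. Query
#' coordinates are always stored on the forward strand, whatever the
#' source format's convention (PAF already is; chain and delta are
#' converted on parse). When a CIGAR is present its target consumption
#' must equal `tEnd - tStart` and its query consumption `qEnd - qStart`.
#'
#' @param qName,qLen,qStart,qEnd Query sequence name, length and 0-based
#'   half-open span (forward strand).
#' @param strand `"+"` or `"-"`.
#' @param tName,tLen,tStart,tEnd Target equivalents.
#' @param score Optional score.
#' @param cigar Optional CIGAR string.
#' @param source Format tag (`"paf"`, `"delta"`, `"chain"`, `"anchors"`).
#' @param level For anchors: `"gene"` or `"block"`.
#' @return An object of class `SyntenyBlock`.
#' @export
synteny_block <- function(qName, qLen, qStart, qEnd, strand, tName, tLen,
                          tStart, tEnd, score = NA_real_, cigar = NULL,
                          source = "paf", level = NA_character_) {
  stopifnot(qStart <= qEnd, tStart <= tEnd, strand %in% c("+", "-"))
  if (!is.null(cigar)) {
    ops <- parse_cigar(cigar)
    tc <- sum(ops$len[ops$op %in% CIGAR_T_OPS])
    qc <- sum(ops$len[ops$op %in% CIGAR_Q_OPS])
    if (tc != tEnd - tStart)
      stop("block ", qName, "/", tName, ": CIGAR consumes ", tc,
           " target bases, span is ", tEnd - tStart)
    if (qc != qEnd - qStart)
      stop("block ", qName, "/", tName, ": CIGAR consumes ", qc,
           " query bases, span is ", qEnd - qStart)
  }
  structure(list(qName = qName, qLen = as.numeric(qLen),
                 qStart = as.numeric(qStart), qEnd = as.numeric(qEnd),
                 strand = strand, tName = tName, tLen = as.numeric(tLen),
                 tStart = as.numeric(tStart), tEnd = as.numeric(tEnd),
                 score = score, cigar = cigar, source = source,
                 level = level),
            class = "SyntenyBlock")
}

# -- PAF -----------------------------------------------------------------

#' Parse one PAF line
#'
#' Columns 1-12 per the PAF specification; a `cg:Z` tag is parsed into
#' the block's CIGAR. In permissive mode (for mashmap-style output)
#' whitespace-separated lines with >= 10 columns are accepted and the
#' missing columns defaulted.
#'
#' @param line One PAF line.
#' @param permissive Accept mashmap-like lines.
#' @return A [synteny_block()].
#' @export
parse_paf <- function(line, permissive = FALSE) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 12 && permissive)
    f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) < 12 && !(permissive && length(f) >= 10))
    stop("PAF line has ", length(f), " columns; >= 12 required")
  cigar <- NULL
  if (length(f) > 12) {
    cg <- grep("^cg:Z:", f[13:length(f)], value = TRUE)
    if (length(cg)) cigar <- sub("^cg:Z:", "", cg[1])
  }
  synteny_block(qName = f[1], qLen = as.numeric(f[2]),
                qStart = as.numeric(f[3]), qEnd = as.numeric(f[4]),
                strand = f[5], tName = f[6], tLen = as.numeric(f[7]),
                tStart = as.numeric(f[8]), tEnd = as.numeric(f[9]),
                score = if (length(f) >= 10) as.numeric(f[10]) else NA,
                cigar = cigar, source = "paf")
}

#' Read a PAF file
#'
#' @param path PAF path (plain or gzipped).
#' @param permissive Passed to [parse_paf()].
#' @return List of [synteny_block()]s.
#' @export
read_paf <- function(path, permissive = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lapply(lines[nzchar(lines)], parse_paf, permissive = permissive)
}

#' Write synteny blocks as PAF
#'
#' @param blocks List of [synteny_block()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  lines <- vapply(blocks, function(b) {
    matches <- if (!is.null(b$cigar)) {
      ops <- parse_cigar(b$cigar)
      sum(ops$len[ops$op %in% c("M", "=")])
    } else min(b$qEnd - b$qStart, b$tEnd - b$tStart)
    paste(c(b$qName, fmt_int(b$qLen), fmt_int(b$qStart), fmt_int(b$qEnd),
            b$strand, b$tName, fmt_int(b$tLen), fmt_int(b$tStart),
            fmt_int(b$tEnd), fmt_int(matches),
            fmt_int(max(b$qEnd - b$qStart, b$tEnd - b$tStart)), "60",
            if (!is.null(b$cigar)) paste0("cg:Z:", b$cigar)),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

# -- MUMmer delta --------------------------------------------------------

#' Parse MUMmer (nucmer) delta alignments
#'
#' Walks the delta layout: a file header, `>ref qry rlen qlen` sequence
#' sections, per-alignment headers `rs re qs qe e1 e2 e3` (1-based
#' inclusive), then signed indel distances terminated by `0`. A positive
#' distance `d` means `d - 1` matched positions followed by a base
#' present in the reference but not the query (a query deletion, CIGAR
#' `D`); negative means an extra query base (CIGAR `I`). `qs > qe`
#' signals a reverse-strand match; coordinates are converted to
#' forward-strand 0-based half-open.
#'
#' @param text Delta file content as a character vector of lines (or one
#'   string with embedded newlines), or a file path.
#' @return List of [synteny_block()]s (target = reference).
#' @export
parse_delta <- function(text) {
  lines <- delta_lines(text)
  i <- 1
  # file header: two paths + program line (tolerate either being absent)
  while (i <= length(lines) && !startsWith(lines[i], ">")) i <- i + 1
  blocks <- list()
  rname <- qname <- NA; rlen <- qlen <- NA
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      f <- strsplit(sub("^>", "", ln), "\\s+")[[1]]
      rname <- f[1]; qname <- f[2]
      rlen <- as.numeric(f[3]); qlen <- as.numeric(f[4])
      i <- i + 1
      next
    }
    hdr <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    if (length(hdr) != 7)
      stop("delta alignment header expected 7 numbers, got: '", ln, "'")
    rs <- hdr[1]; re <- hdr[2]; qs <- hdr[3]; qe <- hdr[4]
    i <- i + 1
    dists <- numeric()
    terminated <- FALSE
    while (i <= length(lines)) {
      d <- suppressWarnings(as.numeric(trimws(lines[i])))
      if (is.na(d)) break
      i <- i + 1
      if (d == 0) { terminated <- TRUE; break }
      dists <- c(dists, d)
    }
    if (!terminated)
      stop("delta alignment ", rname, "/", qname,
           " missing its 0 terminator")
    strand <- if (qs <= qe) "+" else "-"
    qlo <- min(qs, qe) - 1; qhi <- max(qs, qe)
    tStart <- rs - 1; tEnd <- re
    cigar <- delta_to_cigar(dists, tEnd - tStart, qhi - qlo)
    blocks[[length(blocks) + 1]] <-
      synteny_block(qName = qname, qLen = qlen, qStart = qlo, qEnd = qhi,
                    strand = strand, tName = rname, tLen = rlen,
                    tStart = tStart, tEnd = tEnd, cigar = cigar,
                    source = "delta")
  }
  blocks
}

delta_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text[nzchar(text)]
}

delta_to_cigar <- function(dists, tSpan, qSpan) {
  ops <- character(); lens <- numeric()
  push <- function(op, len) {
    if (len == 0) return()
    n <- length(ops)
    if (n && ops[n] == op) lens[n] <<- lens[n] + len
    else { ops[n + 1] <<- op; lens[n + 1] <<- len }
  }
  tUsed <- 0; qUsed <- 0
  for (d in dists) {
    push("M", abs(d) - 1)
    tUsed <- tUsed + abs(d) - 1; qUsed <- qUsed + abs(d) - 1
    if (d > 0) { push("D", 1); tUsed <- tUsed + 1 }
    else { push("I", 1); qUsed <- qUsed + 1 }
  }
  tail <- tSpan - tUsed
  if (tail != qSpan - qUsed)
    stop("delta distances inconsistent with alignment spans")
  push("M", tail)
  paste0(lens, ops, collapse = "")
}

# -- UCSC chain ----------------------------------------------------------

#' Parse UCSC chain alignments
#'
#' Each chain is a `chain score tName tSize tStrand tStart tEnd qName
#' qSize qStrand qStart qEnd id` header followed by `size dt dq` block
#' triplets and a final bare `size`. `dt` skips target bases (CIGAR `D`),
#' `dq` skips query bases (CIGAR `I`). Minus-strand query coordinates are
#' converted to forward-strand (`qSize - end`, `qSize - start`).
#'
#' @param text Lines, one string, or a file path.
#' @return List of [synteny_block()]s.
#' @export
parse_chain <- function(text) {
  lines <- delta_lines(text)
  blocks <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, "chain")) { i <- i + 1; next }
    h <- strsplit(ln, "\\s+")[[1]]
    if (length(h) < 12) stop("chain header too short: '", ln, "'")
    score <- as.numeric(h[2])
    tName <- h[3]; tSize <- as.numeric(h[4]); tStrand <- h[5]
    tStart <- as.numeric(h[6]); tEnd <- as.numeric(h[7])
    qName <- h[8]; qSize <- as.numeric(h[9]); qStrand <- h[10]
    qStart <- as.numeric(h[11]); qEnd <- as.numeric(h[12])
    if (tStrand != "+") stop("chain with tStrand '-' not supported")
    i <- i + 1
    ops <- character(); lens <- numeric()
    push <- function(op, len) {
      if (len == 0) return()
      n <- length(ops)
      if (n && ops[n] == op) lens[n] <<- lens[n] + len
      else { ops[n + 1] <<- op; lens[n + 1] <<- len }
    }
    tSum <- 0; qSum <- 0
    repeat {
      if (i > length(lines)) stop("chain ended before its final size line")
      triplet <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
      push("M", triplet[1])
      tSum <- tSum + triplet[1]; qSum <- qSum + triplet[1]
      if (length(triplet) == 1) break
      push("D", triplet[2]); push("I", triplet[3])
      tSum <- tSum + triplet[2]; qSum <- qSum + triplet[3]
    }
    if (tSum != tEnd - tStart || qSum != qEnd - qStart)
      stop("chain block sizes do not sum to the header spans (",
           tSum, " vs ", tEnd - tStart, " target, ",
           qSum, " vs ", qEnd - qStart, " query)")
    if (qStrand == "-") {
      tmp <- qSize - qEnd
      qEnd <- qSize - qStart
      qStart <- tmp
    }
    blocks[[length(blocks) + 1]] <-
      synteny_block(qName = qName, qLen = qSize, qStart = qStart,
                    qEnd = qEnd, strand = if (qStrand == "-") "-" else "+",
                    tName = tName, tLen = tSize, tStart = tStart,
                    tEnd = tEnd, score = score,
                    cigar = paste0(lens, ops, collapse = ""),
                    source = "chain")
  }
  blocks
}

#' Write synteny blocks as a UCSC chain file
#'
#' Inverse of [parse_chain()] (used for round trips and fixtures); the
#' block CIGAR is re-run-length-encoded into `size dt dq` triplets.
#'
#' @param blocks List of [synteny_block()]s with CIGARs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(blocks, path) {
  out <- character()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    qStart <- b$qStart; qEnd <- b$qEnd
    if (b$strand == "-") {
      qStart <- b$qLen - b$qEnd
      qEnd <- b$qLen - b$qStart
    }
    score <- if (is.na(b$score)) 0 else b$score
    out <- c(out, paste("chain", fmt_int(score), b$tName, fmt_int(b$tLen),
                        "+", fmt_int(b$tStart), fmt_int(b$tEnd), b$qName,
                        fmt_int(b$qLen), b$strand, fmt_int(qStart),
                        fmt_int(qEnd), bi))
    ops <- if (!is.null(b$cigar)) parse_cigar(b$cigar)
           else data.frame(op = "M", len = b$tEnd - b$tStart)
    # collapse into size/dt/dq triplets
    sizes <- numeric(); dts <- numeric(); dqs <- numeric()
    cur <- 0; dt <- 0; dq <- 0; inGap <- FALSE
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        if (inGap) {
          sizes <- c(sizes, cur); dts <- c(dts, dt); dqs <- c(dqs, dq)
          cur <- 0; dt <- 0; dq <- 0; inGap <- FALSE
        }
        cur <- cur + len
      } else if (op %in% c("D", "N")) { dt <- dt + len; inGap <- TRUE }
      else if (op == "I") { dq <- dq + len; inGap <- TRUE }
    }
    lines_ <- c(if (length(sizes))
      paste(fmt_int(sizes), fmt_int(dts), fmt_int(dqs)), fmt_int(cur))
    out <- c(out, lines_, "")
  }
  writeLines(out, path)
  invisible(path)
}

# -- MCScan anchors ------------------------------------------------------

read_bed4 <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          fill = TRUE)
  out <- data.frame(refName = df[[1]], start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]), name = as.character(df[[4]]),
                    strand = if (ncol(df) >= 6) as.character(df[[6]])
                             else "+",
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  out
}

#' Parse MCScan anchors with companion BED files
#'
#' Anchors lines are `geneA geneB score` with `###` separating collinear
#' blocks; the two BED files supply gene coordinates and strands (query
#' genes in `qBed`, target genes in `tBed`). Returns one `level="gene"`
#' block per pair plus one merged `level="block"` block per `###` group
#' spanning the min..max of its pairs; group strand is the majority vote
#' of its pairs (ties `"+"`). Pairs naming a gene absent from the BEDs
#' are skipped with a warning.
#'
#' @param anchorsPath `.anchors` path.
#' @param qBed,tBed BED paths for query and target gene models.
#' @return List of [synteny_block()]s.
#' @export
parse_anchors <- function(anchorsPath, qBed, tBed) {
  qb <- read_bed4(qBed); tb <- read_bed4(tBed)
  qi <- stats::setNames(seq_len(nrow(qb)), qb$name)
  ti <- stats::setNames(seq_len(nrow(tb)), tb$name)
  lines <- readLines(anchorsPath)
  blocks <- list()
  group <- list()
  flush_group <- function() {
    if (length(group) < 1) return()
    qs <- vapply(group, `[[`, 0, "qStart"); qe <- vapply(group, `[[`, 0, "qEnd")
    ts <- vapply(group, `[[`, 0, "tStart"); te <- vapply(group, `[[`, 0, "tEnd")
    strands <- vapply(group, `[[`, "", "strand")
    maj <- if (sum(strands == "-") > sum(strands == "+")) "-" else "+"
    blocks[[length(blocks) + 1]] <<-
      synteny_block(qName = group[[1]]$qName, qLen = NA, qStart = min(qs),
                    qEnd = max(qe), strand = maj,
                    tName = group[[1]]$tName, tLen = NA, tStart = min(ts),
                    tEnd = max(te), source = "anchors", level = "block")
    group <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "###")) { flush_group(); next }
    if (!nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gq <- f[1]; gt <- f[2]
    iq <- qi[gq]; it <- ti[gt]
    if (is.na(iq) || is.na(it)) {
      warning("anchors pair ", gq, "/", gt, ": gene not found in BED; skipped")
      next
    }
    strand <- if (qb$strand[iq] == tb$strand[it]) "+" else "-"
    b <- synteny_block(qName = qb$refName[iq], qLen = NA,
                       qStart = qb$start[iq], qEnd = qb$end[iq],
                       strand = strand, tName = tb$refName[it], tLen = NA,
                       tStart = tb$start[it], tEnd = tb$end[it],
                       score = suppressWarnings(as.numeric(f[3])),
                       source = "anchors", level = "gene")
    blocks[[length(blocks) + 1]] <- b
    group[[length(group) + 1]] <- b
  }
  flush_group()
  blocks
}

# -- Dotplot geometry ----------------------------------------------------

#' Dotplot polyline of a synteny block
#'
#' Without a CIGAR the path is the two corner vertices (anti-diagonal for
#' `-` strand). With a CIGAR, match ops advance both axes, `D`/`N` the
#' target only, `I` the query only; on the `-` strand the query
#' coordinate starts at `qEnd` and steps downward. The target coordinate
#' is non-decreasing throughout.
#'
#' @param block A [synteny_block()].
#' @return Data frame of vertices with columns `t` and `q` (bp).
#' @export
dotplot_path <- function(block) {
  if (is.null(block$cigar)) {
    if (block$strand == "+")
      return(data.frame(t = c(block$tStart, block$tEnd),
                        q = c(block$qStart, block$qEnd)))
    return(data.frame(t = c(block$tStart, block$tEnd),
                      q = c(block$qEnd, block$qStart)))
  }
  ops <- parse_cigar(block$cigar)
  dir <- if (block$strand == "+") 1 else -1
  t <- block$tStart
  q <- if (block$strand == "+") block$qStart else block$qEnd
  ts <- t; qs <- q
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) { t <- t + len; q <- q + dir * len }
    else if (op %in% c("D", "N")) t <- t + len
    else if (op == "I") q <- q + dir * len
    else next
    ts <- c(ts, t); qs <- c(qs, q)
  }
  data.frame(t = ts, q = qs)
}
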