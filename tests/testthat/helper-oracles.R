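# Shared fixtures and independent oracles used across the suite.

toy_assembly <- function(lens = c(chr1 = 1000, chr2 = 1000),
                         aliases = character()) {
  assembly("toy", data.frame(refName = names(lens), length = unname(lens),
                             stringsAsFactors = FALSE), aliases)
}

random_region_stack <- function(assembly, n, allow_reversed = TRUE) {
  regs <- lapply(seq_len(n), function(i) {
    cn <- sample(assembly$sequences$refName, 1)
    len <- assembly$sequences$length[assembly$sequences$refName == cn]
    s <- sample.int(len - 10, 1) - 1
    e <- s + sample.int(min(200, len - s), 1)
    region(cn, s, e, reversed = allow_reversed && stats::runif(1) < 0.3)
  })
  suppressMessages(displayed_regions(regs, assembly,
                                     interRegionPadding = sample(0:4, 1)))
}

# brute-force bp->px: walk the region stack base by base
oracle_bp_to_px <- function(refName, coord, displayed, bpPerPx) {
  px <- 0
  for (i in seq_along(displayed$regions)) {
    r <- displayed$regions[[i]]
    if (i > 1) px <- px + displayed$interRegionPadding
    coords <- if (r$reversed) rev(seq(r$start, r$end - 1))
              else seq(r$start, r$end - 1)
    if (r$refName == refName && coord %in% coords) {
      return(px + (which(coords == coord)[1] - 1) / bpPerPx)
    }
    px <- px + (r$end - r$start) / bpPerPx
  }
  NA_real_
}

# brute-force maximum interval overlap depth over integer coordinates
oracle_max_depth <- function(starts, ends) {
  if (!length(starts)) return(0L)
  events <- rbind(data.frame(x = starts, d = 1),
                  data.frame(x = ends, d = -1))
  events <- events[order(events$x, events$d), ]
  max(cumsum(events$d))
}

# per-base aligned coverage of reads over a region (M/=/X only)
oracle_coverage <- function(reads, region) {
  depth <- numeric(region$end - region$start)
  for (r in reads) {
    pos <- r$start
    ops <- parse_cigar(r$cigar)
    for (i in seq_len(nrow(ops))) {
      op <- ops$op[i]; len <- ops$len[i]
      if (op %in% c("M", "=", "X")) {
        for (p in seq(pos, pos + len - 1)) {
          if (p >= region$start && p < region$end)
            depth[p - region$start + 1] <- depth[p - region$start + 1] + 1
        }
      }
      if (op %in% c("M", "D", "N", "=", "X")) pos <- pos + len
    }
  }
  depth
}

# linear full-scan search oracle for the trix index
oracle_prefix_search <- function(docs, prefix) {
  p <- tolower(prefix)
  exact <- character(); part <- character()
  for (i in seq_len(nrow(docs))) {
    toks <- strsplit(tolower(docs$text[i]), "[^a-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (any(toks == p)) exact <- c(exact, docs$docId[i])
    else if (any(startsWith(toks, p))) part <- c(part, docs$docId[i])
  }
  c(sort(unique(exact), method = "radix"),
    setdiff(sort(unique(part), method = "radix"), exact))
}

random_cigar <- function() {
  n <- sample(1:6, 1)
  mid_ops <- sample(c("M", "I", "D"), n, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2))
  # normalize: must start/end with M between optional clips
  mid_ops[1] <- "M"; mid_ops[n] <- "M"
  lens <- sample(1:30, n, replace = TRUE)
  pre <- if (stats::runif(1) < 0.4) paste0(sample(1:10, 1), "S") else ""
  post <- if (stats::runif(1) < 0.4) paste0(sample(1:10, 1), "S") else ""
  paste0(pre, paste0(lens, mid_ops, collapse = ""), post)
}

read_from_cigar <- function(cigar, start = 0, strand = "+",
                            name = "r") {
  sp <- cigar_spans(cigar)
  aligned_read(name, "chr1", start, cigar, strand = strand,
               seq = paste(rep("A", sp$querySpan), collapse = ""))
}

sam_line <- function(qname, flag, rname, pos1, mapq, cigar, seq,
                     tags = character()) {
  paste(c(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, seq,
          "*", tags), collapse = "\t")
}
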