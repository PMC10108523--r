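# -- Synthetic genomes ---------------------------------------------------

#' Generate a random genome
#'
#' Uniform random A/C/G/T per chromosome, deterministic per seed. The
#' draw order is one `sample()` call per chromosome, in order, so
#' outputs are reproducible across versions.
#'
#' @param chromLengths Numeric vector of chromosome lengths (>= 1).
#' @param seed Integer seed.
#' @param chromNames Names; default `chr1`, `chr2`, ...
#' @return List with `name` and `seqs` (named character vector).
#' @export
make_genome <- function(chromLengths, seed = 1,
                        chromNames = paste0("chr", seq_along(chromLengths))) {
  if (any(chromLengths < 1)) stop("chromosome lengths must be >= 1")
  set.seed(seed)
  seqs <- vapply(chromLengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  names(seqs) <- chromNames
  list(name = "synthetic", seqs = seqs)
}

#' Write sequences as FASTA (with .fai index)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(nchar(s), starts + 59)), con)
  }
  close(con)
  Rsamtools::indexFa(path)
  invisible(path)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# -- SV specification ----------------------------------------------------

#' Specify a structural variant for the fixture generator
#'
#' @param kind One of `deletion`, `duplication`, `inversion`,
#'   `insertion`, `translocation`.
#' @param chrom,start First (or only) breakpoint; `start`/`end` are
#'   0-based half-open on the reference.
#' @param end Interval end (deletion/duplication/inversion).
#' @param insertSeq Inserted sequence (insertion).
#' @param chrom2,pos2 Partner breakpoint (translocation; reciprocal).
#' @param id Event id; defaults to `kind` + index assigned later.
#' @return An object of class `SvSpec`.
#' @export
sv_spec <- function(kind, chrom, start, end = NA, insertSeq = NA,
                    chrom2 = NA, pos2 = NA, id = NA) {
  kind <- match.arg(kind, c("deletion", "duplication", "inversion",
                            "insertion", "translocation"))
  structure(list(kind = kind, chrom = chrom, start = start, end = end,
                 insertSeq = insertSeq, chrom2 = chrom2, pos2 = pos2,
                 id = id),
            class = "SvSpec")
}

validate_svs <- function(genome, specs) {
  ivs <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    if (is.na(sp$id)) specs[[k]]$id <- sp$id <- paste0(sp$kind, k)
    len <- nchar(genome$seqs[[sp$chrom]])
    if (is.null(len)) stop("SV ", sp$id, ": unknown chrom ", sp$chrom)
    if (sp$kind == "translocation") {
      len2 <- nchar(genome$seqs[[sp$chrom2]])
      if (sp$start <= 0 || sp$start >= len || sp$pos2 <= 0 ||
          sp$pos2 >= len2)
        stop("SV ", sp$id, ": breakpoint out of bounds")
      ivs[[length(ivs) + 1]] <- c(sp$chrom, sp$start, sp$start + 1)
      ivs[[length(ivs) + 1]] <- c(sp$chrom2, sp$pos2, sp$pos2 + 1)
    } else if (sp$kind == "insertion") {
      if (sp$start < 0 || sp$start > len)
        stop("SV ", sp$id, ": position out of bounds")
      ivs[[length(ivs) + 1]] <- c(sp$chrom, sp$start, sp$start + 1)
    } else {
      if (sp$start < 0 || sp$end > len || sp$start >= sp$end)
        stop("SV ", sp$id, ": interval out of bounds")
      ivs[[length(ivs) + 1]] <- c(sp$chrom, sp$start, sp$end)
    }
  }
  iv <- data.frame(chrom = vapply(ivs, `[`, "", 1),
                   s = as.numeric(vapply(ivs, `[`, "", 2)),
                   e = as.numeric(vapply(ivs, `[`, "", 3)))
  for (cn in unique(iv$chrom)) {
    sub <- iv[iv$chrom == cn, ]
    sub <- sub[order(sub$s), ]
    if (nrow(sub) > 1 && any(sub$s[-1] < sub$e[-nrow(sub)]))
      stop("overlapping SV specs on ", cn)
  }
  specs
}

new_seg <- function(ref, refStart, refEnd, strand = "+", ins = NA) {
  data.frame(ref = ref, refStart = refStart, refEnd = refEnd,
             strand = strand, ins = ins, stringsAsFactors = FALSE)
}

# split a segment chain at a reference point (which must fall inside a
# forward-strand segment); returns list(head, tail)
split_chain_at_ref <- function(chain, chrom, pos) {
  for (i in seq_len(nrow(chain))) {
    sg <- chain[i, ]
    if (!is.na(sg$ins) || sg$ref != chrom) next
    if (pos > sg$refStart && pos < sg$refEnd) {
      if (sg$strand != "+")
        stop("translocation breakpoint inside an inverted segment")
      head <- rbind(chain[seq_len(i - 1), , drop = FALSE],
                    new_seg(sg$ref, sg$refStart, pos))
      tail <- rbind(new_seg(sg$ref, pos, sg$refEnd),
                    chain[seq_len(nrow(chain)) > i, , drop = FALSE])
      return(list(head = head, tail = tail))
    }
    if (pos == sg$refStart && sg$strand == "+")
      return(list(head = chain[seq_len(i - 1), , drop = FALSE],
                  tail = chain[seq_len(nrow(chain)) >= i, , drop = FALSE]))
  }
  stop("translocation breakpoint ", chrom, ":", pos,
       " not found on a forward segment")
}

#' Apply structural variants to a genome
#'
#' Realizes each SV in derived sequences, tracks an exact liftover map
#' (derived intervals -> reference segments with strand), and encodes
#' the truth as VCF records: translocations as two breakend pairs with
#' mutual `MATEID`s and bracket orientations read off the derived
#' adjacency; the rest as symbolic records with `END`.
#'
#' @param genome From [make_genome()] (or any `list(name, seqs)`).
#' @param specs List of [sv_spec()]s; intervals must not overlap.
#' @return List with `seqs` (derived sequences), `segments` (named list
#'   of liftover tables with `dStart`/`dEnd` derived coordinates),
#'   `vcfLines` (truth VCF body), `truthEvents` (data frame: id, kind,
#'   refName1, pos1, refName2, pos2, joinSide1, joinSide2), and `specs`.
#' @export
apply_svs <- function(genome, specs) {
  specs <- validate_svs(genome, specs)
  chains <- lapply(names(genome$seqs), function(cn)
    new_seg(cn, 0, nchar(genome$seqs[[cn]])))
  names(chains) <- names(genome$seqs)
  symbolic <- list()
  # intra-chromosomal events first
  for (sp in specs) {
    if (sp$kind == "translocation") next
    cn <- sp$chrom
    chain <- chains[[cn]]
    out <- new_seg("x", 0, 0)[0, ]
    for (i in seq_len(nrow(chain))) {
      sg <- chain[i, ]
      if (!is.na(sg$ins) || sg$ref != cn ||
          sp$start < sg$refStart ||
          (if (sp$kind == "insertion") sp$start > sg$refEnd
           else sp$end > sg$refEnd)) {
        out <- rbind(out, sg)
        next
      }
      pre <- new_seg(cn, sg$refStart, sp$start)
      post_from <- if (sp$kind == "insertion") sp$start else sp$end
      post <- new_seg(cn, post_from, sg$refEnd)
      mid <- switch(sp$kind,
        deletion = NULL,
        inversion = new_seg(cn, sp$start, sp$end, strand = "-"),
        duplication = rbind(new_seg(cn, sp$start, sp$end),
                            new_seg(cn, sp$start, sp$end)),
        insertion = new_seg(NA_character_, 0, nchar(sp$insertSeq),
                            ins = sp$insertSeq))
      keep <- function(s) s[s$refEnd > s$refStart | !is.na(s$ins), ,
                            drop = FALSE]
      out <- rbind(out, keep(pre), mid, keep(post))
    }
    chains[[cn]] <- out
    symbolic[[length(symbolic) + 1]] <- sp
  }
  # translocations: reciprocal tail exchange on the current derived state
  for (sp in specs) {
    if (sp$kind != "translocation") next
    loc1 <- locate_chain(chains, sp$chrom, sp$start)
    s1 <- split_chain_at_ref(chains[[loc1]], sp$chrom, sp$start)
    loc2 <- locate_chain(chains, sp$chrom2, sp$pos2)
    if (loc1 == loc2) stop("translocation breakpoints on one derived chrom")
    s2 <- split_chain_at_ref(chains[[loc2]], sp$chrom2, sp$pos2)
    chains[[loc1]] <- rbind(s1$head, s2$tail)
    chains[[loc2]] <- rbind(s2$head, s1$tail)
  }
  # derived sequences + liftover coordinates
  seqs <- character(); segments <- list()
  for (cn in names(chains)) {
    chain <- chains[[cn]]
    pieces <- vapply(seq_len(nrow(chain)), function(i) {
      sg <- chain[i, ]
      if (!is.na(sg$ins)) return(sg$ins)
      s <- substr(genome$seqs[[sg$ref]], sg$refStart + 1, sg$refEnd)
      if (sg$strand == "-") revcomp(s) else s
    }, "")
    lens <- nchar(pieces)
    chain$dStart <- cumsum(c(0, lens[-length(lens)]))
    chain$dEnd <- chain$dStart + lens
    seqs[[cn]] <- paste(pieces, collapse = "")
    segments[[cn]] <- chain
  }
  truth <- build_truth(genome, segments, symbolic)
  list(seqs = seqs, segments = segments, vcfLines = truth$vcfLines,
       truthEvents = truth$events, specs = specs)
}

locate_chain <- function(chains, chrom, pos) {
  for (cn in names(chains)) {
    ch <- chains[[cn]]
    hit <- !is.na(ch$ref) & ch$ref == chrom & ch$strand == "+" &
      is.na(ch$ins) & ch$refStart < pos & pos <= ch$refEnd
    if (any(hit)) return(cn)
  }
  stop("position ", chrom, ":", pos, " not on any forward derived segment")
}

ref_base <- function(genome, chrom, pos1) {
  substr(genome$seqs[[chrom]], pos1, pos1)
}

build_truth <- function(genome, segments, symbolic) {
  lines <- character()
  events <- list()
  bndN <- 0
  seen <- character()
  for (cn in names(segments)) {
    chain <- segments[[cn]]
    for (i in seq_len(nrow(chain) - 1)) {
      a <- chain[i, ]; b <- chain[i + 1, ]
      if (is.na(a$ins) && is.na(b$ins) && !is.na(a$ref) && !is.na(b$ref) &&
          a$ref != b$ref && a$strand == "+" && b$strand == "+") {
        # cross-chromosome junction: left side keeps [.., a$refEnd),
        # right side keeps [b$refStart, ..)
        key <- paste(a$ref, a$refEnd, b$ref, b$refStart)
        if (key %in% seen) next
        seen <- c(seen, key)
        bndN <- bndN + 1
        id1 <- sprintf("bnd_%d_1", bndN); id2 <- sprintf("bnd_%d_2", bndN)
        p1 <- a$refEnd             # 1-based last retained base
        p2 <- b$refStart + 1       # 1-based first retained base
        t1 <- ref_base(genome, a$ref, p1)
        t2 <- ref_base(genome, b$ref, p2)
        lines <- c(lines,
          paste(a$ref, p1, id1, t1,
                sprintf("%s[%s:%d[", t1, b$ref, p2), ".", "PASS",
                sprintf("SVTYPE=BND;MATEID=%s", id2), sep = "\t"),
          paste(b$ref, p2, id2, t2,
                sprintf("]%s:%d]%s", a$ref, p1, t2), ".", "PASS",
                sprintf("SVTYPE=BND;MATEID=%s", id1), sep = "\t"))
        events[[length(events) + 1]] <- data.frame(
          id = id1, kind = "BND", refName1 = a$ref, pos1 = p1,
          refName2 = b$ref, pos2 = p2, joinSide1 = "left_of_pos",
          joinSide2 = "right_of_pos", stringsAsFactors = FALSE)
      }
    }
  }
  for (sp in symbolic) {
    type <- switch(sp$kind, deletion = "DEL", duplication = "DUP",
                   inversion = "INV", insertion = "INS")
    pos1 <- sp$start               # 1-based base before the event
    endPos <- if (sp$kind == "insertion") sp$start else sp$end
    info <- sprintf("SVTYPE=%s;END=%d", type, as.integer(endPos))
    if (sp$kind == "insertion")
      info <- paste0(info, ";SVLEN=", nchar(sp$insertSeq))
    lines <- c(lines,
               paste(sp$chrom, max(1, pos1), sp$id,
                     ref_base(genome, sp$chrom, max(1, pos1)),
                     paste0("<", type, ">"), ".", "PASS", info,
                     sep = "\t"))
    events[[length(events) + 1]] <- data.frame(
      id = sp$id, kind = type, refName1 = sp$chrom, pos1 = max(1, pos1),
      refName2 = sp$chrom, pos2 = endPos, joinSide1 = NA, joinSide2 = NA,
      stringsAsFactors = FALSE)
  }
  list(vcfLines = lines,
       events = if (length(events)) do.call(rbind, events)
                else data.frame())
}

#' Write the truth VCF of an [apply_svs()] result
#'
#' @param sv Result of [apply_svs()].
#' @param genome The reference genome the specs were applied to.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(sv, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           vapply(names(genome$seqs), function(cn)
             sprintf("##contig=<ID=%s,length=%d>", cn,
                     nchar(genome$seqs[[cn]])), ""),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  writeLines(c(hdr, sv$vcfLines), path)
  invisible(path)
}

# -- Read simulation -----------------------------------------------------

#' Simulate reads from a derived genome, aligned to the reference
#'
#' Reads are sampled uniformly from the derived genome and their
#' reference alignments computed exactly by lifting each read's derived
#' interval through the SV segment map — no aligner involved, so every
#' mapping is correct by construction. A read crossing an SV junction
#' becomes two or more alignment segments (primary = longest, the rest
#' supplementary) with mutual SA tags and exact soft clips; reads are
#' error-free by default so evidence geometry is exact. A fraction of
#' reads carries MM/ML tags marking CpG cytosines (5mC) on the original
#' read.
#'
#' @param sv Result of [apply_svs()].
#' @param genome The reference genome (for SA tag sanity only).
#' @param readLenBp Read length.
#' @param coverage Target mean coverage of the derived genome.
#' @param seed Integer seed.
#' @param mmFraction Fraction of reads given MM/ML tags.
#' @return List with `reads` (list of [aligned_read()], coordinate
#'   sorted), `truth` (data frame: readName, derivedChrom, dStart, dEnd,
#'   nSegments) and `readSegments` (list of per-read segment tables with
#'   qs/qe/refName/rs/re/strand).
#' @export
simulate_reads <- function(sv, genome, readLenBp = 1000, coverage = 10,
                           seed = 1, mmFraction = 0.25) {
  stopifnot(coverage > 0)
  set.seed(seed)
  reads <- list(); truth <- list(); segTables <- list()
  rn <- 0
  for (cn in names(sv$seqs)) {
    L <- nchar(sv$seqs[[cn]])
    if (L < readLenBp) next
    n <- round(coverage * L / readLenBp)
    starts <- sort(sample.int(L - readLenBp + 1, n, replace = TRUE) - 1)
    hasMM <- stats::runif(n) < mmFraction
    chain <- sv$segments[[cn]]
    for (k in seq_len(n)) {
      rn <- rn + 1
      nm <- sprintf("read%05d", rn)
      s <- starts[k]; e <- s + readLenBp
      frag <- substr(sv$seqs[[cn]], s + 1, e)
      segs <- lift_interval(chain, s, e)
      alns <- make_read_alignments(nm, frag, segs, readLenBp,
                                   mm = hasMM[k])
      reads <- c(reads, alns)
      truth[[rn]] <- data.frame(readName = nm, derivedChrom = cn,
                                dStart = s, dEnd = e,
                                nSegments = length(alns),
                                stringsAsFactors = FALSE)
      segTables[[nm]] <- segs
    }
  }
  o <- order(vapply(reads, `[[`, "", "refName"),
             vapply(reads, `[[`, 0, "start"))
  list(reads = reads[o],
       truth = do.call(rbind, truth),
       readSegments = segTables)
}

# intersect a derived interval with the segment chain; returns per-piece
# query offsets and reference coordinates
lift_interval <- function(chain, s, e) {
  out <- list()
  for (i in seq_len(nrow(chain))) {
    sg <- chain[i, ]
    lo <- max(s, sg$dStart); hi <- min(e, sg$dEnd)
    if (lo >= hi || !is.na(sg$ins)) next
    off1 <- lo - sg$dStart; off2 <- hi - sg$dStart
    if (sg$strand == "+") {
      rs <- sg$refStart + off1; re <- sg$refStart + off2
    } else {
      rs <- sg$refEnd - off2; re <- sg$refEnd - off1
    }
    out[[length(out) + 1]] <- data.frame(
      qs = lo - s, qe = hi - s, refName = sg$ref, rs = rs, re = re,
      strand = sg$strand, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

make_read_alignments <- function(name, frag, segs, readLen, mm = FALSE) {
  if (!nrow(segs)) return(list())
  primary <- which.max(segs$qe - segs$qs)
  mmTags <- NULL
  if (mm) {
    cpg <- gregexpr("CG", frag, fixed = TRUE)[[1]]
    cpg <- cpg[cpg > 0]
    if (length(cpg)) {
      occ <- which(strsplit(frag, "", fixed = TRUE)[[1]] == "C")
      idx <- match(cpg, occ)
      deltas <- diff(c(0L, idx)) - 1L
      mmTags <- list(MM = paste0("C+m,", paste(deltas, collapse = ","), ";"),
                     ML = as.integer(180 + (seq_along(idx) * 37) %% 70))
    }
  }
  descr <- lapply(seq_len(nrow(segs)), function(i) {
    sg <- segs[i, ]
    len <- sg$qe - sg$qs
    if (sg$strand == "+") {
      pre <- sg$qs; post <- readLen - sg$qe
      seq <- frag; strand <- "+"
    } else {
      pre <- readLen - sg$qe; post <- sg$qs
      seq <- revcomp(frag); strand <- "-"
    }
    cigar <- paste0(if (pre > 0) paste0(pre, "S"), len, "M",
                    if (post > 0) paste0(post, "S"))
    list(refName = sg$refName, pos = sg$rs, strand = strand,
         cigar = cigar, seq = seq)
  })
  sa_of <- function(i) {
    others <- setdiff(seq_along(descr), i)
    if (!length(others)) return(NULL)
    paste(vapply(others, function(j) {
      d <- descr[[j]]
      sprintf("%s,%d,%s,%s,60,0;", d$refName, as.integer(d$pos + 1),
              d$strand, d$cigar)
    }, ""), collapse = "")
  }
  lapply(seq_along(descr), function(i) {
    d <- descr[[i]]
    supp <- i != primary
    tags <- list(NM = 0L)
    sa <- sa_of(i)
    if (!is.null(sa)) tags$SA <- sa
    if (!supp && !is.null(mmTags)) tags <- c(tags, mmTags)
    aligned_read(name, d$refName, d$pos, d$cigar, strand = d$strand,
                 flags = bitwOr(if (supp) 0x800L else 0L,
                                if (d$strand == "-") 0x10L else 0L),
                 mapq = 60L, seq = d$seq, tags = tags)
  })
}

# -- Synthetic synteny ---------------------------------------------------

#' Derive exact whole-genome alignments from the SV liftover map
#'
#' One PAF-style block per contiguous lifted segment of each derived
#' chromosome, with full-match CIGARs; strands reflect inversions. With
#' no SVs this is one full-length 100%-identity block per chromosome.
#'
#' @param sv Result of [apply_svs()].
#' @param genome The reference genome.
#' @return List of [synteny_block()]s (query = derived, target =
#'   reference).
#' @export
simulate_synteny <- function(sv, genome) {
  blocks <- list()
  for (cn in names(sv$segments)) {
    chain <- sv$segments[[cn]]
    qLen <- nchar(sv$seqs[[cn]])
    for (i in seq_len(nrow(chain))) {
      sg <- chain[i, ]
      if (!is.na(sg$ins)) next
      len <- sg$refEnd - sg$refStart
      blocks[[length(blocks) + 1]] <-
        synteny_block(qName = cn, qLen = qLen, qStart = sg$dStart,
                      qEnd = sg$dEnd, strand = sg$strand,
                      tName = sg$ref, tLen = nchar(genome$seqs[[sg$ref]]),
                      tStart = sg$refStart, tEnd = sg$refEnd,
                      score = len, cigar = paste0(len, "M"),
                      source = "paf")
    }
  }
  blocks
}

# -- Gene annotation fixtures -------------------------------------------

#' Generate random gene annotations for a genome
#'
#' Non-overlapping gene -> mRNA -> exon trees with deterministic names
#' (`GENE0001`, ...) and a small vocabulary of description words, for
#' feature-track and text-index fixtures.
#'
#' @param genome A genome (`list(name, seqs)`).
#' @param nPerChrom Genes per chromosome.
#' @param seed Integer seed.
#' @return List of [feature()]s.
#' @export
make_genes <- function(genome, nPerChrom = 10, seed = 1) {
  set.seed(seed)
  words <- c("kinase", "transporter", "receptor", "helicase", "ligase",
             "channel", "protease", "synthase")
  feats <- list(); g <- 0
  for (cn in names(genome$seqs)) {
    L <- nchar(genome$seqs[[cn]])
    slot <- floor(L / nPerChrom)
    for (i in seq_len(nPerChrom)) {
      g <- g + 1
      gs <- (i - 1) * slot + sample.int(max(1, slot %/% 4), 1)
      glen <- sample(200:max(300, slot %/% 2), 1)
      ge <- min(L, gs + glen)
      nm <- sprintf("GENE%04d", g)
      strand <- sample(c("+", "-"), 1)
      mid <- floor((gs + ge) / 2)
      exons <- list(
        feature(paste0(nm, ".t1.e1"), cn, gs, mid, strand, "exon"),
        feature(paste0(nm, ".t1.e2"), cn, min(mid + 10, ge), ge, strand,
                "exon"))
      tx <- feature(paste0(nm, ".t1"), cn, gs, ge, strand, "mRNA",
                    subfeatures = exons)
      feats[[g]] <- feature(nm, cn, gs, ge, strand, "gene", name = nm,
                            attributes = list(
                              description = sample(words, 2)),
                            subfeatures = list(tx))
    }
  }
  feats
}

# -- Preset bundles ------------------------------------------------------

#' Write a complete offline fixture bundle
#'
#' Generates a toy genome, engineered SVs, exact split reads, truth VCF,
#' synteny PAF, gene GFF3, a coverage BigWig and a ready-to-render JSON
#' config into a directory.
#'
#' Presets: `"sv-demo"` — two 100 kb chromosomes with two reciprocal
#' translocations, one inversion and one deletion, 1 kb reads at 8x
#' (the desk-scale stand-in for a rearranged cancer genome);
#' `"tiny"` — two 10 kb chromosomes, one translocation, 500 bp reads.
#'
#' @param dir Output directory (created).
#' @param preset `"sv-demo"` or `"tiny"`.
#' @param seed Integer seed governing all randomness.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
make_fixture_bundle <- function(dir, preset = c("sv-demo", "tiny"),
                                seed = 1) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "sv-demo") {
    genome <- make_genome(c(1e5, 1e5), seed = seed)
    specs <- list(
      sv_spec("translocation", "chr1", 30000, chrom2 = "chr2",
              pos2 = 40000),
      sv_spec("translocation", "chr1", 60000, chrom2 = "chr2",
              pos2 = 70000),
      sv_spec("inversion", "chr1", 10000, 15000),
      sv_spec("deletion", "chr2", 20000, 21000))
    readLen <- 1000; cov <- 8
  } else {
    genome <- make_genome(c(1e4, 1e4), seed = seed)
    specs <- list(sv_spec("translocation", "chr1", 4000, chrom2 = "chr2",
                          pos2 = 6000))
    readLen <- 500; cov <- 6
  }
  sv <- apply_svs(genome, specs)
  sim <- simulate_reads(sv, genome, readLenBp = readLen, coverage = cov,
                        seed = seed + 1)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    derived = file.path(dir, "derived.fa"),
    vcf = file.path(dir, "truth.vcf"),
    sam = file.path(dir, "reads.sam"),
    paf = file.path(dir, "synteny.paf"),
    gff = file.path(dir, "genes.gff3"),
    bigwig = file.path(dir, "coverage.bw"),
    config = file.path(dir, "config.json"))
  write_fasta(genome$seqs, paths$fasta)
  write_fasta(sv$seqs, paths$derived)
  write_truth_vcf(sv, genome, paths$vcf)
  asm <- assembly(genome$name,
                  data.frame(refName = names(genome$seqs),
                             length = nchar(genome$seqs)))
  write_sam(sim$reads, paths$sam, asm)
  write_paf(simulate_synteny(sv, genome), paths$paf)
  genes <- make_genes(genome, nPerChrom = 10, seed = seed + 2)
  write_gff3(genes, paths$gff)
  write_coverage_bigwig(sim$reads, asm, paths$bigwig)
  cfg <- list(
    formatVersion = 1,
    assemblies = list(
      list(name = "ref", fasta = "genome.fa"),
      list(name = "derived", fasta = "derived.fa")),
    tracks = list(
      list(trackId = "genes", type = "feature", assemblyNames = list("ref"),
           path = "genes.gff3"),
      list(trackId = "reads", type = "alignments",
           assemblyNames = list("ref"), path = "reads.sam"),
      list(trackId = "truth-sv", type = "variant",
           assemblyNames = list("ref"), path = "truth.vcf"),
      list(trackId = "coverage", type = "quantitative",
           assemblyNames = list("ref"), path = "coverage.bw"),
      list(trackId = "wga", type = "synteny",
           assemblyNames = list("ref", "derived"), path = "synteny.paf")))
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = genome, sv = sv, sim = sim, assembly = asm,
                 paths = paths))
}

write_coverage_bigwig <- function(reads, asm, path) {
  chroms <- character(); s1 <- numeric(); e1 <- numeric(); v <- numeric()
  for (cn in asm$sequences$refName) {
    len <- seq_length(asm, cn)
    cov <- compute_coverage(reads, region(cn, 0, len), binSizeBp = 100)
    nb <- length(cov$values)
    starts <- seq(0, by = 100, length.out = nb)
    chroms <- c(chroms, rep(cn, nb))
    s1 <- c(s1, starts + 1)
    e1 <- c(e1, pmin(len, starts + 100))
    v <- c(v, ifelse(is.na(cov$values), 0, cov$values))
  }
  gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(s1, e1), score = v,
    seqlengths = stats::setNames(asm$sequences$length,
                                 asm$sequences$refName))
  rtracklayer::export.bw(gr, path)
  invisible(path)
}
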