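# -- Unified feature model ----------------------------------------------

#' Create a feature record
#'
#' The unified annotation record all feature readers normalize into.
#' Coordinates are 0-based half-open.
#'
#' @param uniqueId Identifier unique within one track load.
#' @param refName Canonical sequence name.
#' @param start,end 0-based half-open bp interval.
#' @param strand One of `"+"`, `"-"`, `"none"`.
#' @param type Feature type (e.g. gene, mRNA, exon).
#' @param name Optional display name.
#' @param attributes Named list of character vectors.
#' @param subfeatures List of child `Feature`s.
#' @return An object of class `Feature`.
#' @export
feature <- function(uniqueId, refName, start, end, strand = "none",
                    type = "feature", name = NULL, attributes = list(),
                    subfeatures = list()) {
  stopifnot(start <= end, strand %in% c("+", "-", "none"))
  structure(list(uniqueId = as.character(uniqueId),
                 refName = as.character(refName),
                 start = as.numeric(start), end = as.numeric(end),
                 strand = strand, type = as.character(type),
                 name = if (is.null(name)) NULL else as.character(name),
                 attributes = attributes, subfeatures = subfeatures),
            class = "Feature")
}

#' @export
print.Feature <- function(x, ...) {
  cat(sprintf("<%s> %s %s:%d-%d (%s)%s\n", x$type,
              if (is.null(x$name)) x$uniqueId else x$name,
              x$refName, x$start, x$end, x$strand,
              if (length(x$subfeatures))
                paste0(" + ", length(x$subfeatures), " subfeature(s)") else ""))
  invisible(x)
}

overlaps_region <- function(start, end, region) {
  start < region$end & end > region$start
}

strand_chr <- function(s) {
  s <- as.character(s)
  ifelse(s %in% c("+", "-"), s, "none")
}

# -- GFF3 / GTF / BED ----------------------------------------------------

#' Read annotation features from GFF3, GTF or BED
#'
#' Parses with [rtracklayer::import()] and assembles parent/child rows
#' (GFF3 `Parent=`, GTF `gene_id`/`transcript_id`) into nested [feature()]
#' trees. Coordinates are converted to 0-based half-open. When `region` is
#' given only features overlapping it (`start < regionEnd && end >
#' regionStart`) are returned; bgzipped files with a `.tbi` index are
#' queried through tabix, others are scanned and filtered.
#'
#' GFF3 features naming several parents are duplicated under each parent
#' (with a message): the tree model stays simple. GTF assembly is limited
#' to gene/transcript/exon/CDS rows, which is what a feature track draws.
#'
#' @param path File path (plain or bgzip+tabix).
#' @param format One of `"gff3"`, `"gtf"`, `"bed"`; default guessed from
#'   the file extension.
#' @param region Optional [region()] restricting the query.
#' @return List of top-level `Feature` objects.
#' @export
read_features <- function(path, format = NULL, region = NULL) {
  if (is.null(format)) {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- switch(tolower(tools::file_ext(base)),
                     gff = , gff3 = "gff3", gtf = "gtf", bed = "bed",
                     stop("unknown format for '", path, "'"))
  }
  format <- match.arg(format, c("gff3", "gtf", "bed"))
  tbi <- paste0(path, ".tbi")
  use_tabix <- grepl("\\.(gz|bgz)$", path) && file.exists(tbi) &&
    !is.null(region)
  gr <- tryCatch({
    if (use_tabix) {
      which <- GenomicRanges::GRanges(region$refName,
                                      IRanges::IRanges(region$start + 1,
                                                       region$end))
      # rtracklayer's tabix path emits deprecation/rewind chatter
      suppressWarnings(
        rtracklayer::import(Rsamtools::TabixFile(path), format = format,
                            which = which))
    } else {
      rtracklayer::import(path, format = format)
    }
  }, error = function(e) stop("malformed ", format, " file '", path, "': ",
                              conditionMessage(e)))
  if (length(gr) == 0) return(list())
  df <- data.frame(refName = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = strand_chr(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  feats <- switch(format,
                  gff3 = assemble_gff3(df, mc),
                  gtf = assemble_gtf(df, mc),
                  bed = assemble_bed(df, mc))
  if (!is.null(region)) {
    keep <- vapply(feats, function(f)
      f$refName == region$refName && overlaps_region(f$start, f$end, region),
      TRUE)
    feats <- feats[keep]
  }
  feats
}

attr_list <- function(mc, i, drop = character()) {
  out <- list()
  for (nm in setdiff(names(mc), c("type", "phase", drop))) {
    v <- mc[[nm]][i]
    if (methods::is(v, "List") || is.list(v)) v <- unlist(v[[1]])
    v <- as.character(v)
    v <- v[!is.na(v)]
    if (length(v)) out[[nm]] <- v
  }
  out
}

assemble_gff3 <- function(df, mc) {
  n <- nrow(df)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA, n)
  auto <- paste0("feat", seq_len(n))
  uid <- ifelse(is.na(ids), auto, ids)
  if (anyDuplicated(uid)) uid <- make.unique(uid, sep = "#")
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- if ("Name" %in% names(mc)) as.character(mc$Name[i]) else NA
    nodes[[i]] <- feature(uid[i], df$refName[i], df$start[i], df$end[i],
                          df$strand[i], as.character(mc$type[i]),
                          name = if (is.na(nm)) NULL else nm,
                          attributes = attr_list(mc, i, c("Parent", "source",
                                                          "score")))
  }
  parents <- if ("Parent" %in% names(mc)) mc$Parent else NULL
  children <- integer(0)
  kids_of <- rep(list(integer(0)), n)
  if (!is.null(parents)) {
    id_row <- stats::setNames(seq_len(n), ids)
    for (i in seq_len(n)) {
      ps <- unlist(parents[[i]])
      ps <- ps[!is.na(ps)]
      if (!length(ps)) next
      if (length(ps) > 1)
        message("note: feature ", uid[i], " duplicated under ",
                length(ps), " parents")
      hit <- FALSE
      for (p in ps) {
        j <- id_row[p]
        if (!is.na(j)) { kids_of[[j]] <- c(kids_of[[j]], i); hit <- TRUE }
      }
      if (hit) children <- c(children, i)
    }
  }
  build <- function(i) {
    f <- nodes[[i]]
    if (length(kids_of[[i]])) {
      f$subfeatures <- lapply(kids_of[[i]], build)
      for (s in f$subfeatures)
        if (s$start < f$start || s$end > f$end)
          message("note: subfeature ", s$uniqueId,
                  " extends outside parent ", f$uniqueId)
    }
    f
  }
  lapply(setdiff(seq_len(n), unique(children)), build)
}

assemble_gtf <- function(df, mc) {
  type <- as.character(mc$type)
  keep <- type %in% c("gene", "transcript", "mRNA", "exon", "CDS")
  gene_id <- as.character(mc$gene_id)
  tx_id <- if ("transcript_id" %in% names(mc))
    as.character(mc$transcript_id) else rep(NA, nrow(df))
  out <- list()
  for (g in unique(gene_id[keep])) {
    rows <- which(keep & gene_id == g)
    grow <- rows[type[rows] == "gene"]
    gstart <- min(df$start[rows]); gend <- max(df$end[rows])
    if (length(grow)) { gstart <- df$start[grow[1]]; gend <- df$end[grow[1]] }
    gf <- feature(g, df$refName[rows[1]], gstart, gend,
                  df$strand[rows[1]], "gene", name = g)
    for (t in unique(stats::na.omit(tx_id[rows]))) {
      trows <- rows[!is.na(tx_id[rows]) & tx_id[rows] == t]
      xrow <- trows[type[trows] %in% c("transcript", "mRNA")]
      tstart <- min(df$start[trows]); tend <- max(df$end[trows])
      if (length(xrow)) { tstart <- df$start[xrow[1]]; tend <- df$end[xrow[1]] }
      tf <- feature(t, df$refName[trows[1]], tstart, tend,
                    df$strand[trows[1]], "mRNA", name = t,
                    attributes = list(gene_id = g))
      leaves <- trows[type[trows] %in% c("exon", "CDS")]
      leaves <- leaves[order(df$start[leaves])]
      tf$subfeatures <- lapply(seq_along(leaves), function(k) {
        i <- leaves[k]
        feature(paste0(t, ":", type[i], ":", k), df$refName[i],
                df$start[i], df$end[i], df$strand[i], type[i])
      })
      gf$subfeatures <- c(gf$subfeatures, list(tf))
    }
    out <- c(out, list(gf))
  }
  out
}

assemble_bed <- function(df, mc) {
  n <- nrow(df)
  nm <- if ("name" %in% names(mc)) as.character(mc$name) else rep(NA, n)
  lapply(seq_len(n), function(i) {
    feature(if (is.na(nm[i]) || nm[i] == ".") paste0("bed", i) else nm[i],
            df$refName[i], df$start[i], df$end[i], df$strand[i], "region",
            name = if (is.na(nm[i])) NULL else nm[i],
            attributes = attr_list(mc, i, c("name")))
  })
}

#' Write features to a GFF3 file
#'
#' Inverse of [read_features()] for the GFF3 format, used for round trips
#' and fixture construction.
#'
#' @param features List of [feature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  esc <- function(x) gsub("([;=,&\t])", "", x)
  emit <- function(f, parent = NULL) {
    attrs <- c(paste0("ID=", esc(f$uniqueId)),
               if (!is.null(f$name)) paste0("Name=", esc(f$name)),
               if (!is.null(parent)) paste0("Parent=", esc(parent)),
               vapply(names(f$attributes), function(k)
                 paste0(k, "=", paste(esc(f$attributes[[k]]), collapse = ",")),
                 ""))
    writeLines(paste(f$refName, "genomesketch", f$type, f$start + 1, f$end,
                     ".", if (f$strand == "none") "." else f$strand, ".",
                     paste(attrs, collapse = ";"), sep = "\t"), con)
    for (s in f$subfeatures) emit(s, f$uniqueId)
  }
  for (f in features) emit(f)
  invisible(path)
}

# -- VCF -----------------------------------------------------------------

#' Create a variant feature
#'
#' A [feature()] carrying VCF fields: alleles, quality, filter, INFO and
#' per-sample genotypes. Breakend and symbolic ALT alleles are preserved
#' verbatim for the SV toolkit.
#'
#' @inheritParams feature
#' @param ref Reference allele.
#' @param alts Character vector of ALT alleles (verbatim).
#' @param qual QUAL value (`NA` for missing).
#' @param filter FILTER string.
#' @param info Named list of INFO values (flags stored as `TRUE`).
#' @param samples Ordered character vector of sample names.
#' @param genotypes List (one per sample, in `samples` order) of named
#'   lists keyed by FORMAT field.
#' @return An object of class `c("VariantFeature", "Feature")`.
#' @export
variant_feature <- function(uniqueId, refName, start, end, ref, alts,
                            qual = NA_real_, filter = ".", info = list(),
                            samples = character(), genotypes = list(),
                            name = NULL) {
  f <- feature(uniqueId, refName, start, end, type = "variant", name = name)
  f$ref <- ref; f$alts <- alts; f$qual <- qual; f$filter <- filter
  f$info <- info; f$samples <- samples; f$genotypes <- genotypes
  class(f) <- c("VariantFeature", "Feature")
  f
}

parse_vcf_info <- function(s) {
  if (s == "." || s == "") return(list())
  out <- list()
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    else out[[kv]] <- TRUE
  }
  out
}

#' Read variant records from a VCF file
#'
#' A streaming VCF 4.x reader that keeps every sample's genotypes (ordered
#' as in the header), all INFO keys, and symbolic/breakend ALT strings
#' verbatim. `end` is `start + nchar(ref)` for sequence alleles; for
#' symbolic alleles the INFO `END` key is used when present.
#'
#' @param path VCF path, plain text or bgzipped (`.gz`); a `.tbi` index is
#'   used for region queries when present.
#' @param region Optional [region()]; records overlapping it are returned.
#' @return List of [variant_feature()] objects.
#' @export
read_variants <- function(path, region = NULL) {
  tbi <- paste0(path, ".tbi")
  if (!is.null(region) && grepl("\\.(gz|bgz)$", path) && file.exists(tbi)) {
    which <- GenomicRanges::GRanges(region$refName,
                                    IRanges::IRanges(region$start + 1,
                                                     region$end))
    body <- unlist(Rsamtools::scanTabix(path, param = which), use.names = FALSE)
    hdr <- Rsamtools::headerTabix(path)$header
    lines <- c(hdr, body)
    region_done <- TRUE
  } else {
    con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path) else file(path)
    lines <- readLines(con)
    close(con)
    region_done <- FALSE
  }
  hdr_i <- grep("^#CHROM\t", lines)
  if (length(hdr_i) != 1)
    stop("VCF '", path, "': missing #CHROM header line")
  hcols <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  samples <- if (length(hcols) > 9) hcols[-(1:9)] else character()
  body <- lines[seq_along(lines) > hdr_i & !startsWith(lines, "#")]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("VCF '", path, "' record ", k, ": fewer than 8 columns")
    if (length(samples) && length(f) != 9 + length(samples))
      stop("VCF '", path, "' record ", k, ": column count does not match ",
           length(samples), "-sample header")
    pos <- as.numeric(f[2]); ref <- f[4]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    info <- parse_vcf_info(f[8])
    start <- pos - 1
    symbolic <- any(grepl("^<.*>$", alts))
    # INFO END sets the record span for symbolic alleles, except when it
    # refers to another chromosome (CHR2, e.g. Sniffles <TRA> records)
    end <- start + nchar(ref)
    if (symbolic && !is.null(info$END) &&
        (is.null(info$CHR2) || info$CHR2 == f[1]) &&
        as.numeric(info$END) >= start)
      end <- as.numeric(info$END)
    gts <- list()
    if (length(samples)) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gts <- lapply(seq_along(samples), function(s) {
        v <- strsplit(f[9 + s], ":", fixed = TRUE)[[1]]
        stats::setNames(as.list(v), fmt[seq_along(v)])
      })
    }
    id <- if (f[3] == ".") paste0(f[1], ":", f[2], ":", k) else f[3]
    out[[k]] <- variant_feature(id, f[1], start, end, ref, alts,
                                qual = suppressWarnings(as.numeric(f[6])),
                                filter = f[7], info = info,
                                samples = samples, genotypes = gts)
  }
  if (!is.null(region) && !region_done) {
    keep <- vapply(out, function(v)
      v$refName == region$refName && overlaps_region(v$start, v$end, region),
      TRUE)
    out <- out[keep]
  }
  out
}

# -- Quantitative signal -------------------------------------------------

#' Create a quantitative signal
#'
#' A binned signal over a region; `values[i]` covers bases
#' `[start + (i-1)*binSizeBp, start + i*binSizeBp)`. `NA` marks missing.
#'
#' @param region A [region()] (or `NULL` for free-standing signals such as
#'   per-sequence GC content).
#' @param binSizeBp Bin width in bp.
#' @param values Numeric vector, `ceiling(regionWidth / binSizeBp)` long.
#' @return An object of class `QuantSignal`.
#' @export
quant_signal <- function(region, binSizeBp, values) {
  if (!is.null(region)) {
    stopifnot(inherits(region, "Region"))
    nb <- ceiling(region_width(region) / binSizeBp)
    if (length(values) != nb)
      stop("QuantSignal needs ", nb, " values, got ", length(values))
  }
  structure(list(region = region, binSizeBp = as.numeric(binSizeBp),
                 values = as.numeric(values)),
            class = "QuantSignal")
}

bin_means <- function(perBase, binSizeBp) {
  n <- length(perBase)
  nb <- ceiling(n / binSizeBp)
  vapply(seq_len(nb), function(b) {
    v <- perBase[(floor((b - 1) * binSizeBp) + 1):min(n, floor(b * binSizeBp))]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
}

#' Read a binned signal from a BigWig file
#'
#' Computes, per bin, the mean of the BigWig values covering its bases;
#' bins with no covering value are `NA`.
#'
#' @param path BigWig path.
#' @param region A [region()] within the file's declared chrom sizes.
#' @param binSizeBp Bin width in bp.
#' @return A [quant_signal()].
#' @export
read_quant <- function(path, region, binSizeBp = 1) {
  bwf <- rtracklayer::BigWigFile(path)
  si <- GenomeInfoDb::seqinfo(bwf)
  if (!region$refName %in% GenomeInfoDb::seqnames(si))
    stop("unknown chrom '", region$refName, "' in BigWig '", path, "'")
  chromLen <- GenomeInfoDb::seqlengths(si)[[region$refName]]
  if (region$end > chromLen)
    stop("region end ", region$end, " beyond chrom length ", chromLen)
  which <- GenomicRanges::GRanges(region$refName,
                                  IRanges::IRanges(region$start + 1,
                                                   region$end))
  gr <- rtracklayer::import(bwf, which = which)
  perBase <- rep(NA_real_, region_width(region))
  if (length(gr)) {
    s <- pmax(GenomicRanges::start(gr) - 1, region$start) - region$start
    e <- pmin(GenomicRanges::end(gr), region$end) - region$start
    v <- gr$score
    for (i in seq_along(v)) perBase[(s[i] + 1):e[i]] <- v[i]
  }
  quant_signal(region, binSizeBp, bin_means(perBase, binSizeBp))
}

# -- Sequence-derived tracks ---------------------------------------------

#' GC content along a sequence
#'
#' Fraction of G/C per window (case-insensitive); `N` and other ambiguity
#' codes are excluded from the denominator. A window with no unambiguous
#' base yields `NA`.
#'
#' @param sequence DNA sequence text.
#' @param windowBp Window width, >= 1.
#' @param stepBp Step between window starts; defaults to `windowBp`
#'   (non-overlapping windows).
#' @return A [quant_signal()] (region-free) with one value per window.
#' @export
gc_content <- function(sequence, windowBp, stepBp = windowBp) {
  stopifnot(windowBp >= 1, stepBp >= 1)
  n <- nchar(sequence)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  isGC <- chars %in% c("G", "C")
  isAT <- chars %in% c("A", "T")
  starts <- seq(1, max(1, n - windowBp + 1), by = stepBp)
  if (n < windowBp) starts <- 1
  vals <- vapply(starts, function(s) {
    e <- min(n, s + windowBp - 1)
    gc <- sum(isGC[s:e]); at <- sum(isAT[s:e])
    if (gc + at == 0) NA_real_ else gc / (gc + at)
  }, 0)
  quant_signal(NULL, stepBp, vals)
}

#' Three-frame translation of a DNA sequence
#'
#' Translates frames 0, 1, 2 of the given (forward) strand with the
#' standard genetic code. IUPAC ambiguity codes translate to `X` unless the
#' codon is unambiguous; the trailing partial codon is dropped.
#'
#' @param sequence DNA sequence text.
#' @return Character vector of 3 peptides (frames 0, 1, 2).
#' @export
three_frame_translation <- function(sequence) {
  vapply(0:2, function(off) {
    s <- substr(sequence, off + 1, nchar(sequence))
    keep <- nchar(s) - nchar(s) %% 3
    if (keep == 0) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1, keep)),
      if.fuzzy.codon = "solve"))
  }, "")
}
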