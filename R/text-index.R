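# -- trix-style text index ----------------------------------------------
#
# Two-file prefix index: .ix holds sorted "term docId,wordPos ..." lines,
# .ixx holds a sparse list of (5-char prefix, byte offset of an ix line)
# so a prefix search can seek instead of scanning the whole file. The
# dialect here is self-defined (versioned below); byte compatibility with
# the UCSC ixIxx output is not asserted.

TRIX_VERSION <- "genomesketch-trix 1"
TRIX_STRIDE <- 64L      # one .ixx entry every this many .ix lines
TRIX_PREFIX_WIDTH <- 5L

trix_tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a trix-style index over documents
#'
#' Text is tokenized on non-alphanumerics and lowercased. Each `.ix` line
#' is a term followed by space-separated `docId,wordPos` hits sorted by
#' docId then position; terms are unique and strictly sorted. Every 64th
#' line contributes an `.ixx` entry: the first 5 characters of its term
#' (right-padded with spaces) plus the 10-digit lowercase-hex byte
#' offset of that line. Both constants are arguments.
#'
#' @param docs Data frame with columns `docId` (no whitespace allowed)
#'   and `text`.
#' @param stride `.ixx` sampling stride (lines).
#' @param prefixWidth `.ixx` prefix width (characters).
#' @return An object of class `TrixIndex`: `ixLines`, `terms`,
#'   `offsets` (0-based byte offset per line), `ixxEntries` (data frame
#'   `prefix`, `offset`), `stride`, `prefixWidth`.
#' @export
build_index <- function(docs, stride = TRIX_STRIDE,
                        prefixWidth = TRIX_PREFIX_WIDTH) {
  stopifnot(is.data.frame(docs), all(c("docId", "text") %in% names(docs)))
  if (any(grepl("[[:space:]]", docs$docId)))
    stop("docIds must not contain whitespace")
  hits <- list()
  for (i in seq_len(nrow(docs))) {
    toks <- trix_tokenize(docs$text[i])
    for (p in seq_along(toks)) {
      tm <- toks[p]
      hits[[tm]] <- c(hits[[tm]], paste0(docs$docId[i], ",", p - 1L))
    }
  }
  terms <- if (length(hits)) sort(names(hits), method = "radix")
           else character()
  ixLines <- vapply(terms, function(tm) {
    h <- hits[[tm]]
    ids <- sub(",.*$", "", h)
    pos <- as.integer(sub("^.*,", "", h))
    o <- order(ids, pos, method = "radix")
    paste(tm, paste(h[o], collapse = " "))
  }, "", USE.NAMES = FALSE)
  nb <- nchar(ixLines, type = "bytes") + 1L  # trailing newline
  offsets <- cumsum(c(0L, nb[-length(nb)]))
  if (!length(ixLines)) offsets <- integer()
  sel <- if (length(ixLines)) seq(1L, length(ixLines), by = stride)
         else integer()
  ixx <- data.frame(
    prefix = formatC(substr(terms[sel], 1, prefixWidth),
                     width = prefixWidth, flag = "-"),
    offset = offsets[sel], stringsAsFactors = FALSE)
  structure(list(ixLines = ixLines, terms = terms, offsets = offsets,
                 ixxEntries = ixx, stride = stride,
                 prefixWidth = prefixWidth),
            class = "TrixIndex")
}

#' Write a trix index to `.ix`/`.ixx` files
#'
#' The `.ixx` starts with a `#`-prefixed dialect version line (ignored
#' on read); offsets refer to the `.ix` file bytes.
#'
#' @param index A [build_index()] result.
#' @param prefix Output path prefix (writes `prefix.ix`, `prefix.ixx`).
#' @return Character vector of the two paths, invisibly.
#' @export
write_trix <- function(index, prefix) {
  ix <- paste0(prefix, ".ix"); ixx <- paste0(prefix, ".ixx")
  con <- file(ix, "wb")
  if (length(index$ixLines))
    writeBin(charToRaw(paste0(paste(index$ixLines, collapse = "\n"), "\n")),
             con)
  close(con)
  lines <- paste0(index$ixxEntries$prefix,
                  sprintf("%010x", index$ixxEntries$offset))
  writeLines(c(paste0("# ", TRIX_VERSION), lines), ixx)
  invisible(c(ix, ixx))
}

#' Read a trix index from `.ix`/`.ixx` files
#'
#' @param prefix Path prefix used at [write_trix()] time.
#' @return A `TrixIndex`.
#' @export
read_trix <- function(prefix) {
  ixLines <- readLines(paste0(prefix, ".ix"))
  ixxLines <- readLines(paste0(prefix, ".ixx"))
  ixxLines <- ixxLines[!startsWith(ixxLines, "#")]
  pw <- TRIX_PREFIX_WIDTH
  ixx <- data.frame(
    prefix = substr(ixxLines, 1, pw),
    offset = strtoi(substr(ixxLines, pw + 1, pw + 10), base = 16L),
    stringsAsFactors = FALSE)
  nb <- nchar(ixLines, type = "bytes") + 1L
  structure(list(ixLines = ixLines,
                 terms = sub(" .*$", "", ixLines),
                 offsets = cumsum(c(0L, nb[-length(nb)])),
                 ixxEntries = ixx, stride = TRIX_STRIDE, prefixWidth = pw),
            class = "TrixIndex")
}

#' Prefix search in a trix index
#'
#' Finds every document with a term starting with `prefix`
#' (case-insensitive): a binary search over the `.ixx` entries picks the
#' scan start, then a linear scan of `.ix` lines collects hits until the
#' terms sort past the prefix. Exact-term matches come first, then
#' prefix matches, each group sorted by docId.
#'
#' @param index A `TrixIndex`.
#' @param prefix Non-empty search string.
#' @param limit Maximum number of docIds to return.
#' @return Character vector of docIds.
#' @export
search_index <- function(index, prefix, limit = 100L) {
  stopifnot(nzchar(prefix))
  p <- tolower(prefix)
  if (!length(index$ixLines)) return(character())
  # binary search: last ixx entry whose (trimmed) prefix <= p
  ent <- trimws(index$ixxEntries$prefix, which = "right")
  lo <- 1L; hi <- length(ent); startOff <- 0L
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (ent[mid] <= p) {
      startOff <- index$ixxEntries$offset[mid]
      lo <- mid + 1L
    } else hi <- mid - 1L
  }
  startLine <- match(startOff, index$offsets)
  if (is.na(startLine)) startLine <- 1L
  exact <- character(); part <- character()
  for (i in startLine:length(index$ixLines)) {
    tm <- index$terms[i]
    if (startsWith(tm, p)) {
      ids <- sub(",[0-9]+$", "",
                 strsplit(index$ixLines[i], " ", fixed = TRUE)[[1]][-1])
      if (tm == p) exact <- c(exact, ids) else part <- c(part, ids)
    } else if (tm > p) break
  }
  out <- c(sort(unique(exact), method = "radix"),
           setdiff(sort(unique(part), method = "radix"), exact))
  utils::head(out, limit)
}

# -- Track indexing ------------------------------------------------------

collect_feature_docs <- function(feats, fields, trackId) {
  rows <- list()
  walk <- function(f) {
    vals <- character()
    for (fd in fields) {
      v <- if (fd == "Name") f$name
           else if (fd == "ID") f$uniqueId
           else f$attributes[[fd]]
      if (!is.null(v)) vals <- c(vals, v)
    }
    if (length(vals)) {
      display <- if (!is.null(f$name)) f$name else f$uniqueId
      docId <- paste0(f$refName, ":", f$start, "-", f$end, "|", trackId,
                      "|", display)
      docId <- gsub("[[:space:]]+", "_", docId)
      rows[[length(rows) + 1]] <<- data.frame(
        docId = docId, text = paste(vals, collapse = " "),
        stringsAsFactors = FALSE)
    }
    for (s in f$subfeatures) walk(s)
  }
  for (f in feats) walk(f)
  if (!length(rows)) data.frame(docId = character(), text = character())
  else do.call(rbind, rows)
}

#' Index feature names across annotation tracks
#'
#' Builds per-track (or one aggregate) trix indexes over the requested
#' attribute fields of GFF3/GTF/BED/VCF tracks. Document ids encode the
#' hit location as `refName:start-end|trackId|displayName`, so a search
#' resolves straight to a navigable location via [parse_trix_docid()].
#' Features missing every requested field are skipped.
#'
#' @param trackFiles Character vector of annotation file paths.
#' @param fields Attribute names to index (default `Name`, `ID`,
#'   `description`, `Note`, `gene_name`).
#' @param aggregate Build one combined index instead of per-track ones.
#' @return A `TrixIndex`, or a named list of them when
#'   `aggregate = FALSE` and several tracks are given.
#' @export
index_tracks <- function(trackFiles,
                         fields = c("Name", "ID", "description", "Note",
                                    "gene_name"),
                         aggregate = FALSE) {
  docs <- list()
  for (path in trackFiles) {
    trackId <- sub("\\.(gff3?|gtf|bed|vcf)(\\.gz)?$", "", basename(path))
    if (grepl("\\.vcf(\\.gz)?$", path)) {
      vars <- read_variants(path)
      rows <- lapply(vars, function(v) {
        docId <- gsub("[[:space:]]+", "_",
                      paste0(v$refName, ":", v$start, "-", v$end, "|",
                             trackId, "|", v$uniqueId))
        data.frame(docId = docId, text = v$uniqueId,
                   stringsAsFactors = FALSE)
      })
      docs[[trackId]] <- if (length(rows)) do.call(rbind, rows)
        else data.frame(docId = character(), text = character())
    } else {
      feats <- read_features(path)
      docs[[trackId]] <- collect_feature_docs(feats, fields, trackId)
    }
  }
  if (aggregate || length(docs) == 1) {
    build_index(do.call(rbind, unname(docs)))
  } else {
    lapply(docs, build_index)
  }
}

#' Decode a trix document id into its location
#'
#' @param docId A docId produced by [index_tracks()].
#' @return List with `refName`, `start`, `end`, `trackId`, `name`.
#' @export
parse_trix_docid <- function(docId) {
  parts <- strsplit(docId, "|", fixed = TRUE)[[1]]
  loc <- regmatches(parts[1],
                    regexec("^(.+):([0-9]+)-([0-9]+)$", parts[1]))[[1]]
  list(refName = loc[2], start = as.numeric(loc[3]),
       end = as.numeric(loc[4]), trackId = parts[2], name = parts[3])
}
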