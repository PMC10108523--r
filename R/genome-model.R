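# -- Assembly ------------------------------------------------------------

#' Create an assembly
#'
#' An assembly names an ordered set of reference sequences, an alias map for
#' chromosome names that are to be treated as identical (e.g. `"1"` and
#' `"chr1"`), and optional cytogenetic bands used to draw ideogram overviews.
#'
#' @param name Assembly name.
#' @param sequences Data frame with columns `refName` (character) and
#'   `length` (integer bp), in display order.
#' @param aliases Named character vector mapping alias -> canonical refName.
#'   Matching is exact and case-sensitive.
#' @param cytobands Optional data frame with columns `refName`, `start`,
#'   `end` (0-based half-open bp), `bandName`, `stain` (gieStain class).
#' @return An object of class `Assembly`.
#' @export
#' @examples
#' asm <- assembly("toy", data.frame(refName = "chr1", length = 1000L),
#'                 aliases = c("1" = "chr1"))
#' canonical_refname("1", asm)
assembly <- function(name, sequences, aliases = character(), cytobands = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.data.frame(sequences),
            all(c("refName", "length") %in% names(sequences)))
  sequences$refName <- as.character(sequences$refName)
  sequences$length <- as.numeric(sequences$length)
  if (anyDuplicated(sequences$refName))
    stop("duplicate canonical refName in assembly '", name, "'")
  if (any(sequences$length < 0))
    stop("negative sequence length in assembly '", name, "'")
  aliases <- unlist(aliases)
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(names(aliases) == ""))
      stop("aliases must be a named vector (alias -> canonical)")
    bad <- setdiff(unname(aliases), sequences$refName)
    if (length(bad))
      stop("alias target(s) not in assembly: ", paste(bad, collapse = ", "))
    clash <- intersect(names(aliases),
                       setdiff(sequences$refName, unname(aliases[names(aliases)])))
    clash <- clash[aliases[clash] != clash]
    if (length(clash))
      stop("alias equals a different canonical name: ",
           paste(clash, collapse = ", "))
  }
  if (!is.null(cytobands)) {
    stopifnot(all(c("refName", "start", "end", "bandName", "stain") %in%
                    names(cytobands)))
    len <- stats::setNames(sequences$length, sequences$refName)
    if (any(!cytobands$refName %in% sequences$refName))
      stop("cytoband refName not in assembly")
    if (any(cytobands$start < 0 | cytobands$end > len[cytobands$refName]))
      stop("cytoband interval outside its sequence")
  }
  structure(list(name = name, sequences = sequences,
                 aliases = aliases, cytobands = cytobands),
            class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat("Assembly '", x$name, "': ", nrow(x$sequences), " sequence(s), ",
      length(x$aliases), " alias(es)",
      if (!is.null(x$cytobands)) paste0(", ", nrow(x$cytobands), " cytoband(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Resolve a sequence name to its canonical form
#'
#' Canonical names resolve to themselves; aliases resolve through the
#' assembly's alias map. Matching is exact (case-sensitive) — no implicit
#' "chr" stripping.
#'
#' @param name Query sequence name.
#' @param assembly An [assembly()].
#' @return The canonical refName.
#' @export
canonical_refname <- function(name, assembly) {
  stopifnot(inherits(assembly, "Assembly"))
  if (name %in% assembly$sequences$refName) return(name)
  if (name %in% names(assembly$aliases))
    return(unname(assembly$aliases[[name]]))
  stop("unknown sequence name '", name, "' in assembly '", assembly$name, "'")
}

seq_length <- function(assembly, refName) {
  i <- match(refName, assembly$sequences$refName)
  if (is.na(i)) stop("unknown refName '", refName, "'")
  assembly$sequences$length[i]
}

#' Load an assembly from FASTA/fai plus optional alias and cytoband files
#'
#' Sequence names and lengths come from the `.fai` index (created with
#' [Rsamtools::indexFa()] if absent). The alias file holds one line per
#' sequence: the canonical name followed by tab-separated aliases. The
#' cytoband file is UCSC `cytoBand.txt` format (chrom, start, end, name,
#' gieStain; 0-based half-open).
#'
#' @param fasta Path to a FASTA file (a sibling `.fai` is used or created).
#' @param aliases Optional path to an alias text file.
#' @param cytobands Optional path to a UCSC cytoband file.
#' @param name Assembly name; defaults to the FASTA basename.
#' @return An [assembly()].
#' @export
read_assembly <- function(fasta, aliases = NULL, cytobands = NULL,
                          name = NULL) {
  fai <- paste0(fasta, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(fasta)
  idx <- utils::read.table(fai, sep = "\t", stringsAsFactors = FALSE)
  seqs <- data.frame(refName = idx[[1]], length = idx[[2]],
                     stringsAsFactors = FALSE)
  amap <- character()
  if (!is.null(aliases) && file.exists(aliases)) {
    for (ln in readLines(aliases)) {
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) >= 2)
        amap[f[-1]] <- f[1]
    }
  }
  cyto <- NULL
  if (!is.null(cytobands) && file.exists(cytobands)) {
    cy <- utils::read.table(cytobands, sep = "\t", stringsAsFactors = FALSE)
    cyto <- data.frame(refName = cy[[1]], start = cy[[2]], end = cy[[3]],
                       bandName = cy[[4]], stain = cy[[5]],
                       stringsAsFactors = FALSE)
  }
  if (is.null(name))
    name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(fasta))
  assembly(name, seqs, amap, cyto)
}

# -- Regions -------------------------------------------------------------

#' Create a region
#'
#' Coordinates are 0-based half-open throughout the package; 1-based
#' inclusive appears only in locstrings and VCF I/O.
#'
#' @param refName Canonical sequence name.
#' @param start,end 0-based half-open interval, `0 <= start <= end`.
#' @param reversed Display the region right-to-left.
#' @return An object of class `Region`.
#' @export
region <- function(refName, start, end, reversed = FALSE) {
  stopifnot(length(refName) == 1L, start >= 0, start <= end)
  structure(list(refName = as.character(refName), start = as.numeric(start),
                 end = as.numeric(end), reversed = isTRUE(reversed)),
            class = "Region")
}

#' @export
print.Region <- function(x, ...) {
  cat(sprintf("%s:%s-%s%s\n", x$refName, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), if (x$reversed) " [rev]" else ""))
  invisible(x)
}

region_width <- function(r) r$end - r$start

#' Create an ordered, possibly discontiguous set of displayed regions
#'
#' The view coordinate system every linear renderer draws against. Order is
#' significant; the same refName may appear more than once (e.g. chr3 and
#' chr4 side by side, or a region shown twice). Overlapping duplicates are
#' permitted and flagged with a message.
#'
#' @param regions List of [region()] objects.
#' @param assembly Optional [assembly()]; when given, every region is
#'   validated against its sequence length.
#' @param interRegionPadding Pixel gap inserted at each region boundary
#'   (default 2).
#' @return An object of class `DisplayedRegions`.
#' @export
displayed_regions <- function(regions, assembly = NULL,
                              interRegionPadding = 2) {
  stopifnot(is.list(regions), all(vapply(regions, inherits, TRUE, "Region")))
  if (!is.null(assembly)) {
    for (r in regions) {
      n <- canonical_refname(r$refName, assembly)
      if (r$end > seq_length(assembly, n))
        stop("region ", r$refName, ":", r$start, "-", r$end,
             " exceeds sequence length")
    }
  }
  if (length(regions) > 1) {
    key <- vapply(regions, function(r) r$refName, "")
    for (nm in unique(key[duplicated(key)])) {
      rs <- regions[key == nm]
      ivs <- cbind(vapply(rs, `[[`, 0, "start"), vapply(rs, `[[`, 0, "end"))
      o <- order(ivs[, 1])
      if (any(ivs[o, 1][-1] < ivs[o, 2][-nrow(ivs)]))
        message("note: displayed regions overlap on ", nm)
    }
  }
  structure(list(regions = regions,
                 interRegionPadding = as.numeric(interRegionPadding)),
            class = "DisplayedRegions")
}

#' Total displayed length in bp
#'
#' @param displayed A [displayed_regions()] object.
#' @return Sum of region widths in bp.
#' @export
total_bp <- function(displayed) {
  stopifnot(inherits(displayed, "DisplayedRegions"))
  sum(vapply(displayed$regions, region_width, 0))
}

#' Total view width in px at a zoom level
#'
#' @inheritParams total_bp
#' @param bpPerPx Zoom level (bases per horizontal pixel), > 0.
#' @return Width in px including inter-region padding.
#' @export
view_width_px <- function(displayed, bpPerPx) {
  n <- length(displayed$regions)
  total_bp(displayed) / bpPerPx + max(0L, n - 1L) * displayed$interRegionPadding
}

#' Map a genomic coordinate to a horizontal pixel offset
#'
#' The offset is the cumulative width of preceding regions (plus one
#' inter-region padding per crossed boundary) plus the within-region offset
#' divided by `bpPerPx`. Within a reversed region the within-region offset
#' is mirrored: base `end - 1 - coord` positions from the region's left
#' edge. A coordinate falling in no displayed region yields `NA` (absence
#' is a value, not an error).
#'
#' When the same coordinate is displayed more than once, the first matching
#' region in display order wins.
#'
#' @param refName Canonical sequence name.
#' @param coord 0-based bp coordinate.
#' @param displayed A [displayed_regions()] object.
#' @param bpPerPx Zoom level, > 0.
#' @return Pixel offset (numeric) or `NA_real_`.
#' @export
bp_to_px <- function(refName, coord, displayed, bpPerPx) {
  stopifnot(bpPerPx > 0)
  off <- 0
  pad <- displayed$interRegionPadding
  for (i in seq_along(displayed$regions)) {
    r <- displayed$regions[[i]]
    if (i > 1) off <- off + pad
    if (r$refName == refName && coord >= r$start && coord < r$end) {
      within <- if (r$reversed) r$end - 1 - coord else coord - r$start
      return(off + within / bpPerPx)
    }
    off <- off + region_width(r) / bpPerPx
  }
  NA_real_
}

#' Map a pixel offset back to a genomic coordinate
#'
#' Inverse of [bp_to_px()] on region interiors:
#' `px_to_bp(bp_to_px(x)) == x` for every displayed bp. Offsets falling
#' inside inter-region padding return a gap marker.
#'
#' @param offsetPx Pixel offset in `[0, view_width_px(...)]`.
#' @inheritParams bp_to_px
#' @return A list with elements `refName` and `coord`, or a list with
#'   `gap = TRUE` (and `afterRegion`, the index of the preceding region)
#'   when the offset falls between regions.
#' @export
px_to_bp <- function(offsetPx, displayed, bpPerPx) {
  stopifnot(bpPerPx > 0)
  if (offsetPx < 0 || offsetPx > view_width_px(displayed, bpPerPx))
    stop("pixel offset ", offsetPx, " outside the view")
  off <- 0
  pad <- displayed$interRegionPadding
  for (i in seq_along(displayed$regions)) {
    r <- displayed$regions[[i]]
    if (i > 1) {
      if (offsetPx < off + pad - 1e-9)
        return(list(gap = TRUE, afterRegion = i - 1L))
      off <- off + pad
    }
    w <- region_width(r) / bpPerPx
    if (offsetPx < off + w - 1e-9 ||
        (i == length(displayed$regions) && offsetPx <= off + w + 1e-9)) {
      within <- floor((offsetPx - off) * bpPerPx + 1e-6)
      within <- min(within, region_width(r) - 1)
      coord <- if (r$reversed) r$end - 1 - within else r$start + within
      return(list(refName = r$refName, coord = coord))
    }
    off <- off + w
  }
  list(gap = TRUE, afterRegion = length(displayed$regions))
}
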