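# -- Feature tables ------------------------------------------------------

flatten_info <- function(info) {
  out <- list()
  for (k in names(info)) {
    v <- info[[k]]
    if (is.list(v) || length(v) > 1) next
    out[[paste0("info.", k)]] <- if (isTRUE(v)) "TRUE" else as.character(v)
  }
  out
}

#' Summarize features, variants or SV events as a table
#'
#' The generic table behind the Tabular View and the SV Inspector's list
#' panel. Canonical columns are `id`, `refName`, `start`, `end`, `type`,
#' `name`, plus kind-specific ones (`mateRef`/`matePos` for SV events;
#' `ref`/`alt`/`qual`/`filter` for variants); INFO keys are flattened as
#' `info.KEY`. Display coordinates are 1-based inclusive — internal
#' 0-based coordinates are converted at this single point.
#'
#' @param items Homogeneous list of [feature()]s, [variant_feature()]s
#'   or `SVEvent`s.
#' @return A data frame of class `c("FeatureTable", "data.frame")`.
#' @export
to_table <- function(items) {
  if (!length(items)) {
    tab <- data.frame(id = character(), refName = character(),
                      start = numeric(), end = numeric(),
                      type = character(), name = character(),
                      stringsAsFactors = FALSE)
    class(tab) <- c("FeatureTable", "data.frame")
    return(tab)
  }
  kinds <- unique(vapply(items, function(x) class(x)[1], ""))
  if (length(kinds) > 1)
    stop("to_table needs a homogeneous item list, got: ",
         paste(kinds, collapse = ", "))
  rows <- lapply(items, function(x) {
    base <- if (inherits(x, "SVEvent")) {
      c(list(id = x$id, refName = x$end1$refName, start = x$end1$pos + 1,
             end = x$end1$pos + 1,
             mateRef = if (is.null(x$end2)) NA_character_
                       else x$end2$refName,
             matePos = if (is.null(x$end2)) NA_real_ else x$end2$pos + 1,
             type = x$kind, name = x$id),
        flatten_info(x$info))
    } else if (inherits(x, "VariantFeature")) {
      c(list(id = x$uniqueId, refName = x$refName, start = x$start + 1,
             end = x$end, type = if (!is.null(x$info$SVTYPE))
               as.character(x$info$SVTYPE) else "variant",
             name = x$uniqueId, ref = x$ref,
             alt = paste(x$alts, collapse = ","),
             qual = x$qual, filter = x$filter),
        flatten_info(x$info))
    } else {
      list(id = x$uniqueId, refName = x$refName, start = x$start + 1,
           end = x$end, type = x$type,
           name = if (is.null(x$name)) NA_character_ else x$name)
    }
    base
  })
  cols <- unique(unlist(lapply(rows, names)))
  tab <- as.data.frame(
    stats::setNames(lapply(cols, function(cl) {
      vals <- lapply(rows, function(r) if (is.null(r[[cl]])) NA else r[[cl]])
      unlist(vals)
    }), cols),
    stringsAsFactors = FALSE, check.names = FALSE)
  class(tab) <- c("FeatureTable", "data.frame")
  tab
}

#' Sort a feature table by one column
#'
#' Stable; numeric columns sort numerically, text lexicographically;
#' missing values go last in either direction.
#'
#' @param table A data frame (e.g. from [to_table()]).
#' @param column Column name.
#' @param descending Sort order.
#' @return The sorted table.
#' @export
sort_table <- function(table, column, descending = FALSE) {
  if (!column %in% names(table))
    stop("unknown column '", column, "'")
  x <- table[[column]]
  miss <- is.na(x)
  o <- if (is.numeric(x)) order(x[!miss], decreasing = descending)
       else order(x[!miss], decreasing = descending, method = "radix")
  idx <- c(which(!miss)[o], which(miss))
  table[idx, , drop = FALSE]
}

#' Export a table as TSV or CSV
#'
#' @param table A data frame.
#' @param path Output path; `.csv` selects comma separation.
#' @return `path`, invisibly.
#' @export
write_table_file <- function(table, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
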