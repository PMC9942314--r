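#' Genomic intervals in BED convention
#'
#' All coordinates inside the package are 0-based half-open (`[start, end)`),
#' the BED convention. Conversion to 1-based coordinates happens only at the
#' VCF boundary and when talking to Bioconductor range classes.
#'
#' @param contig character vector of sequence names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end`.
#' @param label optional character vector of interval names.
#' @return a `genomic_intervals` data frame with columns `contig`, `start`,
#'   `end`, `label`.
#' @examples
#' genomic_intervals("chrA", 0, 100, "locus1")
#' @export
genomic_intervals <- function(contig = character(), start = integer(),
                              end = integer(), label = NA_character_) {
  x <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    label = rep_len(as.character(label), length(contig)),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

validate_intervals <- function(x, what = "interval") {
  if (nrow(x) == 0L) return(invisible(x))
  bad <- !nzchar(x$contig) | is.na(x$contig)
  if (any(bad)) {
    stop_validation("invalid ", what, ": empty contig name in row ",
                    paste(which(bad), collapse = ", "))
  }
  bad <- is.na(x$start) | is.na(x$end) | x$start < 0L | x$start >= x$end
  if (any(bad)) {
    stop_validation("invalid ", what, ": need 0 <= start < end in row ",
                    paste(which(bad), collapse = ", "))
  }
  invisible(x)
}

as_genomic_intervals <- function(x) {
  if (inherits(x, "genomic_intervals")) return(x)
  genomic_intervals(x$contig, x$start, x$end, x$label %||% NA_character_)
}

#' @export
print.genomic_intervals <- function(x, ...) {
  cat(sprintf("genomic_intervals: %d interval(s), %d base(s) covered\n",
              nrow(x), interval_bases(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Total number of bases covered by a set of intervals
#'
#' Overlapping intervals are collapsed first, so each base is counted once.
#' @param x a `genomic_intervals` object.
#' @return integer count of distinct covered bases.
#' @export
interval_bases <- function(x) {
  if (nrow(x) == 0L) return(0L)
  n <- normalize_intervals(x)
  sum(n$end - n$start)
}

#' Sort and merge intervals
#'
#' Sorts by (contig, start) and merges overlapping or abutting intervals on
#' the same contig. Abutting intervals are merged because masking semantics
#' are unaffected by the split point. The operation is idempotent and
#' conserves the set of covered bases.
#'
#' @param x a `genomic_intervals` object (or data frame with the same
#'   columns).
#' @return a normalized `genomic_intervals` object. Merged intervals keep the
#'   label of their first (leftmost) constituent.
#' @examples
#' normalize_intervals(genomic_intervals(c("chrA", "chrA"), c(5, 8), c(10, 20)))
#' @export
normalize_intervals <- function(x) {
  x <- as_genomic_intervals(x)
  if (nrow(x) <= 1L) {
    rownames(x) <- NULL
    return(x)
  }
  o <- order(x$contig, x$start, x$end, method = "radix")
  x <- x[o, , drop = FALSE]
  keep_contig <- character(0)
  keep_start <- integer(0)
  keep_end <- integer(0)
  keep_label <- character(0)
  cur_contig <- x$contig[1L]
  cur_start <- x$start[1L]
  cur_end <- x$end[1L]
  cur_label <- x$label[1L]
  for (i in seq_len(nrow(x))[-1L]) {
    if (x$contig[i] == cur_contig && x$start[i] <= cur_end) {
      cur_end <- max(cur_end, x$end[i])
    } else {
      keep_contig <- c(keep_contig, cur_contig)
      keep_start <- c(keep_start, cur_start)
      keep_end <- c(keep_end, cur_end)
      keep_label <- c(keep_label, cur_label)
      cur_contig <- x$contig[i]
      cur_start <- x$start[i]
      cur_end <- x$end[i]
      cur_label <- x$label[i]
    }
  }
  genomic_intervals(c(keep_contig, cur_contig), c(keep_start, cur_start),
                    c(keep_end, cur_end), c(keep_label, cur_label))
}

#' Convert intervals to a GRanges (1-based, closed)
#' @keywords internal
intervals_to_granges <- function(x, seqlengths = NULL) {
  if (nrow(x) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (is.null(seqlengths)) {
    GenomicRanges::GRanges(
      seqnames = x$contig,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
    )
  } else {
    GenomicRanges::GRanges(
      seqnames = factor(x$contig, levels = names(seqlengths)),
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      seqlengths = seqlengths
    )
  }
}

#' Does each query interval overlap any subject interval?
#'
#' Overlap means at least one shared base under the half-open convention.
#' @param query,subject `genomic_intervals` objects.
#' @return logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, subject) {
  query <- as_genomic_intervals(query)
  subject <- as_genomic_intervals(subject)
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$contig == query$contig[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

#' Read a BED file as genomic intervals
#'
#' Accepts 3- or 4-column BED (tab-separated, 0-based half-open). Lines
#' starting with `#` and empty lines are ignored. Malformed lines raise a
#' parse error naming the offending line number.
#'
#' @param path path to a BED file.
#' @return a `genomic_intervals` object.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_validation("BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) return(genomic_intervals())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop_validation("malformed BED line ", keep[which(nf < 3L)[1L]], " in ",
                    path, ": fewer than 3 tab-separated fields")
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- keep[which(is.na(start) | is.na(end))[1L]]
    stop_validation("malformed BED line ", bad, " in ", path,
                    ": non-numeric start/end")
  }
  label <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))], ""),
                  NA_character_)
  label[nf < 4L] <- NA_character_
  tryCatch(
    genomic_intervals(vapply(parts, `[[`, "", 1L), start, end, label),
    refix_validation_error = function(e) {
      stop_validation("invalid interval in ", path, ": ", conditionMessage(e))
    }
  )
}

#' Write genomic intervals as BED
#'
#' @param x a `genomic_intervals` object.
#' @param path output path. Labelled intervals produce 4-column BED,
#'   unlabelled 3-column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_genomic_intervals(x)
  if (nrow(x) && any(!is.na(x$label))) {
    lab <- ifelse(is.na(x$label), ".", x$label)
    lines <- sprintf("%s\t%d\t%d\t%s", x$contig, x$start, x$end, lab)
  } else {
    lines <- sprintf("%s\t%d\t%d", x$contig, x$start, x$end)
  }
  writeLines(lines, path)
  invisible(path)
}

# Pad every interval by `pad` on both sides, clipped to [0, bound].
pad_intervals <- function(x, pad, seqlengths = NULL) {
  x <- as_genomic_intervals(x)
  if (nrow(x) == 0L) return(x)
  s <- pmax(0L, x$start - as.integer(pad))
  e <- x$end + as.integer(pad)
  if (!is.null(seqlengths)) {
    lim <- seqlengths[x$contig]
    e <- pmin(e, as.integer(lim))
  }
  genomic_intervals(x$contig, s, e, x$label)
}
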