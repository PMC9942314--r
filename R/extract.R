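#' Select alignment records overlapping the homolog intervals
#'
#' Returns every record with at least one base of reference-span overlap
#' with the union of the regions' homolog intervals, excluding records with
#' any of the flag bits in [exclusion_mask()] (unmapped, mate unmapped,
#' secondary, supplementary -- mask 2316). Duplicate-flagged and QC-fail
#' records are retained. Each record is reported once even when it overlaps
#' several intervals.
#'
#' @param bam indexed, coordinate-sorted BAM.
#' @param regions an [error_region_set()] (or plain [genomic_intervals()]
#'   used directly as the read-collection intervals).
#' @return an alignment data frame (see [read_alignments()]).
#' @export
select_alignments <- function(bam, regions) {
  which <- if (inherits(regions, "error_region_set")) homolog_union(regions)
           else normalize_intervals(as_genomic_intervals(regions))
  if (nrow(which) == 0L) return(empty_alignments())
  out <- read_alignments(bam, which = which, apply_mask = TRUE)
  o <- order(out$rname, out$pos, out$qname, out$flag, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

restore_orientation <- function(seq, qual, flag) {
  rev <- flag_test(flag, FLAG_REVERSE)
  if (any(rev)) {
    seq[rev] <- revcomp_chr(seq[rev])
    qual[rev] <- vapply(qual[rev], function(q) {
      paste(rev(strsplit(q, "")[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  list(seq = seq, qual = qual)
}

#' Reconstitute complete, uniquely named read pairs
#'
#' Groups selected records by read name and emits one pair per name for
#' which both mates are available. When exactly one mate was selected, mate
#' rescue fetches the missing mate at its recorded mate position (within
#' `rescue_window` bases) from the source BAM, subject to the same exclusion
#' mask. Names with more than two surviving records, or with two records on
#' the same mate side, are dropped entirely; unrescued singletons are
#' dropped too (the pipeline is strictly paired-end). Sequences are
#' reverse-complemented back to original read orientation where the stored
#' alignment was on the reverse strand.
#'
#' @param records output of [select_alignments()].
#' @param bam the source BAM (for mate rescue).
#' @param rescue_window how far around the recorded mate position to search
#'   (bp).
#' @return a list with `pairs` (data frame `name, seq1, qual1, seq2, qual2,
#'   rg`) and `stats` (counts: selected, pairs, rescued, dropped_singleton,
#'   dropped_multi).
#' @export
pair_and_dedup <- function(records, bam, rescue_window = 1000L) {
  stats <- list(n_selected = nrow(records), n_pairs = 0L, n_rescued = 0L,
                n_dropped_singleton = 0L, n_dropped_multi = 0L)
  if (nrow(records) == 0L) {
    return(list(pairs = empty_pairs(), stats = stats))
  }
  cnt <- table(records$qname)
  multi <- names(cnt)[cnt > 2L]
  stats$n_dropped_multi <- length(multi)
  records <- records[!records$qname %in% multi, , drop = FALSE]

  first <- flag_test(records$flag, FLAG_FIRST)
  second <- flag_test(records$flag, FLAG_SECOND)
  ok <- xor(first, second) & flag_test(records$flag, FLAG_PAIRED)
  records <- records[ok, , drop = FALSE]
  first <- flag_test(records$flag, FLAG_FIRST)

  # a name seen twice on the same mate side is irreconcilable
  key <- paste(records$qname, first)
  dup_names <- unique(records$qname[key %in% key[duplicated(key)]])
  stats$n_dropped_multi <- stats$n_dropped_multi + length(dup_names)
  records <- records[!records$qname %in% dup_names, , drop = FALSE]

  cnt <- table(records$qname)
  singles <- names(cnt)[cnt == 1L]
  if (length(singles)) {
    sing <- records[records$qname %in% singles, , drop = FALSE]
    rescued <- rescue_mates(sing, bam, rescue_window)
    stats$n_rescued <- nrow(rescued)
    stats$n_dropped_singleton <- length(singles) - nrow(rescued)
    keep <- records$qname %in% names(cnt)[cnt == 2L] |
      records$qname %in% rescued$qname
    records <- rbind(records[keep, , drop = FALSE], rescued)
  }

  if (nrow(records) == 0L) {
    return(list(pairs = empty_pairs(), stats = stats))
  }
  first <- flag_test(records$flag, FLAG_FIRST)
  r1 <- records[first, , drop = FALSE]
  r2 <- records[!first, , drop = FALSE]
  m <- match(r1$qname, r2$qname)
  pairedup <- !is.na(m)
  r1 <- r1[pairedup, , drop = FALSE]
  r2 <- r2[m[pairedup], , drop = FALSE]
  o1 <- restore_orientation(r1$seq, r1$qual, r1$flag)
  o2 <- restore_orientation(r2$seq, r2$qual, r2$flag)
  pairs <- data.frame(name = r1$qname, seq1 = o1$seq, qual1 = o1$qual,
                      seq2 = o2$seq, qual2 = o2$qual,
                      rg = ifelse(is.na(r1$rg), r2$rg, r1$rg),
                      stringsAsFactors = FALSE)
  o <- order(pairs$name, method = "radix")
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  stats$n_pairs <- nrow(pairs)
  list(pairs = pairs, stats = stats)
}

empty_pairs <- function() {
  data.frame(name = character(0), seq1 = character(0), qual1 = character(0),
             seq2 = character(0), qual2 = character(0), rg = character(0),
             stringsAsFactors = FALSE)
}

# Fetch missing mates near their recorded positions.
rescue_mates <- function(singletons, bam, rescue_window) {
  if (nrow(singletons) == 0L) return(empty_alignments())
  loc <- data.frame(contig = singletons$mrnm, pos = singletons$mpos,
                    qname = singletons$qname,
                    want_first = !flag_test(singletons$flag, FLAG_FIRST),
                    stringsAsFactors = FALSE)
  loc <- loc[!is.na(loc$contig) & loc$contig != "*" & !is.na(loc$pos), ,
             drop = FALSE]
  if (nrow(loc) == 0L) return(empty_alignments())
  win <- genomic_intervals(loc$contig, pmax(0L, loc$pos - as.integer(rescue_window)),
                           loc$pos + as.integer(rescue_window) + 1L)
  fetched <- read_alignments(bam, which = normalize_intervals(win),
                             apply_mask = TRUE)
  if (nrow(fetched) == 0L) return(empty_alignments())
  want_first <- loc$want_first[match(fetched$qname, loc$qname)]
  hit <- !is.na(want_first) &
    flag_test(fetched$flag, FLAG_FIRST) == want_first &
    xor(flag_test(fetched$flag, FLAG_FIRST), flag_test(fetched$flag, FLAG_SECOND))
  fetched <- fetched[hit, , drop = FALSE]
  fetched[!duplicated(fetched$qname), , drop = FALSE]
}

#' Write read pairs as two FASTQ streams
#'
#' Mate 1 records go to `fq1`, mate 2 to `fq2`, in the same order, names
#' without `/1` `/2` suffixes, qualities Phred+33.
#'
#' @param pairs read-pair data frame.
#' @param fq1,fq2 output paths.
#' @return `c(fq1, fq2)`, invisibly.
#' @export
pairs_to_fastq <- function(pairs, fq1, fq2) {
  fq_lines <- function(name, seq, qual) {
    if (length(name) == 0L) return(character(0))
    as.vector(rbind(paste0("@", name), seq, "+", qual))
  }
  writeLines(fq_lines(pairs$name, pairs$seq1, pairs$qual1), fq1)
  writeLines(fq_lines(pairs$name, pairs$seq2, pairs$qual2), fq2)
  invisible(c(fq1, fq2))
}

#' Read two FASTQ streams back into a pair table
#'
#' @param fq1,fq2 FASTQ paths (plain text, Phred+33); records must be in
#'   matching order.
#' @return a read-pair data frame.
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  parse_fq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) {
      stop_validation("truncated FASTQ: ", path)
    }
    i <- seq(1L, length(lines), by = 4L)
    data.frame(name = sub("^@", "", sub("\\s.*$", "", lines[i])),
               seq = lines[i + 1L], qual = lines[i + 3L],
               stringsAsFactors = FALSE)
  }
  a <- parse_fq(fq1)
  b <- parse_fq(fq2)
  if (nrow(a) != nrow(b) || !all(a$name == b$name)) {
    stop_validation("FASTQ mates out of sync between ", fq1, " and ", fq2)
  }
  data.frame(name = a$name, seq1 = a$seq, qual1 = a$qual, seq2 = b$seq,
             qual2 = b$qual, rg = NA_character_, stringsAsFactors = FALSE)
}

#' Extract the affected read pairs from a BAM
#'
#' Convenience wrapper: [select_alignments()] then [pair_and_dedup()].
#'
#' @inheritParams select_alignments
#' @inheritParams pair_and_dedup
#' @return a list with `pairs` and `stats` (see [pair_and_dedup()]).
#' @export
extract_reads <- function(bam, regions, rescue_window = 1000L) {
  records <- select_alignments(bam, regions)
  pair_and_dedup(records, bam, rescue_window)
}
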