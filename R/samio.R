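# SAM flag bits and the extraction exclusion mask.
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_QCFAIL <- 0x200L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' The record-exclusion flag mask used throughout the pipeline
#'
#' Records with any of: read unmapped (0x4), mate unmapped (0x8), secondary
#' (0x100) or supplementary (0x800) are excluded from extraction, from the
#' diagnostics, and from the pileup genotyper -- the combined mask is 2316.
#' Duplicate-flagged (0x400) and QC-fail (0x200) records are deliberately
#' retained, matching this mask.
#'
#' @return integer scalar 2316.
#' @export
exclusion_mask <- function() {
  FLAG_UNMAPPED + FLAG_MATE_UNMAPPED + FLAG_SECONDARY + FLAG_SUPPLEMENTARY
}

flag_test <- function(flag, bit) bitwAnd(as.integer(flag), as.integer(bit)) != 0L

# ScanBamParam flag filter equivalent to the exclusion mask.
exclusion_scan_flag <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE)
}

#' Reference-span width of CIGAR strings
#' @param cigar character vector of CIGAR strings (`"*"` allowed -> NA).
#' @return integer vector of widths along the reference.
#' @keywords internal
cigar_ref_width <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    out[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  }
  out
}

# An empty alignment data frame; `pos` is 0-based internally, -1 = unmapped.
empty_alignments <- function() {
  data.frame(
    qname = character(0), flag = integer(0), rname = character(0),
    pos = integer(0), mapq = integer(0), cigar = character(0),
    mrnm = character(0), mpos = integer(0), isize = integer(0),
    seq = character(0), qual = character(0), rg = character(0),
    stringsAsFactors = FALSE
  )
}

#' Read alignment records from an indexed BAM
#'
#' Thin wrapper around [Rsamtools::scanBam()] returning a plain data frame
#' with 0-based positions, suitable for the extraction and diagnostics
#' layers. Records are deduplicated when several query intervals return the
#' same record.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param which optional [genomic_intervals()] restricting the query; `NULL`
#'   reads the whole file.
#' @param apply_mask if `TRUE` (default) records matching [exclusion_mask()]
#'   are excluded by the BAM reader.
#' @return a data frame with columns `qname, flag, rname, pos, mapq, cigar,
#'   mrnm, mpos, isize, seq, qual, rg`.
#' @export
read_alignments <- function(bam, which = NULL, apply_mask = TRUE) {
  check_bam_index(bam)
  flag <- if (apply_mask) exclusion_scan_flag() else Rsamtools::scanBamFlag()
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos",
            "isize", "seq", "qual")
  if (is.null(which) || nrow(which) == 0L) {
    param <- Rsamtools::ScanBamParam(what = what, tag = "RG", flag = flag)
    chunks <- Rsamtools::scanBam(bam, param = param)
  } else {
    hdr_len <- bam_seqlengths(bam)
    known <- which$contig %in% names(hdr_len)
    if (any(!known)) {
      warning("skipping region(s) on contig(s) absent from BAM header: ",
              paste(unique(which$contig[!known]), collapse = ", "))
      which <- which[known, , drop = FALSE]
      if (nrow(which) == 0L) return(empty_alignments())
    }
    which <- as_genomic_intervals(which)
    which$end <- pmin(which$end, as.integer(hdr_len[which$contig]))
    gr <- intervals_to_granges(which, seqlengths = hdr_len)
    param <- Rsamtools::ScanBamParam(what = what, tag = "RG", flag = flag,
                                     which = gr)
    chunks <- Rsamtools::scanBam(bam, param = param)
  }
  parts <- lapply(chunks, function(ch) {
    n <- length(ch$qname)
    if (n == 0L) return(empty_alignments())
    rg <- ch$tag$RG %||% rep(NA_character_, n)
    data.frame(
      qname = ch$qname, flag = as.integer(ch$flag),
      rname = as.character(ch$rname), pos = as.integer(ch$pos) - 1L,
      mapq = as.integer(ch$mapq),
      cigar = as.character(ch$cigar),
      mrnm = as.character(ch$mrnm), mpos = as.integer(ch$mpos) - 1L,
      isize = as.integer(ch$isize),
      seq = as.character(ch$seq), qual = as.character(ch$qual),
      rg = as.character(rg), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (nrow(out) > 1L) {
    key <- paste(out$qname, out$flag, out$rname, out$pos, sep = "\r")
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

check_bam_index <- function(bam) {
  if (!file.exists(bam)) stop_validation("alignment file not found: ", bam)
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(idx))) {
    stop_validation("alignment file is not indexed: ", bam,
                    " -- index it first (Rsamtools::indexBam or samtools index)")
  }
  invisible(TRUE)
}

bam_seqlengths <- function(bam) {
  h <- Rsamtools::scanBamHeader(bam)[[1L]]
  h$targets
}

bam_header_lines <- function(bam) {
  h <- Rsamtools::scanBamHeader(bam)[[1L]]$text
  vapply(seq_along(h), function(i) {
    paste(c(names(h)[i], h[[i]]), collapse = "\t")
  }, character(1))
}

# @SQ (+@HD) header lines for a reference.
sam_header_for_ref <- function(ref, extra = character()) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref), Biostrings::width(ref)),
    extra)
}

#' Write alignment records to a sorted, indexed BAM
#'
#' Records are emitted as SAM text and converted with [Rsamtools::asBam()],
#' which coordinate-sorts and indexes the result.
#'
#' @param aln alignment data frame (see [read_alignments()]; `pos` 0-based,
#'   `-1`/`NA` meaning unmapped).
#' @param header_lines character vector of SAM header lines (`@HD`, `@SQ`,
#'   `@RG`, ...).
#' @param bam_out destination BAM path (ending in `.bam`).
#' @return the BAM path, invisibly.
#' @export
write_bam <- function(aln, header_lines, bam_out) {
  stopifnot(grepl("\\.bam$", bam_out))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header_lines, alignments_to_sam(aln)), sam)
  dest <- sub("\\.bam$", "", bam_out)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  invisible(bam_out)
}

alignments_to_sam <- function(aln) {
  if (nrow(aln) == 0L) return(character(0))
  unmapped <- is.na(aln$pos) | aln$pos < 0L
  rname <- ifelse(unmapped & (is.na(aln$rname) | aln$rname == "*"), "*", aln$rname)
  pos1 <- ifelse(is.na(aln$pos) | aln$pos < 0L, 0L, aln$pos + 1L)
  mpos1 <- ifelse(is.na(aln$mpos) | aln$mpos < 0L, 0L, aln$mpos + 1L)
  mrnm <- ifelse(is.na(aln$mrnm) | aln$mrnm == "", "*", aln$mrnm)
  # use '=' shorthand where mate contig equals contig
  mrnm <- ifelse(mrnm != "*" & mrnm == rname, "=", mrnm)
  cigar <- ifelse(is.na(aln$cigar) | aln$cigar == "", "*", aln$cigar)
  isize <- ifelse(is.na(aln$isize), 0L, aln$isize)
  tags <- character(nrow(aln))
  has_rg <- !is.na(aln$rg) & nzchar(aln$rg)
  tags[has_rg] <- paste0("\tRG:Z:", aln$rg[has_rg])
  if (!is.null(aln$nm)) {
    has_nm <- !is.na(aln$nm)
    tags[has_nm] <- paste0(tags[has_nm], "\tNM:i:", aln$nm[has_nm])
  }
  paste0(aln$qname, "\t", aln$flag, "\t", rname, "\t", pos1, "\t", aln$mapq,
         "\t", cigar, "\t", mrnm, "\t", mpos1, "\t", isize, "\t", aln$seq,
         "\t", aln$qual, tags)
}

# Convert a BAM to SAM text lines (header + records), preserving all tags.
bam_to_sam_lines <- function(bam) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  Rsamtools::asSam(bam, sub("\\.sam$", "", sam), overwrite = TRUE)
  readLines(sam)
}

sam_is_header <- function(lines) startsWith(lines, "@")
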